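#' Three-channel fluorescence field
#'
#' Container for one microscope field as three co-registered single-channel
#' planes: all cell nuclei (DAPI), Ki67 signal, and cytokeratin (CK).
#' Planes are numeric matrices of identical dimensions with intensities on
#' \[0, 1\]; values outside that range are clipped. Pixel coordinates
#' throughout the package are 1-based (row, col).
#'
#' @param nuclei,ki67,ck numeric matrices of identical dimensions, intensities
#'   on \[0, 1\] (out-of-range values are clipped).
#' @return An object of class `multichannel_field`: a list with elements
#'   `nuclei`, `ki67`, `ck`.
#' @examples
#' f <- multichannel_field(matrix(0, 64, 64), matrix(0, 64, 64), matrix(0, 64, 64))
#' dim(f$nuclei)
#' @export
multichannel_field <- function(nuclei, ki67, ck) {
  .check_matrix(nuclei, "nuclei")
  .check_matrix(ki67, "ki67")
  .check_matrix(ck, "ck")
  if (!all(dim(nuclei) == dim(ki67)) || !all(dim(nuclei) == dim(ck)))
    stop(sprintf(
      "all planes must share one shape; got nuclei %dx%d, ki67 %dx%d, ck %dx%d",
      nrow(nuclei), ncol(nuclei), nrow(ki67), ncol(ki67), nrow(ck), ncol(ck)),
      call. = FALSE)
  structure(
    list(nuclei = .clip01(nuclei), ki67 = .clip01(ki67), ck = .clip01(ck)),
    class = "multichannel_field"
  )
}

#' @export
print.multichannel_field <- function(x, ...) {
  cat(sprintf("<multichannel_field> %d x %d px (nuclei, ki67, ck planes on [0,1])\n",
              nrow(x$nuclei), ncol(x$nuclei)))
  invisible(x)
}

#' @export
plot.multichannel_field <- function(x, ...) {
  ## display convention: nuclei blue, Ki67 red, CK yellow (red+green)
  rgb <- array(0, c(nrow(x$nuclei), ncol(x$nuclei), 3L))
  rgb[, , 1L] <- .clip01(x$ki67 + x$ck)
  rgb[, , 2L] <- x$ck
  rgb[, , 3L] <- x$nuclei
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(x$nuclei) / nrow(x$nuclei))
  graphics::rasterImage(rgb, 0, 0, 1, 1)
  invisible(x)
}
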