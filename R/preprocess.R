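#' Median denoising
#'
#' Replaces every pixel by the median of its `kernel_px` x `kernel_px`
#' neighborhood. Image edges are handled by symmetric reflection, so the
#' output has the shape of the input. The filter is exact: it is computed by
#' a vectorized compare--exchange network over the shifted neighborhood
#' planes, which is fast for the small kernels used in practice (the default
#' pipeline kernel is 3).
#'
#' @param plane numeric matrix, intensities on \[0, 1\].
#' @param kernel_px odd positive integer, side length of the square
#'   neighborhood. `1` is the identity.
#' @return Numeric matrix of the same dimensions.
#' @examples
#' x <- matrix(0, 9, 9); x[5, 5] <- 1
#' max(median_denoise(x, 3))  # isolated pixel removed -> 0
#' @export
median_denoise <- function(plane, kernel_px = 3L) {
  .check_matrix(plane, "plane")
  k <- .check_count(kernel_px, "kernel_px", min = 1L)
  if (k %% 2L == 0L)
    stop("'kernel_px' must be odd", call. = FALSE)
  if (k == 1L) return(plane)
  p <- (k - 1L) %/% 2L
  if (p > nrow(plane) || p > ncol(plane))
    stop("'kernel_px' too large for the image", call. = FALSE)
  ri <- c(p:1, seq_len(nrow(plane)), nrow(plane):(nrow(plane) - p + 1L))
  ci <- c(p:1, seq_len(ncol(plane)), ncol(plane):(ncol(plane) - p + 1L))
  padded <- plane[ri, ci, drop = FALSE]
  n <- k * k
  planes <- vector("list", n)
  i <- 0L
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      i <- i + 1L
      planes[[i]] <- padded[dr:(dr + nrow(plane) - 1L),
                            dc:(dc + ncol(plane) - 1L), drop = FALSE]
    }
  }
  ## odd-even transposition sort across the n neighborhood planes
  for (pass in seq_len(n)) {
    for (j in seq.int(1L + pass %% 2L, n - 1L, by = 2L)) {
      lo <- pmin(planes[[j]], planes[[j + 1L]])
      hi <- pmax(planes[[j]], planes[[j + 1L]])
      planes[[j]] <- lo
      planes[[j + 1L]] <- hi
    }
  }
  planes[[(n + 1L) %/% 2L]]
}

#' Percentile contrast stretching
#'
#' Linearly rescales intensities so the `low_pct` percentile maps to 0 and
#' the `high_pct` percentile maps to 1, then clips to \[0, 1\]. If the two
#' percentile values coincide (e.g. a constant image) the input is returned
#' unchanged with a warning.
#'
#' @param plane numeric matrix, intensities on \[0, 1\].
#' @param low_pct,high_pct percentiles in \[0, 100\] with
#'   `low_pct < high_pct`. Defaults (1, 99) are robust to hot pixels.
#' @return Numeric matrix of the same dimensions, values on \[0, 1\].
#' @examples
#' x <- matrix(seq(0.1, 0.2, length.out = 25), 5, 5)
#' range(contrast_stretch(x, 0, 100))
#' @export
contrast_stretch <- function(plane, low_pct = 1, high_pct = 99) {
  .check_matrix(plane, "plane")
  lo_p <- .check_number(low_pct, "low_pct", 0, 100)
  hi_p <- .check_number(high_pct, "high_pct", 0, 100)
  if (lo_p >= hi_p)
    stop("'low_pct' must be strictly less than 'high_pct'", call. = FALSE)
  q <- stats::quantile(plane, c(lo_p, hi_p) / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("percentile values coincide (flat image); returning input unchanged")
    return(plane)
  }
  .clip01((plane - q[1]) / (q[2] - q[1]))
}

## denoise + stretch one plane with the pipeline's parameters
.preprocess_plane <- function(plane, config) {
  plane <- median_denoise(plane, config$median_kernel_px)
  contrast_stretch(plane, config$stretch_low_pct, config$stretch_high_pct)
}
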