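## read one grayscale 8/16-bit TIFF or PNG plane as a [0,1] matrix
.read_plane <- function(path) {
  if (!file.exists(path))
    stop(sprintf("unreadable file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '.%s': %s", ext, path), call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop(sprintf("expected a single-channel grayscale image: %s", path),
              call. = FALSE)
  }
  img
}

#' Load a three-channel field from image files
#'
#' Reads either three single-channel files (`nuclei`, `ki67`, `ck`) or one
#' multi-page TIFF `stack` whose page order is declared by `channel_order`.
#' 8- and 16-bit grayscale TIFF and PNG are supported; intensities are
#' scaled to \[0, 1\] by the image bit depth.
#'
#' @param nuclei,ki67,ck paths to single-channel images (all three required
#'   unless `stack` is given).
#' @param stack path to a 3-page grayscale TIFF.
#' @param channel_order page order of `stack`, a permutation of
#'   `c("nuclei", "ki67", "ck")`.
#' @return A [multichannel_field()].
#' @export
load_field <- function(nuclei = NULL, ki67 = NULL, ck = NULL, stack = NULL,
                       channel_order = c("nuclei", "ki67", "ck")) {
  if (!is.null(stack)) {
    if (!file.exists(stack))
      stop(sprintf("unreadable file: %s", stack), call. = FALSE)
    if (!is.character(channel_order) || length(channel_order) != 3L ||
        !setequal(channel_order, c("nuclei", "ki67", "ck")))
      stop("'channel_order' must be a permutation of c(\"nuclei\", \"ki67\", \"ck\")",
           call. = FALSE)
    pages <- tiff::readTIFF(stack, all = TRUE)
    if (length(pages) != 3L)
      stop(sprintf("expected a 3-page stack, got %d page(s): %s",
                   length(pages), stack), call. = FALSE)
    names(pages) <- channel_order
    return(multichannel_field(pages[["nuclei"]], pages[["ki67"]], pages[["ck"]]))
  }
  if (is.null(nuclei) || is.null(ki67) || is.null(ck))
    stop("provide either 'stack' or all of 'nuclei', 'ki67', 'ck'", call. = FALSE)
  planes <- lapply(c(nuclei = nuclei, ki67 = ki67, ck = ck), .read_plane)
  multichannel_field(planes$nuclei, planes$ki67, planes$ck)
}

#' Write a synthetic scene to files
#'
#' Writes the three planes as 16-bit grayscale TIFFs (`nuclei.tif`,
#' `ki67.tif`, `ck.tif`), the ground-truth nucleus table as `truth.csv`
#' (columns id, row, col, radius, is_tumor, is_ki67_positive; 1-based pixel
#' coordinates) and the true label image as 16-bit `truth_labels.tif`.
#'
#' @param scene a `ki67_scene` from [generate_scene()] or
#'   [render_noise_free()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "ki67_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("nuclei", "ki67", "ck"))
    tiff::writeTIFF(scene$field[[nm]], file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L)
  utils::write.csv(scene$truth$nuclei, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  write_labels(scene$truth$label_map_truth, file.path(dir, "truth_labels.tif"))
  invisible(dir)
}

#' Read/write a label map as a 16-bit TIFF
#'
#' Labels are stored as 16-bit gray levels (label / 65535), supporting up to
#' 65535 objects; `read_labels()` restores the integer label matrix exactly.
#'
#' @param labels integer label matrix.
#' @param path file path.
#' @return `read_labels()` returns an integer label matrix;
#'   `write_labels()` returns `path` invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- .check_labels(labels)
  if (max(labels) > 65535L)
    stop("more than 65535 labels cannot be stored in a 16-bit TIFF", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  m <- .read_plane(path)
  out <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  out
}

#' Write counting results to an output directory
#'
#' Writes `result.csv` (field_id, counts, index to 2 decimals, grade),
#' `records.csv` (one row per detected nucleus), `labels.tif` (16-bit label
#' image), `overlay.png` (green = counted nuclei, cyan = counted
#' Ki67-positive nuclei) and `run_log.txt` (config echo, package and R
#' versions, seed) — a machine-readable record of the run.
#'
#' @param fit a `ki67_count` object.
#' @param out_dir output directory (created if missing).
#' @param field_id identifier written to `result.csv`.
#' @return The directory path, invisibly.
#' @export
write_results <- function(fit, out_dir, field_id = "field") {
  stopifnot(inherits(fit, "ki67_count"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- fit$result
  utils::write.csv(data.frame(
    field_id = field_id,
    n_nuclei_in_ck = res$n_nuclei_in_ck,
    n_ki67_pos_in_ck = res$n_ki67_positive_in_ck,
    index_percent = if (is.na(res$index_percent)) NA
                    else round(res$index_percent, 2),
    grade = if (is.na(res$grade)) NA else res$grade
  ), file.path(out_dir, "result.csv"), row.names = FALSE)
  utils::write.csv(fit$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  write_labels(fit$labels, file.path(out_dir, "labels.tif"))
  png::writePNG(overlay_rgb(fit), file.path(out_dir, "overlay.png"))
  log <- c(
    sprintf("ki67count_version = %s",
            as.character(utils::packageVersion("ki67count"))),
    sprintf("r_version = %s", R.version.string),
    vapply(names(fit$config), function(nm)
      sprintf("%s = %s", nm, paste(fit$config[[nm]], collapse = ",")), ""),
    sprintf("n_nuclei_detected = %d", nrow(fit$records)),
    sprintf("otsu_threshold_nuclei = %.6f", fit$thresholds[["nuclei"]]),
    sprintf("otsu_threshold_ki67 = %.6f", fit$thresholds[["ki67"]]),
    sprintf("otsu_threshold_ck = %.6f", fit$thresholds[["ck"]])
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a records.csv written by [write_results()]
#'
#' @param path path to `records.csv`.
#' @return Data frame of nucleus records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path), call. = FALSE)
  utils::read.csv(path)
}
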