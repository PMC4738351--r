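#' 3x3 grid partition of an image
#'
#' Splits the image into 9 rectangular parts by cutting the rows at
#' `floor(H/3)` and `floor(2H/3)` and the columns likewise (0-based
#' half-open intervals), tiling the image exactly with no overlap.
#'
#' @param height_px,width_px image dimensions (>= 3).
#' @return A data frame with 9 rows: `part_row`, `part_col` (1..3) and the
#'   0-based half-open bounds `row0`, `row1`, `col0`, `col1` (the part covers
#'   pixels `[row0, row1) x [col0, col1)`).
#' @examples
#' grid_partition(10, 10)  # part extents (3, 3, 4) per axis
#' @export
grid_partition <- function(height_px, width_px) {
  h <- .check_count(height_px, "height_px", min = 1L)
  w <- .check_count(width_px, "width_px", min = 1L)
  if (h < 3L || w < 3L)
    stop("'height_px' and 'width_px' must be >= 3", call. = FALSE)
  rb <- c(0L, (h %/% 3L), (2L * h) %/% 3L, h)
  cb <- c(0L, (w %/% 3L), (2L * w) %/% 3L, w)
  out <- expand.grid(part_row = 1:3, part_col = 1:3, KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$part_row, out$part_col), ]
  rownames(out) <- NULL
  out$row0 <- rb[out$part_row]; out$row1 <- rb[out$part_row + 1L]
  out$col0 <- cb[out$part_col]; out$col1 <- cb[out$part_col + 1L]
  out
}

#' Grid-assisted reference counting of nuclei
#'
#' Implements the marked manual-counting rule used as a careful reference
#' for the Ki67 index: the field is divided into 9 equal parts and objects
#' on each part's upper/left boundary line are counted with that part while
#' objects on its right/bottom lines are not, so every object is counted
#' exactly once. For point objects (centroids) this is realized by assigning
#' each point to the unique half-open part containing it. Only eligible
#' points (those inside the tumor compartment) are tallied, separately for
#' all nuclei and for Ki67-positive nuclei; the grid index is
#' `100 * total positives / total nuclei` over the eligible points.
#'
#' @param points data frame with numeric columns `row`, `col` (1-based pixel
#'   coordinates, fractions allowed; must lie inside the image), a logical
#'   `eligible` column (e.g. centroid inside the CK mask) and a logical
#'   `ki67_positive` column.
#' @param height_px,width_px image dimensions (>= 3).
#' @return An object of class `ki67_grid_count`: list with 3x3 integer
#'   matrices `part_nuclei` and `part_ki67`, totals `n_nuclei`, `n_ki67`,
#'   and `m_index_percent` (NA when no eligible nuclei).
#' @examples
#' pts <- data.frame(row = c(2, 50, 88), col = c(2, 50, 88),
#'                   eligible = TRUE, ki67_positive = c(TRUE, FALSE, FALSE))
#' grid_count(pts, 90, 90)
#' @export
grid_count <- function(points, height_px, width_px) {
  h <- .check_count(height_px, "height_px", min = 3L)
  w <- .check_count(width_px, "width_px", min = 3L)
  stopifnot(is.data.frame(points),
            all(c("row", "col", "eligible", "ki67_positive") %in% names(points)))
  if (nrow(points) > 0L) {
    r0 <- points$row - 1  # 0-based continuous coordinates
    c0 <- points$col - 1
    if (any(r0 < 0 | r0 >= h | c0 < 0 | c0 >= w))
      stop("point outside image", call. = FALSE)
  }
  part_nuclei <- part_ki67 <- matrix(0L, 3L, 3L)
  el <- points[points$eligible, , drop = FALSE]
  if (nrow(el) > 0L) {
    rb <- c((h %/% 3L), (2L * h) %/% 3L)
    cb <- c((w %/% 3L), (2L * w) %/% 3L)
    pr <- findInterval(el$row - 1, rb) + 1L   # boundary point -> next part
    pc <- findInterval(el$col - 1, cb) + 1L
    for (i in seq_len(nrow(el))) {
      part_nuclei[pr[i], pc[i]] <- part_nuclei[pr[i], pc[i]] + 1L
      if (el$ki67_positive[i])
        part_ki67[pr[i], pc[i]] <- part_ki67[pr[i], pc[i]] + 1L
    }
  }
  n <- sum(part_nuclei); npos <- sum(part_ki67)
  structure(list(
    part_nuclei = part_nuclei, part_ki67 = part_ki67,
    n_nuclei = n, n_ki67 = npos,
    m_index_percent = if (n > 0L) 100 * npos / n else NA_real_
  ), class = "ki67_grid_count")
}

#' @export
print.ki67_grid_count <- function(x, ...) {
  cat(sprintf("<ki67_grid_count> %d eligible nuclei, %d Ki67-positive; grid index: %s\n",
              x$n_nuclei, x$n_ki67,
              if (is.na(x$m_index_percent)) "not computable"
              else sprintf("%.2f%%", x$m_index_percent)))
  cat("  per-part nuclei counts:\n")
  print(x$part_nuclei)
  invisible(x)
}

#' Grid counting applied to a synthetic scene's ground truth
#'
#' Convenience wrapper: counts the true nuclei of a [generate_scene()] /
#' [render_noise_free()] scene with [grid_count()], with eligibility =
#' tumor membership (tumor nuclei lie inside the CK region by construction,
#' stromal centroids outside it).
#'
#' @param scene a `ki67_scene`.
#' @return A `ki67_grid_count`.
#' @export
grid_count_truth <- function(scene) {
  stopifnot(inherits(scene, "ki67_scene"))
  pts <- scene$truth$nuclei
  pts$eligible <- pts$is_tumor
  grid_count(pts[, c("row", "col", "eligible", "is_ki67_positive")] |>
               stats::setNames(c("row", "col", "eligible", "ki67_positive")),
             scene$spec$height_px, scene$spec$width_px)
}

#' Grid counting applied to pipeline-detected nuclei
#'
#' Counts the nucleus records of a [ki67_count()] fit with [grid_count()],
#' with eligibility = tumor-compartment membership (`in_ck`).
#'
#' @param fit a `ki67_count` object.
#' @return A `ki67_grid_count`.
#' @export
grid_count_records <- function(fit) {
  stopifnot(inherits(fit, "ki67_count"))
  pts <- fit$records
  pts$eligible <- pts$in_ck
  grid_count(pts[, c("row", "col", "eligible", "ki67_positive")],
             nrow(fit$labels), ncol(fit$labels))
}
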