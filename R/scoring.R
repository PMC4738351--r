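#' Assign tumor-compartment membership to segmented nuclei
#'
#' Builds one record per labeled nucleus and sets `in_ck` to whether the
#' nucleus centroid's nearest integer pixel lies inside the cytokeratin
#' mask. Membership is decided by the centroid (not area overlap): a whole
#' nucleus is either counted in the tumor compartment or not.
#'
#' @param labels integer label matrix of segmented nuclei.
#' @param ck_mask logical cytokeratin-compartment mask, same shape.
#' @return A data frame with one row per nucleus: `id`, `row`, `col`
#'   (1-based centroid), `area_px`, `in_ck`.
#' @export
assign_compartment <- function(labels, ck_mask) {
  labels <- .check_labels(labels)
  ck_mask <- .check_mask(ck_mask, "ck_mask")
  if (!all(dim(labels) == dim(ck_mask)))
    stop(sprintf("shape mismatch: labels %dx%d vs ck_mask %dx%d",
                 nrow(labels), ncol(labels), nrow(ck_mask), ncol(ck_mask)),
         call. = FALSE)
  rec <- .label_stats(labels)
  rec$in_ck <- if (nrow(rec) > 0L)
    ck_mask[cbind(.nearest_px(rec$row, nrow(ck_mask)),
                  .nearest_px(rec$col, ncol(ck_mask)))]
  else logical(0)
  rec
}

#' Assign Ki67 status to nucleus records
#'
#' For each nucleus, `ki67_overlap_fraction` is the fraction of its pixels
#' that fall inside the Ki67 mask; the nucleus is `ki67_positive` when that
#' fraction is at least `tau`.
#'
#' @param records data frame from [assign_compartment()].
#' @param labels the label matrix the records were derived from.
#' @param ki67_mask logical Ki67 signal mask, same shape as `labels`.
#' @param tau positivity threshold in (0, 1\].
#' @return `records` with columns `ki67_overlap_fraction` and
#'   `ki67_positive` added.
#' @export
assign_ki67 <- function(records, labels, ki67_mask, tau = 0.5) {
  labels <- .check_labels(labels)
  ki67_mask <- .check_mask(ki67_mask, "ki67_mask")
  if (!all(dim(labels) == dim(ki67_mask)))
    stop("shape mismatch between labels and ki67_mask", call. = FALSE)
  tau <- .check_number(tau, "tau", 0, 1)
  if (tau <= 0) stop("'tau' must be in (0, 1]", call. = FALSE)
  if (nrow(records) == 0L) {
    records$ki67_overlap_fraction <- numeric(0)
    records$ki67_positive <- logical(0)
    return(records)
  }
  nz <- labels > 0L
  ov <- rowsum(as.numeric(ki67_mask[nz]), labels[nz])
  frac <- numeric(nrow(records))
  m <- match(records$id, as.integer(rownames(ov)))
  frac[!is.na(m)] <- ov[m[!is.na(m)], 1L]
  records$ki67_overlap_fraction <- frac / records$area_px
  records$ki67_positive <- records$ki67_overlap_fraction >= tau
  records
}

#' Compute the Ki67 index from nucleus records
#'
#' Counts are restricted to records with `in_ck = TRUE`; the index is
#' `100 * positives / nuclei` within the tumor compartment, and the grade
#' follows [ki67_grade()]. With zero in-compartment nuclei the index and
#' grade are not computable (`NA`) but the counts are still reported.
#'
#' @param records data frame with columns `in_ck` and `ki67_positive`.
#' @return An object of class `ki67_result`: list with
#'   `n_nuclei_in_ck`, `n_ki67_positive_in_ck`, `index_percent`, `grade`.
#' @export
compute_index <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("in_ck", "ki67_positive") %in% names(records)))
  n <- sum(records$in_ck)
  npos <- sum(records$in_ck & records$ki67_positive)
  idx <- if (n > 0L) 100 * npos / n else NA_real_
  structure(list(
    n_nuclei_in_ck = as.integer(n),
    n_ki67_positive_in_ck = as.integer(npos),
    index_percent = idx,
    grade = if (is.na(idx)) NA_character_ else ki67_grade(idx)
  ), class = "ki67_result")
}

#' @export
print.ki67_result <- function(x, ...) {
  cat(sprintf("<ki67_result> %d nuclei in tumor compartment, %d Ki67-positive\n",
              x$n_nuclei_in_ck, x$n_ki67_positive_in_ck))
  cat(if (is.na(x$index_percent)) "  Ki67 index: not computable (no in-compartment nuclei)\n"
      else sprintf("  Ki67 index: %.2f%% (grade: %s)\n", x$index_percent, x$grade))
  invisible(x)
}

#' Ki67 grade bands
#'
#' Standard proliferation grade bands: low for an index of at most 10%,
#' moderate above 10% and below 50%, high at 50% or above.
#'
#' @param index_percent Ki67 index in \[0, 100\] (vectorized).
#' @return Character vector: `"low"`, `"moderate"` or `"high"`.
#' @examples
#' ki67_grade(c(10, 10.01, 49.99, 50))
#' @export
ki67_grade <- function(index_percent) {
  if (!is.numeric(index_percent) || any(is.na(index_percent)) ||
      any(index_percent < 0 | index_percent > 100))
    stop("'index_percent' must be in [0, 100]", call. = FALSE)
  ifelse(index_percent <= 10, "low",
         ifelse(index_percent < 50, "moderate", "high"))
}

## tag stage errors with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Count Ki67-positive tumor nuclei in a three-channel field
#'
#' The full automated counting pipeline. Each plane is median-denoised and
#' contrast-stretched, then binarized by Otsu's threshold and cleaned
#' morphologically with holes filled. The cytokeratin (CK) mask defines the
#' tumor compartment (no watershed: it is a compartment, not objects). The
#' nuclei mask is split into individual nuclei by marker-controlled
#' watershed, followed by area-bound correction of over- and
#' under-segmentation. Each nucleus is then attributed to the tumor
#' compartment by its centroid, its Ki67 status is called from its overlap
#' with the cleaned Ki67 mask, and the Ki67 index is the percentage of
#' Ki67-positive nuclei among nuclei inside the CK compartment. The run is
#' deterministic: the same field and configuration give identical results.
#'
#' @param field a [multichannel_field()].
#' @param config a [ki67_config()].
#' @return An object of class `ki67_count`: list with elements `result`
#'   (a `ki67_result`), `records` (per-nucleus data frame), `labels`
#'   (nucleus label matrix), `masks` (list of logical `nuclei`, `ki67`,
#'   `ck` masks), `thresholds` (per-plane Otsu thresholds) and `config`.
#' @seealso [generate_scene()] for synthetic inputs, [write_results()] for
#'   output files.
#' @examples
#' sc <- render_noise_free(scene_spec(256, 256, n_tumor_nuclei = 15,
#'                                    ki67_fraction_tumor = 0.4,
#'                                    n_stromal_nuclei = 3, seed = 7,
#'                                    touch_probability = 0))
#' fit <- ki67_count(sc$field)
#' fit$result
#' @export
ki67_count <- function(field, config = ki67_config()) {
  stopifnot(inherits(field, "multichannel_field"), inherits(config, "ki67_config"))
  pre <- .stage("preprocess", lapply(field[c("nuclei", "ki67", "ck")],
                                     .preprocess_plane, config = config))
  bin <- .stage("otsu", lapply(pre, otsu_binarize))
  masks <- .stage("mask-cleaning", lapply(bin, function(b)
    fill_holes(clean_mask(b$mask, config$open_radius_px, config$close_radius_px))))
  labels <- .stage("watershed",
                   split_touching(masks$nuclei, config$min_marker_distance_px))
  labels <- .stage("postprocess-labels",
                   postprocess_labels(labels, config$min_area_px, config$max_area_px,
                                      config$min_marker_distance_px))
  if (config$border_policy == "drop") {
    edge <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
    labels[labels %in% edge[edge > 0L]] <- 0L
    labels <- .relabel(labels)
  }
  records <- .stage("compartment", assign_compartment(labels, masks$ck))
  records <- .stage("ki67-status",
                    assign_ki67(records, labels, masks$ki67, config$tau))
  result <- .stage("index", compute_index(records))
  structure(list(
    result = result, records = records, labels = labels,
    masks = lapply(masks, identity),
    thresholds = vapply(bin, `[[`, numeric(1), "threshold"),
    config = config
  ), class = "ki67_count")
}

#' @export
print.ki67_count <- function(x, ...) {
  print(x$result)
  invisible(x)
}

#' @export
summary.ki67_count <- function(object, ...) {
  r <- object$records
  cat(sprintf("Ki67 counting summary\n  nuclei detected: %d (in tumor compartment: %d)\n",
              nrow(r), sum(r$in_ck)))
  cat(sprintf("  Ki67-positive in compartment: %d\n", sum(r$in_ck & r$ki67_positive)))
  cat(if (is.na(object$result$index_percent))
        "  Ki67 index: not computable\n"
      else sprintf("  Ki67 index: %.2f%% (grade: %s)\n",
                   object$result$index_percent, object$result$grade))
  cat(sprintf("  Otsu thresholds (nuclei/ki67/ck): %.3f / %.3f / %.3f\n",
              object$thresholds[["nuclei"]], object$thresholds[["ki67"]],
              object$thresholds[["ck"]]))
  if (nrow(r) > 0L)
    cat(sprintf("  nucleus area (px): median %.0f, range %d-%d\n",
                stats::median(r$area_px), min(r$area_px), max(r$area_px)))
  invisible(object)
}

#' Pseudocolor overlay of a counting result
#'
#' Counted nuclei (inside the tumor compartment) are shown in green and
#' counted Ki67-positive nuclei in cyan, over the CK compartment outline in
#' dim yellow; excluded (stromal) nuclei stay gray.
#'
#' @param fit a `ki67_count` object.
#' @return An `height x width x 3` RGB array on \[0, 1\] (invisibly for the
#'   plot method).
#' @export
overlay_rgb <- function(fit) {
  stopifnot(inherits(fit, "ki67_count"))
  h <- nrow(fit$labels); w <- ncol(fit$labels)
  rgb <- array(0, c(h, w, 3L))
  ck <- fit$masks$ck
  rgb[, , 1L][ck] <- 0.25; rgb[, , 2L][ck] <- 0.25   # dim yellow compartment
  all_nuc <- fit$labels > 0L
  rgb[, , 1L][all_nuc] <- 0.5; rgb[, , 2L][all_nuc] <- 0.5; rgb[, , 3L][all_nuc] <- 0.5
  rec <- fit$records
  counted <- rec$id[rec$in_ck]
  pos <- rec$id[rec$in_ck & rec$ki67_positive]
  gm <- matrix(fit$labels %in% counted, h, w)
  cm <- matrix(fit$labels %in% pos, h, w)
  rgb[, , 1L][gm] <- 0; rgb[, , 2L][gm] <- 1; rgb[, , 3L][gm] <- 0   # green
  rgb[, , 2L][cm] <- 1; rgb[, , 3L][cm] <- 1                         # cyan
  rgb
}

#' @export
plot.ki67_count <- function(x, ...) {
  rgb <- overlay_rgb(x)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(x$labels) / nrow(x$labels))
  graphics::rasterImage(rgb, 0, 0, 1, 1)
  invisible(rgb)
}

#' Aggregate per-field Ki67 results to the patient level
#'
#' Either averages the per-field indexes (default; fields where the index is
#' not computable are dropped from the mean) or pools the counts across
#' fields and recomputes one index.
#'
#' @param results list of `ki67_result` (or `ki67_count`) objects, e.g. the
#'   several fields imaged per tissue section.
#' @param method `"mean"` or `"pooled"`.
#' @return A `ki67_result` for the patient. For `"mean"` the counts are the
#'   summed counts (reported for reference) while the index is the mean of
#'   the per-field indexes.
#' @export
aggregate_fields <- function(results, method = c("mean", "pooled")) {
  method <- match.arg(method)
  results <- lapply(results, function(r) if (inherits(r, "ki67_count")) r$result else r)
  stopifnot(length(results) > 0L,
            all(vapply(results, inherits, logical(1), "ki67_result")))
  n <- sum(vapply(results, `[[`, integer(1), "n_nuclei_in_ck"))
  npos <- sum(vapply(results, `[[`, integer(1), "n_ki67_positive_in_ck"))
  idx <- if (method == "pooled") {
    if (n > 0L) 100 * npos / n else NA_real_
  } else {
    per <- vapply(results, `[[`, numeric(1), "index_percent")
    if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  }
  structure(list(
    n_nuclei_in_ck = as.integer(n),
    n_ki67_positive_in_ck = as.integer(npos),
    index_percent = idx,
    grade = if (is.na(idx)) NA_character_ else ki67_grade(idx)
  ), class = "ki67_result")
}
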