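#' Pipeline configuration
#'
#' Validated parameter set for [ki67_count()]. Every parameter is checked
#' against the precondition of the stage that consumes it.
#'
#' @param median_kernel_px odd positive integer, median filter kernel side.
#' @param stretch_low_pct,stretch_high_pct contrast-stretch percentiles,
#'   `0 <= low < high <= 100`.
#' @param open_radius_px,close_radius_px non-negative disk radii for
#'   morphological mask cleaning.
#' @param min_marker_distance_px minimum watershed marker separation (px);
#'   sensible value: the expected nucleus radius.
#' @param min_area_px,max_area_px nucleus area bounds (px) for segmentation
#'   correction, `0 < min < max`.
#' @param tau Ki67 positivity threshold in (0, 1\]: a nucleus is positive when
#'   at least this fraction of its pixels overlaps the Ki67 mask. The default
#'   0.5 (majority coverage) is robust both to segmentation jitter and to
#'   Ki67 signal shared with, or bleeding from, an adjacent positive nucleus.
#' @param border_policy `"keep"` (default) or `"drop"` nuclei touching the
#'   field border.
#' @param channel_order character vector naming the page order of a
#'   multi-page stack; a permutation of `c("nuclei", "ki67", "ck")`.
#' @param aggregation `"mean"` (average per-field indexes) or `"pooled"`
#'   (sum counts across fields) for patient-level aggregation.
#' @param seed integer seed recorded with results for reproducibility.
#' @return An object of class `ki67_config` (a validated named list).
#' @export
ki67_config <- function(median_kernel_px = 3L,
                        stretch_low_pct = 1, stretch_high_pct = 99,
                        open_radius_px = 1L, close_radius_px = 1L,
                        min_marker_distance_px = 12L,
                        min_area_px = 30L, max_area_px = 5000L,
                        tau = 0.5,
                        border_policy = c("keep", "drop"),
                        channel_order = c("nuclei", "ki67", "ck"),
                        aggregation = c("mean", "pooled"),
                        seed = 1L) {
  k <- .check_count(median_kernel_px, "median_kernel_px", min = 1L)
  if (k %% 2L == 0L) stop("'median_kernel_px' must be odd", call. = FALSE)
  lo <- .check_number(stretch_low_pct, "stretch_low_pct", 0, 100)
  hi <- .check_number(stretch_high_pct, "stretch_high_pct", 0, 100)
  if (lo >= hi) stop("'stretch_low_pct' must be < 'stretch_high_pct'", call. = FALSE)
  mn <- .check_count(min_area_px, "min_area_px", min = 1L)
  mx <- .check_count(max_area_px, "max_area_px", min = 1L)
  if (mn >= mx) stop("'min_area_px' must be < 'max_area_px'", call. = FALSE)
  tau <- .check_number(tau, "tau", 0, 1)
  if (tau <= 0) stop("'tau' must be in (0, 1]", call. = FALSE)
  border_policy <- match.arg(border_policy)
  aggregation <- match.arg(aggregation)
  if (!is.character(channel_order) || length(channel_order) != 3L ||
      !setequal(channel_order, c("nuclei", "ki67", "ck")))
    stop("'channel_order' must be a permutation of c(\"nuclei\", \"ki67\", \"ck\")",
         call. = FALSE)
  structure(list(
    median_kernel_px = k,
    stretch_low_pct = lo, stretch_high_pct = hi,
    open_radius_px = .check_count(open_radius_px, "open_radius_px", min = 0L),
    close_radius_px = .check_count(close_radius_px, "close_radius_px", min = 0L),
    min_marker_distance_px = .check_count(min_marker_distance_px,
                                          "min_marker_distance_px", min = 1L),
    min_area_px = mn, max_area_px = mx, tau = tau,
    border_policy = border_policy, channel_order = channel_order,
    aggregation = aggregation,
    seed = .check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "ki67_config")
}

#' @export
print.ki67_config <- function(x, ...) {
  cat("<ki67_config>\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}

#' Read/write a pipeline configuration as a flat key-value file
#'
#' The file format is one `key = value` pair per line (`#` comments and blank
#' lines ignored); `channel_order` is comma-separated. Unknown keys are
#' rejected. `write_config()` then `read_config()` round-trips exactly.
#'
#' @param path file path.
#' @param config a [ki67_config()].
#' @return `read_config()` returns a validated `ki67_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop(sprintf("malformed config line: '%s'", lines[bad][1]), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  allowed <- names(formals(ki67_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate config keys", call. = FALSE)
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- switch(keys[i],
      border_policy = , aggregation = v,
      channel_order = trimws(strsplit(v, ",", fixed = TRUE)[[1L]]),
      as.numeric(v))
  }
  do.call(ki67_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ki67_config"))
  lines <- vapply(names(config), function(nm)
    sprintf("%s = %s", nm, paste(config[[nm]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
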