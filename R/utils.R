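## internal helpers shared across modules

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi), call. = FALSE)
  as.numeric(x)
}

.check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  x
}

.check_mask <- function(x, name = "mask") {
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))) {
    m <- x == 1
    dim(m) <- dim(x)
    return(m)
  }
  stop(sprintf("'%s' must be a logical (binary) matrix", name), call. = FALSE)
}

.check_labels <- function(x, name = "labels") {
  if (!is.matrix(x) || !is.numeric(x) || any(x < 0) || any(x != floor(x)))
    stop(sprintf("'%s' must be a non-negative integer label matrix", name), call. = FALSE)
  x
}

## run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## disk-shaped structuring element of the given radius (EBImage brush)
.disc <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

## nearest integer pixel of a (possibly fractional) 1-based coordinate
.nearest_px <- function(x, n) {
  pmin(pmax(as.integer(floor(x + 0.5)), 1L), as.integer(n))
}

## renumber a label matrix to consecutive labels 1..L (order of first pixel)
.relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) {
    out <- matrix(0L, nrow(labels), ncol(labels))
    return(out)
  }
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  nz <- labels > 0
  out[nz] <- lut[labels[nz]]
  storage.mode(out) <- "integer"
  out
}

## per-label centroids and areas of a label matrix
.label_stats <- function(labels) {
  nz <- which(labels > 0)
  if (length(nz) == 0L)
    return(data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      area_px = integer(0)))
  lab <- labels[nz]
  rr <- ((nz - 1L) %% nrow(labels)) + 1L
  cc <- ((nz - 1L) %/% nrow(labels)) + 1L
  ids <- sort(unique(lab))
  area <- as.integer(tabulate(lab, nbins = max(ids))[ids])
  data.frame(
    id = ids,
    row = as.numeric(rowsum(rr, lab)[, 1L]) / area,
    col = as.numeric(rowsum(cc, lab)[, 1L]) / area,
    area_px = area
  )
}
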