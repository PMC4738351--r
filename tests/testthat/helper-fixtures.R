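## fixture builders and independent oracles shared across test files

## logical matrix with disks at the given centers/radii
disk_mask <- function(h, w, centers, radii) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centers))) {
    rr <- outer(seq_len(h) - centers[i, 1], rep(1, w))
    cc <- outer(rep(1, h), seq_len(w) - centers[i, 2])
    m <- m | (rr^2 + cc^2 <= radii[i]^2)
  }
  m
}

## brute-force median filter (direct neighborhood scan, reflecting edges)
median_oracle <- function(x, k) {
  p <- (k - 1) %/% 2
  ri <- c(p:1, seq_len(nrow(x)), nrow(x):(nrow(x) - p + 1))
  ci <- c(p:1, seq_len(ncol(x)), ncol(x):(ncol(x) - p + 1))
  xp <- x[ri, ci]
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    out[i, j] <- stats::median(xp[i:(i + 2 * p), j:(j + 2 * p)])
  out
}

## exhaustive Otsu search: try all 255 cut points on the 256-bin histogram,
## maximizing between-class variance directly from class weights and means
otsu_oracle <- function(plane) {
  v <- as.integer(floor(pmin(pmax(plane, 0), 1) * 255 + 0.5))
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:254) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t / 255
}

## mid-rank Spearman with t-approximation p-value, by direct arithmetic
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

## two-way mean-squares ICC(3,1) by direct closed-form arithmetic
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm)^2)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  f <- msr / mse
  list(icc = (msr - mse) / (msr + (k - 1) * mse),
       p = stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

## small default scene specs used by several test files (kept small so the
## full suite stays fast)
quick_spec <- function(...) {
  args <- list(height_px = 384, width_px = 384, n_tumor_nuclei = 40,
               ki67_fraction_tumor = 0.25, n_stromal_nuclei = 8,
               ki67_fraction_stromal = 0.5, nucleus_radius_px = c(12, 2),
               ck_margin_px = 10, touch_probability = 0,
               blur_sigma_px = 0, noise_sd = 0, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}
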