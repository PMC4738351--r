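#' Specification of a synthetic three-channel field
#'
#' Parameters of the synthetic tissue generator. The generator emulates an
#' unmixed three-channel fluorescence field of breast-cancer tissue imaged at
#' high magnification: elliptical tumor nuclei (some touching or fused, to
#' exercise watershed splitting) inside a cytokeratin (CK) cytoplasm region,
#' a configurable fraction of them Ki67-positive, plus stromal distractor
#' nuclei outside the CK region, with per-nucleus staining variability,
#' Gaussian blur and additive Gaussian noise.
#'
#' Ki67-positive nuclei are assigned deterministically as the first
#' `round(fraction * n)` entries of a seeded random permutation, so the true
#' index is exact rather than binomially distributed.
#'
#' @param height_px,width_px field dimensions in pixels (>= 64).
#' @param n_tumor_nuclei number of tumor nuclei.
#' @param ki67_fraction_tumor fraction of tumor nuclei that are Ki67-positive,
#'   in \[0, 1\].
#' @param n_stromal_nuclei number of stromal nuclei (placed outside the CK
#'   region).
#' @param ki67_fraction_stromal fraction of stromal nuclei Ki67-positive.
#' @param nucleus_radius_px length-2 numeric `(mean, sd)` of the nucleus
#'   equivalent radius in pixels; drawn radii are clipped at 2 px.
#' @param touch_probability probability that a tumor nucleus is placed
#'   adjacent/overlapping an existing one (at center distance 1.2--1.8 times
#'   the mean of the two radii), creating fused blobs.
#' @param ck_margin_px width in pixels of the cytoplasm halo around tumor
#'   nuclei that forms the CK region.
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation on the \[0, 1\]
#'   intensity scale (0 = none).
#' @param seed integer RNG seed; equal spec + seed gives bit-identical output.
#' @return An object of class `scene_spec`.
#' @seealso [generate_scene()], [render_noise_free()]
#' @export
scene_spec <- function(height_px = 1040L, width_px = 1392L,
                       n_tumor_nuclei = 300L, ki67_fraction_tumor = 0.25,
                       n_stromal_nuclei = 40L, ki67_fraction_stromal = 0.2,
                       nucleus_radius_px = c(12, 2), touch_probability = 0.3,
                       ck_margin_px = 10, blur_sigma_px = 1, noise_sd = 0.05,
                       seed = 1L) {
  h <- .check_count(height_px, "height_px", min = 1L)
  w <- .check_count(width_px, "width_px", min = 1L)
  if (h < 64L || w < 64L)
    stop("'height_px' and 'width_px' must be >= 64", call. = FALSE)
  if (!is.numeric(nucleus_radius_px) || length(nucleus_radius_px) != 2L)
    stop("'nucleus_radius_px' must be c(mean, sd)", call. = FALSE)
  if (nucleus_radius_px[1] <= 0)
    stop("nucleus radius mean must be positive", call. = FALSE)
  if (nucleus_radius_px[2] < 0)
    stop("nucleus radius sd must be non-negative", call. = FALSE)
  spec <- list(
    height_px = h, width_px = w,
    n_tumor_nuclei = .check_count(n_tumor_nuclei, "n_tumor_nuclei"),
    ki67_fraction_tumor = .check_number(ki67_fraction_tumor, "ki67_fraction_tumor", 0, 1),
    n_stromal_nuclei = .check_count(n_stromal_nuclei, "n_stromal_nuclei"),
    ki67_fraction_stromal = .check_number(ki67_fraction_stromal, "ki67_fraction_stromal", 0, 1),
    nucleus_radius_px = as.numeric(nucleus_radius_px),
    touch_probability = .check_number(touch_probability, "touch_probability", 0, 1),
    ck_margin_px = .check_number(ck_margin_px, "ck_margin_px", 0, Inf),
    blur_sigma_px = .check_number(blur_sigma_px, "blur_sigma_px", 0, Inf),
    noise_sd = .check_number(noise_sd, "noise_sd", 0, Inf),
    seed = .check_count(seed, "seed", min = -.Machine$integer.max)
  )
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px, %d tumor nuclei (Ki67 fraction %.2f), %d stromal (Ki67 fraction %.2f)\n",
              x$height_px, x$width_px, x$n_tumor_nuclei, x$ki67_fraction_tumor,
              x$n_stromal_nuclei, x$ki67_fraction_stromal))
  cat(sprintf("  radius ~ N(%.1f, %.1f) px, touch p=%.2f, CK margin %.1f px, blur %.1f px, noise sd %.3f, seed %d\n",
              x$nucleus_radius_px[1], x$nucleus_radius_px[2], x$touch_probability,
              x$ck_margin_px, x$blur_sigma_px, x$noise_sd, x$seed))
  invisible(x)
}

## ellipse pixel list: linear indices of pixels inside the ellipse
.ellipse_pixels <- function(h, w, r0, c0, a, b, theta) {
  rr <- max(1L, floor(r0 - a)):min(h, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(w, ceiling(c0 + a))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- u * u + v * v <= 1
  idx <- which(inside)
  (cc[((idx - 1L) %/% length(rr)) + 1L] - 1L) * h + rr[((idx - 1L) %% length(rr)) + 1L]
}

## deterministic scene geometry: nuclei table, pixel lists, masks, labels.
## RNG order: tumor nuclei (shape, placement, peak), tumor Ki67 permutation,
## stromal nuclei, stromal Ki67 permutation -- so adding stromal nuclei or
## changing blur/noise never alters the tumor geometry.
.scene_geometry <- function(spec) {
  h <- spec$height_px; w <- spec$width_px
  rm_ <- spec$nucleus_radius_px[1]; rs_ <- spec$nucleus_radius_px[2]
  ## inset so nuclei lie fully inside the field
  inset <- ceiling((rm_ + 3 * rs_) / sqrt(0.7)) + 2
  if (2 * inset >= min(h, w))
    stop("field too small for the requested nucleus radius", call. = FALSE)
  nt <- spec$n_tumor_nuclei; ns <- spec$n_stromal_nuclei
  n <- nt + ns
  row <- col <- radius <- amax <- aax <- bax <- aang <- numeric(n)
  pix <- vector("list", n)
  ## tumor nuclei
  for (i in seq_len(nt)) {
    r_i <- max(2, stats::rnorm(1, rm_, rs_))
    q <- stats::runif(1, 0.7, 1)
    th <- stats::runif(1, 0, pi)
    peak_i <- stats::runif(1, 0.6, 1)
    a <- r_i / sqrt(q); b <- r_i * sqrt(q)
    placed <- FALSE
    if (i > 1L && stats::runif(1) < spec$touch_probability) {
      ## touching placement: adjacent/overlapping its chosen neighbor j but
      ## clear of every other nucleus, so clusters grow as chains of
      ## pairwise-abutting nuclei rather than solid clumps
      j <- sample.int(i - 1L, 1L)
      for (att in seq_len(100L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        ## radius of each ellipse along the placement direction, so overlap
        ## depth is controlled relative to the actual shapes (equals the
        ## plain radius for circular nuclei)
        ext_i <- sqrt((a * cos(ang - th))^2 + (b * sin(ang - th))^2)
        ext_j <- sqrt((aax[j] * cos(ang - aang[j]))^2 +
                      (bax[j] * sin(ang - aang[j]))^2)
        d <- stats::runif(1, 1.2, 1.8) * (ext_i + ext_j) / 2
        rr <- min(max(row[j] + d * cos(ang), inset), h - inset)
        cc <- min(max(col[j] + d * sin(ang), inset), w - inset)
        others <- setdiff(seq_len(i - 1L), j)
        if (length(others) == 0L ||
            all(sqrt((row[others] - rr)^2 + (col[others] - cc)^2) >=
                amax[others] + a + 1)) {
          row[i] <- rr; col[i] <- cc
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      ## keep >= 4 px boundary gap to every placed tumor nucleus so that
      ## deliberately separate nuclei survive morphological closing
      for (att in seq_len(1000L)) {
        rr <- stats::runif(1, inset, h - inset)
        cc <- stats::runif(1, inset, w - inset)
        if (i == 1L ||
            all(sqrt((row[seq_len(i - 1L)] - rr)^2 + (col[seq_len(i - 1L)] - cc)^2) >=
                amax[seq_len(i - 1L)] + a + 4)) {
          row[i] <- rr; col[i] <- cc
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place tumor nucleus after 1000 attempts; reduce density",
             call. = FALSE)
    }
    radius[i] <- r_i; amax[i] <- a
    aax[i] <- a; bax[i] <- b; aang[i] <- th
    pix[[i]] <- .ellipse_pixels(h, w, row[i], col[i], a, b, th)
    if (i == 1L) peaks <- numeric(n)
    peaks[i] <- peak_i
  }
  if (nt == 0L) peaks <- numeric(n)
  ## Ki67 positives: first round(f*n) of a seeded permutation (exact count)
  is_pos <- logical(n)
  if (nt > 0L) {
    k <- round(spec$ki67_fraction_tumor * nt)
    if (k > 0L) is_pos[sample.int(nt)[seq_len(k)]] <- TRUE
  }
  ## stromal nuclei: whole ellipse clears the CK region (tumor + margin) by >= 2 px
  for (i in seq.int(nt + 1L, length.out = ns)) {
    r_i <- max(2, stats::rnorm(1, rm_, rs_))
    q <- stats::runif(1, 0.7, 1)
    th <- stats::runif(1, 0, pi)
    peaks[i] <- stats::runif(1, 0.6, 1)
    a <- r_i / sqrt(q); b <- r_i * sqrt(q)
    placed <- FALSE
    for (att in seq_len(1000L)) {
      rr <- stats::runif(1, inset, h - inset)
      cc <- stats::runif(1, inset, w - inset)
      if (nt == 0L ||
          all(sqrt((row[seq_len(nt)] - rr)^2 + (col[seq_len(nt)] - cc)^2) >
              amax[seq_len(nt)] + spec$ck_margin_px + a + 2)) {
        row[i] <- rr; col[i] <- cc
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place stromal nucleus outside the CK region after 1000 attempts",
           call. = FALSE)
    radius[i] <- r_i; amax[i] <- a
    pix[[i]] <- .ellipse_pixels(h, w, rr, cc, a, b, th)
  }
  if (ns > 0L) {
    k <- round(spec$ki67_fraction_stromal * ns)
    if (k > 0L) is_pos[nt + sample.int(ns)[seq_len(k)]] <- TRUE
  }
  labels <- matrix(0L, h, w)
  for (i in seq_len(n)) labels[pix[[i]]] <- i
  nuclei_mask <- labels > 0L
  tumor_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nt)) tumor_mask[pix[[i]]] <- TRUE
  if (nt > 0L) {
    d_out <- as.matrix(EBImage::distmap((!tumor_mask) * 1))
    ck_mask <- tumor_mask | (d_out <= spec$ck_margin_px)
  } else {
    ck_mask <- matrix(FALSE, h, w)
  }
  ki67_mask <- matrix(FALSE, h, w)
  for (i in which(is_pos)) ki67_mask[pix[[i]]] <- TRUE
  list(
    nuclei = data.frame(
      id = seq_len(n), row = row, col = col, radius = radius,
      is_tumor = seq_len(n) <= nt, is_ki67_positive = is_pos
    ),
    pix = pix, peaks = peaks, labels = labels,
    nuclei_mask = nuclei_mask, ki67_mask = ki67_mask,
    tumor_mask = tumor_mask, ck_mask = ck_mask
  )
}

.scene_truth <- function(geom, nt) {
  idx <- if (nt > 0L)
    100 * sum(geom$nuclei$is_tumor & geom$nuclei$is_ki67_positive) / nt
  else NA_real_
  structure(
    list(nuclei = geom$nuclei, true_index_percent = idx,
         label_map_truth = geom$labels),
    class = "scene_truth"
  )
}

#' @export
print.scene_truth <- function(x, ...) {
  nt <- sum(x$nuclei$is_tumor)
  cat(sprintf("<scene_truth> %d nuclei (%d tumor, %d stromal); true Ki67 index: %s\n",
              nrow(x$nuclei), nt, nrow(x$nuclei) - nt,
              if (is.na(x$true_index_percent)) "not computable (no tumor nuclei)"
              else sprintf("%.2f%%", x$true_index_percent)))
  invisible(x)
}

#' Generate a synthetic three-channel field with ground truth
#'
#' Renders the scene described by `spec`: the nuclei plane lights every
#' nucleus, the Ki67 plane lights exactly the Ki67-positive nuclei (tumor and
#' stromal), and the CK plane lights the cytoplasm region (tumor nuclei
#' dilated by `ck_margin_px`, nucleus interiors included). Per-nucleus peak
#' intensity is drawn from Uniform(0.6, 1) to emulate staining variability;
#' the field is then blurred and corrupted with additive Gaussian noise as
#' specified. Equal `spec` (including seed) gives bit-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [scene_spec()].
#' @return An object of class `ki67_scene`: list with elements `field`
#'   (a [multichannel_field()]), `truth` (class `scene_truth`: per-nucleus
#'   table, `true_index_percent`, `label_map_truth`), and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(256, 256, n_tumor_nuclei = 20, seed = 1))
#' sc$truth
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, {
    geom <- .scene_geometry(spec)
    h <- spec$height_px; w <- spec$width_px
    nuclei <- ki67 <- matrix(0, h, w)
    for (i in seq_len(nrow(geom$nuclei)))
      nuclei[geom$pix[[i]]] <- pmax(nuclei[geom$pix[[i]]], geom$peaks[i])
    for (i in which(geom$nuclei$is_ki67_positive))
      ki67[geom$pix[[i]]] <- pmax(ki67[geom$pix[[i]]], geom$peaks[i])
    ck <- geom$ck_mask * 0.8
    if (spec$blur_sigma_px > 0) {
      nuclei <- as.matrix(EBImage::gblur(nuclei, spec$blur_sigma_px))
      ki67 <- as.matrix(EBImage::gblur(ki67, spec$blur_sigma_px))
      ck <- as.matrix(EBImage::gblur(ck, spec$blur_sigma_px))
    }
    if (spec$noise_sd > 0) {
      nuclei <- nuclei + stats::rnorm(h * w, 0, spec$noise_sd)
      ki67 <- ki67 + stats::rnorm(h * w, 0, spec$noise_sd)
      ck <- ck + stats::rnorm(h * w, 0, spec$noise_sd)
    }
    structure(
      list(field = multichannel_field(.clip01(nuclei), .clip01(ki67), .clip01(ck)),
           truth = .scene_truth(geom, spec$n_tumor_nuclei), spec = spec),
      class = "ki67_scene"
    )
  })
}

#' Render a scene without blur, noise or intensity variation
#'
#' Identical geometry (and ground truth) to [generate_scene()] for the same
#' spec, but with binary-valued planes: blur and noise are skipped and every
#' nucleus/CK pixel has value exactly 1. Useful as an ideal-input fixture.
#'
#' @inheritParams generate_scene
#' @return An object of class `ki67_scene` (see [generate_scene()]).
#' @export
render_noise_free <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, {
    geom <- .scene_geometry(spec)
    structure(
      list(field = multichannel_field(geom$nuclei_mask * 1, geom$ki67_mask * 1,
                                      geom$ck_mask * 1),
           truth = .scene_truth(geom, spec$n_tumor_nuclei), spec = spec),
      class = "ki67_scene"
    )
  })
}

#' @export
print.ki67_scene <- function(x, ...) {
  print(x$spec)
  print(x$truth)
  invisible(x)
}

#' @export
plot.ki67_scene <- function(x, ...) plot(x$field, ...)
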