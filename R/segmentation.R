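#' Otsu binarization
#'
#' Global thresholding by Otsu's criterion: the threshold maximizes the
#' between-class variance over a 256-bin histogram of the plane (intensities
#' are quantized to 8-bit levels for the histogram regardless of input bit
#' depth, for reproducibility). Ties in the between-class variance are broken
#' toward the lower threshold. The returned threshold is on the \[0, 1\]
#' intensity scale and the mask is `plane > threshold`.
#'
#' @param plane numeric matrix on \[0, 1\] with at least two distinct values.
#' @return A list with elements `mask` (logical matrix) and `threshold`
#'   (numeric scalar in \[0, 1\]).
#' @examples
#' x <- matrix(rep(c(0, 1), each = 50), 10, 10)
#' otsu_binarize(x)$threshold
#' @export
otsu_binarize <- function(plane) {
  .check_matrix(plane, "plane")
  v <- as.integer(floor(.clip01(plane) * 255 + 0.5))
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("no threshold exists: plane has fewer than 2 distinct values", call. = FALSE)
  p <- counts / sum(counts)
  w0 <- cumsum(p)                      # weight of class {bins <= t}
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_cand <- 1:255                      # cut after bin t-1, i.e. t = 0..254
  w0c <- w0[t_cand]
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0c[valid] - mu[t_cand][valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  t_best <- which.max(sigma_b) - 1L    # which.max takes the first (lowest) max
  thr <- t_best / 255
  mask <- plane > thr
  dim(mask) <- dim(plane)
  list(mask = mask, threshold = thr)
}

#' Morphological mask cleaning
#'
#' Morphological opening with a disk of radius `open_radius_px` (removes
#' speckle smaller than the disk) followed by closing with a disk of radius
#' `close_radius_px` (bridges small gaps and smooths contours). A radius of 0
#' skips that step.
#'
#' @param mask logical matrix.
#' @param open_radius_px,close_radius_px non-negative integer disk radii.
#' @return Logical matrix of the same dimensions.
#' @export
clean_mask <- function(mask, open_radius_px = 1L, close_radius_px = 1L) {
  mask <- .check_mask(mask)
  ro <- .check_count(open_radius_px, "open_radius_px", min = 0L)
  rc <- .check_count(close_radius_px, "close_radius_px", min = 0L)
  m <- mask * 1
  if (ro > 0L) m <- EBImage::opening(m, .disc(ro))
  if (rc > 0L) m <- EBImage::closing(m, .disc(rc))
  out <- as.matrix(m) > 0.5
  dim(out) <- dim(mask)
  out
}

#' Fill interior holes of a binary mask
#'
#' Every background region not connected to the image border (4-connectivity
#' for background, the standard dual of 8-connected foreground) becomes
#' foreground.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same dimensions.
#' @export
fill_holes <- function(mask) {
  mask <- .check_mask(mask)
  out <- as.matrix(EBImage::fillHull(mask * 1)) > 0.5
  dim(out) <- dim(mask)
  out
}

#' Split touching nuclei by marker-controlled watershed
#'
#' Computes the Euclidean distance transform of the mask, takes its regional
#' maxima separated by at least `min_marker_distance_px` as markers (maxima
#' closer together are merged into one marker), and grows the markers over
#' the mask by watershed on the negated distance transform
#' ([EBImage::propagate()]). Every foreground pixel receives exactly one
#' label; foreground is conserved. An empty mask yields an empty label map.
#'
#' @param mask logical matrix.
#' @param min_marker_distance_px integer >= 1; minimum separation of markers.
#'   Sensible default: the expected nucleus radius.
#' @return Integer label matrix (0 = background, labels 1..L consecutive).
#' @examples
#' m <- outer(1:40, 1:60, function(r, c)
#'   sqrt((r - 20)^2 + (c - 23)^2) <= 10 | sqrt((r - 20)^2 + (c - 37)^2) <= 10)
#' max(split_touching(m, 7))  # two fused disks -> 2 labels
#' @export
split_touching <- function(mask, min_marker_distance_px = 7L) {
  mask <- .check_mask(mask)
  d <- .check_count(min_marker_distance_px, "min_marker_distance_px", min = 1L)
  if (!any(mask))
    return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- as.matrix(EBImage::distmap(mask * 1))
  ## regional maxima of the distance transform (8-neighborhood plateaus);
  ## maxima closer than d are then merged into a single marker
  localmax <- as.matrix(EBImage::dilate(dm, EBImage::makeBrush(3L, "box")))
  peaks <- mask & (dm >= localmax - 1e-7)
  seeds <- as.matrix(EBImage::bwlabel(peaks * 1))
  storage.mode(seeds) <- "integer"
  seeds <- .merge_close_markers(seeds, d, dm)
  lab <- as.matrix(EBImage::propagate(dm, seeds, mask = mask * 1))
  storage.mode(lab) <- "integer"
  ## small satellite components can lose their maximum to a larger neighbor's
  ## dilation window; label any uncovered foreground as its own objects
  rest <- mask & lab == 0L
  if (any(rest)) {
    extra <- as.matrix(EBImage::bwlabel(rest * 1))
    lab[rest] <- as.integer(extra[rest]) + max(lab)
  }
  .relabel(lab)
}

## enforce the minimum marker separation: visit maxima strongest-first,
## keep those at least d away from every already-kept marker, and absorb
## the rest into their nearest kept marker (greedy non-maximum suppression;
## the discrete distance transform has spurious ridge maxima that must be
## absorbed without bridging two genuine nucleus centers)
.merge_close_markers <- function(seeds, d, dm) {
  st <- .label_stats(seeds)
  n <- nrow(st)
  if (n < 2L) return(seeds)
  st$value <- dm[cbind(.nearest_px(st$row, nrow(dm)), .nearest_px(st$col, ncol(dm)))]
  ord <- order(-st$value, st$id)
  kept <- integer(0)
  assign_to <- integer(n)
  for (i in ord) {
    if (length(kept) == 0L) { kept <- i; assign_to[i] <- i; next }
    dd <- sqrt((st$row[kept] - st$row[i])^2 + (st$col[kept] - st$col[i])^2)
    if (all(dd >= d)) {
      kept <- c(kept, i)
      assign_to[i] <- i
    } else {
      assign_to[i] <- kept[which.min(dd)]
    }
  }
  lut <- integer(max(st$id))
  lut[st$id] <- st$id[assign_to]
  nz <- seeds > 0L
  seeds[nz] <- lut[seeds[nz]]
  seeds
}

#' Correct over- and under-segmentation by area bounds
#'
#' Objects smaller than `min_area_px` are merged into an adjacent
#' (8-connected) label when one touches them, and deleted otherwise.
#' Objects larger than `max_area_px` are re-split by recursively applying
#' [split_touching()] with the marker distance halved at each level
#' (floor 1). Labels are renumbered consecutively.
#'
#' @param labels integer label matrix.
#' @param min_area_px,max_area_px positive integers with
#'   `min_area_px < max_area_px`.
#' @param min_marker_distance_px marker distance used by the originating
#'   [split_touching()] call; re-splitting starts from half this value.
#' @return Integer label matrix with consecutive labels.
#' @export
postprocess_labels <- function(labels, min_area_px = 30L, max_area_px = 5000L,
                               min_marker_distance_px = 7L) {
  labels <- .check_labels(labels)
  min_a <- .check_count(min_area_px, "min_area_px", min = 1L)
  max_a <- .check_count(max_area_px, "max_area_px", min = 1L)
  if (min_a >= max_a)
    stop("'min_area_px' must be strictly less than 'max_area_px'", call. = FALSE)
  d0 <- .check_count(min_marker_distance_px, "min_marker_distance_px", min = 1L)
  storage.mode(labels) <- "integer"
  if (!any(labels > 0L)) return(.relabel(labels))

  area <- tabulate(labels[labels > 0L], nbins = max(labels))
  ## merge-or-delete small objects
  for (L in which(area > 0L & area < min_a)) {
    obj <- labels == L
    nb <- .adjacent_labels(labels, obj, L)
    if (length(nb) > 0L) {
      labels[obj] <- nb[1L]            # most frequent neighbor, lowest label on ties
    } else {
      labels[obj] <- 0L
    }
  }
  ## re-split oversized objects
  area <- tabulate(labels[labels > 0L], nbins = max(labels))
  big <- which(area > max_a)
  if (length(big) > 0L) {
    nxt <- max(labels)
    for (L in big) {
      obj <- labels == L
      sub <- .resplit(obj, max(1L, d0 %/% 2L), max_a)
      if (max(sub) >= 2L) {
        labels[obj] <- 0L
        nz <- sub > 0L
        labels[nz] <- sub[nz] + nxt
        nxt <- nxt + max(sub)
      }
    }
  }
  .relabel(labels)
}

## labels 8-adjacent to object `obj`, most frequent first (lowest on ties)
.adjacent_labels <- function(labels, obj, self) {
  grown <- as.matrix(EBImage::dilate(obj * 1, .disc(1L))) > 0.5
  ring <- grown & !obj
  nb <- labels[ring]
  nb <- nb[nb > 0L & nb != self]
  if (length(nb) == 0L) return(integer(0))
  tab <- sort(table(nb), decreasing = TRUE)
  as.integer(names(tab))
}

## recursively split one oversized object, halving the marker distance
.resplit <- function(obj, d, max_a) {
  sub <- split_touching(obj, d)
  if (d > 1L) {
    area <- tabulate(sub[sub > 0L], nbins = max(sub, 1L))
    if (max(sub) < 2L && any(area > max_a)) {
      return(.resplit(obj, max(1L, d %/% 2L), max_a))
    }
    for (L in which(area > max_a)) {
      part <- sub == L
      deeper <- .resplit(part, max(1L, d %/% 2L), max_a)
      if (max(deeper) >= 2L) {
        nxt <- max(sub)
        sub[part] <- 0L
        nz <- deeper > 0L
        sub[nz] <- deeper[nz] + nxt
      }
    }
  }
  .relabel(sub)
}
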