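#' Intraclass correlation (two-way mixed, single measure, consistency)
#'
#' Consistency-type ICC for agreement between counting methods measured on
#' the same images, computed from the mean squares of the two-way layout
#' (images x methods): `ICC = (MSR - MSE) / (MSR + (k - 1) MSE)` with `MSR`
#' the between-image and `MSE` the residual mean square. Being the
#' consistency form, it is invariant under adding a constant to one method's
#' column. The p-value is the upper tail of `F = MSR / MSE` on
#' `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param values numeric matrix or data frame, images in rows, methods in
#'   columns (column names = method names); no missing cells, values on
#'   \[0, 100\].
#' @param pair optional length-2 character vector selecting two method
#'   columns; default uses all columns.
#' @return An object of class `ki67_icc`: list with `icc`, `F`, `df1`,
#'   `df2`, `p_value`, `n`, `k`, `methods`. With zero variance across
#'   images the ICC is undefined: `icc` is `NA` with a warning.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))
#' icc_consistency(m)$icc  # additive offset: consistency ICC = 1
#' @export
icc_consistency <- function(values, pair = NULL) {
  x <- as.matrix(values)
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L, all(pair %in% colnames(x)))
    x <- x[, pair, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 methods", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 images", call. = FALSE)
  if (anyNA(x)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(
    y = as.vector(x),
    image = factor(rep(seq_len(n), k)),
    method = factor(rep(seq_len(k), each = n))
  )
  ms <- .quiet_perfect_fit(stats::anova(stats::aov(y ~ image + method, data = long)))
  msr <- ms["image", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
  if (msr < .Machine$double.eps^0.75 && mse < .Machine$double.eps^0.75) {
    warning("zero variance across images; ICC undefined")
    icc <- NA_real_; f <- NA_real_; p <- NA_real_
  } else if (mse < .Machine$double.eps^0.75) {
    icc <- 1; f <- Inf; p <- 0
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(icc = icc, F = f, df1 = df1, df2 = df2, p_value = p,
                 n = n, k = k,
                 methods = colnames(x) %||% paste0("method", seq_len(k))),
            class = "ki67_icc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## perfect agreement (zero residual) makes anova.lm warn; the degenerate
## case is handled explicitly by the callers, so muffle that warning only
.quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' @export
print.ki67_icc <- function(x, ...) {
  cat(sprintf("ICC (two-way mixed, single measure, consistency) between %s\n",
              paste(x$methods, collapse = ", ")))
  cat(sprintf("  ICC = %s, F(%d, %d) = %s, P = %s (n = %d images)\n",
              format(x$icc, digits = 4), x$df1, x$df2,
              format(x$F, digits = 4), format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' Spearman rank correlation with mid-ranks
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks (average
#' ranks for ties); the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return An object of class `ki67_spearman`: list with `rho`, `p_value`,
#'   `n`. With a constant vector rho is undefined: `NA` with a warning.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman's rho undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = length(x)),
                     class = "ki67_spearman"))
  }
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "ki67_spearman")
}

#' @export
print.ki67_spearman <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %s, P = %s (n = %d)\n",
              format(x$rho, digits = 4), format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' Compare Ki67 counting methods across grade strata
#'
#' Method-comparison report over per-image Ki67 indexes from two or more
#' counting methods. Per stratum (each grade, then all images pooled as
#' "overall"): descriptives in median (range) form per method; a
#' repeated-measures one-way ANOVA across methods with images as blocks;
#' pairwise paired contrasts (paired t-tests, unadjusted two-sided P);
#' pairwise consistency ICC ([icc_consistency()]); and pairwise Spearman
#' correlation ([spearman_assoc()]). Strata with fewer than 3 images are
#' skipped with a warning.
#'
#' @param values numeric matrix or data frame, images in rows, methods in
#'   columns (column names = method names), values in \[0, 100\].
#' @param grade factor or character vector (one per image) of grade labels.
#' @return An object of class `ki67_method_comparison`: list with data
#'   frames `descriptives` (stratum, method, n, median, min, max,
#'   `median_range` formatted) and `pairwise` (stratum, method_a, method_b,
#'   anova_p, contrast_p, icc, icc_p, rho, rho_p).
#' @export
compare_methods <- function(values, grade) {
  x <- as.matrix(values)
  if (is.null(colnames(x))) colnames(x) <- paste0("method", seq_len(ncol(x)))
  if (ncol(x) < 2L) stop("need at least 2 methods", call. = FALSE)
  if (any(x < 0 | x > 100)) stop("index values must be in [0, 100]", call. = FALSE)
  grade <- as.character(grade)
  stopifnot(length(grade) == nrow(x))
  strata <- c(as.list(stats::setNames(unique(grade), unique(grade))),
              list(overall = unique(grade)))
  desc <- list(); pw <- list()
  for (s in names(strata)) {
    rows <- grade %in% strata[[s]]
    xs <- x[rows, , drop = FALSE]
    if (nrow(xs) < 3L) {
      warning(sprintf("stratum '%s' has fewer than 3 images; skipped", s))
      next
    }
    desc[[s]] <- data.frame(
      stratum = s, method = colnames(xs), n = nrow(xs),
      median = apply(xs, 2, stats::median),
      min = apply(xs, 2, min), max = apply(xs, 2, max),
      row.names = NULL
    )
    desc[[s]]$median_range <- sprintf("%s (%s-%s)",
      format(desc[[s]]$median, trim = TRUE), format(desc[[s]]$min, trim = TRUE),
      format(desc[[s]]$max, trim = TRUE))
    ## omnibus repeated-measures ANOVA: methods as treatment, images as blocks
    long <- data.frame(
      y = as.vector(xs),
      image = factor(rep(seq_len(nrow(xs)), ncol(xs))),
      method = factor(rep(colnames(xs), each = nrow(xs)), levels = colnames(xs))
    )
    ms <- .quiet_perfect_fit(stats::anova(stats::aov(y ~ method + image, data = long)))
    anova_p <- ms["method", "Pr(>F)"]
    cmb <- utils::combn(colnames(xs), 2L)
    pw[[s]] <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      dif <- xs[, a] - xs[, b]
      ## a constant difference makes the paired t degenerate: no evidence of
      ## a difference when it is 0, overwhelming evidence otherwise
      contrast_p <- if (stats::sd(dif) == 0) (if (mean(dif) == 0) 1 else 0)
        else stats::t.test(xs[, a], xs[, b], paired = TRUE)$p.value
      icc <- suppressWarnings(icc_consistency(xs, pair = c(a, b)))
      sp <- suppressWarnings(spearman_assoc(xs[, a], xs[, b]))
      data.frame(stratum = s, method_a = a, method_b = b,
                 anova_p = anova_p, contrast_p = contrast_p,
                 icc = icc$icc, icc_p = icc$p_value,
                 rho = sp$rho, rho_p = sp$p_value, row.names = NULL)
    }))
  }
  structure(list(
    descriptives = do.call(rbind, c(desc, list(make.row.names = FALSE))),
    pairwise = do.call(rbind, c(pw, list(make.row.names = FALSE))),
    icc_model = "two-way mixed, single measure, consistency",
    anova = "repeated-measures one-way (images as blocks), paired contrasts, unadjusted two-sided P"
  ), class = "ki67_method_comparison")
}

#' @export
print.ki67_method_comparison <- function(x, ...) {
  cat("Ki67 counting method comparison\n")
  cat(sprintf("  ICC model: %s\n  ANOVA: %s\n\n", x$icc_model, x$anova))
  cat("Descriptives, median (range):\n")
  print(x$descriptives[, c("stratum", "method", "n", "median_range")],
        row.names = FALSE)
  cat("\nPairwise comparisons:\n")
  pv <- x$pairwise
  pv$anova_p <- signif(pv$anova_p, 3); pv$contrast_p <- signif(pv$contrast_p, 3)
  pv$icc <- signif(pv$icc, 3); pv$icc_p <- signif(pv$icc_p, 3)
  pv$rho <- signif(pv$rho, 3); pv$rho_p <- signif(pv$rho_p, 3)
  print(pv, row.names = FALSE)
  invisible(x)
}
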