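test_that("ICC is 1 for identical columns and invariant to additive offsets", {
  a <- c(3, 7, 12, 20, 44)
  expect_equal(icc_consistency(cbind(m1 = a, m2 = a))$icc, 1)
  # consistency type is shift-invariant
  expect_equal(icc_consistency(cbind(m1 = 1:4, m2 = 2:5))$icc, 1)
  off <- icc_consistency(cbind(m1 = a, m2 = a + 5, m3 = a - 2))
  expect_equal(off$icc, 1)
})

test_that("ICC matches the closed-form two-way mean-squares oracle", {
  x5 <- cbind(a = c(2, 4, 6, 8, 9), b = c(3, 3, 7, 9, 12))
  got <- icc_consistency(x5)
  want <- icc_oracle(x5)
  expect_equal(got$icc, want$icc, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  # larger random tables, three methods
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(runif(24, 0, 100), 8, 3)
    colnames(x) <- c("m1", "m2", "m3")
    expect_equal(icc_consistency(x)$icc, icc_oracle(x)$icc, tolerance = 1e-10)
    # pair selection works by name
    expect_equal(icc_consistency(x, pair = c("m1", "m3"))$icc,
                 icc_oracle(x[, c(1, 3)])$icc, tolerance = 1e-10)
  }
})

test_that("ICC is symmetric in its arguments and validates input", {
  set.seed(3)
  x <- matrix(runif(10, 0, 100), 5, 2, dimnames = list(NULL, c("p", "q")))
  expect_equal(icc_consistency(x, pair = c("p", "q"))$icc,
               icc_consistency(x[, 2:1], pair = c("q", "p"))$icc)
  expect_error(icc_consistency(x[1:2, ]), "at least 3")
  expect_error(icc_consistency(x[, 1, drop = FALSE]), "at least 2")
  expect_warning(icc_consistency(cbind(a = rep(4, 4), b = rep(4, 4))), "undefined")
})

test_that("Spearman rho handles monotone, antitone and tied data", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  # invariance under strictly monotone transforms
  set.seed(8)
  x <- runif(20); y <- runif(20)
  expect_equal(spearman_assoc(x, y)$rho, spearman_assoc(exp(x), y^3)$rho)
  # tied fixture against the mid-rank oracle
  xt <- c(1, 2, 2, 4); yt <- c(1, 3, 2, 4)
  got <- spearman_assoc(xt, yt)
  want <- spearman_oracle(xt, yt)
  expect_equal(got$rho, want$rho, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  # rho agrees with the standard estimator
  expect_equal(got$rho, unname(cor(xt, yt, method = "spearman")))
  expect_warning(spearman_assoc(rep(1, 5), 1:5), "undefined")
  expect_error(spearman_assoc(1:2, 1:2), "n >= 3")
})

test_that("method comparison reports strata, contrasts and agreement", {
  set.seed(21)
  truth <- c(runif(10, 1, 10), runif(10, 11, 49), runif(10, 50, 90))
  grade <- rep(c("low", "moderate", "high"), each = 10)
  tab <- cbind(marked = truth,
               automated = pmin(100, pmax(0, truth + rnorm(30, 0, 2))),
               visual = pmin(100, pmax(0, truth + rnorm(30, 0, 6))))
  rep_ <- compare_methods(tab, grade)
  expect_s3_class(rep_, "ki67_method_comparison")
  expect_setequal(unique(rep_$pairwise$stratum), c("low", "moderate", "high", "overall"))
  expect_equal(nrow(rep_$pairwise), 4 * 3)      # 4 strata x 3 pairs
  expect_true(all(rep_$pairwise$anova_p >= 0 & rep_$pairwise$anova_p <= 1))
  expect_true(all(abs(rep_$pairwise$icc) <= 1))
  # descriptives carry the median (range) format
  expect_match(rep_$descriptives$median_range[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")

  # identical methods: ICC and rho 1, paired contrast P = 1
  same <- cbind(a = truth, b = truth)
  rs <- suppressWarnings(compare_methods(same, grade))
  expect_equal(rs$pairwise$icc, rep(1, 4))
  expect_equal(rs$pairwise$rho, rep(1, 4))
  expect_equal(rs$pairwise$contrast_p, rep(1, 4))

  # constant offset: ICC(consistency) still 1, paired contrast significant
  shift <- cbind(a = truth, b = truth + 5)
  rsh <- suppressWarnings(compare_methods(shift, grade))
  expect_equal(rsh$pairwise$icc, rep(1, 4))
  expect_true(all(rsh$pairwise$contrast_p < 1e-6))

  # a 2-image stratum is skipped with a warning
  expect_warning(compare_methods(tab[c(1, 2, 11:30), ], grade[c(1, 2, 11:30)]),
                 "fewer than 3")
})
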