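test_that("compartment membership follows the centroid rule", {
  labels <- matrix(0L, 30, 30)
  labels[disk_mask(30, 30, cbind(8, 8), 4)] <- 1L     # fully inside CK
  labels[disk_mask(30, 30, cbind(22, 22), 4)] <- 2L   # fully outside CK
  ck <- matrix(FALSE, 30, 30); ck[1:14, 1:14] <- TRUE
  rec <- assign_compartment(labels, ck)
  expect_equal(rec$in_ck, c(TRUE, FALSE))

  # straddling nucleus with centroid 1 px outside: excluded
  lab2 <- matrix(0L, 21, 21)
  lab2[9:13, 9:13] <- 1L                              # centroid at (11, 11)
  ck2 <- matrix(FALSE, 21, 21); ck2[1:21, 1:10] <- TRUE
  expect_false(assign_compartment(lab2, ck2)$in_ck)

  expect_error(assign_compartment(labels, ck[1:10, ]), "mismatch")
})

test_that("Ki67 status uses the overlap fraction with a >= threshold", {
  labels <- matrix(0L, 20, 40)
  labels[6:15, 6:15] <- 1L      # area 100
  labels[6:15, 26:35] <- 2L     # area 100
  ck <- matrix(TRUE, 20, 40)
  rec <- assign_compartment(labels, ck)

  # full overlap positive for any tau; zero overlap negative
  ki67 <- matrix(FALSE, 20, 40); ki67[6:15, 6:15] <- TRUE
  r1 <- assign_ki67(rec, labels, ki67, tau = 0.99)
  expect_equal(r1$ki67_positive, c(TRUE, FALSE))
  expect_equal(r1$ki67_overlap_fraction, c(1, 0))

  # overlap exactly tau counts as positive (>= rule): 50 of 100 px
  ki2 <- matrix(FALSE, 20, 40); ki2[6:10, 26:35] <- TRUE
  r2 <- assign_ki67(rec, labels, ki2, tau = 0.5)
  expect_equal(r2$ki67_overlap_fraction[2], 0.5)
  expect_true(r2$ki67_positive[2])
  r3 <- assign_ki67(rec, labels, ki2, tau = 0.501)
  expect_false(r3$ki67_positive[2])
})

test_that("the index restricts counts to the tumor compartment", {
  rec <- data.frame(in_ck = rep(c(TRUE, FALSE), c(200, 10)),
                    ki67_positive = c(rep(TRUE, 50), rep(FALSE, 150), rep(TRUE, 10)))
  res <- compute_index(rec)
  expect_equal(res$index_percent, 25)
  expect_equal(res$n_nuclei_in_ck, 200L)
  expect_equal(res$grade, "moderate")

  # all nuclei outside CK: counts reported, index not computable
  out <- compute_index(data.frame(in_ck = rep(FALSE, 10),
                                  ki67_positive = rep(TRUE, 10)))
  expect_equal(out$n_nuclei_in_ck, 0L)
  expect_true(is.na(out$index_percent))
  expect_true(is.na(out$grade))

  # zero positives: 0%, grade low
  res0 <- compute_index(data.frame(in_ck = rep(TRUE, 80),
                                   ki67_positive = rep(FALSE, 80)))
  expect_equal(res0$index_percent, 0)
  expect_equal(res0$grade, "low")
})

test_that("grade bands follow the clinical cut points", {
  expect_equal(ki67_grade(c(0, 10, 10.01, 26, 49.99, 50, 100)),
               c("low", "low", "moderate", "moderate", "moderate", "high", "high"))
  expect_error(ki67_grade(101), "\\[0, 100\\]")
  expect_error(ki67_grade(-1), "\\[0, 100\\]")
})

test_that("the pipeline recovers the true index exactly on ideal input", {
  sp <- quick_spec(n_tumor_nuclei = 60, ki67_fraction_tumor = 0.25,
                   n_stromal_nuclei = 12, ki67_fraction_stromal = 0.5,
                   height_px = 512, width_px = 512, seed = 13)
  sc <- render_noise_free(sp)
  fit <- ki67_count(sc$field)
  expect_equal(fit$result$index_percent, sc$truth$true_index_percent)
  expect_equal(fit$result$n_nuclei_in_ck, 60L)
  # determinism: identical reruns
  fit2 <- ki67_count(sc$field)
  expect_identical(fit$result, fit2$result)
  expect_identical(fit$records, fit2$records)
})

test_that("stromal nuclei never perturb the compartment counts on ideal input", {
  base <- quick_spec(n_tumor_nuclei = 45, ki67_fraction_tumor = 0.4,
                     n_stromal_nuclei = 0, height_px = 512, width_px = 512,
                     seed = 17)
  with_stroma <- quick_spec(n_tumor_nuclei = 45, ki67_fraction_tumor = 0.4,
                            n_stromal_nuclei = 30, ki67_fraction_stromal = 0.5,
                            height_px = 512, width_px = 512, seed = 17)
  f0 <- ki67_count(render_noise_free(base)$field)
  f1 <- ki67_count(render_noise_free(with_stroma)$field)
  expect_equal(f1$result$n_nuclei_in_ck, f0$result$n_nuclei_in_ck)
  expect_equal(f1$result$index_percent, f0$result$index_percent)
})

test_that("raising the Ki67 fraction never lowers the recovered index", {
  idx <- sapply(c(0.1, 0.3, 0.5, 0.8), function(f) {
    sc <- render_noise_free(quick_spec(n_tumor_nuclei = 40, ki67_fraction_tumor = f,
                                       seed = 19))
    ki67_count(sc$field)$result$index_percent
  })
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= 0 & idx <= 100))
})

test_that("border policy 'drop' removes edge-touching nuclei only", {
  sc <- render_noise_free(quick_spec(seed = 23))
  keep <- ki67_count(sc$field, ki67_config(border_policy = "keep"))
  drop <- ki67_count(sc$field, ki67_config(border_policy = "drop"))
  # the generator insets nuclei away from the border, so both agree here
  expect_equal(drop$result$index_percent, keep$result$index_percent)
  # but a synthetic edge blob is dropped
  f <- sc$field
  f$nuclei[1:18, 200:217] <- 1
  keep2 <- ki67_count(f, ki67_config(border_policy = "keep"))
  drop2 <- ki67_count(f, ki67_config(border_policy = "drop"))
  expect_equal(nrow(keep2$records) - nrow(drop2$records), 1)
})

test_that("patient-level aggregation averages or pools fields", {
  r1 <- compute_index(data.frame(in_ck = rep(TRUE, 100),
                                 ki67_positive = rep(c(TRUE, FALSE), c(20, 80))))
  r2 <- compute_index(data.frame(in_ck = rep(TRUE, 50),
                                 ki67_positive = rep(c(TRUE, FALSE), c(25, 25))))
  m <- aggregate_fields(list(r1, r2), "mean")
  expect_equal(m$index_percent, (20 + 50) / 2)
  p <- aggregate_fields(list(r1, r2), "pooled")
  expect_equal(p$index_percent, 100 * 45 / 150)
  expect_equal(p$n_nuclei_in_ck, 150L)
})

test_that("pipeline errors carry the failing stage name", {
  f <- multichannel_field(matrix(0.5, 64, 64), matrix(0.5, 64, 64),
                          matrix(0.5, 64, 64))
  expect_error(suppressWarnings(ki67_count(f)), "otsu")
})
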