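test_that("phantom pairs are bit-identical for identical spec and seed", {
  a <- make_phantom_pair(tiny_spec(seed = 4))
  b <- make_phantom_pair(tiny_spec(seed = 4))
  expect_identical(a$recent$pixels, b$recent$pixels)
  expect_identical(a$prior$pixels, b$prior$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$true_field$dx, b$true_field$dx)
})

test_that("degenerate spec yields a pixel-identical pair", {
  p <- make_phantom_pair(frozen_spec(seed = 2, n_old_benign = 0,
                                     n_new_benign = 0, n_new_suspicious = 0))
  expect_identical(p$recent$pixels, p$prior$pixels)
  expect_equal(nrow(p$truth), 0)
})

test_that("truth carries the requested counts and new findings are recent-only", {
  p <- make_phantom_pair(tiny_spec(seed = 5, n_old_benign = 5,
                                   n_new_benign = 0, n_new_suspicious = 4))
  expect_equal(sum(p$truth$status == "old"), 5)
  expect_equal(sum(p$truth$status == "new"), 4)
  # every new centroid is brighter in the recent image than in the prior
  for (i in which(p$truth$status == "new")) {
    r <- round(p$truth$y[i]) + 1; c <- round(p$truth$x[i]) + 1
    expect_gt(p$recent$pixels[r, c], p$prior$pixels[r, c])
  }
})

test_that("without deformation or noise the prior is the recent image minus new spots", {
  p <- make_phantom_pair(frozen_spec(seed = 3))
  d <- p$recent$pixels - p$prior$pixels
  expect_true(all(d >= -1e-12))
  # difference vanishes away from the new findings
  H <- nrow(d); W <- ncol(d)
  far <- matrix(TRUE, H, W)
  for (i in which(p$truth$status == "new")) {
    r <- round(p$truth$y[i]) + 1; c <- round(p$truth$x[i]) + 1
    rr <- pmax(1, r - 15):pmin(H, r + 15)
    cc <- pmax(1, c - 15):pmin(W, c + 15)
    far[rr, cc] <- FALSE
  }
  expect_equal(max(abs(d[far])), 0)
  # and every new finding leaves a positive residual at its centre
  for (i in which(p$truth$status == "new")) {
    r <- round(p$truth$y[i]) + 1; c <- round(p$truth$x[i]) + 1
    expect_gt(d[r, c], 0.1)
  }
})

test_that("infeasible microcalcification counts raise a generation error", {
  expect_error(
    make_phantom_pair(tiny_spec(height = 64L, width = 48L, n_old_benign = 60L)),
    "cannot place")
})

test_that("phantom_spec validates its arguments", {
  expect_error(phantom_spec(n_old_benign = -1), ">= 0")
  expect_error(phantom_spec(mc_amplitude = 0), "0, 1")
  expect_error(phantom_spec(deformation_amplitude_px = -2), ">= 0")
})

test_that("feature cohorts have the documented shape and grouping", {
  coh <- make_feature_cohort(6, 2, seed = 9, n_per_patient = 3)
  expect_equal(nrow(coh), 18)
  expect_identical(setdiff(names(coh), c("patient_id", "label")),
                   feature_names())
  expect_equal(dplyr::n_distinct(coh$patient_id), 6)
  # labels are constant within patient
  per <- dplyr::summarise(dplyr::group_by(coh, patient_id),
                          n_lab = dplyr::n_distinct(label))
  expect_true(all(per$n_lab == 1))
  # reproducible
  expect_identical(coh, make_feature_cohort(6, 2, seed = 9, n_per_patient = 3))
  expect_error(make_feature_cohort(1, 2), ">= 2")
})

test_that("a 3-patient cohort yields exactly 3 LOPO folds downstream", {
  coh <- make_feature_cohort(3, 1, seed = 2)
  cv <- build_cv(unique(coh$patient_id), "lopo")
  expect_equal(nrow(cv), 3)
  expect_true(all(lengths(cv$test) == 1))
})
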