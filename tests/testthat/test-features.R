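disc_candidate <- function(radius, centre = 32, size = 64) {
  b <- matrix(FALSE, size, size)
  for (r in seq_len(size)) for (c in seq_len(size)) {
    if ((r - centre)^2 + (c - centre)^2 <= radius^2) b[r, c] <- TRUE
  }
  st <- tsmammo:::label_stats(tsmammo:::label8(b))
  tibble::tibble(candidate_id = 1L, row0 = st$row0, col0 = st$col0,
                 row1 = st$row1, col1 = st$col1,
                 centroid_row = st$centroid_row, centroid_col = st$centroid_col,
                 area_px = as.integer(st$area),
                 mask = list(b[st$row0:st$row1, st$col0:st$col1]),
                 source = "subtracted", patient_id = "P1", view = "CC")
}

test_that("feature vectors have exactly 96 named entries, 72 of them GLCM", {
  set.seed(5)
  img <- matrix(runif(64 * 64, 0.2, 0.8), 64, 64)
  fv <- extract_features(disc_candidate(5), img)
  expect_length(fv, 96)
  expect_identical(names(fv), feature_names())
  expect_equal(sum(grepl("^glcm_", names(fv))), 72)
  expect_equal(sum(grepl("^shape_", names(fv))), 12)
  expect_equal(sum(grepl("^int_", names(fv))), 12)
  expect_true(all(is.finite(fv)))
})

test_that("a circular disc yields circular shape descriptors", {
  img <- matrix(0.4, 64, 64)
  fv <- extract_features(disc_candidate(5), img)
  expect_gt(fv[["shape_circularity"]], 0.9)
  expect_lt(fv[["shape_circularity"]], 1.1)
  expect_lt(fv[["shape_eccentricity"]], 0.2)
  expect_equal(fv[["shape_area"]], 81)
  expect_gt(fv[["shape_solidity"]], 0.9)
})

test_that("zero-texture patches have zero angular spread in GLCM features", {
  # radius large enough that the patch needs no zero padding, on a
  # constant image: all four angles see the same trivial matrix
  img <- matrix(0.5, 64, 64)
  fv <- extract_features(disc_candidate(14), img)
  sd_feats <- fv[grepl("^glcm_.*_sd$", names(fv))]
  expect_true(all(abs(sd_feats) < 1e-12))
  expect_equal(unname(fv[["int_sd"]]), 0)
  expect_equal(unname(fv[["int_skewness"]]), 0)
})

test_that("features are invariant to integer translation of the candidate", {
  set.seed(9)
  base <- matrix(runif(40 * 40, 0.2, 0.8), 40, 40)
  img1 <- matrix(0.3, 120, 120); img1[10:49, 10:49] <- base
  img2 <- matrix(0.3, 120, 120); img2[60:99, 55:94] <- base
  mk <- function(r0, c0) {
    b <- matrix(FALSE, 9, 9); b[2:8, 3:7] <- TRUE
    tibble::tibble(candidate_id = 1L, row0 = r0, col0 = c0,
                   row1 = r0 + 8, col1 = c0 + 8,
                   centroid_row = r0 + 4, centroid_col = c0 + 4,
                   area_px = sum(b), mask = list(b), source = "subtracted",
                   patient_id = "P1", view = "CC")
  }
  f1 <- extract_features(mk(25, 25), img1)   # same content offset (15, 15)
  f2 <- extract_features(mk(75, 70), img2)
  expect_lt(max(abs(f1 - f2)), 1e-9)
})

test_that("degenerate masks raise a feature error naming the candidate", {
  cand <- disc_candidate(5)
  cand$mask <- list(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  expect_error(extract_features(cand, matrix(0.5, 64, 64)), "degenerate")
})

test_that("feature tables carry one row per candidate with metadata", {
  p <- make_phantom_pair(frozen_spec(seed = 51))
  d <- p$recent$pixels - p$prior$pixels
  cands <- detect_candidates(d, mask = p$breast_mask, threshold = 0.1,
                             patient_id = "ph", view = "CC")
  ft <- extract_features_table(cands, d)
  expect_equal(nrow(ft), nrow(cands))
  expect_equal(ncol(ft), 100)
  expect_identical(names(ft)[5:100], feature_names())
})

test_that("selection keeps strongly separated features and bounds the set size", {
  set.seed(13)
  n <- 50
  X <- as.data.frame(matrix(rnorm(2 * n * 30), 2 * n, 30))
  names(X) <- sprintf("f%02d", 1:30)
  y <- rep(c("a", "b"), each = n)
  X$f01 <- X$f01 + ifelse(y == "b", 10, 0)   # 10 SD separation
  X$f02 <- 5                                  # identical in both classes
  rep <- select_features(X, y, top_k = 5)
  expect_s3_class(rep, "selection_report")
  expect_lt(rep$p_value[rep$feature == "f01"], 1e-10)
  expect_true(rep$selected[rep$feature == "f01"])
  expect_gt(rep$p_value[rep$feature == "f02"], 0.9)
  expect_false(rep$selected[rep$feature == "f02"])
  expect_lte(sum(rep$selected), 5)
  expect_gt(sum(rep$selected), 0)
  expect_error(select_features(X, rep("a", 2 * n)), "two classes")
})
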