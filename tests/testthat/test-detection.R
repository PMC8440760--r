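test_that("range filter matches its closed forms", {
  expect_true(all(range_filter(matrix(0.4, 10, 10), 3) == 0))
  px <- matrix(0, 9, 9); px[5, 5] <- 1
  rf <- range_filter(px, 3)
  expect_true(all(rf[4:6, 4:6] == 1))
  expect_true(all(rf[-(4:6), ] %in% 0) && all(rf[, -(4:6)] %in% 0))
  expect_error(range_filter(px, 4), "odd")
  expect_error(range_filter(px, 1), "odd")
})

test_that("range filter equals the nested-loop oracle on random images", {
  set.seed(42)
  for (w in c(3, 5)) {
    for (rep in 1:3) {
      img <- matrix(runif(256), 16, 16)
      expect_equal(range_filter(img, w), range_filter_oracle(img, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("binarisation respects threshold semantics and monotonicity", {
  expect_identical(as.vector(binarise(matrix(c(0.4, 0.6), 1, 2), 0.5)),
                   c(FALSE, TRUE))
  img <- matrix(runif(100), 10, 10)
  expect_identical(binarise(img, 1e-9), img >= 1e-9)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t) sum(binarise(img, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarise(img, 0), "in \\(0, 1\\)")
  expect_error(binarise(img, 1.2), "in \\(0, 1\\)")
})

test_that("morphological cleaning filters small specks and bridges gaps", {
  b <- matrix(FALSE, 30, 30)
  b[2, 2] <- TRUE; b[28, 3] <- TRUE            # two 1-px specks
  b[10:15, 10:14] <- TRUE                       # 30-px blob
  cands <- morph_clean(b, min_area = 5, gap_close_radius = 0)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$area_px, 30)

  split <- matrix(FALSE, 20, 20)
  split[10, 3:8] <- TRUE; split[10, 10:15] <- TRUE  # 1-px gap at col 9
  expect_equal(nrow(morph_clean(split, min_area = 2, gap_close_radius = 0)), 2)
  expect_equal(nrow(morph_clean(split, min_area = 2, gap_close_radius = 2)), 1)
})

test_that("candidates are 8-connected and satisfy the area floor", {
  p <- make_phantom_pair(frozen_spec(seed = 41))
  d <- p$recent$pixels - p$prior$pixels
  cands <- detect_candidates(d, mask = p$breast_mask, threshold = 0.1,
                             min_area = 4)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    expect_gte(cands$area_px[i], 4)
    sub_lab <- tsmammo:::label8(cands$mask[[i]])
    expect_equal(max(sub_lab), 1)  # single 8-connected component
    expect_true(cands$centroid_row[i] >= cands$row0[i] &&
                cands$centroid_row[i] <= cands$row1[i])
  }
})

test_that("every seeded new microcalcification is covered by a candidate", {
  # clustered spots may merge into one candidate, so coverage (centroid
  # inside some candidate mask) is the right notion here, not
  # one-to-one matching
  for (s in 42:44) {
    p <- make_phantom_pair(frozen_spec(seed = s))
    d <- p$recent$pixels - p$prior$pixels
    cands <- detect_candidates(d, mask = p$breast_mask, threshold = 0.1)
    new_truth <- dplyr::filter(p$truth, status == "new")
    for (i in seq_len(nrow(new_truth))) {
      r <- round(new_truth$y[i]) + 1; c <- round(new_truth$x[i]) + 1
      covered <- any(vapply(seq_len(nrow(cands)), function(k) {
        r >= cands$row0[k] && r <= cands$row1[k] &&
          c >= cands$col0[k] && c <= cands$col1[k] &&
          cands$mask[[k]][r - cands$row0[k] + 1, c - cands$col0[k] + 1]
      }, logical(1)))
      expect_true(covered)
    }
  }
})

test_that("greedy matching handles exact hits and one-to-one ties", {
  cand <- function(r, c) tibble::tibble(
    candidate_id = 1L, row0 = r - 1, col0 = c - 1, row1 = r + 1, col1 = c + 1,
    centroid_row = r, centroid_col = c, area_px = 9L,
    mask = list(matrix(TRUE, 3, 3)), source = "subtracted",
    patient_id = NA_character_, view = NA_character_)
  ann <- tibble::tibble(x = 10 - 1, y = 10 - 1)  # 0-based
  one <- match_candidates(cand(10, 10), ann)
  expect_equal(c(one$tp, one$fp, one$fn), c(1, 0, 0))

  two <- dplyr::bind_rows(cand(10, 10), cand(12, 10))
  two$candidate_id <- 1:2
  res <- match_candidates(two, ann)
  expect_equal(c(res$tp, res$fp, res$fn), c(1, 1, 0))
  # the nearer candidate wins
  expect_equal(res$pairs$candidate, 1L)
})

test_that("greedy matching attains the optimal assignment on small instances", {
  set.seed(7)
  for (rep in 1:20) {
    nc <- sample(1:5, 1); na <- sample(1:5, 1)
    cands <- purrr::map_dfr(seq_len(nc), function(i) {
      r <- sample(5:60, 1); c <- sample(5:60, 1)
      tibble::tibble(candidate_id = i, row0 = r, col0 = c, row1 = r + 1,
                     col1 = c + 1, centroid_row = r + 0.5,
                     centroid_col = c + 0.5, area_px = 4L,
                     mask = list(matrix(TRUE, 2, 2)), source = "subtracted",
                     patient_id = NA_character_, view = NA_character_)
    })
    ann <- tibble::tibble(x = sample(5:60, na, replace = TRUE),
                          y = sample(5:60, na, replace = TRUE))
    got <- match_candidates(cands, ann, tol_px = 8)$tp
    want <- match_oracle_tp(cands, ann, tol_px = 8)
    expect_equal(got, want)
  }
})

test_that("threshold optimisation honours its argmax contract", {
  p <- make_phantom_pair(frozen_spec(seed = 45))
  d <- p$recent$pixels - p$prior$pixels
  labelled <- list(list(img = d, mask = p$breast_mask,
                        annotations = dplyr::filter(p$truth, status == "new")))
  expect_equal(optimise_threshold(labelled, grid = 0.3), 0.3)
  grid <- c(0.05, 0.15, 0.3)
  th <- optimise_threshold(labelled, grid = grid)
  obj <- vapply(grid, function(t) {
    cands <- detect_candidates(d, mask = p$breast_mask, threshold = t)
    mr <- match_candidates(cands, dplyr::filter(p$truth, status == "new"))
    mr$tp - mr$fp
  }, numeric(1))
  expect_equal(obj[match(th, grid)], max(obj))
  expect_error(optimise_threshold(labelled, grid = numeric(0)), "non-empty")
})
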