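test_that("registering an image onto itself leaves the field near zero", {
  p <- make_phantom_pair(frozen_spec(seed = 11))
  px <- p$recent$pixels
  fld <- demons_register(px, px, params = fast_demons())
  expect_lt(max(sqrt(fld$dx^2 + fld$dy^2)), 0.1)
})

test_that("a pure translation is recovered to sub-pixel accuracy", {
  p <- make_phantom_pair(frozen_spec(seed = 12, n_old_benign = 0,
                                     n_new_benign = 0, n_new_suspicious = 0))
  fixed <- p$recent$pixels
  H <- nrow(fixed); W <- ncol(fixed)
  # content shifted right by 3 px: moving(r, c) = fixed(r, c - 3), so
  # the backward field mapping moving onto fixed is dx = +3
  moving <- cbind(matrix(0, H, 3), fixed[, 1:(W - 3)])
  fld <- demons_register(fixed, moving, params = fast_demons())
  interior <- p$breast_mask
  interior[c(1:12, (H - 11):H), ] <- FALSE
  interior[, c(1:12, (W - 11):W)] <- FALSE
  expect_lt(abs(mean(fld$dx[interior]) - 3), 0.5)
  expect_lt(abs(mean(fld$dy[interior])), 0.5)
})

test_that("the registration metric never increases across pyramid levels", {
  p <- make_phantom_pair(tiny_spec(seed = 13))
  pre <- preprocess_pair(p$recent, p$prior)
  fld <- demons_register(pre$recent, pre$prior, params = fast_demons(),
                         mask = pre$mask$mask)
  lm <- fld$level_metrics
  expect_true(all(lm$final_msd <= lm$initial_msd + 1e-12))
  expect_true(all(is.finite(fld$dx)) && all(is.finite(fld$dy)))
})

test_that("registration substantially recovers the phantom deformation", {
  p <- make_phantom_pair(tiny_spec(seed = 14))
  pre <- preprocess_pair(p$recent, p$prior)
  fld <- demons_register(pre$recent, pre$prior, mask = pre$mask$mask)
  msk <- p$breast_mask
  epe0 <- mean(sqrt(p$true_field$dx[msk]^2 + p$true_field$dy[msk]^2))
  epe <- mean_endpoint_error(fld, p$true_field, msk)
  expect_lt(epe, 0.5 * epe0)
})

test_that("warping obeys its interpolation contracts", {
  p <- make_phantom_pair(frozen_spec(seed = 15))
  px <- p$recent$pixels
  H <- nrow(px); W <- ncol(px)
  zero <- deformation_field(matrix(0, H, W), matrix(0, H, W))
  expect_lt(max(abs(warp(px, zero) - px)), 1e-6)

  # integer translation equals an array shift (out-of-bounds -> 0)
  shift <- deformation_field(matrix(2, H, W), matrix(0, H, W))
  shifted <- warp(px, shift)
  expect_equal(shifted[, 1:(W - 2)], px[, 3:W])
  expect_true(all(shifted[, (W - 1):W] == 0))

  # warp by f then -f approximately restores smooth images
  f <- p$true_field
  sm <- EBImage::gblur(px, 3)
  fwd <- deformation_field(matrix(1.5, H, W), matrix(-1, H, W))
  bwd <- deformation_field(-fwd$dx, -fwd$dy)
  inner <- 6:(H - 6)
  err <- abs(warp(warp(sm, fwd), bwd) - sm)[inner, 6:(W - 6)]
  expect_lt(mean(err), 0.02 * diff(range(sm)))
})

test_that("contract violations are rejected", {
  a <- matrix(runif(64), 8, 8)
  expect_error(demons_register(a, matrix(0.1, 4, 4)), "identical shape")
  b <- a; b[1, 1] <- NA
  expect_error(demons_register(a, b), "finite")
  expect_error(warp(a, deformation_field(matrix(0, 4, 4), matrix(0, 4, 4))),
               "identical shape")
  expect_error(deformation_field(matrix(0, 2, 2), matrix(0, 3, 3)), "congruent")
  expect_error(deformation_field(matrix(Inf, 2, 2), matrix(0, 2, 2)), "finite")
})
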