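#' Specification of a synthetic sequential mammogram pair
#'
#' Describes the study conditions emulated by the phantom generator: a
#' breast-shaped textured background imaged at two screening rounds.
#' Benign microcalcifications present in both rounds ("old") persist
#' from prior to recent; new findings appear only in the recent round,
#' with suspicious ones rendered smaller, irregular, and tightly
#' clustered, and benign ones larger, rounder, and scattered. Between
#' rounds the breast undergoes a smooth non-rigid deformation plus
#' independent noise and a mild global intensity drift.
#'
#' @param height,width Image size in pixels. The default 512 x 416 is
#'   1/8 of full-field digital mammography resolution (4096 x 3328) so
#'   that a full registration run takes seconds.
#' @param n_old_benign Number of benign microcalcifications present in
#'   BOTH rounds.
#' @param n_new_benign,n_new_suspicious Numbers of benign / suspicious
#'   microcalcifications present only in the recent round.
#' @param mc_amplitude Contrast of a microcalcification above its local
#'   background, on the unit intensity scale.
#' @param mc_radius_px Length-2 range of benign microcalcification radii
#'   in pixels; suspicious ones are drawn at half this radius.
#' @param deformation_amplitude_px Peak magnitude of the smooth
#'   inter-round displacement field, in pixels.
#' @param deformation_sigma_px Gaussian smoothness scale of the
#'   displacement field. Larger values give smoother, more recoverable
#'   warps.
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   applied independently to each round.
#' @param intensity_drift Fractional global intensity loss of the prior
#'   round relative to the recent one.
#' @param seed RNG seed; the pair is fully reproducible from the spec.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @export
phantom_spec <- function(height = 512L, width = 416L,
                         n_old_benign = 6L, n_new_benign = 2L,
                         n_new_suspicious = 6L,
                         mc_amplitude = 0.30,
                         mc_radius_px = c(2, 3.5),
                         deformation_amplitude_px = 6,
                         deformation_sigma_px = 32,
                         noise_sigma = 0.01,
                         intensity_drift = 0.02,
                         seed = 1L) {
  stopifnot(height > 0, width > 0)
  counts <- c(n_old_benign, n_new_benign, n_new_suspicious)
  if (any(counts < 0)) abort("Microcalcification counts must be >= 0.")
  if (deformation_amplitude_px < 0) abort("`deformation_amplitude_px` must be >= 0.")
  if (mc_amplitude <= 0 || mc_amplitude > 1) abort("`mc_amplitude` must lie in (0, 1].")
  if (length(mc_radius_px) != 2 || any(mc_radius_px <= 0)) {
    abort("`mc_radius_px` must be a positive length-2 range.")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_old_benign = as.integer(n_old_benign),
                 n_new_benign = as.integer(n_new_benign),
                 n_new_suspicious = as.integer(n_new_suspicious),
                 mc_amplitude = mc_amplitude, mc_radius_px = sort(mc_radius_px),
                 deformation_amplitude_px = deformation_amplitude_px,
                 deformation_sigma_px = deformation_sigma_px,
                 noise_sigma = noise_sigma, intensity_drift = intensity_drift,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Gaussian blur with the kernel capped to the image extent so small
## images remain usable.
gblur_capped <- function(x, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  m <- min(dim(x))
  if (r > m) r <- m - (1 - m %% 2)
  EBImage::gblur(x, sigma, radius = r)
}

## Smooth multi-scale blob texture on [lo, hi].
phantom_texture <- function(H, W, lo = 0.12, hi = 0.55) {
  tex <- matrix(0, H, W)
  for (s in c(4, 8, 16, 32)) {
    tex <- tex + gblur_capped(matrix(rnorm(H * W), H, W), s) * s
  }
  (tex - min(tex)) / (max(tex) - min(tex)) * (hi - lo) + lo
}

## Half-elliptical breast mask anchored to the left image edge.
phantom_breast_mask <- function(H, W, jitter = TRUE) {
  cy <- H / 2 + if (jitter) runif(1, -0.04, 0.04) * H else 0
  a <- (0.42 + if (jitter) runif(1, -0.02, 0.02) else 0) * H
  b <- (0.82 + if (jitter) runif(1, -0.02, 0.02) else 0) * W
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  q <- ((rr - cy) / a)^2 + ((cc - 1) / b)^2
  list(mask = q <= 1, q = q)
}

## Render one soft-edged bright spot, optionally an irregular perturbed
## ellipse, additively onto `canvas`. Returns the updated canvas.
render_spot <- function(canvas, row, col, radius, amplitude,
                        irregularity = 0, eccentricity = 0) {
  H <- nrow(canvas); W <- ncol(canvas)
  half <- ceiling(radius * 3 + 2)
  r0 <- max(1, round(row) - half); r1 <- min(H, round(row) + half)
  c0 <- max(1, round(col) - half); c1 <- min(W, round(col) + half)
  rr <- matrix(seq(r0, r1), r1 - r0 + 1, c1 - c0 + 1)
  cc <- matrix(seq(c0, c1), r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  theta <- runif(1, 0, pi)
  dy <- rr - row; dx <- cc - col
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  ax <- radius * (1 + eccentricity); bx <- radius / (1 + eccentricity)
  rho <- sqrt((u / ax)^2 + (v / bx)^2)  # 1 on the ellipse boundary
  if (irregularity > 0) {
    ang <- atan2(v, u)
    wig <- 0
    for (k in 2:4) wig <- wig + runif(1, -1, 1) * cos(k * ang + runif(1, 0, 2 * pi))
    rho <- rho * (1 + irregularity * wig / 3)
  }
  edge <- 0.6 / radius  # soft rim ~0.6 px wide in normalised units
  prof <- pmin(pmax((1 - rho) / edge, 0), 1)
  canvas[r0:r1, c0:c1] <- canvas[r0:r1, c0:c1] + amplitude * prof
  canvas
}

## Rejection-sample `n` spot centres inside the mask interior subject to
## a minimum pairwise spacing and exclusion discs.
place_points <- function(n, q, q_max = 0.72, spacing = 0, avoid = NULL,
                         avoid_radius = 0, max_tries = 4000) {
  H <- nrow(q); W <- ncol(q)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort(sprintf("Phantom generation error: cannot place %d microcalcifications with spacing %.1f px in the breast mask.", n, spacing))
    }
    r <- runif(1, 2, H - 1); c <- runif(1, 2, W - 1)
    if (q[ceiling(r), ceiling(c)] > q_max) next
    if (nrow(pts) > 0 && spacing > 0 &&
        min(sqrt((pts[, 1] - r)^2 + (pts[, 2] - c)^2)) < spacing) next
    if (!is.null(avoid) && nrow(avoid) > 0 &&
        min(sqrt((avoid[, 1] - r)^2 + (avoid[, 2] - c)^2)) < avoid_radius) next
    pts <- rbind(pts, c(r, c))
  }
  pts
}

## Smooth random displacement field with peak magnitude `amp`, plus its
## numerical inverse (fixed-point iteration).
phantom_field <- function(H, W, amp, sigma) {
  ux <- gblur_capped(matrix(rnorm(H * W), H, W), sigma)
  uy <- gblur_capped(matrix(rnorm(H * W), H, W), sigma)
  peak <- max(sqrt(ux^2 + uy^2))
  if (peak > 0 && amp > 0) {
    ux <- ux / peak * amp; uy <- uy / peak * amp
  } else {
    ux <- matrix(0, H, W); uy <- matrix(0, H, W)
  }
  tx <- -ux; ty <- -uy
  if (amp > 0) {
    for (k in 1:15) {
      tx <- -warp_bilinear(ux, tx, ty)
      ty <- -warp_bilinear(uy, tx, ty)
    }
  }
  list(ux = ux, uy = uy, tx = tx, ty = ty)
}

#' Generate a synthetic sequential mammogram pair with ground truth
#'
#' Builds the recent-round image (textured breast, persistent "old"
#' benign microcalcifications, plus newly appeared benign and suspicious
#' findings), then derives the prior round by removing the new findings
#' and warping with a smooth random deformation, adding noise and a
#' global intensity drift. The returned `true_field` is the displacement
#' field that maps the prior image back into the recent frame, i.e. the
#' field a registration algorithm should recover.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair` with elements `recent` and
#'   `prior` ([mammo_image()]s on the unit intensity scale), `truth`
#'   (tibble of microcalcification centres with `label` and `status`),
#'   `true_field` (a [deformation_field()]), `breast_mask` (logical
#'   matrix), and `spec`.
#' @export
#' @examples
#' pair <- make_phantom_pair(phantom_spec(height = 128, width = 104, seed = 3))
#' table(pair$truth$status)
make_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  bm <- phantom_breast_mask(H, W)
  clean <- phantom_texture(H, W) * bm$mask

  r_ben <- spec$mc_radius_px
  cluster_radius <- 10 * mean(r_ben)
  benign_spacing <- 5 * max(r_ben)

  ## Suspicious cluster centre first, then scattered benign points kept
  ## clear of the cluster so change signals do not overlap.
  cluster_centre <- if (spec$n_new_suspicious > 0) {
    place_points(1, bm$q, q_max = 0.6)
  } else {
    matrix(numeric(0), 0, 2)
  }
  n_ben <- spec$n_old_benign + spec$n_new_benign
  ben_pts <- place_points(n_ben, bm$q, spacing = benign_spacing,
                          avoid = cluster_centre,
                          avoid_radius = 2 * cluster_radius)

  truth <- list()
  add_truth <- function(row, col, label, status) {
    tibble(patient_id = "phantom", view = "CC", round = "recent",
           x = col - 1, y = row - 1, label = label, status = status)
  }

  ## old benign: into the clean (both-rounds) layer
  idx_old <- seq_len(spec$n_old_benign)
  for (i in idx_old) {
    r <- runif(1, r_ben[1], r_ben[2])
    clean <- render_spot(clean, ben_pts[i, 1], ben_pts[i, 2], r,
                         spec$mc_amplitude, irregularity = 0,
                         eccentricity = runif(1, 0, 0.15))
    truth[[length(truth) + 1]] <-
      add_truth(ben_pts[i, 1], ben_pts[i, 2], "benign", "old")
  }

  ## new findings: rendered only into the recent round
  new_layer <- matrix(0, H, W)
  if (spec$n_new_benign > 0) {
    for (i in spec$n_old_benign + seq_len(spec$n_new_benign)) {
      r <- runif(1, r_ben[1], r_ben[2])
      new_layer <- render_spot(new_layer, ben_pts[i, 1], ben_pts[i, 2], r,
                               spec$mc_amplitude, irregularity = 0,
                               eccentricity = runif(1, 0, 0.15))
      truth[[length(truth) + 1]] <-
        add_truth(ben_pts[i, 1], ben_pts[i, 2], "benign", "new")
    }
  }
  if (spec$n_new_suspicious > 0) {
    ## sample cluster members inside the cluster disc, the image frame,
    ## and the breast, with a minimal spread so spots stay resolvable
    draw_member <- function(existing) {
      for (t in 1:400) {
        a2 <- runif(1, 0, 2 * pi); rd <- cluster_radius * sqrt(runif(1))
        r <- cluster_centre[1, 1] + rd * sin(a2)
        c <- cluster_centre[1, 2] + rd * cos(a2)
        if (r < 3 || r > H - 2 || c < 3 || c > W - 2) next
        if (bm$q[ceiling(r), ceiling(c)] > 0.85) next
        if (nrow(existing) > 0 &&
            min(sqrt((existing[, 1] - r)^2 + (existing[, 2] - c)^2)) <
              2.5 * max(r_ben)) next
        return(c(r, c))
      }
      abort("Phantom generation error: cannot place the suspicious cluster inside the breast.")
    }
    sus_pts <- matrix(numeric(0), 0, 2)
    for (i in seq_len(spec$n_new_suspicious)) {
      sus_pts <- rbind(sus_pts, draw_member(sus_pts))
      r <- runif(1, r_ben[1] / 2, r_ben[2] / 2)
      new_layer <- render_spot(new_layer, sus_pts[i, 1], sus_pts[i, 2], r,
                               spec$mc_amplitude, irregularity = 0.5,
                               eccentricity = runif(1, 0.1, 0.5))
      truth[[length(truth) + 1]] <-
        add_truth(sus_pts[i, 1], sus_pts[i, 2], "suspicious", "new")
    }
  }
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble(patient_id = character(), view = character(), round = character(),
           x = numeric(), y = numeric(), label = character(), status = character())

  recent <- pmin(clean + new_layer, 1)

  fld <- phantom_field(H, W, spec$deformation_amplitude_px,
                       spec$deformation_sigma_px)
  prior <- if (spec$deformation_amplitude_px > 0) {
    warp_bilinear(clean, fld$tx, fld$ty)
  } else {
    clean
  }
  prior <- prior * (1 - spec$intensity_drift)
  if (spec$noise_sigma > 0) {
    recent <- recent + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    prior <- prior + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
  }
  recent <- pmin(pmax(recent, 0), 1)
  prior <- pmin(pmax(prior, 0), 1)

  structure(list(
    recent = mammo_image(recent, patient_id = "phantom", round = "recent"),
    prior = mammo_image(prior, patient_id = "phantom", round = "prior"),
    truth = truth,
    true_field = deformation_field(fld$ux, fld$uy),
    breast_mask = bm$mask,
    spec = spec
  ), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %d x %d, %d truth points (%d old / %d new), deformation %.1f px\n",
              nrow(x$recent$pixels), ncol(x$recent$pixels), nrow(x$truth),
              sum(x$truth$status == "old"), sum(x$truth$status == "new"),
              x$spec$deformation_amplitude_px))
  invisible(x)
}

#' Generate a labelled synthetic feature cohort
#'
#' Draws per-patient 96-dimensional feature vectors from two Gaussian
#' classes whose means differ by `class_separation` (in units of the
#' within-class standard deviation) along a random direction, with a
#' patient-level random effect so that patient-grouped cross-validation
#' is meaningfully different from row-wise splitting. Used to exercise
#' the classification harness without imaging.
#'
#' @param n_patients Number of patients (>= 2); class labels are
#'   assigned per patient, balanced.
#' @param class_separation Mahalanobis-type distance between the class
#'   means, in within-class standard deviations. 0 means no signal.
#' @param seed RNG seed.
#' @param n_per_patient Feature vectors (lesions) per patient.
#' @param patient_sd Standard deviation of the per-patient random
#'   offset.
#' @return A tibble with `patient_id`, `label`
#'   (`benign` / `suspicious`), and the 96 canonical feature columns.
#' @export
make_feature_cohort <- function(n_patients, class_separation, seed = 1L,
                                n_per_patient = 4L, patient_sd = 0.25) {
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  if (class_separation < 0) abort("`class_separation` must be >= 0.")
  set.seed(seed)
  p <- 96L
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  labels <- rep(c("benign", "suspicious"), length.out = n_patients)
  labels <- sample(labels)
  rows <- purrr::map_dfr(seq_len(n_patients), function(i) {
    offset <- rnorm(p, 0, patient_sd)
    mu <- (if (labels[i] == "suspicious") 0.5 else -0.5) * class_separation * dir
    vals <- matrix(rnorm(n_per_patient * p), n_per_patient, p) +
      matrix(mu + offset, n_per_patient, p, byrow = TRUE)
    colnames(vals) <- feature_names()
    dplyr::bind_cols(
      tibble(patient_id = sprintf("P%03d", i), label = labels[i]),
      as_tibble(vals)
    )
  })
  rows
}
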