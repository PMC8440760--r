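#' Run the temporal-subtraction pipeline on one image pair
#'
#' End-to-end single-pair processing: preprocessing of both rounds,
#' Demons registration of the prior onto the recent view, warping,
#' subtraction, and candidate detection. The recent-only comparison arm
#' (detection straight from the preprocessed recent image, skipping
#' registration and subtraction) is returned alongside.
#'
#' @param recent,prior The two rounds ([mammo_image()] or matrix).
#' @param gamma Preprocessing gamma.
#' @param params Registration parameters ([demons_params()]).
#' @param threshold,window,min_area,gap_close_radius Detection
#'   parameters (see [detect_candidates()]).
#' @return A list with `pre` (preprocessed pair + mask), `field`,
#'   `prior_warped`, `subtraction` (a `subtraction_result`), and
#'   candidate tibbles `candidates_subtracted`, `candidates_recent`.
#' @export
run_pair <- function(recent, prior, gamma = 2, params = demons_params(),
                     threshold = 0.2, window = 3, min_area = 4,
                     gap_close_radius = 1) {
  pre <- preprocess_pair(recent, prior, gamma = gamma)
  field <- demons_register(pre$recent, pre$prior, params = params,
                           mask = pre$mask$mask)
  prior_warped <- warp(pre$prior, field)
  sub <- subtract(pre$recent, prior_warped, pre$mask)
  cand_sub <- detect_candidates(sub$diff, mask = pre$mask,
                                threshold = threshold, window = window,
                                min_area = min_area,
                                gap_close_radius = gap_close_radius,
                                source = "subtracted")
  cand_rec <- detect_candidates(pre$recent, mask = pre$mask,
                                threshold = threshold, window = window,
                                min_area = min_area,
                                gap_close_radius = gap_close_radius,
                                source = "recent_only")
  list(pre = pre, field = field, prior_warped = prior_warped,
       subtraction = sub, candidates_subtracted = cand_sub,
       candidates_recent = cand_rec)
}

#' Pooled detection operating curve over labelled images
#'
#' Runs detection and greedy matching on every labelled image for every
#' threshold in `grid` and pools the counts, yielding the operating
#' curve from which an equal-sensitivity comparison between pipeline
#' arms can be read off.
#'
#' @param labelled List of elements with fields `img`, `annotations`,
#'   optional `mask`.
#' @param grid Thresholds to scan.
#' @param tol_px Matching tolerance.
#' @param ... Passed to [detect_candidates()].
#' @return Tibble with `threshold`, pooled `tp`, `fp`, `fn`, and
#'   `sensitivity` (percent).
#' @export
detection_curve <- function(labelled, grid, tol_px = 8, ...) {
  purrr::map_dfr(grid, function(th) {
    counts <- purrr::map_dfr(labelled, function(el) {
      cands <- detect_candidates(el$img, mask = el$mask, threshold = th, ...)
      mr <- match_candidates(cands, el$annotations, tol_px = tol_px)
      tibble(tp = mr$tp, fp = mr$fp, fn = mr$fn)
    })
    tibble(threshold = th, tp = sum(counts$tp), fp = sum(counts$fp),
           fn = sum(counts$fn),
           sensitivity = 100 * sum(counts$tp) / max(sum(counts$tp) + sum(counts$fn), 1))
  })
}

#' Highest threshold reaching a target sensitivity
#'
#' @param curve A [detection_curve()] tibble.
#' @param target_sensitivity Percent sensitivity the operating point
#'   must reach; if unreachable, the threshold with the highest
#'   sensitivity is returned.
#' @return One row of `curve`.
#' @export
operating_point <- function(curve, target_sensitivity = 90) {
  ok <- curve[curve$sensitivity >= target_sensitivity, ]
  if (nrow(ok) > 0) {
    ok[which.max(ok$threshold), ]
  } else {
    curve[which.max(curve$sensitivity), ]
  }
}

#' Registration / subtraction / detection study over phantom seeds
#'
#' Generates one phantom pair per seed, runs the full pipeline, and
#' collects per-seed quality metrics: endpoint error of the recovered
#' deformation against the generator's true field (and of the zero
#' field), contrast ratios before and after subtraction, intensity
#' reduction, and elimination accounting for old versus new
#' microcalcifications.
#'
#' @param seeds Integer vector of phantom seeds.
#' @param base_spec A [phantom_spec()] whose `seed` is replaced per run.
#' @param gamma,params,residual_frac_threshold,window_px Pipeline
#'   parameters.
#' @param keep_pairs Also return the per-seed pipeline outputs (memory
#'   heavy; needed for detection studies).
#' @return A list with `metrics` (tibble, one row per seed) and, when
#'   `keep_pairs`, `runs` (list of per-seed `list(pair, out)`).
#' @export
run_phantom_study <- function(seeds, base_spec = phantom_spec(),
                              gamma = 2, params = demons_params(),
                              residual_frac_threshold = 0.5, window_px = 5,
                              keep_pairs = FALSE) {
  runs <- list()
  metrics <- purrr::map_dfr(seeds, function(s) {
    spec <- base_spec; spec$seed <- as.integer(s)
    pair <- make_phantom_pair(spec)
    out <- run_pair(pair$recent, pair$prior, gamma = gamma, params = params)
    msk <- pair$breast_mask
    epe0 <- mean(sqrt(pair$true_field$dx[msk]^2 + pair$true_field$dy[msk]^2))
    epe <- mean_endpoint_error(out$field, pair$true_field, mask = msk)
    rs <- removal_stats(out$subtraction, out$pre$recent, pair$truth,
                        residual_frac_threshold = residual_frac_threshold,
                        window_px = window_px)
    if (keep_pairs) runs[[as.character(s)]] <<- list(pair = pair, out = out)
    tibble(seed = s,
           epe_zero_field = epe0, epe_registered = epe,
           epe_reduction_pct = if (epe0 > 0) 100 * (1 - epe / epe0) else NA_real_,
           contrast_ratio_recent = out$subtraction$contrast_ratio_recent,
           contrast_ratio_diff = out$subtraction$contrast_ratio_diff,
           intensity_reduction_pct = out$subtraction$intensity_reduction_pct,
           n_old = rs$n_prior_mcs, n_old_removed = rs$n_overlapping,
           n_new = rs$n_recent_mcs - rs$n_prior_mcs,
           n_new_removed = rs$n_new_removed)
  })
  out <- list(metrics = metrics)
  if (keep_pairs) out$runs <- runs
  out
}
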