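#' Build a patient-grouped cross-validation plan
#'
#' Leave-one-patient-out (LOPO) puts each patient's images alone in the
#' test fold; grouped k-fold partitions the patients (never individual
#' images) into `k` near-equal folds after a seeded shuffle. Either way
#' no patient ever appears on both sides of a split, which prevents the
#' optimistic bias of patient leakage.
#'
#' @param patient_ids Character vector of patient identifiers (>= 2
#'   unique values).
#' @param scheme `"lopo"` or `"grouped_kfold"`.
#' @param k Number of folds for `grouped_kfold`; must not exceed the
#'   number of patients.
#' @param seed Shuffle seed for `grouped_kfold`.
#' @return An object of class `cv_plan`: a tibble with one row per fold
#'   and list-columns `train` and `test` of patient ids.
#' @export
build_cv <- function(patient_ids, scheme = c("lopo", "grouped_kfold"),
                     k = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  ids <- unique(as.character(patient_ids))
  if (length(ids) < 2) abort("Need at least 2 patients to cross-validate.")
  folds <- if (scheme == "lopo") {
    purrr::map(ids, function(p) list(train = setdiff(ids, p), test = p))
  } else {
    if (is.null(k)) abort("`k` is required for grouped k-fold.")
    if (k > length(ids)) abort("`k` cannot exceed the number of patients.")
    if (k < 2) abort("`k` must be >= 2.")
    shuffled <- withr::with_seed(seed, sample(ids))
    assign_fold <- rep(seq_len(k), length.out = length(ids))
    purrr::map(seq_len(k), function(f) {
      test <- shuffled[assign_fold == f]
      list(train = setdiff(ids, test), test = test)
    })
  }
  plan <- tibble(fold = seq_along(folds),
                 train = purrr::map(folds, "train"),
                 test = purrr::map(folds, "test"))
  for (i in seq_len(nrow(plan))) {
    stopifnot(length(intersect(plan$train[[i]], plan$test[[i]])) == 0)
  }
  class(plan) <- c("cv_plan", class(plan))
  plan
}
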