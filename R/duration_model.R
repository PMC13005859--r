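#' Cross-validated SVR prediction of video duration from event counts
#'
#' Fits a support-vector regression of the true video duration on the
#' accumulated salient-event count of a single network, under k-fold
#' cross-validation at the trial level: trials are shuffled (seeded) into
#' k folds, each fold is predicted by a model trained on the other k - 1,
#' and the out-of-fold predictions are pooled so that no trial is ever
#' predicted by a model that saw it. The feature is standardized with
#' training-fold statistics.
#'
#' @param counts Integer vector of per-trial event counts for one network,
#'   or a trials x networks matrix for the joint all-networks model (one
#'   standardized feature per column).
#' @param durations Numeric vector of true durations (seconds), same
#'   length and order as `counts`.
#' @param meta Data frame with columns `subject`, `trial`, `scene`
#'   aligned with `counts`.
#' @param k Number of folds (default 10).
#' @param svr_config List of e1071 SVR settings: `kernel` (default
#'   `"radial"`), `cost` (1), `epsilon` (0.1), `gamma` (1 for the single
#'   standardized feature).
#' @param seed Integer seed for the fold shuffle.
#' @param network Network id carried into the result.
#' @return Object of class `duration_predictions`: data frame with
#'   columns subject, trial, scene, network, true_duration_s,
#'   predicted_duration_s, fold.
#' @export
fit_predict_duration_cv <- function(counts, durations, meta, k = 10,
                                    svr_config = list(), seed = 1L,
                                    network = NA_character_) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(length(durations) == n, nrow(meta) == n)
  assert_columns(meta, c("subject", "trial", "scene"), "meta")
  if (any(counts < 0)) stop_("event counts must be non-negative")
  if (k > n) stop_("k = %d folds but only %d trials", k, n)
  if (is.na(network) && ncol(counts) > 1) network <- "joint"
  cfg <- utils::modifyList(list(kernel = "radial", cost = 1, epsilon = 0.1,
                                gamma = 1 / ncol(counts)), svr_config)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    mu <- colMeans(counts[tr, , drop = FALSE])
    sdev <- apply(counts[tr, , drop = FALSE], 2, sd)
    sdev[!is.finite(sdev) | sdev == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, mu), 2, sdev, "/")
    fit <- e1071::svm(x = std(counts[tr, , drop = FALSE]),
                      y = durations[tr], type = "eps-regression",
                      kernel = cfg$kernel, cost = cfg$cost,
                      epsilon = cfg$epsilon, gamma = cfg$gamma,
                      scale = FALSE)
    pred[!tr] <- predict(fit, std(counts[!tr, , drop = FALSE]))
  }
  out <- data.frame(subject = meta$subject, trial = meta$trial,
                    scene = meta$scene, network = network,
                    true_duration_s = durations,
                    predicted_duration_s = pred, fold = folds,
                    stringsAsFactors = FALSE)
  class(out) <- c("duration_predictions", "data.frame")
  out
}

#' Normalized bias of model-predicted durations
#'
#' Applies the normalized-bias definition to SVR-predicted durations in
#' place of human reports: for each subject and true-duration category,
#' the category mean of the predictions is the reference.
#'
#' @param preds A `duration_predictions` table.
#' @return A `bias_table` (see [normalized_bias()]).
#' @export
model_bias <- function(preds) {
  assert_columns(preds, c("subject", "trial", "scene", "true_duration_s",
                          "predicted_duration_s"), "predictions")
  normalized_bias(data.frame(subject = preds$subject, trial = preds$trial,
                             duration_category_s = preds$true_duration_s,
                             scene = preds$scene,
                             value_s = preds$predicted_duration_s,
                             stringsAsFactors = FALSE))
}
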