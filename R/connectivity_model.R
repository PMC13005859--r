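#' Edge index map for upper-triangular connectivity vectors
#'
#' Fixed row-major ordering of the region pairs (i < j):
#' (1,2), (1,3), ..., (1,p), (2,3), ... so that saved coefficient
#' vectors are portable across runs.
#'
#' @param p Number of regions.
#' @param region_ids Optional region id labels.
#' @return Data frame with `edge_id`, `i`, `j` and, when labels are
#'   given, `region_i`, `region_j`; `p * (p - 1) / 2` rows.
#' @export
fc_edge_index <- function(p, region_ids = NULL) {
  idx <- t(utils::combn(p, 2))
  out <- data.frame(edge_id = seq_len(nrow(idx)), i = idx[, 1], j = idx[, 2])
  if (!is.null(region_ids)) {
    out$region_i <- region_ids[out$i]
    out$region_j <- region_ids[out$j]
  }
  out
}

#' Trial-wise functional connectivity vector
#'
#' Pearson correlation between every pair of regional time-series within
#' one trial window, returned as the upper triangle in the fixed
#' row-major (i < j) order of [fc_edge_index()]. For p regions the vector
#' has p(p-1)/2 entries (64620 edges at 360 regions).
#'
#' @param trial A `trial_series` (or a plain regions x timepoints matrix).
#' @param regions Optional subset of region ids to restrict to (e.g. the
#'   visual network).
#' @return Object of class `fc_vector`: list with `values`, `edge_index`,
#'   `subject`, `trial`.
#' @export
trial_fc <- function(trial, regions = NULL) {
  if (inherits(trial, "trial_series")) {
    X <- trial$X; subject <- trial$subject; tid <- trial$trial
  } else {
    X <- trial; subject <- NA_character_; tid <- NA_character_
  }
  if (!is.null(regions)) {
    present <- intersect(regions, rownames(X))
    if (length(present) == 0) stop_("none of the requested regions present")
    X <- X[present, , drop = FALSE]
  }
  if (ncol(X) < 3) stop_("need at least 3 timepoints for trial FC, got %d",
                         ncol(X))
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(X)[sds == 0] %||% which(sds == 0)
    stop_("constant time-series in region(s): %s",
          paste(head(bad, 5), collapse = ", "))
  }
  C <- cor(t(X))
  ei <- fc_edge_index(nrow(X), rownames(X))
  structure(list(values = C[cbind(ei$i, ei$j)], edge_index = ei,
                 subject = subject, trial = tid), class = "fc_vector")
}

# stack FC vectors of a cohort into a trials x edges matrix
#' Functional-connectivity feature matrix for a cohort
#'
#' @param cohort A `bold_cohort` with series.
#' @param regions Optional region subset passed to [trial_fc()].
#' @return List with `fc` (trials x edges matrix), `meta` (subject,
#'   trial, scene, duration_s), `edge_index`.
#' @export
cohort_fc <- function(cohort, regions = NULL) {
  stopifnot(!is.null(cohort$trials))
  vecs <- lapply(cohort$trials, trial_fc, regions = regions)
  fc <- do.call(rbind, lapply(vecs, `[[`, "values"))
  meta <- cohort$behavior[, c("subject", "trial", "scene", "duration_s")]
  rownames(fc) <- paste(meta$subject, meta$trial, sep = "/")
  list(fc = fc, meta = meta, edge_index = vecs[[1]]$edge_index)
}

#' Elastic-net hyperparameter specification
#'
#' Grids for the mixing parameter alpha (L1 vs squared-L2 balance) and
#' the overall penalty lambda; 10 uniformly spaced values each by
#' default, alpha over `[0.1, 1]` and lambda over `[0.01, 1]`.
#'
#' @param alpha_grid,lambda_grid Numeric grids.
#' @param inner_folds Subject-grouped folds for the inner hyperparameter
#'   search inside [loso_predict()] (default 3).
#' @return Object of class `elastic_net_spec`.
#' @export
elastic_net_spec <- function(alpha_grid = seq(0.1, 1, length.out = 10),
                             lambda_grid = seq(0.01, 1, length.out = 10),
                             inner_folds = 3) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1), all(lambda_grid >= 0),
            inner_folds >= 2)
  structure(list(alpha_grid = alpha_grid, lambda_grid = lambda_grid,
                 inner_folds = as.integer(inner_folds)),
            class = "elastic_net_spec")
}

#' Fit an elastic net at a single (alpha, lambda)
#'
#' Minimizes
#' \deqn{\frac{1}{2N}\sum_i (y_i - x_i^\top\beta)^2 +
#'   \lambda(\alpha\|\beta\|_1 + \tfrac12(1-\alpha)\|\beta\|_2^2)}
#' via glmnet's coordinate descent along a decreasing lambda path ending
#' at the requested value. Features are standardized with the supplied
#' (training) statistics before fitting; coefficients are returned on the
#' standardized scale together with the centering/scaling used.
#'
#' @param X Trials x features matrix.
#' @param y Response vector.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param lam Penalty `>= 0` (`0` recovers ordinary least squares).
#' @param center,scale Optional feature statistics; default: computed
#'   from `X`.
#' @return Object of class `enet_fit`: list with `beta` (standardized
#'   scale), `intercept`, `alpha`, `lambda`, `center`, `scale`.
#' @export
elastic_net_fit <- function(X, y, alpha, lam, center = NULL, scale = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_("non-finite values in X or y")
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / (n * max(alpha, 1e-3))
  lmax <- max(lmax, lam * 1.01, 1e-4)
  path <- exp(seq(log(lmax), log(max(lam, lmax * 1e-6, 1e-8)),
                  length.out = 60))
  path <- sort(unique(c(path, lam)), decreasing = TRUE)
  fit <- glmnet::glmnet(Xs, y, alpha = alpha, lambda = path,
                        standardize = FALSE, thresh = 1e-12)
  at <- which.min(abs(fit$lambda - lam))
  structure(list(beta = as.numeric(fit$beta[, at]),
                 intercept = as.numeric(fit$a0[at]), alpha = alpha,
                 lambda = lam, center = center, scale = scale),
            class = "enet_fit")
}

#' Predict from an elastic-net fit
#'
#' @param object An `enet_fit`.
#' @param newdata Trials x features matrix on the original scale.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.enet_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  drop(Xs %*% object$beta) + object$intercept
}

# Eq-16 objective, used by tests and the inner search
enet_objective <- function(X, y, beta, intercept, alpha, lam) {
  n <- nrow(X)
  rss <- sum((y - drop(X %*% beta) - intercept)^2)
  rss / (2 * n) + lam * (alpha * sum(abs(beta)) +
                           0.5 * (1 - alpha) * sum(beta^2))
}

# assign subjects to k groups, balanced, deterministic given seed
.subject_folds <- function(subjects, k, seed) {
  u <- unique(subjects)
  g <- withr::with_seed(seed, sample(rep_len(seq_len(k), length(u))))
  g[match(subjects, u)]
}

#' Leave-one-subject-out elastic-net prediction
#'
#' For each held-out subject, hyperparameters are selected by a nested
#' subject-grouped grid search on the training subjects only (minimizing
#' inner-CV mean squared error over the alpha x lambda grid), the model
#' is refit on all training subjects at the selected pair, and the
#' held-out subject's trials are predicted. Feature standardization
#' always uses training-fold statistics.
#'
#' @param fc Trials x features matrix.
#' @param meta Data frame with `subject`, `trial` aligned with `fc` rows.
#' @param y Response vector (normalized bias or duration).
#' @param spec An [elastic_net_spec()].
#' @param seed Integer seed (inner fold assignment).
#' @return List with `predictions` (data frame subject, trial, truth,
#'   prediction, fold, alpha, lambda), `r2` (pooled coefficient of
#'   determination of the out-of-subject predictions), `chosen` (per-fold
#'   hyperparameters).
#' @export
loso_predict <- function(fc, meta, y, spec = elastic_net_spec(), seed = 1L) {
  stopifnot(nrow(fc) == length(y), nrow(meta) == length(y))
  subjects <- unique(meta$subject)
  if (length(subjects) < 2) stop_("leave-one-subject-out needs >= 2 subjects")
  preds <- vector("list", length(subjects))
  chosen <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    test <- meta$subject == subjects[si]
    Xtr <- fc[!test, , drop = FALSE]; ytr <- y[!test]
    sub_tr <- meta$subject[!test]
    k <- min(spec$inner_folds, length(unique(sub_tr)))
    inner <- .subject_folds(sub_tr, k, derive_seed(seed, si))
    cv_mse <- matrix(Inf, length(spec$alpha_grid), length(spec$lambda_grid))
    for (ai in seq_along(spec$alpha_grid)) {
      errs <- matrix(0, k, length(spec$lambda_grid))
      for (f in seq_len(k)) {
        itr <- inner != f
        ctr <- colMeans(Xtr[itr, , drop = FALSE])
        sc <- apply(Xtr[itr, , drop = FALSE], 2, sd)
        sc[!is.finite(sc) | sc == 0] <- 1
        Xs <- sweep(sweep(Xtr[itr, , drop = FALSE], 2, ctr), 2, sc, "/")
        Xv <- sweep(sweep(Xtr[!itr, , drop = FALSE], 2, ctr), 2, sc, "/")
        fit <- glmnet::glmnet(Xs, ytr[itr], alpha = spec$alpha_grid[ai],
                              lambda = sort(spec$lambda_grid,
                                            decreasing = TRUE),
                              standardize = FALSE, thresh = 1e-9)
        pv <- predict(fit, Xv)
        cols <- vapply(spec$lambda_grid,
                       function(l) which.min(abs(fit$lambda - l)), integer(1))
        errs[f, ] <- colMeans((pv[, cols, drop = FALSE] - ytr[!itr])^2)
      }
      cv_mse[ai, ] <- colMeans(errs)
    }
    best <- which(cv_mse == min(cv_mse), arr.ind = TRUE)[1, ]
    a_best <- spec$alpha_grid[best[1]]
    l_best <- spec$lambda_grid[best[2]]
    fit <- elastic_net_fit(Xtr, ytr, a_best, l_best)
    preds[[si]] <- data.frame(subject = meta$subject[test],
                              trial = meta$trial[test], truth = y[test],
                              prediction = predict(fit, fc[test, , drop = FALSE]),
                              fold = si, alpha = a_best, lambda = l_best,
                              stringsAsFactors = FALSE)
    chosen[[si]] <- data.frame(subject = subjects[si], alpha = a_best,
                               lambda = l_best,
                               inner_mse = min(cv_mse))
  }
  out <- do.call(rbind, preds)
  ss_res <- sum((out$truth - out$prediction)^2)
  ss_tot <- sum((out$truth - mean(out$truth))^2)
  list(predictions = out, r2 = 1 - ss_res / ss_tot,
       chosen = do.call(rbind, chosen))
}

#' Random-window control features
#'
#' For each real trial, samples a uniformly random contiguous window of
#' the same length from the subject's concatenated block series and
#' computes its FC vector. Prediction performance from these
#' task-unrelated windows isolates the trial-length confound: any
#' accuracy they retain is attributable to window length, not to
#' trial-locked dynamics.
#'
#' @param cohort A `bold_cohort` with series.
#' @param regions Optional region subset.
#' @param seed Integer seed (windows are deterministic given it).
#' @return Same shape as [cohort_fc()], plus `windows` (start index and
#'   length per pseudo-trial).
#' @export
random_window_control <- function(cohort, regions = NULL, seed = 1L) {
  stopifnot(!is.null(cohort$trials))
  b <- cohort$behavior
  subjects <- unique(b$subject)
  blocks <- lapply(setNames(subjects, subjects), function(s) {
    do.call(cbind, lapply(cohort$trials[b$subject == s], `[[`, "X"))
  })
  rows <- vector("list", length(cohort$trials))
  winfo <- vector("list", length(cohort$trials))
  ei <- NULL
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    block <- blocks[[tr$subject]]
    len <- tr$n_timepoints
    if (len > ncol(block))
      stop_("trial %s/%s longer than its subject's block", tr$subject, tr$trial)
    start <- withr::with_seed(derive_seed(seed, i),
                              sample.int(ncol(block) - len + 1, 1))
    win <- block[, start:(start + len - 1), drop = FALSE]
    v <- trial_fc(win, regions = regions)
    rows[[i]] <- v$values
    ei <- ei %||% v$edge_index
    winfo[[i]] <- data.frame(subject = tr$subject, trial = tr$trial,
                             start = start, length = len)
  }
  fc <- do.call(rbind, rows)
  meta <- b[, c("subject", "trial", "scene", "duration_s")]
  rownames(fc) <- paste(meta$subject, meta$trial, sep = "/")
  list(fc = fc, meta = meta, edge_index = ei,
       windows = do.call(rbind, winfo))
}

#' Duration-to-bias reconstruction pipeline on FC features
#'
#' Predicts trial duration from trial-wise FC with the leave-one-subject-
#' out elastic net, converts the predictions to a model normalized bias,
#' and tests the association with the human bias (OLS with one-tailed
#' inference on the slope) together with the mixed-model scene-effect
#' test on the model bias.
#'
#' @param cohort A `bold_cohort` with series.
#' @param spec An [elastic_net_spec()].
#' @param regions Optional region subset (e.g. visual network only).
#' @param seed Integer seed.
#' @return List with `duration_fit` (the [loso_predict()] result),
#'   `model_bias` (bias table), `regression` (a `bias_regression`),
#'   `scene_lrt` (an `lrt_result`).
#' @export
fc_duration_bias_pipeline <- function(cohort, spec = elastic_net_spec(),
                                      regions = NULL, seed = 1L) {
  feats <- cohort_fc(cohort, regions = regions)
  fit <- loso_predict(feats$fc, feats$meta, feats$meta$duration_s,
                      spec = spec, seed = seed)
  p <- fit$predictions
  scene <- feats$meta$scene[match(paste(p$subject, p$trial, sep = "/"),
                                  paste(feats$meta$subject, feats$meta$trial,
                                        sep = "/"))]
  mb <- normalized_bias(data.frame(subject = p$subject, trial = p$trial,
                                   duration_category_s = p$truth,
                                   scene = scene, value_s = p$prediction,
                                   stringsAsFactors = FALSE))
  hb <- human_bias(cohort)
  list(duration_fit = fit, model_bias = mb,
       regression = bias_regression(hb, mb),
       scene_lrt = scene_effect_lrt(mb))
}
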