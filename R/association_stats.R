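#' Likelihood-ratio test of the scene effect on bias
#'
#' Fits the random-intercept mixed model
#' `bias ~ 1 + scene + (1 | subject)` by maximum likelihood and compares
#' it against the reduced model without the scene fixed effect with a
#' chi-squared likelihood-ratio test on 1 degree of freedom. Scene is
#' coded with office as the reference level, so the fixed-effect estimate
#' is the city - office bias difference.
#'
#' @param bias A `bias_table` with columns `subject`, `scene`, `bias`.
#' @param alpha Significance level used only for the reported decision
#'   (default 0.05).
#' @return Object of class `lrt_result`: list with `bias_difference`
#'   (scene fixed-effect estimate), `se`, `ci95`, `chisq`, `df`,
#'   `pvalue`, `significant`, `singular` (TRUE when the random-intercept
#'   variance fit is singular), and the two fitted models.
#' @export
scene_effect_lrt <- function(bias, alpha = 0.05) {
  assert_columns(bias, c("subject", "scene", "bias"), "bias table")
  scenes <- unique(bias$scene)
  if (length(scenes) < 2) stop_("both scenes required; found: %s",
                                paste(scenes, collapse = ", "))
  if (length(unique(bias$subject)) < 2) stop_("at least 2 participants required")
  d <- data.frame(bias = bias$bias,
                  scene = factor(bias$scene, levels = c("office", "city")),
                  subject = factor(bias$subject))
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(bias ~ scene + (1 | subject), data = d, REML = FALSE)))
  reduced <- suppressMessages(suppressWarnings(
    lme4::lmer(bias ~ 1 + (1 | subject), data = d, REML = FALSE)))
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  fe <- summary(full)$coefficients
  est <- fe["scenecity", "Estimate"]
  se <- fe["scenecity", "Std. Error"]
  structure(list(bias_difference = est, se = se,
                 ci95 = est + c(-1, 1) * qnorm(0.975) * se,
                 chisq = chisq, df = 1L, pvalue = p,
                 significant = p < alpha,
                 singular = lme4::isSingular(full) || lme4::isSingular(reduced),
                 model_full = full, model_reduced = reduced),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Scene effect on bias: %.3f +/- %.3f [%.3f, %.3f], chisq(1) = %.2f, p = %.3g%s\n",
              x$bias_difference, x$se, x$ci95[1], x$ci95[2], x$chisq,
              x$pvalue, if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' Regression of human bias on model bias
#'
#' Ordinary least squares of `bias_human ~ beta0 + beta1 * bias_model`
#' pooled over trials, with a one-tailed p-value for the directional
#' hypothesis beta1 > 0 (upper tail of the t statistic).
#'
#' @param human,model `bias_table`s aligned on (subject, trial).
#' @return Object of class `bias_regression`: list with `beta0`, `beta1`,
#'   `se1`, `t1`, `p_one_tailed`, `pearson_r`, `n`.
#' @export
bias_regression <- function(human, model) {
  assert_columns(human, c("subject", "trial", "bias"), "human bias table")
  assert_columns(model, c("subject", "trial", "bias"), "model bias table")
  key_h <- paste(human$subject, human$trial, sep = "/")
  key_m <- paste(model$subject, model$trial, sep = "/")
  miss_m <- setdiff(key_h, key_m)
  miss_h <- setdiff(key_m, key_h)
  if (length(miss_m) || length(miss_h))
    stop_("bias tables are misaligned; missing from model: %s; missing from human: %s",
          paste(head(miss_m, 5), collapse = ", ") %||% "",
          paste(head(miss_h, 5), collapse = ", ") %||% "")
  m <- model$bias[match(key_h, key_m)]
  h <- human$bias
  if (sd(m) == 0) {
    res <- list(beta0 = mean(h), beta1 = NA_real_, se1 = NA_real_,
                t1 = NA_real_, p_one_tailed = NA_real_,
                pearson_r = NA_real_, n = length(h),
                degenerate = "model bias has zero variance")
    class(res) <- "bias_regression"
    return(res)
  }
  fit <- lm(h ~ m)
  sm <- summary(fit)$coefficients
  t1 <- sm["m", "t value"]
  res <- list(beta0 = sm["(Intercept)", "Estimate"],
              beta1 = sm["m", "Estimate"], se1 = sm["m", "Std. Error"],
              t1 = t1,
              p_one_tailed = pt(t1, df = fit$df.residual, lower.tail = FALSE),
              pearson_r = cor(h, m), n = length(h), degenerate = NULL)
  class(res) <- "bias_regression"
  res
}

#' @export
print.bias_regression <- function(x, ...) {
  if (!is.null(x$degenerate)) {
    cat(sprintf("Bias regression degenerate: %s (n = %d)\n", x$degenerate, x$n))
  } else {
    cat(sprintf("bias_human ~ %.4f + %.4f x bias_model; one-tailed p(beta1 > 0) = %.3g, r = %.3f, n = %d\n",
                x$beta0, x$beta1, x$p_one_tailed, x$pearson_r, x$n))
  }
  invisible(x)
}

#' Criterion-parameter grid specification
#'
#' Axes for the robustness sweep over the salience-criterion parameters:
#' `theta_min` takes `n_min` linearly spaced values between 3 SD and 0 SD
#' below the mean, `theta_max` independently `n_max` values between 0 and
#' 2.5 SD above the mean; 50 x 50 = 2500 cells by default.
#'
#' @param n_min,n_max Number of grid values per axis (default 50 each).
#' @param theta_min_range,theta_max_range Axis ranges.
#' @return List with `theta_min_axis`, `theta_max_axis`, `cells` (data
#'   frame of all combinations with a `cell` index).
#' @export
criterion_grid <- function(n_min = 50, n_max = 50,
                           theta_min_range = c(-3, 0),
                           theta_max_range = c(0, 2.5)) {
  tmin <- seq(theta_min_range[1], theta_min_range[2], length.out = n_min)
  tmax <- seq(theta_max_range[1], theta_max_range[2], length.out = n_max)
  cells <- expand.grid(theta_min = tmin, theta_max = tmax,
                       KEEP.OUT.ATTRS = FALSE)
  cells$cell <- seq_len(nrow(cells))
  list(theta_min_axis = tmin, theta_max_axis = tmax, cells = cells)
}

# one robustness cell for one network: events -> SVR -> model bias -> regression
.robustness_cell <- function(zseries, meta, durations, human, theta_min,
                             theta_max, base_params, cell_seed, k, svr_config) {
  params <- criterion_params(theta_min = theta_min, theta_max = theta_max,
                             noise_variance = base_params$noise_variance,
                             formula_variant = base_params$formula_variant,
                             seed = cell_seed)
  counts <- vapply(seq_along(zseries), function(i) {
    p_i <- params
    p_i$seed <- derive_seed(cell_seed, 0, i)
    count_salient_events(zseries[[i]], p_i)$count
  }, integer(1))
  preds <- fit_predict_duration_cv(counts, durations, meta, k = k,
                                   svr_config = svr_config, seed = cell_seed)
  reg <- bias_regression(human, model_bias(preds))
  list(p = reg$p_one_tailed, r = reg$pearson_r)
}

#' Robustness sweep of the event-accumulation pipeline over criterion
#' parameters
#'
#' For every (theta_min, theta_max) cell of the grid and every network,
#' reruns the full accumulation pipeline -- salient-event counting with
#' the cell's criterion, cross-validated SVR duration prediction, model
#' bias, and the regression of human bias on model bias -- and records
#' the one-tailed p-value and Pearson correlation. Each cell uses an RNG
#' seed derived deterministically from `(seed, network, cell)`, so any
#' cell can be recomputed in isolation and reproduces its stored value.
#'
#' @param trials List of `trial_series`.
#' @param network_map Region -> network map.
#' @param human_bias A `bias_table` of human reports for the same trials.
#' @param grid A [criterion_grid()].
#' @param networks Networks to sweep (default: all present in the map).
#' @param noise_variance,formula_variant Criterion settings shared by all
#'   cells (defaults 0.05, `"sum"`).
#' @param zscope Z-scoring scope for the change series, `"trial"` or
#'   `"pool"` (see [accumulate_events()]).
#' @param k SVR cross-validation folds (default 10).
#' @param svr_config Passed to [fit_predict_duration_cv()].
#' @param alpha Significance level for the summary fraction (default 0.05).
#' @param seed Base seed.
#' @return Object of class `robustness_grid`: list with `results` (long
#'   data frame network, cell, theta_min, theta_max, pvalue, pearson_r),
#'   `pvalue_matrices` (per network, theta_min x theta_max),
#'   `significant_fraction` (named vector), `pearson_significant` (list
#'   of r values over significant cells), `grid`, `alpha`, `seed`.
#' @export
robustness_grid <- function(trials, network_map, human_bias,
                            grid = criterion_grid(), networks = NULL,
                            noise_variance = 0.05,
                            formula_variant = "sum", zscope = "trial",
                            k = 10, svr_config = list(), alpha = 0.05,
                            seed = 1L) {
  nets <- networks %||% intersect(network_names(), unique(network_map))
  durations <- vapply(trials, function(t) t$duration_s, numeric(1))
  meta <- data.frame(subject = vapply(trials, `[[`, "", "subject"),
                     trial = vapply(trials, `[[`, "", "trial"),
                     scene = vapply(trials, `[[`, "", "scene"),
                     stringsAsFactors = FALSE)
  base <- criterion_params(noise_variance = noise_variance,
                           formula_variant = formula_variant, seed = seed)
  rows <- vector("list", length(nets) * nrow(grid$cells))
  ri <- 0
  pmats <- list()
  for (ni in seq_along(nets)) {
    zseries <- network_zseries(trials, regions_of(network_map, nets[ni]),
                               nets[ni], zscope)
    pm <- matrix(NA_real_, length(grid$theta_min_axis),
                 length(grid$theta_max_axis),
                 dimnames = list(signif(grid$theta_min_axis, 4),
                                 signif(grid$theta_max_axis, 4)))
    for (ci in seq_len(nrow(grid$cells))) {
      ri <- ri + 1
      tmin <- grid$cells$theta_min[ci]
      tmax <- grid$cells$theta_max[ci]
      cell_seed <- derive_seed(seed, ci, ni)
      cell <- tryCatch(
        .robustness_cell(zseries, meta, durations, human_bias, tmin, tmax,
                         base, cell_seed, k, svr_config),
        error = function(e) list(p = NA_real_, r = NA_real_,
                                 error = conditionMessage(e)))
      pm[match(tmin, grid$theta_min_axis),
         match(tmax, grid$theta_max_axis)] <- cell$p
      rows[[ri]] <- data.frame(network = nets[ni], cell = ci,
                               theta_min = tmin, theta_max = tmax,
                               pvalue = cell$p, pearson_r = cell$r,
                               failed = !is.null(cell$error),
                               stringsAsFactors = FALSE)
    }
    pmats[[nets[ni]]] <- pm
  }
  results <- do.call(rbind, rows)
  sig_frac <- vapply(nets, function(nw) {
    p <- results$pvalue[results$network == nw]
    mean(!is.na(p) & p < alpha)
  }, numeric(1))
  pearson_sig <- lapply(setNames(nets, nets), function(nw) {
    sub <- results[results$network == nw, ]
    sub$pearson_r[!is.na(sub$pvalue) & sub$pvalue < alpha]
  })
  structure(list(results = results, pvalue_matrices = pmats,
                 significant_fraction = sig_frac,
                 pearson_significant = pearson_sig, grid = grid,
                 alpha = alpha, seed = seed),
            class = "robustness_grid")
}

#' Heat map of robustness-grid p-values
#'
#' @param rg A `robustness_grid`.
#' @param network Network to plot.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted p-value matrix.
#' @export
robustness_heatmap <- function(rg, network, ...) {
  pm <- rg$pvalue_matrices[[network]]
  if (is.null(pm)) stop_("no grid results for network '%s'", network)
  graphics::image(x = rg$grid$theta_min_axis, y = rg$grid$theta_max_axis,
                  z = pm, xlab = "theta_min (SD)", ylab = "theta_max (SD)",
                  main = sprintf("one-tailed p for beta1 (%s)", network), ...)
  invisible(pm)
}
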