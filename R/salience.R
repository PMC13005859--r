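#' Network BOLD change series
#'
#' The change statistic for a functional network is the frame-to-frame
#' difference of the BOLD signal summed over the network's regions:
#' \deqn{\Delta_{TP} = \sum_v (X_{TP,v} - X_{TP-1,v}), \quad TP = 2..n}
#' which telescopes to the first difference of the network-summed series.
#'
#' @param trial A `trial_series`.
#' @param network_regions Character vector of region ids forming the
#'   network; must intersect the trial's region set.
#' @param network Optional network id carried into the result.
#' @return Object of class `change_series`: list with `values` (length
#'   `n_timepoints - 1`), `zvalues` (`NULL` until [zscore_changes()]),
#'   `network`, `subject`, `trial`.
#' @export
network_change_series <- function(trial, network_regions, network = NA_character_) {
  stopifnot(inherits(trial, "trial_series"))
  present <- intersect(network_regions, rownames(trial$X))
  if (length(present) == 0)
    stop_("no region of the requested network is present in trial %s/%s",
          trial$subject, trial$trial)
  summed <- colSums(trial$X[present, , drop = FALSE])
  structure(list(values = diff(summed), zvalues = NULL, network = network,
                 subject = trial$subject, trial = trial$trial),
            class = "change_series")
}

#' Z-score a change series
#'
#' Standardizes the change values either within the trial (default) or
#' against externally supplied pooled statistics (e.g. pooled over all of
#' a subject's trials). The sample SD (denominator n - 1) is used.
#'
#' @param series A `change_series`.
#' @param scope `"trial"` (mean/SD of this series) or `"pool"` (use
#'   `pool_mean` / `pool_sd`).
#' @param pool_mean,pool_sd Pooled statistics, required for
#'   `scope = "pool"`.
#' @return The series with `zvalues` filled in.
#' @export
zscore_changes <- function(series, scope = c("trial", "pool"),
                           pool_mean = NULL, pool_sd = NULL) {
  stopifnot(inherits(series, "change_series"))
  scope <- match.arg(scope)
  if (scope == "trial") {
    m <- mean(series$values)
    s <- sd(series$values)
  } else {
    if (is.null(pool_mean) || is.null(pool_sd))
      stop_("pool scope requires pool_mean and pool_sd")
    m <- pool_mean
    s <- pool_sd
  }
  if (!is.finite(s) || s <= 0)
    stop_("zero or undefined SD of change values in trial %s/%s; cannot z-score",
          series$subject, series$trial)
  series$zvalues <- (series$values - m) / s
  series
}

#' Salience criterion parameters
#'
#' Parameters of the dynamic detection threshold
#' \deqn{\vartheta(t) = (\vartheta_{max} + \vartheta_{min}) e^{-t} +
#'   \vartheta_{min} + \varepsilon, \quad \varepsilon \sim N(0, 0.05)}
#' where t counts TRs since the trial start or the last detected event
#' (the threshold resets to its t = 0 value after each detection).
#' `theta_min` and `theta_max` are in SD units of the z-scored change
#' series: standard deviations below and above the mean respectively.
#' The default values (-1, 1.5) are the layer-1 perceptual-hierarchy
#' parameters.
#'
#' Two algebraic variants are provided. `"sum"` uses the decay factor
#' `(theta_max + theta_min)`, so with the defaults the threshold starts at
#' -0.5 SD and relaxes towards `theta_min`. `"difference"` uses
#' `(theta_max - theta_min)`, which makes the t = 0 threshold exactly
#' `theta_max` (the threshold decays from the ceiling to the floor); this
#' is the variant in which `theta_max` actually acts as the starting
#' ceiling. `"sum"` is the default.
#'
#' @param theta_min Threshold floor, SD units (conventionally <= 0).
#' @param theta_max Threshold ceiling, SD units (>= 0).
#' @param noise_variance Variance of the additive Gaussian threshold
#'   noise (default 0.05, i.e. SD ~ 0.224).
#' @param formula_variant `"sum"` or `"difference"` (see above).
#' @param seed Optional integer seed for the threshold-noise stream used
#'   by [count_salient_events()].
#' @return Object of class `criterion_params`.
#' @export
criterion_params <- function(theta_min = -1, theta_max = 1.5,
                             noise_variance = 0.05,
                             formula_variant = c("sum", "difference"),
                             seed = NULL) {
  formula_variant <- match.arg(formula_variant)
  if (noise_variance < 0) stop_("noise_variance must be >= 0")
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 noise_variance = noise_variance,
                 formula_variant = formula_variant,
                 seed = if (!is.null(seed)) as.integer(seed) else NULL),
            class = "criterion_params")
}

#' Evaluate the dynamic criterion
#'
#' @param t_since_reset Non-negative integer(s): TRs elapsed since trial
#'   start or since the last detected event.
#' @param params A [criterion_params()].
#' @param epsilon Threshold noise value(s) to add (default 0; the
#'   stochastic draw happens in [count_salient_events()]).
#' @return Threshold value(s) in SD units.
#' @export
criterion_value <- function(t_since_reset, params, epsilon = 0) {
  stopifnot(inherits(params, "criterion_params"))
  if (any(t_since_reset < 0)) stop_("t_since_reset must be >= 0")
  decay <- switch(params$formula_variant,
                  sum = params$theta_max + params$theta_min,
                  difference = params$theta_max - params$theta_min)
  decay * exp(-t_since_reset) + params$theta_min + epsilon
}

#' Count salient events in a z-scored change series
#'
#' Walks the z-scored change values in temporal order, comparing each to
#' the noise-corrupted dynamic criterion. A timepoint is salient when its
#' z-value exceeds the threshold; each detection resets the threshold
#' clock to 0 for the next step, otherwise the clock advances by one.
#' Threshold noise is drawn fresh per timepoint from
#' `N(0, noise_variance)` using `params$seed` when given (otherwise the
#' current RNG stream), unless an explicit `epsilon` vector is supplied
#' (used e.g. for step-through replay).
#'
#' @param series A `change_series` with `zvalues` present.
#' @param params A [criterion_params()].
#' @param epsilon Optional numeric vector of threshold-noise values, one
#'   per change timepoint, overriding the random draw.
#' @return List with `count` (integer), `event_timepoints` (indices on
#'   the original timepoint axis, i.e. in `2..n_timepoints`), and
#'   `epsilon` (the noise actually used).
#' @export
count_salient_events <- function(series, params, epsilon = NULL) {
  stopifnot(inherits(series, "change_series"), inherits(params, "criterion_params"))
  z <- series$zvalues
  if (is.null(z)) stop_("series has no zvalues; call zscore_changes() first")
  n <- length(z)
  if (is.null(epsilon)) {
    draw <- function() rnorm(n, 0, sqrt(params$noise_variance))
    epsilon <- if (!is.null(params$seed)) withr::with_seed(params$seed, draw())
               else draw()
  }
  if (length(epsilon) != n)
    stop_("epsilon must have one value per change timepoint (%d), got %d",
          n, length(epsilon))
  t_since <- 0L
  events <- integer(0)
  for (k in seq_len(n)) {
    th <- criterion_value(t_since, params, epsilon[k])
    if (z[k] > th) {
      events <- c(events, k)
      t_since <- 0L
    } else {
      t_since <- t_since + 1L
    }
  }
  list(count = length(events), event_timepoints = events + 1L,
       epsilon = epsilon)
}

# z-scored change series for one network across trials, under either scope
network_zseries <- function(trials, regions, network, zscope = c("trial", "pool")) {
  zscope <- match.arg(zscope)
  series <- lapply(trials, function(tr)
    network_change_series(tr, regions, network))
  if (zscope == "trial")
    return(lapply(series, zscore_changes, scope = "trial"))
  subj <- vapply(series, `[[`, "", "subject")
  out <- series
  for (s in unique(subj)) {
    pooled <- unlist(lapply(series[subj == s], `[[`, "values"))
    m <- mean(pooled)
    sdev <- sd(pooled)
    out[subj == s] <- lapply(series[subj == s], zscore_changes,
                             scope = "pool", pool_mean = m, pool_sd = sdev)
  }
  out
}

#' Accumulated salient-event counts per trial and network
#'
#' Applies [network_change_series()], [zscore_changes()] and
#' [count_salient_events()] to every trial x network combination.
#' Threshold noise for each (trial, network) cell comes from a seed
#' derived deterministically from `params$seed`, so the whole matrix is
#' reproducible and any single cell can be recomputed in isolation.
#'
#' Z-scoring scope: `"trial"` standardizes each trial's change series by
#' its own mean and SD; `"pool"` standardizes every trial of a subject by
#' the mean and SD of that subject's pooled change values for the
#' network. Per-trial scoring makes the standardized series -- and hence
#' the event count, up to threshold noise -- insensitive to how much
#' genuine event content the individual trial carries, because trial-level
#' signal is absorbed into the trial's own normalization; pooled scoring
#' preserves between-trial differences in event content.
#'
#' @param trials List of `trial_series` with consistent region labelling.
#' @param network_map Named character vector region id -> network id.
#' @param params A [criterion_params()] with a non-`NULL` `seed`.
#' @param zscope Z-scoring scope, `"trial"` (default) or `"pool"`.
#' @return Object of class `event_features`: list with `counts` (integer
#'   matrix trials x networks, rownames `subject/trial`), `events` (list
#'   of per-network event timepoint lists), `meta` (data frame subject,
#'   trial, n_timepoints).
#' @export
accumulate_events <- function(trials, network_map, params,
                              zscope = c("trial", "pool")) {
  zscope <- match.arg(zscope)
  stopifnot(length(trials) > 0, inherits(params, "criterion_params"))
  if (is.null(params$seed))
    stop_("params$seed must be set for reproducible event accumulation")
  nets <- network_names()
  present <- intersect(nets, unique(network_map))
  counts <- matrix(NA_integer_, length(trials), length(present),
                   dimnames = list(NULL, present))
  events <- vector("list", length(trials))
  meta <- data.frame(subject = character(length(trials)),
                     trial = character(length(trials)),
                     n_timepoints = integer(length(trials)),
                     stringsAsFactors = FALSE)
  meta$subject <- vapply(trials, `[[`, "", "subject")
  meta$trial <- vapply(trials, `[[`, "", "trial")
  meta$n_timepoints <- vapply(trials, `[[`, integer(1), "n_timepoints")
  events <- replicate(length(trials), list(), simplify = FALSE)
  for (j in seq_along(present)) {
    zs <- network_zseries(trials, regions_of(network_map, present[j]),
                          present[j], zscope)
    for (i in seq_along(trials)) {
      cell_params <- params
      cell_params$seed <- derive_seed(params$seed, 0, i, j)
      res <- count_salient_events(zs[[i]], cell_params)
      counts[i, j] <- res$count
      events[[i]][[present[j]]] <- res$event_timepoints
    }
  }
  rownames(counts) <- paste(meta$subject, meta$trial, sep = "/")
  structure(list(counts = counts, events = events, meta = meta),
            class = "event_features")
}
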