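#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated video-watching experiment: each subject watches
#' silent office/city videos of 8-24 s and reports the perceived duration
#' on a 0-40 s scale while a parcellated BOLD-like signal is recorded at
#' TR = 0.8 s. Each functional network carries a shared latent signal that
#' follows a random walk punctuated by jump ("salient event") discontinuities;
#' regions observe their network signal plus independent noise. Reports are
#' coupled to the event count of one designated timer network and to the
#' scene category, so that downstream recovery of both couplings can be
#' tested against known ground truth.
#'
#' @param n_subjects Number of subjects (default 38).
#' @param duration_categories_s Video duration conditions in seconds, all
#'   within 8-24 s (default `c(8, 12, 16, 20, 24)`).
#' @param trials_per_condition Trials per (duration, scene) condition per
#'   subject (default 4).
#' @param tr_s Sampling interval (repetition time) in seconds, default 0.8.
#' @param n_regions Number of cortical regions (default 360).
#' @param network_labels Named character vector mapping region id to one of
#'   the seven networks; defaults to [default_network_map()].
#' @param event_rate_per_tr Matrix (7 networks x 2 scenes, dimnames
#'   `network_names()` x `c("office", "city")`) of per-TR Bernoulli salient
#'   event probabilities. Default: 0.10 for office, 0.15 for city in every
#'   network (salient scene changes are sparse; city scenes carry more).
#' @param jump_amplitude Signal jump added to the network random walk at
#'   each planted event (default 3; sized so single jumps stand well clear
#'   of the walk/observation noise in the network change series).
#' @param walk_sd Random-walk innovation SD per TR (default 0.3).
#' @param obs_noise_sd Per-region observation noise SD (default 0.5).
#' @param coupling_gamma Dimensionless strength coupling the timer-network
#'   event count to the duration report (default 0.3).
#' @param scene_bias_beta Relative report inflation for city scenes
#'   (default 0.1).
#' @param report_noise_sd SD of additive report noise in seconds (default 2).
#' @param report_scale_max_s Upper end of the response scale (40 s).
#' @param timer_network Network whose event count drives the report
#'   coupling (default `"vis"`).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#'
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 38,
                         duration_categories_s = c(8, 12, 16, 20, 24),
                         trials_per_condition = 4,
                         tr_s = 0.8,
                         n_regions = 360,
                         network_labels = NULL,
                         event_rate_per_tr = NULL,
                         jump_amplitude = 3,
                         walk_sd = 0.3,
                         obs_noise_sd = 0.5,
                         coupling_gamma = 0.3,
                         scene_bias_beta = 0.1,
                         report_noise_sd = 2,
                         report_scale_max_s = 40,
                         timer_network = "vis",
                         seed = 1L) {
  nets <- network_names()
  if (is.null(network_labels)) network_labels <- default_network_map(n_regions)
  if (length(network_labels) != n_regions)
    stop_("network_labels has length %d but n_regions is %d",
          length(network_labels), n_regions)
  if (!all(network_labels %in% nets))
    stop_("network_labels contains unknown network id(s): %s",
          paste(setdiff(unique(network_labels), nets), collapse = ", "))
  if (!all(nets %in% network_labels))
    stop_("every one of the 7 networks needs at least one region; missing: %s",
          paste(setdiff(nets, unique(network_labels)), collapse = ", "))
  if (is.null(event_rate_per_tr)) {
    event_rate_per_tr <- matrix(rep(c(0.10, 0.15), each = 7), nrow = 7,
                                dimnames = list(nets, c("office", "city")))
  }
  if (!all(rownames(event_rate_per_tr) == nets) ||
      !all(colnames(event_rate_per_tr) == c("office", "city")))
    stop_("event_rate_per_tr must have rownames network_names() and colnames c('office','city')")
  if (any(event_rate_per_tr < 0 | event_rate_per_tr > 1))
    stop_("event rates must lie in [0, 1]")
  if (any(duration_categories_s < 8 | duration_categories_s > 24))
    stop_("duration categories must lie within [8, 24] s")
  if (any(round(duration_categories_s / tr_s) < 2))
    stop_("every duration must span at least 2 timepoints at TR = %g s", tr_s)
  if (!timer_network %in% nets)
    stop_("unknown timer_network '%s'", timer_network)
  stopifnot(trials_per_condition >= 1, n_subjects >= 1,
            walk_sd >= 0, obs_noise_sd >= 0, report_noise_sd >= 0,
            report_scale_max_s > 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    duration_categories_s = duration_categories_s,
    trials_per_condition = as.integer(trials_per_condition),
    tr_s = tr_s, n_regions = as.integer(n_regions),
    network_labels = network_labels,
    event_rate_per_tr = event_rate_per_tr,
    jump_amplitude = jump_amplitude, walk_sd = walk_sd,
    obs_noise_sd = obs_noise_sd, coupling_gamma = coupling_gamma,
    scene_bias_beta = scene_bias_beta, report_noise_sd = report_noise_sd,
    report_scale_max_s = report_scale_max_s, timer_network = timer_network,
    seed = as.integer(seed)), class = "synth_config")
}

new_trial_series <- function(subject, trial, scene, duration_s, X, tr_s) {
  n_tp <- ncol(X)
  if (n_tp < 2) stop_("trial %s/%s has %d timepoints; need at least 2",
                      subject, trial, n_tp)
  structure(list(subject = subject, trial = trial, scene = scene,
                 duration_s = duration_s, X = X, n_timepoints = n_tp,
                 tr_s = tr_s), class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("<trial_series> subject %s trial %s | %s scene | %g s (%d TPs x %d regions)\n",
              x$subject, x$trial, x$scene, x$duration_s, x$n_timepoints,
              nrow(x$X)))
  invisible(x)
}

# One trial's draws, all from a trial-specific substream so that reports are
# identical whether or not region series are materialized. `s0` is the
# network signal level carried over from the subject's previous trial, so
# that a subject's session forms one continuous series (random windows
# drawn across trial boundaries then behave like windows of a real
# continuous block).
.simulate_trial <- function(config, subject, trial_id, scene, duration_s,
                            trial_seed, include_series, s0 = rep(0, 7)) {
  n_tp <- round(duration_s / config$tr_s)
  nets <- network_names()
  rate <- config$event_rate_per_tr[, scene]
  out <- local_seed(trial_seed, {
    events <- matrix(rbinom(n_tp * 7L, 1L, rep(rate, each = n_tp)), n_tp, 7,
                     dimnames = list(NULL, nets))
    walk <- matrix(rnorm(n_tp * 7, 0, config$walk_sd), n_tp, 7)
    report_eps <- rnorm(1, 0, config$report_noise_sd)
    list(events = events, walk = walk, report_eps = report_eps)
  })
  # shared network signal: random walk with event-driven jumps,
  # continuing from the subject's running level
  s_net <- apply(out$events * config$jump_amplitude + out$walk, 2, cumsum)
  s_net <- sweep(s_net, 2, s0, "+")
  colnames(s_net) <- nets

  e_timer <- sum(out$events[, config$timer_network])
  mu_timer <- rate[[config$timer_network]] * n_tp
  raw_report <- duration_s *
    (1 + config$scene_bias_beta * (scene == "city") +
       config$coupling_gamma * (e_timer - mu_timer) / max(1, mu_timer)) +
    out$report_eps
  report_s <- clip(raw_report, 0, config$report_scale_max_s)

  series <- NULL
  if (include_series) {
    obs <- local_seed(derive_seed(trial_seed, 0, 0, 5), {
      matrix(rnorm(config$n_regions * n_tp, 0, config$obs_noise_sd),
             config$n_regions, n_tp)
    })
    X <- t(s_net[, config$network_labels, drop = FALSE]) + obs
    rownames(X) <- names(config$network_labels)
    colnames(X) <- seq_len(n_tp)
    series <- new_trial_series(subject, trial_id, scene, duration_s, X,
                               config$tr_s)
  }
  list(series = series, s_end = s_net[n_tp, ],
       report_s = report_s, clipped = report_s != raw_report,
       planted_event_count = e_timer, n_timepoints = n_tp)
}

#' Generate a synthetic trial-wise BOLD cohort
#'
#' Simulates, for every subject and every (duration, scene) condition,
#' `trials_per_condition` trials of parcellated BOLD-like series together
#' with behavioral duration reports (see [synth_config()] for the model).
#' The cohort is a pure function of the configuration: the same config
#' (including its `seed`) always yields an identical cohort, and each
#' trial has its own derived random substream.
#'
#' @param config A [synth_config()].
#' @param include_series If `FALSE`, skip the region x timepoint matrices
#'   and return behavioral records only (reports are unchanged); useful for
#'   large behavioral-only calibration runs.
#' @return Object of class `bold_cohort`: a list with `trials` (list of
#'   `trial_series`), `behavior` (data frame with columns subject, trial,
#'   scene, duration_s, report_s, clipped, planted_event_count,
#'   n_timepoints) and `config`.
#' @export
generate_cohort <- function(config, include_series = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  conditions <- expand.grid(duration_s = config$duration_categories_s,
                            scene = c("office", "city"),
                            rep = seq_len(config$trials_per_condition),
                            stringsAsFactors = FALSE)
  n_total <- config$n_subjects * nrow(conditions)
  trials <- vector("list", n_total)
  behavior <- data.frame(
    subject = rep(sprintf("s%02d", seq_len(config$n_subjects)),
                  each = nrow(conditions)),
    trial = rep(sprintf("t%03d", seq_len(nrow(conditions))),
                config$n_subjects),
    scene = rep(conditions$scene, config$n_subjects),
    duration_s = rep(conditions$duration_s, config$n_subjects),
    report_s = numeric(n_total), clipped = logical(n_total),
    planted_event_count = integer(n_total), n_timepoints = integer(n_total),
    stringsAsFactors = FALSE)
  k <- 0
  for (si in seq_len(config$n_subjects)) {
    subject <- sprintf("s%02d", si)
    s_level <- rep(0, 7)
    for (ci in seq_len(nrow(conditions))) {
      k <- k + 1
      tseed <- derive_seed(config$seed, si, ci)
      sim <- .simulate_trial(config, subject, sprintf("t%03d", ci),
                             conditions$scene[ci], conditions$duration_s[ci],
                             tseed, include_series, s0 = s_level)
      s_level <- unname(sim$s_end)
      if (include_series) trials[[k]] <- sim$series
      behavior$report_s[k] <- sim$report_s
      behavior$clipped[k] <- sim$clipped
      behavior$planted_event_count[k] <- sim$planted_event_count
      behavior$n_timepoints[k] <- sim$n_timepoints
    }
  }
  structure(list(trials = if (include_series) trials else NULL,
                 behavior = behavior, config = config),
            class = "bold_cohort")
}

#' Generate a null cohort (no event/report and no scene coupling)
#'
#' Identical to [generate_cohort()] but with `coupling_gamma = 0` and
#' `scene_bias_beta = 0`, so reports depend on the true duration and
#' report noise only. Used for type-I-error calibration.
#'
#' @inheritParams generate_cohort
#' @return A `bold_cohort`; see [generate_cohort()].
#' @export
generate_null_cohort <- function(config, include_series = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  config$coupling_gamma <- 0
  config$scene_bias_beta <- 0
  generate_cohort(config, include_series = include_series)
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d subjects, %d trials%s\n",
              length(unique(x$behavior$subject)), nrow(x$behavior),
              if (is.null(x$trials)) " (behavior only)" else ""))
  invisible(x)
}
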