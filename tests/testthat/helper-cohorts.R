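# Shared fixtures, all generated in code.

# small cohort with default signal physics
tiny_cohort <- function(n_subjects = 4, n_regions = 14,
                        trials_per_condition = 2, seed = 1, ...) {
  generate_cohort(synth_config(n_subjects = n_subjects,
                               n_regions = n_regions,
                               trials_per_condition = trials_per_condition,
                               seed = seed, ...))
}

# completely silent configuration: no events, no noise, no coupling
silent_config <- function(n_subjects = 2, seed = 1) {
  rates <- matrix(0, 7, 2,
                  dimnames = list(network_names(), c("office", "city")))
  synth_config(n_subjects = n_subjects, n_regions = 7,
               trials_per_condition = 1, event_rate_per_tr = rates,
               walk_sd = 0, obs_noise_sd = 0, coupling_gamma = 0,
               scene_bias_beta = 0, report_noise_sd = 0, seed = seed)
}

# hand-made change series with given (z-scored) values
zseries <- function(z, values = z) {
  structure(list(values = values, zvalues = z, network = "vis",
                 subject = "sX", trial = "tX"), class = "change_series")
}

# literal re-simulation of the reset recursion, kept deliberately naive:
# the independent oracle for count_salient_events
oracle_count <- function(z, theta_min, theta_max, epsilon,
                         variant = c("sum", "difference")) {
  variant <- match.arg(variant)
  base <- if (variant == "sum") theta_max + theta_min else theta_max - theta_min
  t_since <- 0
  count <- 0
  times <- integer(0)
  for (k in seq_along(z)) {
    threshold <- base * exp(-t_since) + theta_min + epsilon[k]
    if (z[k] > threshold) {
      count <- count + 1
      times <- c(times, k)
      t_since <- 0
    } else {
      t_since <- t_since + 1
    }
  }
  list(count = count, times = times)
}
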