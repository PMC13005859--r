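trial_from_matrix <- function(X, subject = "s01", trial = "t001") {
  rownames(X) <- sprintf("r%03d", seq_len(nrow(X)))
  salientime:::new_trial_series(subject, trial, "office",
                                ncol(X) * 0.8, X, 0.8)
}

test_that("network change series is the voxel-summed first difference", {
  X <- rbind(c(1, 2, 2), c(2, 4, 4))
  cs <- network_change_series(trial_from_matrix(X), c("r001", "r002"))
  expect_equal(cs$values, c(3, 0), ignore_attr = TRUE)
  # constant series: all zeros
  Xc <- matrix(5, 3, 6)
  expect_equal(network_change_series(trial_from_matrix(Xc),
                                     c("r001", "r002", "r003"))$values,
               rep(0, 5), ignore_attr = TRUE)
})

test_that("change series equals first difference of column sums (oracle)", {
  set.seed(7)
  X <- matrix(rnorm(100), 5, 20)
  cs <- network_change_series(trial_from_matrix(X), sprintf("r%03d", 1:5))
  expect_equal(cs$values, diff(colSums(X)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("telescoping identity holds", {
  set.seed(8)
  X <- matrix(rnorm(60), 4, 15)
  cs <- network_change_series(trial_from_matrix(X), sprintf("r%03d", 1:4))
  sums <- colSums(X)
  expect_equal(sum(cs$values), sums[15] - sums[1], tolerance = 1e-9)
})

test_that("unknown network regions are rejected", {
  X <- matrix(rnorm(20), 2, 10)
  expect_error(network_change_series(trial_from_matrix(X), c("r999")),
               "no region")
})

test_that("z-scoring uses the sample SD and is affine-invariant", {
  cs <- zseries(NULL, values = c(-1, 0, 1))
  z <- zscore_changes(cs)
  expect_equal(z$zvalues, c(-1, 0, 1))  # sample SD convention: sd = 1
  z2 <- zscore_changes(zseries(NULL, values = 2.5 * c(-1, 0, 1) + 7))
  expect_equal(z2$zvalues, z$zvalues)
  expect_error(zscore_changes(zseries(NULL, values = c(2, 2, 2))), "SD")
  expect_equal(mean(z$zvalues), 0, tolerance = 1e-9)
  expect_equal(sd(z$zvalues), 1, tolerance = 1e-9)
})

test_that("criterion closed forms hold under both variants", {
  p <- criterion_params(theta_min = -1, theta_max = 1.5)
  expect_equal(criterion_value(0, p), -0.5)          # (1.5 - 1)*1 - 1
  expect_equal(criterion_value(50, p), -1, tolerance = 1e-12)
  pd <- criterion_params(theta_min = -1, theta_max = 1.5,
                         formula_variant = "difference")
  expect_equal(criterion_value(0, pd), 1.5)
  expect_equal(criterion_value(50, pd), -1, tolerance = 1e-12)
  # variants coincide when the floor is at the mean
  p0s <- criterion_params(theta_min = 0, theta_max = 2)
  p0d <- criterion_params(theta_min = 0, theta_max = 2,
                          formula_variant = "difference")
  expect_equal(criterion_value(0:5, p0s), criterion_value(0:5, p0d))
  expect_equal(criterion_value(0, p0s), 2)
  expect_error(criterion_value(-1, p), ">= 0")
})

test_that("noise-free criterion decays monotonically when it should", {
  t <- 0:20
  p <- criterion_params(theta_min = -1, theta_max = 1.5)  # sum: 0.5 > 0
  expect_true(all(diff(criterion_value(t, p)) <= 0))
  pd <- criterion_params(theta_min = -2, theta_max = 1,
                         formula_variant = "difference")
  expect_true(all(diff(criterion_value(t, pd)) <= 0))
})

test_that("event counting follows the reset recursion exactly", {
  # degenerate extremes
  p_high <- criterion_params(theta_min = 1, theta_max = 1)
  expect_equal(count_salient_events(zseries(rep(0, 8)), p_high,
                                    epsilon = rep(0, 8))$count, 0)
  p_low <- criterion_params(theta_min = -50, theta_max = 0)
  expect_equal(count_salient_events(zseries(rnorm(8)), p_low,
                                    epsilon = rep(0, 8))$count, 8)
  # the worked 4-step case, stepped through by the naive oracle
  z <- c(0.5, 2.0, 0.1, 1.6)
  p <- criterion_params(theta_min = -1, theta_max = 1.5)
  got <- count_salient_events(zseries(z), p, epsilon = rep(0, 4))
  want <- oracle_count(z, -1, 1.5, rep(0, 4), "sum")
  expect_equal(got$count, want$count)
  expect_equal(got$event_timepoints, want$times + 1L)
})

test_that("counting matches the literal oracle across a parameter sweep", {
  set.seed(42)
  for (len in 2:6) {
    for (rep in 1:20) {
      z <- rnorm(len, sd = 1.5)
      eps <- rnorm(len, 0, sqrt(0.05))
      tmin <- runif(1, -3, 0)
      tmax <- runif(1, 0, 2.5)
      for (variant in c("sum", "difference")) {
        p <- criterion_params(tmin, tmax, formula_variant = variant)
        got <- count_salient_events(zseries(z), p, epsilon = eps)
        want <- oracle_count(z, tmin, tmax, eps, variant)
        expect_equal(got$count, want$count)
        expect_equal(got$event_timepoints, want$times + 1L)
      }
    }
  }
})

test_that("seeded threshold noise is reproducible", {
  z <- rnorm(12)
  p <- criterion_params(seed = 77)
  a <- count_salient_events(zseries(z), p)
  b <- count_salient_events(zseries(z), p)
  expect_identical(a, b)
  expect_equal(sd(a$epsilon), sqrt(0.05), tolerance = 0.5)
})

test_that("event count never increases when both thresholds shift upward", {
  set.seed(9)
  z <- rnorm(30)
  for (shift in c(0, 0.3, 0.8, 1.5)) {
    c0 <- count_salient_events(zseries(z),
                               criterion_params(-1 + shift, 1.5 + shift),
                               epsilon = rep(0, 30))$count
    if (shift == 0) prev <- c0
    expect_lte(c0, prev)
    prev <- c0
  }
})

test_that("accumulate_events is shaped, bounded and deterministic", {
  coh <- tiny_cohort(n_subjects = 2, trials_per_condition = 1, seed = 2)
  p <- criterion_params(seed = 5)
  ef <- accumulate_events(coh$trials, coh$config$network_labels, p)
  expect_equal(dim(ef$counts), c(length(coh$trials), 7))
  expect_true(all(ef$counts >= 0))
  expect_true(all(ef$counts <= ef$meta$n_timepoints - 1))
  ef2 <- accumulate_events(coh$trials, coh$config$network_labels, p)
  expect_identical(ef$counts, ef2$counts)
  expect_error(accumulate_events(coh$trials, coh$config$network_labels,
                                 criterion_params()), "seed")
})

test_that("event-rich trials accumulate more detections than event-poor ones", {
  # Monte-Carlo ordering within the timer network: above-median planted
  # event content must yield more detections under pooled scoring.
  # (Across networks the z-normalization equalizes detection rates, so the
  # ordering is only identified within a network.)
  rates <- matrix(0, 7, 2, dimnames = list(network_names(),
                                           c("office", "city")))
  rates["vis", ] <- 0.25
  cfg <- synth_config(n_subjects = 6, n_regions = 14,
                      trials_per_condition = 2, event_rate_per_tr = rates,
                      seed = 6)
  coh <- generate_cohort(cfg)
  ef <- accumulate_events(coh$trials, cfg$network_labels,
                          criterion_params(theta_min = 0, theta_max = 2,
                                           seed = 3), zscope = "pool")
  b <- coh$behavior
  # compare within one duration category so length cannot confound
  sel <- b$duration_s == 16
  k <- b$planted_event_count[sel]
  d <- ef$counts[sel, "vis"]
  expect_gt(mean(d[k > stats::median(k)]), mean(d[k < stats::median(k)]))
})

test_that("pooled z-scoring preserves trial-level event content", {
  cfg <- synth_config(n_subjects = 6, n_regions = 14,
                      trials_per_condition = 2, seed = 12)
  coh <- generate_cohort(cfg)
  b <- coh$behavior
  ef <- accumulate_events(coh$trials, cfg$network_labels,
                          criterion_params(theta_min = 0, theta_max = 2,
                                           seed = 4), zscope = "pool")
  g <- interaction(b$subject, b$duration_s)
  r <- cor(ef$counts[, "vis"] - ave(ef$counts[, "vis"], g),
           b$planted_event_count - ave(b$planted_event_count, g))
  expect_gt(r, 0.2)
})
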