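zero_model <- function(input = 3, hidden = 2, head_bias = 0) {
  m <- init_lstm(input, hidden, seed = 1)
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$W[] <- 0
    m$layers[[l]]$U[] <- 0
    m$layers[[l]]$b[] <- 0
  }
  m$head$w[] <- 0
  m$head$b <- head_bias
  m
}

test_that("gate closed forms hold at zero weights", {
  m <- zero_model()
  prev <- list(h = c(0.3, -0.2), C = c(1, -2))
  s <- lstm_step(c(5, -1, 2), prev, m$layers[[1]])
  expect_equal(as.numeric(s$f), c(0.5, 0.5))
  expect_equal(as.numeric(s$i), c(0.5, 0.5))
  expect_equal(as.numeric(s$o), c(0.5, 0.5))
  expect_equal(as.numeric(s$C), 0.5 * prev$C)   # i*tanh(0) + 0.5*C
  expect_equal(as.numeric(s$h), 0.5 * tanh(0.5 * prev$C))
})

test_that("saturated gates implement perfect memory", {
  m <- zero_model()
  w <- m$layers[[1]]
  H <- 2
  w$b[1:H] <- 50        # forget gate ~ 1
  w$b[(H + 1):(2 * H)] <- -50  # input gate ~ 0
  prev <- list(h = c(0, 0), C = c(0.7, -1.3))
  s <- lstm_step(rnorm(3), prev, w)
  expect_equal(as.numeric(s$C), prev$C, tolerance = 1e-10)
})

test_that("gate equations match a scalar step-through oracle", {
  set.seed(5)
  H <- 3; D <- 2
  m <- init_lstm(D, H, seed = 5)
  w <- m$layers[[1]]
  x <- matrix(rnorm(D * 3), D, 3)  # 3 timesteps, scalar batch
  h <- rep(0, H); C <- rep(0, H)
  gr <- list(f = 1:H, i = (H + 1):(2 * H), o = (2 * H + 1):(3 * H),
             g = (3 * H + 1):(4 * H))
  for (t in 1:3) {
    s <- lstm_step(x[, t], list(h = h, C = C), w)
    # naive scalar recomputation, element by element
    for (u in 1:H) {
      af <- sum(w$W[gr$f[u], ] * x[, t]) + sum(w$U[gr$f[u], ] * h) + w$b[gr$f[u]]
      ai <- sum(w$W[gr$i[u], ] * x[, t]) + sum(w$U[gr$i[u], ] * h) + w$b[gr$i[u]]
      ao <- sum(w$W[gr$o[u], ] * x[, t]) + sum(w$U[gr$o[u], ] * h) + w$b[gr$o[u]]
      ag <- sum(w$W[gr$g[u], ] * x[, t]) + sum(w$U[gr$g[u], ] * h) + w$b[gr$g[u]]
      Cu <- 1 / (1 + exp(-ai)) * tanh(ag) + 1 / (1 + exp(-af)) * C[u]
      hu <- 1 / (1 + exp(-ao)) * tanh(Cu)
      expect_equal(s$C[u, 1], Cu, tolerance = 1e-10)
      expect_equal(s$h[u, 1], hu, tolerance = 1e-10)
    }
    h <- as.numeric(s$h); C <- as.numeric(s$C)
  }
  expect_true(all(s$f > 0 & s$f < 1))
  expect_true(all(abs(s$g) < 1))
})

test_that("predictions are invariant to the amount of zero padding", {
  m <- init_lstm(4, 5, seed = 9)
  core <- matrix(rnorm(4 * 6), 4, 6)
  for (pool in c("top", "both")) {
    pads <- sapply(c(6, 12, 31), function(Tpad) {
      X <- array(0, c(4, Tpad, 1))
      X[, 1:6, 1] <- core
      lstm_forward(m, X, 6, keep_cache = TRUE, pool = pool)$pred
    })
    expect_lt(diff(range(pads)), 1e-12)
  }
})

test_that("all-zero weights predict the head bias everywhere", {
  m <- zero_model(head_bias = 0.42)
  X <- array(rnorm(3 * 7 * 4), c(3, 7, 4))
  expect_equal(lstm_forward(m, X, c(7, 5, 3, 2))$pred, rep(0.42, 4))
})

test_that("batched and single-trial forward passes agree", {
  m <- init_lstm(3, 4, seed = 11)
  X <- array(rnorm(3 * 8 * 5), c(3, 8, 5))
  lens <- c(8, 6, 4, 3, 2)
  batch <- lstm_forward(m, X, lens)$pred
  single <- vapply(1:5, function(i)
    lstm_forward(m, X[, , i, drop = FALSE], lens[i])$pred, numeric(1))
  expect_equal(batch, single, tolerance = 1e-6)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(13)
  m <- init_lstm(2, 3, seed = 13)
  X <- array(rnorm(2 * 4 * 2), c(2, 4, 2))
  lens <- c(4, 3)
  y <- c(0.5, -0.2)
  loss <- function(model) {
    p <- lstm_forward(model, X, lens)$pred
    mean((p - y)^2)
  }
  fw <- lstm_forward(m, X, lens, keep_cache = TRUE)
  gr <- salientime:::.lstm_backward(m, fw, 2 * (fw$pred - y) / 2)
  eps <- 1e-6
  for (l in 1:2) for (p in c("W", "U", "b")) {
    pick <- seq_len(min(8, length(m$layers[[l]][[p]])))
    for (i in pick) {
      mp <- m; mp$layers[[l]][[p]][i] <- mp$layers[[l]][[p]][i] + eps
      mm <- m; mm$layers[[l]][[p]][i] <- mm$layers[[l]][[p]][i] - eps
      expect_equal(gr$layers[[l]][[p]][i],
                   (loss(mp) - loss(mm)) / (2 * eps), tolerance = 1e-5)
    }
  }
  for (p in c("w", "b")) for (i in seq_along(m$head[[p]])) {
    mp <- m; mp$head[[p]][i] <- mp$head[[p]][i] + eps
    mm <- m; mm$head[[p]][i] <- mm$head[[p]][i] - eps
    expect_equal(gr$head[[p]][i], (loss(mp) - loss(mm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("training loss decreases in the noise-free overfit regime", {
  set.seed(17)
  X <- array(rnorm(3 * 6 * 8), c(3, 6, 8))
  lens <- rep(6, 8)
  y <- rnorm(8)
  cfg <- train_config(learning_rate = 0.2, epochs = 80, hidden_size = 6,
                      batch_size = 8, momentum = 0.9, scheduler_step = 40,
                      seed = 1)
  res <- salientime:::.train_lstm(X, lens, y, cfg, init_seed = 1)
  expect_lt(res$losses[80], res$losses[1])
  expect_lt(res$losses[80], 0.05 * res$losses[1])
})

test_that("LOSO training is deterministic and learns the length signal", {
  coh <- generate_cohort(synth_config(n_subjects = 3, n_regions = 14,
                                      trials_per_condition = 1, seed = 19))
  cfg <- train_config(epochs = 4, hidden_size = 4, seed = 7)
  r1 <- train_loso(coh, "duration_s", cfg)
  r2 <- train_loso(coh, "duration_s", cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$losses, r2$losses)
  expect_length(r1$failed_folds, 0)
  # every trial predicted exactly once, never by its own subject's fold
  expect_equal(sort(paste(r1$predictions$subject, r1$predictions$trial)),
               sort(paste(coh$behavior$subject, coh$behavior$trial)))
  # the trivial duration/length association is learnable
  cfg2 <- train_config(epochs = 10, hidden_size = 6, seed = 3)
  coh2 <- generate_cohort(synth_config(n_subjects = 5, n_regions = 14,
                                       trials_per_condition = 2, seed = 23))
  r3 <- train_loso(coh2, "duration_s", cfg2)
  expect_gt(cor(r3$predictions$truth, r3$predictions$prediction), 0)
})

test_that("AUC matches its closed forms and the reference implementation", {
  expect_equal(evaluate_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(evaluate_auc(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(evaluate_auc(c(0.2, 0.8), c(1, 1)), "both classes")
  set.seed(29)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  expect_equal(evaluate_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
  # label shuffling centres the AUC on 1/2
  aucs <- replicate(200, evaluate_auc(scores, sample(labels)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the hyperparameter search returns the best validated combination", {
  coh <- generate_cohort(synth_config(n_subjects = 4, n_regions = 14,
                                      trials_per_condition = 1, seed = 47))
  base <- train_config(epochs = 3, hidden_size = 3, seed = 5)
  out <- tune_sequence_model(coh, "duration_s", base,
                             lr_grid = c(0.02, 0.1), step_grid = 2,
                             gamma_grid = 0.5)
  expect_equal(nrow(out$results), 2)
  expect_false(any(is.na(out$results$val_mse)))
  best <- out$results[which.min(out$results$val_mse), ]
  expect_equal(out$config$learning_rate, best$learning_rate)
  expect_s3_class(out$config, "train_config")
})
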