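#' Training configuration for the sequence model
#'
#' Hyperparameters of the two-layer masked LSTM regressor. The scheduler
#' multiplies the learning rate by `scheduler_gamma` every
#' `scheduler_step` epochs (stepwise decay). Defaults are sized for
#' desk-scale cohorts.
#'
#' @param learning_rate Initial SGD learning rate (default 0.05).
#' @param scheduler_step Epochs between learning-rate decays (default 10).
#' @param scheduler_gamma Multiplicative decay factor in (0, 1] (default 0.5).
#' @param epochs Training epochs per fold (default 30).
#' @param hidden_size LSTM hidden units per layer (default 8).
#' @param batch_size Minibatch size (default 32).
#' @param momentum SGD momentum (default 0.9).
#' @param pool `"top"`: masked temporal mean of the top layer's hidden
#'   states feeds the linear head; `"both"`: elementwise mean of both
#'   layers' pooled states.
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, scheduler_step = 10,
                         scheduler_gamma = 0.5, epochs = 30,
                         hidden_size = 8, batch_size = 32,
                         momentum = 0.9, pool = c("top", "both"),
                         seed = 1L) {
  pool <- match.arg(pool)
  stopifnot(learning_rate > 0, scheduler_step >= 1, epochs >= 1,
            hidden_size >= 1, batch_size >= 1, momentum >= 0, momentum < 1,
            scheduler_gamma > 0, scheduler_gamma <= 1)
  structure(list(learning_rate = learning_rate,
                 scheduler_step = as.integer(scheduler_step),
                 scheduler_gamma = scheduler_gamma,
                 epochs = as.integer(epochs),
                 hidden_size = as.integer(hidden_size),
                 batch_size = as.integer(batch_size),
                 momentum = momentum, pool = pool,
                 seed = as.integer(seed)), class = "train_config")
}

# gate row blocks within the stacked 4H weight matrices, in f,i,o,g order
.gate_rows <- function(H) list(f = 1:H, i = (H + 1):(2 * H),
                               o = (2 * H + 1):(3 * H), g = (3 * H + 1):(4 * H))

#' Initialize LSTM weights
#'
#' Two stacked recurrent layers plus a scalar linear head. Each layer
#' holds input weights `W` (4H x D, gate blocks f, i, o, c stacked),
#' recurrent weights `U` (4H x H) and biases `b` (4H); the head maps the
#' pooled hidden state to one output. Weights are drawn uniformly from
#' `[-1/sqrt(H), 1/sqrt(H)]`.
#'
#' @param input_size Input dimension (number of regions).
#' @param hidden_size Hidden units per layer.
#' @param n_layers Number of stacked layers (default 2).
#' @param seed Integer seed.
#' @return Object of class `lstm_model`.
#' @export
init_lstm <- function(input_size, hidden_size, n_layers = 2, seed = 1L) {
  k <- 1 / sqrt(hidden_size)
  withr::with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      D <- if (l == 1) input_size else hidden_size
      list(W = matrix(runif(4 * hidden_size * D, -k, k), 4 * hidden_size, D),
           U = matrix(runif(4 * hidden_size * hidden_size, -k, k),
                      4 * hidden_size, hidden_size),
           b = runif(4 * hidden_size, -k, k))
    })
    head <- list(w = runif(hidden_size, -k, k), b = runif(1, -k, k))
    structure(list(layers = layers, head = head,
                   input_size = as.integer(input_size),
                   hidden_size = as.integer(hidden_size),
                   n_layers = as.integer(n_layers)),
              class = "lstm_model")
  })
}

#' One LSTM cell step
#'
#' Applies the gate equations to one timestep:
#' forget `f = sigmoid(W_f x + U_f h + b_f)`, input
#' `i = sigmoid(W_i x + U_i h + b_i)`, output
#' `o = sigmoid(W_o x + U_o h + b_o)`, candidate cell
#' `g = tanh(W_c x + U_c h + b_c)`, cell state `C = i * g + f * C_prev`,
#' hidden state `h = o * tanh(C)` (all products elementwise).
#'
#' @param x Input: numeric vector (length D) or D x B matrix.
#' @param prev List with `h` and `C` (H vectors or H x B matrices).
#' @param wts One layer's weights: list `W` (4H x D), `U` (4H x H),
#'   `b` (4H).
#' @return List with gate activations `f`, `i`, `o`, candidate `g`, cell
#'   state `C` and hidden state `h`.
#' @export
lstm_step <- function(x, prev, wts) {
  x <- as.matrix(x)
  h <- as.matrix(prev$h)
  C <- as.matrix(prev$C)
  H <- nrow(h)
  if (nrow(wts$W) != 4 * H || ncol(wts$W) != nrow(x) || ncol(wts$U) != H)
    stop_("dimension mismatch: W is %dx%d, U is %dx%d, x has %d rows, h has %d rows",
          nrow(wts$W), ncol(wts$W), nrow(wts$U), ncol(wts$U), nrow(x), H)
  gr <- .gate_rows(H)
  A <- wts$W %*% x + wts$U %*% h + wts$b
  f <- plogis(A[gr$f, , drop = FALSE])
  i <- plogis(A[gr$i, , drop = FALSE])
  o <- plogis(A[gr$o, , drop = FALSE])
  g <- tanh(A[gr$g, , drop = FALSE])
  Cn <- i * g + f * C
  list(f = f, i = i, o = o, g = g, C = Cn, h = o * tanh(Cn))
}

# slice timepoint t of a D x T x B array as a D x B matrix
.slice_t <- function(X, t) matrix(X[, t, ], nrow = dim(X)[1])

#' Forward pass of the masked two-layer LSTM regressor
#'
#' Runs the stacked layers over a zero-padded batch, pools the hidden
#' states by a masked temporal mean over each trial's true length only
#' (padded timepoints never contribute, so predictions are invariant to
#' the padded length), and applies the scalar linear head
#' `pred = b + w . h_pooled`.
#'
#' @param model An `lstm_model`.
#' @param X Array D x T x B (regions x padded time x trials), or a D x T
#'   matrix for a single trial.
#' @param lengths Integer vector of true sequence lengths (1..T).
#' @param keep_cache Keep per-step activations for backpropagation.
#' @param pool `"top"` or `"both"` (see [train_config()]).
#' @return List with `pred` (length-B vector), `pooled` (H x B) and,
#'   when requested, `cache`.
#' @export
lstm_forward <- function(model, X, lengths, keep_cache = FALSE,
                         pool = "top") {
  if (length(dim(X)) == 2) X <- array(X, c(dim(X), 1))
  D <- dim(X)[1]; Tmax <- dim(X)[2]; B <- dim(X)[3]
  stopifnot(D == model$input_size, length(lengths) == B)
  if (any(lengths < 1)) stop_("every trial must have length >= 1")
  if (any(lengths > Tmax)) stop_("length exceeds padded size")
  H <- model$hidden_size
  cache <- vector("list", model$n_layers)
  input <- X
  for (l in seq_len(model$n_layers)) {
    wts <- model$layers[[l]]
    h <- matrix(0, H, B); C <- matrix(0, H, B)
    st <- list(f = array(0, c(H, Tmax, B)), i = array(0, c(H, Tmax, B)),
               o = array(0, c(H, Tmax, B)), g = array(0, c(H, Tmax, B)),
               C = array(0, c(H, Tmax, B)), h = array(0, c(H, Tmax, B)))
    for (t in seq_len(Tmax)) {
      s <- lstm_step(.slice_t(input, t), list(h = h, C = C), wts)
      h <- s$h; C <- s$C
      st$f[, t, ] <- s$f; st$i[, t, ] <- s$i; st$o[, t, ] <- s$o
      st$g[, t, ] <- s$g; st$C[, t, ] <- s$C; st$h[, t, ] <- s$h
    }
    if (keep_cache) cache[[l]] <- c(st, list(input = input))
    hl <- st$h
    input <- hl
  }
  mask <- outer(seq_len(Tmax), lengths, `<=`)  # T x B
  pool_layer <- function(harr) {
    pooled <- matrix(0, H, B)
    for (t in seq_len(Tmax)) {
      mt <- mask[t, ]
      if (any(mt)) pooled[, mt] <- pooled[, mt] +
          matrix(harr[, t, ], H, B)[, mt, drop = FALSE]
    }
    sweep(pooled, 2, lengths, "/")
  }
  top <- if (keep_cache) cache[[model$n_layers]]$h else hl
  pooled <- pool_layer(top)
  if (pool == "both") {
    if (!keep_cache) stop_("pool = 'both' requires keep_cache = TRUE internally")
    pooled <- (pooled + pool_layer(cache[[1]]$h)) / 2
  }
  pred <- drop(crossprod(model$head$w, pooled)) + model$head$b
  out <- list(pred = as.numeric(pred), pooled = pooled)
  if (keep_cache) out$cache <- list(layers = cache, mask = mask,
                                    lengths = lengths, pool = pool)
  out
}

# Backpropagation through time. Returns gradients with the same shapes as
# the model parameters. dpred: length-B vector of dLoss/dpred.
.lstm_backward <- function(model, fw, dpred) {
  cache <- fw$cache
  mask <- cache$mask
  lengths <- cache$lengths
  H <- model$hidden_size
  Tmax <- nrow(mask); B <- ncol(mask)
  gr <- .gate_rows(H)
  dpooled <- model$head$w %o% dpred               # H x B
  ghead <- list(w = drop(fw$pooled %*% dpred), b = sum(dpred))
  # distribute pooled gradient over valid timesteps
  pool_w <- if (cache$pool == "both") 0.5 else 1
  dh_pool <- function() {
    dh <- array(0, c(H, Tmax, B))
    for (t in seq_len(Tmax)) {
      mt <- mask[t, ]
      if (any(mt)) {
        tmp <- matrix(0, H, B)
        tmp[, mt] <- sweep(dpooled[, mt, drop = FALSE], 2, lengths[mt], "/")
        dh[, t, ] <- tmp * pool_w
      }
    }
    dh
  }
  grads <- vector("list", model$n_layers)
  dinput_next <- NULL   # gradient wrt the input of the layer above
  for (l in rev(seq_len(model$n_layers))) {
    st <- cache$layers[[l]]
    wts <- model$layers[[l]]
    dh_ext <- array(0, c(H, Tmax, B))
    if (l == model$n_layers) dh_ext <- dh_ext + dh_pool()
    if (l == 1 && cache$pool == "both") dh_ext <- dh_ext + dh_pool()
    if (!is.null(dinput_next)) dh_ext <- dh_ext + dinput_next
    dW <- matrix(0, nrow(wts$W), ncol(wts$W))
    dU <- matrix(0, nrow(wts$U), ncol(wts$U))
    db <- numeric(length(wts$b))
    dh_carry <- matrix(0, H, B)
    dC_carry <- matrix(0, H, B)
    dinput <- array(0, c(dim(st$input)[1], Tmax, B))
    for (t in rev(seq_len(Tmax))) {
      f <- matrix(st$f[, t, ], H, B); i <- matrix(st$i[, t, ], H, B)
      o <- matrix(st$o[, t, ], H, B); g <- matrix(st$g[, t, ], H, B)
      C <- matrix(st$C[, t, ], H, B)
      Cprev <- if (t > 1) matrix(st$C[, t - 1, ], H, B) else matrix(0, H, B)
      hprev <- if (t > 1) matrix(st$h[, t - 1, ], H, B) else matrix(0, H, B)
      dh <- dh_carry + matrix(dh_ext[, t, ], H, B)
      tC <- tanh(C)
      do_ <- dh * tC
      dC <- dC_carry + dh * o * (1 - tC^2)
      df <- dC * Cprev
      di <- dC * g
      dg <- dC * i
      dC_carry <- dC * f
      da <- rbind(df * f * (1 - f), di * i * (1 - i),
                  do_ * o * (1 - o), dg * (1 - g^2))
      x <- .slice_t(st$input, t)
      dW <- dW + tcrossprod(da, x)
      dU <- dU + tcrossprod(da, hprev)
      db <- db + rowSums(da)
      dinput[, t, ] <- crossprod(wts$W, da)
      dh_carry <- crossprod(wts$U, da)
    }
    grads[[l]] <- list(W = dW, U = dU, b = db)
    dinput_next <- dinput
  }
  list(layers = grads, head = ghead)
}

# Train on (X, lengths, y) with SGD + momentum and stepwise lr decay.
# Returns the model and the per-epoch training MSE.
.train_lstm <- function(X, lengths, y, config, init_seed) {
  B <- dim(X)[3]
  model <- init_lstm(dim(X)[1], config$hidden_size, seed = init_seed)
  vel <- rapply(model[c("layers", "head")], function(p) p * 0, how = "replace")
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      config$scheduler_gamma^((epoch - 1) %/% config$scheduler_step)
    ord <- withr::with_seed(derive_seed(init_seed, epoch), sample(B))
    batch_losses <- c()
    for (start in seq(1, B, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, B)]
      fw <- lstm_forward(model, X[, , idx, drop = FALSE], lengths[idx],
                         keep_cache = TRUE, pool = config$pool)
      err <- fw$pred - y[idx]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop_("training diverged (non-finite loss) at epoch %d", epoch)
      gr <- .lstm_backward(model, fw, 2 * err / length(idx))
      for (l in seq_along(model$layers)) {
        for (p in c("W", "U", "b")) {
          vel$layers[[l]][[p]] <- config$momentum * vel$layers[[l]][[p]] -
            lr * gr$layers[[l]][[p]]
          model$layers[[l]][[p]] <- model$layers[[l]][[p]] + vel$layers[[l]][[p]]
        }
      }
      for (p in c("w", "b")) {
        vel$head[[p]] <- config$momentum * vel$head[[p]] - lr * gr$head[[p]]
        model$head[[p]] <- model$head[[p]] + vel$head[[p]]
      }
      batch_losses <- c(batch_losses, loss)
    }
    losses[epoch] <- mean(batch_losses)
  }
  list(model = model, losses = losses)
}

# build the padded array (D x Tmax x N) for a cohort
.cohort_array <- function(cohort) {
  stopifnot(!is.null(cohort$trials))
  lengths <- vapply(cohort$trials, `[[`, integer(1), "n_timepoints")
  D <- nrow(cohort$trials[[1]]$X)
  Tmax <- max(lengths)
  X <- array(0, c(D, Tmax, length(cohort$trials)))
  for (i in seq_along(cohort$trials))
    X[, seq_len(lengths[i]), i] <- cohort$trials[[i]]$X
  list(X = X, lengths = lengths)
}

#' Leave-one-subject-out training of the sequence model
#'
#' Trains the two-layer masked LSTM on zero-padded trial series under
#' leave-one-subject-out cross-validation: for each subject, a fresh
#' model is trained with minibatch SGD (MSE cost, stepwise learning-rate
#' decay) on all other subjects' trials and predicts the held-out
#' subject's trials. Targets are standardized with training-fold
#' statistics and predictions mapped back. The run is deterministic given
#' `config$seed`.
#'
#' @param cohort A `bold_cohort` with series.
#' @param target `"duration_s"` (true duration), `"normalized_bias"`
#'   (human bias), or `"scene_label"` (city = 1, office = 0).
#' @param config A [train_config()].
#' @return List with `predictions` (data frame subject, trial, truth,
#'   prediction, fold), `losses` (data frame fold, epoch, mse), `target`,
#'   `config`, `failed_folds` (named list of error messages, empty when
#'   all folds trained).
#' @export
train_loso <- function(cohort,
                       target = c("duration_s", "normalized_bias",
                                  "scene_label"),
                       config = train_config()) {
  target <- match.arg(target)
  stopifnot(inherits(config, "train_config"))
  b <- cohort$behavior
  subjects <- unique(b$subject)
  if (length(subjects) < 2) stop_("leave-one-subject-out needs >= 2 subjects")
  arr <- .cohort_array(cohort)
  y <- switch(target,
              duration_s = b$duration_s,
              scene_label = as.numeric(b$scene == "city"),
              normalized_bias = human_bias(cohort)$bias)
  preds <- vector("list", length(subjects))
  losses <- vector("list", length(subjects))
  failed <- list()
  for (si in seq_along(subjects)) {
    test <- b$subject == subjects[si]
    fold_seed <- derive_seed(config$seed, si)
    res <- tryCatch({
      ytr <- y[!test]
      mu <- mean(ytr); sdev <- sd(ytr)
      if (!is.finite(sdev) || sdev == 0) sdev <- 1
      tr <- .train_lstm(arr$X[, , !test, drop = FALSE], arr$lengths[!test],
                        (ytr - mu) / sdev, config, fold_seed)
      fw <- lstm_forward(tr$model, arr$X[, , test, drop = FALSE],
                         arr$lengths[test], pool = config$pool,
                         keep_cache = (config$pool == "both"))
      list(pred = fw$pred * sdev + mu, losses = tr$losses)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[subjects[si]]] <- conditionMessage(res)
      next
    }
    preds[[si]] <- data.frame(subject = b$subject[test],
                              trial = b$trial[test], truth = y[test],
                              prediction = res$pred, fold = si,
                              stringsAsFactors = FALSE)
    losses[[si]] <- data.frame(fold = si,
                               epoch = seq_along(res$losses),
                               mse = res$losses)
  }
  list(predictions = do.call(rbind, preds),
       losses = do.call(rbind, losses), target = target, config = config,
       failed_folds = failed)
}

#' Rank-based AUC of continuous predictions against binary labels
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney statistic), with ties mid-ranked.
#'
#' @param predictions Numeric vector of scores.
#' @param labels Vector coercible to 0/1; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(predictions, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(predictions) == length(labels),
            all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_("both classes must be present to compute an AUC")
  r <- rank(predictions)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Small hyperparameter search for the sequence model
#'
#' Grid search over the three training hyperparameters (learning rate,
#' scheduler step size, scheduler gamma) using an inner validation split
#' of the training subjects: for each combination the model is trained on
#' the non-validation subjects and scored by MSE on the validation
#' subjects' trials; the best combination is returned as an updated
#' config. Intended to run on training subjects only, before a final
#' [train_loso()].
#'
#' @param cohort A `bold_cohort` with series.
#' @param target As in [train_loso()].
#' @param base_config A [train_config()] providing everything not tuned.
#' @param lr_grid,step_grid,gamma_grid Candidate values.
#' @param val_fraction Fraction of subjects held out for validation
#'   (default 0.25, at least one subject).
#' @return List with `config` (the winning [train_config()]), `results`
#'   (data frame of all combinations and their validation MSE).
#' @export
tune_sequence_model <- function(cohort, target = "duration_s",
                                base_config = train_config(),
                                lr_grid = c(0.01, 0.05, 0.1),
                                step_grid = c(5, 10),
                                gamma_grid = c(0.5, 0.9),
                                val_fraction = 0.25) {
  b <- cohort$behavior
  subjects <- unique(b$subject)
  if (length(subjects) < 2) stop_("need >= 2 subjects to split")
  n_val <- max(1, floor(val_fraction * length(subjects)))
  val_subjects <- withr::with_seed(base_config$seed,
                                   sample(subjects, n_val))
  arr <- .cohort_array(cohort)
  y <- switch(target,
              duration_s = b$duration_s,
              scene_label = as.numeric(b$scene == "city"),
              normalized_bias = human_bias(cohort)$bias)
  val <- b$subject %in% val_subjects
  ytr <- y[!val]
  mu <- mean(ytr); sdev <- sd(ytr)
  if (!is.finite(sdev) || sdev == 0) sdev <- 1
  combos <- expand.grid(learning_rate = lr_grid, scheduler_step = step_grid,
                        scheduler_gamma = gamma_grid,
                        KEEP.OUT.ATTRS = FALSE)
  combos$val_mse <- NA_real_
  for (i in seq_len(nrow(combos))) {
    cfg <- base_config
    cfg$learning_rate <- combos$learning_rate[i]
    cfg$scheduler_step <- as.integer(combos$scheduler_step[i])
    cfg$scheduler_gamma <- combos$scheduler_gamma[i]
    fit <- tryCatch(
      .train_lstm(arr$X[, , !val, drop = FALSE], arr$lengths[!val],
                  (ytr - mu) / sdev, cfg, derive_seed(cfg$seed, i)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fw <- lstm_forward(fit$model, arr$X[, , val, drop = FALSE],
                       arr$lengths[val], pool = cfg$pool,
                       keep_cache = (cfg$pool == "both"))
    combos$val_mse[i] <- mean((fw$pred * sdev + mu - y[val])^2)
  }
  if (all(is.na(combos$val_mse))) stop_("every combination diverged")
  best <- combos[which.min(combos$val_mse), ]
  cfg <- base_config
  cfg$learning_rate <- best$learning_rate
  cfg$scheduler_step <- as.integer(best$scheduler_step)
  cfg$scheduler_gamma <- best$scheduler_gamma
  list(config = cfg, results = combos)
}
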