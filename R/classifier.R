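#' Configuration of the 1D-CNN genotype classifier
#'
#' Defaults are conventional small-model choices: 32 filters of width 4 at
#' stride 1 with ReLU, a 64-unit fully connected layer, dropout 0.5 after
#' flattening, Adam-style adaptive steps at learning rate 1e-3, batch size
#' 64, at most 200 epochs with early-stopping patience 10. Inputs are fed as
#' the raw \{-1, 0, 1, 2\} codes without standardization. Class imbalance is
#' handled by inverse-frequency class weights in the loss (`class_weight`,
#' toggleable).
#'
#' @param n_filters Convolution filter count.
#' @param kernel_size Convolution window length, in SNPs.
#' @param stride Convolution stride.
#' @param fc_units Fully-connected hidden width.
#' @param dropout_rate Dropout probability in `[0, 1)`, applied after
#'   flattening (and at inference in Monte Carlo dropout mode).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stop patience, in epochs without validation-loss
#'   improvement; must be below `max_epochs`.
#' @param class_weight Use inverse-frequency class weights in the loss.
#' @param weight_decay Decoupled L2 penalty applied to the weight matrices
#'   (not biases) at each Adam step; default 0. Useful when the signal is
#'   sparse relative to the input width.
#' @param n_restarts Random initializations per fit; the restart with the
#'   lowest best validation loss is kept. More than one restart guards
#'   against optimization collapse when the signal is very sparse.
#' @param seed Seed governing initialization, shuffling, and dropout
#'   (restart seeds derive from it).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_filters = 32L, kernel_size = 4L, stride = 1L,
                       fc_units = 64L, dropout_rate = 0.5,
                       learning_rate = 1e-3, batch_size = 64L,
                       max_epochs = 200L, patience = 10L,
                       class_weight = TRUE, weight_decay = 0,
                       n_restarts = 1L, seed = 1L) {
  if (kernel_size < 1) stopf("kernel_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must lie in [0, 1)")
  if (patience >= max_epochs) stopf("patience must be below max_epochs")
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  structure(
    list(n_filters = as.integer(n_filters), kernel_size = as.integer(kernel_size),
         stride = as.integer(stride), fc_units = as.integer(fc_units),
         dropout_rate = dropout_rate, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), class_weight = isTRUE(class_weight),
         weight_decay = weight_decay,
         n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
    class = "cnn_config"
  )
}

#' Repeated stratified train/validation/test split plans
#'
#' For each repeat, shuffles with a repeat-specific seed (derived from `seed`
#' via [stage_seed()]), holds out a stratified 20% test set, and splits the
#' remainder 80/20 (stratified) into training and validation — 64/16/20
#' overall, with the case fraction equal across partitions within rounding.
#'
#' @param labels Binary class labels (0/1) of all samples.
#' @param n_repeats Number of repeats (default 5).
#' @param seed Master seed.
#' @return A list of `n_repeats` plans, each with `repeat_id`, `train`,
#'   `validation`, `test` index vectors, and `seed`.
#' @export
make_splits <- function(labels, n_repeats = 5L, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stopf("both classes must be present")
  for (cl in classes) {
    if (sum(labels == cl) < n_repeats) {
      stopf("class %s has fewer members (%d) than n_repeats (%d)",
            cl, sum(labels == cl), n_repeats)
    }
  }
  lapply(seq_len(n_repeats), function(r) {
    rs <- stage_seed(seed, r)
    set.seed(rs)
    train <- validation <- test <- integer(0)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_test <- round(0.20 * n)
      n_val <- round(0.16 * n)
      test <- c(test, idx[seq_len(n_test)])
      validation <- c(validation, idx[n_test + seq_len(n_val)])
      train <- c(train, idx[(n_test + n_val + 1):n])
    }
    list(repeat_id = r, train = sort(train), validation = sort(validation),
         test = sort(test), stratified = TRUE, seed = rs)
  })
}

#' Train the 1D-CNN classifier
#'
#' Minimizes (class-weighted) binary cross-entropy on the training partition
#' with Adam, evaluating validation loss after every epoch; training stops
#' when the validation loss has not improved for `patience` epochs and the
#' best-epoch weights are restored. With `n_restarts > 1` the fit is run
#' from several seeded initializations and the restart with the lowest best
#' validation loss is kept. Fully deterministic given `config$seed` and
#' fixed data.
#'
#' @param X An `encoded_matrix` (or plain numeric matrix), samples x SNPs.
#' @param labels Binary labels (0/1) for all rows of `X`.
#' @param plan One split plan from [make_splits()].
#' @param config A [cnn_config()].
#' @return A `cnn_model`: list with `config`, `params` (weights), `dims`,
#'   `history` (per-epoch train/validation losses of the kept restart),
#'   `best_epoch`, `restart` (which restart won), and the class weights used.
#' @export
cnn_train <- function(X, labels, plan, config = cnn_config()) {
  n_restarts <- config$n_restarts %||% 1L
  best_model <- NULL
  for (r in seq_len(n_restarts)) {
    cfg_r <- config
    cfg_r$seed <- if (r == 1L) config$seed else stage_seed(config$seed, 7000L + r)
    m <- cnn_train_once(X, labels, plan, cfg_r)
    m$restart <- r
    if (is.null(best_model) || m$val_loss < best_model$val_loss) best_model <- m
  }
  best_model$config <- config
  best_model
}

cnn_train_once <- function(X, labels, plan, config) {
  X <- unclass(X)
  storage.mode(X) <- "double"
  y_tr <- labels[plan$train]
  y_val <- labels[plan$validation]
  X_tr <- X[plan$train, , drop = FALSE]
  X_val <- X[plan$validation, , drop = FALSE]
  dims <- nn_dims(ncol(X), config)
  idx <- nn_im2col_index(dims)

  if (config$class_weight) {
    n <- length(y_tr)
    w1 <- n / (2 * sum(y_tr == 1))
    w0 <- n / (2 * sum(y_tr == 0))
  } else {
    w1 <- w0 <- 1
  }
  wts_tr <- ifelse(y_tr == 1, w1, w0)
  wts_val <- ifelse(y_val == 1, w1, w0)

  set.seed(config$seed)
  params <- nn_init(dims)
  state <- nn_adam_init(params)
  keep <- 1 - config$dropout_rate
  n_tr <- length(y_tr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_tr)
    batch_losses <- numeric(0)
    start <- 1L
    while (start <= n_tr) {
      end <- min(start + config$batch_size - 1L, n_tr)
      b_idx <- perm[start:end]
      Xb <- X_tr[b_idx, , drop = FALSE]
      yb <- y_tr[b_idx]
      wb <- wts_tr[b_idx]
      mask <- if (config$dropout_rate > 0) {
        matrix(stats::rbinom(nrow(Xb) * dims$L * dims$F, 1L, keep) / keep,
               nrow(Xb), dims$L * dims$F)
      } else NULL
      fwd <- nn_forward(params, Xb, dims, idx, mask)
      if (!all(is.finite(fwd$o))) {
        stopf("non-finite pre-activation at epoch %d (train loss so far %.4f); try a lower learning rate",
              epoch, mean(batch_losses))
      }
      batch_losses <- c(batch_losses, nn_loss(fwd$p, yb, wb))
      grads <- nn_backward(params, fwd, yb, wb, dims, mask)
      upd <- nn_adam_step(params, grads, state, config$learning_rate,
                          weight_decay = config$weight_decay %||% 0)
      params <- upd$params
      state <- upd$state
      start <- end + 1L
    }
    p_val <- nn_predict_prob(params, X_val, dims, idx)
    val_loss <- nn_loss(p_val, y_val, wts_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }

  structure(
    list(config = config, params = best$params, dims = dims,
         history = history, best_epoch = best$epoch, val_loss = best$loss,
         class_weights = c(control = w0, case = w1)),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> input %d SNPs | conv %d x %d (stride %d) | fc %d | best epoch %d/%d\n",
    x$dims$N, x$dims$F, x$dims$k, x$dims$s, x$dims$H, x$best_epoch,
    nrow(x$history)))
  invisible(x)
}

#' Predict case probabilities from a trained CNN
#'
#' Deterministic at inference: dropout is disabled unless Monte Carlo mode is
#' requested. In MC-dropout mode (`mc = TRUE`) the model runs `n_passes`
#' stochastic forward passes with dropout active at `mc_rate` (default 0.5,
#' the Bayesian-approximation setting) and returns the per-sample mean and
#' spread.
#'
#' @param model A `cnn_model`.
#' @param X Matrix whose column count equals the model input width.
#' @param mc Enable Monte Carlo dropout.
#' @param n_passes Number of stochastic passes in MC mode.
#' @param mc_rate Dropout rate at inference in MC mode.
#' @param seed Seed for the MC passes.
#' @return Numeric probability vector, or in MC mode a list with `mean`,
#'   `sd`, and `n_passes`.
#' @export
cnn_predict <- function(model, X, mc = FALSE, n_passes = 100L, mc_rate = 0.5,
                        seed = 1L) {
  X <- unclass(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$dims$N) {
    stopf("input width %d does not match model input width %d", ncol(X), model$dims$N)
  }
  idx <- nn_im2col_index(model$dims)
  if (!mc) {
    return(nn_predict_prob(model$params, X, model$dims, idx))
  }
  set.seed(seed)
  keep <- 1 - mc_rate
  LF <- model$dims$L * model$dims$F
  draws <- vapply(seq_len(n_passes), function(i) {
    nn_predict_prob(model$params, X, model$dims, idx,
                    dropout_mask_fn = function(B) {
                      matrix(stats::rbinom(B * LF, 1L, keep) / keep, B, LF)
                    })
  }, numeric(nrow(X)))
  list(mean = rowMeans(draws), sd = apply(draws, 1, stats::sd),
       n_passes = n_passes)
}

#' Fit the comparison baselines
#'
#' Produces test-set probabilities, under the same split, for four reference
#' methods: the CNN with Monte Carlo dropout 0.5 at inference (a Bayesian
#' approximation), L1-penalized logistic regression (lasso), L2-penalized
#' logistic regression (ridge), and unpenalized logistic regression. The
#' penalized fits use glmnet with the penalty chosen by validation-set
#' log-loss over the regularization path. When the unpenalized fit is
#' singular or fails to converge (e.g. more SNPs than samples) it falls back
#' to ridge with a tiny penalty and is flagged.
#'
#' @param X Encoded matrix, samples x SNPs.
#' @param labels Binary labels.
#' @param plan One split plan.
#' @param config CNN configuration for the MC-dropout baseline.
#' @param model Optional already-trained `cnn_model` to reuse.
#' @param mc_passes Monte Carlo forward passes.
#' @return A list with per-method test-set probability vectors
#'   (`cnn_mc_dropout`, `lasso`, `ridge`, `logistic`), the `test` indices,
#'   and `flags` (e.g. `logistic_fallback_ridge`).
#' @export
fit_baselines <- function(X, labels, plan, config = cnn_config(), model = NULL,
                          mc_passes = 100L) {
  X <- unclass(X)
  storage.mode(X) <- "double"
  tr <- c(plan$train, plan$validation)
  X_tr <- X[plan$train, , drop = FALSE]
  y_tr <- labels[plan$train]
  X_val <- X[plan$validation, , drop = FALSE]
  y_val <- labels[plan$validation]
  X_test <- X[plan$test, , drop = FALSE]
  flags <- character(0)

  if (is.null(model)) model <- cnn_train(X, labels, plan, config)
  p_mc <- cnn_predict(model, X_test, mc = TRUE, n_passes = mc_passes,
                      seed = stage_seed(config$seed, 31L))$mean

  pick_lambda <- function(alpha) {
    fit <- glmnet::glmnet(X_tr, y_tr, family = "binomial", alpha = alpha)
    pv <- stats::predict(fit, X_val, type = "response")
    losses <- apply(pv, 2, function(p) {
      p <- clip01(p)
      -mean(y_val * log(p) + (1 - y_val) * log(1 - p))
    })
    list(fit = fit, lambda = fit$lambda[which.min(losses)])
  }
  las <- pick_lambda(1)
  rid <- pick_lambda(0)
  p_lasso <- as.vector(stats::predict(las$fit, X_test, s = las$lambda, type = "response"))
  p_ridge <- as.vector(stats::predict(rid$fit, X_test, s = rid$lambda, type = "response"))

  p_logit <- tryCatch({
    df_tr <- cbind(1, X[tr, , drop = FALSE])
    if (ncol(df_tr) >= length(tr)) stop("underdetermined")
    fit <- suppressWarnings(stats::glm.fit(df_tr, labels[tr], family = stats::binomial()))
    if (!fit$converged || anyNA(fit$coefficients)) stop("singular or unconverged")
    as.vector(stats::plogis(cbind(1, X_test) %*% fit$coefficients))
  }, error = function(e) {
    flags <<- c(flags, "logistic_fallback_ridge")
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], labels[tr], family = "binomial",
                          alpha = 0, lambda = 1e-6)
    as.vector(stats::predict(fit, X_test, s = 1e-6, type = "response"))
  })

  list(cnn_mc_dropout = p_mc, lasso = p_lasso, ridge = p_ridge,
       logistic = p_logit, test = plan$test, flags = flags, model = model)
}
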