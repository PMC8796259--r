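# Internal 1D-CNN engine.
#
# Architecture (fixed topology, tunable sizes): input N x 1 -> 1D convolution
# (n_filters, kernel_size, stride, ReLU) -> flatten -> dropout -> fully
# connected (fc_units, ReLU) -> single logistic output. Implemented with
# dense matrix algebra: the convolution is an im2col gather followed by one
# (B*L) x k by k x F multiplication, so all heavy work goes through BLAS.
#
# Layout conventions used throughout (B samples, L conv positions, F filters):
#   ZZ   (B*L) x k   row (u-1)*B + b holds input window u of sample b
#   A    (B*L) x F   conv activation A[b, u, f] at row (u-1)*B + b
#   Aflat  B x (L*F) column (f-1)*L + u  (the same memory, re-dimensioned)
# W1 rows follow the Aflat column order.

nn_dims <- function(N, config) {
  k <- config$kernel_size
  s <- config$stride
  if (N < k) stopf("kernel_size (%d) exceeds feature count (%d)", k, N)
  L <- (N - k) %/% s + 1L
  list(N = N, k = k, s = s, L = L, F = config$n_filters, H = config$fc_units)
}

nn_im2col_index <- function(dims) {
  # L x k matrix of input column indices
  outer(seq_len(dims$L) - 1L, seq_len(dims$k), function(u, j) u * dims$s + j)
}

nn_init <- function(dims) {
  # He initialization for the ReLU layers, small logistic head
  list(
    Wc = matrix(stats::rnorm(dims$k * dims$F, sd = sqrt(2 / dims$k)), dims$k, dims$F),
    bc = numeric(dims$F),
    W1 = matrix(stats::rnorm(dims$L * dims$F * dims$H, sd = sqrt(2 / (dims$L * dims$F))),
                dims$L * dims$F, dims$H),
    b1 = numeric(dims$H),
    w2 = matrix(stats::rnorm(dims$H, sd = sqrt(1 / dims$H)), dims$H, 1),
    b2 = 0
  )
}

nn_forward <- function(params, X, dims, idx, dropout_mask = NULL) {
  B <- nrow(X)
  ZZ <- X[, as.vector(idx), drop = FALSE]
  dim(ZZ) <- c(B * dims$L, dims$k)
  Cpre <- ZZ %*% params$Wc
  Cpre <- Cpre + rep(params$bc, each = nrow(Cpre))
  A <- pmax(Cpre, 0)
  Aflat <- A
  dim(Aflat) <- c(B, dims$L * dims$F)
  Adrop <- if (is.null(dropout_mask)) Aflat else Aflat * dropout_mask
  Hpre <- Adrop %*% params$W1
  Hpre <- Hpre + rep(params$b1, each = B)
  Hact <- pmax(Hpre, 0)
  o <- as.vector(Hact %*% params$w2) + params$b2
  list(ZZ = ZZ, Cpre = Cpre, A = A, Aflat = Aflat, Adrop = Adrop,
       Hpre = Hpre, Hact = Hact, o = o, p = stats::plogis(o))
}

nn_backward <- function(params, fwd, y, wts, dims, dropout_mask = NULL) {
  B <- length(y)
  d_o <- matrix(wts * (fwd$p - y) / B, B, 1)
  g_w2 <- crossprod(fwd$Hact, d_o)
  g_b2 <- sum(d_o)
  d_h <- (d_o %*% t(params$w2)) * (fwd$Hpre > 0)
  g_W1 <- crossprod(fwd$Adrop, d_h)
  g_b1 <- colSums(d_h)
  d_Aflat <- d_h %*% t(params$W1)
  if (!is.null(dropout_mask)) d_Aflat <- d_Aflat * dropout_mask
  dim(d_Aflat) <- c(B * dims$L, dims$F)
  d_C <- d_Aflat * (fwd$Cpre > 0)
  g_Wc <- crossprod(fwd$ZZ, d_C)
  g_bc <- colSums(d_C)
  list(Wc = g_Wc, bc = g_bc, W1 = g_W1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
}

nn_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr, weight_decay = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- mhat / (sqrt(vhat) + eps)
    # decoupled L2 decay on weight matrices, never on biases
    if (weight_decay > 0 && nm %in% c("Wc", "W1", "w2")) {
      step <- step + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

nn_loss <- function(p, y, wts, eps = 1e-7) {
  p <- clip01(p, eps)
  -mean(wts * (y * log(p) + (1 - y) * log(1 - p)))
}

# forward in memory-bounded chunks, probabilities only
nn_predict_prob <- function(params, X, dims, idx, chunk = 1024L,
                            dropout_mask_fn = NULL) {
  B <- nrow(X)
  p <- numeric(B)
  start <- 1L
  while (start <= B) {
    end <- min(start + chunk - 1L, B)
    Xi <- X[start:end, , drop = FALSE]
    mask <- if (is.null(dropout_mask_fn)) NULL else dropout_mask_fn(nrow(Xi))
    p[start:end] <- nn_forward(params, Xi, dims, idx, mask)$p
    start <- end + 1L
  }
  p
}
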