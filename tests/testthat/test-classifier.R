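test_that("split plans are 64/16/20, stratified, disjoint, deterministic", {
  y <- rep(c(1, 0), c(872, 5486))
  plans <- make_splits(y, n_repeats = 3, seed = 9)
  for (pl in plans) {
    all_idx <- c(pl$train, pl$validation, pl$test)
    expect_equal(sort(all_idx), seq_along(y))           # exhaustive, disjoint
    expect_equal(length(pl$test), round(0.2 * 872) + round(0.2 * 5486))
    expect_lte(abs(length(pl$train) - 0.64 * length(y)), 2)
    expect_lte(abs(length(pl$validation) - 0.16 * length(y)), 2)
    # case fraction preserved within rounding in every partition
    frac <- mean(y == 1)
    for (part in list(pl$train, pl$validation, pl$test)) {
      expect_lt(abs(mean(y[part] == 1) - frac), 1.5 / length(part) + 1e-9)
    }
  }
  plans2 <- make_splits(y, n_repeats = 3, seed = 9)
  expect_identical(plans, plans2)
  expect_false(identical(plans, make_splits(y, n_repeats = 3, seed = 10)))
  # balanced toy case: exactly 64/16/20
  y2 <- rep(c(0, 1), each = 50)
  pl2 <- make_splits(y2, n_repeats = 1, seed = 1)[[1]]
  expect_equal(lengths(pl2[c("train", "validation", "test")]),
               c(train = 64, validation = 16, test = 20))
})

test_that("a class smaller than the repeat count is rejected", {
  expect_error(make_splits(c(1, rep(0, 50)), n_repeats = 5, seed = 1),
               "fewer members")
})

test_that("constant inputs learn the base rate and nothing else", {
  set.seed(4)
  y <- rbinom(300, 1, 0.3)
  y[1:2] <- c(0, 1)
  X <- matrix(1, 300, 8)
  plan <- make_splits(y, n_repeats = 1, seed = 2)[[1]]
  m <- cnn_train(X, y, plan, fast_cnn(seed = 3, class_weight = FALSE,
                                      dropout_rate = 0))
  p <- cnn_predict(m, X[plan$validation, , drop = FALSE])
  base <- mean(y[plan$train])
  expect_lt(max(abs(p - base)), 0.12)
  # identical inputs give identical predictions: all ties, rank AUC exactly 0.5
  expect_equal(auc_mann_whitney(p, y[plan$validation]), 0.5)
})

test_that("a perfectly separating SNP is learned to AUC ~ 1", {
  set.seed(2)
  n <- 600
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(sample(0:2, n * 10, TRUE), n, 10)
  X[, 5] <- ifelse(y == 1, 2L, 0L)
  plan <- make_splits(y, n_repeats = 1, seed = 5)[[1]]
  m <- cnn_train(X, y, plan, fast_cnn(seed = 7))
  p <- cnn_predict(m, X[plan$test, , drop = FALSE])
  expect_gte(auc_mann_whitney(p, y[plan$test]), 0.99)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(8)
  y <- rbinom(200, 1, 0.5)
  y[1:2] <- c(0, 1)
  X <- matrix(rnorm(200 * 12), 200, 12)
  plan <- make_splits(y, n_repeats = 1, seed = 3)[[1]]
  cfg <- fast_cnn(seed = 21, max_epochs = 15, patience = 5)
  m1 <- cnn_train(X, y, plan, cfg)
  m2 <- cnn_train(X, y, plan, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("early stopping restores the epoch with minimal validation loss", {
  set.seed(9)
  y <- rbinom(250, 1, 0.4)
  y[1:2] <- c(0, 1)
  X <- matrix(rnorm(250 * 10), 250, 10)
  X[, 3] <- X[, 3] + y
  plan <- make_splits(y, n_repeats = 1, seed = 4)[[1]]
  m <- cnn_train(X, y, plan, fast_cnn(seed = 5, max_epochs = 30, patience = 4))
  expect_equal(m$history$val_loss[m$best_epoch], min(m$history$val_loss))
  expect_lte(m$best_epoch, nrow(m$history))
})

test_that("prediction is probabilistic, deterministic, and width-checked", {
  set.seed(10)
  y <- rep(c(0, 1), each = 50)
  X <- matrix(sample(0:2, 100 * 6, TRUE), 100, 6)
  plan <- make_splits(y, n_repeats = 1, seed = 6)[[1]]
  m <- cnn_train(X, y, plan, fast_cnn(seed = 11, max_epochs = 10, patience = 3))
  p <- cnn_predict(m, X)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated rows give identical probabilities
  X2 <- X[c(1, 1, 2, 2), , drop = FALSE]
  p2 <- cnn_predict(m, X2)
  expect_equal(p2[1], p2[2])
  expect_equal(p2[3], p2[4])
  expect_error(cnn_predict(m, X[, 1:5]), "width")
})

test_that("MC dropout returns per-sample mean and spread", {
  set.seed(12)
  y <- rep(c(0, 1), each = 50)
  X <- matrix(sample(0:2, 100 * 6, TRUE), 100, 6)
  X[, 2] <- ifelse(y == 1, 2L, 0L)
  plan <- make_splits(y, n_repeats = 1, seed = 7)[[1]]
  m <- cnn_train(X, y, plan, fast_cnn(seed = 13, max_epochs = 15, patience = 4))
  mc <- cnn_predict(m, X[1:10, , drop = FALSE], mc = TRUE, n_passes = 50,
                    mc_rate = 0.5, seed = 2)
  expect_length(mc$mean, 10)
  expect_length(mc$sd, 10)
  expect_true(all(mc$mean >= 0 & mc$mean <= 1))
  expect_true(any(mc$sd > 0))       # dropout at inference produces spread
  mc2 <- cnn_predict(m, X[1:10, , drop = FALSE], mc = TRUE, n_passes = 50,
                     mc_rate = 0.5, seed = 2)
  expect_identical(mc$mean, mc2$mean)
})

test_that("heavy weight decay drives the network toward the base rate", {
  set.seed(19)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(sample(0:2, n * 8, TRUE), n, 8)
  X[, 4] <- ifelse(y == 1, 2L, 0L)
  plan <- make_splits(y, n_repeats = 1, seed = 10)[[1]]
  free <- cnn_train(X, y, plan, fast_cnn(seed = 20, max_epochs = 15,
                                         patience = 14, dropout_rate = 0))
  heavy <- cnn_train(X, y, plan, fast_cnn(seed = 20, max_epochs = 15,
                                          patience = 14, dropout_rate = 0,
                                          weight_decay = 10))
  expect_lt(mean(abs(heavy$params$W1)), mean(abs(free$params$W1)))
  # heavy decay flattens the prediction spread relative to the free fit
  p_heavy <- cnn_predict(heavy, X[plan$test, , drop = FALSE])
  p_free <- cnn_predict(free, X[plan$test, , drop = FALSE])
  expect_lt(diff(range(p_heavy)), diff(range(p_free)))
})

test_that("ridge in the heavy-penalty limit predicts the base rate", {
  set.seed(14)
  y <- rbinom(200, 1, 0.3)
  y[1:2] <- c(0, 1)
  X <- matrix(rnorm(200 * 5), 200, 5)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = c(1e6, 1e-2))
  p <- predict(fit, X, s = 1e6, type = "response")
  expect_lt(max(abs(p - mean(y))), 0.01)
})

test_that("all four baselines separate an informative SNP", {
  set.seed(15)
  n <- 600
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(sample(0:2, n * 8, TRUE), n, 8)
  X[, 4] <- ifelse(y == 1, 2L, 0L)
  colnames(X) <- paste0("rs", 1:8)
  plan <- make_splits(y, n_repeats = 1, seed = 8)[[1]]
  res <- fit_baselines(X, y, plan, fast_cnn(seed = 16), mc_passes = 30)
  y_test <- y[plan$test]
  for (method in c("cnn_mc_dropout", "lasso", "ridge", "logistic")) {
    expect_gte(auc_mann_whitney(res[[method]], y_test), 0.95)
  }
})

test_that("unpenalized logistic falls back to tiny ridge when underdetermined", {
  set.seed(16)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(sample(0:2, n * 80, TRUE), n, 80)   # more SNPs than samples
  colnames(X) <- paste0("rs", 1:80)
  plan <- make_splits(y, n_repeats = 1, seed = 9)[[1]]
  res <- fit_baselines(X, y, plan,
                       fast_cnn(seed = 17, max_epochs = 8, patience = 2),
                       mc_passes = 10)
  expect_true("logistic_fallback_ridge" %in% res$flags)
  expect_true(all(res$logistic >= 0 & res$logistic <= 1))
})

test_that("label permutation yields chance-level test AUC", {
  set.seed(18)
  coh <- tiny_cohort(n_cases = 150, n_controls = 450, n_snps = 30,
                     log_or = c(rep(0.5, 5), rep(0, 25)), seed = 44)
  X <- encode_genotypes(coh, all_features(coh))
  y_perm <- sample(coh$samples$status)
  res <- run_cnn_pipeline(X, y_perm, n_repeats = 5, config = fast_cnn(seed = 19),
                          seed = 20)
  m <- res$report$summary
  expect_lt(abs(m$auc[m$stat == "mean"] - 0.5), 0.05)
})
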