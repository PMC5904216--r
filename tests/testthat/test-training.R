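tiny_config <- function(...) {
  args <- utils::modifyList(list(mode = "gru_mean", hidden_size = 6L,
                                 max_epochs = 15L, patience = 15L,
                                 batch_size = 32L, seed = 9L),
                            list(...))
  do.call(model_config, args)
}

test_that("predict_proba limits for untrained heads", {
  H <- 4
  hb <- grud:::new_head(H, model_config(head = "binary", batch_norm = FALSE))
  expect_equal(predict_proba(rnorm(H), hb), 0.5)
  hs <- grud:::new_head(H, model_config(head = "softmax", n_out = 3,
                                        batch_norm = FALSE))
  expect_equal(predict_proba(rnorm(H), hs), matrix(1 / 3, 1, 3))
  hs$W <- matrix(rnorm(3 * H), 3, H); hs$b <- rnorm(3)
  p <- predict_proba(matrix(rnorm(5 * H), 5, H), hs)
  expect_equal(rowSums(p), rep(1, 5))
})

test_that("cross-entropy at a zero head equals log 2 per binary label", {
  lg <- grud:::head_loss_grad(matrix(0, 8, 1), matrix(0.5, 8, 1),
                              rep(c(0, 1), 4), "binary")
  expect_equal(lg$loss, log(2))
})

test_that("co-occurrence prior: counts, degenerate rows, penalty behavior", {
  Y <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 0, 0))
  A <- cooccurrence_prior(Y)
  expect_true(isSymmetric(A))
  expect_equal(A["c", ], c(a = 1 / 6, b = 1 / 6, c = 1 / 3))  # uniform row sym.
  # disjoint tasks: identity affinity, zero off-diagonal penalty
  Yd <- cbind(c(1, 0), c(0, 1))
  Ad <- cooccurrence_prior(Yd)
  expect_equal(Ad, diag(2))
  W <- matrix(rnorm(6), 2, 3)
  expect_equal(grud:::laplacian_penalty(W, Ad, 1)$value, 0)
  # penalty is nonnegative, zero iff co-occurring rows coincide, and its
  # gradient matches finite differences / points rows toward each other
  Ac <- matrix(c(0, 1, 1, 0), 2, 2)
  W <- matrix(rnorm(6), 2, 3)
  pen <- grud:::laplacian_penalty(W, Ac, 0.7)
  expect_true(pen$value > 0)
  expect_equal(grud:::laplacian_penalty(rbind(W[1, ], W[1, ]), Ac, 0.7)$value,
               0)
  fd <- matrix(fd_grad(function(v)
    grud:::laplacian_penalty(matrix(v, 2, 3), Ac, 0.7)$value,
    as.numeric(W)), 2, 3)
  expect_equal(pen$grad, fd, tolerance = 1e-6)
  expect_true(sum((W[1, ] - pen$grad[1, ] * 1e-3 -
                   (W[2, ] - pen$grad[2, ] * 1e-3))^2) < sum((W[1, ] - W[2, ])^2))
})

test_that("fit_model learns a separable toy problem and is deterministic", {
  ds <- separable_dataset(n = 120, seed = 51)
  parts <- train_valid_test_split(ds, c(0.7, 0.3, 0), seed = 52)
  cfg <- tiny_config(max_epochs = 50L, patience = 50L)
  m <- suppressMessages(fit_model(parts$train, parts$valid, cfg))
  tr_auc <- auc(predict(m, parts$train), parts$train$labels)
  expect_gt(tr_auc, 0.99)
  # early stopping bookkeeping
  expect_equal(m$best_valid_auc, max(m$history$valid_auc))
  # first-epoch loss starts near the uninformative log 2 (zero-init head)
  expect_lt(abs(m$history$train_loss[1] - log(2)), 0.15)
  # determinism under a fixed seed
  m2 <- suppressMessages(fit_model(parts$train, parts$valid, cfg))
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
})

test_that("with no missingness and no dropout, mean- and forward-imputation
           models coincide exactly", {
  cfg0 <- synthetic_config(n_samples = 60, D = 3, T_len = 6,
                           base_rates = rep(0, 3), informative = rep(0, 3),
                           signal_strength = 1, seed = 61)
  ds <- generate_synthetic(cfg0)$dataset
  parts <- train_valid_test_split(ds, c(0.7, 0.3, 0), seed = 62)
  base <- tiny_config(max_epochs = 5L, recurrent_dropout = 0,
                      head_dropout = 0)
  ma <- suppressMessages(fit_model(parts$train, parts$valid, base))
  base$mode <- "gru_forward"
  mb <- suppressMessages(fit_model(parts$train, parts$valid, base))
  expect_equal(ma$history, mb$history, tolerance = 1e-12)
})

test_that("multitask head with co-occurrence prior trains", {
  ds <- separable_dataset(n = 60, seed = 71)
  y <- ds$labels
  ds$labels <- cbind(t1 = y, t2 = y, t3 = as.integer(runif(length(y)) < 0.3))
  parts <- train_valid_test_split(ds, c(0.7, 0.3, 0), seed = 72)
  cfg <- tiny_config(head = "multitask", n_out = 3L, lambda = 0.1,
                     max_epochs = 5L)
  m <- suppressMessages(fit_model(parts$train, parts$valid, cfg))
  p <- predict(m, parts$valid)
  expect_equal(dim(p), c(length(parts$valid$samples), 3L))
  expect_true(all(p > 0 & p < 1))
  # lambda = 0 gives a different (unpenalized) but also deterministic run
  cfg0 <- cfg; cfg0$lambda <- 0
  m0a <- suppressMessages(fit_model(parts$train, parts$valid, cfg0))
  m0b <- suppressMessages(fit_model(parts$train, parts$valid, cfg0))
  expect_identical(m0a$history, m0b$history)
})

test_that("cross-validation is stratified, fold-deterministic, and sane", {
  ds <- separable_dataset(n = 100, seed = 81)
  cfg <- tiny_config(max_epochs = 10L)
  res <- suppressMessages(evaluate_cv(ds, cfg, k = 5))
  expect_length(res$fold_auc, 5)
  expect_gt(res$mean, 0.95)
  f1 <- grud:::stratified_folds(ds$labels, 5, cfg$seed)
  f2 <- grud:::stratified_folds(ds$labels, 5, cfg$seed)
  expect_identical(f1, f2)
  for (k in 1:5) expect_true(length(unique(ds$labels[f1 == k])) == 2)
  # random labels hover at chance
  set.seed(82)
  ds$labels <- sample(ds$labels)
  res0 <- suppressMessages(evaluate_cv(ds, tiny_config(max_epochs = 4L),
                                       k = 3))
  expect_lt(abs(res0$mean - 0.5), 0.2)
})
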