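test_that("decay_rate follows the exponentiated negative rectifier", {
  expect_equal(decay_rate(c(3, 7), c(0, 0), c(0, 0)), c(1, 1))
  expect_equal(decay_rate(log(2), 1, 0), 0.5)
  expect_equal(decay_rate(5, -1, 0), 1)        # rectifier clamps negatives
  expect_error(decay_rate(-0.1, 1, 0), "nonnegative")
  # dense (hidden) case
  W <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(decay_rate(c(log(2), 0), W, c(0, 0)), c(0.5, 1))
})

test_that("decay rates live in (0, 1] and hit 1 iff preactivation <= 0", {
  set.seed(5)
  for (i in 1:100) {
    delta <- runif(4, 0, 10)
    w <- rnorm(4); b <- rnorm(4)
    g <- decay_rate(delta, w, b)
    expect_true(all(g > 0 & g <= 1))
    expect_identical(g == 1, w * delta + b <= 0)
  }
})

test_that("decay is monotone in delta when weights are nonnegative", {
  set.seed(6)
  w <- runif(3); b <- rnorm(3)
  grid <- seq(0, 8, by = 0.25)
  for (d in 1:3) {
    vals <- vapply(grid, function(x) decay_rate(rep(x, 3), w, b)[d],
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-15))
  }
})

test_that("input decay blends last observation and mean; observed pass through", {
  last <- last_observation_state(1)
  last$last_values <- 2; last$seen <- 1
  expect_equal(apply_input_decay(9, 1, last, 0, 0.3), 9)
  expect_equal(apply_input_decay(0, 0, last, 0, 1), 2)
  expect_equal(apply_input_decay(0, 0, last, 0, 0.5), 1)
  cold <- last_observation_state(1)
  expect_equal(apply_input_decay(0, 0, cold, 7, 0.123), 7)  # unseen -> mean
})

test_that("hidden decay is the elementwise product", {
  expect_equal(apply_hidden_decay(c(2, 3), c(1, 1)), c(2, 3))
  expect_equal(apply_hidden_decay(c(0, 0), c(0.2, 0.9)), c(0, 0))
  expect_equal(apply_hidden_decay(c(2, 3), c(0.5, 1)), c(1, 3))
})

test_that("gru_step limits: zero parameters halve the state; z=0 copies", {
  H <- 3
  p <- gru_parameters(2, H)
  for (f in c("W_r", "W_z", "W", "U_r", "U_z", "U"))
    p[[f]] <- p[[f]] * 0
  h <- c(1, -2, 0.5)
  expect_equal(gru_step(c(0.3, -0.1), h, p), 0.5 * h)
  p$b_z <- rep(-40, H)      # update gate pinned near 0
  expect_equal(gru_step(c(0.3, -0.1), h, p), h, tolerance = 1e-12)
  expect_error(gru_step(c(NA, 1), h, p), "finite")
})

test_that("gru_step matches the scalar-loop oracle", {
  set.seed(21)
  for (i in 1:100) {
    Din <- sample(1:4, 1); H <- sample(1:5, 1)
    p <- rand_gru_params(Din, H)
    x <- rnorm(Din); h <- rnorm(H)
    expect_equal(gru_step(x, h, p), oracle_gru_step(x, h, p),
                 tolerance = 1e-12)
  }
})

test_that("grud_step limits and oracle agreement", {
  D <- 2; H <- 3
  p0 <- grud_parameters(D, H)
  for (f in c("W_r", "W_z", "W", "U_r", "U_z", "U", "V_r", "V_z", "V"))
    p0[[f]] <- p0[[f]] * 0
  h <- c(1, -1, 2)
  last <- last_observation_state(D)
  st <- grud_step(c(1, 2), c(1, 1), c(0, 0), h, last, c(0, 0), p0)
  expect_equal(st$h, 0.5 * h)
  expect_equal(st$last$last_values, c(1, 2))
  # cold start, everything missing
  st2 <- grud_step(c(0, 0), c(0, 0), c(1, 2), h, last_observation_state(D),
                   c(0, 0), p0)
  expect_equal(st2$h, 0.5 * h)
  expect_equal(st2$last$seen, c(0, 0))

  set.seed(22)
  for (i in 1:100) {
    D <- sample(1:4, 1); H <- sample(1:4, 1)
    p <- rand_grud_params(D, H)
    x <- rnorm(D); m <- rbinom(D, 1, 0.5); delta <- runif(D, 0, 3)
    h <- rnorm(H); means <- rnorm(D)
    last <- last_observation_state(D)
    last$last_values <- rnorm(D); last$seen <- rbinom(D, 1, 0.5)
    got <- grud_step(x, m, delta, h, last, means, p)
    ref <- oracle_grud_step(x, m, delta, h, last, means, p)
    expect_equal(got$h, ref$h, tolerance = 1e-12)
    expect_equal(got$last$last_values, ref$last$last_values)
    expect_equal(got$last$seen, as.numeric(ref$last$seen))
  }
})

test_that("grud_step equals composing the decay ops with a gated step", {
  set.seed(23)
  D <- 3; H <- 4
  p <- rand_grud_params(D, H)
  x <- rnorm(D); m <- c(1, 0, 0); delta <- c(1, 2, 0.5)
  h <- rnorm(H); means <- rnorm(D)
  last <- last_observation_state(D)
  last$last_values <- rnorm(D); last$seen <- c(1, 1, 0)
  gx <- decay_rate(delta, p$w_gx, p$b_gx)
  gh <- decay_rate(delta, p$W_gh, p$b_gh)
  xhat <- apply_input_decay(x, m, last, means, gx)
  hhat <- apply_hidden_decay(h, gh)
  # gated step with V m added: reuse gru_step by folding V m into biases
  pf <- p
  pf$b_r <- p$b_r + as.numeric(p$V_r %*% m)
  pf$b_z <- p$b_z + as.numeric(p$V_z %*% m)
  pf$b <- p$b + as.numeric(p$V %*% m)
  class(pf) <- "gru_parameters"
  expect_equal(grud_step(x, m, delta, h, last, means, p)$h,
               gru_step(xhat, hhat, pf), tolerance = 1e-12)
})

test_that("forward_sequence unrolls from h0 = 0 and exposes every state", {
  set.seed(31)
  s1 <- rand_sample(1, 2, miss = 0)
  p <- rand_grud_params(2, 3)
  hs <- forward_sequence(s1, p, c(0, 0), mode = "grud")
  one <- grud_step(s1$values[1, ], s1$mask[1, ], s1$intervals[1, ],
                   numeric(3), last_observation_state(2), c(0, 0), p)
  expect_equal(hs[1, ], one$h)

  full <- rand_sample(6, 2, miss = 0)
  pg <- rand_gru_params(2, 3)
  expect_equal(forward_sequence(full, pg, c(0, 0), mode = "gru_mean"),
               forward_sequence(full, pg, c(0, 0), mode = "gru_forward"))
})

test_that("hidden norm is nonincreasing when inputs stay missing", {
  # zero gate params except the blend; zero means; all-missing input
  set.seed(32)
  D <- 2; H <- 3
  p <- grud_parameters(D, H)
  p$W_gh <- matrix(abs(rnorm(H * D)), H, D)   # nonneg: gamma_h <= 1
  h <- rnorm(H)
  last <- last_observation_state(D)
  norms <- numeric(10)
  for (t in 1:10) {
    st <- grud_step(numeric(D), numeric(D), rep(t, D), h, last, numeric(D), p)
    h <- st$h; last <- st$last
    norms[t] <- sqrt(sum(h^2))
  }
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("batched forward equals the per-sample reference on ragged batches", {
  set.seed(33)
  D <- 3; H <- 4
  samples <- lapply(c(4, 7, 2), function(Tn) rand_sample(Tn, D, 0.5))
  ds <- ts_dataset(samples, labels = c(0, 1, 0))
  means <- rnorm(D)
  p <- rand_grud_params(D, H)
  bt <- grud:::batch_tensors(ds, means, "grud")
  fw <- grud:::grud_forward_batch(bt, p, means, all_states = TRUE)
  for (i in 1:3) {
    hs <- forward_sequence(samples[[i]], p, means, mode = "grud")
    Tn <- nrow(hs)
    expect_equal(fw$h_last[i, ], hs[Tn, ], tolerance = 1e-12)
    for (t in seq_len(Tn))
      expect_equal(fw$states[[t]][i, ], hs[t, ], tolerance = 1e-12)
  }
  # baseline path too
  pg <- rand_gru_params(D, H)
  btg <- grud:::batch_tensors(ds, means, "gru_forward")
  fwg <- grud:::gru_forward_batch(btg, pg)
  for (i in 1:3) {
    hs <- forward_sequence(samples[[i]], pg, means, mode = "gru_forward")
    expect_equal(fwg$h_last[i, ], hs[nrow(hs), ], tolerance = 1e-12)
  }
})

test_that("parameter counting enumerates every trainable scalar", {
  expect_equal(count_parameters("gru_mean", 1, 1), 9)
  expect_equal(count_parameters("grud", 1, 1), 16)
  expect_equal(count_parameters("gru_simple", 1, 1),
               count_parameters("gru_mean", 3, 1))
  hs <- list(n_out = 1, batch_norm = TRUE)
  expect_equal(count_parameters("gru_mean", 5, 4, hs),
               count_parameters("gru_mean", 5, 4) + 4 + 1 + 8)
})

test_that("match_hidden_size is a fixed point, monotone, and equals the scan", {
  hs <- list(n_out = 1, batch_norm = TRUE)
  own <- count_parameters("grud", 10, 32, hs)
  expect_equal(match_hidden_size(own, "grud", 10, hs)$H, 32)
  h1 <- match_hidden_size(5000, "gru_simple", 10, hs)$H
  h2 <- match_hidden_size(20000, "gru_simple", 10, hs)$H
  expect_true(h2 >= h1)
  ref <- count_parameters("gru_simple", 10, 32, hs)
  expect_equal(match_hidden_size(ref, "grud", 10, hs)$H,
               oracle_match_H(ref, "grud", 10, hs))
  expect_error(match_hidden_size(3, "grud", 10, hs), "feasible")
})

test_that("checkpoint serialization restores parameters exactly", {
  set.seed(41)
  p <- rand_grud_params(3, 4)
  q <- grud:::deserialize_params(grud:::serialize_params(p))
  for (f in grud:::param_fields(p)) expect_identical(q[[f]], p[[f]])
})
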