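# Independent reference implementations ("oracles") used to check the
# package's vectorized code.  These are deliberately written as plain
# scalar loops / brute force and share no code with R/.

# Elapsed time since last observation by direct search: for each t, find
# the most recent step t* < t with mask 1 and return stamps[t] - stamps[t*]
# (or stamps[t] - stamps[1] if none).
oracle_delta <- function(stamps, mask) {
  Tn <- length(stamps); D <- ncol(mask)
  out <- matrix(0, Tn, D)
  for (d in seq_len(D)) {
    for (t in seq_len(Tn)) {
      if (t == 1) { out[t, d] <- 0; next }
      tstar <- 0
      for (u in seq_len(t - 1)) if (mask[u, d] == 1) tstar <- u
      out[t, d] <- if (tstar == 0) stamps[t] - stamps[1]
                   else stamps[t] - stamps[tstar]
    }
  }
  out
}

oracle_sigmoid <- function(v) 1 / (1 + exp(-v))

# Scalar-loop GRU step.
oracle_gru_step <- function(x, h, p) {
  H <- length(h)
  r <- z <- cand <- hn <- numeric(H)
  for (j in seq_len(H)) {
    r[j] <- oracle_sigmoid(sum(p$W_r[j, ] * x) + sum(p$U_r[j, ] * h) +
                           p$b_r[j])
    z[j] <- oracle_sigmoid(sum(p$W_z[j, ] * x) + sum(p$U_z[j, ] * h) +
                           p$b_z[j])
  }
  for (j in seq_len(H)) {
    cand[j] <- tanh(sum(p$W[j, ] * x) + sum(p$U[j, ] * (r * h)) + p$b[j])
    hn[j] <- (1 - z[j]) * h[j] + z[j] * cand[j]
  }
  hn
}

# Scalar-loop GRU-D step.  `last` is a list(last_values, seen) as in the
# package but consumed with explicit loops.
oracle_grud_step <- function(x, m, delta, h, last, means, p) {
  D <- length(x); H <- length(h)
  gx <- numeric(D)
  for (d in seq_len(D))
    gx[d] <- exp(-max(0, p$w_gx[d] * delta[d] + p$b_gx[d]))
  gh <- numeric(H)
  for (j in seq_len(H))
    gh[j] <- exp(-max(0, sum(p$W_gh[j, ] * delta) + p$b_gh[j]))
  xhat <- numeric(D)
  for (d in seq_len(D)) {
    carried <- if (last$seen[d] == 1) last$last_values[d] else means[d]
    xhat[d] <- m[d] * x[d] +
      (1 - m[d]) * (gx[d] * carried + (1 - gx[d]) * means[d])
  }
  hhat <- gh * h
  r <- z <- cand <- hn <- numeric(H)
  for (j in seq_len(H)) {
    r[j] <- oracle_sigmoid(sum(p$W_r[j, ] * xhat) + sum(p$U_r[j, ] * hhat) +
                           sum(p$V_r[j, ] * m) + p$b_r[j])
    z[j] <- oracle_sigmoid(sum(p$W_z[j, ] * xhat) + sum(p$U_z[j, ] * hhat) +
                           sum(p$V_z[j, ] * m) + p$b_z[j])
  }
  for (j in seq_len(H)) {
    cand[j] <- tanh(sum(p$W[j, ] * xhat) + sum(p$U[j, ] * (r * hhat)) +
                    sum(p$V[j, ] * m) + p$b[j])
    hn[j] <- (1 - z[j]) * hhat[j] + z[j] * cand[j]
  }
  for (d in seq_len(D)) {
    if (m[d] == 1) { last$last_values[d] <- x[d]; last$seen[d] <- 1 }
  }
  list(h = hn, last = last)
}

# O(n^2) pairwise AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Brute-force hidden-size scan.
oracle_match_H <- function(reference, mode, D, head_spec, Hmax = 300) {
  best <- NA_integer_
  for (H in seq_len(Hmax))
    if (count_parameters(mode, D, H, head_spec) <= reference) best <- H
  best
}

# Random sample with controllable missingness; stamps irregular.
rand_sample <- function(Tn, D, miss = 0.4, id = "s") {
  raw <- matrix(rnorm(Tn * D), Tn, D)
  raw[matrix(runif(Tn * D) < miss, Tn, D)] <- NA
  stamps <- c(0, sort(runif(Tn - 1, 0, Tn)))
  ts_sample(raw, stamps, id)
}

# Randomized GRU-D parameters (decay weights included, so decay
# preactivations are generically away from the ReLU kink).
rand_grud_params <- function(D, H, scale = 0.5) {
  p <- grud_parameters(D, H)
  for (f in c("W_r", "W_z", "W", "V_r", "V_z", "V"))
    p[[f]] <- matrix(rnorm(H * D, 0, scale), H, D)
  for (f in c("U_r", "U_z", "U"))
    p[[f]] <- matrix(rnorm(H * H, 0, scale), H, H)
  for (f in c("b_r", "b_z", "b", "b_gh")) p[[f]] <- rnorm(H, 0, scale)
  p$w_gx <- rnorm(D, 0, scale); p$b_gx <- rnorm(D, 0, scale)
  p$W_gh <- matrix(rnorm(H * D, 0, scale), H, D)
  p
}

rand_gru_params <- function(Din, H, scale = 0.5) {
  p <- gru_parameters(Din, H)
  for (f in c("W_r", "W_z", "W"))
    p[[f]] <- matrix(rnorm(H * Din, 0, scale), H, Din)
  for (f in c("U_r", "U_z", "U"))
    p[[f]] <- matrix(rnorm(H * H, 0, scale), H, H)
  for (f in c("b_r", "b_z", "b")) p[[f]] <- rnorm(H, 0, scale)
  p
}

# Small linearly separable dataset: classes differ by the mean of an
# always-observed variable.
separable_dataset <- function(n = 120, Tn = 8, D = 4, shift = 4, seed = 1) {
  cfg <- synthetic_config(n_samples = n, D = D, T_len = Tn,
                          base_rates = c(0, rep(0.3, D - 1)),
                          informative = rep(0, D), rho = 0,
                          signal_strength = shift, signal_vars = 1L,
                          seed = seed)
  generate_synthetic(cfg)$dataset
}

# Central finite differences of f at x.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e1 <- x; e1[i] <- e1[i] + h
    e0 <- x; e0[i] <- e0[i] - h
    (f(e1) - f(e0)) / (2 * h)
  }, numeric(1))
}
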