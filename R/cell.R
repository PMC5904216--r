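sigmoid <- function(x) 1 / (1 + exp(-x))

#' Trainable decay rate
#'
#' `gamma = exp(-max(0, W delta + b))`, elementwise, always in `(0, 1]`.
#' The exponentiated negative rectifier keeps the rate monotonically
#' nonincreasing in the elapsed time whenever the weights are nonnegative,
#' and equal to 1 exactly when the rectified preactivation is zero.
#'
#' @param delta nonnegative elapsed-time vector (length `D`).
#' @param weight either a length-`D` vector (diagonal case: per-variable
#'   input decay) or an `H x D` matrix (dense case: hidden decay).
#' @param bias length matching the output.
#' @return decay vector in `(0, 1]` (length `D` or `H`).
#' @export
decay_rate <- function(delta, weight, bias) {
  if (any(delta < 0)) stop("delta must be nonnegative")
  pre <- if (is.matrix(weight)) as.numeric(weight %*% delta) + bias
         else weight * delta + bias
  exp(-pmax(0, pre))
}

#' Decay a stale input toward the empirical mean
#'
#' For an observed variable the measurement passes through unchanged.  For a
#' missing variable the model uses a convex blend of the last observation
#' and the training mean, `gamma * x_last + (1 - gamma) * mean`, so the
#' imputed value relaxes toward the mean as the variable stays unobserved.
#' Before a variable's first observation the blend collapses to the mean.
#'
#' @param x length-`D` current measurements (placeholder where missing).
#' @param m length-`D` 0/1 mask.
#' @param last a [last_observation_state()].
#' @param means length-`D` empirical means.
#' @param gamma_x length-`D` input decay rates in `(0, 1]`.
#' @return length-`D` decayed input.
#' @export
apply_input_decay <- function(x, m, last, means, gamma_x) {
  stopifnot(length(x) == length(m), length(x) == length(gamma_x))
  carried <- ifelse(last$seen == 1, last$last_values, means)
  m * x + (1 - m) * (gamma_x * carried + (1 - gamma_x) * means)
}

#' Decay the previous hidden state
#'
#' @param h_prev length-`H` hidden state.
#' @param gamma_h length-`H` decay rates in `(0, 1]`.
#' @return `gamma_h * h_prev`.
#' @export
apply_hidden_decay <- function(h_prev, gamma_h) {
  stopifnot(length(h_prev) == length(gamma_h))
  gamma_h * h_prev
}

#' Carry-forward state for the input decay
#'
#' Tracks, per variable, the last observed value and whether any observation
#' has occurred yet.  `last_values[d]` is meaningful only where
#' `seen[d] == 1`.
#'
#' @param D number of variables.
#' @return object of class `last_observation_state`.
#' @export
last_observation_state <- function(D) {
  structure(list(last_values = numeric(D), seen = numeric(D)),
            class = "last_observation_state")
}

update_last_observation <- function(last, x, m) {
  last$last_values <- m * x + (1 - m) * last$last_values
  last$seen <- pmax(last$seen, m)
  last
}

#' One step of a standard GRU cell
#'
#' Reset gate `r = sigma(W_r x + U_r h + b_r)`, update gate
#' `z = sigma(W_z x + U_z h + b_z)`, candidate
#' `c = tanh(W x + U (r * h) + b)`, new state
#' `h' = (1 - z) * h + z * c`.
#'
#' @param x length-`Din` input.
#' @param h_prev length-`H` previous hidden state.
#' @param params a [gru_parameters()] object.
#' @param trace if `TRUE`, attach the gate activations as attribute
#'   `"trace"` (testing aid, not part of the public contract).
#' @return length-`H` new hidden state.
#' @export
gru_step <- function(x, h_prev, params, trace = FALSE) {
  if (!all(is.finite(x)) || !all(is.finite(h_prev)))
    stop("non-finite input to gru_step")
  r <- sigmoid(as.numeric(params$W_r %*% x + params$U_r %*% h_prev) + params$b_r)
  z <- sigmoid(as.numeric(params$W_z %*% x + params$U_z %*% h_prev) + params$b_z)
  cand <- tanh(as.numeric(params$W %*% x + params$U %*% (r * h_prev)) + params$b)
  h <- (1 - z) * h_prev + z * cand
  if (trace) attr(h, "trace") <- list(r = r, z = z, candidate = cand)
  h
}

#' One step of the GRU-D cell
#'
#' Computes the per-variable input decay from the elapsed times, blends
#' missing inputs toward the empirical mean, decays the previous hidden
#' state, and applies GRU gating with the mask fed to every gate through the
#' `V` matrices:
#' `r = sigma(W_r xhat + U_r hhat + V_r m + b_r)` (and likewise for `z` and
#' the candidate), `h' = (1 - z) * hhat + z * c`.
#'
#' @param x,m,delta length-`D` measurements, mask and elapsed times.
#' @param h_prev length-`H` previous hidden state.
#' @param last a [last_observation_state()]; updated where `m == 1`.
#' @param means length-`D` empirical means.
#' @param params a [grud_parameters()] object.
#' @param trace attach gate activations and decays as attribute `"trace"`.
#' @return list with `h` (length `H`) and the updated `last`.
#' @export
grud_step <- function(x, m, delta, h_prev, last, means, params,
                      trace = FALSE) {
  if (!all(is.finite(x)) || !all(is.finite(h_prev)))
    stop("non-finite input to grud_step")
  gamma_x <- decay_rate(delta, params$w_gx, params$b_gx)
  gamma_h <- decay_rate(delta, params$W_gh, params$b_gh)
  xhat <- apply_input_decay(x, m, last, means, gamma_x)
  hhat <- apply_hidden_decay(h_prev, gamma_h)
  r <- sigmoid(as.numeric(params$W_r %*% xhat + params$U_r %*% hhat +
                          params$V_r %*% m) + params$b_r)
  z <- sigmoid(as.numeric(params$W_z %*% xhat + params$U_z %*% hhat +
                          params$V_z %*% m) + params$b_z)
  cand <- tanh(as.numeric(params$W %*% xhat + params$U %*% (r * hhat) +
                          params$V %*% m) + params$b)
  h <- (1 - z) * hhat + z * cand
  last <- update_last_observation(last, x, m)
  if (trace)
    attr(h, "trace") <- list(r = r, z = z, candidate = cand,
                             gamma_x = gamma_x, gamma_h = gamma_h,
                             xhat = xhat, hhat = hhat)
  list(h = h, last = last)
}

#' Unroll a recurrent cell over one sample
#'
#' Starts from `h_0 = 0` and returns every hidden state, so online
#' (truncated-prefix) evaluation can read any prefix.  For the baseline
#' modes the sample is first turned into a complete input matrix (mean or
#' forward imputation, optionally concatenated with mask and intervals) and
#' fed to a plain GRU; `"grud"` runs the decay cell on the raw
#' values/mask/interval representation.
#'
#' @param sample a `ts_sample`.
#' @param params `gru_parameters` (baselines) or `grud_parameters`
#'   (`"grud"`).
#' @param means length-`D` empirical means from the training split.
#' @param mode `"grud"`, `"gru_mean"`, `"gru_forward"` or `"gru_simple"`.
#' @param variant [simple_variant()], used by `"gru_simple"`.
#' @return `T x H` matrix of hidden states `h_1 .. h_T`.
#' @export
forward_sequence <- function(sample, params, means,
                             mode = c("grud", "gru_mean", "gru_forward",
                                      "gru_simple"),
                             variant = simple_variant()) {
  mode <- match.arg(mode)
  Tn <- nrow(sample$values)
  H <- params$hidden_size
  hs <- matrix(0, Tn, H)
  h <- numeric(H)
  if (mode == "grud") {
    if (!inherits(params, "grud_parameters"))
      stop("mode 'grud' needs grud_parameters")
    last <- last_observation_state(ncol(sample$values))
    for (t in seq_len(Tn)) {
      st <- grud_step(sample$values[t, ], sample$mask[t, ],
                      sample$intervals[t, ], h, last, means, params)
      h <- st$h; last <- st$last
      hs[t, ] <- h
    }
  } else {
    xin <- model_input_matrix(sample, means, mode, variant)
    if (ncol(xin) != params$input_size)
      stop("parameter input size does not match mode input width")
    for (t in seq_len(Tn)) {
      h <- gru_step(xin[t, ], h, params)
      hs[t, ] <- h
    }
  }
  hs
}

## Complete input matrix for the baseline (plain-GRU) modes.
model_input_matrix <- function(sample, means, mode,
                               variant = simple_variant()) {
  switch(mode,
    gru_mean = mean_impute(sample, means),
    gru_forward = forward_impute(sample, means),
    gru_simple = simple_concat(sample, mean_impute(sample, means), variant),
    stop("unknown baseline mode: ", mode))
}
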