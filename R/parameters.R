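## Trainable parameter containers.  Weight matrices follow the H x Din
## convention (gate preactivation = W %*% x + U %*% h + b); batched code
## multiplies with the transposes.

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize parameters for a plain GRU cell
#'
#' Gate weights use fan-based uniform (Glorot) initialization; biases start
#' at zero.
#'
#' @param input_size input width `Din`.
#' @param hidden_size hidden width `H`.
#' @return object of class `gru_parameters`: `W_r, W_z, W` (`H x Din`),
#'   `U_r, U_z, U` (`H x H`), `b_r, b_z, b` (length `H`).
#' @export
gru_parameters <- function(input_size, hidden_size) {
  H <- hidden_size; Din <- input_size
  structure(list(
    W_r = glorot(H, Din), W_z = glorot(H, Din), W = glorot(H, Din),
    U_r = glorot(H, H),   U_z = glorot(H, H),   U = glorot(H, H),
    b_r = numeric(H), b_z = numeric(H), b = numeric(H),
    input_size = Din, hidden_size = H
  ), class = "gru_parameters")
}

#' Initialize parameters for a GRU-D cell
#'
#' On top of the plain GRU weights (with `Din = D`), GRU-D owns mask-input
#' matrices `V_r, V_z, V` (`H x D`), a diagonal input-decay weight stored as
#' the length-`D` vector `w_gx` with bias `b_gx`, and a dense hidden-decay
#' weight `W_gh` (`H x D`) with bias `b_gh`.  Decay parameters start at zero
#' so training begins at decay rate 1 (no decay), i.e. in the standard-GRU
#' regime.  The input-decay weight is diagonal by design so each variable's
#' decay depends only on its own elapsed time.
#'
#' @param n_variables number of input variables `D`.
#' @param hidden_size hidden width `H`.
#' @return object of class `grud_parameters` (also `gru_parameters`).
#' @export
grud_parameters <- function(n_variables, hidden_size) {
  p <- gru_parameters(n_variables, hidden_size)
  H <- hidden_size; D <- n_variables
  p$V_r <- glorot(H, D); p$V_z <- glorot(H, D); p$V <- glorot(H, D)
  p$w_gx <- numeric(D); p$b_gx <- numeric(D)
  p$W_gh <- matrix(0, H, D); p$b_gh <- numeric(H)
  class(p) <- c("grud_parameters", "gru_parameters")
  p
}

gru_input_size <- function(mode, D, variant = simple_variant()) {
  switch(mode,
    grud = D,
    gru_mean = D,
    gru_forward = D,
    gru_simple = D * (1 + variant$include_mask + variant$include_interval),
    stop("unknown mode: ", mode))
}

head_param_count <- function(H, head_spec) {
  if (is.null(head_spec)) return(0L)
  n_out <- head_spec$n_out %||% 1L
  cnt <- H * n_out + n_out
  if (isTRUE(head_spec$batch_norm)) cnt <- cnt + 2L * H
  as.integer(cnt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count trainable scalars of a model
#'
#' Recurrent cell plus (optionally) the classification head.  The plain GRU
#' has `3 (H Din + H^2 + H)` scalars; GRU-D adds `3 H D` mask weights,
#' `2 D` input-decay and `H D + H` hidden-decay scalars.
#'
#' @param mode one of `"grud"`, `"gru_mean"`, `"gru_forward"`,
#'   `"gru_simple"`.
#' @param D number of input variables.
#' @param H hidden width.
#' @param head_spec `NULL`, or a list with `n_out` (output units) and
#'   logical `batch_norm`.
#' @param variant [simple_variant()] for `gru_simple`.
#' @return integer count.
#' @export
count_parameters <- function(mode, D, H, head_spec = NULL,
                             variant = simple_variant()) {
  Din <- gru_input_size(mode, D, variant)
  n <- 3L * (H * Din + H * H + H)
  if (mode == "grud") n <- n + 3L * H * D + 2L * D + H * D + H
  as.integer(n + head_param_count(H, head_spec))
}

#' Choose a hidden size matching a reference parameter budget
#'
#' Returns the largest `H >= 1` whose [count_parameters()] does not exceed
#' `reference_count`, so differently structured cells can be compared at
#' similar capacity.
#'
#' @param reference_count parameter budget (e.g. the count of a reference
#'   mean-imputation model).
#' @inheritParams count_parameters
#' @return list with `H`, `count`, and `relative_gap`
#'   (`(reference - count) / reference`).
#' @export
match_hidden_size <- function(reference_count, mode, D, head_spec = NULL,
                              variant = simple_variant()) {
  if (count_parameters(mode, D, 1L, head_spec, variant) > reference_count)
    stop("no feasible hidden size: budget too small for H = 1")
  H <- 1L
  while (count_parameters(mode, D, H + 1L, head_spec, variant) <=
         reference_count) {
    H <- H + 1L
  }
  cnt <- count_parameters(mode, D, H, head_spec, variant)
  list(H = H, count = cnt,
       relative_gap = (reference_count - cnt) / reference_count)
}

## Flatten/unflatten parameter lists for the optimizer and for finite
## differences.  Order is fixed by the names listed here.
param_fields <- function(params) {
  base <- c("W_r", "W_z", "W", "U_r", "U_z", "U", "b_r", "b_z", "b")
  if (inherits(params, "grud_parameters"))
    base <- c(base, "V_r", "V_z", "V", "w_gx", "b_gx", "W_gh", "b_gh")
  base
}

params_to_vector <- function(params) {
  unlist(lapply(param_fields(params), function(f) as.numeric(params[[f]])),
         use.names = FALSE)
}

vector_to_params <- function(vec, template) {
  i <- 0L
  for (f in param_fields(template)) {
    k <- length(template[[f]])
    x <- vec[(i + 1L):(i + k)]
    template[[f]] <- if (is.matrix(template[[f]]))
      matrix(x, nrow(template[[f]]), ncol(template[[f]])) else x
    i <- i + k
  }
  if (i != length(vec)) stop("parameter vector length mismatch")
  template
}

## Checkpoint I/O: named arrays keyed by symbol name, JSON on disk so the
## format is portable across languages.
serialize_params <- function(params) {
  out <- lapply(param_fields(params), function(f) {
    v <- params[[f]]
    if (is.matrix(v)) list(dim = dim(v), data = as.numeric(v))
    else list(dim = length(v), data = as.numeric(v))
  })
  names(out) <- param_fields(params)
  out$input_size <- params$input_size
  out$hidden_size <- params$hidden_size
  out$class <- class(params)[1]
  out
}

deserialize_params <- function(obj) {
  H <- obj$hidden_size; Din <- obj$input_size
  params <- if (identical(obj$class, "grud_parameters"))
    grud_parameters(Din, H) else gru_parameters(Din, H)
  for (f in param_fields(params)) {
    e <- obj[[f]]
    params[[f]] <- if (length(e$dim) == 2)
      matrix(e$data, e$dim[1], e$dim[2]) else as.numeric(e$data)
  }
  params
}
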