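#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted half: the probability
#' that a positive sample is scored above a uniformly drawn negative one.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(y) != length(scores)) stop("scores and labels length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

truncate_sample <- function(sample, cutoff) {
  keep <- which(sample$stamps <= cutoff)
  if (length(keep) == 0) return(NULL)
  stamps <- sample$stamps[keep]
  s <- sample
  s$values <- s$values[keep, , drop = FALSE]
  s$mask <- s$mask[keep, , drop = FALSE]
  s$stamps <- stamps
  s$intervals <- compute_time_interval(stamps, s$mask)
  s
}

#' Online (truncated-prefix) prediction curve
#'
#' Scores a trained model on growing observation prefixes: for each cutoff
#' time, every test sequence is truncated to stamps `<= cutoff`, the
#' intervals are recomputed on the prefix (the interval recursion is causal,
#' so this equals the full-sequence intervals restricted to the prefix), the
#' model is run on the prefix only, and the AUC at the prefix's last hidden
#' state is recorded.  No future observations are used at any cutoff.
#'
#' @param model a fitted binary `grud_model`.
#' @param dataset a labeled test `ts_dataset`.
#' @param cutoffs cutoff times in the stamps' native units; default is the
#'   deciles of the observation window.
#' @return data frame with columns `cutoff` and `auc`, sorted by cutoff.
#' @export
online_prediction_curve <- function(model, dataset, cutoffs = NULL) {
  if (model$head$kind != "binary")
    stop("online curves are defined for the binary head")
  max_stamp <- max(vapply(dataset$samples, function(s) max(s$stamps),
                          numeric(1)))
  if (is.null(cutoffs))
    cutoffs <- stats::quantile(seq(0, max_stamp, length.out = 100),
                               probs = seq(0.1, 1, by = 0.1), names = FALSE)
  cutoffs <- sort(cutoffs)
  out <- data.frame(cutoff = cutoffs, auc = NA_real_)
  y <- dataset$labels
  for (k in seq_along(cutoffs)) {
    trunc <- lapply(dataset$samples, truncate_sample, cutoff = cutoffs[k])
    if (all(vapply(trunc, is.null, logical(1))))
      stop("cutoff ", cutoffs[k], " precedes every sample's first stamp")
    keep <- !vapply(trunc, is.null, logical(1))
    ds <- ts_dataset(trunc[keep], slice_labels(y, which(keep)),
                     dataset$variable_names)
    scores <- predict(model, ds)
    out$auc[k] <- auc(scores, ds$labels)
  }
  out
}

#' Inspect the learned decay parameters of a GRU-D model
#'
#' Reports, per input variable, the learned input-decay curve
#' `gamma_x(delta) = exp(-max(0, w_d * delta + b_d))` evaluated on a grid of
#' elapsed times, and the distribution (all `H` values plus mean absolute
#' magnitude) of the hidden-decay weight column attached to that variable.
#' Variables whose missingness timing matters to the prediction tend to
#' acquire larger hidden-decay magnitudes.
#'
#' The report depends only on the trained parameters, not on any dataset.
#'
#' @param model a fitted `grud_model` with `mode == "grud"`, or a
#'   `grud_parameters` object.
#' @param delta_grid elapsed-time grid for the input-decay curves.
#' @param variable_names optional length-`D` names.
#' @return object of class `decay_report`: list with `delta_grid`,
#'   `gamma_x` (`length(grid) x D` matrix), `W_gh` (`H x D`),
#'   `mean_abs_W_gh` (length-`D`).
#' @export
decay_report <- function(model, delta_grid = seq(0, 10, by = 0.5),
                         variable_names = NULL) {
  params <- if (inherits(model, "grud_model")) {
    if (model$mode != "grud") stop("decay_report needs a GRU-D model")
    model$params
  } else if (inherits(model, "grud_parameters")) model
  else stop("decay_report needs a GRU-D model")
  D <- params$input_size
  gx <- vapply(seq_len(D), function(d)
    exp(-pmax(0, params$w_gx[d] * delta_grid + params$b_gx[d])),
    numeric(length(delta_grid)))
  gx <- matrix(gx, length(delta_grid), D)
  if (is.null(variable_names)) variable_names <- paste0("v", seq_len(D))
  colnames(gx) <- variable_names
  mabs <- colMeans(abs(params$W_gh))
  names(mabs) <- variable_names
  structure(list(delta_grid = delta_grid, gamma_x = gx,
                 W_gh = params$W_gh, mean_abs_W_gh = mabs),
            class = "decay_report")
}

#' @export
print.decay_report <- function(x, ...) {
  cat("<decay_report>\n  mean |W_gh| per variable:\n")
  print(round(x$mean_abs_W_gh, 4))
  invisible(x)
}
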