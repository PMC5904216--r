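#' Input layout for the concatenation baseline
#'
#' The concatenation baseline feeds `[x; m; delta]` at every step.  The two
#' published ablations drop either the mask block (`include_mask = FALSE`)
#' or the interval block (`include_interval = FALSE`).
#'
#' @param include_mask keep the mask block.
#' @param include_interval keep the interval block.
#' @return object of class `simple_variant`.
#' @export
simple_variant <- function(include_mask = TRUE, include_interval = TRUE) {
  structure(list(include_mask = isTRUE(include_mask),
                 include_interval = isTRUE(include_interval)),
            class = "simple_variant")
}

#' Mean imputation
#'
#' Replaces each missing entry of a sample by the training-split mean of its
#' variable: `x <- m * x + (1 - m) * mean`.  Observed entries are untouched.
#'
#' @param sample a `ts_sample`.
#' @param means length-`D` training means (see [compute_empirical_means()]).
#' @return `T x D` complete matrix.
#' @export
mean_impute <- function(sample, means) {
  D <- ncol(sample$values)
  if (length(means) != D) stop("means length must equal D")
  sample$mask * sample$values +
    (1 - sample$mask) * matrix(means, nrow(sample$values), D, byrow = TRUE)
}

#' Forward (last-observation-carried-forward) imputation
#'
#' Each missing entry is replaced by the variable's most recent observed
#' value.  Entries missing before the variable's first observation fall back
#' to the training mean, the same default used by mean imputation.
#'
#' @inheritParams mean_impute
#' @return `T x D` complete matrix.
#' @export
forward_impute <- function(sample, means) {
  D <- ncol(sample$values)
  if (length(means) != D) stop("means length must equal D")
  out <- sample$values
  Tn <- nrow(out)
  last <- as.numeric(means)
  for (t in seq_len(Tn)) {
    m <- sample$mask[t, ]
    last <- m * out[t, ] + (1 - m) * last
    out[t, ] <- m * out[t, ] + (1 - m) * last
  }
  out
}

#' Concatenate measurements with masks and intervals
#'
#' Builds the widened per-step input `[x; m; delta]` (blocks dropped
#' according to `variant`), where `x` is an imputed measurement matrix from
#' [mean_impute()] or [forward_impute()].  Output width is `D`, `2D` or `3D`.
#'
#' @param sample the `ts_sample` providing `mask` and `intervals`.
#' @param base imputed `T x D` matrix.
#' @param variant a [simple_variant()].
#' @return `T x D'` matrix; column layout is values, then mask (if kept),
#'   then intervals (if kept).
#' @export
simple_concat <- function(sample, base, variant = simple_variant()) {
  base <- as.matrix(base)
  if (!identical(dim(base), dim(sample$values)))
    stop("base matrix shape must match the sample")
  blocks <- list(base)
  if (variant$include_mask) blocks <- c(blocks, list(sample$mask))
  if (variant$include_interval) blocks <- c(blocks, list(sample$intervals))
  do.call(cbind, blocks)
}
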