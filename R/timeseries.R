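#' Construct a single multivariate time-series sample
#'
#' A sample holds the `T x D` measurement matrix `values`, the binary
#' observation mask `mask` (1 = observed), the shared time stamps `stamps`
#' (first stamp is 0 by convention), and the derived per-variable elapsed
#' times `intervals` (time since the variable was last observed).
#'
#' Unobserved entries of `values` carry a 0 placeholder after mask
#' construction; no operation in this package reads the placeholder except
#' through an imputation or decay step.
#'
#' @param raw_values `T x D` numeric matrix; missing entries encoded as
#'   `NA`/`NaN` (any non-finite value).
#' @param stamps length-`T` nondecreasing numeric vector with `stamps[1] == 0`.
#' @param sample_id opaque identifier.
#' @return An object of class `ts_sample` with fields `values`, `mask`,
#'   `stamps`, `intervals`, `sample_id`.
#' @export
ts_sample <- function(raw_values, stamps = NULL, sample_id = "s1") {
  raw_values <- as.matrix(raw_values)
  if (is.null(stamps)) stamps <- seq_len(nrow(raw_values)) - 1
  stamps <- as.numeric(stamps)
  if (length(stamps) != nrow(raw_values))
    stop("stamps length must equal the number of time steps")
  if (length(stamps) > 0 && abs(stamps[1]) > 0)
    stop("first stamp must be 0 (shift times so the first observation is at 0)")
  bm <- build_mask(raw_values)
  structure(list(
    values    = bm$values,
    mask      = bm$mask,
    stamps    = stamps,
    intervals = compute_time_interval(stamps, bm$mask),
    sample_id = sample_id
  ), class = "ts_sample")
}

#' Split raw measurements into values and an observation mask
#'
#' `mask[t, d]` is 1 exactly when `raw_values[t, d]` is finite; the returned
#' `values` equal the input where observed and 0 elsewhere.  An all-missing
#' column is allowed here (it is rejected later, when training means are
#' computed).
#'
#' @param raw_values rectangular numeric matrix with non-finite entries
#'   marking missing observations.
#' @return list with `values` and `mask`, both `T x D`.
#' @export
build_mask <- function(raw_values) {
  if (!is.matrix(raw_values)) {
    raw_values <- try(as.matrix(raw_values), silent = TRUE)
    if (inherits(raw_values, "try-error") || !is.numeric(raw_values))
      stop("raw_values must be coercible to a numeric matrix")
  }
  mask <- ifelse(is.finite(raw_values), 1, 0)
  values <- ifelse(mask == 1, raw_values, 0)
  storage.mode(mask) <- "double"
  storage.mode(values) <- "double"
  list(values = values, mask = mask)
}

#' Per-variable elapsed time since the last observation
#'
#' Implements the standard interval recursion: `delta[1, d] = 0`, and for
#' `t > 1`, `delta[t, d] = stamps[t] - stamps[t-1] + delta[t-1, d]` when
#' variable `d` was missing at `t-1`, else `stamps[t] - stamps[t-1]`.
#' Equivalently, `delta[t, d]` is the time elapsed since the last step
#' before `t` at which `d` was observed (or since the first stamp when it
#' never was).
#'
#' @param stamps length-`T` nondecreasing numeric vector.
#' @param mask `T x D` binary matrix.
#' @return `T x D` nonnegative matrix of intervals, same time units as
#'   `stamps`.
#' @export
compute_time_interval <- function(stamps, mask) {
  mask <- as.matrix(mask)
  Tn <- length(stamps); D <- ncol(mask)
  if (nrow(mask) != Tn) stop("mask rows must match stamps length")
  if (Tn == 0) return(matrix(0, 0, D))
  if (Tn > 1 && any(diff(stamps) < 0)) stop("stamps must be nondecreasing")
  delta <- matrix(0, Tn, D)
  if (Tn > 1) {
    gaps <- diff(stamps)
    for (t in 2:Tn) {
      delta[t, ] <- gaps[t - 1] + (1 - mask[t - 1, ]) * delta[t - 1, ]
    }
  }
  delta
}

#' Bundle samples and labels into a dataset
#'
#' @param samples list of [ts_sample()] objects sharing a common `D`.
#' @param labels per-sample labels: a binary 0/1 vector, an integer class
#'   index in `1..L`, or an `N x n` binary matrix for multi-task problems.
#' @param variable_names length-`D` character vector.
#' @param empirical_means optional length-`D` vector of per-variable means
#'   over observed training entries (set by [compute_empirical_means()]).
#' @param norm_stats optional [norm_stats()] object.
#' @return object of class `ts_dataset`.
#' @export
ts_dataset <- function(samples, labels = NULL, variable_names = NULL,
                       empirical_means = NULL, norm_stats = NULL) {
  if (length(samples) == 0) stop("dataset must contain at least one sample")
  D <- ncol(samples[[1]]$values)
  ok <- vapply(samples, function(s) ncol(s$values) == D, logical(1))
  if (!all(ok)) stop("all samples must share the same number of variables")
  if (is.null(variable_names)) variable_names <- paste0("v", seq_len(D))
  if (length(variable_names) != D) stop("variable_names must have length D")
  if (!is.null(labels)) {
    n_lab <- if (is.matrix(labels)) nrow(labels) else length(labels)
    if (n_lab != length(samples)) stop("labels length must match sample count")
  }
  structure(list(
    samples = samples, labels = labels, variable_names = variable_names,
    empirical_means = empirical_means, norm_stats = norm_stats
  ), class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  Tl <- vapply(x$samples, function(s) length(s$stamps), numeric(1))
  cat(sprintf("<ts_dataset> %d samples, D = %d, T in [%d, %d]\n",
              length(x$samples), length(x$variable_names),
              min(Tl), max(Tl)))
  invisible(x)
}

n_samples <- function(dataset) length(dataset$samples)
n_variables <- function(dataset) length(dataset$variable_names)

#' Per-variable empirical means over observed training entries
#'
#' The mean of each variable over all observed `(sample, time)` entries of
#' the training split.  These means serve both as the mean-imputation value
#' and as the resting value toward which the input decay relaxes stale
#' measurements; they must always come from the training split and be reused
#' unchanged on validation and test data.
#'
#' @param train a `ts_dataset` (training split).
#' @return length-`D` numeric vector.
#' @export
compute_empirical_means <- function(train) {
  D <- n_variables(train)
  num <- numeric(D); den <- numeric(D)
  for (s in train$samples) {
    num <- num + colSums(s$mask * s$values)
    den <- den + colSums(s$mask)
  }
  if (any(den == 0)) {
    bad <- train$variable_names[den == 0]
    stop("never-observed variable(s) in training data: ",
         paste(bad, collapse = ", "))
  }
  means <- num / den
  names(means) <- train$variable_names
  means
}

#' Per-variable normalization statistics from a training split
#'
#' Mean and standard deviation of each variable over its observed entries.
#' A constant variable (zero spread) keeps its mean but has its standard
#' deviation forced to 1, so column indices stay aligned rather than the
#' variable being dropped.
#'
#' @param train a `ts_dataset`.
#' @param provenance free-text tag recording which split produced the stats.
#' @return object of class `norm_stats` with fields `mean`, `sd`,
#'   `provenance`.
#' @export
norm_stats <- function(train, provenance = "train") {
  D <- n_variables(train)
  num <- numeric(D); den <- numeric(D); ss <- numeric(D)
  for (s in train$samples) {
    num <- num + colSums(s$mask * s$values)
    den <- den + colSums(s$mask)
  }
  if (any(den == 0)) {
    bad <- train$variable_names[den == 0]
    stop("never-observed variable(s) in training data: ",
         paste(bad, collapse = ", "))
  }
  mu <- num / den
  for (s in train$samples) {
    ctr <- sweep(s$values, 2, mu)
    ss <- ss + colSums(s$mask * ctr^2)
  }
  sd <- sqrt(ss / den)           # population sd over observed entries
  sd[sd == 0] <- 1
  structure(list(mean = mu, sd = sd, provenance = provenance),
            class = "norm_stats")
}

#' Z-score a dataset with training-split statistics
#'
#' Observed entries are standardized per variable; masks, stamps and
#' intervals are untouched.  Empirical means are recomputed on the
#' normalized scale (approximately 0 on the split that produced the stats),
#' because the input decay blends on the model's input scale.
#'
#' @param dataset a `ts_dataset`.
#' @param stats a [norm_stats()] object computed from the training split.
#' @return normalized `ts_dataset` carrying `stats` and fresh
#'   `empirical_means`.
#' @export
normalize_dataset <- function(dataset, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  D <- n_variables(dataset)
  if (length(stats$mean) != D) stop("stats dimension does not match dataset")
  samples <- lapply(dataset$samples, function(s) {
    z <- sweep(sweep(s$values, 2, stats$mean), 2, stats$sd, "/")
    s$values <- s$mask * z      # keep the 0 placeholder on missing entries
    s
  })
  out <- ts_dataset(samples, dataset$labels, dataset$variable_names,
                    norm_stats = stats)
  out$empirical_means <- compute_empirical_means(out)
  out
}

#' Undo [normalize_dataset()] with the same statistics
#'
#' @param dataset a normalized `ts_dataset`.
#' @param stats the `norm_stats` used to normalize it.
#' @return dataset on the original scale.
#' @export
denormalize_dataset <- function(dataset, stats) {
  samples <- lapply(dataset$samples, function(s) {
    x <- sweep(sweep(s$values, 2, stats$sd, "*"), 2, stats$mean, "+")
    s$values <- s$mask * x
    s
  })
  ts_dataset(samples, dataset$labels, dataset$variable_names)
}
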