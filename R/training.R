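#' Model and training configuration
#'
#' @param mode recurrent variant: `"grud"`, `"gru_mean"`, `"gru_forward"`
#'   or `"gru_simple"`.
#' @param hidden_size hidden width `H`; ignored when `reference_count` is
#'   given.
#' @param reference_count optional parameter budget; the hidden size is then
#'   chosen by [match_hidden_size()] so all modes run at similar capacity.
#' @param head one of `"binary"` (single sigmoid), `"softmax"` (`L`-class),
#'   `"multitask"` (`n` independent sigmoids).
#' @param n_out number of outputs (classes or tasks); 1 for binary.
#' @param head_dropout dropout rate on the head input (0.5 by default).
#' @param recurrent_dropout per-sequence dropout rate on the recurrent
#'   weight inputs, the same draw reused at every time step (0.3 default).
#' @param batch_norm apply batch normalization before the head.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation improvement).
#' @param batch_size minibatch size.
#' @param lambda strength of the label co-occurrence prior (multitask only).
#' @param variant [simple_variant()] for `"gru_simple"`.
#' @param seed integer seed controlling every source of randomness in
#'   [fit_model()].
#' @return object of class `model_config`.
#' @export
model_config <- function(mode = "grud", hidden_size = 16L,
                         reference_count = NULL,
                         head = c("binary", "softmax", "multitask"),
                         n_out = 1L, head_dropout = 0.5,
                         recurrent_dropout = 0.3, batch_norm = TRUE,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, max_epochs = 40L, patience = 5L,
                         batch_size = 32L, lambda = 0,
                         variant = simple_variant(), seed = 1L) {
  head <- match.arg(head)
  stopifnot(head_dropout >= 0, head_dropout < 1,
            recurrent_dropout >= 0, recurrent_dropout < 1)
  structure(list(mode = mode, hidden_size = as.integer(hidden_size),
                 reference_count = reference_count, head = head,
                 n_out = as.integer(n_out), head_dropout = head_dropout,
                 recurrent_dropout = recurrent_dropout,
                 batch_norm = isTRUE(batch_norm),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 variant = variant, seed = as.integer(seed)),
            class = "model_config")
}

new_head <- function(H, config) {
  list(kind = config$head, n_out = config$n_out,
       batch_norm = config$batch_norm, dropout = config$head_dropout,
       W = matrix(0, config$n_out, H), b = numeric(config$n_out),
       bn = if (config$batch_norm)
         list(gamma = rep(1, H), beta = numeric(H),
              run_mean = numeric(H), run_var = rep(1, H),
              momentum = 0.9, eps = 1e-5) else NULL)
}

head_forward <- function(hT, head, training = FALSE) {
  A <- hT
  cache <- list(h = hT)
  if (head$batch_norm) {
    bn <- head$bn
    if (training) {
      mu <- colMeans(A)
      ctr <- sweep(A, 2, mu)
      va <- colMeans(ctr^2)
      inv <- 1 / sqrt(va + bn$eps)
      xh <- sweep(ctr, 2, inv, "*")
      cache$bn <- list(mu = mu, va = va, inv = inv, xh = xh, ctr = ctr)
    } else {
      xh <- sweep(sweep(A, 2, bn$run_mean), 2,
                  1 / sqrt(bn$run_var + bn$eps), "*")
    }
    A <- sweep(sweep(xh, 2, bn$gamma, "*"), 2, bn$beta, "+")
  }
  if (training && head$dropout > 0) {
    keep <- 1 - head$dropout
    dmask <- matrix(stats::rbinom(length(A), 1, keep) / keep,
                    nrow(A), ncol(A))
    cache$dmask <- dmask
    A <- A * dmask
  }
  cache$A <- A
  logits <- sweep(A %*% t(head$W), 2, head$b, "+")
  probs <- switch(head$kind,
    binary = sigmoid(logits),
    multitask = sigmoid(logits),
    softmax = {
      e <- exp(logits - apply(logits, 1, max))
      e / rowSums(e)
    })
  list(logits = logits, probs = probs, cache = cache)
}

head_backward <- function(dlogits, head, cache) {
  gW <- t(dlogits) %*% cache$A
  gb <- colSums(dlogits)
  dA <- dlogits %*% head$W
  if (!is.null(cache$dmask)) dA <- dA * cache$dmask
  ggamma <- gbeta <- NULL
  if (head$batch_norm) {
    bnc <- cache$bn
    ggamma <- colSums(dA * bnc$xh)
    gbeta <- colSums(dA)
    N <- nrow(dA)
    dxh <- sweep(dA, 2, head$bn$gamma, "*")
    dva <- colSums(dxh * bnc$ctr) * (-0.5) * bnc$inv^3
    dmu <- colSums(dxh) * (-bnc$inv)
    dh <- sweep(dxh, 2, bnc$inv, "*") +
      sweep(bnc$ctr, 2, 2 * dva / N, "*") +
      matrix(dmu / N, N, length(dmu), byrow = TRUE)
  } else {
    dh <- dA
  }
  list(dh = dh, gW = gW, gb = gb, ggamma = ggamma, gbeta = gbeta)
}

## Cross-entropy loss and gradient w.r.t. logits (mean over samples; summed
## over tasks for the multitask head).
head_loss_grad <- function(logits, probs, labels, kind) {
  N <- nrow(logits)
  eps <- 1e-12
  if (kind == "binary") {
    y <- as.numeric(labels)
    p <- pmin(pmax(probs[, 1], eps), 1 - eps)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dlogits <- matrix((probs[, 1] - y) / N, N, 1)
  } else if (kind == "multitask") {
    Y <- as.matrix(labels)
    P <- pmin(pmax(probs, eps), 1 - eps)
    loss <- -sum(Y * log(P) + (1 - Y) * log(1 - P)) / N
    dlogits <- (probs - Y) / N
  } else {
    y <- as.integer(labels)
    P <- pmin(pmax(probs, eps), 1 - eps)
    loss <- -mean(log(P[cbind(seq_len(N), y)]))
    onehot <- matrix(0, N, ncol(probs))
    onehot[cbind(seq_len(N), y)] <- 1
    dlogits <- (probs - onehot) / N
  }
  list(loss = loss, dlogits = dlogits)
}

#' Class probabilities from a hidden state
#'
#' Applies the classification head (batch normalization in inference mode,
#' no dropout) to one or more hidden-state vectors.
#'
#' @param hidden length-`H` vector or `N x H` matrix of final hidden states.
#' @param head a head object from a fitted model.
#' @return binary: vector of probabilities in `(0, 1)`; softmax: `N x L`
#'   rows on the simplex; multitask: `N x n` independent probabilities.
#' @export
predict_proba <- function(hidden, head) {
  if (!is.matrix(hidden)) hidden <- matrix(hidden, 1)
  out <- head_forward(hidden, head, training = FALSE)$probs
  if (head$kind == "binary") as.numeric(out) else out
}

#' Label co-occurrence prior for multi-task heads
#'
#' Row-normalized co-occurrence counts of positive labels, symmetrized.
#' Used as the affinity matrix of a graph-Laplacian penalty
#' `lambda * sum_ij A_ij ||w_i - w_j||^2` that pulls the head-weight rows of
#' frequently co-occurring tasks together.  A task with no positive labels
#' gets a uniform row.
#'
#' @param labels `N x n` binary matrix (`n >= 2` tasks).
#' @return symmetric `n x n` affinity matrix.
#' @export
cooccurrence_prior <- function(labels) {
  Y <- as.matrix(labels)
  n <- ncol(Y)
  if (n < 2) stop("the co-occurrence prior needs at least 2 tasks")
  C <- t(Y) %*% Y
  rs <- rowSums(C)
  R <- C / ifelse(rs == 0, 1, rs)
  R[rs == 0, ] <- 1 / n
  (R + t(R)) / 2
}

laplacian_penalty <- function(W, A, lambda) {
  if (lambda == 0) return(list(value = 0, grad = 0 * W))
  n <- nrow(W)
  dif2 <- as.matrix(stats::dist(W))^2
  value <- lambda * sum(A * dif2)
  L <- diag(rowSums(A)) - A
  list(value = value, grad = 4 * lambda * (L %*% W))
}

## --- Adam over a flat parameter vector --------------------------------

flatten_state <- function(params, head) {
  v <- c(params_to_vector(params), as.numeric(head$W), head$b)
  if (head$batch_norm) v <- c(v, head$bn$gamma, head$bn$beta)
  v
}

unflatten_state <- function(vec, params, head) {
  np <- length(params_to_vector(params))
  params <- vector_to_params(vec[seq_len(np)], params)
  i <- np
  k <- length(head$W)
  head$W <- matrix(vec[(i + 1):(i + k)], nrow(head$W), ncol(head$W)); i <- i + k
  k <- length(head$b)
  head$b <- vec[(i + 1):(i + k)]; i <- i + k
  if (head$batch_norm) {
    k <- length(head$bn$gamma)
    head$bn$gamma <- vec[(i + 1):(i + k)]; i <- i + k
    head$bn$beta <- vec[(i + 1):(i + k)]; i <- i + k
  }
  list(params = params, head = head)
}

flatten_grads <- function(gcell, ghead, params, head) {
  tmpl <- params
  for (f in param_fields(params)) tmpl[[f]] <- gcell[[f]]
  v <- c(params_to_vector(tmpl), as.numeric(ghead$gW), ghead$gb)
  if (head$batch_norm) v <- c(v, ghead$ggamma, ghead$gbeta)
  v
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_update <- function(theta, grad, st, lr, b1, b2, eps) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

## Row-subset of batch tensors (minibatching).
bt_slice <- function(bt, idx) {
  sl <- function(lst) lapply(lst, function(m) m[idx, , drop = FALSE])
  if (bt$type == "grud") {
    list(type = "grud", X = sl(bt$X), M = sl(bt$M), Delta = sl(bt$Delta),
         valid = lapply(bt$valid, function(v) v[idx]),
         lens = bt$lens[idx], N = length(idx), Tmax = bt$Tmax, D = bt$D)
  } else {
    list(type = "gru", Xin = sl(bt$Xin),
         valid = lapply(bt$valid, function(v) v[idx]),
         lens = bt$lens[idx], N = length(idx), Tmax = bt$Tmax, Din = bt$Din)
  }
}

slice_labels <- function(labels, idx) {
  if (is.matrix(labels)) labels[idx, , drop = FALSE] else labels[idx]
}

validation_score <- function(scores, labels, kind) {
  if (kind == "binary") return(auc(scores, labels))
  if (kind == "multitask") {
    Y <- as.matrix(labels)
    mean(vapply(seq_len(ncol(Y)), function(j) auc(scores[, j], Y[, j]),
                numeric(1)))
  } else {
    y <- as.integer(labels)
    mean(vapply(seq_len(ncol(scores)), function(j)
      auc(scores[, j], as.numeric(y == j)), numeric(1)))
  }
}

#' Fit a recurrent classifier on irregular multivariate time series
#'
#' Normalizes both splits with training-split statistics, computes the
#' training empirical means (on the normalized scale), unrolls the selected
#' recurrent cell, and minimizes cross-entropy with Adam.  Per-sequence
#' recurrent dropout is applied to the inputs of the `W`, `U` (and, for
#' GRU-D, `V`) products with the same draw at every time step; the head
#' applies batch normalization then dropout.  After every epoch the model is
#' scored on the validation split by AUC (mean AUC across tasks or classes),
#' and the parameters with the best validation score are returned (early
#' stopping after `patience` epochs without improvement).
#'
#' @param train,valid disjoint `ts_dataset`s with labels.
#' @param config a [model_config()].
#' @return object of class `grud_model` with elements `params`, `head`,
#'   `norm_stats`, `empirical_means` (normalized scale), `config`, `mode`,
#'   and `history` (per-epoch train loss and validation AUC).
#' @export
fit_model <- function(train, valid, config) {
  set.seed(config$seed)
  if (is.null(train$labels) || is.null(valid$labels))
    stop("both splits must carry labels")
  stats <- norm_stats(train)
  train_n <- normalize_dataset(train, stats)
  valid_n <- normalize_dataset(valid, stats)
  means <- train_n$empirical_means
  D <- n_variables(train_n)
  head_spec <- list(n_out = config$n_out, batch_norm = config$batch_norm)
  H <- if (!is.null(config$reference_count))
    match_hidden_size(config$reference_count, config$mode, D, head_spec,
                      config$variant)$H else config$hidden_size
  Din <- gru_input_size(config$mode, D, config$variant)
  params <- if (config$mode == "grud") grud_parameters(D, H)
            else gru_parameters(Din, H)
  head <- new_head(H, config)
  bt_train <- batch_tensors(train_n, means, config$mode, config$variant)
  bt_valid <- batch_tensors(valid_n, means, config$mode, config$variant)
  N <- bt_train$N
  prior_A <- if (config$head == "multitask" && config$lambda > 0)
    cooccurrence_prior(train_n$labels) else NULL
  theta <- flatten_state(params, head)
  opt <- adam_init(length(theta))
  best <- list(score = -Inf, params = params, head = head)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_auc = numeric())
  stall <- 0L
  mask_size <- if (config$mode == "grud") D else NULL
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (idx in batches) {
      bt <- bt_slice(bt_train, idx)
      yb <- slice_labels(train_n$labels, idx)
      drop <- make_dropout_masks(length(idx), Din, H, mask_size,
                                 config$recurrent_dropout)
      fw <- net_forward(bt, params, means, drop, collect = TRUE)
      hf <- head_forward(fw$h_last, head, training = TRUE)
      lg <- head_loss_grad(hf$logits, hf$probs, yb, config$head)
      loss <- lg$loss
      pen <- if (is.null(prior_A)) list(value = 0, grad = 0 * head$W)
             else laplacian_penalty(head$W, prior_A, config$lambda)
      loss <- loss + pen$value
      hb <- head_backward(lg$dlogits, head, hf$cache)
      hb$gW <- hb$gW + pen$grad
      gcell <- net_backward(bt, params, means, fw$caches, hb$dh, drop)
      grad <- flatten_grads(gcell, hb, params, head)
      upd <- adam_update(theta, grad, opt, config$learning_rate,
                         config$beta1, config$beta2, config$epsilon)
      theta <- upd$theta; opt <- upd$state
      uf <- unflatten_state(theta, params, head)
      params <- uf$params; head <- uf$head
      if (head$batch_norm) {     # running stats for inference
        mom <- head$bn$momentum
        head$bn$run_mean <- mom * head$bn$run_mean +
          (1 - mom) * hf$cache$bn$mu
        head$bn$run_var <- mom * head$bn$run_var +
          (1 - mom) * hf$cache$bn$va
      }
      epoch_loss <- epoch_loss + loss * length(idx)
    }
    epoch_loss <- epoch_loss / N
    if (!is.finite(epoch_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           "; history: ",
           paste(sprintf("%.4g", history$train_loss), collapse = ", "))
    vw <- net_forward(bt_valid, params, means)
    vp <- head_forward(vw$h_last, head, training = FALSE)$probs
    vscore <- validation_score(
      if (config$head == "binary") as.numeric(vp) else vp,
      valid_n$labels, config$head)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         valid_auc = vscore))
    if (vscore > best$score) {
      best <- list(score = vscore, params = params, head = head)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(params = best$params, head = best$head, norm_stats = stats,
                 empirical_means = means, config = config,
                 mode = config$mode, variant = config$variant,
                 history = history, best_valid_auc = best$score),
            class = "grud_model")
}

#' @export
print.grud_model <- function(x, ...) {
  cat(sprintf("<grud_model> mode = %s, H = %d, best validation AUC = %.4f\n",
              x$mode, x$params$hidden_size, x$best_valid_auc))
  invisible(x)
}

#' Predict scores for new samples
#'
#' Applies the stored normalization, unrolls the recurrent cell and scores
#' the final hidden state with the head in inference mode.
#'
#' @param object a fitted `grud_model`.
#' @param dataset a `ts_dataset` (labels not required).
#' @param ... unused.
#' @return numeric vector of probabilities (binary head) or an `N x n_out`
#'   matrix.
#' @export
predict.grud_model <- function(object, dataset, ...) {
  ds <- normalize_dataset(dataset, object$norm_stats)
  bt <- batch_tensors(ds, object$empirical_means, object$mode,
                      object$variant)
  fw <- net_forward(bt, object$params, object$empirical_means)
  p <- head_forward(fw$h_last, object$head, training = FALSE)$probs
  if (object$head$kind == "binary") as.numeric(p) else p
}

stratified_folds <- function(labels, k, seed) {
  y <- if (is.matrix(labels)) labels[, 1] else labels
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated AUC
#'
#' Within each fold the held-in data are further split (stratified, 80/20)
#' into training and validation subsets for early stopping; normalization
#' statistics and empirical means are recomputed from each fold's training
#' subset only.
#'
#' @param dataset a labeled `ts_dataset`.
#' @param config a [model_config()].
#' @param k number of folds (`>= 2`).
#' @return list with `fold_auc`, `mean`, `sd`.
#' @export
evaluate_cv <- function(dataset, config, k = 5L) {
  stopifnot(k >= 2)
  fold <- stratified_folds(dataset$labels, k, config$seed)
  y1 <- if (is.matrix(dataset$labels)) dataset$labels[, 1] else
    dataset$labels
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    rest <- which(fold != f)
    if (length(unique(y1[test_idx])) < 2 ||
        length(unique(y1[rest])) < 2)
      stop("stratification failed: a fold lacks one of the classes")
    vfold <- stratified_folds(slice_labels(dataset$labels, rest), 5L,
                              config$seed + f)
    vidx <- rest[vfold == 1]
    tidx <- rest[vfold != 1]
    tr <- subset_dataset(dataset, tidx)
    va <- subset_dataset(dataset, vidx)
    te <- subset_dataset(dataset, test_idx)
    model <- fit_model(tr, va, config)
    scores <- predict(model, te)
    aucs[f] <- validation_score(scores, te$labels, config$head)
  }
  list(fold_auc = aucs, mean = mean(aucs), sd = stats::sd(aucs))
}

#' Subset a dataset by sample index
#'
#' @param dataset a `ts_dataset`.
#' @param idx integer indices.
#' @return the sub-dataset (normalization metadata is dropped, since it must
#'   be recomputed on whatever becomes the training split).
#' @export
subset_dataset <- function(dataset, idx) {
  ts_dataset(dataset$samples[idx], slice_labels(dataset$labels, idx),
             dataset$variable_names)
}
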