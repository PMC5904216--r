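## Batched recurrent computation.  All training-time math runs over a batch
## of padded sequences, represented as per-step N x D (or N x Din) matrices;
## the per-sample API in cell.R is the readable reference the batched code
## is tested against.
##
## Padding convention: steps beyond a sample's length have mask 0, values 0,
## delta 0 and validity 0; the hidden state is frozen across invalid steps,
## so the final state equals the state at the sample's last real step.

## Convert a dataset into padded per-step tensors for one mode.
batch_tensors <- function(dataset, means, mode, variant = simple_variant()) {
  N <- n_samples(dataset)
  lens <- vapply(dataset$samples, function(s) nrow(s$values), integer(1))
  Tmax <- max(lens)
  if (mode == "grud") {
    D <- n_variables(dataset)
    X <- M <- Delta <- vector("list", Tmax)
    for (t in seq_len(Tmax)) {
      X[[t]] <- matrix(0, N, D); M[[t]] <- matrix(0, N, D)
      Delta[[t]] <- matrix(0, N, D)
    }
    for (i in seq_len(N)) {
      s <- dataset$samples[[i]]
      for (t in seq_len(lens[i])) {
        X[[t]][i, ] <- s$values[t, ]
        M[[t]][i, ] <- s$mask[t, ]
        Delta[[t]][i, ] <- s$intervals[t, ]
      }
    }
    valid <- lapply(seq_len(Tmax), function(t) as.numeric(lens >= t))
    list(type = "grud", X = X, M = M, Delta = Delta, valid = valid,
         lens = lens, N = N, Tmax = Tmax, D = D)
  } else {
    ins <- lapply(dataset$samples, model_input_matrix, means = means,
                  mode = mode, variant = variant)
    Din <- ncol(ins[[1]])
    Xin <- lapply(seq_len(Tmax), function(t) matrix(0, N, Din))
    for (i in seq_len(N)) {
      for (t in seq_len(lens[i])) Xin[[t]][i, ] <- ins[[i]][t, ]
    }
    valid <- lapply(seq_len(Tmax), function(t) as.numeric(lens >= t))
    list(type = "gru", Xin = Xin, valid = valid, lens = lens, N = N,
         Tmax = Tmax, Din = Din)
  }
}

## Per-sequence dropout masks (inverted scaling), one draw per sequence
## reused at every time step, applied to the inputs of the W, U and V
## products.  rate = 0 returns NULL (no-op).
make_dropout_masks <- function(N, input_size, hidden_size, mask_size, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  dm <- function(k) matrix(stats::rbinom(N * k, 1, keep) / keep, N, k)
  list(d_x = dm(input_size), d_u = dm(hidden_size),
       d_m = if (!is.null(mask_size)) dm(mask_size) else NULL)
}

grud_forward_batch <- function(bt, params, means, drop = NULL,
                               collect = FALSE, all_states = FALSE) {
  N <- bt$N; D <- bt$D; H <- params$hidden_size
  h <- matrix(0, N, H)
  Xmean <- matrix(means, N, D, byrow = TRUE)
  Xlast <- Xmean                      # cold start: decay blend equals mean
  caches <- if (collect) vector("list", bt$Tmax) else NULL
  hs <- if (all_states) vector("list", bt$Tmax) else NULL
  w_gx <- matrix(params$w_gx, N, D, byrow = TRUE)
  b_gx <- matrix(params$b_gx, N, D, byrow = TRUE)
  for (t in seq_len(bt$Tmax)) {
    Xt <- bt$X[[t]]; Mt <- bt$M[[t]]; Dt <- bt$Delta[[t]]
    v <- bt$valid[[t]]
    q <- Dt * w_gx + b_gx
    gx <- exp(-pmax(0, q))
    p <- Dt %*% t(params$W_gh)
    p <- sweep(p, 2, params$b_gh, "+")
    gh <- exp(-pmax(0, p))
    xhat <- Mt * Xt + (1 - Mt) * (gx * Xlast + (1 - gx) * Xmean)
    hhat <- gh * h
    xd <- if (is.null(drop)) xhat else xhat * drop$d_x
    hd <- if (is.null(drop)) hhat else hhat * drop$d_u
    md <- if (is.null(drop)) Mt else Mt * drop$d_m
    a_r <- xd %*% t(params$W_r) + hd %*% t(params$U_r) + md %*% t(params$V_r)
    r <- sigmoid(sweep(a_r, 2, params$b_r, "+"))
    a_z <- xd %*% t(params$W_z) + hd %*% t(params$U_z) + md %*% t(params$V_z)
    z <- sigmoid(sweep(a_z, 2, params$b_z, "+"))
    a_c <- xd %*% t(params$W) + (r * hd) %*% t(params$U) + md %*% t(params$V)
    cand <- tanh(sweep(a_c, 2, params$b, "+"))
    h_new <- (1 - z) * hhat + z * cand
    if (collect)
      caches[[t]] <- list(Xt = Xt, Mt = Mt, Dt = Dt, v = v, q = q, gx = gx,
                          p = p, gh = gh, xhat = xhat, hhat = hhat, xd = xd,
                          hd = hd, md = md, r = r, z = z, cand = cand,
                          h_prev = h, Xlast_prev = Xlast)
    h <- v * h_new + (1 - v) * h
    Xlast <- Mt * Xt + (1 - Mt) * Xlast
    if (all_states) hs[[t]] <- h
  }
  list(h_last = h, caches = caches, states = hs)
}

grud_backward_batch <- function(bt, params, means, caches, dh_last,
                                drop = NULL) {
  N <- bt$N; D <- bt$D; H <- params$hidden_size
  Xmean <- matrix(means, N, D, byrow = TRUE)
  g <- list(W_r = matrix(0, H, params$input_size),
            W_z = matrix(0, H, params$input_size),
            W = matrix(0, H, params$input_size),
            U_r = matrix(0, H, H), U_z = matrix(0, H, H), U = matrix(0, H, H),
            b_r = numeric(H), b_z = numeric(H), b = numeric(H),
            V_r = matrix(0, H, D), V_z = matrix(0, H, D), V = matrix(0, H, D),
            w_gx = numeric(D), b_gx = numeric(D),
            W_gh = matrix(0, H, D), b_gh = numeric(H))
  dh <- dh_last
  for (t in rev(seq_len(bt$Tmax))) {
    cc <- caches[[t]]
    dh_new <- dh * cc$v
    dh_carry <- dh * (1 - cc$v)
    dz <- dh_new * (cc$cand - cc$hhat)
    dcand <- dh_new * cc$z
    dhhat <- dh_new * (1 - cc$z)
    da_c <- dcand * (1 - cc$cand^2)
    g$W <- g$W + t(da_c) %*% cc$xd
    g$U <- g$U + t(da_c) %*% (cc$r * cc$hd)
    g$V <- g$V + t(da_c) %*% cc$md
    g$b <- g$b + colSums(da_c)
    du_in <- da_c %*% params$U
    dr <- du_in * cc$hd
    dhd <- du_in * cc$r
    dxd <- da_c %*% params$W
    da_r <- dr * cc$r * (1 - cc$r)
    g$W_r <- g$W_r + t(da_r) %*% cc$xd
    g$U_r <- g$U_r + t(da_r) %*% cc$hd
    g$V_r <- g$V_r + t(da_r) %*% cc$md
    g$b_r <- g$b_r + colSums(da_r)
    dhd <- dhd + da_r %*% params$U_r
    dxd <- dxd + da_r %*% params$W_r
    da_z <- dz * cc$z * (1 - cc$z)
    g$W_z <- g$W_z + t(da_z) %*% cc$xd
    g$U_z <- g$U_z + t(da_z) %*% cc$hd
    g$V_z <- g$V_z + t(da_z) %*% cc$md
    g$b_z <- g$b_z + colSums(da_z)
    dhd <- dhd + da_z %*% params$U_z
    dxd <- dxd + da_z %*% params$W_z
    dxhat <- if (is.null(drop)) dxd else dxd * drop$d_x
    dhhat <- dhhat + if (is.null(drop)) dhd else dhd * drop$d_u
    ## input decay path
    dgx <- dxhat * (1 - cc$Mt) * (cc$Xlast_prev - Xmean)
    dq <- -dgx * cc$gx * (cc$q >= 0)
    g$w_gx <- g$w_gx + colSums(dq * cc$Dt)
    g$b_gx <- g$b_gx + colSums(dq)
    ## hidden decay path
    dgh <- dhhat * cc$h_prev
    dh_prev <- dhhat * cc$gh
    dp <- -dgh * cc$gh * (cc$p >= 0)
    g$W_gh <- g$W_gh + t(dp) %*% cc$Dt
    g$b_gh <- g$b_gh + colSums(dp)
    dh <- dh_prev + dh_carry
  }
  g
}

gru_forward_batch <- function(bt, params, drop = NULL, collect = FALSE,
                              all_states = FALSE) {
  N <- bt$N; H <- params$hidden_size
  h <- matrix(0, N, H)
  caches <- if (collect) vector("list", bt$Tmax) else NULL
  hs <- if (all_states) vector("list", bt$Tmax) else NULL
  for (t in seq_len(bt$Tmax)) {
    Xt <- bt$Xin[[t]]; v <- bt$valid[[t]]
    xd <- if (is.null(drop)) Xt else Xt * drop$d_x
    hd <- if (is.null(drop)) h else h * drop$d_u
    r <- sigmoid(sweep(xd %*% t(params$W_r) + hd %*% t(params$U_r),
                       2, params$b_r, "+"))
    z <- sigmoid(sweep(xd %*% t(params$W_z) + hd %*% t(params$U_z),
                       2, params$b_z, "+"))
    cand <- tanh(sweep(xd %*% t(params$W) + (r * hd) %*% t(params$U),
                       2, params$b, "+"))
    h_new <- (1 - z) * h + z * cand
    if (collect)
      caches[[t]] <- list(v = v, xd = xd, hd = hd, r = r, z = z, cand = cand,
                          h_prev = h)
    h <- v * h_new + (1 - v) * h
    if (all_states) hs[[t]] <- h
  }
  list(h_last = h, caches = caches, states = hs)
}

gru_backward_batch <- function(bt, params, caches, dh_last, drop = NULL) {
  H <- params$hidden_size; Din <- params$input_size
  g <- list(W_r = matrix(0, H, Din), W_z = matrix(0, H, Din),
            W = matrix(0, H, Din),
            U_r = matrix(0, H, H), U_z = matrix(0, H, H), U = matrix(0, H, H),
            b_r = numeric(H), b_z = numeric(H), b = numeric(H))
  dh <- dh_last
  for (t in rev(seq_len(bt$Tmax))) {
    cc <- caches[[t]]
    dh_new <- dh * cc$v
    dh_carry <- dh * (1 - cc$v)
    dz <- dh_new * (cc$cand - cc$h_prev)
    dcand <- dh_new * cc$z
    dh_prev <- dh_new * (1 - cc$z)
    da_c <- dcand * (1 - cc$cand^2)
    g$W <- g$W + t(da_c) %*% cc$xd
    g$U <- g$U + t(da_c) %*% (cc$r * cc$hd)
    g$b <- g$b + colSums(da_c)
    du_in <- da_c %*% params$U
    dr <- du_in * cc$hd
    dhd <- du_in * cc$r
    da_r <- dr * cc$r * (1 - cc$r)
    g$W_r <- g$W_r + t(da_r) %*% cc$xd
    g$U_r <- g$U_r + t(da_r) %*% cc$hd
    g$b_r <- g$b_r + colSums(da_r)
    dhd <- dhd + da_r %*% params$U_r
    da_z <- dz * cc$z * (1 - cc$z)
    g$W_z <- g$W_z + t(da_z) %*% cc$xd
    g$U_z <- g$U_z + t(da_z) %*% cc$hd
    g$b_z <- g$b_z + colSums(da_z)
    dhd <- dhd + da_z %*% params$U_z
    dhd_undropped <- if (is.null(drop)) dhd else dhd * drop$d_u
    dh <- dh_prev + dhd_undropped + dh_carry
  }
  g
}

## Dispatch helpers so training code is mode-agnostic.
net_forward <- function(bt, params, means, drop = NULL, collect = FALSE,
                        all_states = FALSE) {
  if (bt$type == "grud")
    grud_forward_batch(bt, params, means, drop, collect, all_states)
  else gru_forward_batch(bt, params, drop, collect, all_states)
}

net_backward <- function(bt, params, means, caches, dh_last, drop = NULL) {
  if (bt$type == "grud")
    grud_backward_batch(bt, params, means, caches, dh_last, drop)
  else gru_backward_batch(bt, params, caches, dh_last, drop)
}
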