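# Gated recurrent unit (GRU) layers with masking for variable-length
# episode histories, plus the recurrent network used by the history-based
# value and policy functions: a stack of GRU layers whose final hidden
# state is concatenated with the current (non-sequential) features and fed
# to a dense head. Backpropagation through time is exact and checked
# against numerical gradients in the tests.
#
# Gate equations (per layer, per step, with update gate z, reset gate r):
#   z = sigmoid(X W_z + H U_z + b_z)
#   r = sigmoid(X W_r + H U_r + b_r)
#   hc = tanh(X W_c + (r * H) U_c + b_c)
#   H' = (1 - z) * H + z * hc
# Padded steps (beyond a sequence's length) leave H unchanged.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_layer_init <- function(n_in, n_hidden) {
  sd_in <- sqrt(1 / n_in); sd_h <- sqrt(1 / n_hidden)
  list(W_zr = matrix(stats::rnorm(n_in * 2 * n_hidden, sd = sd_in),
                     n_in, 2 * n_hidden),
       U_zr = matrix(stats::rnorm(n_hidden * 2 * n_hidden, sd = sd_h),
                     n_hidden, 2 * n_hidden),
       b_zr = rep(0, 2 * n_hidden),
       W_c = matrix(stats::rnorm(n_in * n_hidden, sd = sd_in),
                    n_in, n_hidden),
       U_c = matrix(stats::rnorm(n_hidden * n_hidden, sd = sd_h),
                    n_hidden, n_hidden),
       b_c = rep(0, n_hidden))
}

# forward one GRU layer over a sequence list; X_seq: list over t of n x d,
# mask: n x T matrix in {0,1}. Returns H_seq (list of n x h) and cache.
gru_layer_forward <- function(layer, X_seq, mask, cache = FALSE) {
  Tn <- length(X_seq)
  n <- nrow(X_seq[[1]])
  h <- length(layer$b_c)
  H <- matrix(0, n, h)
  H_seq <- vector("list", Tn)
  cc <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Xt <- X_seq[[t]]
    zr <- sigmoid(sweep(Xt %*% layer$W_zr + H %*% layer$U_zr, 2,
                        layer$b_zr, `+`))
    z <- zr[, seq_len(h), drop = FALSE]
    r <- zr[, h + seq_len(h), drop = FALSE]
    A <- r * H
    hc <- tanh(sweep(Xt %*% layer$W_c + A %*% layer$U_c, 2, layer$b_c, `+`))
    Hnew <- (1 - z) * H + z * hc
    m <- mask[, t]
    Ht <- Hnew * m + H * (1 - m)
    if (cache) cc[[t]] <- list(Xt = Xt, Hp = H, z = z, r = r, hc = hc)
    H <- Ht
    H_seq[[t]] <- Ht
  }
  list(H_seq = H_seq, H_final = H, cache = cc)
}

# backward through one GRU layer. dH_seq: list over t of n x h gradients
# flowing into H_t from outside the recurrence (zeros where unused).
gru_layer_backward <- function(layer, cache, mask, dH_seq) {
  Tn <- length(cache)
  h <- length(layer$b_c)
  g <- param_map(layer[c("W_zr", "U_zr", "b_zr", "W_c", "U_c", "b_c")],
                 function(x) x * 0)
  dX_seq <- vector("list", Tn)
  dH <- dH_seq[[Tn]] * 0
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dHt <- dH + dH_seq[[t]]
    m <- mask[, t]
    dHnew <- dHt * m
    dHp <- dHt * (1 - m)
    z <- cc$z; r <- cc$r; hc <- cc$hc; Hp <- cc$Hp
    dz <- dHnew * (hc - Hp)
    dhc <- dHnew * z
    dHp <- dHp + dHnew * (1 - z)
    dc_pre <- dhc * (1 - hc^2)
    dA <- dc_pre %*% t(layer$U_c)
    dr <- dA * Hp
    dHp <- dHp + dA * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    dzr_pre <- cbind(dz_pre, dr_pre)
    dHp <- dHp + dzr_pre %*% t(layer$U_zr)
    g$W_zr <- g$W_zr + crossprod(cc$Xt, dzr_pre)
    g$U_zr <- g$U_zr + crossprod(Hp, dzr_pre)
    g$b_zr <- g$b_zr + colSums(dzr_pre)
    g$W_c <- g$W_c + crossprod(cc$Xt, dc_pre)
    g$U_c <- g$U_c + crossprod(r * Hp, dc_pre)
    g$b_c <- g$b_c + colSums(dc_pre)
    dX_seq[[t]] <- dzr_pre %*% t(layer$W_zr) + dc_pre %*% t(layer$W_c)
    dH <- dHp
  }
  list(grads = g, dX_seq = dX_seq)
}

#' Recurrent network: stacked GRU encoder plus a dense head
#'
#' The encoder consumes the per-step history (scaled measurement and the
#' scaled input pair applied before it); its final hidden state is
#' concatenated with the current non-sequential features (scaled
#' measurement, optional step index, and for a critic the candidate action)
#' and passed through a ReLU feed-forward head with a linear output.
#'
#' @param seq_dim features per history step.
#' @param extra_dim number of non-sequential features appended to the
#'   encoder output.
#' @param gru_units widths of the GRU layers.
#' @param head_units widths of the dense head's hidden layers.
#' @param out_dim output dimension.
#' @return object of class `rnet`.
#' @export
rnet <- function(seq_dim, extra_dim, gru_units = c(64, 64),
                 head_units = c(128, 128), out_dim = 1) {
  layers <- list()
  d <- seq_dim
  for (h in gru_units) {
    layers[[length(layers) + 1]] <- gru_layer_init(d, h)
    d <- h
  }
  head <- mlp(c(d + extra_dim, head_units, out_dim))
  structure(list(gru = layers, head = head, seq_dim = seq_dim,
                 extra_dim = extra_dim, out_dim = out_dim),
            class = "rnet")
}

rnet_params <- function(model) {
  list(gru = lapply(model$gru, function(l)
    l[c("W_zr", "U_zr", "b_zr", "W_c", "U_c", "b_c")]),
    head = mlp_params(model$head))
}

rnet_set_params <- function(model, p) {
  for (i in seq_along(model$gru)) model$gru[[i]][names(p$gru[[i]])] <-
      p$gru[[i]]
  model$head <- mlp_set_params(model$head, p$head)
  model
}

# build the list-over-time + mask representation from a 3D array
seq_batch <- function(X, lengths) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  mask <- outer(seq_len(n), seq_len(Tn),
                function(i, t) as.numeric(t <= lengths[i]))
  X_seq <- lapply(seq_len(Tn), function(t)
    matrix(X[, t, ], nrow = n))
  list(X_seq = X_seq, mask = mask)
}

#' Forward pass of a recurrent network
#'
#' @param model an [rnet()].
#' @param X `n x T x seq_dim` array of (zero-padded) history sequences.
#' @param lengths integer vector of true sequence lengths (>= 1).
#' @param extra `n x extra_dim` matrix of non-sequential features.
#' @param cache keep intermediates for [rnet_backward()].
#' @return `n x out_dim` output matrix (cache attached as attribute).
#' @export
rnet_forward <- function(model, X, lengths, extra, cache = FALSE) {
  sb <- seq_batch(X, lengths)
  X_seq <- sb$X_seq
  gcaches <- vector("list", length(model$gru))
  Hfin <- NULL
  for (i in seq_along(model$gru)) {
    fw <- gru_layer_forward(model$gru[[i]], X_seq, sb$mask, cache = cache)
    gcaches[[i]] <- fw$cache
    X_seq <- fw$H_seq
    Hfin <- fw$H_final
  }
  head_in <- cbind(Hfin, extra)
  out <- mlp_forward(model$head, head_in, cache = cache)
  if (cache)
    attr(out, "rcache") <- list(gcaches = gcaches, mask = sb$mask,
                                n_steps = length(sb$X_seq),
                                head_in = head_in)
  out
}

# backward pass; dOut is n x out_dim. Returns grads (matching rnet_params)
# and dExtra (gradient w.r.t. the non-sequential features).
rnet_backward <- function(model, out, dOut) {
  rc <- attr(out, "rcache")
  hb <- mlp_backward(model$head, out, dOut)
  h_top <- ncol(rc$head_in) - model$extra_dim
  dHfin <- hb$dX[, seq_len(h_top), drop = FALSE]
  dExtra <- hb$dX[, h_top + seq_len(model$extra_dim), drop = FALSE]
  n <- nrow(dHfin); Tn <- rc$n_steps
  grads_gru <- vector("list", length(model$gru))
  dH_seq <- lapply(seq_len(Tn), function(t) matrix(0, n, h_top))
  dH_seq[[Tn]] <- dHfin
  dIn <- dH_seq
  for (i in rev(seq_along(model$gru))) {
    bw <- gru_layer_backward(model$gru[[i]], rc$gcaches[[i]], rc$mask, dIn)
    grads_gru[[i]] <- bw$grads
    dIn <- bw$dX_seq
  }
  list(grads = list(gru = grads_gru, head = hb$grads), dExtra = dExtra)
}

#' Train a recurrent network by mini-batch MSE regression
#'
#' @param model an [rnet()].
#' @param X,lengths,extra as in [rnet_forward()].
#' @param y length-n scalar targets (scaled).
#' @param target_col optional output-column selector per sample (discrete
#'   action index for a recurrent Q-network).
#' @param epochs,batch_size,lr,opt,shuffle as in [mlp_train()].
#' @export
rnet_train <- function(model, X, lengths, extra, y, target_col = NULL,
                       epochs = 10, batch_size = 256, lr = 1e-3,
                       opt = NULL, shuffle = TRUE) {
  n <- length(y)
  if (is.null(target_col)) target_col <- rep(1L, n)
  if (is.null(opt)) opt <- adam(rnet_params(model), lr = lr)
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    idx <- if (shuffle) sample.int(n) else seq_len(n)
    tot <- 0
    for (start in seq(1, n, by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1, n)]
      nb <- length(take)
      out <- rnet_forward(model, X[take, , , drop = FALSE], lengths[take],
                          extra[take, , drop = FALSE], cache = TRUE)
      sel <- cbind(seq_len(nb), target_col[take])
      resid <- out[sel] - y[take]
      if (any(!is.finite(resid))) stop("divergent regression loss")
      dOut <- matrix(0, nb, ncol(out))
      dOut[sel] <- 2 * resid / nb
      bw <- rnet_backward(model, out, dOut)
      stepped <- adam_step(opt, rnet_params(model), bw$grads)
      model <- rnet_set_params(model, stepped$params)
      opt <- stepped$opt
      tot <- tot + sum(resid^2)
    }
    loss <- tot / n
  }
  list(net = model, loss = loss, opt = opt)
}
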