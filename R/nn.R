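# Minimal dense neural-network machinery: ReLU multilayer perceptrons,
# mean-squared-error regression, Adam. Everything operates on row-major
# batches (n x d matrices) and keeps parameters as plain lists of matrices,
# so snapshots serialise to JSON. Gradients are exact backpropagation and
# are verified against numerical differentiation in the test suite.

# He-scaled initialisation for a dense layer
dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

#' Construct a multilayer perceptron
#'
#' Fully connected network with rectified-linear hidden layers and a linear
#' output layer. Parameters are initialised from the current RNG state, so
#' seeding is the caller's responsibility.
#'
#' @param sizes integer vector of layer widths, input first, output last
#'   (e.g. `c(11, 100, 100, 100)` for the discrete-action value network).
#' @return an object of class `mlp`.
#' @export
mlp <- function(sizes) {
  stopifnot(length(sizes) >= 2)
  layers <- lapply(seq_len(length(sizes) - 1),
                   function(l) dense_init(sizes[l], sizes[l + 1]))
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

#' Forward pass of an MLP
#'
#' @param net an [mlp()].
#' @param X n x d input batch.
#' @param cache keep intermediate activations for [mlp_backward()].
#' @return output matrix, with the forward cache attached as an attribute
#'   when `cache = TRUE`.
#' @export
mlp_forward <- function(net, X, cache = FALSE) {
  X <- as.matrix(X)
  L <- length(net$layers)
  acts <- if (cache) vector("list", L + 1) else NULL
  if (cache) acts[[1]] <- X
  H <- X
  for (l in seq_len(L)) {
    H <- sweep(H %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, `+`)
    if (l < L) H[H < 0] <- 0
    if (cache) acts[[l + 1]] <- H
  }
  if (cache) attr(H, "acts") <- acts
  H
}

# backpropagate dL/dout through the MLP; returns list(grads, dX)
mlp_backward <- function(net, out, dOut) {
  acts <- attr(out, "acts")
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (acts[[l + 1]] > 0)
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    delta <- delta %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

# ---- generic Adam over nested parameter lists ------------------------------

# walk two parallel nested lists of numeric arrays, applying f elementwise
param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- param_map(a[[i]], f)
    out
  } else f(a)
}

#' Adam optimiser state
#'
#' @param params nested list of numeric arrays (the parameters that will be
#'   updated).
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabiliser.
#' @export
adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                 eps = 1e-8) {
  structure(list(m = param_map(params, function(x) x * 0),
                 v = param_map(params, function(x) x * 0),
                 t = 0, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam")
}

#' One Adam update
#'
#' @param opt an [adam()] state.
#' @param params current parameters (nested list of arrays).
#' @param grads gradients with the same structure.
#' @return list with updated `params` and `opt`.
#' @export
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  opt$m <- param_map2(opt$m, grads, function(m, g) opt$beta1 * m +
                        (1 - opt$beta1) * g)
  opt$v <- param_map2(opt$v, grads, function(v, g) opt$beta2 * v +
                        (1 - opt$beta2) * g * g)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  upd <- param_map2(opt$m, opt$v, function(m, v)
    opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps))
  list(params = param_map2(params, upd, `-`), opt = opt)
}

# extract/replace the parameter lists of an mlp (for Adam and snapshots)
mlp_params <- function(net) net$layers
mlp_set_params <- function(net, p) { net$layers <- p; net }

#' Train an MLP by mini-batch MSE regression
#'
#' Regresses selected output units onto scalar targets: when `target_col`
#' is supplied, sample i contributes only through output column
#' `target_col[i]` (the Q-value of the action actually taken); otherwise
#' output column 1 is used for all samples.
#'
#' @param net an [mlp()].
#' @param X n x d inputs.
#' @param y length-n targets (already scaled).
#' @param target_col optional length-n integer vector of output columns.
#' @param epochs passes over the data.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param opt optional pre-existing [adam()] state (kept across calls).
#' @param shuffle permute samples between epochs.
#' @return list with trained `net`, final epoch mean `loss` and `opt`.
#' @export
mlp_train <- function(net, X, y, target_col = NULL, epochs = 10,
                      batch_size = 256, lr = 1e-3, opt = NULL,
                      shuffle = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(target_col)) target_col <- rep(1L, n)
  if (is.null(opt)) opt <- adam(mlp_params(net), lr = lr)
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    idx <- if (shuffle) sample.int(n) else seq_len(n)
    tot <- 0
    for (start in seq(1, n, by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1, n)]
      nb <- length(take)
      out <- mlp_forward(net, X[take, , drop = FALSE], cache = TRUE)
      sel <- cbind(seq_len(nb), target_col[take])
      resid <- out[sel] - y[take]
      if (any(!is.finite(resid))) stop("divergent regression loss")
      dOut <- matrix(0, nb, ncol(out))
      dOut[sel] <- 2 * resid / nb
      bp <- mlp_backward(net, out, dOut)
      stepped <- adam_step(opt, mlp_params(net), bp$grads)
      net <- mlp_set_params(net, stepped$params)
      opt <- stepped$opt
      tot <- tot + sum(resid^2)
    }
    loss <- tot / n
  }
  list(net = net, loss = loss, opt = opt)
}
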