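# the dense and recurrent networks are hand-implemented, so their
# backpropagation is verified against numerical differentiation before any
# agent relies on them

numgrad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

flatten <- function(p) unlist(p, use.names = FALSE)

unflatten <- function(p, template) {
  relist_one <- function(tpl, vals, pos) {
    if (is.list(tpl)) {
      out <- tpl
      for (i in seq_along(tpl)) {
        r <- relist_one(tpl[[i]], vals, pos)
        out[[i]] <- r$x; pos <- r$pos
      }
      list(x = out, pos = pos)
    } else {
      n <- length(tpl)
      x <- tpl; x[] <- vals[pos + seq_len(n)]
      list(x = x, pos = pos + n)
    }
  }
  relist_one(template, p, 0)$x
}

test_that("MLP backpropagation matches numerical gradients", {
  set.seed(11)
  net <- mlp(c(4, 7, 5, 3))
  X <- matrix(rnorm(6 * 4), 6)
  y <- rnorm(6)
  cols <- sample(1:3, 6, replace = TRUE)
  loss_at <- function(theta) {
    n2 <- mlp_set_params(net, unflatten(theta, mlp_params(net)))
    out <- mlp_forward(n2, X)
    mean((out[cbind(1:6, cols)] - y)^2)
  }
  theta0 <- flatten(mlp_params(net))
  out <- mlp_forward(net, X, cache = TRUE)
  resid <- out[cbind(1:6, cols)] - y
  dOut <- matrix(0, 6, 3); dOut[cbind(1:6, cols)] <- 2 * resid / 6
  bp <- mlp_backward(net, out, dOut)
  expect_equal(flatten(bp$grads), numgrad(loss_at, theta0),
               tolerance = 1e-5)
})

test_that("GRU network backpropagation through time matches numerical
           gradients, including masking and the extra-input path", {
  set.seed(12)
  model <- rnet(3, 2, gru_units = c(5, 4), head_units = c(6), out_dim = 2)
  n <- 5; Tn <- 4
  X <- array(rnorm(n * Tn * 3), c(n, Tn, 3))
  lengths <- c(1, 2, 4, 3, 4)
  extra <- matrix(rnorm(n * 2), n)
  y <- rnorm(n)
  cols <- c(1, 2, 1, 2, 1)
  loss_at <- function(theta) {
    m2 <- rnet_set_params(model, unflatten(theta, rnet_params(model)))
    out <- rnet_forward(m2, X, lengths, extra)
    mean((out[cbind(1:n, cols)] - y)^2)
  }
  theta0 <- flatten(rnet_params(model))
  out <- rnet_forward(model, X, lengths, extra, cache = TRUE)
  resid <- out[cbind(1:n, cols)] - y
  dOut <- matrix(0, n, 2); dOut[cbind(1:n, cols)] <- 2 * resid / n
  bw <- rnet_backward(model, out, dOut)
  expect_equal(flatten(bw$grads), numgrad(loss_at, theta0),
               tolerance = 1e-5)
})

test_that("the gradient with respect to appended features matches
           numerical differentiation (actor-through-critic path)", {
  set.seed(13)
  model <- rnet(2, 3, gru_units = c(4), head_units = c(5), out_dim = 1)
  n <- 4; Tn <- 3
  X <- array(rnorm(n * Tn * 2), c(n, Tn, 2))
  lengths <- rep(Tn, n)
  extra <- matrix(rnorm(n * 3), n)
  mean_q <- function(ex_flat) {
    ex <- matrix(ex_flat, n)
    mean(rnet_forward(model, X, lengths, ex))
  }
  out <- rnet_forward(model, X, lengths, extra, cache = TRUE)
  bw <- rnet_backward(model, out, matrix(1 / n, n, 1))
  expect_equal(as.numeric(bw$dExtra),
               numgrad(mean_q, as.numeric(extra)), tolerance = 1e-6)
})

test_that("masked padding steps do not affect the output", {
  set.seed(14)
  model <- rnet(3, 1, gru_units = c(4), head_units = c(5), out_dim = 1)
  X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  lengths <- c(3, 5)
  o1 <- rnet_forward(model, X, lengths, matrix(c(0.3, 0.4), 2))
  X2 <- X
  X2[1, 4:5, ] <- 99      # junk beyond the sequence end
  o2 <- rnet_forward(model, X2, lengths, matrix(c(0.3, 0.4), 2))
  expect_equal(o1, o2)
})

test_that("Adam descends a simple quadratic and MLP regression fits a
           smooth function", {
  set.seed(15)
  params <- list(w = c(5, -3))
  opt <- adam(params, lr = 0.1)
  for (i in 1:200) {
    g <- list(w = 2 * params$w)
    st <- adam_step(opt, params, g)
    params <- st$params; opt <- st$opt
  }
  expect_lt(sum(params$w^2), 1e-3)

  set.seed(16)
  X <- matrix(runif(400, -1, 1), ncol = 2)
  y <- sin(2 * X[, 1]) + X[, 2]^2
  net <- mlp(c(2, 32, 32, 1))
  fit <- mlp_train(net, X, y, epochs = 200, batch_size = 64, lr = 3e-3)
  pred <- mlp_forward(fit$net, X)[, 1]
  expect_lt(mean((pred - y)^2), 0.01)
})

test_that("snapshots of networks round-trip through JSON", {
  set.seed(17)
  net <- mlp(c(3, 8, 2))
  path <- tempfile(fileext = ".json")
  save_snapshot(net, path)
  net2 <- load_snapshot(path)
  X <- matrix(rnorm(12), 4)
  expect_equal(mlp_forward(net, X), mlp_forward(net2, X))

  rn <- rnet(3, 2, gru_units = c(4, 4), head_units = c(5), out_dim = 2)
  save_snapshot(rn, path)
  rn2 <- load_snapshot(path)
  X3 <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  ex3 <- matrix(rnorm(4), 2)
  expect_equal(rnet_forward(rn, X3, c(2, 3), ex3),
               rnet_forward(rn2, X3, c(2, 3), ex3), tolerance = 1e-12)
})
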