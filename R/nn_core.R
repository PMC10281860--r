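# Shared neural-network primitives: initialisation, dense / batch-norm /
# dropout layers with explicit backward passes, the Adam optimizer, and the
# binary cross-entropy objective.  Everything is deterministic given R's
# RNG state; all parameters live in flat named lists of arrays so the
# optimizer can treat them uniformly.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot/Xavier uniform initialisation; draws from the current RNG stream.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with probabilities clipped to
#' `[eps, 1 - eps]`.
#'
#' @param probabilities Numeric vector of predicted probabilities in (0,1).
#' @param labels Numeric vector of 0/1 labels, same length.
#' @param eps Clipping constant, default `1e-7`.
#' @return Scalar loss (nonnegative).
#' @examples
#' bce_loss(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
bce_loss <- function(probabilities, labels, eps = 1e-7) {
  if (length(probabilities) != length(labels))
    stop("shape error: probabilities and labels differ in length")
  if (!all(labels %in% c(0, 1)))
    stop("bce_loss: labels must be 0 or 1")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- dense layer ----------------------------------------------------------

dense_forward <- function(X, W, b) {
  # X: N x d_in, W: d_in x d_out, b: length d_out
  sweep(X %*% W, 2L, b, "+")
}

dense_backward <- function(dZ, X, W) {
  list(dX = dZ %*% t(W), dW = crossprod(X, dZ), db = colSums(dZ))
}

relu <- function(x) pmax(x, 0)

# ---- batch normalization --------------------------------------------------

# Per-feature batch norm over the rows of X.  In training mode the batch
# statistics are used and running statistics updated (momentum 0.9); in
# inference mode the running statistics are used, so repeated scoring of
# the same input is bit-identical.
bn_forward <- function(X, gamma, beta, running_mean, running_var,
                       training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    var <- colMeans(xc^2)
    inv_std <- 1 / sqrt(var + eps)
    xhat <- sweep(xc, 2L, inv_std, "*")
    running_mean <- momentum * running_mean + (1 - momentum) * mu
    running_var <- momentum * running_var + (1 - momentum) * var
    cache <- list(xhat = xhat, inv_std = inv_std, gamma = gamma)
  } else {
    xhat <- sweep(sweep(X, 2L, running_mean), 2L,
                  1 / sqrt(running_var + eps), "*")
    cache <- NULL
  }
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = cache,
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dout, cache) {
  xhat <- cache$xhat
  n <- nrow(xhat)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  # gradient through the batch statistics
  dX <- sweep(
    dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
      sweep(xhat, 2L, colMeans(dxhat * xhat), "*"),
    2L, cache$inv_std, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout --------------------------------------------------------------

# Inverted dropout; mask drawn from the current RNG stream.
dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- array(stats::rbinom(length(X), 1L, 1 - rate) / (1 - rate), dim(X))
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim(as.array(p))))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Ridge-regularised logistic regression by IRLS; returns c(intercept,
# coefficients).  Used to fit the scorer's sigmoid head to convergence
# on the (frozen) encoder features -- the head problem is convex, so the
# exact fit replaces what many SGD epochs would approach.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 50L,
                           tol = 1e-8) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    beta_new <- tryCatch(
      solve(XtW %*% Xd + pen, XtW %*% z),
      error = function(e) beta)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

# Global-norm gradient clipping (standard for recurrent nets).
clip_gradients <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

# Stratified mini-batch index generator: shuffles once per call.
make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
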