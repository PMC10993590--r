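## Minimal neural-network building blocks: parameter trees, Xavier
## initialization, AdamW, and forward/backward primitives used by the
## instrumented transformer.  Everything is plain R matrix code; gradients
## are exact reverse-mode derivatives (finite differences are the test
## oracle, never the implementation).

.xavier <- function(nin, nout) {
  b <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -b, b), nin, nout)
}

## ---- parameter-tree utilities --------------------------------------------

.tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, .tree_map, f = f) else f(tree)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

.tree_zeros_like <- function(tree) .tree_map(function(x) x * 0, tree)

.tree_count <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, .tree_count, 0)) else length(tree)
}

.tree_axpy <- function(a, x, y) .tree_map2(function(xi, yi) a * xi + yi, x, y)

## ---- AdamW ----------------------------------------------------------------

.adamw_init <- function(params) {
  list(m = .tree_zeros_like(params), v = .tree_zeros_like(params), t = 0L)
}

## decoupled weight decay applied to matrices only (vectors are biases and
## layer-norm scales)
.adamw_step <- function(params, grads, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- .tree_map2(function(p, u) {
    wd <- if (is.matrix(p)) weight_decay else 0
    p - lr * (u + wd * p)
  }, params, upd)
  list(params = params, state = state)
}

## ---- primitives -----------------------------------------------------------

.softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

## d/dscores of softmax given dalpha (both S x S), rows independent
.softmax_rows_backward <- function(alpha, dalpha) {
  alpha * (dalpha - rowSums(dalpha * alpha))
}

.layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, gamma, `*`)
  y <- sweep(y, 2L, beta, `+`)
  list(out = y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

.layernorm_backward <- function(cache, dy) {
  xhat <- cache$xhat; inv <- cache$inv; gamma <- cache$gamma
  E <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  # per-row: dx = inv/E * (E*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dx <- inv / E * (E * dxhat - s1 - xhat * s2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.relu <- function(x) pmax(x, 0)

.dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - rate), nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

.dropout_backward <- function(mask, dy) if (is.null(mask)) dy else dy * mask

.softmax_vec <- function(x) { e <- exp(x - max(x)); e / sum(e) }

## cross entropy over a logits matrix (positions x classes), target ids,
## position weights; returns loss and dlogits
.cross_entropy <- function(logits, targets, weights = NULL) {
  n <- nrow(logits)
  if (is.null(weights)) weights <- rep(1, n)
  p <- t(apply(logits, 1L, .softmax_vec))
  idx <- cbind(seq_len(n), targets)
  wsum <- sum(weights)
  loss <- -sum(weights * log(pmax(p[idx], 1e-12))) / max(wsum, 1e-12)
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  dlog <- dlog * (weights / max(wsum, 1e-12))
  list(loss = loss, dlogits = dlog)
}
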