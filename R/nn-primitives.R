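# Low-level neural-network primitives: parameter initialisation, layer
# normalisation, linear layers, GELU, dropout, and nested-parameter-list
# arithmetic.  Every forward returns list(out, cache); every backward takes
# (params, cache, dout) and returns gradients with the same nesting as the
# parameters, so whole-model backpropagation is plain list recursion.

LN_EPS <- 1e-5

#' @keywords internal
trunc_normal_init <- function(n_in, n_out, sd = 0.02) {
  # truncated at +-2 sd (inverse-CDF sampling), the usual ViT initialiser
  lo <- stats::pnorm(-2)
  x <- stats::qnorm(stats::runif(n_in * n_out, lo, 1 - lo)) * sd
  matrix(x, n_in, n_out)
}

#' @keywords internal
xavier_uniform_init <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out)
}

linear_init <- function(n_in, n_out, sd = 0.02) {
  list(W = trunc_normal_init(n_in, n_out, sd), b = numeric(n_out))
}

ln_init <- function(d) list(g = rep(1, d), b = numeric(d))

## ---- layer normalisation ---------------------------------------------------

ln_fwd <- function(p, x) {
  # x: (T x D) matrix, normalised per row
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- sweep(xhat, 2, p$g, `*`)
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(p, cache, dout) {
  xhat <- cache$xhat
  inv <- cache$inv
  D <- ncol(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, p$g, `*`)
  # dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, grads = list(g = dg, b = db))
}

## ---- linear ----------------------------------------------------------------

linear_fwd <- function(p, x) {
  out <- x %*% p$W
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, cache = list(x = x))
}

linear_bwd <- function(p, cache, dout) {
  list(
    dx = dout %*% t(p$W),
    grads = list(W = crossprod(cache$x, dout), b = colSums(dout))
  )
}

## ---- GELU (exact, Gaussian CDF form) ---------------------------------------

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## ---- softmax over rows ------------------------------------------------------

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

## ---- dropout ----------------------------------------------------------------

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- array(stats::rbinom(length(x), 1, 1 - rate), dim = dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(mask, dout) {
  if (is.null(mask)) dout else dout * mask
}

## ---- MLP block (fc1 -> GELU -> dropout -> fc2) ------------------------------

mlp_init <- function(d, ratio = 4L) {
  list(fc1 = linear_init(d, d * ratio), fc2 = linear_init(d * ratio, d))
}

mlp_fwd <- function(p, x, dropout = 0, training = FALSE) {
  f1 <- linear_fwd(p$fc1, x)
  a <- gelu(f1$out)
  dr <- dropout_fwd(a, dropout, training)
  f2 <- linear_fwd(p$fc2, dr$out)
  list(out = f2$out, cache = list(f1 = f1, pre = f1$out, mask = dr$mask, f2 = f2))
}

mlp_bwd <- function(p, cache, dout) {
  b2 <- linear_bwd(p$fc2, cache$f2$cache, dout)
  da <- dropout_bwd(cache$mask, b2$dx)
  dpre <- da * gelu_grad(cache$pre)
  b1 <- linear_bwd(p$fc1, cache$f1$cache, dpre)
  list(dx = b1$dx, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}

## ---- nested parameter-list arithmetic ---------------------------------------

#' @keywords internal
nl_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(nl_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

nl_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  nl_map2(a, b, `+`)
}

nl_zeros_like <- function(a) {
  if (is.list(a)) return(lapply(a, nl_zeros_like))
  a * 0
}

nl_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, nl_scale, s = s))
  a * s
}

#' Count numeric entries in a nested parameter list
#' @keywords internal
nl_count <- function(a) {
  if (is.list(a)) return(sum(vapply(a, nl_count, numeric(1))))
  length(a)
}

#' Flatten a nested parameter list to a named flat list (dot-joined names)
#' @keywords internal
nl_flatten <- function(a, prefix = "") {
  if (!is.list(a)) {
    out <- list(a)
    names(out) <- prefix
    return(out)
  }
  nms <- names(a)
  if (is.null(nms)) nms <- as.character(seq_along(a))
  out <- list()
  for (i in seq_along(a)) {
    key <- if (prefix == "") nms[i] else paste0(prefix, ".", nms[i])
    out <- c(out, nl_flatten(a[[i]], key))
  }
  out
}

#' Global L2 norm of a nested gradient list
#' @keywords internal
nl_global_norm <- function(a) {
  sq <- function(x) if (is.list(x)) sum(vapply(x, sq, numeric(1))) else sum(x^2)
  sqrt(sq(a))
}

## ---- cross entropy ----------------------------------------------------------

#' Softmax cross-entropy for a single logit vector
#'
#' @param logits numeric vector.
#' @param target 1-based index of the true class.
#' @return list with `loss`, `probs` and gradient `dlogits`.
#' @keywords internal
cross_entropy <- function(logits, target) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  d <- p
  d[target] <- d[target] - 1
  list(loss = -log(p[target]), probs = p, dlogits = d)
}
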