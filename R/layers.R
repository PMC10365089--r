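# Layer primitives for the CSD networks. Convolutions run through the
# compiled im2col kernels; pooling/upsampling/activations are cheap array
# operations kept in R. All tensors are H x W x C arrays of doubles.

as_chw <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

conv_param <- function(c_in, c_out, k = 3L, init = c("he", "zero")) {
  init <- match.arg(init)
  fan_in <- k * k * c_in
  w <- if (init == "zero") {
    matrix(0, fan_in, c_out)
  } else {
    matrix(rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
  }
  list(W = w, b = numeric(c_out), k = k, c_in = c_in, c_out = c_out)
}

conv_fw <- function(x, p, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  conv2d_fw(as_chw(x), p$W, p$b, p$k, stride, pad)
}

conv_bw <- function(x, p, gout, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  conv2d_bw(as_chw(x), p$W, as_chw(gout), p$k, stride, pad)
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bw <- function(g, mask) g * mask

lrelu_fw <- function(x, alpha = 0.2) {
  mask <- x > 0
  list(y = ifelse(mask, x, alpha * x), mask = mask, alpha = alpha)
}

lrelu_bw <- function(g, cache) ifelse(cache$mask, g, cache$alpha * g)

avgpool2_fw <- function(x) {
  x <- as_chw(x)
  h <- dim(x)[1]
  w <- dim(x)[2]
  if (h %% 2L || w %% 2L) stop("pooling needs even spatial dimensions")
  o1 <- seq(1L, h, 2L)
  o2 <- seq(2L, h, 2L)
  q1 <- seq(1L, w, 2L)
  q2 <- seq(2L, w, 2L)
  (x[o1, q1, , drop = FALSE] + x[o2, q1, , drop = FALSE] +
     x[o1, q2, , drop = FALSE] + x[o2, q2, , drop = FALSE]) / 4
}

avgpool2_bw <- function(g) {
  g <- as_chw(g)
  h <- dim(g)[1] * 2L
  w <- dim(g)[2] * 2L
  out <- array(0, c(h, w, dim(g)[3]))
  gq <- g / 4
  out[seq(1L, h, 2L), seq(1L, w, 2L), ] <- gq
  out[seq(2L, h, 2L), seq(1L, w, 2L), ] <- gq
  out[seq(1L, h, 2L), seq(2L, w, 2L), ] <- gq
  out[seq(2L, h, 2L), seq(2L, w, 2L), ] <- gq
  out
}

upsample2_fw <- function(x) {
  x <- as_chw(x)
  ri <- rep(seq_len(dim(x)[1]), each = 2L)
  ci <- rep(seq_len(dim(x)[2]), each = 2L)
  x[ri, ci, , drop = FALSE]
}

upsample2_bw <- function(g) {
  g <- as_chw(g)
  h <- dim(g)[1] %/% 2L
  w <- dim(g)[2] %/% 2L
  o1 <- seq(1L, dim(g)[1], 2L)
  o2 <- seq(2L, dim(g)[1], 2L)
  q1 <- seq(1L, dim(g)[2], 2L)
  q2 <- seq(2L, dim(g)[2], 2L)
  g[o1, q1, , drop = FALSE] + g[o2, q1, , drop = FALSE] +
    g[o1, q2, , drop = FALSE] + g[o2, q2, , drop = FALSE]
}

concat_c <- function(a, b) {
  a <- as_chw(a)
  b <- as_chw(b)
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

# elementwise combination over nested parameter lists (leaves are numeric)
map_params <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- map_params(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

# only W and b leaves participate in optimization; k/c_in/c_out are metadata
param_leaves <- function(p) {
  if (is.list(p)) {
    if (!is.null(p$W)) {
      list(W = p$W, b = p$b)
    } else {
      lapply(p, param_leaves)
    }
  } else {
    p
  }
}
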