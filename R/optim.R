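# Adam optimizer over nested parameter lists. Leaves are conv layers
# (lists carrying W and b); everything else is structural.

adam_init <- function(params) {
  init_leaf <- function(p) {
    if (is.list(p) && !is.null(p$W)) {
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
    } else {
      lapply(p, init_leaf)
    }
  }
  list(t = 0L, s = init_leaf(params))
}

# params: network parameter sub-list (e.g. net[c("convs","enc","dec","out")])
# grads: same structure with W/b leaves
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(p, g, s) {
    if (is.list(p) && !is.null(p$W)) {
      s$mW <- beta1 * s$mW + (1 - beta1) * g$W
      s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
      s$mb <- beta1 * s$mb + (1 - beta1) * g$b
      s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
      p$W <- p$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
      p$b <- p$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
      list(p = p, s = s)
    } else {
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], s[[i]])
        p[[i]] <- r$p
        s[[i]] <- r$s
      }
      list(p = p, s = s)
    }
  }
  r <- upd(params, grads, state$s)
  list(params = r$p, state = list(t = state$t, s = r$s))
}

# accumulate grad structures (a + scale * b); NULL a treated as zero
acc_grads <- function(a, b, scale = 1) {
  if (is.null(a)) {
    return(scale_grads(b, scale))
  }
  if (is.list(a) && !is.null(a$W)) {
    list(W = a$W + scale * b$W, b = a$b + scale * b$b)
  } else {
    for (i in seq_along(a)) a[[i]] <- acc_grads(a[[i]], b[[i]], scale)
    a
  }
}

scale_grads <- function(g, scale) {
  if (scale == 1) return(g)
  if (is.list(g) && !is.null(g$W)) {
    list(W = g$W * scale, b = g$b * scale)
  } else {
    lapply(g, scale_grads, scale = scale)
  }
}

# network-level convenience: update a built network in place
update_network <- function(net, grads, opt_state, lr) {
  keys <- intersect(names(net), c("convs", "enc", "dec", "out"))
  params <- unclass(net)[keys]
  r <- adam_step(params, grads, opt_state, lr)
  for (k in keys) net[[k]] <- restore_meta(net[[k]], r$params[[k]])
  list(net = net, state = r$state)
}
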