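#' Declarative network specifications
#'
#' Describes one of the three CSD networks. Architecture families follow the
#' framework design: the simulator is a u-shaped encoder-decoder with skip
#' connections at matching scales; the denoiser is a residual plain
#' convolutional network (DnCNN-style: it predicts the noise and subtracts it
#' from its input); the discriminator is a strided patch classifier with a
#' sigmoid head. Depth/width are free profile choices, exposed here rather
#' than fixed.
#'
#' `depth` means: number of convolution layers for the denoiser; number of
#' resolution levels for the simulator (each level past the first halves the
#' spatial scale); number of convolution layers for the discriminator (all
#' but the last with stride 2).
#'
#' @param role `"simulator"`, `"denoiser"`, or `"discriminator"`.
#' @param depth Layer/level count (role-dependent default).
#' @param width Base channel count.
#' @param init `"he"` for random He-initialized weights, or `"zero-residual"`
#'   (denoiser only) to zero the final layer so the network is exactly the
#'   identity at initialization.
#' @param hu_window HU window mapped affinely onto \[-1, 1\] at the network
#'   boundary (inverse applied on output); recorded in checkpoints.
#' @return A `network_spec` object with a derived `receptive_field` (pixels).
#' @examples
#' network_spec("denoiser", depth = 5, width = 8)
#' @export
network_spec <- function(role = c("simulator", "denoiser", "discriminator"),
                         depth = NULL, width = NULL,
                         init = c("he", "zero-residual"),
                         hu_window = c(-1024, 1024)) {
  role <- match.arg(role)
  init <- match.arg(init)
  depth <- depth %||% switch(role, simulator = 3, denoiser = 8,
                             discriminator = 4)
  width <- width %||% switch(role, simulator = 16, denoiser = 32,
                             discriminator = 32)
  if (depth < 1 || width < 1) stop("`depth` and `width` must be >= 1")
  if (role == "denoiser" && depth < 2) stop("denoiser needs depth >= 2")
  if (role == "discriminator" && depth < 2) {
    stop("discriminator needs depth >= 2")
  }
  if (init == "zero-residual" && role != "denoiser") {
    stop("zero-residual init applies to the denoiser only")
  }
  rf <- switch(role,
               denoiser = 2L * depth + 1L,
               simulator = as.integer(4 * 2^(depth - 1) + 1),
               discriminator = as.integer(2^(depth + 1)))
  structure(list(role = role, depth = as.integer(depth),
                 width = as.integer(width), residual = role != "discriminator",
                 init = init, hu_window = hu_window,
                 receptive_field = rf),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: depth %d, width %d, receptive field ~%d px\n",
              x$role, x$depth, x$width, x$receptive_field))
  invisible(x)
}

check_role <- function(spec, role) {
  if (!inherits(spec, "network_spec")) stop("`spec` must be a network_spec")
  if (spec$role != role) {
    stop("spec role is '", spec$role, "', expected '", role, "'")
  }
}

#' Build the residual convolutional denoiser
#'
#' A plain chain of 3x3 convolutions with ReLU activations whose output is
#' interpreted as the noise estimate; the network returns input minus
#' predicted noise. Fully convolutional, so any input size works and
#' geometry is preserved. Weight initialization is deterministic given
#' `seed`.
#'
#' @param spec A [network_spec()] with role `"denoiser"`.
#' @param seed Integer seed for weight initialization.
#' @return A `csd_denoiser` object.
#' @export
build_denoiser <- function(spec, seed) {
  check_role(spec, "denoiser")
  convs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(spec$depth), function(i) {
      c_in <- if (i == 1) 1L else spec$width
      c_out <- if (i == spec$depth) 1L else spec$width
      conv_param(c_in, c_out,
                 init = if (i == spec$depth && spec$init == "zero-residual")
                   "zero" else "he")
    })
  })
  structure(list(spec = spec, convs = convs, seed = as.integer(seed)),
            class = "csd_denoiser")
}

forward_denoiser <- function(net, x, cache = FALSE) {
  x <- as_chw(x)
  a <- x
  ins <- if (cache) vector("list", net$spec$depth)
  masks <- if (cache) vector("list", net$spec$depth - 1L)
  for (i in seq_len(net$spec$depth)) {
    if (cache) ins[[i]] <- a
    a <- conv_fw(a, net$convs[[i]])
    if (i < net$spec$depth) {
      # leaky activations: without normalization layers, hard ReLUs let
      # whole channels die mid-training in a plain deep chain
      r <- lrelu_fw(a, alpha = 0.1)
      a <- r$y
      if (cache) masks[[i]] <- r
    }
  }
  y <- x - a
  if (cache) list(y = y, cache = list(ins = ins, masks = masks)) else
    list(y = y)
}

backward_denoiser <- function(net, cache, gy) {
  gy <- as_chw(gy)
  g <- -gy
  grads <- vector("list", net$spec$depth)
  for (i in rev(seq_len(net$spec$depth))) {
    bw <- conv_bw(cache$ins[[i]], net$convs[[i]], g)
    grads[[i]] <- list(W = bw$gw, b = bw$gb)
    g <- bw$gx
    if (i > 1) g <- lrelu_bw(g, cache$masks[[i - 1L]])
  }
  list(grads = list(convs = grads), gx = gy + g)
}

#' Build the u-shaped noise simulator
#'
#' An encoder-decoder with skip connections at matching scales. The input is
#' the clean image concatenated with a unit-Gaussian noise channel (the
#' stochastic source the network shapes into dose-matched noise); the output
#' is the input image plus a learned residual. Spatial dimensions must be
#' divisible by `2^(depth - 1)`.
#'
#' @param spec A [network_spec()] with role `"simulator"`.
#' @param seed Integer seed for weight initialization.
#' @return A `csd_simulator` object.
#' @export
build_simulator <- function(spec, seed) {
  check_role(spec, "simulator")
  lv <- spec$depth
  w <- spec$width * 2^(seq_len(lv) - 1L)
  params <- withr::with_seed(as.integer(seed), {
    enc <- lapply(seq_len(lv), function(i) {
      conv_param(if (i == 1) 2L else w[i - 1L], w[i])
    })
    dec <- if (lv > 1) {
      lapply(seq_len(lv - 1L), function(j) {
        conv_param(w[j + 1L] + w[j], w[j])
      })
    } else {
      list()
    }
    # the output head sees the decoder features AND the raw latent noise
    # channel, so spectrally white noise is directly expressible
    out <- conv_param(w[1L] + 1L, 1L)
    # near-identity start: a small residual head keeps the initial simulated
    # image close to its input, so adversarial training grows the injected
    # noise toward the real amplitude instead of taming a huge random field
    out$W <- out$W * 0.02
    list(enc = enc, dec = dec, out = out)
  })
  structure(list(spec = spec, enc = params$enc, dec = params$dec,
                 out = params$out, seed = as.integer(seed)),
            class = "csd_simulator")
}

forward_simulator <- function(net, x, z, cache = FALSE) {
  x <- as_chw(x)
  z <- as_chw(z)
  lv <- net$spec$depth
  if (any(dim(x)[1:2] %% 2^(lv - 1L) != 0)) {
    stop("input size must be divisible by ", 2^(lv - 1L))
  }
  xin <- concat_c(x, z)
  e <- vector("list", lv)
  enc_in <- vector("list", lv)
  enc_mask <- vector("list", lv)
  a <- xin
  for (i in seq_len(lv)) {
    if (i > 1) a <- avgpool2_fw(e[[i - 1L]])
    enc_in[[i]] <- a
    r <- relu_fw(conv_fw(a, net$enc[[i]]))
    e[[i]] <- r$y
    enc_mask[[i]] <- r$mask
  }
  d <- e[[lv]]
  dec_in <- vector("list", max(lv - 1L, 0L))
  dec_mask <- vector("list", max(lv - 1L, 0L))
  if (lv > 1) {
    for (j in rev(seq_len(lv - 1L))) {
      cat_in <- concat_c(upsample2_fw(d), e[[j]])
      dec_in[[j]] <- cat_in
      r <- relu_fw(conv_fw(cat_in, net$dec[[j]]))
      d <- r$y
      dec_mask[[j]] <- r$mask
    }
  }
  out_in <- concat_c(d, z)
  res <- conv_fw(out_in, net$out)
  y <- x + res
  if (cache) {
    list(y = y, cache = list(enc_in = enc_in, enc_mask = enc_mask,
                             dec_in = dec_in, dec_mask = dec_mask,
                             out_in = out_in))
  } else {
    list(y = y)
  }
}

backward_simulator <- function(net, cache, gy) {
  gy <- as_chw(gy)
  lv <- net$spec$depth
  wch <- net$spec$width * 2^(seq_len(lv) - 1L)
  bw_out <- conv_bw(cache$out_in, net$out, gy)
  g_out <- list(W = bw_out$gw, b = bw_out$gb)
  g_e <- vector("list", lv)
  g_dec <- vector("list", max(lv - 1L, 0L))
  # decoder backward: walk the cycle d_1 <- dec_1 <- d_2 <- ... <- d_L = e_L
  # (dropping the z channel appended to the output head's input)
  g_d <- bw_out$gx[, , seq_len(wch[1L]), drop = FALSE]
  if (lv > 1) {
    for (j in seq_len(lv - 1L)) {
      g <- relu_bw(g_d, cache$dec_mask[[j]])
      bw <- conv_bw(cache$dec_in[[j]], net$dec[[j]], g)
      g_dec[[j]] <- list(W = bw$gw, b = bw$gb)
      g_up <- bw$gx[, , seq_len(wch[j + 1L]), drop = FALSE]
      g_skip <- bw$gx[, , wch[j + 1L] + seq_len(wch[j]), drop = FALSE]
      g_e[[j]] <- add_maybe(g_e[[j]], g_skip)
      g_d <- upsample2_bw(g_up)
    }
  }
  g_e[[lv]] <- add_maybe(g_e[[lv]], g_d)
  g_enc <- vector("list", lv)
  g_carry <- NULL
  for (i in rev(seq_len(lv))) {
    g <- g_e[[i]]
    if (!is.null(g_carry)) g <- add_maybe(g, g_carry)
    g <- relu_bw(g, cache$enc_mask[[i]])
    bw <- conv_bw(cache$enc_in[[i]], net$enc[[i]], g)
    g_enc[[i]] <- list(W = bw$gw, b = bw$gb)
    g_carry <- if (i > 1) avgpool2_bw(bw$gx) else NULL
    if (i == 1) g_xin <- bw$gx
  }
  gx <- gy + g_xin[, , 1L, drop = FALSE]
  list(grads = list(enc = g_enc, dec = g_dec, out = g_out), gx = gx)
}

add_maybe <- function(a, b) {
  if (is.null(a)) b else if (is.null(b)) a else a + b
}

#' Build the patch discriminator
#'
#' A strided convolutional classifier: all layers but the last use stride 2
#' with leaky-ReLU activations; the final 3x3 convolution maps to one channel
#' and a sigmoid squashes each spatial position into (0, 1). The network
#' returns the vector of per-patch probabilities (reducible to a scalar score
#' by averaging).
#'
#' @param spec A [network_spec()] with role `"discriminator"`.
#' @param seed Integer seed for weight initialization.
#' @return A `csd_discriminator` object.
#' @export
build_discriminator <- function(spec, seed) {
  check_role(spec, "discriminator")
  d <- spec$depth
  widths <- spec$width * 2^(seq_len(d - 1L) - 1L)
  convs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(d), function(i) {
      c_in <- if (i == 1) 1L else widths[i - 1L]
      c_out <- if (i == d) 1L else widths[i]
      conv_param(c_in, c_out)
    })
  })
  structure(list(spec = spec, convs = convs, seed = as.integer(seed)),
            class = "csd_discriminator")
}

forward_discriminator <- function(net, x, cache = FALSE) {
  a <- as_chw(x)
  d <- net$spec$depth
  ins <- if (cache) vector("list", d)
  masks <- if (cache) vector("list", d - 1L)
  for (i in seq_len(d)) {
    if (cache) ins[[i]] <- a
    a <- conv_fw(a, net$convs[[i]], stride = if (i < d) 2L else 1L)
    if (i < d) {
      r <- lrelu_fw(a)
      a <- r$y
      if (cache) masks[[i]] <- r
    }
  }
  # clamp away from exact 0/1: the sigmoid saturates in floating point for
  # extreme logits, and downstream log-losses need open-interval outputs
  p <- pmin(pmax(sigmoid(a), 1e-12), 1 - 1e-12)
  out <- list(prob = as.vector(p))
  if (cache) out$cache <- list(ins = ins, masks = masks, p = p)
  out
}

backward_discriminator <- function(net, cache, gp) {
  d <- net$spec$depth
  p <- cache$p
  g <- array(gp, dim(p)) * p * (1 - p)
  grads <- vector("list", d)
  for (i in rev(seq_len(d))) {
    bw <- conv_bw(cache$ins[[i]], net$convs[[i]], g,
                  stride = if (i < d) 2L else 1L)
    grads[[i]] <- list(W = bw$gw, b = bw$gb)
    g <- bw$gx
    if (i > 1) g <- lrelu_bw(g, cache$masks[[i - 1L]])
  }
  list(grads = list(convs = grads), gx = g)
}

#' Number of trainable parameters
#'
#' @param x A built network or a [network_spec()].
#' @return Integer parameter count.
#' @export
param_count <- function(x) {
  if (inherits(x, "network_spec")) {
    w <- x$width
    return(switch(
      x$role,
      denoiser = (9L * w + w) + (x$depth - 2L) * (9L * w * w + w) +
        (9L * w + 1L),
      simulator = {
        lv <- x$depth
        ws <- w * 2^(seq_len(lv) - 1L)
        enc <- sum(vapply(seq_len(lv), function(i) {
          cin <- if (i == 1) 2L else ws[i - 1L]
          9L * cin * ws[i] + ws[i]
        }, numeric(1)))
        dec <- if (lv > 1) sum(vapply(seq_len(lv - 1L), function(j) {
          9L * (ws[j + 1L] + ws[j]) * ws[j] + ws[j]
        }, numeric(1))) else 0L
        as.integer(enc + dec + 9L * (w + 1L) + 1L)
      },
      discriminator = {
        d <- x$depth
        ws <- w * 2^(seq_len(d - 1L) - 1L)
        tot <- 0L
        for (i in seq_len(d)) {
          cin <- if (i == 1) 1L else ws[i - 1L]
          cout <- if (i == d) 1L else ws[i]
          tot <- tot + 9L * cin * cout + cout
        }
        as.integer(tot)
      }))
  }
  leaves <- param_leaves(unclass(x)[intersect(names(x),
                                              c("convs", "enc", "dec",
                                                "out"))])
  count_leaf <- function(p) {
    if (is.list(p)) sum(vapply(p, count_leaf, numeric(1))) else length(p)
  }
  as.integer(count_leaf(leaves))
}

trainable_params <- function(net) {
  param_leaves(unclass(net)[intersect(names(net),
                                      c("convs", "enc", "dec", "out"))])
}

set_trainable_params <- function(net, params) {
  for (nm in names(params)) {
    net[[nm]] <- restore_meta(net[[nm]], params[[nm]])
  }
  net
}

restore_meta <- function(old, new) {
  if (is.list(old) && !is.null(old$W)) {
    old$W <- new$W
    old$b <- new$b
    old
  } else {
    for (i in seq_along(old)) old[[i]] <- restore_meta(old[[i]], new[[i]])
    old
  }
}

#' Apply a denoiser to a CT image
#'
#' Normalizes the image with the network's HU window, runs the residual
#' denoiser, and maps back to HU. Works for a bare `csd_denoiser`, a training
#' state, or a fitted CSD object.
#'
#' @param object A `csd_denoiser`, `csd_state`, or `csd_fit`.
#' @param image A [ct_image()] or HU matrix.
#' @return Denoised image of the same type as the input.
#' @export
denoise <- function(object, image) {
  net <- resolve_denoiser(object)
  px <- as_pixels(image)
  xn <- hu_normalize(px, net$spec$hu_window)
  y <- forward_denoiser(net, xn)$y[, , 1L]
  out <- hu_denormalize(y, net$spec$hu_window)
  if (inherits(image, "ct_image")) {
    res <- image
    res$pixels <- out
    res$id <- paste0(image$id, "_denoised")
    res
  } else {
    out
  }
}

resolve_denoiser <- function(object) {
  if (inherits(object, "csd_denoiser")) return(object)
  if (inherits(object, "csd_fit")) return(resolve_denoiser(object$state))
  if (inherits(object, "csd_state")) {
    # inference uses the best-validation denoiser when one was tracked
    return(object$best_denoiser %||% object$denoiser)
  }
  stop("cannot extract a denoiser from a ", class(object)[1])
}

resolve_simulator <- function(object) {
  if (inherits(object, "csd_simulator")) return(object)
  if (inherits(object, "csd_fit")) return(resolve_simulator(object$state))
  if (inherits(object, "csd_state")) {
    # inference prefers the Polyak-averaged simulator when one is tracked
    return(object$sim_ema %||% object$simulator)
  }
  stop("cannot extract a simulator from a ", class(object)[1])
}

#' Simulate a low-dose acquisition with the trained simulator
#'
#' Draws the simulator's latent noise channel, runs the u-shaped network, and
#' returns the simulated low-dose image in HU. With `seed` given the output
#' is reproducible; otherwise the current RNG stream is used.
#'
#' @param object A `csd_simulator`, `csd_state`, or `csd_fit`.
#' @param image Clean [ct_image()] or HU matrix.
#' @param seed Optional integer seed for the latent noise channel.
#' @return Simulated low-dose image of the same type as the input.
#' @export
simulate_lowdose <- function(object, image, seed = NULL) {
  net <- resolve_simulator(object)
  px <- as_pixels(image)
  xn <- hu_normalize(px, net$spec$hu_window)
  draw <- function() matrix(rnorm(length(px)), nrow(px))
  z <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed),
                                                       draw())
  y <- forward_simulator(net, xn, z)$y[, , 1L]
  out <- hu_denormalize(y, net$spec$hu_window)
  if (inherits(image, "ct_image")) {
    res <- image
    res$pixels <- out
    res$id <- paste0(image$id, "_sim")
    res
  } else {
    out
  }
}

#' Save and load checkpoints
#'
#' Checkpoints are self-describing: they hold network weights and specs, the
#' optimizer state, the loss-weight vector, step counters, and the RNG state,
#' so a resumed run continues bit-identically on the same device.
#'
#' @param object Any state/fit object.
#' @param path File path.
#' @return `load_checkpoint()` returns the saved object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
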