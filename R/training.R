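#' Training plan for the cyclic simulation-and-denoising schedule
#'
#' Describes the full two-stage schedule: stage 1 pretrains the simulator
#' (adversarially, against real phantom low-dose scans) and the denoiser
#' (supervised, on paired phantom scans) independently; stage 2 alternates
#' the two cyclic updates — S2D (clean to simulated-noisy to denoised) and
#' D2S (noisy to denoised to re-simulated) — within every macro-step.
#'
#' @param stage1_steps,stage2_steps Step budgets for the two stages (>= 1).
#' @param batch_size Patches per update (>= 1).
#' @param patch_size Training crop side in pixels; full-image inference is
#'   unaffected.
#' @param s2d_d2s_ratio Integer pair: how many S2D and D2S updates run per
#'   macro-step. Both must be >= 1 so the cycles truly alternate.
#' @param lr_g,lr_d,lr_den Adam learning rates: `lr_g` for the simulator,
#'   `lr_d` for the discriminator, `lr_den` for the denoiser. The
#'   adversarial pair needs a fast discriminator and a slow generator; the
#'   denoiser is plain supervised regression and tolerates a much larger
#'   rate.
#' @param lambda Nonnegative 4-vector of loss weights
#'   `(gan_s2d, gan_d2s, l1_s2d, l1_d2s)`. Defaults weight the pixel terms
#'   above the adversarial terms, the stable regime for image-to-image
#'   adversarial training.
#' @param seed Integer master seed; every random draw in training derives
#'   from it.
#' @param simulator_spec,denoiser_spec,discriminator_spec
#'   [network_spec()]s for the three networks.
#' @param sim_feedback How the denoiser's l1 performance feeds back into the
#'   simulator during S2D. `"none"` (default): the l1 terms are losses of
#'   the denoiser alone and the simulator learns from the adversarial terms
#'   only — the cycle still couples the two through the data each feeds the
#'   other. `"joint"`: the S2D l1 gradient also flows into the simulator
#'   cooperatively (this pulls the injected noise toward zero when the l1
#'   weight dominates). `"adversarial"`: the reversed sign — the simulator
#'   tries to make denoising harder.
#' @param d2s_inputs `"mixed"` feeds the denoiser both phantom low-dose and
#'   simulated patient low-dose images in D2S; `"noisy-only"` restricts it to
#'   original noisy scans (the ablation/fair-comparison mode).
#' @param s2d_clean_domains Domains that must be present in every S2D clean
#'   batch.
#' @param val_every Macro-step cadence for scoring the denoiser on the
#'   held-out phantom split; the best-scoring denoiser is the one inference
#'   uses (fixed step budget + best-checkpoint selection).
#' @param sim_ema_decay Polyak-averaging decay for the simulator during the
#'   cyclic stage: inference uses the exponential moving average of the
#'   simulator weights (a ~1/(1-decay)-step horizon), which sits at the
#'   center of the adversarial orbit rather than on it. `0` disables
#'   averaging.
#' @param checkpoint_every Macro-step cadence for checkpoints (Inf = only at
#'   end when a checkpoint directory is supplied).
#' @return A `training_plan` object.
#' @export
training_plan <- function(stage1_steps = 200, stage2_steps = 500,
                          batch_size = 2, patch_size = 32,
                          s2d_d2s_ratio = c(1, 1),
                          lr_g = 2e-4, lr_d = 1e-4, lr_den = 1e-3,
                          lambda = c(1, 1, 10, 10), seed = 1,
                          simulator_spec = network_spec("simulator"),
                          denoiser_spec = network_spec("denoiser"),
                          discriminator_spec = network_spec("discriminator"),
                          sim_feedback = c("none", "joint", "adversarial"),
                          d2s_inputs = c("mixed", "noisy-only"),
                          s2d_clean_domains = c("phantom", "patient"),
                          sim_ema_decay = 0.995,
                          val_every = 25,
                          checkpoint_every = Inf) {
  if (sim_ema_decay < 0 || sim_ema_decay >= 1) {
    stop("`sim_ema_decay` must lie in [0, 1)")
  }
  stopifnot(stage1_steps >= 1, stage2_steps >= 1, batch_size >= 1,
            patch_size >= 8, lr_g > 0, lr_d > 0, lr_den > 0)
  if (length(s2d_d2s_ratio) != 2L || any(s2d_d2s_ratio < 1)) {
    stop("`s2d_d2s_ratio` must be two counts >= 1 (both cycles run every ",
         "macro-step)")
  }
  if (length(lambda) != 4L || any(lambda < 0)) {
    stop("`lambda` must be a nonnegative 4-vector")
  }
  div <- 2^(simulator_spec$depth - 1L)
  if (patch_size %% div != 0) {
    stop("`patch_size` must be divisible by ", div,
         " for the simulator's u-shape")
  }
  structure(list(
    stage1_steps = as.integer(stage1_steps),
    stage2_steps = as.integer(stage2_steps),
    batch_size = as.integer(batch_size),
    patch_size = as.integer(patch_size),
    s2d_d2s_ratio = as.integer(s2d_d2s_ratio),
    lr_g = lr_g, lr_d = lr_d, lr_den = lr_den,
    lambda = lambda, seed = as.integer(seed),
    simulator_spec = simulator_spec, denoiser_spec = denoiser_spec,
    discriminator_spec = discriminator_spec,
    sim_feedback = match.arg(sim_feedback),
    d2s_inputs = match.arg(d2s_inputs),
    s2d_clean_domains = s2d_clean_domains,
    sim_ema_decay = sim_ema_decay, val_every = val_every,
    checkpoint_every = checkpoint_every), class = "training_plan")
}

#' Desk-scale ("tiny") training profile
#'
#' Small network and schedule defaults sized for single-CPU experimentation
#' and the package's test suite: 8-channel networks, 32-pixel patches,
#' batches of 2. All arguments of [training_plan()] can be overridden.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [training_plan()].
#' @return A `training_plan`.
#' @export
tiny_profile <- function(seed = 1, ...) {
  args <- list(
    stage1_steps = 300, stage2_steps = 300, batch_size = 4,
    patch_size = 32, seed = seed, lr_g = 1e-4, lr_d = 2e-3, lr_den = 2e-3,
    denoiser_spec = network_spec("denoiser", depth = 5, width = 8,
                                 init = "zero-residual"),
    simulator_spec = network_spec("simulator", depth = 2, width = 8),
    discriminator_spec = network_spec("discriminator", depth = 3, width = 8))
  do.call(training_plan, modifyList(args, list(...)))
}

init_state <- function(plan) {
  sim <- build_simulator(plan$simulator_spec, derive_seed(plan$seed, 11))
  den <- build_denoiser(plan$denoiser_spec, derive_seed(plan$seed, 12))
  dis <- build_discriminator(plan$discriminator_spec,
                             derive_seed(plan$seed, 13))
  structure(list(
    simulator = sim, denoiser = den, discriminator = dis,
    opt = list(sim = adam_init(trainable_params(sim)),
               den = adam_init(trainable_params(den)),
               dis = adam_init(trainable_params(dis))),
    lambda = plan$lambda, step = 0L, seed = plan$seed,
    stage = "init", plan = plan), class = "csd_state")
}

#' @export
print.csd_state <- function(x, ...) {
  cat(sprintf("<csd_state> stage '%s', step %d, lambda (%s)\n",
              x$stage, x$step, paste(x$lambda, collapse = ", ")))
  invisible(x)
}

# ---- internal batch helpers (all patches are normalized matrices) ----

norm_patch <- function(img, size, window) {
  hu_normalize(crop_patch(as_pixels(img), size), window)
}

norm_patch_pair <- function(a, b, size, window) {
  pa <- as_pixels_any(a)
  pb <- as_pixels_any(b)
  n <- nrow(pa)
  m <- ncol(pa)
  i <- if (n == size) 1L else sample.int(n - size + 1L, 1L)
  j <- if (m == size) 1L else sample.int(m - size + 1L, 1L)
  ri <- i:(i + size - 1L)
  ci <- j:(j + size - 1L)
  list(a = hu_normalize(pa[ri, ci, drop = FALSE], window),
       b = hu_normalize(pb[ri, ci, drop = FALSE], window))
}

sample_items <- function(items, n) {
  items[sample.int(length(items), n, replace = length(items) < n)]
}

# Polyak (exponential moving average) tracking of the simulator weights;
# inference uses the average, training keeps the raw iterate.
ema_update <- function(state) {
  decay <- state$plan$sim_ema_decay
  if (decay <= 0) return(state)
  if (is.null(state$sim_ema)) {
    state$sim_ema <- state$simulator
    return(state)
  }
  mix <- function(e, w) {
    if (is.list(w) && !is.null(w$W)) {
      e$W <- decay * e$W + (1 - decay) * w$W
      e$b <- decay * e$b + (1 - decay) * w$b
      e
    } else {
      for (i in seq_along(w)) e[[i]] <- mix(e[[i]], w[[i]])
      e
    }
  }
  for (k in c("enc", "dec", "out")) {
    state$sim_ema[[k]] <- mix(state$sim_ema[[k]], state$simulator[[k]])
  }
  state
}

# One discriminator ascent step on pooled patch probabilities.
# Returns updated state and the minimax value on this batch.
disc_step <- function(state, real_patches, fake_patches, weight) {
  net <- state$discriminator
  eps <- 1e-7
  fw_r <- lapply(real_patches, forward_discriminator, net = net, cache = TRUE)
  fw_f <- lapply(fake_patches, forward_discriminator, net = net, cache = TRUE)
  pr <- unlist(lapply(fw_r, `[[`, "prob"))
  pf <- unlist(lapply(fw_f, `[[`, "prob"))
  value <- gan_loss(pr, pf)
  n_r <- length(pr)
  n_f <- length(pf)
  g <- NULL
  for (f in fw_r) {
    p <- pmin(pmax(f$prob, eps), 1 - eps)
    bw <- backward_discriminator(net, f$cache, -1 / (n_r * p))
    g <- acc_grads(g, bw$grads, weight)
  }
  for (f in fw_f) {
    p <- pmin(pmax(f$prob, eps), 1 - eps)
    bw <- backward_discriminator(net, f$cache, 1 / (n_f * (1 - p)))
    g <- acc_grads(g, bw$grads, weight)
  }
  r <- update_network(net, g, state$opt$dis, state$plan$lr_d)
  state$discriminator <- r$net
  state$opt$dis <- r$state
  list(state = state, value = value)
}

# Non-saturating generator gradient through the (current) discriminator:
# returns the gradient w.r.t. each fake input patch.
gen_adv_input_grads <- function(state, fake_patches) {
  net <- state$discriminator
  eps <- 1e-7
  n_tot <- 0L
  fws <- lapply(fake_patches, function(x) {
    f <- forward_discriminator(net, x, cache = TRUE)
    n_tot <<- n_tot + length(f$prob)
    f
  })
  lapply(fws, function(f) {
    p <- pmin(pmax(f$prob, eps), 1 - eps)
    backward_discriminator(net, f$cache, -1 / (n_tot * p))$gx
  })
}

#' Stage-1 pretraining on paired phantom scans
#'
#' Trains the simulator and denoiser independently on the phantom dose
#' ladder: the simulator adversarially (its output must fool a discriminator
#' that also sees real phantom low-dose patches), the denoiser by supervised
#' l1 regression from low-dose to standard-dose patches. Initializing stage 2
#' from these weights is what makes the interacting cycles converge at small
#' budgets.
#'
#' @param plan A [training_plan()].
#' @param phantom_pairs Nonempty list of [paired_scan()]s.
#' @return A `csd_state` at stage `"pretrain"`, with a `pretrain_history`
#'   tibble attached.
#' @export
pretrain <- function(plan, phantom_pairs) {
  stopifnot(inherits(plan, "training_plan"))
  if (length(phantom_pairs) == 0) stop("`phantom_pairs` must be nonempty")
  state <- init_state(plan)
  set.seed(plan$seed)
  window <- plan$denoiser_spec$hu_window
  ps <- plan$patch_size
  bs <- plan$batch_size
  rows <- vector("list", plan$stage1_steps)
  for (step in seq_len(plan$stage1_steps)) {
    # denoiser: supervised l1 on paired patches
    gden <- NULL
    l1_val <- 0
    for (b in seq_len(bs)) {
      pair <- sample_items(phantom_pairs, 1L)[[1L]]
      pp <- norm_patch_pair(pair$low, pair$standard, ps, window)
      fw <- forward_denoiser(state$denoiser, pp$a, cache = TRUE)
      diff <- fw$y[, , 1L] - pp$b
      l1_val <- l1_val + mean(abs(diff)) / bs
      gy <- sign(diff) / (length(diff) * bs)
      bw <- backward_denoiser(state$denoiser, fw$cache, gy)
      gden <- acc_grads(gden, bw$grads)
    }
    r <- update_network(state$denoiser, gden, state$opt$den, plan$lr_den)
    state$denoiser <- r$net
    state$opt$den <- r$state
    # simulator: adversarial against real phantom low-dose patches
    fakes <- vector("list", bs)
    caches <- vector("list", bs)
    reals <- vector("list", bs)
    for (b in seq_len(bs)) {
      pair <- sample_items(phantom_pairs, 1L)[[1L]]
      h <- norm_patch(pair$standard, ps, window)
      z <- matrix(rnorm(length(h)), nrow(h))
      fw <- forward_simulator(state$simulator, h, z, cache = TRUE)
      fakes[[b]] <- fw$y
      caches[[b]] <- fw$cache
      reals[[b]] <- norm_patch(sample_items(phantom_pairs, 1L)[[1L]]$low,
                               ps, window)
    }
    ds <- disc_step(state, reals, fakes, weight = 1)
    state <- ds$state
    gxs <- gen_adv_input_grads(state, fakes)
    gsim <- NULL
    for (b in seq_len(bs)) {
      bw <- backward_simulator(state$simulator, caches[[b]], gxs[[b]])
      gsim <- acc_grads(gsim, bw$grads)
    }
    r <- update_network(state$simulator, gsim, state$opt$sim, plan$lr_g)
    state$simulator <- r$net
    state$opt$sim <- r$state
    rows[[step]] <- tibble::tibble(step = step, l1_pre = l1_val,
                                   gan_pre = ds$value)
  }
  state$stage <- "pretrain"
  state$pretrain_history <- dplyr::bind_rows(rows)
  state
}

check_past_pretrain <- function(state) {
  if (!inherits(state, "csd_state") ||
      !state$stage %in% c("pretrain", "cyclic")) {
    stop("state must be past pretraining (stage 'pretrain' or 'cyclic')")
  }
}

#' One S2D cyclic update (clean -> simulated-noisy -> denoised)
#'
#' Runs the forward cycle on a mixed clean batch: the simulator turns clean
#' patches into simulated low-dose patches; the discriminator is pushed to
#' tell them from real phantom low-dose patches (weight `lambda[1]`); the
#' simulator descends the adversarial term (plus the optional l1 feedback
#' coupling selected by the plan's `sim_feedback`); the denoiser regresses
#' the simulated patches back to their clean inputs (weight `lambda[3]`).
#'
#' @param state A `csd_state` past pretraining.
#' @param clean_batch List of clean [ct_image()]s; must contain every domain
#'   named in the plan's `s2d_clean_domains`.
#' @param real_low_batch List of real low-dose images (phantom ladder).
#' @return `list(state, report)` where `report` is a [loss_report()] row.
#' @export
s2d_step <- function(state, clean_batch, real_low_batch) {
  check_past_pretrain(state)
  plan <- state$plan
  lam <- state$lambda
  doms <- vapply(clean_batch, function(x) {
    if (inherits(x, "ct_image")) x$domain_tag else NA_character_
  }, character(1))
  if (!all(is.na(doms))) {
    missing_dom <- setdiff(plan$s2d_clean_domains, doms)
    if (length(missing_dom)) {
      stop("S2D clean batch is missing required domain(s): ",
           paste(missing_dom, collapse = ", "))
    }
  }
  window <- plan$denoiser_spec$hu_window
  ps <- plan$patch_size
  nb <- length(clean_batch)
  hs <- vector("list", nb)
  fakes <- vector("list", nb)
  sim_caches <- vector("list", nb)
  for (b in seq_len(nb)) {
    h <- norm_patch(clean_batch[[b]], ps, window)
    z <- matrix(rnorm(length(h)), nrow(h))
    fw <- forward_simulator(state$simulator, h, z,
                            cache = lam[1] > 0 || lam[3] > 0)
    hs[[b]] <- h
    fakes[[b]] <- fw$y
    sim_caches[[b]] <- fw$cache
  }
  gan_val <- 0
  if (lam[1] > 0) {
    reals <- lapply(sample_items(real_low_batch, nb), norm_patch,
                    size = ps, window = window)
    ds <- disc_step(state, reals, fakes, weight = lam[1])
    state <- ds$state
    gan_val <- ds$value
  }
  # simulator + denoiser gradients through the cycle; a zero weight must
  # freeze its whole path, so the simulator update is skipped (not applied
  # with a zero gradient, which Adam momentum would still turn into motion)
  fb_sign <- switch(plan$sim_feedback, none = 0, joint = 1, adversarial = -1)
  sim_has_grad <- lam[1] > 0 || (lam[3] > 0 && fb_sign != 0)
  g_fakes <- if (lam[1] > 0) {
    lapply(gen_adv_input_grads(state, fakes), function(g) lam[1] * g)
  } else {
    lapply(fakes, function(f) array(0, dim(as_chw(f))))
  }
  l1_val <- 0
  gden <- NULL
  if (lam[3] > 0) {
    for (b in seq_len(nb)) {
      fw <- forward_denoiser(state$denoiser, fakes[[b]], cache = TRUE)
      diff <- fw$y[, , 1L] - hs[[b]]
      l1_val <- l1_val + mean(abs(diff)) / nb
      gy <- sign(diff) / (length(diff) * nb)
      bw <- backward_denoiser(state$denoiser, fw$cache, gy)
      gden <- acc_grads(gden, bw$grads, lam[3])
      g_fakes[[b]] <- g_fakes[[b]] + fb_sign * lam[3] * bw$gx
    }
  }
  if (sim_has_grad) {
    gsim <- NULL
    for (b in seq_len(nb)) {
      bw <- backward_simulator(state$simulator, sim_caches[[b]], g_fakes[[b]])
      gsim <- acc_grads(gsim, bw$grads)
    }
    r <- update_network(state$simulator, gsim, state$opt$sim, plan$lr_g)
    state$simulator <- r$net
    state$opt$sim <- r$state
    state <- ema_update(state)
  }
  if (lam[3] > 0) {
    r <- update_network(state$denoiser, gden, state$opt$den, plan$lr_den)
    state$denoiser <- r$net
    state$opt$den <- r$state
  }
  state$step <- state$step + 1L
  state$stage <- "cyclic"
  list(state = state,
       report = loss_report(gan_s2d = gan_val, l1_s2d = l1_val,
                            lambda = lam))
}

#' One D2S cyclic update (noisy -> denoised -> re-simulated)
#'
#' The denoiser learns by supervised l1 (weight `lambda[4]`) from phantom
#' pairs plus simulated patient low-dose inputs; the simulator re-noises the
#' denoiser's output and, with the discriminator (weight `lambda[2]`), is
#' pushed to match the real low-dose distribution, closing the reverse
#' cycle.
#'
#' @param state A `csd_state` past pretraining.
#' @param pairs List of phantom [paired_scan()]s.
#' @param sim_low_batch List of `list(low =, standard =)` HU matrices or
#'   images: simulator outputs on patient standard-dose inputs with their
#'   clean targets. Required when the plan's `d2s_inputs` is `"mixed"`;
#'   ignored under `"noisy-only"` (the ablation mode that restricts the
#'   denoiser to original noisy scans).
#' @return `list(state, report)`.
#' @export
d2s_step <- function(state, pairs, sim_low_batch = list()) {
  check_past_pretrain(state)
  plan <- state$plan
  lam <- state$lambda
  if (plan$d2s_inputs == "mixed" && lam[4] > 0 &&
      length(sim_low_batch) == 0) {
    stop("plan demands mixed D2S inputs but `sim_low_batch` is empty")
  }
  window <- plan$denoiser_spec$hu_window
  ps <- plan$patch_size
  l1_val <- 0
  if (lam[4] > 0) {
    sources <- lapply(pairs, function(p) list(low = p$low,
                                              standard = p$standard))
    if (plan$d2s_inputs == "mixed") sources <- c(sources, sim_low_batch)
    nb <- length(sources)
    gden <- NULL
    for (b in seq_len(nb)) {
      pp <- norm_patch_pair(sources[[b]]$low, sources[[b]]$standard, ps,
                            window)
      fw <- forward_denoiser(state$denoiser, pp$a, cache = TRUE)
      diff <- fw$y[, , 1L] - pp$b
      l1_val <- l1_val + mean(abs(diff)) / nb
      gy <- sign(diff) / (length(diff) * nb)
      bw <- backward_denoiser(state$denoiser, fw$cache, gy)
      gden <- acc_grads(gden, bw$grads, lam[4])
    }
    r <- update_network(state$denoiser, gden, state$opt$den, plan$lr_den)
    state$denoiser <- r$net
    state$opt$den <- r$state
  }
  gan_val <- 0
  if (lam[2] > 0) {
    nb <- length(pairs)
    fakes <- vector("list", nb)
    caches <- vector("list", nb)
    reals <- vector("list", nb)
    for (b in seq_len(nb)) {
      l_patch <- norm_patch(pairs[[b]]$low, ps, window)
      hhat <- forward_denoiser(state$denoiser, l_patch)$y[, , 1L]
      z <- matrix(rnorm(length(hhat)), nrow(hhat))
      fw <- forward_simulator(state$simulator, hhat, z, cache = TRUE)
      fakes[[b]] <- fw$y
      caches[[b]] <- fw$cache
      reals[[b]] <- norm_patch(sample_items(pairs, 1L)[[1L]]$low, ps, window)
    }
    ds <- disc_step(state, reals, fakes, weight = lam[2])
    state <- ds$state
    gan_val <- ds$value
    gxs <- gen_adv_input_grads(state, fakes)
    gsim <- NULL
    for (b in seq_len(nb)) {
      bw <- backward_simulator(state$simulator, caches[[b]],
                               lam[2] * gxs[[b]])
      gsim <- acc_grads(gsim, bw$grads)
    }
    r <- update_network(state$simulator, gsim, state$opt$sim, plan$lr_g)
    state$simulator <- r$net
    state$opt$sim <- r$state
    state <- ema_update(state)
  }
  state$step <- state$step + 1L
  state$stage <- "cyclic"
  list(state = state,
       report = loss_report(gan_d2s = gan_val, l1_d2s = l1_val,
                            lambda = lam))
}

#' Train a baseline denoiser by plain supervised regression
#'
#' The comparison arms of the evaluation harness are denoisers that differ
#' only in their training pairs: a phantom-only baseline trains on the
#' phantom dose ladder, a Gaussian baseline on clean patient-like images
#' corrupted by the additive noise model. This helper runs the supervised
#' half of the schedule alone: `steps` l1 updates on random paired crops.
#'
#' @param plan A [training_plan()] (network specs, patch/batch sizes, lr).
#' @param pairs Nonempty list of [paired_scan()]s.
#' @param steps Number of updates (default: the plan's full denoiser budget,
#'   `stage1_steps + 2 * stage2_steps`, matching the updates the denoiser
#'   receives across both CSD cycles).
#' @return A trained `csd_denoiser`.
#' @export
train_denoiser_supervised <- function(plan, pairs,
                                      steps = plan$stage1_steps +
                                        2L * plan$stage2_steps) {
  stopifnot(inherits(plan, "training_plan"))
  if (length(pairs) == 0) stop("`pairs` must be nonempty")
  net <- build_denoiser(plan$denoiser_spec, derive_seed(plan$seed, 12))
  opt <- adam_init(trainable_params(net))
  set.seed(plan$seed)
  window <- plan$denoiser_spec$hu_window
  ps <- plan$patch_size
  bs <- plan$batch_size
  for (step in seq_len(steps)) {
    g <- NULL
    for (b in seq_len(bs)) {
      pair <- sample_items(pairs, 1L)[[1L]]
      pp <- norm_patch_pair(pair$low, pair$standard, ps, window)
      fw <- forward_denoiser(net, pp$a, cache = TRUE)
      gy <- sign(fw$y[, , 1L] - pp$b) / (length(pp$b) * bs)
      g <- acc_grads(g, backward_denoiser(net, fw$cache, gy)$grads)
    }
    r <- update_network(net, g, opt, plan$lr_den)
    net <- r$net
    opt <- r$state
  }
  net
}

# validation l1 of the denoiser on full held-out phantom pairs (no RNG use)
validation_l1 <- function(state, val_pairs) {
  if (length(val_pairs) == 0) return(NA_real_)
  window <- state$plan$denoiser_spec$hu_window
  mean(vapply(val_pairs, function(p) {
    xn <- hu_normalize(as_pixels(p$low), window)
    y <- forward_denoiser(state$denoiser, xn)$y[, , 1L]
    mean(abs(y - hu_normalize(as_pixels(p$standard), window)))
  }, numeric(1)))
}

#' Train the full CSD model from a dataset manifest
#'
#' Runs stage-1 pretraining on the manifest's phantom pairs, then the
#' alternating S2D/D2S schedule for `stage2_steps` macro-steps, mixing
#' phantom pairs with unpaired patient standard-dose images. Emits a
#' per-update loss history, optionally checkpoints at a fixed cadence
#' (tracking the best validation l1 on the held-out phantom split), and is
#' resumable bit-exactly via [resume_csd()].
#'
#' @param plan A [training_plan()].
#' @param manifest A manifest from [build_manifest()] / [read_manifest()]
#'   containing phantom pairs and patient standard-dose entries.
#' @param checkpoint_dir Optional directory for checkpoints.
#' @param log_file Optional path; per-update loss rows are appended as JSON
#'   lines.
#' @return A `csd_fit`: the final `state`, the loss `history` tibble, the
#'   plan, and validation tracking.
#' @export
train_csd <- function(plan, manifest, checkpoint_dir = NULL,
                      log_file = NULL) {
  stopifnot(inherits(plan, "training_plan"))
  data <- load_manifest_images(manifest, "train")
  if (length(data$phantom_pairs) == 0 ||
      length(data$patient_standard) == 0) {
    stop("manifest must provide phantom pairs and patient standard-dose ",
         "images in the training split")
  }
  val_pairs <- load_manifest_images(manifest, "test")$phantom_pairs
  state <- pretrain(plan, data$phantom_pairs)
  run <- run_stage2(state, data, val_pairs, plan, history = list(),
                    start_step = 1L, checkpoint_dir = checkpoint_dir,
                    log_file = log_file)
  new_csd_fit(run, plan, val_pairs)
}

new_csd_fit <- function(run, plan, val_pairs) {
  structure(list(
    state = run$state,
    history = dplyr::bind_rows(run$history),
    plan = plan,
    pretrain_history = run$state$pretrain_history,
    val_l1 = validation_l1(run$state, val_pairs),
    best = run$best), class = "csd_fit")
}

run_stage2 <- function(state, data, val_pairs, plan, history, start_step,
                       checkpoint_dir, log_file) {
  phantom_stds <- unique_standards(data$phantom_pairs)
  if (is.null(state$best_val)) state$best_val <- NA_real_
  log_con <- if (!is.null(log_file)) {
    con <- file(log_file, open = "a")
    on.exit(close(con), add = TRUE)
    con
  }
  window <- plan$denoiser_spec$hu_window
  best <- list(val = Inf, path = NA_character_)
  for (macro in start_step:plan$stage2_steps) {
    for (r1 in seq_len(plan$s2d_d2s_ratio[1])) {
      clean <- c(sample_items(phantom_stds, 1L),
                 sample_items(data$patient_standard,
                              max(plan$batch_size - 1L, 1L)))
      lows <- lapply(sample_items(data$phantom_pairs, plan$batch_size),
                     `[[`, "low")
      st <- s2d_step(state, clean, lows)
      state <- st$state
      history[[length(history) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(step = macro, cycle = "s2d"),
                         st$report)
      log_row(log_con, macro, "s2d", st$report)
    }
    for (r2 in seq_len(plan$s2d_d2s_ratio[2])) {
      pairs <- sample_items(data$phantom_pairs, plan$batch_size)
      sims <- make_sim_lows(state, data$patient_standard, plan, window)
      st <- d2s_step(state, pairs, sims)
      state <- st$state
      history[[length(history) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(step = macro, cycle = "d2s"),
                         st$report)
      log_row(log_con, macro, "d2s", st$report)
    }
    if (length(val_pairs) > 0 &&
        (macro %% plan$val_every == 0 || macro == plan$stage2_steps)) {
      val <- validation_l1(state, val_pairs)
      if (is.na(state$best_val) || val < state$best_val) {
        state$best_val <- val
        state$best_denoiser <- state$denoiser
        state$best_step <- macro
      }
    }
    if (!is.null(checkpoint_dir) &&
        (macro %% plan$checkpoint_every == 0 ||
           macro == plan$stage2_steps)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      val <- validation_l1(state, val_pairs)
      path <- file.path(checkpoint_dir, sprintf("ckpt_%06d.rds", macro))
      save_checkpoint(list(state = state, history = history,
                           macro_step = macro, plan = plan,
                           rng = get(".Random.seed", envir = globalenv()),
                           val_l1 = val), path)
      if (!is.na(val) && val < best$val) best <- list(val = val, path = path)
    }
  }
  list(state = state, history = history, best = best)
}

unique_standards <- function(pairs) {
  stds <- lapply(pairs, `[[`, "standard")
  stds[!duplicated(vapply(stds, `[[`, character(1), "id"))]
}

# simulated patient low-dose patches for D2S (detached simulator outputs).
# The Polyak-averaged simulator generates them when available: the raw
# adversarial iterate carries transient distortions that the denoiser would
# otherwise learn to invert.
make_sim_lows <- function(state, patient_standard, plan, window) {
  if (plan$d2s_inputs != "mixed") return(list())
  sim <- state$sim_ema %||% state$simulator
  lapply(sample_items(patient_standard, plan$batch_size), function(img) {
    h <- crop_patch(as_pixels(img), plan$patch_size)
    hn <- hu_normalize(h, window)
    z <- matrix(rnorm(length(hn)), nrow(hn))
    low <- forward_simulator(sim, hn, z)$y[, , 1L]
    list(low = hu_denormalize(low, window), standard = h)
  })
}

log_row <- function(con, macro, cycle, report) {
  if (is.null(con)) return(invisible())
  writeLines(jsonlite::toJSON(
    c(list(step = macro, cycle = cycle), as.list(report)),
    auto_unbox = TRUE, digits = NA), con)
}

#' Resume a checkpointed CSD run
#'
#' Restores weights, optimizer state, loss history, and the RNG stream from a
#' checkpoint and continues the stage-2 loop to the plan's step budget. On a
#' single device the resumed run reproduces the uninterrupted run's final
#' weights bit-exactly.
#'
#' @param checkpoint_path Path written by [train_csd()].
#' @param manifest The same manifest the original run used.
#' @param checkpoint_dir,log_file As in [train_csd()].
#' @return A `csd_fit`.
#' @export
resume_csd <- function(checkpoint_path, manifest, checkpoint_dir = NULL,
                       log_file = NULL) {
  ck <- load_checkpoint(checkpoint_path)
  plan <- ck$plan
  data <- load_manifest_images(manifest, "train")
  val_pairs <- load_manifest_images(manifest, "test")$phantom_pairs
  if (!identical(ck$state$plan$denoiser_spec, plan$denoiser_spec)) {
    stop("checkpoint spec does not match plan")
  }
  assign(".Random.seed", ck$rng, envir = globalenv())
  if (ck$macro_step >= plan$stage2_steps) {
    run <- list(state = ck$state, history = ck$history,
                best = list(val = ck$val_l1, path = checkpoint_path))
  } else {
    run <- run_stage2(ck$state, data, val_pairs, plan,
                      history = ck$history,
                      start_step = ck$macro_step + 1L,
                      checkpoint_dir = checkpoint_dir, log_file = log_file)
  }
  new_csd_fit(run, plan, val_pairs)
}

#' @export
print.csd_fit <- function(x, ...) {
  cat(sprintf(
    "<csd_fit> %d pretrain + %d macro-steps; final total loss %.4g\n",
    x$plan$stage1_steps, x$plan$stage2_steps,
    tail(x$history$total, 1)))
  if (!is.na(x$val_l1)) {
    cat(sprintf("  validation l1 (held-out phantom): %.4g\n", x$val_l1))
  }
  invisible(x)
}
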