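#' Synthetic head-phantom slice
#'
#' Generates a clean, standard-dose, head-phantom-like CT slice: an elliptical
#' skull ring at bone HU (~ +1000) enclosing a uniform soft-tissue interior
#' (40 HU) with a few uniform tissue-equivalent inserts, on an air (-1000 HU)
#' background. The image is piecewise constant: physical phantoms carry the
#' scanner's true noise statistics but no anatomical texture, and that absence
#' of texture is exactly what this generator reproduces.
#'
#' @param seed Integer seed; the slice is a deterministic function of it.
#' @param size Image side in pixels (>= 32).
#' @param spacing Pixel spacing in mm/pixel.
#' @return A clean phantom [ct_image()].
#' @examples
#' ph <- generate_phantom_slice(seed = 1, size = 64)
#' range(ph$pixels)
#' @export
generate_phantom_slice <- function(seed, size = 128, spacing = 1) {
  check_slice_size(size)
  withr::with_seed(as.integer(seed), {
    geo <- head_geometry(size, perturb = FALSE)
    px <- matrix(-1000, size, size)
    px[geo$skull] <- 1000
    px[geo$brain] <- 40
    # uniform tissue-equivalent inserts at distinct HU
    hu_pool <- c(-100, 0, 60, 120, 800)
    n_ins <- sample(3:5, 1)
    hus <- sample(hu_pool, n_ins)
    for (ins in seq_len(n_ins)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.25, 0.55)
      icx <- geo$cx + rad * geo$a * 0.8 * cos(ang)
      icy <- geo$cy + rad * geo$b * 0.8 * sin(ang)
      ir <- runif(1, 0.04, 0.07) * size
      disc <- (geo$col - icx)^2 + (geo$row - icy)^2 < ir^2
      px[disc & geo$brain] <- hus[ins]
    }
    ct_image(px, spacing = spacing, id = paste0("phantom", seed),
             domain_tag = "phantom")
  })
}

#' Synthetic patient-like slice
#'
#' Generates a clean, standard-dose, patient-like head slice. It shares the
#' phantom's gross geometry (skull ring, soft-tissue interior, air background)
#' but adds what phantoms lack: irregular anatomy (harmonically perturbed head
#' outline, ventricle-like low-HU structures) and correlated intra-tissue
#' texture (a smoothed Gaussian random field, amplitude 5-15 HU, correlation
#' length 2-8 px). That texture is the feature a denoiser trained only on
#' phantoms destroys, and the feature the cyclic training must preserve.
#'
#' @inheritParams generate_phantom_slice
#' @return A clean patient-like [ct_image()].
#' @export
generate_patient_slice <- function(seed, size = 128, spacing = 1) {
  check_slice_size(size)
  withr::with_seed(as.integer(seed), {
    geo <- head_geometry(size, perturb = TRUE)
    px <- matrix(-1000, size, size)
    px[geo$skull] <- 1000
    px[geo$brain] <- 40
    # ventricle-like paired low-HU structures near the centre
    for (sgn in c(-1, 1)) {
      vcx <- geo$cx + sgn * 0.10 * size + rnorm(1, 0, 0.01 * size)
      vcy <- geo$cy - 0.03 * size + rnorm(1, 0, 0.01 * size)
      va <- 0.035 * size * runif(1, 0.8, 1.2)
      vb <- 0.10 * size * runif(1, 0.8, 1.2)
      vent <- ((geo$col - vcx) / va)^2 + ((geo$row - vcy) / vb)^2 < 1
      px[vent & geo$brain] <- 8
    }
    # correlated intra-tissue texture on all soft tissue
    amp <- runif(1, 5, 15)                     # HU
    corr_len <- runif(1, 2, 8)                 # pixels
    field <- gauss_filter2(matrix(rnorm(size * size), size), corr_len / 2)
    tissue <- geo$brain
    field <- field / stats::sd(field[tissue])
    px[tissue] <- px[tissue] + amp * field[tissue]
    ct_image(px, spacing = spacing, id = paste0("patient", seed),
             domain_tag = "patient")
  })
}

check_slice_size <- function(size) {
  if (!is.numeric(size) || length(size) != 1L || size < 32) {
    stop("`size` must be a single value >= 32 pixels")
  }
}

# Shared head geometry: masks for skull ring and brain interior, plus the
# coordinate grids. `perturb` adds low-order harmonic irregularity.
head_geometry <- function(size, perturb) {
  cx <- size * (0.5 + runif(1, -0.02, 0.02))
  cy <- size * (0.5 + runif(1, -0.02, 0.02))
  a <- size * 0.36 * runif(1, 0.95, 1.05)
  b <- size * 0.44 * runif(1, 0.95, 1.05)
  thick <- max(2, 0.06 * size)
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  xs <- (col - cx) / a
  ys <- (row - cy) / b
  rn <- sqrt(xs^2 + ys^2)
  rho <- 1
  if (perturb) {
    th <- atan2(ys, xs)
    for (m in 2:5) {
      rho <- rho + runif(1, 0.01, 0.035) * cos(m * th + runif(1, 0, 2 * pi))
    }
  }
  inner_scale <- 1 - thick / min(a, b)
  outer <- rn < rho
  inner <- rn < rho * inner_scale
  list(cx = cx, cy = cy, a = a, b = b, row = row, col = col,
       skull = outer & !inner, brain = inner)
}

#' Texture statistic separating phantom from patient slices
#'
#' Median local standard deviation (5x5 windows) over soft-tissue windows:
#' only windows lying entirely inside the soft-tissue HU band
#' (\[-200, 200\]) count, which drops windows touching the skull, air, or
#' high-HU inserts. Piecewise-constant phantom interiors score ~0 (most
#' windows are constant and the median ignores the insert boundaries);
#' textured patient-like interiors score near their texture amplitude. This
#' one-number statistic is what makes the two image domains trivially
#' separable, the premise behind phantom-only training failing on patients.
#'
#' @param image A [ct_image()] or numeric HU matrix.
#' @return Median local standard deviation in HU.
#' @export
texture_stat <- function(image) {
  px <- as_pixels(image)
  n <- nrow(px)
  m <- ncol(px)
  sweep5 <- function(x, f, init) {
    xp <- pad_symmetric(x, 2L)
    out <- matrix(init, n, m + 4L)
    for (t in 0:4) out <- f(out, xp[t + seq_len(n), , drop = FALSE])
    res <- matrix(init, n, m)
    for (t in 0:4) res <- f(res, out[, t + seq_len(m), drop = FALSE])
    res
  }
  box <- function(x) sweep5(x, `+`, 0) / 25
  mu <- box(px)
  v <- pmax(box(px^2) - mu^2, 0)
  wmin <- sweep5(px, pmin, Inf)
  wmax <- sweep5(px, pmax, -Inf)
  mask <- wmin > -200 & wmax < 200
  if (!any(mask)) return(0)
  stats::median(sqrt(v[mask]))
}

#' Paired standard/low-dose scan
#'
#' @param standard Clean [ct_image()].
#' @param low Low-dose [ct_image()] of identical geometry.
#' @param dose The [dose_level()] of `low`.
#' @return A `paired_scan` object.
#' @export
paired_scan <- function(standard, low, dose) {
  check_same_geometry(standard, low)
  stopifnot(inherits(dose, "dose_level"))
  structure(list(standard = standard, low = low, dose = dose),
            class = "paired_scan")
}

#' Simulate a phantom dose ladder
#'
#' Repeated "scans" of one clean base image at a descending series of doses:
#' for each requested dose the additive quantum-noise model injects the
#' dose-matched Gaussian field with a per-acquisition derived seed. The
#' standard-dose image is shared across pairs, as with a physical phantom.
#'
#' @param base Clean [ct_image()] (the standard-dose acquisition).
#' @param doses Numeric vector of doses in mAs, all below the model's
#'   reference dose, or a list of [dose_level()] objects.
#' @param seed Integer seed from which per-acquisition seeds are derived.
#' @param model A [noise_model()] used when `doses` is numeric.
#' @param n_per_dose Number of independent low-dose acquisitions per dose.
#' @return A list of [paired_scan()] objects (length `length(doses) *
#'   n_per_dose`).
#' @examples
#' base <- generate_phantom_slice(1, 64)
#' ladder <- generate_dose_ladder(base, seq(5, 95, by = 5), seed = 7)
#' length(ladder)
#' @export
generate_dose_ladder <- function(base, doses, seed, model = noise_model(),
                                 n_per_dose = 1) {
  if (length(doses) == 0) stop("`doses` must be nonempty")
  if (is.numeric(doses)) {
    doses <- lapply(doses, dose_level, model = model)
  }
  out <- vector("list", length(doses) * n_per_dose)
  idx <- 0L
  for (d in seq_along(doses)) {
    dl <- doses[[d]]
    if (dl$sigma <= 0) {
      stop("dose ", dl$mAs, " mAs is at or above the reference dose")
    }
    for (r in seq_len(n_per_dose)) {
      idx <- idx + 1L
      low <- add_lowdose_noise(base, dl, derive_seed(seed, idx))
      if (n_per_dose > 1) low$id <- paste0(low$id, "_r", r)
      out[[idx]] <- paired_scan(base, low, dl)
    }
  }
  out
}

#' Build a synthetic dataset on disk with a train/test manifest
#'
#' Generates `n_phantom` phantom slices, each expanded into a paired dose
#' ladder, plus `n_patient` unpaired standard-dose patient-like slices; writes
#' every image as a lossless container under `dir`; and returns a tibble
#' manifest. The train/test split takes `floor(n * train_fraction)` shuffled
#' units per domain, splitting by pair id so a phantom's standard and low-dose
#' images never straddle the split.
#'
#' @param dir Output directory (created if needed).
#' @param n_phantom Number of phantom base slices (>= 1).
#' @param n_patient Number of patient-like slices (>= 1).
#' @param doses Training dose levels in mAs.
#' @param train_fraction Fraction of units assigned to training, in (0, 1).
#' @param seed Integer seed controlling slice content, noise, and split.
#' @param size Image side in pixels.
#' @param model A [noise_model()].
#' @param n_per_dose Independent low-dose acquisitions per phantom and dose.
#' @return A tibble with columns `id`, `path`, `domain`, `dose_mAs`,
#'   `pair_id`, `split`, carrying `seed`, `size` and the noise model as
#'   attributes (class `csd_manifest`).
#' @export
build_manifest <- function(dir, n_phantom = 4, n_patient = 8,
                           doses = c(20, 30, 60), train_fraction = 0.8,
                           seed = 1, size = 64, model = noise_model(),
                           n_per_dose = 1) {
  if (n_phantom < 1 || n_patient < 1) stop("counts must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be inside (0, 1)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n_phantom)) {
    base <- generate_phantom_slice(derive_seed(seed, i), size)
    pid <- sprintf("ph%03d", i)
    base$id <- pid
    ladder <- generate_dose_ladder(base, doses, derive_seed(seed, 5000 + i),
                                   model = model, n_per_dose = n_per_dose)
    p <- file.path(dir, paste0(pid, "_std.cthu"))
    write_ct(base, p)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = pid, path = p, domain = "phantom", dose_mAs = NA_real_,
      pair_id = pid)
    for (li in seq_along(ladder)) {
      ps <- ladder[[li]]
      lid <- sprintf("%s_%03dmAs_%02d", pid,
                     as.integer(round(ps$dose$mAs)), li)
      ps$low$id <- lid
      pl <- file.path(dir, paste0(lid, ".cthu"))
      write_ct(ps$low, pl)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = lid, path = pl, domain = "phantom", dose_mAs = ps$dose$mAs,
        pair_id = pid)
    }
  }
  for (j in seq_len(n_patient)) {
    img <- generate_patient_slice(derive_seed(seed, 10000 + j), size)
    pid <- sprintf("pt%03d", j)
    img$id <- pid
    p <- file.path(dir, paste0(pid, "_std.cthu"))
    write_ct(img, p)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = pid, path = p, domain = "patient", dose_mAs = NA_real_,
      pair_id = pid)
  }
  man <- dplyr::bind_rows(rows)
  split_tbl <- withr::with_seed(derive_seed(seed, 999), {
    dplyr::bind_rows(lapply(split(unique(man$pair_id),
                                  sub("^(ph|pt).*", "\\1",
                                      unique(man$pair_id))), function(ids) {
      ids <- sample(ids)
      n_train <- floor(length(ids) * train_fraction)
      tibble::tibble(pair_id = ids,
                     split = rep(c("train", "test"),
                                 c(n_train, length(ids) - n_train)))
    }))
  })
  man <- dplyr::left_join(man, split_tbl, by = "pair_id")
  attr(man, "seed") <- seed
  attr(man, "size") <- size
  attr(man, "noise_model") <- model
  class(man) <- c("csd_manifest", class(man))
  man
}

#' Assign a train/test split to a set of unit ids
#'
#' Shuffles the ids and assigns the first `floor(n * train_fraction)` to the
#' training split; deterministic given `seed`.
#'
#' @param ids Character vector of unit ids.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `split`.
#' @export
split_units <- function(ids, train_fraction = 0.8, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be inside (0, 1)")
  }
  withr::with_seed(as.integer(seed), {
    ids <- sample(ids)
    n_train <- floor(length(ids) * train_fraction)
    tibble::tibble(id = ids,
                   split = rep(c("train", "test"),
                               c(n_train, length(ids) - n_train)))
  })
}

# Load manifest entries into memory, grouped the way training consumes them.
load_manifest_images <- function(manifest, split = "train") {
  sub <- manifest[manifest$split == split, , drop = FALSE]
  model <- attr(manifest, "noise_model") %||% noise_model()
  phantom_std <- sub[sub$domain == "phantom" & is.na(sub$dose_mAs), ]
  pairs <- list()
  for (r in seq_len(nrow(phantom_std))) {
    std <- read_ct(phantom_std$path[r])
    lows <- sub[sub$domain == "phantom" &
                  sub$pair_id == phantom_std$pair_id[r] &
                  !is.na(sub$dose_mAs), ]
    for (l in seq_len(nrow(lows))) {
      pairs[[length(pairs) + 1L]] <- paired_scan(
        std, read_ct(lows$path[l]),
        dose_level(lows$dose_mAs[l], model))
    }
  }
  patient <- sub[sub$domain == "patient", ]
  patient_imgs <- lapply(patient$path, read_ct)
  list(phantom_pairs = pairs, patient_standard = patient_imgs)
}
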