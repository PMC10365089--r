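#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical images have zero MSE and
#' return `Inf` (the exact-match sentinel; display layers cap it). The
#' data-range convention is explicit because reported dB values are not
#' comparable across conventions; the package default elsewhere is the full
#' HU window used for network normalization.
#'
#' @param reference,test Images of identical geometry ([ct_image()] or
#'   matrix).
#' @param data_range Positive scalar: the assumed dynamic range.
#' @return PSNR in dB (possibly `Inf`).
#' @examples
#' a <- matrix(0, 8, 8)
#' psnr(a, a + 10, data_range = 255) # 28.1308 dB
#' @export
psnr <- function(reference, test, data_range) {
  check_same_geometry(reference, test)
  if (!is.numeric(data_range) || data_range <= 0) {
    stop("`data_range` must be positive")
  }
  mse <- mean((as_pixels(reference) - as_pixels(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with the canonical parameters: 11x11 Gaussian window
#' (sigma 1.5, truncated at radius 5), k1 = 0.01, k2 = 0.03, population
#' (non-sample) covariance, symmetric boundary handling, border of one
#' window radius cropped before averaging. Symmetric in its two image
#' arguments and exactly 1 for identical images.
#'
#' @inheritParams psnr
#' @param sigma Gaussian window standard deviation in pixels.
#' @param radius Window truncation radius (window side `2 * radius + 1`).
#' @param k1,k2 Stability constants.
#' @return Mean SSIM over windows, in \[-1, 1\].
#' @export
ssim <- function(reference, test, data_range, sigma = 1.5, radius = 5L,
                 k1 = 0.01, k2 = 0.03) {
  check_same_geometry(reference, test)
  x <- as_pixels(reference)
  y <- as_pixels(test)
  if (min(dim(x)) < 2L * radius + 1L) {
    stop("image smaller than the ", 2 * radius + 1, "-pixel SSIM window")
  }
  if (!is.numeric(data_range) || data_range <= 0) {
    stop("`data_range` must be positive")
  }
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  f <- function(m) gauss_filter2(m, sigma, radius)
  ux <- f(x)
  uy <- f(y)
  uxx <- f(x * x)
  uyy <- f(y * y)
  uxy <- f(x * y)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  cxy <- uxy - ux * uy
  s <- ((2 * ux * uy + c1) * (2 * cxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  core <- s[(radius + 1):(nrow(s) - radius),
            (radius + 1):(ncol(s) - radius)]
  mean(core)
}

#' Image-quality metrics over a set of image pairs
#'
#' Computes PSNR and SSIM per pair and their means. Per-image values are
#' retained; the aggregate is exactly the mean of the per-image values.
#'
#' @param references,tests Lists of images (equal length, pairwise identical
#'   geometry).
#' @param data_range Dynamic-range convention for both metrics.
#' @return A `metric_result`: aggregate `psnr`, `ssim`, `n_images`, and the
#'   `per_image` tibble (with an `exact_match` flag where MSE was zero).
#' @export
metric_result <- function(references, tests, data_range) {
  stopifnot(length(references) == length(tests))
  per <- purrr::map2_dfr(references, tests, function(r, t) {
    p <- psnr(r, t, data_range)
    tibble::tibble(
      id = if (inherits(t, "ct_image")) t$id else NA_character_,
      psnr = p, ssim = ssim(r, t, data_range), exact_match = is.infinite(p))
  })
  structure(list(psnr = mean(per$psnr), ssim = mean(per$ssim),
                 n_images = nrow(per), data_range = data_range,
                 per_image = per), class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  shown <- if (is.infinite(x$psnr)) ">= 99 (exact match)" else
    sprintf("%.4f", x$psnr)
  cat(sprintf("<metric_result> n = %d: PSNR %s dB / SSIM %.4f (range %g)\n",
              x$n_images, shown, x$ssim, x$data_range))
  invisible(x)
}

#' @export
tidy.metric_result <- function(x, ...) x$per_image

#' @export
glance.metric_result <- function(x, ...) {
  tibble::tibble(psnr = x$psnr, ssim = x$ssim, n_images = x$n_images,
                 data_range = x$data_range)
}

#' Compare denoising arms across dose levels
#'
#' The experiment harness: every arm (a trained denoiser, a named baseline,
#' or any image-to-image function) is evaluated on the identical noisy test
#' images at every dose, so differences between arms reflect training
#' regimes only. Rows mirror a "PSNR (dB)/SSIM by noise level (mAs)" table.
#'
#' @param arms Named list. Each element is `"identity"` (the noisy input
#'   itself), a `csd_denoiser`/`csd_state`/`csd_fit`, or a function
#'   `ct_image -> ct_image`.
#' @param test_manifest Manifest whose test-split patient images form the
#'   clean references.
#' @param doses Numeric vector of doses (mAs) to corrupt the references at.
#' @param data_range PSNR/SSIM range convention.
#' @param seed Seed for the (arm-independent) noise realizations.
#' @param domain Which clean test images to use (`"patient"` default).
#' @return A `csd_comparison` tibble: one row per dose x arm with mean
#'   `psnr`, `ssim`, and `n`; per-image values in `attr(, "per_image")`.
#' @export
run_comparison <- function(arms, test_manifest, doses, data_range = 2048,
                           seed = 1, domain = "patient") {
  if (is.null(names(arms)) || any(names(arms) == "")) {
    stop("`arms` must be a named list")
  }
  model <- attr(test_manifest, "noise_model") %||% noise_model()
  test <- load_manifest_images(test_manifest, "test")
  cleans <- if (domain == "patient") test$patient_standard else
    unique_standards(test$phantom_pairs)
  if (length(cleans) == 0) stop("no clean test images in the manifest")
  rows <- list()
  per <- list()
  for (d in seq_along(doses)) {
    dl <- dose_level(doses[d], model)
    noisy <- lapply(seq_along(cleans), function(i) {
      add_lowdose_noise(cleans[[i]], dl, derive_seed(seed, d * 1000 + i))
    })
    for (a in names(arms)) {
      fn <- resolve_arm(arms[[a]])
      outs <- lapply(noisy, fn)
      mr <- metric_result(cleans, outs, data_range)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dose_mAs = doses[d], arm = a, psnr = mr$psnr, ssim = mr$ssim,
        n = mr$n_images)
      per[[length(per) + 1L]] <- dplyr::mutate(mr$per_image,
                                               dose_mAs = doses[d], arm = a)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "per_image") <- dplyr::bind_rows(per)
  attr(out, "data_range") <- data_range
  class(out) <- c("csd_comparison", class(out))
  out
}

resolve_arm <- function(arm) {
  if (is.function(arm)) return(arm)
  if (identical(arm, "identity")) return(function(img) img)
  if (inherits(arm, c("csd_denoiser", "csd_state", "csd_fit"))) {
    net <- resolve_denoiser(arm)
    return(function(img) denoise(net, img))
  }
  stop("cannot interpret an arm of class ", class(arm)[1])
}

#' Pairwise arm differences in a comparison report
#'
#' @param report A `csd_comparison`.
#' @return Tibble of all ordered arm pairs per dose with `d_psnr`, `d_ssim`
#'   (antisymmetric under swapping the pair).
#' @export
comparison_deltas <- function(report) {
  df <- tibble::as_tibble(report)
  dplyr::inner_join(df, df, by = "dose_mAs", suffix = c("_a", "_b"),
                    relationship = "many-to-many") |>
    dplyr::filter(.data$arm_a != .data$arm_b) |>
    dplyr::transmute(dose_mAs = .data$dose_mAs, arm_a = .data$arm_a,
                     arm_b = .data$arm_b,
                     d_psnr = .data$psnr_a - .data$psnr_b,
                     d_ssim = .data$ssim_a - .data$ssim_b)
}

#' @export
autoplot.csd_comparison <- function(object, metric = c("psnr", "ssim"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$dose_mAs, .data[[metric]],
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dose (mAs)",
                  y = if (metric == "psnr") "PSNR (dB)" else "SSIM",
                  colour = "training regime") +
    ggplot2::theme_minimal()
}

#' @export
tidy.csd_fit <- function(x, ...) x$history

#' @export
glance.csd_fit <- function(x, ...) {
  last <- tail(x$history, 1)
  tibble::tibble(
    stage1_steps = x$plan$stage1_steps,
    stage2_steps = x$plan$stage2_steps,
    final_total = last$total,
    final_l1_s2d = last$l1_s2d,
    val_l1 = x$val_l1)
}

#' @export
autoplot.csd_fit <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(
    object$history,
    c("gan_s2d", "gan_d2s", "l1_s2d", "l1_d2s", "total"),
    names_to = "term", values_to = "value")
  hist_long <- dplyr::filter(
    hist_long,
    !(startsWith(.data$term, "gan") & .data$value == 0),
    !(startsWith(.data$term, "l1") & .data$value == 0))
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(.data$step, .data$value,
                               colour = .data$cycle)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "macro-step", y = "loss term") +
    ggplot2::theme_minimal()
}
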