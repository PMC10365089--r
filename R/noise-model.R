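#' mAs-indexed additive quantum-noise model
#'
#' CT quantum noise falls as the photon count (proportional to the tube
#' current-time product, mAs) rises. The package models a low-dose
#' acquisition as the standard-dose image plus zero-mean Gaussian noise whose
#' standard deviation follows the excess-variance law
#' \deqn{\sigma(d) = k \sqrt{\max(0,\; 1/d - 1/d_{ref})}}
#' so the reference (standard) dose `reference_mAs` is exactly noise-free and
#' \eqn{\sigma \propto 1/\sqrt{d}} for doses far below the reference. The
#' calibration constant `k` has units HU·sqrt(mAs).
#'
#' The default `k = 190` puts the 20 mAs ultra-low-dose level at roughly
#' 40 HU of added noise under a 175 mAs reference, a visually severe
#' degradation regime.
#'
#' @param reference_mAs Standard (clean) dose in mAs. Default 175.
#' @param k Calibration constant in HU·sqrt(mAs). Default 190.
#' @param kind Noise family; only `"additive-gaussian"` is implemented.
#' @return A `noise_model` object.
#' @examples
#' m <- noise_model()
#' mas_to_sigma(m, c(20, 60, 175))
#' @export
noise_model <- function(reference_mAs = 175, k = 190,
                        kind = "additive-gaussian") {
  if (!is.numeric(reference_mAs) || reference_mAs <= 0) {
    stop("`reference_mAs` must be positive")
  }
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  kind <- match.arg(kind)
  structure(list(reference_mAs = reference_mAs, k = k, kind = kind),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> %s, reference %.5g mAs, k = %.5g HU*sqrt(mAs)\n",
    x$kind, x$reference_mAs, x$k))
  invisible(x)
}

#' Noise standard deviation for a dose level
#'
#' Evaluates the excess-variance quantum-noise law
#' \eqn{\sigma(d) = k\sqrt{\max(0, 1/d - 1/d_{ref})}}. Strictly decreasing in
#' dose and exactly zero at or above the reference dose.
#'
#' @param model A [noise_model()].
#' @param mAs Dose(s) in mAs; must be positive.
#' @return Noise standard deviation(s) in HU.
#' @export
mas_to_sigma <- function(model, mAs) {
  stopifnot(inherits(model, "noise_model"))
  if (!is.numeric(mAs) || any(!is.finite(mAs)) || any(mAs <= 0)) {
    stop("`mAs` must be positive and finite")
  }
  model$k * sqrt(pmax(0, 1 / mAs - 1 / model$reference_mAs))
}

#' Dose level with derived noise scale
#'
#' Bundles a tube current-time value with the additive-noise standard
#' deviation the model assigns to it.
#'
#' @param mAs Dose in mAs (positive scalar).
#' @param model A [noise_model()].
#' @return A `dose_level` object with fields `mAs` and `sigma` (HU).
#' @export
dose_level <- function(mAs, model = noise_model()) {
  if (length(mAs) != 1L) stop("`mAs` must be a scalar; see dose_ladder()")
  structure(list(mAs = mAs, sigma = mas_to_sigma(model, mAs)),
            class = "dose_level")
}

#' @export
print.dose_level <- function(x, ...) {
  cat(sprintf("<dose_level> %.5g mAs -> sigma %.4g HU\n", x$mAs, x$sigma))
  invisible(x)
}

#' Tabulate a ladder of dose levels
#'
#' @param mAs Vector of doses in mAs.
#' @param model A [noise_model()].
#' @return A tibble with columns `mAs` and `sigma`.
#' @examples
#' dose_ladder(seq(5, 95, by = 5))
#' @export
dose_ladder <- function(mAs, model = noise_model()) {
  tibble::tibble(mAs = mAs, sigma = mas_to_sigma(model, mAs))
}

#' Add simulated low-dose noise to a CT image
#'
#' Implements the additive image-domain degradation L = H + N: a zero-mean
#' Gaussian field with standard deviation `dose$sigma` HU is added to the
#' input. Reproducible given `seed`; geometry and metadata are preserved and
#' the output carries the dose tag.
#'
#' @param image A [ct_image()] (or numeric matrix) of clean HU values.
#' @param dose A [dose_level()].
#' @param seed Integer seed for the noise field.
#' @return A `ct_image` (or matrix, matching the input type).
#' @export
add_lowdose_noise <- function(image, dose, seed) {
  stopifnot(inherits(dose, "dose_level"))
  px <- as_pixels(image)
  if (dose$sigma > 0) {
    noise <- withr::with_seed(
      as.integer(seed),
      matrix(rnorm(length(px), 0, dose$sigma), nrow(px))
    )
    out <- px + noise
  } else {
    out <- px
  }
  if (inherits(image, "ct_image")) {
    res <- image
    res$pixels <- out
    res$dose_mAs <- dose$mAs
    res$id <- paste0(image$id, "_", format(dose$mAs), "mAs")
    res
  } else {
    out
  }
}

#' Estimate additive noise level from an image pair
#'
#' Sample standard deviation of the voxelwise difference between a noisy
#' image and its clean counterpart; a calibration/validation helper. A
#' constant offset between the images does not register as noise.
#'
#' @param noisy,clean Images of identical geometry ([ct_image()] or matrix).
#' @return Estimated noise standard deviation in HU.
#' @export
estimate_noise_sigma <- function(noisy, clean) {
  check_same_geometry(noisy, clean)
  stats::sd(as.vector(as_pixels(noisy) - as_pixels(clean)))
}
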