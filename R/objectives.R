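#' Adversarial (GAN) loss on discriminator probabilities
#'
#' The classic minimax value \eqn{E[\log d_{real}] + E[\log(1 - d_{fake})]},
#' evaluated on the discriminator's probability outputs for real low-dose
#' images and simulated (fake) ones. The discriminator ascends this value;
#' generator updates use the standard non-saturating negation (maximize
#' \eqn{E[\log d_{fake}]}). Probabilities at exactly 0 or 1 are clamped with
#' `eps` inside the logarithms so the value is always finite.
#'
#' @param d_real Probabilities assigned to real low-dose images, in (0, 1).
#' @param d_fake Probabilities assigned to simulator outputs.
#' @param eps Clamping epsilon inside the logs.
#' @return A finite scalar; at most 0, equal to `-2 log 2` when the
#'   discriminator outputs 1/2 everywhere.
#' @examples
#' gan_loss(rep(0.5, 4), rep(0.5, 4)) # -2 log 2
#' @export
gan_loss <- function(d_real, d_fake, eps = 1e-7) {
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1)) {
    stop("discriminator outputs must be probabilities in [0, 1]")
  }
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(dr)) + mean(log(1 - df))
}

#' Mean absolute (l1) loss
#'
#' Mean absolute difference over all pixels and batch entries. The
#' pixel-level supervision used for the denoiser in both training cycles.
#'
#' @param prediction,target Matrices/arrays of identical shape, or lists of
#'   them (a batch).
#' @return Nonnegative scalar.
#' @export
l1_loss <- function(prediction, target) {
  if (is.list(prediction) && !is.matrix(prediction)) {
    if (!is.list(target) || length(prediction) != length(target)) {
      stop("batch lengths differ")
    }
    vals <- mapply(function(p, t) {
      p <- as_pixels_any(p)
      t <- as_pixels_any(t)
      if (!identical(dim(p), dim(t))) stop("shape mismatch in l1_loss")
      c(sum(abs(p - t)), length(p))
    }, prediction, target)
    return(sum(vals[1, ]) / sum(vals[2, ]))
  }
  p <- as_pixels_any(prediction)
  t <- as_pixels_any(target)
  if (!identical(dim(p), dim(t))) stop("shape mismatch in l1_loss")
  mean(abs(p - t))
}

as_pixels_any <- function(x) {
  if (inherits(x, "ct_image")) x$pixels else x
}

#' Weighted total objective
#'
#' The joint objective combines the two adversarial terms and the two l1
#' terms of the S2D and D2S cycles with nonnegative weights:
#' `total = lambda[1]*gan_s2d + lambda[2]*gan_d2s + lambda[3]*l1_s2d +
#' lambda[4]*l1_d2s`.
#'
#' @param terms Numeric 4-vector `(gan_s2d, gan_d2s, l1_s2d, l1_d2s)`.
#' @param lambda Nonnegative 4-vector of loss weights.
#' @return The weighted sum.
#' @export
total_objective <- function(terms, lambda) {
  if (length(terms) != 4L || length(lambda) != 4L) {
    stop("`terms` and `lambda` must have length 4")
  }
  if (any(lambda < 0)) stop("`lambda` must be nonnegative")
  sum(lambda * terms)
}

#' Per-step loss report
#'
#' One tibble row holding the four loss terms, the weight vector, and their
#' exact weighted combination.
#'
#' @param gan_s2d,gan_d2s,l1_s2d,l1_d2s Scalar loss terms.
#' @param lambda Nonnegative 4-vector.
#' @return A one-row tibble with a `total` column satisfying the weighted-sum
#'   identity exactly.
#' @export
loss_report <- function(gan_s2d = 0, gan_d2s = 0, l1_s2d = 0, l1_d2s = 0,
                        lambda = c(1, 1, 10, 10)) {
  terms <- c(gan_s2d, gan_d2s, l1_s2d, l1_d2s)
  tibble::tibble(
    gan_s2d = gan_s2d, gan_d2s = gan_d2s,
    l1_s2d = l1_s2d, l1_d2s = l1_d2s,
    total = total_objective(terms, lambda))
}
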