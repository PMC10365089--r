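# Internal numeric helpers shared across modules.

# Derive a child seed from a base seed; stays well inside 32-bit range.
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(i) %% 1009L
}

# Affine HU <-> normalized mapping used by all networks.
# window = c(lo, hi) in HU; maps lo -> -1, hi -> +1 (no clipping).
hu_normalize <- function(x, window) {
  ctr <- mean(window)
  half <- diff(window) / 2
  (x - ctr) / half
}

hu_denormalize <- function(x, window) {
  ctr <- mean(window)
  half <- diff(window) / 2
  x * half + ctr
}

# Symmetric (half-sample) padding of a matrix by `r` pixels on every side;
# matches scipy.ndimage's "reflect" boundary mode.
pad_symmetric <- function(x, r) {
  n <- nrow(x)
  m <- ncol(x)
  ri <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(m), m + 1 - seq_len(r))
  x[ri, ci, drop = FALSE]
}

# Separable Gaussian filter with symmetric boundary handling.
# Kernel truncated at `radius` taps each side and renormalized.
gauss_filter2 <- function(x, sigma, radius = ceiling(3 * sigma)) {
  w <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  w <- w / sum(w)
  xp <- pad_symmetric(x, radius)
  n <- nrow(x)
  m <- ncol(x)
  # filter rows then columns over the padded image, then crop
  tmp <- matrix(0, n, m + 2 * radius)
  for (t in seq_along(w)) {
    tmp <- tmp + w[t] * xp[(t - 1) + seq_len(n), , drop = FALSE]
  }
  out <- matrix(0, n, m)
  for (t in seq_along(w)) {
    out <- out + w[t] * tmp[, (t - 1) + seq_len(m), drop = FALSE]
  }
  out
}

# Random top-left corner for a patch crop; uses the current RNG stream.
crop_patch <- function(x, size) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < size || m < size) {
    stop("image (", n, "x", m, ") smaller than patch size ", size)
  }
  i <- if (n == size) 1L else sample.int(n - size + 1L, 1L)
  j <- if (m == size) 1L else sample.int(m - size + 1L, 1L)
  x[i:(i + size - 1L), j:(j + size - 1L), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
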