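#' CT slice images in Hounsfield units
#'
#' A `ct_image` is a single 2-D CT slice: a numeric matrix of Hounsfield unit
#' (HU) values plus acquisition metadata. It is the unit every network in the
#' package consumes. Values are expected to be finite and physically plausible
#' (roughly \[-1024, 3071\] before noise is added); the constructor enforces
#' finiteness only, since additive noise legitimately pushes single pixels
#' outside the nominal HU range.
#'
#' @param pixels Numeric matrix of HU values.
#' @param spacing Pixel spacing in mm/pixel (positive scalar).
#' @param id Image identifier string.
#' @param domain_tag Either `"phantom"` or `"patient"`.
#' @param dose_mAs Tube current-time product in mAs for low-dose acquisitions,
#'   or `NA` to mark a clean (standard-dose) image.
#'
#' @return A `ct_image` object.
#' @examples
#' img <- ct_image(matrix(0, 32, 32), id = "water")
#' dim(img)
#' @export
ct_image <- function(pixels, spacing = 1, id = "img",
                     domain_tag = c("patient", "phantom"), dose_mAs = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (!all(is.finite(pixels))) stop("`pixels` must be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a positive scalar (mm/pixel)")
  }
  domain_tag <- match.arg(domain_tag)
  if (!is.na(dose_mAs) && dose_mAs <= 0) stop("`dose_mAs` must be positive")
  structure(
    list(pixels = pixels, spacing = spacing, id = as.character(id),
         domain_tag = domain_tag, dose_mAs = dose_mAs),
    class = "ct_image"
  )
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

#' @export
print.ct_image <- function(x, ...) {
  dose <- if (is.na(x$dose_mAs)) "standard dose" else paste0(x$dose_mAs, " mAs")
  cat(sprintf("<ct_image '%s'> %dx%d px, %.3g mm/px, %s, %s\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing,
              x$domain_tag, dose))
  cat(sprintf("  HU range [%.1f, %.1f], mean %.1f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

# Accept either a ct_image or a bare matrix; return the pixel matrix.
as_pixels <- function(x) {
  if (inherits(x, "ct_image")) x$pixels else if (is.matrix(x)) x else
    stop("expected a ct_image or a numeric matrix")
}

check_same_geometry <- function(a, b) {
  pa <- as_pixels(a)
  pb <- as_pixels(b)
  if (!identical(dim(pa), dim(pb))) {
    stop("images have mismatched geometry: ",
         paste(dim(pa), collapse = "x"), " vs ",
         paste(dim(pb), collapse = "x"))
  }
  invisible(TRUE)
}

#' Plot a CT slice
#'
#' Renders a `ct_image` with ggplot2 on a grey HU scale.
#'
#' @param object A `ct_image`.
#' @param window HU display window, `c(lo, hi)`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ct_image <- function(object, window = c(-1024, 1024), ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$hu <- as.vector(px)[(df$col - 1L) * nrow(px) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = window, oob = scales_squish) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$id, fill = "HU") +
    ggplot2::theme_void()
}

# minimal squish to avoid a scales dependency in Imports
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}
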