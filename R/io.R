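#' Lossless CT image containers
#'
#' The native `.cthu` container stores a slice bit-exactly: a short text
#' header (magic, dimensions, spacing, domain, dose, id) followed by the
#' pixel matrix as little-endian float64, column-major. `write_ct()` /
#' `read_ct()` round-trip every finite double exactly.
#'
#' @param image A [ct_image()].
#' @param path Output file path.
#' @return `write_ct()` returns `path` invisibly; `read_ct()` a `ct_image`.
#' @examples
#' img <- generate_phantom_slice(1, 32)
#' f <- tempfile(fileext = ".cthu")
#' write_ct(img, f)
#' identical(read_ct(f)$pixels, img$pixels)
#' @export
write_ct <- function(image, path) {
  stopifnot(inherits(image, "ct_image"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "CTHU1\n",
    nrow(image$pixels), " ", ncol(image$pixels), "\n",
    format(image$spacing, digits = 17), "\n",
    image$domain_tag, "\n",
    ifelse(is.na(image$dose_mAs), "NA", format(image$dose_mAs, digits = 17)),
    "\n",
    image$id, "\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(image$pixels), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readLines(con, n = 6L)
  if (length(hdr) < 6L || hdr[1] != "CTHU1") {
    stop("not a CTHU container: ", path)
  }
  dims <- as.integer(strsplit(hdr[2], " ")[[1]])
  px <- readBin(con, "double", n = dims[1] * dims[2], size = 8,
                endian = "little")
  ct_image(matrix(px, dims[1], dims[2]),
           spacing = as.numeric(hdr[3]),
           id = hdr[6],
           domain_tag = hdr[4],
           dose_mAs = ifelse(hdr[5] == "NA", NA_real_, as.numeric(hdr[5])))
}

#' Export a slice as a 16-bit integer raster (TIFF)
#'
#' Quantizes HU values onto a 16-bit grid over `window` and writes a 16-bit
#' TIFF. The affine mapping back to HU is returned (and should be recorded in
#' the dataset manifest); the round trip is exact to within one quantization
#' step of the window.
#'
#' @param image A [ct_image()].
#' @param path Output path.
#' @param window HU range mapped onto \[0, 65535\].
#' @return Invisibly, a list with `slope` and `intercept` such that
#'   `HU = slope * stored + intercept`.
#' @export
write_ct_tiff16 <- function(image, path, window = c(-1024, 3071)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for 16-bit raster export")
  }
  stopifnot(inherits(image, "ct_image"))
  slope <- diff(window) / 65535
  intercept <- window[1]
  q <- round((image$pixels - intercept) / slope)
  if (any(q < 0 | q > 65535)) {
    stop("HU values fall outside the export window")
  }
  tiff::writeTIFF(q / 65535, path, bits.per.sample = 16)
  invisible(list(slope = slope, intercept = intercept))
}

#' @rdname write_ct_tiff16
#' @param slope,intercept Affine mapping recorded at export time.
#' @param ... Metadata passed to [ct_image()].
#' @export
read_ct_tiff16 <- function(path, slope, intercept, ...) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for 16-bit raster import")
  }
  q <- round(tiff::readTIFF(path) * 65535)
  ct_image(q * slope + intercept, ...)
}

#' NIfTI import/export adapters
#'
#' Thin adapters over RNifti for users with real data in NIfTI form; values
#' are taken as HU as stored.
#'
#' @param image A [ct_image()].
#' @param path File path.
#' @return `read_ct_nifti()` returns a `ct_image`.
#' @export
write_ct_nifti <- function(image, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the 'RNifti' package is required for NIfTI export")
  }
  stopifnot(inherits(image, "ct_image"))
  RNifti::writeNifti(RNifti::asNifti(image$pixels,
                                     pixdim = rep(image$spacing, 2)), path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @param ... Metadata passed to [ct_image()].
#' @export
read_ct_nifti <- function(path, ...) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the 'RNifti' package is required for NIfTI import")
  }
  arr <- RNifti::readNifti(path)
  px <- as.matrix(arr[, , drop = TRUE])
  sp <- attr(arr, "pixdim")
  ct_image(px, spacing = if (length(sp) >= 1) sp[1] else 1, ...)
}

#' Read a CT slice, dispatching on format
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"cthu"`, `"tiff16"`, or
#'   `"nifti"`.
#' @param ... Extra arguments for the format reader (e.g. `slope`,
#'   `intercept` for `tiff16`).
#' @return A [ct_image()].
#' @export
read_image <- function(path, format = c("auto", "cthu", "tiff16", "nifti"),
                       ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("[.]gz$", "", path)))
    format <- switch(ext,
                     cthu = "cthu",
                     tif = , tiff = "tiff16",
                     nii = "nifti",
                     stop("cannot infer image format for: ", path))
  }
  switch(format,
         cthu = read_ct(path),
         tiff16 = read_ct_tiff16(path, ...),
         nifti = read_ct_nifti(path, ...))
}

#' Write and read dataset manifests
#'
#' Manifests are flat tab-separated tables with `#`-prefixed header lines
#' carrying the generator seed, image size, and noise-model calibration.
#'
#' @param manifest A manifest tibble from [build_manifest()].
#' @param path Output path.
#' @return `read_manifest()` returns the manifest tibble with attributes
#'   restored.
#' @export
write_manifest <- function(manifest, path) {
  model <- attr(manifest, "noise_model") %||% noise_model()
  hdr <- c(
    paste0("# seed: ", attr(manifest, "seed") %||% NA),
    paste0("# size: ", attr(manifest, "size") %||% NA),
    paste0("# reference_mAs: ", model$reference_mAs),
    paste0("# k: ", model$k))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as.data.frame(manifest), path, sep = "\t", row.names = FALSE,
    quote = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*: ", "", m[1])) else NA_real_
  }
  man <- tibble::as_tibble(utils::read.table(
    text = lines[!grepl("^#", lines)], sep = "\t", header = TRUE,
    stringsAsFactors = FALSE))
  man$dose_mAs <- as.numeric(man$dose_mAs)
  attr(man, "seed") <- getv("seed")
  attr(man, "size") <- getv("size")
  attr(man, "noise_model") <- noise_model(
    reference_mAs = getv("reference_mAs") %|na|% 175,
    k = getv("k") %|na|% 190)
  class(man) <- c("csd_manifest", class(man))
  man
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a
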