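# sRGB <-> CIELAB conversion and CIE76 colour difference.
#
# Everything downstream measures colour in CIELAB (D65, 2 degree observer);
# sRGB rasters are converted on read and processed as floating-point Lab
# arrays so 8-bit quantisation cannot interfere with MCDM-scale statistics.

# sRGB (linear) -> XYZ matrix, D65 2-degree observer (IEC 61966-2-1).
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.XYZ_TO_SRGB <- solve(.SRGB_TO_XYZ)

# Reference white taken as the row sums of the matrix so that R=G=B=1 maps
# exactly to L*=100, a*=b*=0.
.WHITE_D65 <- rowSums(.SRGB_TO_XYZ)

#' Construct a CIELAB image
#'
#' A `lab_image` is the package's native image representation: a numeric
#' `H x W x 3` array whose channels are the CIELAB coordinates L* (0-100),
#' a* (red-green) and b* (yellow-blue).
#'
#' @param pixels Numeric `H x W x 3` array of CIELAB values.
#' @return A `lab_image` object.
#' @export
lab_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 numeric array", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("lab_image: non-finite pixel values", call. = FALSE)
  L <- pixels[, , 1]
  if (any(L < -1e-9) || any(L > 100 + 1e-9))
    stop("lab_image: L* outside [0, 100]", call. = FALSE)
  dimnames(pixels) <- list(NULL, NULL, c("L", "a", "b"))
  structure(pixels, class = c("lab_image", "array"))
}

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lab_image %d x %d> L* range [%.1f, %.1f]\n",
              d[1], d[2], min(x[, , 1]), max(x[, , 1])))
  invisible(x)
}

.srgb_eotf <- function(c) {
  ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
}

.srgb_oetf <- function(c) {
  ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert sRGB values to CIELAB
#'
#' Applies the standard sRGB electro-optical transfer function, the
#' sRGB-to-XYZ primaries matrix and the CIELAB transform with the D65
#' 2-degree-observer white point.  Works on an `H x W x 3` array (returned as
#' a [lab_image()]) or an `n x 3` matrix of colours.
#'
#' @param rgb Numeric array (`H x W x 3`) or matrix (`n x 3`) with components
#'   in `[0, 1]`.
#' @return A [lab_image()] for array input, otherwise an `n x 3` matrix with
#'   columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  if (any(!is.finite(rgb)))
    stop("srgb_to_lab: non-finite input", call. = FALSE)
  if (any(rgb < -1e-9) || any(rgb > 1 + 1e-9))
    stop("srgb_to_lab: components must lie in [0, 1]", call. = FALSE)
  as_img <- is.array(rgb) && length(dim(rgb)) == 3L
  m <- if (as_img) matrix(rgb, ncol = 3L) else rbind(as.matrix(rgb))
  xyz <- .srgb_eotf(m) %*% t(.SRGB_TO_XYZ)
  f <- .lab_f(sweep(xyz, 2, .WHITE_D65, "/"))
  lab <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  # clamp tiny negative L* from numerical round-off at black
  lab[, 1] <- pmin(pmax(lab[, 1], 0), 100)
  if (as_img) lab_image(array(lab, dim = dim(rgb))) else lab
}

#' Convert CIELAB values to sRGB
#'
#' Exact inverse of [srgb_to_lab()] for in-gamut colours.  Out-of-gamut
#' pixels are handled per `gamut_policy`: `"clip"` clips components to
#' `[0, 1]` and records the number of affected pixels in the
#' `"clipped_pixels"` attribute (with a warning); `"error"` aborts, reporting
#' the count.
#'
#' @param lab A [lab_image()], `H x W x 3` array, or `n x 3` matrix of CIELAB
#'   values.
#' @param gamut_policy `"clip"` (default) or `"error"`.
#' @param gamut_tol Numerical slack before a component counts as
#'   out-of-gamut.
#' @return sRGB values in `[0, 1]`, same shape as the input, with attribute
#'   `clipped_pixels`.
#' @export
lab_to_srgb <- function(lab, gamut_policy = c("clip", "error"),
                        gamut_tol = 1e-6) {
  gamut_policy <- match.arg(gamut_policy)
  as_img <- is.array(lab) && length(dim(lab)) == 3L
  m <- if (as_img) matrix(lab, ncol = 3L) else rbind(as.matrix(lab))
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- sweep(cbind(.lab_finv(fx), .lab_finv(fy), .lab_finv(fz)),
               2, .WHITE_D65, "*")
  lin <- xyz %*% t(.XYZ_TO_SRGB)
  out <- rowSums(lin < -gamut_tol | lin > 1 + gamut_tol) > 0
  n_out <- sum(out)
  if (n_out > 0 && gamut_policy == "error")
    stop(sprintf("lab_to_srgb: %d pixel(s) outside the sRGB gamut", n_out),
         call. = FALSE)
  if (n_out > 0)
    warning(sprintf("lab_to_srgb: clipped %d out-of-gamut pixel(s)", n_out),
            call. = FALSE)
  lin <- pmin(pmax(lin, 0), 1)
  rgb <- .srgb_oetf(lin)
  rgb <- pmin(pmax(rgb, 0), 1)
  res <- if (as_img) array(rgb, dim = dim(lab)) else rgb
  attr(res, "clipped_pixels") <- n_out
  res
}

#' CIE76 colour difference
#'
#' Euclidean distance between CIELAB colours: the plain
#' \eqn{\Delta E = \sqrt{(\Delta L^*)^2 + (\Delta a^*)^2 + (\Delta b^*)^2}}
#' metric (not CIEDE2000), as used for both skin-uniformity and
#' feature-contrast statistics here.  Vectorised over rows when given
#' matrices.
#'
#' @param c1,c2 Length-3 numeric vectors `(L, a, b)` or `n x 3` matrices.
#' @return Non-negative colour difference(s).
#' @export
delta_e <- function(c1, c2) {
  m1 <- rbind(as.matrix(c1)); m2 <- rbind(as.matrix(c2))
  if (length(c1) == 3L && is.null(dim(c1))) m1 <- matrix(c1, ncol = 3L)
  if (length(c2) == 3L && is.null(dim(c2))) m2 <- matrix(c2, ncol = 3L)
  if (!all(is.finite(m1)) || !all(is.finite(m2)))
    stop("delta_e: non-finite input", call. = FALSE)
  d <- sqrt(rowSums((m1 - m2)^2))
  if (length(d) == 1L) as.numeric(d) else d
}

#' Read a raster image as a CIELAB image
#'
#' Reads an 8- or 16-bit PNG or TIFF (scaled to `[0, 1]` by the reader) and
#' converts it to CIELAB.  Alpha channels are dropped; greyscale rasters are
#' expanded to three channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [lab_image()].
#' @export
read_lab_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rgb <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("read_lab_image: unsupported extension '", ext, "'", call. = FALSE))
  if (length(dim(rgb)) == 2L) rgb <- array(rep(rgb, 3L), dim = c(dim(rgb), 3L))
  if (dim(rgb)[3] == 4L) rgb <- rgb[, , 1:3, drop = FALSE]
  srgb_to_lab(rgb)
}

#' Write a CIELAB image to an sRGB raster file
#'
#' @param img A [lab_image()].
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @param bits Bit depth: PNG is written at 8 bits; TIFF supports 8 or 16.
#' @param gamut_policy Passed to [lab_to_srgb()].
#' @return Invisibly, the number of gamut-clipped pixels.
#' @export
write_lab_image <- function(img, path, bits = 8L,
                            gamut_policy = c("clip", "error")) {
  stopifnot(bits %in% c(8L, 16L))
  rgb <- lab_to_srgb(img, gamut_policy = match.arg(gamut_policy))
  n_clip <- attr(rgb, "clipped_pixels")
  attr(rgb, "clipped_pixels") <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(rgb, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(rgb, where = path, bits.per.sample = bits)
  } else stop("write_lab_image: unsupported extension '", ext, "'",
              call. = FALSE)
  invisible(n_clip)
}

#' Serialise a CIELAB image as raw floats with a JSON header
#'
#' Writes the pixel array as little-endian float64 alongside a JSON header
#' naming the colour space and dimensions, so Lab data survive a round trip
#' without gamut or quantisation loss.
#'
#' @param img A [lab_image()].
#' @param path Output path for the binary payload; the header is written to
#'   `paste0(path, ".json")`.
#' @export
write_lab_array <- function(img, path) {
  d <- dim(img)
  header <- list(colour_space = "CIELAB", white_point = "D65",
                 height = d[1], width = d[2], channels = c("L", "a", "b"),
                 dtype = "float64_le")
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(img), con, size = 8L, endian = "little")
}

#' @rdname write_lab_array
#' @return `read_lab_array()` returns the [lab_image()].
#' @export
read_lab_array <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"))
  n <- header$height * header$width * 3L
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 8L, endian = "little")
  lab_image(array(v, dim = c(header$height, header$width, 3L)))
}
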