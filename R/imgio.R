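# Raster I/O and color-space conversions shared by every pipeline stage.
#
# The working representation is an H x W x 3 numeric array of intensities in
# [0, 1] ("image" below); grayscale planes are plain H x W matrices in [0, 1].
# Conventions fixed package-wide: sRGB primaries with D65 white for CIELab,
# hue stored as a fraction of a turn in [0, 1).

#' Validate and coerce an RGB image array
#'
#' An image is an `H x W x 3` numeric array with all values finite and in
#' \[0, 1\]. A matrix (grayscale plane) is replicated to three channels.
#'
#' @param x Numeric array `H x W x 3`, or an `H x W` matrix.
#' @param clip If `TRUE`, clamp values into \[0, 1\] instead of erroring on
#'   small numerical overshoots.
#' @return The validated `H x W x 3` array.
#' @export
as_image <- function(x, clip = FALSE) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("image values must be finite numbers")
  if (clip) x[] <- pmin(pmax(x, 0), 1)
  if (any(x < 0 | x > 1)) stop("image values must lie in [0, 1]")
  x
}

check_gray <- function(x) {
  if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x)) ||
      any(x < 0 | x > 1))
    stop("channel must be a finite numeric matrix in [0, 1]")
  x
}

#' Read a PNG, JPEG or TIFF file as an RGB image
#'
#' 8-bit samples are scaled by 1/255 and 16-bit samples by 1/65535 (the
#' codecs do this natively); grayscale files are replicated to three
#' channels and an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff` file.
#' @return An `H x W x 3` image array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch(switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  ), error = function(e) stop("cannot read '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3L] >= 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3L] == 2L) # gray + alpha
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  as_image(x, clip = TRUE)
}

#' Write an RGB image to a PNG, JPEG or TIFF file
#'
#' Values are quantized to 8 bits with round-half-up before encoding, so the
#' file contents are platform independent.
#'
#' @param img Image array (see [as_image()]).
#' @param path Output path; the extension selects the codec.
#' @param quality JPEG quality in (0, 1\], ignored for the lossless formats.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, quality = 0.95) {
  img <- as_image(img)
  q <- floor(img * 255 + 0.5) / 255  # round half up to 8-bit levels
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png  = png::writePNG(q, path),
      jpg  = ,
      jpeg = jpeg::writeJPEG(q, path, quality = quality),
      tif  = ,
      tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
      stop("unsupported image format: .", ext))
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' RGB to HSV conversion
#'
#' Hue is a fraction of a turn in \[0, 1); saturation and value in \[0, 1\].
#'
#' @param img Image array.
#' @return `H x W x 3` array with planes H, S, V.
#' @export
rgb_to_hsv <- function(img) {
  img <- as_image(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
             as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  out <- array(0, dim = d)
  out[, , 1L] <- hsv[1L, ] %% 1
  out[, , 2L] <- hsv[2L, ]
  out[, , 3L] <- hsv[3L, ]
  out
}

#' HSV to RGB conversion (inverse of [rgb_to_hsv()])
#'
#' @param hsv `H x W x 3` array with planes H (fraction of turn), S, V.
#' @return Image array.
#' @export
hsv_to_rgb <- function(hsv) {
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3L] != 3L)
    stop("hsv must be an H x W x 3 array")
  h <- (as.vector(hsv[, , 1L]) %% 1) * 6
  s <- as.vector(hsv[, , 2L])
  v <- as.vector(hsv[, , 3L])
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    sel <- i == k
    if (!any(sel)) next
    rgb <- switch(as.character(k),
      "0" = list(v, t, p), "1" = list(q, v, p), "2" = list(p, v, t),
      "3" = list(p, q, v), "4" = list(t, p, v), "5" = list(v, p, q))
    r[sel] <- rgb[[1L]][sel]; g[sel] <- rgb[[2L]][sel]; b[sel] <- rgb[[3L]][sel]
  }
  out <- array(0, dim = dim(hsv))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  out
}

#' Luminance channel
#'
#' The per-pixel average of the three channels, `L = (R + G + B) / 3` — the
#' luminance definition used by the brightness/saliency fusion weights.
#'
#' @param img Image array.
#' @return `H x W` matrix in \[0, 1\].
#' @export
luminance <- function(img) {
  img <- as_image(img)
  matrix(img[, , 1L] + img[, , 2L] + img[, , 3L], dim(img)[1L],
         dim(img)[2L]) / 3
}

#' RGB to CIELab conversion (sRGB primaries, D65 white)
#'
#' @param img Image array.
#' @return `H x W x 3` array with planes L* (0–100), a*, b*.
#' @export
rgb_to_lab <- function(img) {
  img <- as_image(img)
  d <- dim(img)
  m <- cbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
             as.vector(img[, , 3L]))
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  out <- array(0, dim = d)
  out[, , 1L] <- lab[, 1L]; out[, , 2L] <- lab[, 2L]; out[, , 3L] <- lab[, 3L]
  out
}
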