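#' Gaussian convolution kernel
#'
#' Builds an isotropic 2-D Gaussian sampled on the integer grid
#' \eqn{[-r, r]^2} and renormalized to sum to one, so that convolution with a
#' constant plane reproduces that constant exactly.  The renormalization
#' compensates for truncating the Gaussian tails at the kernel radius.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Kernel radius in pixels (integer >= 1).  Defaults to
#'   `ceiling(3 * sigma)`, which keeps more than 99.7 percent of the
#'   continuous mass inside the support.
#' @return A `(2 * radius + 1)` square numeric matrix with attributes
#'   `sigma` and `radius`.  Weights sum to 1 within 1e-9.
#' @examples
#' k <- gaussian_kernel(1, 3)
#' sum(k)                      # 1
#' k[4, 5] / k[4, 4]           # exp(-0.5)
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort_validation("'sigma' must be a single positive number, got ", format(sigma))
  }
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius < 1 || radius != round(radius)) {
    abort_validation("'radius' must be a positive integer, got ", format(radius))
  }
  radius <- as.integer(radius)
  x <- -radius:radius
  w <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  w <- w / sum(w)
  attr(w, "sigma") <- sigma
  attr(w, "radius") <- radius
  w
}

kernel_radius <- function(kernel) {
  r <- attr(kernel, "radius")
  if (is.null(r)) r <- (nrow(kernel) - 1L) %/% 2L
  as.integer(r)
}

# Mirror (symmetric) padding: the r rows/cols nearest each border are
# reflected outward with the edge pixel repeated, e.g. c b a | a b c.
# Requires r <= min(H, W).
pad_reflect <- function(plane, r) {
  H <- nrow(plane)
  W <- ncol(plane)
  ri <- c(r:1, 1:H, H:(H - r + 1L))
  ci <- c(r:1, 1:W, W:(W - r + 1L))
  plane[ri, ci, drop = FALSE]
}

#' Convolve a plane with a kernel
#'
#' Same-shape 2-D convolution with mirror (reflect) boundary padding.  Mirror
#' padding avoids the artificial dark frame that zero padding would inject
#' into surround responses near image borders.  All kernels used by the model
#' are symmetric under 180-degree rotation, so convolution and correlation
#' coincide.
#'
#' @param plane Numeric matrix (finite values).
#' @param kernel Square numeric matrix of odd side, e.g. from
#'   [gaussian_kernel()].
#' @return Numeric matrix of the same shape as `plane`.
#' @export
convolve_plane <- function(plane, kernel) {
  if (!is.matrix(plane) || nrow(plane) < 1L || ncol(plane) < 1L) {
    abort_structural("'plane' must be a non-empty numeric matrix")
  }
  if (!all(is.finite(plane))) {
    abort_validation("'plane' contains non-finite values")
  }
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel) || nrow(kernel) %% 2L != 1L) {
    abort_validation("'kernel' must be a square matrix with odd side length")
  }
  r <- kernel_radius(kernel)
  if (nrow(kernel) > 2L * min(nrow(plane), ncol(plane)) + 1L) {
    abort_structural(
      "kernel side ", nrow(kernel), " exceeds 2 * min(H, W) + 1 = ",
      2L * min(nrow(plane), ncol(plane)) + 1L
    )
  }
  if (r == 0L) {
    return(plane * kernel[1L, 1L])
  }
  H <- nrow(plane)
  W <- ncol(plane)
  padded <- pad_reflect(plane, r)
  out <- matrix(0, H, W)
  for (di in -r:r) {
    rows <- (1L + r + di):(H + r + di)
    for (dj in -r:r) {
      w <- kernel[di + r + 1L, dj + r + 1L]
      out <- out + w * padded[rows, (1L + r + dj):(W + r + dj)]
    }
  }
  out
}

# Coerce to an H x W x 3 array in [0, 1]; grayscale matrices are replicated
# across the three planes, alpha channels are dropped with a warning.
as_rgb_image <- function(x) {
  if (is.matrix(x)) {
    x <- array(rep(x, 3L), dim = c(nrow(x), ncol(x), 3L))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort_structural("expected an H x W x 3 array or an H x W matrix")
  }
  if (dim(x)[3L] == 4L) {
    warning("dropping alpha channel", call. = FALSE)
    x <- x[, , 1:3, drop = FALSE]
  }
  if (dim(x)[3L] == 1L) {
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1L], dim(x)[2L], 3L))
  }
  if (dim(x)[3L] != 3L) {
    abort_structural("expected 1, 3 or 4 channels, got ", dim(x)[3L])
  }
  if (!all(is.finite(x))) abort_validation("image contains non-finite values")
  if (min(x) < 0 || max(x) > 1) {
    abort_validation("image values must lie in [0, 1]; range is [",
                     format(min(x)), ", ", format(max(x)), "]")
  }
  x
}

# Extract channel i as a matrix even for single-row/column images.
channel_plane <- function(img, i) {
  matrix(img[, , i], nrow = dim(img)[1L], ncol = dim(img)[2L])
}

#' Joint-maximum normalization
#'
#' Divides all three channels by the single maximum intensity taken across
#' the three channels, so the brightest value in the image becomes 1 while
#' the ratios between channels (the chromatic content) are preserved.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @return Array of the same shape with global maximum 1.
#' @export
normalize_joint_max <- function(img) {
  img <- as_rgb_image(img)
  m <- max(img)
  if (m <= 0) {
    abort_degenerate("all-zero image: joint-maximum normalization is undefined")
  }
  img / m
}

#' Read an image file
#'
#' Reads PNG, JPEG, TIFF or PPM/PGM raster files and returns an H x W x 3
#' array of floats in \[0, 1\].  Integer formats are scaled by their
#' full-scale value; grayscale images are replicated to three identical
#' planes; alpha channels are dropped with a warning.
#'
#' @param path Path to the image file; format is chosen by extension.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort_validation("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    abort_io("cannot read image: no such file '", path, "'")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    ppm  = ,
    pgm  = read_pnm(path),
    abort_io("unsupported image format '.", ext, "' for '", path, "'")
  )
  # readers already scale integer data to [0, 1]; float TIFFs may not be
  if (max(raw) > 1 || min(raw) < 0) {
    abort_io("pixel values in '", path, "' fall outside [0, 1] after scaling")
  }
  as_rgb_image(raw)
}

#' Write an image file
#'
#' Clips to \[0, 1\] and writes PNG, JPEG, TIFF or PPM.  PNG and PPM support
#' 16-bit output via `bits = 16`.
#'
#' @param img H x W x 3 array (or H x W matrix, written as grayscale RGB).
#' @param path Output path; format chosen by extension.
#' @param bits Bit depth, 8 (default) or 16.  16-bit output is honoured for
#'   TIFF and PPM; PNG and JPEG are always written at 8 bit.
#' @return Invisibly, `path`.
#' @export
save_image <- function(img, path, bits = 8L) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img <- pmin(pmax(img, 0), 1)
  if (!bits %in% c(8L, 16L)) abort_validation("'bits' must be 8 or 16")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path, dpi = NULL),
    jpg  = ,
    jpeg = jpeg::writeJPEG(img, path, quality = 0.95),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
    ppm  = write_ppm(img, path, bits = bits),
    abort_io("unsupported image format '.", ext, "' for '", path, "'")
  )
  invisible(path)
}

# Minimal PPM/PGM reader: ASCII P2/P3 and binary P5/P6, maxval up to 65535.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    abort_io("'", path, "' is not a supported PPM/PGM file (magic '", magic, "')")
  }
  # token reader that skips whitespace and '#' comments
  next_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (length(ch) == 0L) break
      c <- rawToChar(ch)
      if (c == "#") {
        repeat {
          ch <- readBin(con, "raw", 1L)
          if (length(ch) == 0L || rawToChar(ch) == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", c)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, c)
    }
    paste(tok, collapse = "")
  }
  W <- as.integer(next_token())
  H <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(W) || is.na(H) || is.na(maxval) || maxval <= 0L || maxval > 65535L) {
    abort_io("malformed PPM/PGM header in '", path, "'")
  }
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- W * H * nch
  vals <- if (magic %in% c("P2", "P3")) {
    txt <- rawToChar(readBin(con, "raw", file.info(path)$size))
    as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])[seq_len(n)]
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n))
  } else {
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  if (anyNA(vals) || length(vals) < n) {
    abort_io("truncated pixel data in '", path, "'")
  }
  # PNM stores row-major, channel-interleaved
  arr <- array(vals / maxval, dim = c(nch, W, H))
  aperm(arr, c(3L, 2L, 1L))[, , seq_len(nch), drop = (nch == 1L)]
}

write_ppm <- function(img, path, bits = 8L) {
  maxval <- if (bits == 16L) 65535L else 255L
  vals <- as.integer(round(aperm(img, c(3L, 2L, 1L)) * maxval))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n%d\n", ncol(img), nrow(img), maxval),
            con, eos = NULL)
  if (bits == 16L) {
    writeBin(vals, con, size = 2L, endian = "big")
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}
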