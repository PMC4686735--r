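#' Transmission map from disparity
#'
#' Nearer scene points (larger disparity) transmit more of the scene
#' radiance.  The synthesis protocol maps a normalized disparity plane to a
#' transmission map by a single scale: `t = scale * d`, with the default
#' scale 0.8.
#'
#' @param d H x W disparity matrix with values in \[0, 1\].
#' @param scale Scalar in (0, 1\] (default 0.8).
#' @return H x W transmission matrix in \[0, scale\].
#' @export
transmission_from_disparity <- function(d, scale = 0.8) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0 || scale > 1) {
    abort_validation("'scale' must lie in (0, 1], got ", format(scale))
  }
  if (!is.matrix(d) || min(d) < 0 || max(d) > 1) {
    abort_validation("'d' must be a matrix with values in [0, 1]")
  }
  scale * d
}

#' Koschmieder haze synthesis
#'
#' Applies the atmospheric scattering model per channel:
#' `I = J * t + A * (1 - t)`, where `J` is the haze-free scene, `t` the
#' per-pixel transmission and `A` the global airlight (pure white by
#' default).  With full transmission the scene is returned unchanged; with
#' zero transmission only the airlight remains.
#'
#' @param J H x W x 3 haze-free image in \[0, 1\].
#' @param t H x W transmission matrix in \[0, 1\].
#' @param A Airlight: per-channel triple in \[0, 1\] (default white).
#' @return H x W x 3 hazy image.
#' @export
synthesize_haze <- function(J, t, A = c(1, 1, 1)) {
  J <- as_rgb_image(J)
  if (!is.matrix(t) || !identical(dim(t), dim(J)[1:2])) {
    abort_structural("'t' must be an H x W matrix matching the image")
  }
  if (min(t) < 0 || max(t) > 1) abort_validation("'t' must lie in [0, 1]")
  if (length(A) != 3L || !all(is.finite(A)) || min(A) < 0 || max(A) > 1) {
    abort_validation("'A' must be a per-channel triple in [0, 1]")
  }
  out <- array(0, dim = dim(J))
  for (i in 1:3) out[, , i] <- J[, , i] * t + A[i] * (1 - t)
  out
}

#' Mean squared error between two images
#'
#' Mean over all pixels and channels of the squared difference.
#'
#' @param a,b Arrays (or matrices) of identical shape.
#' @return Single non-negative number.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort_structural("'a' and 'b' differ in shape")
  }
  mean((a - b)^2)
}

#' Synthetic haze-free scene with disparity map
#'
#' Generates a deterministic test scene: saturated coloured rectangles and
#' discs over a weakly textured mid-grey background, plus a disparity plane
#' that assigns each object a depth layer (nearer objects get larger
#' disparity and are painted on top).  The disparity plane is smoothed with
#' a small Gaussian so depth edges do not produce single-pixel haze
#' discontinuities.  Saturated hues are used so the single-opponent ganglion
#' channels are exercised.
#'
#' @param seed Integer seed; the same seed gives a bit-identical scene.
#' @param height,width Scene size in pixels (>= 32).
#' @param n_objects Number of foreground objects (>= 1, default 6).
#' @return List with elements `J` (H x W x 3 image in \[0, 1\]), `d`
#'   (H x W disparity matrix in \[0, 1\]) and `seed`.
#' @export
make_synthetic_scene <- function(seed, height = 128L, width = 128L,
                                 n_objects = 6L) {
  if (height < 32L || width < 32L) {
    abort_validation("scene dimensions must be at least 32 pixels")
  }
  if (n_objects < 1L) abort_validation("'n_objects' must be >= 1")
  with_rng_seed(seed, {
    # textured background: mid-grey with smoothed colour noise
    base <- runif(3, 0.25, 0.45)
    noise_kernel <- gaussian_kernel(1, 3)
    J <- array(0, dim = c(height, width, 3L))
    for (i in 1:3) {
      tex <- matrix(runif(height * width, -1, 1), height, width)
      J[, , i] <- base[i] + 0.08 * convolve_plane(tex, noise_kernel)
    }
    d <- matrix(0.2, height, width)

    # nearer objects (larger disparity) are drawn later, on top
    depths <- seq(0.45, 0.95, length.out = n_objects)
    rows <- matrix(rep(seq_len(height), width), height, width)
    cols <- matrix(rep(seq_len(width), each = height), height, width)
    for (i in seq_len(n_objects)) {
      hue <- runif(1)
      col <- as.vector(grDevices::col2rgb(grDevices::hsv(hue, 0.95,
                                                         runif(1, 0.75, 1)))) / 255
      cy <- runif(1, 0.15, 0.85) * height
      cx <- runif(1, 0.15, 0.85) * width
      half <- runif(1, 0.06, 0.16) * min(height, width)
      mask <- if (runif(1) < 0.5) {
        abs(rows - cy) <= half & abs(cols - cx) <= half
      } else {
        (rows - cy)^2 + (cols - cx)^2 <= half^2
      }
      for (ch in 1:3) {
        plane <- J[, , ch]
        plane[mask] <- col[ch]
        J[, , ch] <- plane
      }
      d[mask] <- depths[i]
    }
    d <- convolve_plane(d, gaussian_kernel(1.5, 4))
    J <- pmin(pmax(J, 0), 1)
    d <- pmin(pmax(d, 0), 1)
    list(J = J, d = d, seed = as.integer(seed))
  })
}
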