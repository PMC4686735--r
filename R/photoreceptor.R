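#' Rod luminance channel
#'
#' The rod photoreceptors sample the scene luminance, modelled as the
#' pointwise mean of the three cone channels:
#' \eqn{f_L = (f_R + f_G + f_B) / 3}.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @return H x W numeric matrix.
#' @export
rod_luminance <- function(img) {
  img <- as_rgb_image(img)
  (channel_plane(img, 1L) + channel_plane(img, 2L) + channel_plane(img, 3L)) / 3
}

#' Yellow (diffuse-bipolar) channel
#'
#' Diffuse bipolar cells pool neighbouring cones non-selectively; because L
#' and M cones outnumber S cones roughly twentyfold, their signal is
#' chromatically biased toward yellow.  The channel is modelled as
#' \eqn{f_Y = (f_R + f_G) / 2}, with the blue plane omitted.
#'
#' @inheritParams rod_luminance
#' @return H x W numeric matrix, independent of the blue plane.
#' @export
yellow_channel <- function(img) {
  img <- as_rgb_image(img)
  (channel_plane(img, 1L) + channel_plane(img, 2L)) / 2
}

#' OFF-pathway input
#'
#' OFF bipolar cells respond to light decrements; their drive is the
#' photometric complement \eqn{f' = 1 - f} of the ON input.  The map is an
#' involution: applying it twice returns the input.
#'
#' @param plane H x W numeric matrix with values in \[0, 1\].
#' @return H x W numeric matrix, `1 - plane`.
#' @export
off_input <- function(plane) {
  if (!is.matrix(plane) || !all(is.finite(plane))) {
    abort_structural("'plane' must be a finite numeric matrix")
  }
  if (min(plane) < 0 || max(plane) > 1) {
    abort_validation("OFF input requires values in [0, 1]; range is [",
                     format(min(plane)), ", ", format(max(plane)), "]")
  }
  1 - plane
}

#' Photoreceptor layer
#'
#' Splits a normalized image into the five retinal input channels: the three
#' cone planes R, G, B, the diffuse-bipolar yellow plane Y, and the rod
#' luminance plane L.  The rod pathway has no OFF branch, so [off_input()] is
#' applied downstream only to R, G, B and Y.
#'
#' @param img H x W x 3 array in \[0, 1\], typically the output of
#'   [normalize_joint_max()].
#' @return Named list of H x W matrices: `R`, `G`, `B`, `Y`, `L`.
#' @export
photoreceptor_layer <- function(img) {
  img <- as_rgb_image(img)
  list(
    R = channel_plane(img, 1L),
    G = channel_plane(img, 2L),
    B = channel_plane(img, 3L),
    Y = yellow_channel(img),
    L = rod_luminance(img)
  )
}
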