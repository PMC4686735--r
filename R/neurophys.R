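# In-silico electrophysiology: the two classical receptive-field protocols
# used to characterize the disinhibitory surround of the model ganglion
# cell.  Both protocols drive the ganglion stage directly with the stimulus
# channel planes (no bipolar or amacrine processing), so the measured curves
# isolate the subunit/surround mechanism.

#' Area-summation stimulus
#'
#' A growing bipartite stimulus for a red-ON/green-OFF single-opponent cell:
#' a red disc covering the receptive-field centre (up to `center_radius`), a
#' green annulus of equal luminance extending from the centre edge out to
#' `radius`, and darkness beyond.  Red pixels are (1, 0, 0) and green pixels
#' (0, 1, 0), so the two phases are equi-luminant.
#'
#' @param radius Outer stimulus radius in pixels (>= 0); radius 0 gives a
#'   blank (dark) patch.
#' @param patch_size Odd patch side in pixels; must contain the stimulus.
#' @param center_radius Radius of the red phase (default 3, the
#'   area-summation preset's centre radius).
#' @return `patch_size` x `patch_size` x 3 array in \[0, 1\].
#' @export
make_area_stimulus <- function(radius, patch_size = 41L, center_radius = 3L) {
  if (radius < 0) abort_validation("'radius' must be >= 0")
  if (patch_size %% 2L != 1L) abort_validation("'patch_size' must be odd")
  if (radius > (patch_size - 1L) / 2) {
    abort_structural("stimulus radius ", radius, " exceeds the patch (size ",
                     patch_size, ")")
  }
  c0 <- (patch_size + 1L) / 2
  ax <- seq_len(patch_size) - c0
  dist <- sqrt(outer(ax^2, ax^2, `+`))
  stim <- array(0, dim = c(patch_size, patch_size, 3L))
  if (radius > 0) {
    stim[, , 1L] <- (dist <= min(radius, center_radius)) * 1
    stim[, , 2L] <- (dist <= radius & dist > center_radius) * 1
  }
  stim
}

#' Area-summation parameter preset
#'
#' Receptive-field geometry of the area-summation protocol: centre,
#' surround and subunit radii of 3, 10 and 3 pixels, centre sensitivity 1
#' and surround sensitivity 3.
#'
#' @param A_u Subunit sensitivity.
#' @return A [ganglion_params()] object.
#' @export
area_response_params <- function(A_u) {
  ganglion_params(r_cen = 3, r_sur = 10, r_sub = 3, A_cen = 1, A_s = 3,
                  A_u = A_u)
}

# Centre-pixel response of a red-ON/green-OFF cell driven directly by the
# stimulus channels.  `rectify = FALSE` returns the net opponent drive
# (centre excitation minus surround inhibition) before the output
# nonlinearity.
opponent_center_response <- function(stim, params, rectify) {
  fR <- stim[, , 1L]
  fG <- stim[, , 2L]
  s_g <- surround_pool(subunit_response(fG, params), params)
  excite <- convolve_plane(fR, gaussian_kernel(params$sigma_cen, params$r_cen))
  drive <- excite - params$A_s * s_g
  if (rectify) drive <- pmax(drive, 0)
  c0 <- (nrow(fR) + 1L) / 2
  params$A_cen * drive[c0, c0]
}

#' Area-response curve
#'
#' Measures the centre-pixel response of the model ganglion cell as the
#' bipartite red/green stimulus grows.  With `A_u = 0` the response falls
#' monotonically once the stimulus exceeds the centre; with increasing
#' subunit sensitivity the curves are raised pointwise and, for sufficiently
#' strong mutual inhibition, show the classical secondary rise at large
#' stimulus sizes.
#'
#' By default the curve reports the net opponent drive before the output
#' rectification (`rectify = FALSE`): the rectified spiking output saturates
#' at zero under strong surround inhibition, which would hide the graded
#' recovery that the protocol is designed to expose.
#'
#' @param radii Non-decreasing vector of stimulus radii in pixels.
#' @param A_u Subunit sensitivity.
#' @param preset A [ganglion_params()] object; defaults to
#'   [area_response_params()] with the given `A_u`.
#' @param patch_size Odd patch side (default 41).
#' @param rectify Apply the output rectification (default `FALSE`).
#' @return Data frame with columns `radius` and `response`.
#' @export
area_response_curve <- function(radii, A_u,
                                preset = area_response_params(A_u),
                                patch_size = 41L, rectify = FALSE) {
  if (is.unsorted(radii)) abort_validation("'radii' must be non-decreasing")
  resp <- vapply(radii, function(r) {
    stim <- make_area_stimulus(r, patch_size, preset$r_cen)
    opponent_center_response(stim, preset, rectify)
  }, numeric(1))
  data.frame(radius = radii, response = resp)
}

# The four flux sites of the dispersion protocol: the border midpoints of
# the 5 x 5 patch, all at distance 2 from the centre so that with A_u = 0
# every configuration exerts identical surround inhibition.  The activation
# order (up, right, down, left) makes every added site interact with an
# already active one through the subunit kernel.
dispersion_sites <- function() {
  list(c(-2L, 0L), c(0L, 2L), c(2L, 0L), c(0L, -2L))
}

#' Dispersion stimulus
#'
#' A 5 x 5 patch holding a 3 x 3 red block that covers the full
#' receptive-field centre, plus a white foreground of fixed total flux
#' distributed over 1 to 4 equidistant sites in the surround.  The
#' dispersive angle selects how many sites share the flux:
#' `n = 1 + floor(3 * angle / 180)` (1 site at 0 degrees, all 4 at 180
#' degrees), each receiving `total_flux / n` in every colour channel.  The
#' summed foreground intensity is therefore identical across angles, so any
#' response difference is attributable to spatial redistribution alone.
#'
#' @param angle Dispersive angle in degrees, in \[0, 180\].
#' @param total_flux Total white flux (default 1); the per-site value
#'   `total_flux / n` must not exceed 1.
#' @return 5 x 5 x 3 array in \[0, 1\].
#' @export
make_dispersion_stimulus <- function(angle, total_flux = 1) {
  if (angle < 0 || angle > 180) {
    abort_validation("'angle' must lie in [0, 180] degrees")
  }
  n <- 1L + min(3L, floor(3 * angle / 180))
  v <- total_flux / n
  if (v > 1 || total_flux <= 0) {
    abort_validation("per-site flux ", format(v),
                     " is not representable in [0, 1] pixels")
  }
  stim <- array(0, dim = c(5L, 5L, 3L))
  stim[2:4, 2:4, 1L] <- 1  # red block covering the RF centre
  for (s in dispersion_sites()[seq_len(n)]) {
    stim[s[1L] + 3L, s[2L] + 3L, ] <- v
  }
  stim
}

#' Dispersion parameter preset
#'
#' Receptive-field geometry of the dispersion protocol: centre radius 1
#' (a 3 x 3 centre fully covered by the red block), surround radius 3, and
#' subunit interaction radius 3 so that the mutual inhibition among
#' surround subunits spans the surround.  The subunit sensitivity is tied
#' to the surround sensitivity, `A_u = 0.5 * A_s`.
#'
#' @param A_s Surround sensitivity.
#' @param with_disinhibition If `FALSE`, the subunit mutual inhibition is
#'   switched off (`A_u = 0`).
#' @return A [ganglion_params()] object.
#' @export
dispersion_params <- function(A_s, with_disinhibition = TRUE) {
  ganglion_params(r_cen = 1, r_sur = 3, r_sub = 3, A_cen = 1, A_s = A_s,
                  A_u = if (with_disinhibition) 0.5 * A_s else 0)
}

#' Dispersion-response curve
#'
#' Measures the red-channel centre response while a fixed total white flux
#' is spread over an increasing number of equidistant surround sites.
#' Without subunit disinhibition (`with_disinhibition = FALSE`) the curve is
#' constant: every configuration delivers the same Gaussian-weighted flux to
#' the surround pool.  With disinhibition the mutual inhibition among
#' co-active subunits grows with their number, so the surround inhibition
#' weakens and the response increases with the dispersive angle.
#'
#' @param angles Increasing vector of dispersive angles in degrees.
#' @param A_s Surround sensitivity (the protocol fixes `A_u = 0.5 * A_s`).
#' @param with_disinhibition Include the subunit mutual inhibition
#'   (default `TRUE`).
#' @param total_flux Total white foreground flux (default 1).
#' @param rectify Apply the output rectification (default `TRUE`; the
#'   responses of this protocol are positive either way).
#' @return Data frame with columns `angle`, `n_sites` and `response`.
#' @export
dispersion_response_curve <- function(angles, A_s, with_disinhibition = TRUE,
                                      total_flux = 1, rectify = TRUE) {
  if (is.unsorted(angles, strictly = FALSE)) {
    abort_validation("'angles' must be increasing")
  }
  params <- dispersion_params(A_s, with_disinhibition)
  resp <- vapply(angles, function(a) {
    stim <- make_dispersion_stimulus(a, total_flux)
    opponent_center_response(stim, params, rectify)
  }, numeric(1))
  data.frame(
    angle = angles,
    n_sites = 1L + pmin(3L, floor(3 * angles / 180)),
    response = resp
  )
}
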