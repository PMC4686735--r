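#' Bipolar receptive-field parameters
#'
#' The bipolar receptive field is a difference of Gaussians (DOG): a narrow
#' excitatory centre minus a broader inhibitory annular surround scaled by
#' the surround sensitivity `k`.  Because both Gaussians are normalized, a
#' spatially constant input of value `c` elicits the response `c * (1 - k)`:
#' raising `k` suppresses the zero-frequency content of the image, which is
#' where a dispersed haze veil lives.
#'
#' @param sigma_cen Centre standard deviation in pixels (default 0.5).
#' @param sigma_sur Surround standard deviation in pixels (default 1.0);
#'   must exceed `sigma_cen`.
#' @param k Surround sensitivity in \[0, 1\] (default 0.3).
#' @return An object of class `bipolar_params`.
#' @export
bipolar_params <- function(sigma_cen = 0.5, sigma_sur = 1.0, k = 0.3) {
  for (nm in c("sigma_cen", "sigma_sur", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort_validation("'", nm, "' must be a single finite number")
    }
  }
  if (sigma_cen <= 0) abort_validation("'sigma_cen' must be > 0")
  if (sigma_sur <= sigma_cen) {
    abort_validation("'sigma_sur' (", sigma_sur, ") must exceed 'sigma_cen' (",
                     sigma_cen, ")")
  }
  if (k < 0 || k > 1) abort_validation("'k' must lie in [0, 1], got ", k)
  structure(
    list(sigma_cen = sigma_cen, sigma_sur = sigma_sur, k = k),
    class = "bipolar_params"
  )
}

#' @export
print.bipolar_params <- function(x, ...) {
  cat(sprintf("Bipolar DOG: sigma_cen = %g px, sigma_sur = %g px, k = %g\n",
              x$sigma_cen, x$sigma_sur, x$k))
  invisible(x)
}

#' Difference-of-Gaussians filtering
#'
#' Applies the bipolar receptive field to a single plane:
#' `plane (*) g(sigma_cen) - k * (plane (*) g(sigma_sur))`, where `(*)` is
#' convolution with mirror padding.  The result may contain negative values;
#' rectification is a separate step performed by [bipolar_layer()].
#'
#' @param plane H x W numeric matrix.
#' @param params A [bipolar_params()] object.
#' @return H x W numeric matrix.
#' @export
dog_filter <- function(plane, params = bipolar_params()) {
  stopifnot(inherits(params, "bipolar_params"))
  centre <- convolve_plane(plane, gaussian_kernel(params$sigma_cen))
  if (params$k == 0) {
    return(centre)
  }
  surround <- convolve_plane(plane, gaussian_kernel(params$sigma_sur))
  centre - params$k * surround
}

#' ON/OFF bipolar layer
#'
#' Runs the DOG receptive field over every photoreceptor channel for the ON
#' pathway (R, G, B, Y, L) and over the complement inputs for the OFF pathway
#' (R, G, B, Y; the rod pathway has only ON bipolars).  Responses are
#' rectified (negative values set to zero) and then normalized per polarity:
#' the three cone planes of a polarity are divided by their joint maximum,
#' and the Y and L planes of that polarity by the same joint maximum so the
#' relative scales between channels are preserved.
#'
#' A polarity whose cone responses are identically zero (e.g. the OFF
#' pathway of a uniform full-brightness image) is passed through as zeros;
#' only when both polarities are void is the input reported as degenerate.
#'
#' @param pr Output of [photoreceptor_layer()].
#' @param params A [bipolar_params()] object.
#' @return List with elements `on` (planes R, G, B, Y, L) and `off`
#'   (planes R, G, B, Y); all planes are in \[0, 1\].
#' @export
bipolar_layer <- function(pr, params = bipolar_params()) {
  stopifnot(is.list(pr), all(c("R", "G", "B", "Y", "L") %in% names(pr)))
  on <- lapply(pr[c("R", "G", "B", "Y", "L")], function(p) {
    pmax(dog_filter(p, params), 0)
  })
  off <- lapply(pr[c("R", "G", "B", "Y")], function(p) {
    pmax(dog_filter(off_input(p), params), 0)
  })
  # responses at rounding-noise level (e.g. the k = 1 DOG of a constant)
  # count as zero rather than becoming a normalization divisor
  eps <- 1e-12
  on_max <- max(on$R, on$G, on$B)
  off_max <- max(off$R, off$G, off$B)
  if (on_max <= eps && off_max <= eps) {
    abort_degenerate("both bipolar polarities are all zero")
  }
  list(
    on = if (on_max > eps) lapply(on, function(p) p / on_max) else lapply(on, function(p) p * 0),
    off = if (off_max > eps) lapply(off, function(p) p / off_max) else lapply(off, function(p) p * 0)
  )
}
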