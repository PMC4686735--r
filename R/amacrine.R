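#' Amacrine modulation parameters
#'
#' The AII amacrine cells route the rod-bipolar luminance signal onto the
#' cone bipolars.  `epsilon` offsets the modulator `epsilon + BP_L` so the
#' divisive branch never divides by zero and both gains stay near unity when
#' the luminance response is mid-range.
#'
#' @param epsilon Positive offset (default 0.5).
#' @return An object of class `amacrine_params`.
#' @export
amacrine_params <- function(epsilon = 0.5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    abort_validation("'epsilon' must be a single positive number")
  }
  structure(list(epsilon = epsilon), class = "amacrine_params")
}

#' @export
print.amacrine_params <- function(x, ...) {
  cat(sprintf("Amacrine modulation: epsilon = %g\n", x$epsilon))
  invisible(x)
}

#' AII amacrine modulation of cone bipolars
#'
#' The rod-driven luminance response multiplicatively excites the ON cone
#' bipolars (via gap junctions) and divisively inhibits the OFF cone
#' bipolars (via inhibitory synapses):
#' `MBP_c = BP_c * (epsilon + BP_L)` and
#' `MBP'_c = BP'_c / (epsilon + BP_L)` for c in R, G, B, Y.
#' ON responses are thus amplified in bright regions and OFF responses in
#' dark regions; the two gains are exact reciprocals, so
#' `MBP_c * MBP'_c == BP_c * BP'_c` pointwise.
#'
#' @param bp Output of [bipolar_layer()] (must contain the rod plane
#'   `bp$on$L`).
#' @param params An [amacrine_params()] object.
#' @return List with elements `on` and `off`, each holding planes R, G, B, Y,
#'   plus `modulator`, the plane `epsilon + BP_L`.
#' @export
amacrine_modulate <- function(bp, params = amacrine_params()) {
  stopifnot(inherits(params, "amacrine_params"))
  if (is.null(bp$on$L)) {
    abort_structural("rod-bipolar plane 'bp$on$L' is required for modulation")
  }
  m <- params$epsilon + bp$on$L
  chans <- c("R", "G", "B", "Y")
  list(
    on = lapply(bp$on[chans], function(p) p * m),
    off = lapply(bp$off[chans], function(p) p / m),
    modulator = m
  )
}
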