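#' Pipeline configuration
#'
#' Bundles the parameters of every retinal stage.  The defaults are the
#' dehazing operating point: bipolar surround sensitivity `k = 0.3`,
#' amacrine offset `epsilon = 0.5`, ganglion radii (1, 3, 1) with
#' `A_cen = A_s = 2`, and subunit sensitivity 0.7 for the ON pathway and 0.5
#' for the OFF pathway.
#'
#' @param bipolar A [bipolar_params()] object.
#' @param amacrine An [amacrine_params()] object.
#' @param ganglion_on,ganglion_off [ganglion_params()] for the two
#'   polarities.
#' @param output_mode `"rescale"` (the default) affinely maps each output
#'   channel's range onto \[0, 1\]; `"clip"` clamps the raw fused mixture to
#'   \[0, 1\].  Rescaling is needed because the un-normalized ganglion
#'   magnitudes scale with `A_cen`, so the raw mixture has an arbitrary
#'   offset and gain per channel.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bipolar = bipolar_params(),
                            amacrine = amacrine_params(),
                            ganglion_on = ganglion_params(A_u = 0.7),
                            ganglion_off = ganglion_params(A_u = 0.5),
                            output_mode = c("rescale", "clip")) {
  stopifnot(
    inherits(bipolar, "bipolar_params"),
    inherits(amacrine, "amacrine_params"),
    inherits(ganglion_on, "ganglion_params"),
    inherits(ganglion_off, "ganglion_params")
  )
  output_mode <- match.arg(output_mode)
  structure(
    list(
      bipolar = bipolar, amacrine = amacrine,
      ganglion_on = ganglion_on, ganglion_off = ganglion_off,
      output_mode = output_mode
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Retinal dehazing pipeline\n")
  print(x$bipolar)
  print(x$amacrine)
  cat("ON  "); print(x$ganglion_on)
  cat("OFF "); print(x$ganglion_off)
  cat("Output mode:", x$output_mode, "\n")
  invisible(x)
}

#' Pathway output (diagnostic luminance)
#'
#' Channel-mean of the three single-opponent ganglion planes of one
#' polarity: `(GC_R + GC_G + GC_B) / 3`.  This is the scalar retinal output
#' of one pathway; the colour pipeline fuses the channels individually (see
#' [dehaze()]).
#'
#' @param gc Named list with planes `R`, `G`, `B`.
#' @return H x W numeric matrix.
#' @export
pathway_output <- function(gc) {
  missing <- setdiff(c("R", "G", "B"), names(gc))
  if (length(missing)) {
    abort_structural("missing channel(s): ", paste(missing, collapse = ", "))
  }
  (gc$R + gc$G + gc$B) / 3
}

#' Luminance-weighted ON/OFF fusion
#'
#' Combines the two pathway outputs with a pointwise weight:
#' `Out = w * Out_ON + (1 - w) * (1 - Out_OFF)`.  The OFF output is
#' complemented back into ON polarity before mixing.  With `w = f_L` of the
#' input, bright regions are dominated by the ON pathway and dark regions by
#' the OFF pathway.
#'
#' @param out_on,out_off H x W numeric matrices.
#' @param w H x W weight matrix with values in \[0, 1\].
#' @return H x W numeric matrix.
#' @export
fuse_pathways <- function(out_on, out_off, w) {
  if (!identical(dim(out_on), dim(out_off)) || !identical(dim(out_on), dim(w))) {
    abort_structural("'out_on', 'out_off' and 'w' must share one shape")
  }
  if (min(w) < 0 || max(w) > 1) {
    abort_validation("fusion weight must lie in [0, 1]")
  }
  w * out_on + (1 - w) * (1 - out_off)
}

#' Retina-inspired single-image dehazing
#'
#' Runs the full retinal pipeline on a colour image: joint-maximum
#' normalization, photoreceptor sampling, ON/OFF bipolar DOG filtering with
#' rectification, AII amacrine modulation, single-opponent ganglion cells
#' with disinhibitory surrounds for both polarities, and luminance-weighted
#' fusion.  Fusion is applied channel-wise,
#' `Out_c = w * GC_c + (1 - w) * (1 - GC'_c)` with `w = f_L` of the
#' normalized input, so the result is a full-colour image.
#'
#' The ganglion planes enter the fusion un-normalized, so the raw mixture
#' carries an arbitrary per-channel gain and offset (it scales with
#' `A_cen`); the default output mode therefore maps each fused channel
#' affinely onto \[0, 1\] (see [pipeline_config()]).
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param config A [pipeline_config()] object.
#' @param intermediates If `TRUE`, attach the per-stage planes as attribute
#'   `"stages"` on the returned image (photoreceptor, bipolar, amacrine,
#'   ganglion outputs and the fusion weight).
#' @return H x W x 3 array in \[0, 1\].
#' @export
dehaze <- function(img, config = pipeline_config(), intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  img <- normalize_joint_max(img)
  pr <- photoreceptor_layer(img)
  bp <- bipolar_layer(pr, config$bipolar)
  mbp <- amacrine_modulate(bp, config$amacrine)
  gc <- ganglion_layer(mbp, config$ganglion_on, config$ganglion_off)
  w <- pr$L
  out <- array(0, dim = dim(img))
  for (i in seq_along(opponent_map())) {
    ch <- names(opponent_map())[i]
    out[, , i] <- fuse_pathways(gc$on[[ch]], gc$off[[ch]], w)
  }
  if (config$output_mode == "rescale") {
    for (i in 1:3) {
      rng <- range(out[, , i])
      out[, , i] <- if (rng[2] > rng[1]) {
        (out[, , i] - rng[1]) / (rng[2] - rng[1])
      } else {
        pmin(pmax(out[, , i], 0), 1)
      }
    }
  } else {
    out <- pmin(pmax(out, 0), 1)
  }
  if (intermediates) {
    attr(out, "stages") <- list(
      input = img, photoreceptor = pr, bipolar = bp, amacrine = mbp,
      ganglion = gc, weight = w,
      out_on = pathway_output(gc$on), out_off = pathway_output(gc$off)
    )
  }
  out
}
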