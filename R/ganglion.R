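#' Ganglion receptive-field parameters
#'
#' The ganglion receptive field has a small excitatory centre, an extensive
#' inhibitory surround (the non-classical receptive field), and the surround
#' is built from subunits that first inhibit one another (disinhibition)
#' before inhibiting the centre.  Each region is Gaussian with standard
#' deviation set to one third of its radius.
#'
#' @param r_cen Centre radius in pixels (default 1).
#' @param r_sur Surround radius in pixels (default 3); must exceed `r_cen`.
#' @param r_sub Subunit interaction radius in pixels (default 1).
#' @param A_cen Centre sensitivity (> 0, default 2).
#' @param A_s Surround sensitivity (>= 0, default 2).
#' @param A_u Subunit sensitivity (>= 0): the strength of the mutual
#'   inhibition among surround subunits, hence of the disinhibition of the
#'   centre.  Default 0.7 (the ON-pathway pipeline value).
#' @return An object of class `ganglion_params` with derived sigmas
#'   `sigma_cen`, `sigma_sur`, `sigma_sub` equal to the radii divided by 3.
#' @export
ganglion_params <- function(r_cen = 1, r_sur = 3, r_sub = 1,
                            A_cen = 2, A_s = 2, A_u = 0.7) {
  for (nm in c("r_cen", "r_sur", "r_sub", "A_cen", "A_s", "A_u")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort_validation("'", nm, "' must be a single finite number")
    }
  }
  if (r_cen < 1 || r_cen != round(r_cen)) abort_validation("'r_cen' must be an integer >= 1")
  if (r_sub < 1 || r_sub != round(r_sub)) abort_validation("'r_sub' must be an integer >= 1")
  if (r_sur <= r_cen || r_sur != round(r_sur)) {
    abort_validation("'r_sur' must be an integer > 'r_cen'")
  }
  if (A_cen <= 0) abort_validation("'A_cen' must be > 0")
  if (A_s < 0) abort_validation("'A_s' must be >= 0")
  if (A_u < 0) abort_validation("'A_u' must be >= 0")
  structure(
    list(
      r_cen = as.integer(r_cen), r_sur = as.integer(r_sur),
      r_sub = as.integer(r_sub),
      sigma_cen = r_cen / 3, sigma_sur = r_sur / 3, sigma_sub = r_sub / 3,
      A_cen = A_cen, A_s = A_s, A_u = A_u
    ),
    class = "ganglion_params"
  )
}

#' @export
print.ganglion_params <- function(x, ...) {
  cat(sprintf(
    "Ganglion RF: radii (cen, sur, sub) = (%d, %d, %d) px; A_cen = %g, A_s = %g, A_u = %g\n",
    x$r_cen, x$r_sur, x$r_sub, x$A_cen, x$A_s, x$A_u
  ))
  invisible(x)
}

#' Subunit mutual inhibition
#'
#' Each surround subunit is inhibited by its neighbours before it inhibits
#' the centre: `U = max(0, MBP - A_u * (MBP (*) g(sigma_sub)))`, with the
#' rectification applied pointwise before any pooling.  With `A_u = 0` the
#' input passes through unchanged; a constant plane with `A_u = 1` is fully
#' self-inhibited to zero.
#'
#' @param mbp H x W numeric matrix, >= 0 (a modulated bipolar plane).
#' @param params A [ganglion_params()] object.
#' @return H x W numeric matrix, >= 0.
#' @export
subunit_response <- function(mbp, params = ganglion_params()) {
  stopifnot(inherits(params, "ganglion_params"))
  if (params$A_u == 0) {
    return(mbp)
  }
  inhib <- convolve_plane(mbp, gaussian_kernel(params$sigma_sub, params$r_sub))
  pmax(mbp - params$A_u * inhib, 0)
}

#' Surround pooling
#'
#' Pools the inhibited subunit responses over the receptive-field surround:
#' `S = U (*) g(sigma_sur)`.
#'
#' @param u H x W numeric matrix, >= 0 (subunit responses).
#' @inheritParams subunit_response
#' @return H x W numeric matrix, >= 0.
#' @export
surround_pool <- function(u, params = ganglion_params()) {
  stopifnot(inherits(params, "ganglion_params"))
  convolve_plane(u, gaussian_kernel(params$sigma_sur, params$r_sur))
}

#' Single-opponent centre-surround subtraction
#'
#' The ganglion response is the centre excitation in one channel minus the
#' pooled surround inhibition from its opponent channel, rectified:
#' `GC = A_cen * max(0, centre (*) g(sigma_cen) - A_s * opponent_surround)`.
#'
#' @param centre H x W numeric matrix, >= 0 (the centre channel).
#' @param opponent_surround H x W numeric matrix, >= 0 (pooled subunit
#'   responses of the opponent channel, from [surround_pool()]).
#' @inheritParams subunit_response
#' @return H x W numeric matrix, >= 0.
#' @export
ganglion_opponent <- function(centre, opponent_surround,
                              params = ganglion_params()) {
  stopifnot(inherits(params, "ganglion_params"))
  if (!identical(dim(centre), dim(opponent_surround))) {
    abort_structural("centre and opponent surround planes differ in shape")
  }
  excite <- convolve_plane(centre, gaussian_kernel(params$sigma_cen, params$r_cen))
  params$A_cen * pmax(excite - params$A_s * opponent_surround, 0)
}

#' Single-opponent channel wiring
#'
#' The three single-opponent channels pair each centre channel with the
#' opponent channel feeding its surround: red-centre/green-surround,
#' green-centre/red-surround and blue-centre/yellow-surround.  Yellow only
#' ever serves as a surround and produces no output channel of its own.
#'
#' @return Named character vector mapping centre channel to surround channel.
#' @export
opponent_map <- function() {
  c(R = "G", G = "R", B = "Y")
}

#' Ganglion layer (both polarities)
#'
#' Computes the three single-opponent ganglion channels for the ON pathway
#' from the modulated ON bipolar planes, and identically for the OFF pathway
#' from the modulated OFF planes (the OFF ganglion uses OFF planes for both
#' its centre and its opponent surround).
#'
#' @param mbp Output of [amacrine_modulate()]: lists `on` and `off` with
#'   planes R, G, B, Y.
#' @param params_on,params_off [ganglion_params()] for the two polarities;
#'   the pipeline defaults differ only in `A_u` (0.7 ON, 0.5 OFF).
#' @param opp Opponent wiring, by default [opponent_map()].
#' @return List with elements `on` and `off`, each holding planes R, G, B.
#' @export
ganglion_layer <- function(mbp,
                           params_on = ganglion_params(A_u = 0.7),
                           params_off = ganglion_params(A_u = 0.5),
                           opp = opponent_map()) {
  one_polarity <- function(planes, params) {
    needed <- union(names(opp), unname(opp))
    missing <- setdiff(needed, names(planes))
    if (length(missing)) {
      abort_structural("missing channel(s): ", paste(missing, collapse = ", "))
    }
    pooled <- lapply(planes[unique(unname(opp))], function(p) {
      surround_pool(subunit_response(p, params), params)
    })
    out <- lapply(names(opp), function(ch) {
      ganglion_opponent(planes[[ch]], pooled[[opp[[ch]]]], params)
    })
    names(out) <- names(opp)
    out
  }
  list(
    on = one_polarity(mbp$on, params_on),
    off = one_polarity(mbp$off, params_off)
  )
}
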