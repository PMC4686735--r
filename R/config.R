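# Flat dotted-key configuration schema mirroring pipeline_config().

config_schema <- function() {
  c(
    "bipolar.sigma_cen", "bipolar.sigma_sur", "bipolar.k",
    "amacrine.epsilon",
    "ganglion.r_cen", "ganglion.r_sur", "ganglion.r_sub",
    "ganglion.A_cen", "ganglion.A_s", "ganglion.A_u_on", "ganglion.A_u_off",
    "output_mode"
  )
}

config_defaults <- function() {
  list(
    bipolar.sigma_cen = 0.5, bipolar.sigma_sur = 1.0, bipolar.k = 0.3,
    amacrine.epsilon = 0.5,
    ganglion.r_cen = 1, ganglion.r_sur = 3, ganglion.r_sub = 1,
    ganglion.A_cen = 2, ganglion.A_s = 2,
    ganglion.A_u_on = 0.7, ganglion.A_u_off = 0.5,
    output_mode = "rescale"
  )
}

# Flatten nested YAML lists into dotted keys: list(bipolar = list(k = .3))
# becomes "bipolar.k".  Already-flat dotted keys pass through.
flatten_keys <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_keys(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

#' Parse a pipeline configuration
#'
#' Builds a [pipeline_config()] from an optional YAML file and a list of
#' overrides (e.g. command-line flags), with overrides taking precedence
#' over the file and the file over the defaults.  The YAML may be nested
#' (`bipolar: {k: 0.3}`) or flat (`bipolar.k: 0.3`).  Unknown keys are
#' rejected with the list of valid keys; invariant violations (such as a
#' centre sigma at least as large as the surround sigma) are reported by
#' the stage constructors.
#'
#' @param path Optional path to a YAML configuration file.
#' @param overrides Named list of dotted-key overrides.
#' @return A [pipeline_config()] object.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  vals <- config_defaults()
  apply_layer <- function(vals, layer, origin) {
    layer <- flatten_keys(layer)
    unknown <- setdiff(names(layer), config_schema())
    if (length(unknown)) {
      abort_validation(
        "unknown configuration key(s) in ", origin, ": ",
        paste(unknown, collapse = ", "),
        "; valid keys are: ", paste(config_schema(), collapse = ", ")
      )
    }
    vals[names(layer)] <- layer
    vals
  }
  if (!is.null(path)) {
    if (!file.exists(path)) abort_io("configuration file '", path, "' not found")
    file_vals <- yaml::read_yaml(path)
    if (!is.list(file_vals)) abort_validation("'", path, "' is not a key-value YAML file")
    vals <- apply_layer(vals, file_vals, paste0("'", path, "'"))
  }
  if (length(overrides)) {
    vals <- apply_layer(vals, overrides, "overrides")
  }
  pipeline_config(
    bipolar = bipolar_params(
      sigma_cen = vals$bipolar.sigma_cen,
      sigma_sur = vals$bipolar.sigma_sur,
      k = vals$bipolar.k
    ),
    amacrine = amacrine_params(epsilon = vals$amacrine.epsilon),
    ganglion_on = ganglion_params(
      r_cen = vals$ganglion.r_cen, r_sur = vals$ganglion.r_sur,
      r_sub = vals$ganglion.r_sub, A_cen = vals$ganglion.A_cen,
      A_s = vals$ganglion.A_s, A_u = vals$ganglion.A_u_on
    ),
    ganglion_off = ganglion_params(
      r_cen = vals$ganglion.r_cen, r_sur = vals$ganglion.r_sur,
      r_sub = vals$ganglion.r_sub, A_cen = vals$ganglion.A_cen,
      A_s = vals$ganglion.A_s, A_u = vals$ganglion.A_u_off
    ),
    output_mode = vals$output_mode
  )
}

#' Serialize a pipeline configuration
#'
#' Writes the flat dotted-key representation of a configuration as YAML.
#' `parse_config(serialize_config(cfg))` reproduces `cfg`.
#'
#' @param config A [pipeline_config()] object.
#' @param path Optional output path; if `NULL` the YAML text is returned.
#' @return The YAML text (invisibly if written to `path`).
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- config_as_list(config)
  txt <- yaml::as.yaml(vals)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

config_as_list <- function(config) {
  list(
    bipolar.sigma_cen = config$bipolar$sigma_cen,
    bipolar.sigma_sur = config$bipolar$sigma_sur,
    bipolar.k = config$bipolar$k,
    amacrine.epsilon = config$amacrine$epsilon,
    ganglion.r_cen = config$ganglion_on$r_cen,
    ganglion.r_sur = config$ganglion_on$r_sur,
    ganglion.r_sub = config$ganglion_on$r_sub,
    ganglion.A_cen = config$ganglion_on$A_cen,
    ganglion.A_s = config$ganglion_on$A_s,
    ganglion.A_u_on = config$ganglion_on$A_u,
    ganglion.A_u_off = config$ganglion_off$A_u,
    output_mode = config$output_mode
  )
}
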