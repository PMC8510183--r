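#' Run a simulation from a YAML configuration
#'
#' The YAML file may set any [design_spec()] field (under `design:`),
#' effect-model scalars (`taxon_effect_sd`, `nb_dispersion`,
#' `library_size_lognormal_sd` under `effect_model:`), and a `seed`.
#' Unknown keys are rejected. The parsed configuration is echoed back
#' into the output directory alongside the tables when `outdir` is given.
#'
#' @param path YAML config file.
#' @param seed overrides the config's seed when non-NULL.
#' @param outdir optional output directory for TSV tables + config echo.
#' @return the generated dataset bundle, invisibly when writing.
#' @export
simulate_from_config <- function(path, seed = NULL, outdir = NULL) {
  cfg <- yaml::read_yaml(path) %||% list()
  allowed <- c("design", "effect_model", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  des <- do.call(design_spec, cfg$design %||% list())
  em_args <- cfg$effect_model %||% list()
  bad_em <- setdiff(names(em_args),
                    c("taxon_effect_sd", "nb_dispersion",
                      "library_size_lognormal_sd"))
  if (length(bad_em)) stop("unknown effect_model key(s): ",
                           paste(bad_em, collapse = ", "), call. = FALSE)
  em <- do.call(effect_model, em_args)
  seed <- seed %||% cfg$seed %||% 1L
  ds <- generate_dataset(des, em, mock_spec(), seed = seed)
  if (!is.null(outdir)) {
    write_dataset(ds, outdir)
    yaml::write_yaml(c(cfg, list(seed = seed)),
                     file.path(outdir, "config_echo.yaml"))
    return(invisible(ds))
  }
  ds
}
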