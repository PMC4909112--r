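# Configuration files (YAML), result tables (TSV) and run manifests.

#' Load a run configuration
#'
#' Reads a YAML override file and merges it onto [default_parameters()].
#' Only keys already present in the default set may appear; unknown or
#' structurally mismatched keys are rejected by name. An empty file (or
#' `path = NULL`) returns the exact defaults. Every applied override is
#' reported via `message()`.
#'
#' @param path Path to a YAML file of overrides, or NULL.
#' @param quiet Suppress override messages.
#' @return Parameter list as from [default_parameters()].
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  params <- default_parameters()
  if (is.null(path)) return(params)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ov <- yaml::read_yaml(path)
  if (is.null(ov) || length(ov) == 0) return(params)
  merge_block <- function(base, over, prefix) {
    for (k in names(over)) {
      key <- paste0(prefix, k)
      if (!k %in% names(base)) {
        stop("validation error: unknown config key '", key, "'", call. = FALSE)
      }
      if (is.list(base[[k]]) && !is.data.frame(base[[k]])) {
        if (!is.list(over[[k]])) {
          stop("validation error: key '", key, "' must be a block", call. = FALSE)
        }
        base[[k]] <- merge_block(base[[k]], over[[k]], paste0(key, "."))
      } else {
        if (!is.numeric(over[[k]]) && !is.character(over[[k]]) &&
            !is.logical(over[[k]])) {
          stop("validation error: key '", key, "' has an unusable value",
               call. = FALSE)
        }
        if (is.numeric(base[[k]]) && !is.numeric(over[[k]])) {
          stop("validation error: key '", key, "' must be numeric (",
               "got '", over[[k]], "')", call. = FALSE)
        }
        if (!quiet) message("config override: ", key, " = ",
                            paste(over[[k]], collapse = ","))
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  # compartments is tabular: allow overriding columns by compartment name
  if (!is.null(ov$compartments)) {
    cmp <- params$compartments
    for (nm in names(ov$compartments)) {
      if (!nm %in% cmp$name) {
        stop("validation error: unknown compartment '", nm, "'", call. = FALSE)
      }
      for (col in names(ov$compartments[[nm]])) {
        if (!col %in% setdiff(names(cmp), "name")) {
          stop("validation error: unknown compartment field '", col, "'",
               call. = FALSE)
        }
        if (!quiet) message("config override: compartments.", nm, ".", col,
                            " = ", ov$compartments[[nm]][[col]])
        cmp[cmp$name == nm, col] <- ov$compartments[[nm]][[col]]
      }
    }
    params$compartments <- cmp
    ov$compartments <- NULL
  }
  merge_block(params, ov, "")
}

#' Save a configuration
#'
#' Writes the full parameter set to YAML. `load_config(save_config(p))`
#' round-trips the numeric content identically.
#'
#' @param params Parameter list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  p <- params
  cmp <- p$compartments
  p$compartments <- stats::setNames(lapply(seq_len(nrow(cmp)), function(i) {
    as.list(cmp[i, setdiff(names(cmp), "name")])
  }), cmp$name)
  yaml::write_yaml(p, path, precision = 15)
  invisible(path)
}

#' Write a simulation result as a delimited table
#'
#' Tab-separated wide table, first column `time` (min), fixed column order
#' as produced by [run_scenario()]; byte-identical output for identical
#' results.
#'
#' @param result A `splanchsim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  utils::write.table(format(result$series, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the scenario, every effective parameter and the solver settings
#' as JSON, so any run is reproducible from its manifest alone.
#'
#' @param result A `splanchsim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  scn <- result$scenario
  manifest <- list(
    package = "splanchsim",
    version = as.character(utils::packageVersion("splanchsim")),
    scenario = list(
      glp1_glucose_sensitivity = scn$glp1_glucose_sensitivity,
      p_gl = scn$p_gl,
      pss_resistance = scn$pss_resistance,
      presinusoidal_resistance = scn$presinusoidal_resistance,
      gavage = unclass(scn$gavage),
      overrides = scn$overrides
    ),
    parameters = result$params[setdiff(names(result$params), "compartments")],
    compartments = result$params$compartments
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
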