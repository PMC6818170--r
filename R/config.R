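## Configuration loading, result serialization and run manifests.
##
## Configs are YAML with fixed internal unit conventions (nm, s, molecules;
## diffusivities in um^2/s and catalytic efficiencies in uM^-1 s^-1 at the
## boundary, exactly as the model constructors document).

#' Load a model configuration file
#'
#' Reads a YAML configuration and resolves it into package objects.  The
#' file must name a `model` ("pd1", "pushpull" or "mrt") and may provide a
#' section of constructor arguments under that name; omitted fields take
#' the constructors' published-table defaults.  Unknown keys are collected
#' and reported together.
#'
#' @param path Path to a YAML file.
#' @return For "pd1"/"pushpull", a `signaling_model`; for "mrt", the
#'   argument list resolved for [mrt_wellmixed()].
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must name a 'model' (pd1, pushpull, mrt)")
  model <- match.arg(cfg$model, c("pd1", "pushpull", "mrt"))
  section <- cfg[[model]]
  if (is.null(section)) section <- list()
  target <- switch(model,
    pd1 = pd1_model, pushpull = pushpull_model, mrt = mrt_wellmixed)
  allowed <- names(formals(target))
  bad <- setdiff(names(section), allowed)
  if (length(bad)) {
    stop("unknown keys in '", model, "' section: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  num_bad <- names(section)[vapply(section, function(v)
    is.numeric(v) && any(v < 0) && !identical(v, -1), logical(1))]
  num_bad <- intersect(num_bad, c("D", "L", "lambda", "kcat", "pd1", "cd28",
                                  "E", "S", "F", "D_S", "D_E", "D_F",
                                  "L_e", "L_f", "kcat_e", "kcat_f", "side"))
  if (length(num_bad)) stop("negative values for: ", paste(num_bad, collapse = ", "))
  if (model == "mrt") {
    c(section, list(.what = "mrt"))
  } else {
    do.call(target, section)
  }
}

#' Write a result object to CSV and/or JSON
#'
#' Writes a tidy table (one observation per row) at full floating-point
#' precision so that a read-back reproduces values exactly.
#'
#' @param result A `dose_response`, `steady_state`, `ensemble_summary`, or
#'   plain data.frame/list of equal-length columns.
#' @param path Output file path.
#' @param format "csv" or "json".
#' @return The path, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as_results_table(result)
  if (format == "csv") {
    out <- df
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Tidy table view of a result object
#'
#' @param result See [write_results()].
#' @return A data.frame, one observation per row.
#' @export
as_results_table <- function(result) {
  if (is.data.frame(result)) return(result)
  if (inherits(result, "dose_response")) {
    return(data.frame(concentration = rep(result$concentration, 3),
                      statistic = rep(c("fraction", "se", "converged"),
                                      each = length(result$concentration)),
                      value = c(result$fraction, result$se,
                                as.numeric(result$converged))))
  }
  if (inherits(result, "steady_state")) {
    return(data.frame(statistic = c("fraction", "se", "converged",
                                    "n_trajectories", "t_end", "kappa"),
                      value = c(result$fraction, result$se,
                                as.numeric(result$converged),
                                result$n_trajectories, result$policy$t_end,
                                result$policy$kappa)))
  }
  if (inherits(result, "ensemble_summary")) {
    m <- colMeans(result$avg)
    s <- apply(result$avg, 2, stats::sd) / sqrt(result$n_trajectories)
    return(data.frame(species = rep(result$species, 2),
                      statistic = rep(c("window_mean", "window_se"),
                                      each = length(result$species)),
                      value = c(m, s)))
  }
  if (is.list(result)) return(as.data.frame(result))
  stop("no tidy-table representation for class ", class(result)[1])
}

#' Run manifest for reproducibility
#'
#' Captures the fully resolved parameter set, seed, package version and any
#' derived quantities (converted rates, calibrated indicator parameters,
#' molecule counts) so a run can be reproduced from the manifest alone.
#'
#' @param params Named list of resolved parameters.
#' @param base_seed Integer seed.
#' @param derived Optional named list of derived quantities.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(params, base_seed, derived = list(), path = NULL) {
  man <- list(
    schema_version = 1L,
    package = "reachsim",
    version = as.character(utils::packageVersion("reachsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = base_seed,
    params = params,
    derived = derived)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(man))
  }
  man
}
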