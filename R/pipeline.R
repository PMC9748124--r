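#' Run configuration for a pipeline stage
#'
#' Validated bag of settings for [run_pipeline()]. Unknown keys are
#' rejected with the offending key named; every run writes a provenance
#' block (command, parameters, seed, package version) next to its output.
#'
#' @param command one of the stage names listed under [run_pipeline()].
#' @param input_path input table path (stages that read data).
#' @param output_path output table path; the provenance block goes to
#'   `<output_path>.prov`.
#' @param params named list of stage parameters (model-parameter
#'   overrides); unknown names are rejected by the stage.
#' @param seed integer seed governing any randomness in the stage.
#' @param verbosity 0 = silent, 1 = stage messages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(command, input_path = NULL, output_path = NULL,
                       params = list(), seed = 1L, verbosity = 0L) {
  structure(list(command = command, input_path = input_path,
                 output_path = output_path, params = params,
                 seed = as.integer(seed), verbosity = verbosity),
            class = "run_config")
}

pipeline_stages <- c("hsp-simulate", "hsp-fit", "hsp-halflife",
                     "nash-fit", "nash-predict", "di-fit", "synth-nash")

#' Dispatch a pipeline stage
#'
#' Thin programmatic surface over the module functions, used by the
#' analysis scripts: reads the input table, runs one stage, writes a
#' tab-separated result plus a human-readable provenance block. Flagged
#' non-convergence is reported in the output, never raised.
#'
#' Stages: `hsp-simulate` (params -> curve), `hsp-fit` (curve -> kinetic
#' parameters), `hsp-halflife` (curve -> half-life), `nash-fit`
#' (cohort -> regression), `nash-predict` (params -> NAS), `di-fit`
#' ((si, phi) table -> hyperbola), `synth-nash` (params -> cohort table).
#'
#' @param config a [run_config()].
#' @return list with `status` (0 on success) and `result`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  known <- c("command", "input_path", "output_path", "params", "seed",
             "verbosity")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown config key: '", extra[1L], "'", call. = FALSE)
  }
  if (!config$command %in% pipeline_stages) {
    stop("unknown command '", config$command, "'; available: ",
         paste(pipeline_stages, collapse = ", "), call. = FALSE)
  }
  say <- function(...) if (config$verbosity > 0) message(...)
  p <- config$params
  result <- switch(
    config$command,
    "hsp-simulate" = {
      prm <- do.call(hsp_params, p[setdiff(names(p), "sample_times")])
      st <- if (!is.null(p$sample_times)) p$sample_times else
        seq(0, 240, by = 5)
      sim <- simulate_hsp(prm, sort(unique(c(0, st))))
      out <- timeseries(st, sim$value[match(st, sim$time)] + prm$cb,
                        "min", "ng/mL", basal = prm$cb)
      if (!is.null(config$output_path)) {
        write_timeseries(out, config$output_path)
      }
      out
    },
    "hsp-fit" = {
      obs <- read_timeseries(config$input_path)
      init <- do.call(hsp_params, p)
      fit <- fit_hsp(obs, init)
      if (!is.null(config$output_path)) {
        write_fit_table(fit, config$output_path)
      }
      fit
    },
    "hsp-halflife" = {
      obs <- read_timeseries(config$input_path)
      inc <- timeseries(obs$time, obs$value - obs$basal, obs$time_unit,
                        obs$value_unit)
      half_life(inc)
    },
    "nash-fit" = {
      cohort <- read_table_(config$input_path)
      fit_nas(cohort)
    },
    "nash-predict" = {
      model <- if (length(p$model_coefs)) {
        do.call(nas_model, p$model_coefs)
      } else nas_reference_model()
      predict_nas(model, p$hsp70, p$grp78)
    },
    "di-fit" = {
      tab <- read_table_(config$input_path)
      fit_di(tab$si, tab$phi)
    },
    "synth-nash" = {
      cohort <- do.call(generate_nash_cohort,
                        c(p, list(seed = config$seed)))
      if (!is.null(config$output_path)) {
        utils::write.table(cohort, config$output_path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      cohort
    }
  )
  say("stage ", config$command, " done")
  if (!is.null(config$output_path)) {
    write_provenance(config, paste0(config$output_path, ".prov"))
  }
  invisible(list(status = 0L, result = result))
}

write_fit_table <- function(fit, path) {
  df <- data.frame(parameter = names(fit$estimates),
                   estimate = unname(fit$estimates),
                   std_error = unname(fit$std_errors),
                   converged = fit$converged)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_provenance <- function(config, path) {
  flat <- function(x) paste(vapply(x, function(v)
    paste(format(unlist(v)), collapse = ","), character(1)),
    collapse = "; ")
  writeLines(c(
    sprintf("command: %s", config$command),
    sprintf("seed: %d", config$seed),
    sprintf("params: %s",
            if (length(config$params))
              paste(names(config$params), vapply(config$params, flat,
                                                 character(1)),
                    sep = "=", collapse = "; ") else "(none)"),
    sprintf("package: gutpk %s",
            as.character(utils::packageVersion("gutpk")))
  ), path)
  invisible(path)
}
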