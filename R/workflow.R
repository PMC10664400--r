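# The upstream analysis workflow: structural identifiability first, then —
# informed by it — practical identifiability and/or optimal experiment
# design, with every seed recorded in the report.

#' Run the upstream identifiability workflow
#'
#' Runs the selected stages in the order structural, then OED and/or
#' practical. When the structural stage finds non-identifiable quantities
#' and the practical stage is requested, the practical Cramér-Rao SDs are
#' suppressed with an explicit warning (structural non-identifiability
#' implies practical non-identifiability) unless `config$force` is `TRUE`.
#'
#' @param model An [ode_model()].
#' @param config List with `stages` (non-empty subset of
#'   `c("structural", "practical", "oed")`) and per-stage option lists:
#'   * `structural`: arguments of [observation_setup()] plus `seed`,
#'     `n_points`, `count_solutions` (logical).
#'   * `practical`: `data` (observation table; if omitted, synthetic data are
#'     generated from `theta_true`), `theta_true`, `sigma`, `theta_bounds`,
#'     `n_starts`, `seed`, `input_signal`, `profile` (quantity name),
#'     `grid` (profile grid).
#'   * `oed`: arguments of [design_space()] plus `n_starts`, `seed`.
#'   * `force`: run practical SD reporting even under structural
#'     non-identifiability.
#' @return An `analysis_report`.
#' @export
run_workflow <- function(model, config) {
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L ||
      !all(stages %in% c("structural", "practical", "oed"))) {
    stop(errorCondition(
      "config$stages must be a non-empty subset of structural/practical/oed",
      class = c("odeident_validation_error", "odeident_error")
    ))
  }
  report <- structure(
    list(model_name = model$name, config = .config_echo(config),
         structural = NULL, practical = NULL, design = NULL,
         tool_version = as.character(utils::packageVersion("odeident")),
         seeds = list(), warnings = character(),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "analysis_report"
  )
  fail <- function(stage, e) {
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("odeident_stage_failure", "odeident_error"),
      partial_report = report
    ))
  }

  if ("structural" %in% stages) {
    s <- config$structural %||% list()
    setup <- observation_setup(
      measured_outputs = s$measured %||% names(model$outputs),
      known_ic_overrides = s$known_ic_overrides %||% list(),
      input_class = s$input_class %||% "generic_smooth"
    )
    seed <- s$seed %||% 17L
    report$seeds$structural <- seed
    sr <- tryCatch(
      test_local_identifiability(model, setup, n_points = s$n_points %||% 3L,
                                 seed = seed),
      error = function(e) fail("structural", e)
    )
    report$structural <- sr
    report$warnings <- c(report$warnings, sr$warnings)
    if (isTRUE(s$count_solutions)) {
      cnt <- tryCatch(
        count_output_equivalent_params(model, setup, seed = seed),
        error = function(e) fail("structural", e)
      )
      report$structural$solution_count <- cnt$count
      report$structural$solution_status <- cnt$status
      report$structural$witnesses <- cnt$witnesses
    }
  }

  nonident <- !is.null(report$structural) &&
    any(report$structural$per_quantity_verdict == "non_identifiable")

  if ("oed" %in% stages) {
    o <- config$oed %||% list()
    seed <- o$seed %||% 3L
    report$seeds$oed <- seed
    space <- design_space(
      input_kind = o$input_kind %||% "piecewise_linear",
      n_nodes = o$n_nodes %||% 5L,
      input_bounds = o$input_bounds %||% c(0, 100),
      horizon = o$horizon %||% c(0, 50),
      sampling_times = o$sampling_times,
      sigma = o$sigma %||% 0.05,
      theta_nominal = o$theta_nominal,
      outputs = o$outputs
    )
    report$design <- tryCatch(
      optimize_design(model, space, n_starts = o$n_starts %||% 10L, seed = seed),
      error = function(e) fail("oed", e)
    )
  }

  if ("practical" %in% stages) {
    p <- config$practical %||% list()
    seed <- p$seed %||% 7L
    report$seeds$practical <- seed
    if (nonident && !isTRUE(config$force)) {
      report$warnings <- c(report$warnings,
        "structurally non-identifiable; practical SDs suppressed")
    }
    prac <- tryCatch({
      data <- p$data
      if (is.null(data)) {
        data <- generate_synthetic_data(
          model, theta_true = p$theta_true,
          input_signal = p$input_signal,
          time_grid = p$time_grid %||% seq(0, 50, length.out = 40L),
          noise = list(kind = "additive", sigma = p$sigma %||% 0.05),
          seed = seed, outputs = p$outputs
        )
      }
      fit <- fit_least_squares(model, data,
                               theta_bounds = p$theta_bounds,
                               sigma = p$sigma %||% 0.05,
                               n_starts = p$n_starts %||% 20L, seed = seed,
                               input_signal = p$input_signal)
      prof <- NULL
      if (!is.null(p$profile)) {
        prof <- profile_likelihood(model, data, p$profile, p$grid,
                                   theta_bounds = p$theta_bounds,
                                   sigma = p$sigma %||% 0.05, fit = fit,
                                   input_signal = p$input_signal)
      }
      list(fit = fit, profiles = prof)
    }, error = function(e) fail("practical", e))
    if (nonident && !isTRUE(config$force) && !is.null(prac$fit$fim_at_hat)) {
      prac$fit$fim_at_hat$sds[] <- NA_real_
      prac$fit$fim_at_hat$suppressed <- TRUE
    }
    report$practical <- prac
  }

  report
}

.config_echo <- function(config) {
  rapply(config, function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s (odeident %s)\n", x$model_name,
              x$tool_version))
  if (!is.null(x$structural)) print(x$structural)
  if (!is.null(x$practical)) print(x$practical$fit)
  if (!is.null(x$design)) print(x$design)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report` (or any result object).
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  clean <- .jsonable(unclass(report))
  txt <- jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null", force = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

.jsonable <- function(x) {
  if (is.language(x)) return(deparse1(x))
  if (is.function(x)) return("<function>")
  if (inherits(x, "input_signal")) {
    return(list(kind = x$kind, value = x$value %||% NULL,
                times = x$times %||% NULL, values = x$values %||% NULL))
  }
  if (is.matrix(x)) return(apply(x, 1L, identity, simplify = FALSE))
  if (is.array(x)) return(as.vector(x))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .jsonable))
  }
  x
}
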