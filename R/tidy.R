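# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a structural identifiability result
#'
#' @param x A `structural_result`.
#' @param ... Unused.
#' @return Tibble with one row per unknown quantity: `quantity`, `verdict`,
#'   `identifiable`.
#' @export
tidy.structural_result <- function(x, ...) {
  tibble::tibble(
    quantity = names(x$per_quantity_verdict),
    verdict = unname(x$per_quantity_verdict),
    identifiable = unname(x$per_quantity_verdict) == "locally_identifiable"
  )
}

#' @rdname tidy.structural_result
#' @export
glance.structural_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, generic_rank = x$generic_rank,
    n_unknowns = x$n_unknowns,
    rank_deficiency = x$n_unknowns - x$generic_rank,
    orders_used = x$orders_used,
    evaluation_points = x$evaluation_points_used,
    n_warnings = length(x$warnings)
  )
}

#' Tidy a Fisher-information report
#'
#' @param x A `fim_report`.
#' @param ... Unused.
#' @return Tibble with `quantity`, `nominal`, `sd` (Cramér-Rao), `rel_sd`.
#' @export
tidy.fim_report <- function(x, ...) {
  nom <- unlist(x$theta_nominal)[names(x$sds)]
  tibble::tibble(
    quantity = names(x$sds), nominal = unname(nom),
    sd = unname(x$sds), rel_sd = unname(x$sds / abs(nom))
  )
}

#' @rdname tidy.fim_report
#' @export
glance.fim_report <- function(x, ...) {
  tibble::tibble(
    log_det = x$log_det, det_fim = exp(x$log_det),
    condition_number = x$condition_number, singular = x$singular
  )
}

#' Tidy a least-squares fit
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @return Tibble with `quantity`, `estimate`, `sd` and Wald 95% bounds
#'   (when the FIM at the estimate is non-singular).
#' @export
tidy.fit_result <- function(x, ...) {
  sds <- if (!is.null(x$fim_at_hat)) x$fim_at_hat$sds[x$quantities] else
    stats::setNames(rep(NA_real_, length(x$quantities)), x$quantities)
  tibble::tibble(
    quantity = x$quantities,
    estimate = unname(x$theta_hat[x$quantities]),
    sd = unname(sds),
    conf_low = unname(x$theta_hat[x$quantities] - 1.96 * sds),
    conf_high = unname(x$theta_hat[x$quantities] + 1.96 * sds)
  )
}

#' @rdname tidy.fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, rss = x$rss, n_starts = x$n_starts,
    converged_fraction = x$converged_fraction,
    n_clusters = nrow(solution_clusters(x))
  )
}

#' Tidy a likelihood profile
#'
#' @param x A `likelihood_profile`.
#' @param ... Unused.
#' @return Tibble with `value` (grid), `objective`, `in_ci`.
#' @export
tidy.likelihood_profile <- function(x, ...) {
  tibble::tibble(
    quantity = x$quantity, value = x$grid,
    objective = x$profiled_objective,
    in_ci = !is.na(x$profiled_objective) &
      x$profiled_objective <= x$objective_min + x$delta
  )
}

#' Plot a likelihood profile
#'
#' @param object A `likelihood_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.likelihood_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$objective_min + object$delta,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = unname(object$theta_hat[object$quantity]),
                        linetype = "dotted") +
    ggplot2::labs(x = object$quantity, y = "profiled weighted RSS",
                  title = sprintf("Profile likelihood of %s%s", object$quantity,
                                  if (object$ci$flat) " (flat)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot an optimized input design
#'
#' @param object A `design_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.design_result <- function(object, ...) {
  sig <- object$input_signal
  tt <- seq(object$space$horizon[1L], object$space$horizon[2L],
            length.out = 200L)
  df <- data.frame(time = tt, u = sig$fun(tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$u)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "input u(t)",
                  title = sprintf("D-optimal %s input (log det FIM = %.2f)",
                                  object$space$input_kind,
                                  object$fim_report$log_det)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory
#'
#' @param object An `ode_trajectory`.
#' @param ... Unused.
#' @return A ggplot object (one facet per output).
#' @exportS3Method ggplot2::autoplot
autoplot.ode_trajectory <- function(object, ...) {
  df <- do.call(rbind, lapply(colnames(object$outputs), function(o)
    data.frame(time = object$time, output = o, value = object$outputs[, o])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(x = "time", y = "output",
                  title = object$model_name) +
    ggplot2::theme_minimal()
}
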