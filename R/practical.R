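# Practical identifiability: Fisher information with Cramér-Rao standard
# deviations, multistart weighted least squares, and profile likelihood.
# The objective everywhere is the weighted residual sum of squares
# sum((y_obs - y_model)^2 / sigma^2), i.e. twice the negative Gaussian
# log-likelihood up to a constant, so FIM-based SDs are in parameter units.

#' Describe an experimental design
#'
#' @param times Sampling times (first entry is t0).
#' @param input_signal Optional [input_constant()] / [input_piecewise_linear()].
#' @param sigma Noise SD per measured output (scalar recycled, or named).
#' @param outputs Measured output names (default: all model outputs).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(times, input_signal = NULL, sigma = 0.05,
                              outputs = NULL) {
  structure(list(times = times, input_signal = input_signal, sigma = sigma,
                 outputs = outputs),
            class = "experiment_design")
}

.sigma_vec <- function(sigma, outputs) {
  if (is.null(names(sigma))) {
    stats::setNames(rep(sigma, length.out = length(outputs)), outputs)
  } else {
    missing <- setdiff(outputs, names(sigma))
    if (length(missing)) {
      stop(sprintf("no sigma given for output(s): %s", paste(missing, collapse = ", ")))
    }
    sigma[outputs]
  }
}

#' Fisher information matrix of a design
#'
#' `FIM = sum_k S_y(t_k)' W S_y(t_k)` with `W = diag(1/sigma^2)`, from
#' forward-sensitivity output derivatives at the nominal parameters.
#' A singular FIM is a flagged result (with its null directions), not an
#' error.
#'
#' @param model An [ode_model()].
#' @param theta_nominal Named values of the unknown quantities.
#' @param design An [experiment_design()] (all `sigma` must be > 0).
#' @param bundle Optional precomputed [sensitivities()] bundle.
#' @param tol Integration tolerance for the sensitivity solve.
#' @return A `fim_report`: `fim`, `log_det`, `sds`, `correlations`,
#'   `condition_number`, `singular`, `null_directions`, `design`.
#' @export
compute_fim <- function(model, theta_nominal, design, bundle = NULL,
                        tol = 1e-8) {
  model2 <- substitute_known(model)
  outs <- design$outputs %||% names(model2$outputs)
  sigma <- .sigma_vec(design$sigma, outs)
  if (any(sigma <= 0)) stop("all noise SDs must be > 0 for the FIM")
  if (is.null(bundle)) {
    bundle <- sensitivities(model2, theta_nominal, design$input_signal,
                            design$times, tol = tol)
  }
  q <- bundle$quantities
  nq <- length(q)
  fim <- matrix(0, nq, nq, dimnames = list(q, q))
  for (o in outs) {
    S <- matrix(bundle$output_sens[, o, ], ncol = nq)
    fim <- fim + crossprod(S) / sigma[[o]]^2
  }
  ev <- eigen(fim, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  singular <- nq > 0 && (min(ev$values) < tol)
  log_det <- if (singular) -Inf else sum(log(ev$values))
  if (!singular && nq > 0) {
    covm <- solve(fim)
    sds <- sqrt(diag(covm))
    correlations <- stats::cov2cor(covm)
    condition_number <- max(ev$values) / min(ev$values)
    null_directions <- list()
  } else {
    sds <- stats::setNames(rep(NA_real_, nq), q)
    correlations <- matrix(NA_real_, nq, nq, dimnames = list(q, q))
    condition_number <- Inf
    null_directions <- lapply(which(ev$values < tol), function(i)
      stats::setNames(ev$vectors[, i], q))
  }
  structure(
    list(fim = fim, log_det = log_det,
         sds = stats::setNames(as.numeric(sds), q),
         correlations = correlations, condition_number = condition_number,
         singular = singular, null_directions = null_directions,
         design = design, theta_nominal = theta_nominal,
         outputs = outs, sigma = sigma),
    class = "fim_report"
  )
}

#' @export
print.fim_report <- function(x, ...) {
  cat(sprintf("<fim_report> %d unknowns, log det(FIM) = %.4g%s\n",
              nrow(x$fim), x$log_det,
              if (x$singular) " [SINGULAR]" else ""))
  if (!x$singular) {
    for (q in names(x$sds)) {
      cat(sprintf("  SD(%s) = %.4g\n", q, x$sds[[q]]))
    }
  } else {
    cat("  Cramér-Rao SDs undefined; null directions:\n")
    for (v in x$null_directions) {
      cat("   ", paste(sprintf("%s=%.3f", names(v), v), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# Weighted residual vector for a dataset, with the analytic residual
# Jacobian from forward sensitivities (a finite-difference Jacobian at
# machine-epsilon steps would be dominated by integrator noise).
.residual_fun <- function(model, data, sigma, input_signal, outs) {
  force(model); force(data); force(sigma); force(outs)
  times <- data$time
  nres <- length(times) * length(outs)
  function(theta) {
    traj <- tryCatch(
      simulate_model(model, theta, input_signal, times),
      error = function(e) NULL
    )
    if (is.null(traj)) return(rep(1e4, nres))
    unlist(lapply(outs, function(o)
      (data[[o]] - traj$outputs[, o]) / sigma[[o]]))
  }
}

.residual_jac <- function(model, data, sigma, input_signal, outs, q) {
  force(model); force(data); force(sigma); force(outs); force(q)
  times <- data$time
  nres <- length(times) * length(outs)
  function(theta, ...) {
    sb <- tryCatch(
      sensitivities(model, theta, input_signal, times),
      error = function(e) NULL
    )
    if (is.null(sb)) return(matrix(0, nres, length(q)))
    do.call(rbind, lapply(outs, function(o)
      -matrix(sb$output_sens[, o, q], ncol = length(q)) / sigma[[o]]))
  }
}

#' Multistart weighted least-squares estimation
#'
#' Latin-hypercube starts in log-parameter space within the bounds, each
#' refined by Levenberg-Marquardt ([minpack.lm::nls.lm]); the best terminus
#' is returned together with all termini (for solution-cluster diagnostics)
#' and the FIM evaluated at the estimate.
#'
#' @param model An [ode_model()].
#' @param data Data frame with a `time` column and one column per measured
#'   output.
#' @param theta_bounds Named list of `c(lower, upper)` for each unknown
#'   quantity (positive bounds).
#' @param sigma Noise SD per output (weights; scalar or named).
#' @param n_starts Number of multistart points.
#' @param seed Integer seed (Latin hypercube).
#' @param input_signal Optional input signal.
#' @param start_values Optional explicit start(s): a named vector or a matrix
#'   with one start per row, used instead of the Latin hypercube (e.g. for
#'   replicate studies at reduced cost).
#' @return A `fit_result`: `theta_hat`, `rss`, `n_starts`,
#'   `converged_fraction`, `fim_at_hat`, `termini` (tibble).
#' @export
fit_least_squares <- function(model, data, theta_bounds, sigma = 0.05,
                              n_starts = 20, seed = 7, input_signal = NULL,
                              start_values = NULL) {
  model2 <- substitute_known(model)
  q <- unknown_quantities(model2)
  missing <- setdiff(q, names(theta_bounds))
  if (length(missing)) {
    stop(sprintf("theta_bounds missing: %s", paste(missing, collapse = ", ")))
  }
  lo <- vapply(theta_bounds[q], `[`, numeric(1L), 1L)
  hi <- vapply(theta_bounds[q], `[`, numeric(1L), 2L)
  if (any(lo <= 0)) stop("bounds must be positive")
  outs <- intersect(names(model2$outputs), setdiff(names(data), "time"))
  if (!length(outs)) stop("data columns do not match any model output")
  sigma <- .sigma_vec(sigma, outs)
  resid_fn <- .residual_fun(model2, data, sigma, input_signal, outs)
  jac_fn <- .residual_jac(model2, data, sigma, input_signal, outs, q)

  if (!is.null(start_values)) {
    starts <- if (is.matrix(start_values)) start_values else
      matrix(start_values, nrow = 1L,
             dimnames = list(NULL, names(start_values)))
    starts <- starts[, q, drop = FALSE]
    n_starts <- nrow(starts)
  } else {
    starts <- .with_seed(seed, {
      u <- lhs::randomLHS(n_starts, length(q))
      exp(sweep(sweep(u, 2L, log(hi) - log(lo), "*"), 2L, log(lo), "+"))
    })
    colnames(starts) <- q
  }

  termini <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lo, upper = hi, fn = resid_fn,
        jac = jac_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    termini[[i]] <- if (is.null(fit)) {
      c(rss = NA_real_, converged = 0, stats::setNames(starts[i, ], q))
    } else {
      c(rss = sum(fit$fvec^2), converged = as.numeric(fit$info %in% 1:4),
        stats::setNames(unlist(fit$par)[q], q))
    }
  }
  tt <- tibble::as_tibble(do.call(rbind, termini))
  ok <- !is.na(tt$rss)
  if (!any(ok)) {
    stop(errorCondition("all multistart fits failed",
                        class = c("odeident_estimation_failure", "odeident_error")))
  }
  best <- which.min(tt$rss)
  theta_hat <- stats::setNames(as.numeric(tt[best, q]), q)
  design <- experiment_design(times = data$time, input_signal = input_signal,
                              sigma = sigma, outputs = outs)
  fim_at_hat <- tryCatch(
    compute_fim(model2, theta_hat, design),
    error = function(e) NULL
  )
  structure(
    list(theta_hat = theta_hat, rss = tt$rss[best],
         n_starts = n_starts,
         converged_fraction = mean(tt$converged[ok]),
         fim_at_hat = fim_at_hat, termini = tt, quantities = q,
         bounds = list(lower = lo, upper = hi), sigma = sigma,
         data = data, input_signal = input_signal,
         model_name = model2$name, seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: rss = %.4g (%d starts, %.0f%% converged)\n",
              x$model_name, x$rss, x$n_starts, 100 * x$converged_fraction))
  for (q in names(x$theta_hat)) {
    sd <- if (!is.null(x$fim_at_hat) && !x$fim_at_hat$singular)
      sprintf(" (CR SD %.3g)", x$fim_at_hat$sds[[q]]) else ""
    cat(sprintf("  %s = %.6g%s\n", q, x$theta_hat[[q]], sd))
  }
  invisible(x)
}

#' Cluster the termini of a multistart fit
#'
#' Termini whose best weighted RSS is within `rss_tol` of the optimum are
#' merged into clusters by relative parameter distance. Distinct clusters
#' with equal RSS diagnose output-equivalent parameter sets.
#'
#' @param fit A `fit_result`.
#' @param rel_tol Relative distance below which termini merge.
#' @param rss_tol Keep termini with `rss <= rss_min + rss_tol`
#'   (default `max(1e-6, 1e-3 * rss_min)`).
#' @return Tibble with one row per cluster (`n`, `rss`, parameter columns).
#' @export
solution_clusters <- function(fit, rel_tol = 1e-3, rss_tol = NULL) {
  tt <- fit$termini[!is.na(fit$termini$rss), , drop = FALSE]
  rss_min <- min(tt$rss)
  if (is.null(rss_tol)) rss_tol <- max(1e-6, 1e-3 * rss_min)
  tt <- tt[tt$rss <= rss_min + rss_tol, , drop = FALSE]
  q <- fit$quantities
  reps <- list()
  counts <- integer()
  for (i in seq_len(nrow(tt))) {
    th <- as.numeric(tt[i, q])
    hit <- FALSE
    for (j in seq_along(reps)) {
      if (max(abs(th - reps[[j]]) / (1 + abs(reps[[j]]))) < rel_tol) {
        counts[j] <- counts[j] + 1L
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      reps[[length(reps) + 1L]] <- th
      counts[length(reps)] <- 1L
    }
  }
  out <- tibble::as_tibble(do.call(rbind, lapply(reps, function(r)
    stats::setNames(r, q))))
  out$n <- counts
  out$rss <- vapply(reps, function(r) {
    i <- which.min(apply(tt[, q], 1L, function(row) max(abs(row - r))))
    tt$rss[i]
  }, numeric(1L))
  out[order(-out$n), ]
}

#' Profile likelihood of one unknown quantity
#'
#' Fixes the quantity on a grid and re-optimizes all other unknowns at each
#' grid point (warm-started from the neighbouring solution). The confidence
#' interval collects grid values whose profiled objective lies within
#' `delta` of the minimum (default 3.84: chi-squared, 1 df, 95%). A profile
#' whose total variation is below `delta / 100` is flagged flat.
#'
#' @param model An [ode_model()].
#' @param data Observation table (`time` + output columns).
#' @param quantity Name of the profiled unknown quantity.
#' @param grid Numeric grid of values for the quantity (should span the
#'   estimate).
#' @param theta_bounds Bounds as in [fit_least_squares()].
#' @param sigma Noise SD per output.
#' @param delta Objective offset defining the confidence region.
#' @param fit Optional `fit_result` to reuse (otherwise an internal
#'   multistart fit is run).
#' @param n_starts,seed Passed to the internal fit.
#' @param input_signal Optional input signal.
#' @return A `likelihood_profile`: `quantity`, `grid`, `profiled_objective`,
#'   `ci` (list with `lower`, `upper`, `unbounded_low`, `unbounded_high`,
#'   `flat`), `theta_hat`, `objective_min`.
#' @export
profile_likelihood <- function(model, data, quantity, grid,
                               theta_bounds, sigma = 0.05, delta = 3.84,
                               fit = NULL, n_starts = 20, seed = 7,
                               input_signal = NULL) {
  model2 <- substitute_known(model)
  q <- unknown_quantities(model2)
  if (!quantity %in% q) stop(sprintf("'%s' is not an unknown quantity", quantity))
  if (is.null(fit)) {
    fit <- fit_least_squares(model2, data, theta_bounds, sigma = sigma,
                             n_starts = n_starts, seed = seed,
                             input_signal = input_signal)
  }
  outs <- intersect(names(model2$outputs), setdiff(names(data), "time"))
  sigma <- .sigma_vec(sigma, outs)
  resid_fn <- .residual_fun(model2, data, sigma, input_signal, outs)
  jac_all <- .residual_jac(model2, data, sigma, input_signal, outs, q)
  others <- setdiff(q, quantity)
  oth_idx <- match(others, q)
  lo <- fit$bounds$lower[others]
  hi <- fit$bounds$upper[others]

  prof <- rep(NA_real_, length(grid))
  flags <- rep(FALSE, length(grid))
  # sweep outwards from the grid point nearest the estimate, warm-starting
  i0 <- which.min(abs(grid - fit$theta_hat[[quantity]]))
  order_idx <- c(seq(i0, length(grid)), if (i0 > 1) seq(i0 - 1L, 1L))
  warm_up <- fit$theta_hat[others]
  warm <- warm_up
  for (i in order_idx) {
    if (i == i0 - 1L) warm <- warm_up  # restart for the downward sweep
    val <- grid[i]
    obj <- tryCatch({
      if (length(others)) {
        f <- minpack.lm::nls.lm(
          par = warm, lower = lo, upper = hi,
          fn = function(th) resid_fn(c(stats::setNames(val, quantity), th)),
          jac = function(th, ...) {
            jac_all(c(stats::setNames(val, quantity), th))[, oth_idx,
                                                           drop = FALSE]
          },
          control = minpack.lm::nls.lm.control(maxiter = 150)
        )
        warm <<- stats::setNames(unlist(f$par), others)
        sum(f$fvec^2)
      } else {
        sum(resid_fn(stats::setNames(val, quantity))^2)
      }
    }, error = function(e) NA_real_)
    prof[i] <- obj
    flags[i] <- is.na(obj)
  }
  obj_min <- min(prof, na.rm = TRUE)
  thr <- obj_min + delta
  inside <- !is.na(prof) & prof <= thr
  ci <- list(lower = NA_real_, upper = NA_real_,
             unbounded_low = FALSE, unbounded_high = FALSE, flat = FALSE)
  if (diff(range(prof, na.rm = TRUE)) < delta * 1e-2) {
    ci$flat <- TRUE
    ci$unbounded_low <- TRUE
    ci$unbounded_high <- TRUE
    ci$lower <- grid[1L]
    ci$upper <- grid[length(grid)]
  } else if (any(inside)) {
    lo_i <- which(inside)[1L]
    hi_i <- rev(which(inside))[1L]
    ci$lower <- if (lo_i == 1L) { ci$unbounded_low <- TRUE; grid[1L] } else
      .cross(grid[lo_i - 1L], grid[lo_i], prof[lo_i - 1L], prof[lo_i], thr)
    ci$upper <- if (hi_i == length(grid)) { ci$unbounded_high <- TRUE; grid[length(grid)] } else
      .cross(grid[hi_i], grid[hi_i + 1L], prof[hi_i], prof[hi_i + 1L], thr)
  }
  structure(
    list(quantity = quantity, grid = grid, profiled_objective = prof,
         ci = ci, theta_hat = fit$theta_hat, objective_min = obj_min,
         delta = delta, failed_points = which(flags)),
    class = "likelihood_profile"
  )
}

.cross <- function(x0, x1, y0, y1, thr) {
  if (!is.finite(y0) || !is.finite(y1) || y0 == y1) return(x1)
  x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat(sprintf("<likelihood_profile> %s over [%g, %g]\n", x$quantity,
              min(x$grid), max(x$grid)))
  if (x$ci$flat) {
    cat("  FLAT profile: quantity is not identifiable from these data\n")
  } else {
    cat(sprintf("  95%% CI approx [%s, %s]%s%s\n",
                format(x$ci$lower, digits = 4), format(x$ci$upper, digits = 4),
                if (x$ci$unbounded_low) " (open below)" else "",
                if (x$ci$unbounded_high) " (open above)" else ""))
  }
  invisible(x)
}
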