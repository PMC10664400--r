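# Numerical integration and forward sensitivities. The ODE right-hand side,
# its state Jacobian and the parameter-derivative blocks are generated
# symbolically from the model and evaluated along the trajectory, so lsoda
# always receives an analytic Jacobian (the methanogenesis fixture mixes fast
# gas transfer with slow growth and is moderately stiff).

#' Input signals
#'
#' Constant or piecewise-linear forcing for a model input. Piecewise-linear
#' signals hold their end values outside the node range.
#'
#' @param value Constant input level.
#' @return An `input_signal` object: a list with `kind`, `fun(t)`, and nodes.
#' @export
input_constant <- function(value) {
  structure(list(kind = "constant", value = value,
                 fun = function(t) rep(value, length(t))),
            class = "input_signal")
}

#' @rdname input_constant
#' @param times,values Node times (strictly increasing) and node values.
#' @export
input_piecewise_linear <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2L,
            all(diff(times) > 0))
  f <- stats::approxfun(times, values, rule = 2)
  structure(list(kind = "piecewise_linear", times = times, values = values,
                 fun = f),
            class = "input_signal")
}

# Resolve theta into parameter values and initial conditions.
.theta_env <- function(model, theta) {
  q <- unknown_quantities(model)
  theta <- unlist(theta)
  missing <- setdiff(q, names(theta))
  if (length(missing)) {
    stop(sprintf("theta is missing unknown quantities: %s",
                 paste(missing, collapse = ", ")))
  }
  upars <- model$parameters$name[!model$parameters$known]
  ics <- stats::setNames(model$states$ic_value, model$states$name)
  for (s in unknown_ic_states(model)) ics[[s]] <- theta[[paste0(s, "_0")]]
  list(pars = c(as.list(theta[upars]), as.list(model$constants)),
       ics = ics)
}

# Compile a list of expressions into a fast positional R function
# f(<states>, <inputs>, <unknown params>), with constants folded in as
# numeric literals and the result byte-compiled.
.compile_fun <- function(exprs, argnames, consts) {
  subs <- as.list(consts)
  exprs <- lapply(exprs, function(e) {
    if (is.numeric(e)) e else simplify_expr(subst_expr(e, subs))
  })
  bod <- as.call(c(quote(c), unname(exprs)))
  fml <- stats::setNames(rep(list(quote(expr = )), length(argnames)), argnames)
  f <- eval(call("function", as.pairlist(fml), bod), baseenv())
  compiler::cmpfun(f)
}

.compile_cache <- new.env(parent = emptyenv())

.model_key <- function(model) {
  paste(c(model$name,
          vapply(model$odes, deparse1, character(1L)),
          vapply(model$outputs, deparse1, character(1L)),
          names(model$constants), model$constants,
          model$parameters$name, model$inputs), collapse = "|")
}

# Compiled RHS, state Jacobian, parameter-derivative and output-derivative
# functions for a model, cached by structural content.
.model_funs <- function(model) {
  key <- .model_key(model)
  hit <- .compile_cache[[key]]
  if (!is.null(hit)) return(hit)
  sn <- model$states$name
  upars <- model$parameters$name[!model$parameters$known]
  args <- c(sn, model$inputs, upars)
  cm <- as.list(model$constants)
  jac_exprs <- .state_jacobian_exprs(model)
  fp_exprs <- list()
  for (p in upars) for (i in sn) {
    fp_exprs[[paste0(i, ".", p)]] <- simplify_expr(d_expr(model$odes[[i]], p))
  }
  gx_exprs <- list()
  for (j in sn) for (o in names(model$outputs)) {
    gx_exprs[[paste0(o, ".", j)]] <- simplify_expr(d_expr(model$outputs[[o]], j))
  }
  gp_exprs <- list()
  for (p in upars) for (o in names(model$outputs)) {
    gp_exprs[[paste0(o, ".", p)]] <- simplify_expr(d_expr(model$outputs[[o]], p))
  }
  funs <- list(
    args = args, n_inputs = length(model$inputs), upars = upars,
    f = .compile_fun(model$odes, args, cm),
    g = .compile_fun(model$outputs, args, cm),
    jac = .compile_fun(jac_exprs, args, cm),
    fp = if (length(fp_exprs)) .compile_fun(fp_exprs, args, cm),
    gx = .compile_fun(gx_exprs, args, cm),
    gp = if (length(gp_exprs)) .compile_fun(gp_exprs, args, cm)
  )
  .compile_cache[[key]] <- funs
  funs
}

#' Simulate an ODE model
#'
#' @param model An [ode_model()].
#' @param theta Named vector of values for [unknown_quantities()] (unknown
#'   initial conditions named `<state>_0`). May be omitted when the model has
#'   none.
#' @param input_signal An [input_constant()] / [input_piecewise_linear()]
#'   signal (or a named list of them for several inputs); `NULL` for
#'   input-free models.
#' @param time_grid Strictly increasing time points; the first is t0.
#' @param tol Requested trajectory accuracy (relative). The solver runs at
#'   `rtol = tol/10`, `atol = tol * 1e-3`: local step-error control
#'   under-represents accumulated global error by roughly that factor.
#' @return An `ode_trajectory`: list with `time`, `states` (matrix), and
#'   `outputs` (matrix).
#' @export
simulate_model <- function(model, theta = NULL, input_signal = NULL,
                           time_grid, tol = 1e-8) {
  model <- substitute_known(model)
  te <- .theta_env(model, theta)
  sig <- .input_list(model, input_signal)
  mf <- .model_funs(model)
  ns <- nrow(model$states)
  snames <- model$states$name
  upars <- mf$upars
  pvals <- as.list(unlist(te$pars[upars]))
  ufuns <- lapply(model$inputs, function(u) sig[[u]]$fun)
  argvals <- function(y, t) {
    c(as.list(y), lapply(ufuns, function(f) f(t)), pvals)
  }
  rhs <- function(t, y, parms) list(do.call(mf$f, argvals(y, t)))
  jac <- function(t, y, parms) {
    matrix(do.call(mf$jac, argvals(y, t)), nrow = ns, ncol = ns)
  }
  sol <- deSolve::ode(y = stats::setNames(te$ics, snames), times = time_grid,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = tol / 10, atol = tol * 1e-3,
                      jacfunc = jac, jactype = "fullusr")
  .check_solution(sol, time_grid)
  st <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  colnames(st) <- snames
  outs <- t(vapply(seq_along(time_grid), function(i) {
    do.call(mf$g, argvals(st[i, ], time_grid[i]))
  }, numeric(length(model$outputs))))
  if (length(model$outputs) == 1L) outs <- matrix(outs, ncol = 1L)
  colnames(outs) <- names(model$outputs)
  structure(list(time = time_grid, states = st, outputs = outs,
                 model_name = model$name),
            class = "ode_trajectory")
}

.input_list <- function(model, input_signal) {
  if (length(model$inputs) == 0L) return(list())
  if (inherits(input_signal, "input_signal")) {
    sig <- stats::setNames(list(input_signal), model$inputs[1L])
  } else {
    sig <- input_signal
  }
  missing <- setdiff(model$inputs, names(sig))
  if (length(missing)) {
    stop(sprintf("no input signal supplied for: %s", paste(missing, collapse = ", ")))
  }
  sig
}

.state_jacobian_exprs <- function(model) {
  sn <- model$states$name
  ex <- list()
  for (j in sn) for (i in sn) {
    ex[[paste0(i, ".", j)]] <- simplify_expr(d_expr(model$odes[[i]], j))
  }
  # column-major (i fastest) to match matrix(..., nrow = ns)
  ord <- as.vector(outer(sn, sn, function(i, j) paste0(i, ".", j)))
  ex[ord]
}

.check_solution <- function(sol, time_grid) {
  if (nrow(sol) < length(time_grid) || anyNA(sol) || any(!is.finite(as.matrix(sol)))) {
    last_t <- if (nrow(sol)) sol[nrow(sol), 1L] else time_grid[1L]
    stop(errorCondition(
      sprintf("ODE integration failed; last successful time %g", last_t),
      class = c("odeident_integration_failure", "odeident_error")
    ))
  }
}

#' Forward sensitivities of states and outputs
#'
#' Integrates the variational system `dS/dt = (df/dx) S + df/dtheta` jointly
#' with the states. `S(t0)` is the derivative of the initial condition: an
#' identity block for unknown initial conditions, zero elsewhere.
#'
#' @inheritParams simulate_model
#' @return A `sensitivity_bundle`: `trajectory`, `state_sens`
#'   (grid x n_states x n_unknowns), `output_sens`
#'   (grid x n_outputs x n_unknowns).
#' @export
sensitivities <- function(model, theta = NULL, input_signal = NULL,
                          time_grid, tol = 1e-8) {
  model <- substitute_known(model)
  te <- .theta_env(model, theta)
  sig <- .input_list(model, input_signal)
  snames <- model$states$name
  ns <- length(snames)
  uic <- unknown_ic_states(model)
  q <- unknown_quantities(model)
  nq <- length(q)
  mf <- .model_funs(model)
  upars <- mf$upars
  no <- length(model$outputs)

  theta_vals <- if (nq) unlist(theta)[q] else numeric()
  pvals <- as.list(unlist(te$pars[upars]))
  ufuns <- lapply(model$inputs, function(u) sig[[u]]$fun)
  argvals <- function(y, t) {
    c(as.list(y), lapply(ufuns, function(f) f(t)), pvals)
  }

  S0 <- matrix(0, ns, nq, dimnames = list(snames, q))
  for (s in uic) S0[s, paste0(s, "_0")] <- 1

  rhs <- function(t, y, parms) {
    x <- y[seq_len(ns)]
    S <- matrix(y[-seq_len(ns)], ns, nq)
    av <- argvals(x, t)
    fx <- matrix(do.call(mf$jac, av), ns, ns)
    dS <- fx %*% S
    if (length(upars)) {
      dS[, seq_along(upars)] <- dS[, seq_along(upars)] +
        matrix(do.call(mf$fp, av), ns, length(upars))
    }
    list(c(do.call(mf$f, av), as.vector(dS)))
  }
  y0 <- c(stats::setNames(te$ics, snames), as.vector(S0))
  sol <- deSolve::ode(y = y0, times = time_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = tol / 10, atol = tol * 1e-3)
  .check_solution(sol, time_grid)
  st <- unname(as.matrix(sol[, 1L + seq_len(ns), drop = FALSE]))
  colnames(st) <- snames
  nt <- length(time_grid)
  state_sens <- array(as.matrix(sol[, -seq_len(1L + ns), drop = FALSE]),
                      dim = c(nt, ns, nq),
                      dimnames = list(NULL, snames, q))
  output_sens <- array(0, dim = c(nt, no, nq),
                       dimnames = list(NULL, names(model$outputs), q))
  outs <- matrix(0, nt, no, dimnames = list(NULL, names(model$outputs)))
  for (ti in seq_len(nt)) {
    av <- argvals(st[ti, ], time_grid[ti])
    outs[ti, ] <- do.call(mf$g, av)
    Gx <- matrix(do.call(mf$gx, av), no, ns)
    S <- matrix(state_sens[ti, , ], ns, nq)
    os <- Gx %*% S
    if (length(upars)) {
      Gp <- matrix(do.call(mf$gp, av), no, length(upars))
      os[, seq_along(upars)] <- os[, seq_along(upars)] + Gp
    }
    output_sens[ti, , ] <- os
  }
  traj <- structure(list(time = time_grid, states = st, outputs = outs,
                         model_name = model$name),
                    class = "ode_trajectory")
  structure(list(trajectory = traj, state_sens = state_sens,
                 output_sens = output_sens, quantities = q,
                 theta = theta_vals),
            class = "sensitivity_bundle")
}

# Seed-local RNG evaluation (leaves the caller's RNG stream untouched).
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Generate a synthetic noisy observation table
#'
#' Simulates the model and adds seeded Gaussian noise to the measured
#' outputs: additive (`sd = sigma`) or relative (`sd = sigma * |y|`).
#'
#' @inheritParams simulate_model
#' @param theta_true True values of the unknown quantities.
#' @param noise List with `kind` (`"additive"` or `"relative"`) and `sigma`
#'   (scalar or named per output); `sigma = 0` returns noise-free outputs.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param outputs Outputs to include (default: all).
#' @return A tibble with a `time` column and one column per output.
#' @export
generate_synthetic_data <- function(model, theta_true = NULL,
                                    input_signal = NULL, time_grid,
                                    noise = list(kind = "additive", sigma = 0),
                                    seed = 1, outputs = NULL) {
  traj <- simulate_model(model, theta_true, input_signal, time_grid)
  outs <- outputs %||% colnames(traj$outputs)
  y <- traj$outputs[, outs, drop = FALSE]
  sigma <- noise$sigma %||% 0
  if (is.null(names(sigma))) {
    sigma <- stats::setNames(rep(sigma, length.out = length(outs)), outs)
  }
  kind <- noise$kind %||% "additive"
  y_noisy <- .with_seed(seed, {
    yn <- y
    for (o in outs) {
      sd_o <- if (kind == "relative") sigma[[o]] * abs(y[, o]) else
        rep(sigma[[o]], nrow(y))
      yn[, o] <- y[, o] + stats::rnorm(nrow(y), 0, sd_o)
    }
    yn
  })
  tibble::as_tibble(cbind(data.frame(time = time_grid), as.data.frame(y_noisy)))
}

#' @export
print.ode_trajectory <- function(x, ...) {
  cat(sprintf("<ode_trajectory> %s: %d time points, %d states, %d outputs\n",
              x$model_name, length(x$time), ncol(x$states), ncol(x$outputs)))
  invisible(x)
}

#' Trajectory as a tibble
#' @param x An `ode_trajectory`.
#' @param ... Unused.
#' @export
as_tibble.ode_trajectory <- function(x, ...) {
  tibble::as_tibble(cbind(data.frame(time = x$time),
                          as.data.frame(x$states),
                          as.data.frame(x$outputs)[setdiff(colnames(x$outputs),
                                                           colnames(x$states))]))
}
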