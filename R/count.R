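# Exact counting of output-equivalent parameter sets on small models, in the
# spirit of differential-algebra identifiability software: the first Taylor
# coefficients of every measured output at t = 0 are equated between a random
# rational reference parameterization and a free one, and the resulting
# square/overdetermined system is solved over the admissible (positive real)
# region. Root finding is dense multistart Gauss-Newton with residual
# certification; an unstable or empty solution set raises the
# "symbolic-failure" flag rather than returning a silent wrong count.

#' Count output-equivalent parameter sets of a small model
#'
#' @param model An [ode_model()] with at most 4 unknown quantities and 3
#'   states (guard for exact solvability).
#' @param setup An [observation_setup()]; defaults to all outputs measured
#'   with constant inputs. Input-derivative indeterminates are not supported
#'   here, so `generic_smooth` is treated as `constant`.
#' @param taylor_order Number of Taylor coefficients matched per output
#'   (default `n_unknowns + 2`, must be `>= n_unknowns`).
#' @param n_starts Multistart points per batch (two independent batches are
#'   run; disagreement on the count raises the failure flag).
#' @param seed Integer seed (reference point and starts).
#' @return List with `count` (non-negative integer, or `NA` on failure),
#'   `status` (`"ok"` or `"symbolic-failure"`), `witnesses` (list of named
#'   parameter vectors, one per distinct solution), `reference` (the true
#'   parameterization used), `taylor_order`.
#' @export
count_output_equivalent_params <- function(model, setup = NULL,
                                           taylor_order = NULL,
                                           n_starts = 150, seed = 29) {
  model <- substitute_known(model)
  if (is.null(setup)) {
    setup <- observation_setup(names(model$outputs), input_class = "constant")
  }
  setup$input_class <- "constant"
  model <- apply_setup(model, setup)
  setup$known_ic_overrides <- list()
  q <- unknown_quantities(model)
  nq <- length(q)
  if (nq > 4L || nrow(model$states) > 3L) {
    stop(errorCondition(
      sprintf("model too large for exact solution counting (%d unknowns, %d states; guard: <= 4, <= 3)",
              nq, nrow(model$states)),
      class = c("odeident_guard", "odeident_error")
    ))
  }
  if (is.null(taylor_order)) taylor_order <- nq + 2L
  if (taylor_order < nq) stop("taylor_order must be >= n_unknowns")

  lie <- lie_derivatives(model, setup, taylor_order - 1L)

  upars <- model$parameters$name[!model$parameters$known]
  uic <- unknown_ic_states(model)
  kics <- model$states[model$states$ic_known, , drop = FALSE]
  base <- list2env(c(as.list(model$constants),
                     stats::setNames(as.list(kics$ic_value), kics$name)),
                   parent = baseenv())
  if (length(model$inputs)) {
    stop("solution counting requires an input-free model (fold inputs into constants)")
  }
  coeffs <- function(theta) {
    ev <- list2env(as.list(theta[upars]), parent = base)
    for (s in uic) assign(s, theta[[paste0(s, "_0")]], envir = ev)
    vapply(lie, function(e) eval(e, ev), numeric(1L))
  }

  res <- .with_seed(seed, {
    # random rational reference point: num/den with small terms, distinct
    ref <- stats::setNames(sample(3:19, nq, replace = TRUE) /
                             sample(2:6, nq, replace = TRUE), q)
    while (anyDuplicated(ref)) {
      ref <- stats::setNames(sample(3:19, nq, replace = TRUE) /
                               sample(2:6, nq, replace = TRUE), q)
    }
    c_ref <- coeffs(ref)
    scale <- 1 + abs(c_ref)
    Ffun <- function(th) (coeffs(th) - c_ref) / scale

    solve_batch <- function(batch_seed) {
      set.seed(batch_seed)
      lo <- log(ref / 30)
      span <- log(30^2)
      starts <- rbind(log(ref),
                      matrix(stats::runif((n_starts - 1L) * nq), ncol = nq) *
                        span + rep(lo, each = n_starts - 1L))
      sols <- list()
      for (i in seq_len(nrow(starts))) {
        th <- .polish_root(Ffun, starts[i, ], q)
        if (!is.null(th)) sols[[length(sols) + 1L]] <- th
      }
      .cluster_roots(sols)
    }
    a <- solve_batch(seed * 3L + 1L)
    b <- solve_batch(seed * 5L + 2L)
    list(ref = ref, a = a, b = b)
  })

  ok <- length(res$a) > 0L && length(res$a) == length(res$b)
  if (ok) {
    # the two batches must find the same solution set, not just the same count
    for (v in res$a) {
      if (!any(vapply(res$b, function(w)
        max(abs(log(w) - log(v))) < 1e-4, logical(1L)))) {
        ok <- FALSE
        break
      }
    }
  }
  if (!ok) {
    return(list(count = NA_integer_, status = "symbolic-failure",
                witnesses = list(), reference = res$ref,
                taylor_order = taylor_order))
  }
  wit <- lapply(res$a, function(v) stats::setNames(v, q))
  list(count = length(wit), status = "ok", witnesses = wit,
       reference = res$ref, taylor_order = taylor_order)
}

# Gauss-Newton in log-space with numeric Jacobian; returns the positive root
# or NULL. Certification: scaled residual sup-norm < 1e-9.
.polish_root <- function(Ffun, lth, qnames) {
  nq <- length(lth)
  for (it in 1:60) {
    th <- exp(lth)
    Fv <- tryCatch(Ffun(stats::setNames(th, qnames)), error = function(e) NULL)
    if (is.null(Fv) || any(!is.finite(Fv))) return(NULL)
    if (max(abs(Fv)) < 1e-11) break
    J <- matrix(0, length(Fv), nq)
    h <- 1e-6
    for (j in seq_len(nq)) {
      lp <- lth; lp[j] <- lp[j] + h
      lm <- lth; lm[j] <- lm[j] - h
      Fp <- tryCatch(Ffun(stats::setNames(exp(lp), qnames)), error = function(e) NULL)
      Fm <- tryCatch(Ffun(stats::setNames(exp(lm), qnames)), error = function(e) NULL)
      if (is.null(Fp) || is.null(Fm)) return(NULL)
      J[, j] <- (Fp - Fm) / (2 * h)
    }
    step <- tryCatch(
      qr.solve(rbind(J, diag(1e-10, nq)), c(-Fv, numeric(nq))),
      error = function(e) NULL
    )
    if (is.null(step)) return(NULL)
    # damped update with simple backtracking
    lam <- 1
    f0 <- sum(Fv^2)
    repeat {
      lnew <- lth + lam * step
      if (max(abs(lnew)) > 25) { lam <- lam / 2 } else {
        Fn <- tryCatch(Ffun(stats::setNames(exp(lnew), qnames)),
                       error = function(e) NULL)
        if (!is.null(Fn) && all(is.finite(Fn)) && sum(Fn^2) < f0) break
        lam <- lam / 2
      }
      if (lam < 1e-6) return(NULL)
    }
    lth <- lth + lam * step
  }
  th <- exp(lth)
  Fv <- tryCatch(Ffun(stats::setNames(th, qnames)), error = function(e) NULL)
  if (is.null(Fv) || max(abs(Fv)) > 1e-9) return(NULL)
  th
}

.cluster_roots <- function(sols, tol = 1e-5) {
  reps <- list()
  for (s in sols) {
    hit <- FALSE
    for (j in seq_along(reps)) {
      if (max(abs(log(s) - log(reps[[j]]))) < tol * 10) {
        hit <- TRUE
        break
      }
    }
    if (!hit) reps[[length(reps) + 1L]] <- s
  }
  reps
}
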