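# Local structural identifiability / observability via the rank of the
# Jacobian of stacked output Lie derivatives with respect to (states, unknown
# parameters). Known initial conditions enter as extra unit rows (an output
# observed at t = 0), so the reported generic rank and null space live on the
# unknown-quantity vector (unknown parameters, then unknown-IC states).

#' Describe an observation scenario
#'
#' @param measured_outputs Non-empty subset of the model's output names.
#' @param known_ic_overrides Named list overriding initial-condition status:
#'   a number marks the state's IC known at that value, `NA` marks it unknown.
#' @param input_class `"generic_smooth"` (inputs may vary freely; their time
#'   derivatives enter as independent indeterminates), `"constant"` (input
#'   derivatives vanish), or `"none"`.
#' @return An `observation_setup` object.
#' @export
observation_setup <- function(measured_outputs,
                              known_ic_overrides = list(),
                              input_class = c("generic_smooth", "constant", "none")) {
  input_class <- match.arg(input_class)
  stopifnot(length(measured_outputs) >= 1L)
  structure(
    list(measured_outputs = as.character(measured_outputs),
         known_ic_overrides = known_ic_overrides,
         input_class = input_class),
    class = "observation_setup"
  )
}

# Apply a setup's IC overrides and check output names.
apply_setup <- function(model, setup) {
  bad <- setdiff(setup$measured_outputs, names(model$outputs))
  if (length(bad)) {
    stop(sprintf("measured output(s) not in model '%s': %s",
                 model$name, paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(setup$known_ic_overrides), model$states$name)
  if (length(bad)) {
    stop(sprintf("IC override(s) for undeclared state(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (length(setup$known_ic_overrides)) {
    model <- do.call(set_ic, c(list(model), setup$known_ic_overrides))
  }
  model
}

input_deriv_symbol <- function(input, j) {
  if (j == 0L) input else sprintf("%s__d%d", input, j)
}

# One Lie-derivative step: dL/dt along the vector field, with input
# derivatives chained according to the input class.
lie_step <- function(L, model, input_class, max_u_order) {
  acc <- 0
  for (i in seq_len(nrow(model$states))) {
    s <- model$states$name[i]
    dLds <- d_expr(L, s)
    if (!identical(dLds, 0)) {
      acc <- call("+", acc, call("*", dLds, model$odes[[s]]))
    }
  }
  if (input_class == "generic_smooth") {
    for (u in model$inputs) {
      for (j in 0:max_u_order) {
        uj <- input_deriv_symbol(u, j)
        dLdu <- d_expr(L, uj)
        if (!identical(dLdu, 0)) {
          acc <- call("+", acc,
                      call("*", dLdu, as.symbol(input_deriv_symbol(u, j + 1L))))
        }
      }
    }
  }
  simplify_expr(acc)
}

#' Stacked Lie derivatives of the measured outputs
#'
#' Computes `L^0 h, ..., L^order h` for every measured output `h`, where
#' `L^{j+1} h` is the total time derivative of `L^j h` along the ODE vector
#' field (with input time-derivative symbols `u__d1, u__d2, ...` introduced
#' under the `generic_smooth` input class).
#'
#' @param model An [ode_model()] (known parameters are folded first).
#' @param setup An [observation_setup()].
#' @param order Highest derivative order (>= 0).
#' @param node_budget Abort with a budget-exceeded error if any single
#'   derivative expression exceeds this node count.
#' @return Named list of expressions, stacked order-major
#'   (`"y|0", "z|0", "y|1", ...`).
#' @export
lie_derivatives <- function(model, setup, order, node_budget = 2e5) {
  stopifnot(order >= 0)
  model <- apply_setup(substitute_known(model), setup)
  h <- model$outputs[setup$measured_outputs]
  out <- list()
  cur <- h
  for (j in 0:order) {
    for (nm in names(cur)) {
      if (expr_size(cur[[nm]]) > node_budget) {
        stop(errorCondition(
          sprintf("Lie derivative order %d of '%s' exceeds the node budget (%g)",
                  j, nm, node_budget),
          class = c("odeident_budget_exceeded", "odeident_error")
        ))
      }
      out[[sprintf("%s|%d", nm, j)]] <- cur[[nm]]
    }
    if (j < order) {
      cur <- lapply(cur, lie_step, model = model,
                    input_class = setup$input_class, max_u_order = j)
    }
  }
  out
}

# Random integer evaluation point in [1, 999] for every free symbol.
.structural_point <- function(syms, rng) {
  stats::setNames(floor(rng(length(syms)) * 999) + 1, syms)
}

#' Test local structural identifiability by the observability rank condition
#'
#' Builds the Jacobian of the stacked Lie derivatives with respect to (all
#' states, unknown parameters), appends one unit row per known initial
#' condition, and evaluates it at `n_points` random integer points in exact
#' arithmetic over a prime field. The derivative order is increased until the
#' rank is unchanged for one extra order, capped at
#' `n_states + n_unknowns - 1`. A quantity is locally identifiable iff
#' deleting its column strictly decreases the rank.
#'
#' @param model An [ode_model()].
#' @param setup An [observation_setup()].
#' @param max_order Cap on the Lie-derivative order (default
#'   `n_states + n_unknowns - 1`).
#' @param n_points Number of random evaluation points (rank disagreements are
#'   reported as warnings in the result, never averaged).
#' @param seed Integer seed for the evaluation points.
#' @param node_budget Passed to [lie_derivatives()].
#' @return A `structural_result` with fields `generic_rank`, `n_unknowns`,
#'   `per_quantity_verdict`, `nullspace_basis`, `evaluation_points_used`,
#'   `seed`, `orders_used`, `warnings`.
#' @export
test_local_identifiability <- function(model, setup, max_order = NULL,
                                       n_points = 3, seed = 17,
                                       node_budget = 2e5) {
  model <- apply_setup(substitute_known(model), setup)
  setup$known_ic_overrides <- list()  # already applied

  states <- model$states$name
  upars <- model$parameters$name[!model$parameters$known]
  uic <- unknown_ic_states(model)
  kic <- model$states$name[model$states$ic_known]
  quantities <- c(upars, if (length(uic)) paste0(uic, "_0"))
  n_unknowns <- length(quantities)
  zcols <- c(states, upars)
  qcol <- c(match(upars, zcols), match(uic, zcols))
  names(qcol) <- quantities
  if (is.null(max_order)) max_order <- length(states) + n_unknowns - 1L
  max_order <- max(max_order, 1L)

  warnings <- character()
  const_res <- lapply(as.list(model$constants), gf_const)

  # every symbol a point must cover: states, unknown parameters, inputs and
  # their time-derivative indeterminates up to the order cap
  free_syms <- c(states, upars, model$inputs,
                 unlist(lapply(model$inputs, function(u) {
                   vapply(seq_len(max_order + 1L), function(j)
                     input_deriv_symbol(u, j), character(1L))
                 })))

  set.seed(seed)
  points <- lapply(seq_len(n_points), function(i)
    .structural_point(free_syms, stats::runif))
  memos <- lapply(points, function(p)
    gf_memo(floor(sum(p * seq_along(p))) %% 2147483000 + 1))

  eval_row_gf <- function(row_exprs, point, memo, subs = NULL) {
    env <- c(as.list(vapply(point, gf_const, numeric(1L))), const_res)
    if (!is.null(subs)) env[names(subs)] <- lapply(subs, gf_const)
    vapply(row_exprs, function(e) {
      if (is.numeric(e)) gf_const(e) else gf_eval(e, env, memo)
    }, numeric(1L))
  }

  n_unit <- length(kic)
  unit_block <- if (n_unit) {
    t(vapply(match(kic, zcols), function(i) {
      r <- numeric(length(zcols)); r[i] <- 1; r
    }, numeric(length(zcols))))
  }

  # grow the Lie stack order by order; stop when every point's rank is
  # unchanged for one extra order
  cur <- model$outputs[setup$measured_outputs]
  jac_rows <- list()
  mats <- lapply(seq_len(n_points), function(i) unit_block)
  ranks_full <- rep(-1L, n_points)
  orders_used <- 0L
  for (k in 0:max_order) {
    for (nm in names(cur)) {
      if (expr_size(cur[[nm]]) > node_budget) {
        stop(errorCondition(
          sprintf("Lie derivative order %d of '%s' exceeds the node budget (%g)",
                  k, nm, node_budget),
          class = c("odeident_budget_exceeded", "odeident_error")
        ))
      }
      row <- lapply(zcols, function(z) simplify_expr(d_expr(cur[[nm]], z)))
      jac_rows[[sprintf("%s|%d", nm, k)]] <- row
      for (i in seq_len(n_points)) {
        mats[[i]] <- rbind(mats[[i]],
                           eval_row_gf(row, points[[i]], memos[[i]]))
      }
    }
    r_new <- vapply(mats, gf_rank, integer(1L))
    orders_used <- k
    if (all(r_new == ranks_full) || all(r_new == length(zcols))) {
      ranks_full <- r_new
      break
    }
    ranks_full <- r_new
    if (k < max_order) {
      cur <- lapply(cur, lie_step, model = model,
                    input_class = setup$input_class, max_u_order = k)
    }
  }

  if (length(unique(ranks_full)) > 1L) {
    warnings <- c(warnings, sprintf(
      "rank disagreement across evaluation points (%s); using the maximum",
      paste(ranks_full, collapse = ", ")))
  }
  best <- which.max(ranks_full)
  r_full <- ranks_full[best]
  M <- mats[[best]]
  generic_rank <- r_full - length(kic)

  verdicts <- vapply(quantities, function(q) {
    r_del <- gf_rank(M[, -qcol[[q]], drop = FALSE])
    if (r_del < r_full) "locally_identifiable" else "non_identifiable"
  }, character(1L))

  # diagnostic: rank at the specific numeric known ICs
  if (length(kic)) {
    ics <- stats::setNames(model$states$ic_value[model$states$ic_known], kic)
    M_ic <- tryCatch({
      memo_ic <- gf_memo(4242L)
      rbind(unit_block,
            t(vapply(jac_rows, function(r)
              eval_row_gf(r, points[[best]], memo_ic, subs = as.list(ics)),
              numeric(length(zcols)))))
    }, odeident_error = function(e) NULL)
    if (!is.null(M_ic)) {
      r_ic <- gf_rank(M_ic)
      if (r_ic < r_full) {
        warnings <- c(warnings, sprintf(
          "rank drops from %d to %d at the specific known initial conditions; these ICs may destroy identifiability",
          r_full, r_ic))
      }
    }
  }

  # null-space presentation: exact nullity from the GF rank; the basis is
  # computed in double precision at a moderate random point (better
  # conditioned than the large integer rank points)
  null_point <- stats::setNames(stats::runif(length(free_syms), 1, 3), free_syms)
  nullity <- length(zcols) - r_full
  nullspace <- .nullspace_at_point(jac_rows, zcols, kic, model, null_point,
                                   qcol, quantities, nullity)

  structure(
    list(generic_rank = generic_rank,
         n_unknowns = n_unknowns,
         per_quantity_verdict = verdicts,
         nullspace_basis = nullspace,
         evaluation_points_used = n_points,
         seed = seed,
         orders_used = max(orders_used),
         rank_with_ic_rows = r_full,
         quantities = quantities,
         evaluation_point = null_point,
         rank_points = points,
         warnings = warnings,
         model_name = model$name,
         measured_outputs = setup$measured_outputs),
    class = "structural_result"
  )
}

# Null space of the (double-precision) Jacobian at the given point,
# projected on the unknown-quantity coordinates and canonicalized by RREF;
# entries are scaled to smallest-integer form when a small rational form
# exists. The nullity itself comes from the exact GF-rank computation.
.nullspace_at_point <- function(jac_rows, zcols, kic, model, point, qcol,
                                quantities, nullity) {
  if (nullity == 0L) return(list())
  env <- list2env(c(as.list(point), as.list(model$constants)), parent = baseenv())
  Md <- t(vapply(jac_rows, function(r) {
    vapply(r, function(e) eval(e, env), numeric(1L))
  }, numeric(length(zcols))))
  if (length(kic)) {
    Md <- rbind(Md, t(vapply(match(kic, zcols), function(i) {
      r <- numeric(length(zcols)); r[i] <- 1; r
    }, numeric(length(zcols)))))
  }
  # unit row norms: rescaling rows leaves the null space unchanged
  rn <- sqrt(rowSums(Md^2))
  Md <- Md / pmax(rn, 1e-300)
  V <- svd(Md, nv = ncol(Md))$v
  N <- V[, seq.int(ncol(Md) - nullity + 1L, ncol(Md)), drop = FALSE]
  # project on unknown-quantity coordinates
  N <- N[qcol, , drop = FALSE]
  # RREF canonicalization of t(N)
  B <- t(N)
  lead <- 1L
  for (r in seq_len(nrow(B))) {
    piv <- which(abs(B[r, ]) > 1e-8)
    if (!length(piv)) next
    # use the largest entry as pivot for stability, then re-sort by support
    piv <- piv[which.max(abs(B[r, piv]))]
    B[r, ] <- B[r, ] / B[r, piv]
    for (r2 in seq_len(nrow(B))) {
      if (r2 != r) B[r2, ] <- B[r2, ] - B[r2, piv] * B[r, ]
    }
  }
  basis <- lapply(seq_len(nrow(B)), function(r) {
    v <- B[r, ]
    v[abs(v) < 1e-8] <- 0
    v <- .smallest_integer_form(v)
    stats::setNames(v, quantities)
  })
  basis
}

# Scale a vector so that, when its entries admit small rational
# approximations, it becomes a coprime integer vector.
.smallest_integer_form <- function(v, max_den = 999L) {
  nz <- v[v != 0]
  if (!length(nz)) return(v)
  v <- v / nz[which.max(abs(nz))]
  dens <- integer(length(v))
  ok <- TRUE
  for (i in seq_along(v)) {
    if (v[i] == 0) { dens[i] <- 1L; next }
    f <- .as_fraction(v[i], max_den)
    if (is.null(f)) { ok <- FALSE; break }
    dens[i] <- f[2L]
  }
  if (!ok) return(v)
  L <- Reduce(.lcm, dens)
  w <- round(v * L)
  g <- Reduce(.gcd, abs(w[w != 0]))
  if (g > 0) w <- w / g
  if (sum(w < 0) > sum(w > 0)) w <- -w
  w
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
.lcm <- function(a, b) a / .gcd(a, b) * b

.as_fraction <- function(x, max_den) {
  for (den in seq_len(max_den)) {
    num <- round(x * den)
    if (abs(num / den - x) < 1e-7 * max(1, abs(x))) return(c(num, den))
  }
  NULL
}

#' Null-space directions of a structural result
#'
#' Basis of the Lie-derivative Jacobian null space at the evaluation point,
#' restricted to the unknown-quantity coordinates; each vector is scaled to
#' smallest-integer form where possible. Vectors span the locally
#' compensable parameter directions. Full-rank results give an empty list.
#'
#' @param result A `structural_result`.
#' @return List of named numeric vectors.
#' @export
nullspace_directions <- function(result) {
  stopifnot(inherits(result, "structural_result"))
  result$nullspace_basis
}

#' @export
print.structural_result <- function(x, ...) {
  cat(sprintf("<structural_result> %s (outputs: %s)\n", x$model_name,
              paste(x$measured_outputs, collapse = ", ")))
  cat(sprintf("  generic rank %d of %d unknowns (Lie orders used: %d)\n",
              x$generic_rank, x$n_unknowns, x$orders_used))
  for (q in names(x$per_quantity_verdict)) {
    cat(sprintf("  %-10s %s\n", q, x$per_quantity_verdict[[q]]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
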