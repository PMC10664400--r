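# ode_model: symbolic representation of a nonlinear ODE system
#   dx/dt = f(x, u, p),  y = g(x, u, p),  x(0) = x0(p)
# States and parameters carry a known/unknown status; unknown initial
# conditions join the unknown parameters in one augmented quantity vector
# (parameters first, then unknown-IC states) used by every analysis module.

#' Construct an ODE model
#'
#' @param name Model identifier.
#' @param states Data frame with columns `name`, `ic_known` (logical),
#'   `ic_value` (numeric, `NA` where the initial condition is unknown).
#' @param parameters Data frame with columns `name`, `known` (logical),
#'   `value` (numeric, `NA` where unknown).
#' @param inputs Character vector of input (forcing) names.
#' @param constants Named numeric vector of fixed known constants.
#' @param odes Named list (one entry per state, same order) of right-hand-side
#'   expressions, given as strings or language objects.
#' @param outputs Named non-empty list of output expressions.
#' @param metadata Free-form list (units, nominal values, notes).
#' @return An object of class `ode_model`.
#' @examples
#' m <- ode_model(
#'   "decay",
#'   states = data.frame(name = "x", ic_known = TRUE, ic_value = 1),
#'   parameters = data.frame(name = "k", known = FALSE, value = NA),
#'   odes = list(x = "-k*x"), outputs = list(y = "x")
#' )
#' unknown_quantities(m)
#' @export
ode_model <- function(name, states, parameters = NULL, inputs = character(),
                      constants = numeric(), odes, outputs, metadata = list()) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  if (is.null(states$ic_value)) states$ic_value <- NA_real_
  states$ic_value <- as.numeric(states$ic_value)
  if (is.null(parameters) || nrow(as.data.frame(parameters)) == 0L) {
    parameters <- data.frame(name = character(), known = logical(),
                             value = numeric(), stringsAsFactors = FALSE)
  } else {
    parameters <- as.data.frame(parameters, stringsAsFactors = FALSE)
    if (is.null(parameters$value)) parameters$value <- NA_real_
    parameters$value <- as.numeric(parameters$value)
  }
  constants <- unlist(constants)
  if (is.null(names(constants))) names(constants) <- character(length(constants))

  as_lang <- function(x) if (is.character(x)) parse_expr(x) else simplify_expr(x)
  odes <- lapply(odes, as_lang)
  outputs <- lapply(outputs, as_lang)

  m <- structure(
    list(name = name, states = states, parameters = parameters,
         inputs = as.character(inputs), constants = constants,
         odes = odes, outputs = outputs, metadata = metadata),
    class = "ode_model"
  )
  validate_model(m)
}

validate_model <- function(m) {
  dup <- function(x) x[duplicated(x)]
  all_names <- c(m$states$name, m$parameters$name, m$inputs, names(m$constants))
  if (length(dup(all_names)) > 0L) {
    stop(errorCondition(
      sprintf("duplicate declaration of '%s'", dup(all_names)[1L]),
      class = c("odeident_duplicate_name", "odeident_error")
    ))
  }
  if (!setequal(names(m$odes), m$states$name) ||
      length(m$odes) != nrow(m$states)) {
    stop(errorCondition("odes must have exactly one entry per state",
                        class = c("odeident_invalid_model", "odeident_error")))
  }
  m$odes <- m$odes[m$states$name]
  if (length(m$outputs) == 0L) {
    stop(errorCondition("output map must be non-empty",
                        class = c("odeident_invalid_model", "odeident_error")))
  }
  if (any(m$parameters$known & is.na(m$parameters$value))) {
    stop(errorCondition("known parameters need a value",
                        class = c("odeident_invalid_model", "odeident_error")))
  }
  if (any(m$states$ic_known & is.na(m$states$ic_value))) {
    stop(errorCondition("known initial conditions need a value",
                        class = c("odeident_invalid_model", "odeident_error")))
  }
  for (e in c(m$odes, m$outputs)) {
    for (s in expr_symbols(e)) {
      if (!s %in% all_names) {
        stop(errorCondition(
          sprintf("undeclared symbol '%s' in model '%s'", s, m$name),
          class = c("odeident_undeclared_symbol", "odeident_error")
        ))
      }
    }
  }
  m
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model> %s\n", x$name))
  ics <- ifelse(x$states$ic_known,
                sprintf("%s(0)=%g", x$states$name, x$states$ic_value),
                sprintf("%s(0) unknown", x$states$name))
  cat("  states:    ", paste(ics, collapse = ", "), "\n")
  pp <- if (nrow(x$parameters)) {
    ifelse(x$parameters$known,
           sprintf("%s=%g", x$parameters$name, x$parameters$value),
           x$parameters$name)
  } else "(none)"
  cat("  parameters:", paste(pp, collapse = ", "), "\n")
  if (length(x$inputs)) cat("  inputs:    ", paste(x$inputs, collapse = ", "), "\n")
  if (length(x$constants)) {
    cat("  constants: ",
        paste(sprintf("%s=%g", names(x$constants), x$constants), collapse = ", "), "\n")
  }
  for (s in x$states$name) {
    cat(sprintf("  d%s/dt = %s\n", s, deparse1(x$odes[[s]])))
  }
  for (o in names(x$outputs)) {
    cat(sprintf("  %s = %s\n", o, deparse1(x$outputs[[o]])))
  }
  invisible(x)
}

#' Augmented unknown-quantity vector of a model
#'
#' Unknown parameters in declaration order, then states with unknown initial
#' conditions (named `<state>_0`). This ordering indexes every Jacobian,
#' Fisher-information and sensitivity array in the package.
#'
#' @param model An `ode_model`.
#' @return Character vector of quantity names.
#' @export
unknown_quantities <- function(model) {
  pars <- model$parameters$name[!model$parameters$known]
  ics <- model$states$name[!model$states$ic_known]
  c(pars, if (length(ics)) paste0(ics, "_0"))
}

unknown_ic_states <- function(model) model$states$name[!model$states$ic_known]

#' Parse a model from its JSON definition
#'
#' The schema is `{"name", "states": [{"name", "ic": {"known", "value"?}}],
#' "parameters": [{"name", "known", "value"?}], "inputs": [..],
#' "constants": {..}, "odes": {state: expr}, "outputs": {name: expr}}` with
#' expressions as strings under the model grammar.
#'
#' @param text JSON string, or the path of a `.json` file.
#' @return A validated [ode_model()].
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && !grepl("{", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  j <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  states <- do.call(rbind, lapply(j$states, function(s) {
    data.frame(name = s$name, ic_known = isTRUE(s$ic$known),
               ic_value = if (is.null(s$ic$value)) NA_real_ else s$ic$value)
  }))
  parameters <- if (length(j$parameters)) {
    do.call(rbind, lapply(j$parameters, function(p) {
      data.frame(name = p$name, known = isTRUE(p$known),
                 value = if (is.null(p$value)) NA_real_ else p$value)
    }))
  }
  ode_model(
    name = j$name, states = states, parameters = parameters,
    inputs = unlist(j$inputs) %||% character(),
    constants = unlist(j$constants) %||% numeric(),
    odes = j$odes, outputs = j$outputs,
    metadata = .simplify_meta(j$metadata %||% list())
  )
}

# collapse unnamed lists of scalars back to atomic vectors so that
# serialize -> parse -> serialize is the identity
.simplify_meta <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, .simplify_meta)
  if (length(x) && is.null(names(x)) &&
      all(vapply(x, function(e) is.atomic(e) && length(e) == 1L, logical(1L)))) {
    return(unlist(x))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a model to canonical JSON
#'
#' Round-trips with [parse_model()]: `model_to_json(parse_model(text))` is the
#' canonical form of `text`.
#'
#' @param model An `ode_model`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
model_to_json <- function(model, path = NULL) {
  st <- lapply(seq_len(nrow(model$states)), function(i) {
    s <- model$states[i, ]
    ic <- if (s$ic_known) list(known = TRUE, value = s$ic_value) else list(known = FALSE)
    list(name = s$name, ic = ic)
  })
  pa <- lapply(seq_len(nrow(model$parameters)), function(i) {
    p <- model$parameters[i, ]
    if (p$known) list(name = p$name, known = TRUE, value = p$value)
    else list(name = p$name, known = FALSE)
  })
  obj <- list(
    name = model$name, states = st, parameters = pa,
    inputs = as.list(model$inputs),
    constants = as.list(model$constants),
    odes = lapply(model$odes, deparse1),
    outputs = lapply(model$outputs, deparse1),
    metadata = model$metadata
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Fold known parameters and initial conditions into constants
#'
#' Parameters with a known value are moved into the constants map, so the
#' unknown-quantity vector shrinks accordingly. Idempotent.
#'
#' @param model An `ode_model`.
#' @return A validated `ode_model` whose parameter table only contains
#'   unknown parameters.
#' @export
substitute_known <- function(model) {
  kn <- model$parameters$known
  if (!any(kn)) return(model)
  add <- stats::setNames(model$parameters$value[kn], model$parameters$name[kn])
  model$constants <- c(model$constants, add)
  model$parameters <- model$parameters[!kn, , drop = FALSE]
  rownames(model$parameters) <- NULL
  validate_model(model)
}

#' Mark parameters as known or unknown
#'
#' @param model An `ode_model`.
#' @param ... Named values: `set_known(m, kI = 1)` marks `kI` known with value
#'   1; `set_known(m, kI = NA)` reverts it to unknown.
#' @return The updated model.
#' @export
set_known <- function(model, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    i <- match(nm, model$parameters$name)
    if (is.na(i)) stop(sprintf("no parameter '%s' in model '%s'", nm, model$name))
    if (is.na(vals[[nm]])) {
      model$parameters$known[i] <- FALSE
      model$parameters$value[i] <- NA_real_
    } else {
      model$parameters$known[i] <- TRUE
      model$parameters$value[i] <- as.numeric(vals[[nm]])
    }
  }
  model
}

#' Set initial-condition status of states
#'
#' @param model An `ode_model`.
#' @param ... Named values: a number marks the IC known at that value, `NA`
#'   marks it unknown.
#' @return The updated model.
#' @export
set_ic <- function(model, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    i <- match(nm, model$states$name)
    if (is.na(i)) stop(sprintf("no state '%s' in model '%s'", nm, model$name))
    if (is.na(vals[[nm]])) {
      model$states$ic_known[i] <- FALSE
      model$states$ic_value[i] <- NA_real_
    } else {
      model$states$ic_known[i] <- TRUE
      model$states$ic_value[i] <- as.numeric(vals[[nm]])
    }
  }
  model
}
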