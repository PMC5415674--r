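#' Create an empty model
#'
#' A model is the full collection of signals, operators and probes for one
#' simulation, plus the timestep. Build it incrementally with
#' [add_signal()], [add_operator()] and [add_probe()].
#'
#' @param dt Simulation timestep in seconds. Defaults to 0.001 s, so 1,000
#'   steps correspond to one second of simulated time.
#' @return An object of class `nef_model`.
#' @export
#' @examples
#' m <- nef_model()
#' m <- add_signal(m, nef_signal("x", initial = c(1, 2)))
#' m <- add_signal(m, nef_signal("y", shape = 2))
#' m <- add_operator(m, op_reset("y"))
#' m <- add_operator(m, op_copy("x", "y", mode = "inc"))
#' m
nef_model <- function(dt = 0.001) {
  stopifnot(is.numeric(dt), dt > 0)
  structure(
    list(
      signals = list(), operators = list(), probes = list(),
      dt = dt, op_seq = 0L, gen_seq = 0L
    ),
    class = "nef_model"
  )
}

#' Add a signal or view to a model
#'
#' @param model A `nef_model`.
#' @param sig A `nef_signal` from [nef_signal()] or [nef_view()].
#' @return The updated model.
#' @export
add_signal <- function(model, sig) {
  stopifnot(inherits(model, "nef_model"), inherits(sig, "nef_signal"))
  if (!is.null(model$signals[[sig$name]])) {
    stop("a signal named '", sig$name, "' already exists")
  }
  if (is_view(sig)) {
    base <- model$signals[[sig$base]]
    if (is.null(base)) stop("view '", sig$name, "': unknown base '", sig$base, "'")
    if (is_view(base)) stop("view '", sig$name, "': base must not be a view")
    if (sig$offset + sig$size > base$size) {
      stop("view '", sig$name, "' exceeds the extent of base '", sig$base, "'")
    }
  }
  model$signals[[sig$name]] <- sig
  model
}

#' @rdname add_signal
#' @param name,base,offset,shape Passed to [nef_view()].
#' @export
add_view <- function(model, name, base, offset, shape) {
  add_signal(model, nef_view(name, base, offset, shape))
}

#' Add an operator to a model
#'
#' Validates the operator's signal references and per-tag shape constraints,
#' then stores it under a unique identifier that also records declaration
#' order (used for deterministic tie-breaking in scheduling and merging).
#'
#' @param model A `nef_model`.
#' @param op A `nef_operator`.
#' @param name Optional unique identifier; autogenerated when omitted.
#' @return The updated model.
#' @export
add_operator <- function(model, op, name = NULL) {
  stopifnot(inherits(model, "nef_model"), inherits(op, "nef_operator"))
  validate_operator(op, model$signals)
  model$op_seq <- model$op_seq + 1L
  if (is.null(name)) name <- sprintf("op%04d", model$op_seq)
  if (!is.null(model$operators[[name]])) {
    stop("an operator named '", name, "' already exists")
  }
  op$uid <- name
  op$decl <- model$op_seq
  model$operators[[name]] <- op
  model
}

#' Probe a signal
#'
#' Probed signals are sampled at the end of every simulation step by
#' [run_model()].
#'
#' @param model A `nef_model`.
#' @param target Signal (or view) name to record.
#' @param label Column label for the probe; defaults to the target name.
#' @return The updated model.
#' @export
add_probe <- function(model, target, label = target) {
  stopifnot(inherits(model, "nef_model"))
  if (is.null(model$signals[[target]])) {
    stop("probe target '", target, "' is not a signal of the model")
  }
  model$probes[[length(model$probes) + 1L]] <- list(target = target,
                                                    label = label)
  model
}

#' Number of operators in a model
#' @param model A `nef_model`.
#' @return Integer count.
#' @export
n_operators <- function(model) length(model$operators)

#' Operator tag counts
#' @param model A `nef_model`.
#' @return Named integer table of operator tags.
#' @export
operator_tags <- function(model) {
  table(vapply(model$operators, function(o) o$tag, character(1L)))
}

#' Validate a model
#'
#' Checks every operator's references and shapes, the access-role invariants
#' (no two setters or updaters writing overlapping regions of one memory
#' block), and that the dependency graph is acyclic.
#'
#' @param model A `nef_model`.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "nef_model"))
  for (op in model$operators) validate_operator(op, model$signals)
  g <- build_dependency_graph(model)
  toposort(g)
  invisible(TRUE)
}

#' @export
print.nef_model <- function(x, ...) {
  nv <- sum(vapply(x$signals, is_view, logical(1L)))
  cat(sprintf(
    "<nef_model: %d signals (%d views), %d operators, %d probes, dt=%g s>\n",
    length(x$signals) - nv, nv, length(x$operators), length(x$probes), x$dt
  ))
  if (length(x$operators)) {
    tags <- operator_tags(x)
    cat("  operators:",
        paste(sprintf("%s=%d", names(tags), as.integer(tags)), collapse = " "),
        "\n")
  }
  invisible(x)
}

# Fresh generated signal name (merged bases and replacement views).
fresh_name <- function(model, prefix) {
  repeat {
    model$gen_seq <- model$gen_seq + 1L
    nm <- sprintf("%s%04d", prefix, model$gen_seq)
    if (is.null(model$signals[[nm]])) break
  }
  list(model = model, name = nm)
}
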