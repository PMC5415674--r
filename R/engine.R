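#' Initialize simulator state for a model
#'
#' Allocates one flat row-major buffer per non-view signal, filled with the
#' signal's initial value. Views never own buffers; view access resolves to a
#' slice of the base buffer.
#'
#' @param model A `nef_model`.
#' @return An environment of class `nef_state` with fields `buffers`
#'   (environment of numeric vectors), `t` (simulated time in seconds) and
#'   `step_index`.
#' @export
init_state <- function(model) {
  buffers <- new.env(parent = emptyenv())
  for (sig in model$signals) {
    if (!is_view(sig)) assign(sig$name, sig$initial, envir = buffers)
  }
  st <- new.env(parent = emptyenv())
  st$buffers <- buffers
  st$t <- 0
  st$step_index <- 0L
  st$dt <- model$dt
  class(st) <- "nef_state"
  st
}

# Compile a schedule into resolved instructions: per operator, 1-based flat
# index ranges into base buffers plus any precomputed per-tag data.
compile_plan <- function(model, order = NULL) {
  if (is.null(order)) order <- toposort(build_dependency_graph(model))
  signals <- model$signals
  lapply(order, function(uid) {
    op <- model$operators[[uid]]
    ins <- list(uid = uid, tag = op$tag, params = op$params)
    res <- function(r) resolve_ref(signals, r)
    switch(op$tag,
      Reset = {
        ins$dst <- res(op$sets)
      },
      Copy = {
        ins$src <- res(op$reads)
        ins$dst <- res(c(op$sets, op$incs))
        ins$inc <- identical(op$params$mode, "inc")
      },
      ElementwiseInc = {
        ins$a <- res(op$reads[1L])
        ins$x <- res(op$reads[2L])
        ins$y <- res(op$incs)
      },
      DotInc = {
        ins$a <- res(op$reads[1L])
        ins$x <- res(op$reads[2L])
        ins$y <- res(op$incs)
        ins$m <- signals[[op$reads[1L]]]$shape[1L]
        ins$n <- signals[[op$reads[1L]]]$shape[2L]
      },
      BsrDotInc = {
        ins$x <- res(op$reads)
        ins$y <- res(op$incs)
        bs <- op$params$block_shape
        k <- length(op$params$blocks)
        ins$xs <- lapply(seq_len(k) - 1L, function(i) {
          ins$x$from + i * bs[2L] + seq_len(bs[2L]) - 1L
        })
        ins$ys <- lapply(seq_len(k) - 1L, function(i) {
          ins$y$from + i * bs[1L] + seq_len(bs[1L]) - 1L
        })
      },
      SimNeurons = {
        ins$j <- res(op$reads)
        ins$out <- res(op$sets)
        ins$voltage <- res(op$updates[1L])
        ins$refractory <- res(op$updates[2L])
      },
      UserFunc = {
        ins$fn <- op$params$fn
        ins$out <- res(op$sets)
        ins$input <- if (length(op$reads)) res(op$reads) else NULL
      },
      TimeUpdate = {
        ins$step <- res(op$updates[1L])
        ins$time <- res(op$updates[2L])
      },
      stop("unknown operator tag '", op$tag, "'")
    )
    ins
  })
}

get_slice <- function(buffers, ref) {
  buf <- get(ref$base, envir = buffers)
  buf[ref$from:ref$to]
}

set_slice <- function(buffers, ref, value) {
  buf <- get(ref$base, envir = buffers)
  buf[ref$from:ref$to] <- value
  assign(ref$base, buf, envir = buffers)
}

inc_slice <- function(buffers, ref, value) {
  buf <- get(ref$base, envir = buffers)
  idx <- ref$from:ref$to
  buf[idx] <- buf[idx] + value
  assign(ref$base, buf, envir = buffers)
}

# One leaky integrate-and-fire update with sub-step spike-time correction.
# Voltage follows tau_rc * dv/dt = J - v by the exact exponential solution;
# a spike of amplitude 1/dt is emitted when v crosses threshold 1, after
# which the membrane is clamped for tau_ref seconds.
lif_step <- function(v, refractory, J, dt, tau_rc, tau_ref) {
  if (any(!is.finite(J))) stop("SimNeurons: non-finite input current J")
  refractory <- refractory - dt
  delta_t <- pmin(pmax(dt - refractory, 0), dt)
  v <- J + (v - J) * exp(-delta_t / tau_rc)
  spiked <- v > 1
  out <- numeric(length(v))
  if (any(spiked)) {
    out[spiked] <- 1 / dt
    # time left in the step after the threshold crossing
    t_spike <- dt + tau_rc * log1p(-(v[spiked] - 1) / (J[spiked] - 1))
    refractory[spiked] <- tau_ref + t_spike
    v[spiked] <- 0
  }
  list(v = v, refractory = refractory, out = out)
}

#' Closed-form firing rate of a LIF neuron
#'
#' For a constant suprathreshold input current the leaky integrate-and-fire
#' neuron fires periodically with rate
#' `1 / (tau_ref + tau_rc * log(1 + 1/(J - 1)))`; below threshold (`J <= 1`)
#' the rate is zero.
#'
#' @param J Constant input current (threshold is 1).
#' @param tau_rc Membrane time constant in seconds.
#' @param tau_ref Refractory period in seconds.
#' @return Firing rate in Hz (vectorized over `J`).
#' @export
lif_rate <- function(J, tau_rc = 0.02, tau_ref = 0.002) {
  r <- numeric(length(J))
  supra <- J > 1
  r[supra] <- 1 / (tau_ref + tau_rc * log1p(1 / (J[supra] - 1)))
  r
}

# Apply one compiled instruction to the state buffers.
apply_instr <- function(ins, st) {
  b <- st$buffers
  switch(ins$tag,
    Reset = set_slice(b, ins$dst, rep(ins$params$value, ins$dst$size)),
    Copy = {
      val <- get_slice(b, ins$src)
      if (ins$inc) inc_slice(b, ins$dst, val) else set_slice(b, ins$dst, val)
    },
    ElementwiseInc = {
      inc_slice(b, ins$y, get_slice(b, ins$a) * get_slice(b, ins$x))
    },
    DotInc = {
      A <- matrix(get_slice(b, ins$a), nrow = ins$m, byrow = TRUE)
      inc_slice(b, ins$y, as.numeric(A %*% get_slice(b, ins$x)))
    },
    BsrDotInc = {
      buf <- get(ins$y$base, envir = b)
      xb <- if (identical(ins$x$base, ins$y$base)) buf else
        get(ins$x$base, envir = b)
      blocks <- ins$params$blocks
      for (k in seq_along(blocks)) {
        yk <- ins$ys[[k]]
        buf[yk] <- buf[yk] + as.numeric(blocks[[k]] %*% xb[ins$xs[[k]]])
      }
      assign(ins$y$base, buf, envir = b)
    },
    SimNeurons = {
      r <- lif_step(
        v = get_slice(b, ins$voltage),
        refractory = get_slice(b, ins$refractory),
        J = get_slice(b, ins$j),
        dt = st$dt, tau_rc = ins$params$tau_rc, tau_ref = ins$params$tau_ref
      )
      set_slice(b, ins$out, r$out)
      set_slice(b, ins$voltage, r$v)
      set_slice(b, ins$refractory, r$refractory)
    },
    UserFunc = {
      arg <- if (is.null(ins$input)) st$t else get_slice(b, ins$input)
      val <- as.numeric(ins$fn(arg))
      if (length(val) != ins$out$size) {
        stop("UserFunc '", ins$uid, "': output length ", length(val),
             " != signal size ", ins$out$size)
      }
      set_slice(b, ins$out, val)
    },
    TimeUpdate = {
      steps <- get_slice(b, ins$step) + 1
      set_slice(b, ins$step, steps)
      set_slice(b, ins$time, steps * st$dt)
    }
  )
  invisible(NULL)
}

#' Advance the simulator by one step
#'
#' Applies every compiled instruction once in schedule order, then advances
#' simulated time by `dt`.
#'
#' @param st A `nef_state` from [init_state()].
#' @param compiled A compiled plan as produced internally by [run_model()]
#'   (a list of resolved instructions).
#' @return The state, invisibly (modified in place).
#' @export
sim_step <- function(st, compiled) {
  for (ins in compiled) apply_instr(ins, st)
  st$t <- st$t + st$dt
  st$step_index <- st$step_index + 1L
  invisible(st)
}

#' Run a model
#'
#' Builds the dependency graph, topologically sorts it and executes the plan
#' for `n_steps` steps, sampling every probed signal at the end of each step.
#'
#' @param model A `nef_model`.
#' @param n_steps Number of steps to simulate (>= 0).
#' @param state Optional pre-initialized `nef_state` (used e.g. to continue
#'   after warm-up steps); defaults to a fresh state.
#' @return An object of class `nef_probes`: a named list of
#'   `n_steps x signal-size` matrices, one per probe, with attributes `dt`
#'   and `n_steps`.
#' @export
#' @examples
#' m <- nef_model()
#' m <- add_signal(m, nef_signal("x", initial = c(3, 4)))
#' m <- add_signal(m, nef_signal("y", shape = 2))
#' m <- add_signal(m, nef_signal("A", initial = diag(2)))
#' m <- add_operator(m, op_reset("y"))
#' m <- add_operator(m, op_dot_inc("A", "x", "y"))
#' m <- add_probe(m, "y")
#' run_model(m, 3)
run_model <- function(model, n_steps, state = NULL) {
  stopifnot(inherits(model, "nef_model"), n_steps >= 0)
  compiled <- compile_plan(model)
  st <- if (is.null(state)) init_state(model) else state
  probes <- model$probes
  refs <- lapply(probes, function(p) resolve_ref(model$signals, p$target))
  labels <- vapply(probes, function(p) p$label, character(1L))
  data <- lapply(refs, function(r) matrix(NA_real_, nrow = n_steps,
                                          ncol = r$size))
  for (i in seq_len(n_steps)) {
    sim_step(st, compiled)
    for (k in seq_along(refs)) {
      data[[k]][i, ] <- get_slice(st$buffers, refs[[k]])
    }
  }
  names(data) <- labels
  structure(data, dt = model$dt, n_steps = as.integer(n_steps),
            class = "nef_probes")
}

#' @export
print.nef_probes <- function(x, ...) {
  cat(sprintf("<nef_probes: %d probes, %d steps, dt=%g s>\n",
              length(x), attr(x, "n_steps"), attr(x, "dt")))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d x %d\n", nm, nrow(x[[nm]]), ncol(x[[nm]])))
  }
  invisible(x)
}

#' Maximum absolute difference between two probe recordings
#'
#' @param a,b `nef_probes` objects over the same probes and step count.
#' @return The largest elementwise absolute difference (0 for empty probes).
#' @export
max_trace_diff <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b))) {
    stop("probe recordings cover different probes")
  }
  worst <- 0
  for (nm in names(a)) {
    if (!identical(dim(a[[nm]]), dim(b[[nm]]))) {
      stop("probe '", nm, "': recordings differ in shape")
    }
    if (length(a[[nm]])) worst <- max(worst, max(abs(a[[nm]] - b[[nm]])))
  }
  worst
}

#' Are two probe recordings equivalent?
#'
#' The optimizer's correctness contract: an optimized model must reproduce
#' the unoptimized model's probe traces to within `tol`.
#'
#' @param a,b `nef_probes` objects over the same probes and step count.
#' @param tol Maximum allowed elementwise absolute difference.
#' @return Logical scalar.
#' @export
traces_equivalent <- function(a, b, tol = 1e-9) {
  max_trace_diff(a, b) <= tol
}

#' Export probe data as CSV
#'
#' One row per step; columns are labelled `<probe>[i]` per element, preceded
#' by the simulated time.
#'
#' @param probes A `nef_probes` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probes_csv <- function(probes, path) {
  n <- attr(probes, "n_steps")
  dt <- attr(probes, "dt")
  cols <- list(t = seq_len(n) * dt)
  for (nm in names(probes)) {
    m <- probes[[nm]]
    for (j in seq_len(ncol(m))) {
      cols[[sprintf("%s[%d]", nm, j)]] <- m[, j]
    }
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}
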