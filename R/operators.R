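#' @name operators
#' @title Operator constructors
#'
#' @description Operators are the computation nodes of a model. Each operator
#' declares, for every signal it touches, one of four access roles that order
#' execution within a simulation time step:
#'
#' * **set** -- defines the signal value at the start of the step (at most one
#'   setter per memory region);
#' * **inc** -- adds to the signal value (any number);
#' * **read** -- retrieves the value (any number);
#' * **update** -- writes the value the signal carries into the next step (at
#'   most one updater per region; readers within the step see the previous
#'   step's value).
#'
#' Signals are referenced by name; names may refer to views. The available
#' operator tags are `Reset`, `Copy`, `ElementwiseInc`, `DotInc`, `BsrDotInc`,
#' `SimNeurons`, `UserFunc` and `TimeUpdate`.
#'
#' @param target,src,dst,a,x,y,j,out,voltage,refractory,step,time,input,output
#'   Signal names (character scalars).
#' @param value Constant scalar the target is set to each step (`op_reset`).
#' @param mode For `op_copy`: `"set"` (dst is set) or `"inc"` (dst is
#'   incremented).
#' @param blocks For `op_bsr_dot_inc`: list of equally shaped dense numeric
#'   matrices; block `k` multiplies the `k`-th contiguous slice of `x` into
#'   the `k`-th contiguous slice of `y`.
#' @param tau_rc Membrane time constant in seconds (> 0).
#' @param tau_ref Absolute refractory period in seconds (>= 0).
#' @param fn For `op_user_func`: a function, or the name of a registered
#'   function (see [nef_fn()]). Called as `fn(x)` when `input` is given,
#'   else `fn(t)` with the current simulation time.
#' @return An object of class `nef_operator` (attach it to a model with
#'   [add_operator()]).
NULL

new_operator <- function(tag, sets = character(), incs = character(),
                         reads = character(), updates = character(),
                         params = list()) {
  structure(
    list(
      tag = tag, sets = sets, incs = incs, reads = reads,
      updates = updates, params = params
    ),
    class = "nef_operator"
  )
}

#' @rdname operators
#' @export
op_reset <- function(target, value = 0) {
  stopifnot(is.numeric(value), length(value) == 1L)
  new_operator("Reset", sets = target, params = list(value = as.numeric(value)))
}

#' @rdname operators
#' @export
op_copy <- function(src, dst, mode = c("set", "inc")) {
  mode <- match.arg(mode)
  if (mode == "set") {
    new_operator("Copy", sets = dst, reads = src, params = list(mode = mode))
  } else {
    new_operator("Copy", incs = dst, reads = src, params = list(mode = mode))
  }
}

#' @rdname operators
#' @export
op_elementwise_inc <- function(a, x, y) {
  new_operator("ElementwiseInc", incs = y, reads = c(a, x))
}

#' @rdname operators
#' @export
op_dot_inc <- function(a, x, y) {
  new_operator("DotInc", incs = y, reads = c(a, x))
}

#' @rdname operators
#' @export
op_bsr_dot_inc <- function(blocks, x, y) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  blocks <- lapply(blocks, function(b) {
    if (!is.matrix(b)) b <- matrix(as.numeric(b), nrow = 1L)
    storage.mode(b) <- "double"
    b
  })
  bs <- dim(blocks[[1L]])
  ok <- vapply(blocks, function(b) identical(dim(b), bs), logical(1L))
  if (!all(ok)) stop("BsrDotInc: all blocks must share one (m x n) shape")
  new_operator(
    "BsrDotInc", incs = y, reads = x,
    params = list(blocks = blocks, block_shape = as.integer(bs))
  )
}

#' @rdname operators
#' @export
op_sim_neurons <- function(j, out, voltage, refractory,
                           tau_rc = 0.02, tau_ref = 0.002) {
  if (!(tau_rc > 0)) stop("SimNeurons: tau_rc must be > 0")
  if (tau_ref < 0) stop("SimNeurons: tau_ref must be >= 0")
  new_operator(
    "SimNeurons", sets = out, reads = j, updates = c(voltage, refractory),
    params = list(tau_rc = tau_rc, tau_ref = tau_ref)
  )
}

#' @rdname operators
#' @export
op_user_func <- function(fn, output, input = NULL) {
  fn_name <- NA_character_
  if (is.character(fn)) {
    fn_name <- fn
    fn <- nef_fn(fn)
  }
  stopifnot(is.function(fn))
  new_operator(
    "UserFunc", sets = output,
    reads = if (is.null(input)) character() else input,
    params = list(fn = fn, fn_name = fn_name)
  )
}

#' @rdname operators
#' @export
op_time_update <- function(step, time) {
  new_operator("TimeUpdate", updates = c(step, time))
}

#' Registered user functions
#'
#' UserFunc operators hold arbitrary R functions and therefore cannot be
#' serialized in general. Functions registered here by name round-trip
#' through the JSON model format.
#'
#' @param name Registered function name.
#' @return The registered function.
#' @export
nef_fn <- function(name) {
  fn <- .nef_fns[[name]]
  if (is.null(fn)) {
    stop("no registered user function named '", name, "'")
  }
  fn
}

.nef_fns <- list(
  identity = function(x) x,
  negate = function(x) -x,
  square = function(x) x * x
)

#' @export
print.nef_operator <- function(x, ...) {
  role_str <- function(role) {
    if (length(x[[role]]) == 0L) return(NULL)
    paste0(role, "=[", paste(x[[role]], collapse = ","), "]")
  }
  parts <- Filter(Negate(is.null), lapply(c("sets", "incs", "reads", "updates"),
                                          role_str))
  cat(sprintf("<%s %s>\n", x$tag, paste(unlist(parts), collapse = " ")))
  invisible(x)
}

#' Does an operator type support merging?
#'
#' `UserFunc` operators execute arbitrary user code and can never be merged;
#' all other operator types can.
#'
#' @param tag Operator tag (character scalar).
#' @return Logical scalar.
#' @export
op_mergeable <- function(tag) !identical(tag, "UserFunc")

# All signal references of an operator, in the fixed role scan order
# (sets, incs, reads, updates; declaration order within each role).
op_refs <- function(op) {
  c(op$sets, op$incs, op$reads, op$updates)
}

op_has_view <- function(op, signals) {
  for (r in op_refs(op)) {
    if (is_view(signals[[r]])) return(TRUE)
  }
  FALSE
}

#' Offset and size of an operator's first signal view
#'
#' Scans the operator's signals in the fixed role order (sets, incs, reads,
#' updates; declaration order within each role) and returns `c(offset, size)`
#' of the first view encountered. Operators without any view return
#' `c(0, 0)`, which lets the same merge sweep handle view-free operators.
#'
#' @param op A `nef_operator` (as stored in a model).
#' @param signals The model's signal registry (`model$signals`).
#' @return Integer vector `c(offset, size)` (0-based element offset).
#' @export
first_view_key <- function(op, signals) {
  for (r in op_refs(op)) {
    sig <- signals[[r]]
    if (is_view(sig)) return(c(sig$offset, sig$size))
  }
  c(0L, 0L)
}

# Base of the operator's first view, or NA if the operator has none.
first_view_base <- function(op, signals) {
  for (r in op_refs(op)) {
    sig <- signals[[r]]
    if (is_view(sig)) return(sig$base)
  }
  NA_character_
}

# Per-tag arity and shape validation, given the signal registry.
validate_operator <- function(op, signals) {
  for (r in op_refs(op)) {
    if (is.null(signals[[r]])) {
      stop("operator ", op$tag, " references unknown signal '", r, "'")
    }
  }
  sz <- function(r) signals[[r]]$size
  switch(op$tag,
    Reset = stopifnot(length(op$sets) == 1L),
    Copy = {
      stopifnot(length(op$reads) == 1L)
      dst <- c(op$sets, op$incs)
      stopifnot(length(dst) == 1L)
      if (sz(op$reads) != sz(dst)) {
        stop("Copy: src '", op$reads, "' and dst '", dst, "' differ in size")
      }
    },
    ElementwiseInc = {
      stopifnot(length(op$reads) == 2L, length(op$incs) == 1L)
      sizes <- c(sz(op$reads[1L]), sz(op$reads[2L]), sz(op$incs))
      if (length(unique(sizes)) != 1L) {
        stop("ElementwiseInc: A, X, Y must have equal size")
      }
    },
    DotInc = {
      stopifnot(length(op$reads) == 2L, length(op$incs) == 1L)
      a <- signals[[op$reads[1L]]]
      if (length(a$shape) != 2L) stop("DotInc: A must be 2-D")
      if (sz(op$reads[2L]) != a$shape[2L]) {
        stop("DotInc: length(X) must equal ncol(A)")
      }
      if (sz(op$incs) != a$shape[1L]) {
        stop("DotInc: length(Y) must equal nrow(A)")
      }
    },
    BsrDotInc = {
      stopifnot(length(op$reads) == 1L, length(op$incs) == 1L)
      k <- length(op$params$blocks)
      bs <- op$params$block_shape
      if (sz(op$reads) != k * bs[2L]) {
        stop("BsrDotInc: length(X) must equal n_blocks * block cols")
      }
      if (sz(op$incs) != k * bs[1L]) {
        stop("BsrDotInc: length(Y) must equal n_blocks * block rows")
      }
    },
    SimNeurons = {
      stopifnot(length(op$reads) == 1L, length(op$sets) == 1L,
                length(op$updates) == 2L)
      sizes <- c(sz(op$reads), sz(op$sets), sz(op$updates[1L]),
                 sz(op$updates[2L]))
      if (length(unique(sizes)) != 1L) {
        stop("SimNeurons: J, out, voltage, refractory must have equal size")
      }
    },
    UserFunc = stopifnot(length(op$sets) == 1L, length(op$reads) <= 1L),
    TimeUpdate = {
      stopifnot(length(op$updates) == 2L)
      if (sz(op$updates[1L]) != sz(op$updates[2L])) {
        stop("TimeUpdate: step and time signals must have equal size")
      }
    },
    stop("unknown operator tag '", op$tag, "'")
  )
  invisible(TRUE)
}

#' Dense element storage of a BsrDotInc operator
#'
#' The block-sparse product stores only its dense blocks, so its memory
#' grows linearly in the number of merged operators, not quadratically as a
#' materialized block-diagonal matrix would.
#'
#' @param op A `BsrDotInc` `nef_operator`.
#' @return Number of stored matrix elements (sum over blocks of `m * n`).
#' @export
bsr_storage_elements <- function(op) {
  stopifnot(identical(op$tag, "BsrDotInc"))
  sum(vapply(op$params$blocks, length, numeric(1L)))
}
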