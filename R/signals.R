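#' Create a signal
#'
#' A signal is a named block of simulation memory holding a 1-D vector or a
#' 2-D matrix of 64-bit floats. Every non-view signal owns a distinct memory
#' block; the simulator allocates one flat buffer per signal, stored in
#' row-major element order.
#'
#' @param name Unique character label for the signal within a model.
#' @param initial Initial value: a numeric vector (1-D signal) or matrix
#'   (2-D signal). Defaults to zeros of `shape`.
#' @param shape Integer vector of extents (length 1 or 2). Derived from
#'   `initial` when omitted.
#' @param dtype Element type tag. Only `"float64"` is supported.
#' @return An object of class `nef_signal`.
#' @seealso [nef_view()], [add_signal()]
#' @export
#' @examples
#' nef_signal("x", initial = c(1, 2, 3))
#' nef_signal("A", initial = matrix(1:6, 2, 3))
nef_signal <- function(name, initial = NULL, shape = NULL, dtype = "float64") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!identical(dtype, "float64")) {
    stop("only dtype 'float64' is supported, got '", dtype, "'")
  }
  if (is.null(initial)) {
    if (is.null(shape)) stop("signal '", name, "': give `initial` or `shape`")
    shape <- as.integer(shape)
    flat <- numeric(prod(shape))
  } else if (is.matrix(initial)) {
    inferred <- as.integer(dim(initial))
    flat <- as.numeric(t(initial)) # row-major layout
    if (is.null(shape)) shape <- inferred
    else if (!identical(as.integer(shape), inferred)) {
      stop("signal '", name, "': `shape` does not match dim(initial)")
    }
  } else {
    inferred <- length(initial)
    flat <- as.numeric(initial)
    if (is.null(shape)) shape <- inferred
    shape <- as.integer(shape)
    if (prod(shape) != inferred) {
      stop("signal '", name, "': `shape` does not match length(initial)")
    }
  }
  if (length(shape) < 1L || length(shape) > 2L || any(shape < 1L)) {
    stop("signal '", name, "': shape must be 1-D or 2-D with positive extents")
  }
  structure(
    list(
      name = name, is_view = FALSE, shape = shape, dtype = dtype,
      size = as.integer(prod(shape)), initial = flat
    ),
    class = "nef_signal"
  )
}

#' Create a signal view
#'
#' A view maps into the memory block of a base signal at a 0-based element
#' offset. Views allocate no memory: reading or writing a view reads or
#' writes the base block. All views are contiguous (row-major) over the
#' viewed region, so a view is fully described by its offset and shape;
#' strides are derived.
#'
#' @param name Unique character label.
#' @param base Name of the base signal (must be a non-view signal).
#' @param offset 0-based element offset into the base block.
#' @param shape Integer extents of the viewed region (1-D or 2-D).
#' @return An object of class `nef_signal` flagged as a view. Bounds against
#'   the base are checked when the view is added to a model.
#' @export
#' @examples
#' nef_view("head", base = "x", offset = 0, shape = 2)
nef_view <- function(name, base, offset, shape) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(base), length(base) == 1L)
  offset <- as.integer(offset)
  shape <- as.integer(shape)
  if (offset < 0L) stop("view '", name, "': offset must be >= 0")
  if (length(shape) < 1L || length(shape) > 2L || any(shape < 1L)) {
    stop("view '", name, "': shape must be 1-D or 2-D with positive extents")
  }
  strides <- if (length(shape) == 1L) 1L else c(shape[2L], 1L)
  structure(
    list(
      name = name, is_view = TRUE, base = base, offset = offset,
      shape = shape, dtype = "float64", size = as.integer(prod(shape)),
      strides = as.integer(strides)
    ),
    class = "nef_signal"
  )
}

#' Is a signal a view?
#' @param sig A `nef_signal`.
#' @return Logical scalar.
#' @export
is_view <- function(sig) isTRUE(sig$is_view)

#' @export
print.nef_signal <- function(x, ...) {
  if (is_view(x)) {
    cat(sprintf(
      "<view '%s' into '%s' offset=%d shape=(%s)>\n",
      x$name, x$base, x$offset, paste(x$shape, collapse = ",")
    ))
  } else {
    cat(sprintf(
      "<signal '%s' shape=(%s) dtype=%s>\n",
      x$name, paste(x$shape, collapse = ","), x$dtype
    ))
  }
  invisible(x)
}

# 0-based half-open element range [from, to) of a reference within its base
# block (a non-view signal spans its own whole block).
sig_range <- function(sig) {
  if (is_view(sig)) c(sig$offset, sig$offset + sig$size)
  else c(0L, sig$size)
}

sig_base_name <- function(sig) if (is_view(sig)) sig$base else sig$name

# Resolve a reference name against a signal registry to
# list(base, from, to, shape): `from`/`to` are 1-based inclusive flat indices.
resolve_ref <- function(signals, name) {
  sig <- signals[[name]]
  if (is.null(sig)) stop("unknown signal reference '", name, "'")
  if (is_view(sig)) {
    list(
      base = sig$base, from = sig$offset + 1L,
      to = sig$offset + sig$size, shape = sig$shape, size = sig$size
    )
  } else {
    list(base = sig$name, from = 1L, to = sig$size, shape = sig$shape,
         size = sig$size)
  }
}

# Initial value of a reference as a flat row-major numeric vector.
ref_initial <- function(signals, name) {
  r <- resolve_ref(signals, name)
  base <- signals[[r$base]]
  base$initial[r$from:r$to]
}

# Initial value of a 2-D reference as an R matrix.
ref_initial_matrix <- function(signals, name) {
  sig <- signals[[name]]
  if (length(sig$shape) != 2L) {
    stop("signal '", name, "' is not 2-D")
  }
  matrix(ref_initial(signals, name), nrow = sig$shape[1L], byrow = TRUE)
}
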