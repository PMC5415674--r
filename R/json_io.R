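#' Write a model to the JSON graph format
#'
#' Serializes a model as a JSON object with fields `dt`, `signals` (name,
#' shape, dtype, initial -- nested row-major for matrices), `views` (name,
#' base, offset, shape), `operators` (name, tag, roles, params) and
#' `probes`. `UserFunc` operators serialize only if their function was given
#' by registered name (see [nef_fn()]).
#'
#' @param model A `nef_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model_json()]
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nef_model"))
  sigs <- Filter(Negate(is_view), model$signals)
  views <- Filter(is_view, model$signals)
  sig_json <- lapply(unname(sigs), function(s) {
    ini <- if (length(s$shape) == 2L) {
      m <- matrix(s$initial, nrow = s$shape[1L], byrow = TRUE)
      lapply(seq_len(nrow(m)), function(i) m[i, ])
    } else {
      s$initial
    }
    list(name = s$name, shape = as.integer(s$shape), dtype = s$dtype,
         initial = ini)
  })
  view_json <- lapply(unname(views), function(v) {
    list(name = v$name, base = v$base, offset = v$offset,
         shape = as.integer(v$shape))
  })
  op_json <- lapply(unname(model$operators), function(op) {
    params <- op$params
    if (identical(op$tag, "UserFunc")) {
      if (is.na(params$fn_name)) {
        stop("UserFunc '", op$uid, "' holds an unregistered function and ",
             "cannot be serialized; use a registered name (see nef_fn)")
      }
      params <- list(fn_name = params$fn_name)
    }
    if (identical(op$tag, "BsrDotInc")) {
      params <- list(
        block_shape = params$block_shape,
        blocks = lapply(params$blocks, function(bk) {
          lapply(seq_len(nrow(bk)), function(i) bk[i, ])
        })
      )
    }
    list(
      name = op$uid, tag = op$tag,
      roles = list(sets = op$sets, incs = op$incs, reads = op$reads,
                   updates = op$updates),
      params = params
    )
  })
  probe_json <- lapply(model$probes, function(p) {
    list(target = p$target, label = p$label)
  })
  obj <- list(dt = model$dt, signals = sig_json, views = view_json,
              operators = op_json, probes = probe_json)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from the JSON graph format
#'
#' Reconstructs a model written by [write_model_json()], re-validating all
#' signal, view and operator invariants on the way in.
#'
#' @param path Input file path.
#' @return A `nef_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$dt)) stop("model JSON: missing 'dt'")
  m <- nef_model(dt = as.numeric(obj$dt))
  num <- function(x) vapply(x, as.numeric, numeric(1L))
  for (s in obj$signals) {
    shape <- vapply(s$shape, as.integer, integer(1L))
    ini <- if (length(shape) == 2L) {
      do.call(rbind, lapply(s$initial, num))
    } else {
      num(s$initial)
    }
    m <- add_signal(m, nef_signal(s$name, initial = ini, shape = shape,
                                  dtype = s$dtype))
  }
  for (v in obj$views) {
    m <- add_view(m, v$name, v$base, as.integer(v$offset),
                  vapply(v$shape, as.integer, integer(1L)))
  }
  chr <- function(x) vapply(x, as.character, character(1L))
  for (o in obj$operators) {
    roles <- o$roles
    sets <- if (length(roles$sets)) chr(roles$sets) else character()
    incs <- if (length(roles$incs)) chr(roles$incs) else character()
    reads <- if (length(roles$reads)) chr(roles$reads) else character()
    updates <- if (length(roles$updates)) chr(roles$updates) else character()
    p <- o$params
    op <- switch(o$tag,
      Reset = op_reset(sets[1L], as.numeric(p$value)),
      Copy = op_copy(reads[1L], c(sets, incs)[1L], mode = p$mode),
      ElementwiseInc = op_elementwise_inc(reads[1L], reads[2L], incs[1L]),
      DotInc = op_dot_inc(reads[1L], reads[2L], incs[1L]),
      BsrDotInc = op_bsr_dot_inc(
        lapply(p$blocks, function(bk) do.call(rbind, lapply(bk, num))),
        reads[1L], incs[1L]
      ),
      SimNeurons = op_sim_neurons(reads[1L], sets[1L], updates[1L],
                                  updates[2L], as.numeric(p$tau_rc),
                                  as.numeric(p$tau_ref)),
      UserFunc = op_user_func(p$fn_name, output = sets[1L],
                              input = if (length(reads)) reads[1L] else NULL),
      TimeUpdate = op_time_update(updates[1L], updates[2L]),
      stop("model JSON: unknown operator tag '", o$tag, "'")
    )
    m <- add_operator(m, op, name = o$name)
  }
  for (p in obj$probes) m <- add_probe(m, p$target, p$label)
  validate_model(m)
  m
}
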