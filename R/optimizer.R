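#' Can two non-view signals be merged?
#'
#' Two signals can be concatenated into one sequential memory block when
#' they use the same data type and their shapes agree on all axes except the
#' concatenation axis.
#'
#' @param a,b `nef_signal` objects (not views).
#' @param axis Concatenation axis (1-based; 1 concatenates vectors, or
#'   stacks matrix rows).
#' @return Logical scalar.
#' @export
signals_mergeable <- function(a, b, axis = 1L) {
  if (is_view(a) || is_view(b)) return(FALSE)
  if (!identical(a$dtype, b$dtype)) return(FALSE)
  if (length(a$shape) != length(b$shape)) return(FALSE)
  if (axis < 1L || axis > length(a$shape)) return(FALSE)
  off_axis <- setdiff(seq_along(a$shape), axis)
  all(a$shape[off_axis] == b$shape[off_axis])
}

#' Can two views be merged?
#'
#' Views map into existing memory, so they cannot be relocated; they can
#' only be merged when they already are sequential in memory: same base,
#' equal strides, and the second view's offset equals the first view's
#' offset incremented by its size. Merging then creates one encompassing
#' view and copies no data.
#'
#' @param a,b `nef_signal` views.
#' @return Logical scalar.
#' @export
views_mergeable <- function(a, b) {
  if (!is_view(a) || !is_view(b)) return(FALSE)
  if (!identical(a$base, b$base)) return(FALSE) # different bases: never
  if (!identical(a$strides, b$strides)) return(FALSE)
  identical(b$offset, a$offset + a$size)
}

# ---------------------------------------------------------------------------
# Optimizer working context: a mutable environment holding the model pieces,
# the (lazily recomputed) reachability, the set of operators excluded as
# never-mergeable, and the merge log.

opt_ctx <- function(model) {
  e <- new.env(parent = emptyenv())
  e$sigs <- model$signals
  e$ops <- model$operators
  e$probes <- model$probes
  e$dt <- model$dt
  e$op_seq <- model$op_seq
  e$gen_seq <- model$gen_seq
  e$excluded <- character()
  e$reach <- NULL
  e$n_repl <- 0L
  e$log <- list()
  e
}

ctx_model <- function(e) {
  structure(
    list(
      signals = e$sigs, operators = e$ops, probes = e$probes,
      dt = e$dt, op_seq = e$op_seq, gen_seq = e$gen_seq
    ),
    class = "nef_model"
  )
}

ctx_invalidate <- function(e) {
  e$reach <- NULL
  invisible(e)
}

# Reachability is recomputed from the rewritten graph whenever stale --
# at the start of each group's sweep and after every merge -- so dependence
# queries always see paths routed through freshly merged operators.
ctx_reach <- function(e) {
  if (is.null(e$reach)) {
    g <- build_dependency_graph(e$ops, signals = e$sigs)
    e$reach <- transitive_closure(g)
  }
  e$reach
}

ctx_fresh <- function(e, prefix) {
  repeat {
    e$gen_seq <- e$gen_seq + 1L
    nm <- sprintf("%s%04d", prefix, e$gen_seq)
    if (is.null(e$sigs[[nm]])) return(nm)
  }
}

# ---------------------------------------------------------------------------
# Signal merging (global rewrite)

merge_signals_ctx <- function(e, names, axis = 1L) {
  sigs <- e$sigs[names]
  if (any(vapply(sigs, is.null, logical(1L)))) {
    stop("merge_signals: unknown signal name")
  }
  if (anyDuplicated(names)) {
    stop("merge_signals: cannot merge a signal with itself")
  }
  if (length(names) == 1L) {
    # degenerate merge: a view of the whole signal, data untouched
    vn <- ctx_fresh(e, "..v")
    e$sigs[[vn]] <- nef_view(vn, names, 0L, sigs[[1L]]$shape)
    return(list(base = names, replacements = stats::setNames(vn, names)))
  }
  for (i in seq_len(length(names) - 1L)) {
    if (!signals_mergeable(sigs[[i]], sigs[[i + 1L]], axis = axis)) {
      stop("merge_signals: '", names[i], "' and '", names[i + 1L],
           "' are not mergeable on axis ", axis)
    }
  }
  shapes <- lapply(sigs, function(s) s$shape)
  nd <- length(shapes[[1L]])
  if (!axis %in% seq_len(nd)) stop("merge_signals: bad axis")
  if (nd == 2L && axis == 2L) {
    stop("merge_signals: only axis 1 (row) concatenation is supported")
  }
  merged_shape <- shapes[[1L]]
  merged_shape[1L] <- sum(vapply(shapes, function(s) s[1L], integer(1L)))
  sizes <- vapply(sigs, function(s) s$size, integer(1L))
  offsets <- c(0L, cumsum(sizes))[seq_along(sigs)] # flat row-major offsets
  flat <- unlist(lapply(sigs, function(s) s$initial), use.names = FALSE)

  base_name <- ctx_fresh(e, "..m")
  base <- nef_signal(base_name, initial = flat, shape = merged_shape)

  # registry update: drop the merged signals, add the base and one
  # replacement view per input at its cumulative offset
  e$sigs[names] <- NULL
  e$sigs[[base_name]] <- base
  repl <- character(length(names))
  for (i in seq_along(names)) {
    vn <- ctx_fresh(e, "..v")
    e$sigs[[vn]] <- nef_view(vn, base_name, offsets[i], shapes[[i]])
    repl[i] <- vn
  }
  names(repl) <- names
  off_by_old <- stats::setNames(offsets, names)

  # rebase existing views into any of the merged signals
  rebased <- character()
  for (nm in names(e$sigs)) {
    s <- e$sigs[[nm]]
    if (is_view(s) && s$base %in% names) {
      s$offset <- s$offset + off_by_old[[s$base]]
      s$base <- base_name
      e$sigs[[nm]] <- s
      rebased <- c(rebased, nm)
    }
  }
  # rewrite every operator and probe referencing a merged signal directly;
  # operators whose signals changed (rewritten or rebased) get another shot
  # at merging even if an earlier sweep found them never-mergeable, since
  # their view layout has changed
  for (uid in names(e$ops)) {
    op <- e$ops[[uid]]
    changed <- FALSE
    for (role in c("sets", "incs", "reads", "updates")) {
      hits <- op[[role]] %in% names
      if (any(hits)) {
        op[[role]][hits] <- repl[op[[role]][hits]]
        changed <- TRUE
      }
      if (any(op[[role]] %in% rebased)) changed <- TRUE
    }
    if (changed) {
      e$ops[[uid]] <- op
      e$excluded <- setdiff(e$excluded, uid)
    }
  }
  if (length(e$probes)) {
    for (k in seq_along(e$probes)) {
      tgt <- e$probes[[k]]$target
      if (tgt %in% names) e$probes[[k]]$target <- repl[[tgt]]
    }
  }
  e$n_repl <- e$n_repl + length(names)
  ctx_invalidate(e)
  list(base = base_name, replacements = repl)
}

merge_view_chain_ctx <- function(e, names) {
  views <- e$sigs[names]
  if (any(vapply(views, is.null, logical(1L)))) {
    stop("merge_view_chain: unknown view name")
  }
  if (length(names) == 1L) return(names)
  for (i in seq_len(length(names) - 1L)) {
    if (!views_mergeable(views[[i]], views[[i + 1L]])) {
      stop("merge_view_chain: '", names[i], "' and '", names[i + 1L],
           "' are not sequential views of one base")
    }
  }
  first <- views[[1L]]
  total <- sum(vapply(views, function(v) v$size, integer(1L)))
  shape <- if (length(first$shape) == 1L) total else {
    c(total %/% first$shape[2L], first$shape[2L])
  }
  vn <- ctx_fresh(e, "..v")
  e$sigs[[vn]] <- nef_view(vn, first$base, first$offset, shape)
  vn
}

# ---------------------------------------------------------------------------
# Merge predicate

aligned_roles <- c("sets", "incs", "reads", "updates")

can_merge_ctx <- function(e, ui, uj) {
  oi <- e$ops[[ui]]
  oj <- e$ops[[uj]]
  if (is.null(oi) || is.null(oj)) return(FALSE)
  # (1) same type, and the type supports merging
  if (!identical(oi$tag, oj$tag) || !op_mergeable(oi$tag)) return(FALSE)
  # (2) neither operator's execution may depend on the other
  if (!independent_ops(ui, uj, ctx_reach(e))) return(FALSE)
  # (3) every positionally corresponding signal pair must allow merging
  for (role in aligned_roles) {
    ra <- oi[[role]]
    rb <- oj[[role]]
    if (length(ra) != length(rb)) return(FALSE)
    for (k in seq_along(ra)) {
      sa <- e$sigs[[ra[k]]]
      sb <- e$sigs[[rb[k]]]
      if (is_view(sa) && is_view(sb)) {
        if (!views_mergeable(sa, sb)) return(FALSE)
      } else if (!is_view(sa) && !is_view(sb)) {
        # a signal cannot be concatenated with itself
        if (identical(ra[k], rb[k])) return(FALSE)
        if (!signals_mergeable(sa, sb, axis = 1L)) return(FALSE)
      } else {
        return(FALSE) # view paired with non-view
      }
    }
  }
  # (4) type-specific requirements
  switch(oi$tag,
    DotInc = {
      sa <- e$sigs[[oi$reads[1L]]]
      sb <- e$sigs[[oj$reads[1L]]]
      if (!identical(sa$shape, sb$shape)) return(FALSE) # uniform BSR blocks
    },
    BsrDotInc = {
      if (!identical(oi$params$block_shape, oj$params$block_shape)) {
        return(FALSE)
      }
    },
    SimNeurons = {
      if (!identical(oi$params$tau_rc, oj$params$tau_rc) ||
          !identical(oi$params$tau_ref, oj$params$tau_ref)) {
        return(FALSE)
      }
    },
    Reset = {
      if (!identical(oi$params$value, oj$params$value)) return(FALSE)
    },
    Copy = {
      if (!identical(oi$params$mode, oj$params$mode)) return(FALSE)
    }
  )
  chain_alias_ok(e, c(ui, uj))
}

# Merging concatenates each non-view slot's signals into a fresh base and
# rewrites all references. If one memory block appears at two different slot
# positions within the chain (other than as views everywhere), that rewrite
# would alias slots against each other, so such chains are rejected.
chain_alias_ok <- function(e, uids) {
  slot_of <- list() # base -> slots where it occurs
  nonview <- character() # bases with at least one non-view occurrence
  per_slot <- list() # "base|slot" -> non-view occurrence count
  for (u in uids) {
    op <- e$ops[[u]]
    k <- 0L
    for (role in aligned_roles) {
      for (r in op[[role]]) {
        k <- k + 1L
        s <- e$sigs[[r]]
        b <- sig_base_name(s)
        slot_of[[b]] <- unique(c(slot_of[[b]], k))
        if (!is_view(s)) {
          nonview <- c(nonview, b)
          key <- paste0(b, "|", k)
          per_slot[[key]] <- (per_slot[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  for (b in names(slot_of)) {
    if (length(slot_of[[b]]) > 1L && b %in% nonview) return(FALSE)
  }
  # one memory block cannot be concatenated with itself
  !any(vapply(per_slot, function(x) x > 1L, logical(1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A candidate may join a chain only if it is mergeable with the chain's last
# member, independent of every member (pairwise independence does not imply
# chain-set independence -- a dependence through an interior member would
# let the merge close a cycle), and free of cross-slot aliasing with the
# whole chain.
can_join_chain <- function(e, chain, cand) {
  if (!can_merge_ctx(e, chain[length(chain)], cand)) return(FALSE)
  if (length(chain) > 1L) {
    reach <- ctx_reach(e)
    for (m in chain[-length(chain)]) {
      if (!independent_ops(m, cand, reach)) return(FALSE)
    }
  }
  chain_alias_ok(e, c(chain, cand))
}

#' Can two operators be merged?
#'
#' True when (1) both operators have the same mergeable type, (2) neither
#' depends on the other (checked on the transitive closure of the dependency
#' graph), (3) every positionally corresponding signal pair allows merging
#' -- both sequential views ([views_mergeable()]) or both distinct non-view
#' signals ([signals_mergeable()]); a view paired with a non-view fails --
#' and (4) type-specific extras hold: `DotInc` requires equal weight-matrix
#' shapes (uniform blocks), `SimNeurons` equal time constants, `Reset` equal
#' constants, `Copy` equal modes.
#'
#' @param model A `nef_model`.
#' @param a,b Operator identifiers.
#' @param reach Optional precomputed `nef_reach` for the model's dependency
#'   graph.
#' @return Logical scalar.
#' @export
can_merge <- function(model, a, b, reach = NULL) {
  e <- opt_ctx(model)
  if (!is.null(reach)) e$reach <- reach
  can_merge_ctx(e, a, b)
}

# ---------------------------------------------------------------------------
# Operator merging

merge_slot <- function(e, refs) {
  sigs <- e$sigs[refs]
  vf <- vapply(sigs, is_view, logical(1L))
  if (all(vf)) {
    merge_view_chain_ctx(e, refs)
  } else if (!any(vf)) {
    merge_signals_ctx(e, refs, axis = 1L)$base
  } else {
    stop("merge: slot mixes views and non-view signals")
  }
}

merge_operators_ctx <- function(e, chain) {
  if (length(chain) < 2L) {
    stop("merge requires at least two operators")
  }
  ops <- e$ops[chain]
  if (any(vapply(ops, is.null, logical(1L)))) {
    stop("merge: unknown operator identifier")
  }
  tags <- unique(vapply(ops, function(o) o$tag, character(1L)))
  if (length(tags) != 1L) {
    stop("merge: operators have heterogeneous tags: ",
         paste(tags, collapse = ", "))
  }
  tag <- tags[[1L]]
  if (!op_mergeable(tag)) stop("merge: operator type ", tag, " cannot merge")

  slot_refs <- function(role, k) {
    vapply(e$ops[chain], function(o) o[[role]][k], character(1L))
  }
  merged <- NULL
  if (tag == "DotInc") {
    # Eq.-style block-diagonal product: the dense weight blocks are copied
    # into a block-sparse operator; the zero off-diagonal blocks are never
    # materialized, so storage grows linearly in the number of blocks.
    blocks <- lapply(chain, function(u) {
      a <- e$ops[[u]]$reads[1L]
      if (length(e$sigs[[a]]$shape) != 2L) stop("DotInc merge: A must be 2-D")
      ref_initial_matrix(e$sigs, a)
    })
    a_names <- vapply(e$ops[chain], function(o) o$reads[1L], character(1L))
    xm <- merge_slot(e, slot_refs("reads", 2L))
    ym <- merge_slot(e, slot_refs("incs", 1L))
    merged <- op_bsr_dot_inc(blocks, xm, ym)
  } else if (tag == "BsrDotInc") {
    blocks <- unlist(lapply(e$ops[chain], function(o) o$params$blocks),
                     recursive = FALSE)
    a_names <- character()
    xm <- merge_slot(e, slot_refs("reads", 1L))
    ym <- merge_slot(e, slot_refs("incs", 1L))
    merged <- op_bsr_dot_inc(blocks, xm, ym)
  } else {
    a_names <- character()
    roles <- list()
    for (role in aligned_roles) {
      nref <- length(ops[[1L]][[role]])
      roles[[role]] <- character(nref)
      for (k in seq_len(nref)) {
        roles[[role]][k] <- merge_slot(e, slot_refs(role, k))
      }
    }
    params <- switch(tag,
      Reset = list(value = ops[[1L]]$params$value),
      Copy = list(mode = ops[[1L]]$params$mode),
      SimNeurons = list(tau_rc = ops[[1L]]$params$tau_rc,
                        tau_ref = ops[[1L]]$params$tau_ref),
      list()
    )
    merged <- new_operator(tag, sets = roles$sets, incs = roles$incs,
                           reads = roles$reads, updates = roles$updates,
                           params = params)
  }
  validate_operator(merged, e$sigs)

  # splice: drop the chain, insert the merged operator at the position of
  # the first replaced operator (fresh declaration index)
  e$op_seq <- e$op_seq + 1L
  uid <- sprintf("mg%04d", e$op_seq)
  merged$uid <- uid
  merged$decl <- e$op_seq
  all_uids <- names(e$ops)
  at <- match(chain[1L], all_uids)
  kept <- e$ops[setdiff(all_uids, chain)]
  before <- names(kept)[seq_len(sum(match(names(kept), all_uids) < at))]
  e$ops <- c(kept[before], stats::setNames(list(merged), uid),
             kept[setdiff(names(kept), before)])

  # prune weight-matrix signals orphaned by the block-sparse rewrite
  if (length(a_names)) prune_signals(e, a_names)

  ctx_invalidate(e)
  rec <- list(replaced = chain, merged = uid, tag = tag,
              reduction = length(chain) - 1L)
  e$log[[length(e$log) + 1L]] <- rec
  rec
}

# Remove the named non-view signals (and views into them) if nothing still
# references them.
prune_signals <- function(e, names) {
  referenced <- unique(c(
    unlist(lapply(e$ops, op_refs), use.names = FALSE),
    vapply(e$probes, function(p) p$target, character(1L))
  ))
  view_bases <- unique(vapply(
    e$sigs[intersect(referenced, names(e$sigs))],
    function(s) if (is_view(s)) s$base else NA_character_, character(1L)
  ))
  for (nm in names) {
    if (nm %in% referenced || nm %in% view_bases) next
    dead_views <- vapply(e$sigs, function(s) {
      is_view(s) && identical(s$base, nm) && !(s$name %in% referenced)
    }, logical(1L))
    if (any(dead_views)) e$sigs[names(e$sigs)[dead_views]] <- NULL
    still <- any(vapply(e$sigs, function(s) {
      is_view(s) && identical(s$base, nm)
    }, logical(1L)))
    if (!still) e$sigs[[nm]] <- NULL
  }
  invisible(e)
}

#' Merge a chain of operators
#'
#' Replaces a homogeneous chain of mutually mergeable operators by one
#' operator over concatenated memory. Per-tag construction: `Copy`,
#' `ElementwiseInc`, `Reset`, `SimNeurons` and `TimeUpdate` merge their role
#' signals slot-wise (sequential views span, non-view signals concatenate
#' into a fresh base with all other references rewritten to views);
#' a `DotInc` chain becomes one `BsrDotInc` whose dense blocks are the
#' weight matrices in chain order. The merged operator inherits the union of
#' the replaced operators' dependencies.
#'
#' @param model A `nef_model`.
#' @param chain Character vector (length >= 2) of operator identifiers, in
#'   merge order. Adjacent pairs must satisfy [can_merge()], and every pair
#'   of members must be mutually independent.
#' @return A list with elements `model` (rewritten model) and `record`
#'   (the merge record: `replaced`, `merged`, `tag`, `reduction`).
#' @export
merge_operators <- function(model, chain) {
  e <- opt_ctx(model)
  if (length(chain) < 2L) stop("merge requires at least two operators")
  for (i in seq_len(length(chain) - 1L)) {
    if (!can_join_chain(e, chain[seq_len(i)], chain[i + 1L])) {
      stop("operators '", chain[i], "' and '", chain[i + 1L],
           "' cannot be merged")
    }
  }
  rec <- merge_operators_ctx(e, chain)
  list(model = ctx_model(e), record = rec)
}

#' Merge signals into one sequential memory block
#'
#' Allocates a new block the size of the combined shape, copies the initial
#' data over, and rewrites every operator and probe referencing the inputs
#' to use a contiguous view into the merged block at the input's cumulative
#' offset.
#'
#' @param model A `nef_model`.
#' @param names Signal names in concatenation order (pairwise
#'   [signals_mergeable()]).
#' @param axis Concatenation axis (only axis 1 is supported).
#' @return List with `model`, `base` (merged signal name) and `replacements`
#'   (named character: old name -> replacement view).
#' @export
merge_signals <- function(model, names, axis = 1L) {
  e <- opt_ctx(model)
  r <- merge_signals_ctx(e, names, axis = axis)
  list(model = ctx_model(e), base = r$base, replacements = r$replacements)
}

#' Merge sequential views into one spanning view
#'
#' No data is copied: the result is a single view covering the chain,
#' starting at the first view's offset.
#'
#' @param model A `nef_model`.
#' @param names View names in memory order (pairwise [views_mergeable()]).
#' @return List with `model` and `view` (name of the spanning view).
#' @export
merge_view_chain <- function(model, names) {
  e <- opt_ctx(model)
  vn <- merge_view_chain_ctx(e, names)
  list(model = ctx_model(e), view = vn)
}

# ---------------------------------------------------------------------------
# Sweep over one group

perform_merges_ctx <- function(e, group) {
  group <- setdiff(group, e$excluded)
  group <- intersect(group, names(e$ops))
  if (length(group) < 1L) return(0L)

  # freeze sort keys: offset/size of each operator's first view (0 if none)
  keys <- vapply(group, function(u) {
    first_view_key(e$ops[[u]], e$sigs)
  }, integer(2L))
  voff <- keys[1L, ]
  vsz <- keys[2L, ]
  decl <- vapply(group, function(u) e$ops[[u]]$decl, integer(1L))
  ord <- order(voff, decl)
  O <- group[ord]
  voff <- stats::setNames(voff[ord], O)
  vsz <- stats::setNames(vsz[ord], O)

  consumed <- character()
  n_reduced <- 0L
  for (i in seq_along(O)) {
    oi <- O[i]
    if (oi %in% consumed) next
    m <- oi
    if (i < length(O)) {
      for (j in (i + 1L):length(O)) {
        oj <- O[j]
        if (oj %in% consumed) next
        # skip candidates whose first view starts before the end of oi's:
        # their memory lies in front and can never be sequential after oi
        if (voff[[oj]] < voff[[oi]] + vsz[[oi]]) next
        if (can_join_chain(e, m, oj)) {
          m <- c(m, oj)
        } else if (voff[[m[length(m)]]] + vsz[[m[length(m)]]] < voff[[oj]]) {
          break # all further views are non-consecutive
        }
      }
    }
    if (length(m) > 1L) {
      merge_operators_ctx(e, m)
      consumed <- c(consumed, m)
      n_reduced <- n_reduced + length(m) - 1L
    } else if (op_has_view(e$ops[[oi]], e$sigs)) {
      # a view operator that merged with nothing can never merge later
      e$excluded <- c(e$excluded, oi)
    }
  }
  n_reduced
}

#' Greedy merge sweep over one operator group
#'
#' Implements the per-group merge procedure: operators are stably sorted by
#' the offset of their first signal view (declaration order breaks ties) and
#' scanned greedily, growing a chain while candidates remain mergeable with
#' the chain's tail and independent of every chain member. Candidates whose
#' first view begins before the end of the sweep operator's view are
#' skipped, and the scan breaks once views stop being consecutive. Chains of
#' length >= 2 are merged in place; view operators that merged with nothing
#' are reported as never-mergeable (excludable from later passes).
#'
#' @param model A `nef_model`.
#' @param group Character vector of operator identifiers sharing one tag;
#'   if any has a view, all first views must share one base.
#' @return List with `model`, `n_merged` (reduction in operator count) and
#'   `excluded` (never-mergeable view operators found).
#' @export
perform_merges <- function(model, group) {
  ops <- model$operators[group]
  if (any(vapply(ops, is.null, logical(1L)))) {
    stop("perform_merges: unknown operator identifier")
  }
  tags <- unique(vapply(ops, function(o) o$tag, character(1L)))
  if (length(tags) > 1L) {
    stop("perform_merges: group mixes operator tags: ",
         paste(tags, collapse = ", "))
  }
  bases <- unique(stats::na.omit(vapply(
    ops, function(o) first_view_base(o, model$signals), character(1L)
  )))
  if (length(bases) > 1L) {
    stop("perform_merges: first views of the group lie in different bases")
  }
  e <- opt_ctx(model)
  n <- perform_merges_ctx(e, group)
  list(model = ctx_model(e), n_merged = n, excluded = e$excluded)
}

#' Group operators for merging
#'
#' Different operator types can never merge, and views with different bases
#' can never merge, so operators are grouped by (tag, base of first view);
#' operators without views form their own per-tag group. Groups are emitted
#' in the heuristic tag order `ElementwiseInc`, `Copy`, `DotInc`,
#' `SimNeurons` -- merging these common types first tends to yield better
#' final graphs -- followed by remaining tags alphabetically; within a tag,
#' groups follow first declaration.
#'
#' @param model A `nef_model`.
#' @param uids Operator identifiers to group; defaults to all operators.
#' @return List of character vectors (one group each).
#' @export
group_operators <- function(model, uids = NULL) {
  if (is.null(uids)) uids <- names(model$operators)
  if (length(uids) == 0L) return(list())
  sigs <- model$signals
  tags <- vapply(uids, function(u) model$operators[[u]]$tag, character(1L))
  bases <- vapply(uids, function(u) {
    b <- first_view_base(model$operators[[u]], sigs)
    if (is.na(b)) "" else b
  }, character(1L))
  keyed <- split(uids, paste0(tags, "\036", bases))
  heuristic <- c("ElementwiseInc", "Copy", "DotInc", "SimNeurons")
  key_tags <- vapply(strsplit(names(keyed), "\036", fixed = TRUE),
                     `[[`, character(1L), 1L)
  tag_order <- c(intersect(heuristic, key_tags),
                 sort(setdiff(unique(key_tags), heuristic)))
  out <- list()
  for (tg in tag_order) {
    grp_keys <- names(keyed)[key_tags == tg]
    # deterministic within-tag order: by first declaration of the group
    firsts <- vapply(keyed[grp_keys], function(g) {
      min(vapply(g, function(u) model$operators[[u]]$decl, integer(1L)))
    }, integer(1L))
    for (k in grp_keys[order(firsts)]) out[[length(out) + 1L]] <- keyed[[k]]
  }
  out
}

#' Optimize a model's computation graph
#'
#' Repeatedly sweeps the operator groups, merging identical independent
#' operators and concatenating their operands into sequential memory, until
#' no further reduction in the operator count is possible. Passes are
#' view-first: by default only operators referencing signal views are
#' considered, because views impose a memory order on the merged operands
#' that plain signals do not -- merging view-free operators too early can
#' fix an operand order that blocks later view merges. Only when a pass
#' yields no reduction is one pass over view-free operators allowed, after
#' which view passes resume if it reduced the count. Optionally the process
#' also stops once the merge rate of a pass falls below `rate_threshold`
#' times the average rate over all passes (useful on very large graphs where
#' late passes buy little).
#'
#' The optimized model computes exactly the same per-element arithmetic as
#' the input; probe traces agree to floating-point reproducibility (see
#' [traces_equivalent()]).
#'
#' @param model A `nef_model`.
#' @param enable_rate_stop Enable the merge-rate stopping criterion
#'   (disabled by default: it depends on wall-clock timing and desk-scale
#'   graphs finish in few passes anyway).
#' @param rate_threshold Fraction of the average merge rate below which a
#'   pass triggers the stop (default 0.01).
#' @param clock Time source (a zero-argument function returning seconds);
#'   injectable for deterministic tests of the stopping rule.
#' @param view_first Start with a view-only pass (the default policy).
#'   Setting `FALSE` allows view-free merges in the first pass.
#' @return An object of class `nef_optimization`: list with `model` (the
#'   rewritten model) and `report` (`nef_opt_report`: `ops_before`,
#'   `ops_after`, per-pass counters, `signal_replacement_count`, `merges`).
#' @export
optimize_model <- function(model, enable_rate_stop = FALSE,
                           rate_threshold = 0.01, clock = NULL,
                           view_first = TRUE) {
  stopifnot(inherits(model, "nef_model"))
  if (is.null(clock)) clock <- function() proc.time()[["elapsed"]]
  e <- opt_ctx(model)
  n_all <- length(e$ops)
  n0 <- n_all
  n1 <- 0L
  t_start <- clock()
  t_pass <- t_start
  v <- isTRUE(view_first)
  passes <- list()

  rate_ok <- function() {
    if (!enable_rate_stop) return(TRUE)
    now <- clock()
    total <- now - t_start
    this_pass <- now - t_pass
    if (total <= 0 || this_pass <= 0) return(TRUE)
    rate_threshold * n_all / total < (n0 - n1) / this_pass
  }

  while (v || (n1 < n0 && rate_ok())) {
    t_pass <- clock()
    v <- n0 != n1
    ohat <- character()
    for (uid in names(e$ops)) {
      if (uid %in% e$excluded) next
      if (op_has_view(e$ops[[uid]], e$sigs) == v) ohat <- c(ohat, uid)
    }
    n0 <- length(e$ops)
    pass_merged <- 0L
    groups <- group_operators(ctx_model(e), ohat)
    for (g in groups) {
      ctx_invalidate(e) # fresh closure for every group's sweep
      pass_merged <- pass_merged + perform_merges_ctx(e, g)
    }
    n1 <- length(e$ops)
    passes[[length(passes) + 1L]] <- list(
      view_pass = v, merges = pass_merged, duration = clock() - t_pass
    )
  }

  report <- structure(
    list(
      ops_before = n_all, ops_after = length(e$ops), passes = passes,
      signal_replacement_count = e$n_repl, merges = e$log
    ),
    class = "nef_opt_report"
  )
  structure(list(model = ctx_model(e), report = report),
            class = "nef_optimization")
}

#' @export
print.nef_opt_report <- function(x, ...) {
  cat(sprintf("<optimization: %d -> %d operators in %d passes>\n",
              x$ops_before, x$ops_after, length(x$passes)))
  for (i in seq_along(x$passes)) {
    p <- x$passes[[i]]
    cat(sprintf("  pass %d (%s): %d merged, %.3fs\n", i,
                if (p$view_pass) "views" else "view-free", p$merges,
                p$duration))
  }
  cat(sprintf("  signal replacements: %d\n", x$signal_replacement_count))
  invisible(x)
}

#' @export
print.nef_optimization <- function(x, ...) {
  print(x$report)
  invisible(x)
}
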