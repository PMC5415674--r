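#' Construct a dependency graph object
#'
#' @param vertices Character vector of vertex identifiers.
#' @param edges Named list mapping each vertex to a character vector of
#'   successors. Vertices without successors may be omitted.
#' @return An object of class `nef_graph`.
#' @export
make_graph <- function(vertices, edges = list()) {
  vertices <- as.character(vertices)
  full <- stats::setNames(vector("list", length(vertices)), vertices)
  for (v in vertices) full[[v]] <- character()
  for (v in names(edges)) {
    if (!v %in% vertices) stop("edge source '", v, "' is not a vertex")
    succ <- unique(as.character(edges[[v]]))
    if (!all(succ %in% vertices)) stop("edge target missing from vertices")
    full[[v]] <- succ
  }
  structure(
    list(vertices = vertices, edges = full,
         n_edges = sum(lengths(full))),
    class = "nef_graph"
  )
}

#' @export
print.nef_graph <- function(x, ...) {
  cat(sprintf("<nef_graph: %d vertices, %d edges>\n",
              length(x$vertices), x$n_edges))
  invisible(x)
}

#' Build the operator dependency graph of a model
#'
#' Each operator's declared access roles implicitly order it against other
#' operators touching the same memory. For every pair of operators accessing
#' overlapping regions of one base block, edges enforce: set before
#' increment, increment before read, read before update (and set before
#' read/update, increment before update). Views induce edges through their
#' base; whole-signal access spans the whole block, so disjoint views of one
#' base constrain each other only when their regions overlap.
#'
#' Two setters (or two updaters) writing overlapping regions of one block
#' violate the access-role contract and raise an error naming the signal.
#'
#' @param model A `nef_model` (or a plain list of operators plus a signal
#'   registry via `signals`).
#' @param signals Signal registry; defaults to `model$signals`.
#' @return A `nef_graph` whose vertices are operator identifiers in
#'   declaration order.
#' @export
build_dependency_graph <- function(model, signals = NULL) {
  if (inherits(model, "nef_model")) {
    ops <- model$operators
    if (is.null(signals)) signals <- model$signals
  } else {
    ops <- model
    if (is.null(signals)) stop("`signals` required when passing operators")
  }
  uids <- names(ops)

  # per base block: role accesses as (uid, from, to) with 0-based half-open
  # regions
  acc <- list()
  note <- function(role, uid, ref) {
    sig <- signals[[ref]]
    b <- sig_base_name(sig)
    rg <- sig_range(sig)
    rec <- list(uid = uid, from = rg[1L], to = rg[2L])
    if (is.null(acc[[b]])) {
      acc[[b]] <<- list(sets = list(), incs = list(), reads = list(),
                        updates = list())
    }
    acc[[b]][[role]][[length(acc[[b]][[role]]) + 1L]] <<- rec
  }
  for (uid in uids) {
    op <- ops[[uid]]
    for (r in op$sets) note("sets", uid, r)
    for (r in op$incs) note("incs", uid, r)
    for (r in op$reads) note("reads", uid, r)
    for (r in op$updates) note("updates", uid, r)
  }

  overlap <- function(a, b) max(a$from, b$from) < min(a$to, b$to)
  edges <- stats::setNames(vector("list", length(uids)), uids)
  for (u in uids) edges[[u]] <- character()
  add_edges <- function(pre, post) {
    for (a in pre) {
      for (b in post) {
        if (a$uid != b$uid && overlap(a, b)) {
          edges[[a$uid]] <<- c(edges[[a$uid]], b$uid)
        }
      }
    }
  }
  for (b in names(acc)) {
    roles <- acc[[b]]
    # exclusive-writer invariants at region granularity
    for (excl in c("sets", "updates")) {
      writers <- roles[[excl]]
      if (length(writers) > 1L) {
        for (i in seq_len(length(writers) - 1L)) {
          for (j in (i + 1L):length(writers)) {
            if (writers[[i]]$uid != writers[[j]]$uid &&
                overlap(writers[[i]], writers[[j]])) {
              stop(
                "signal '", b, "': operators '", writers[[i]]$uid, "' and '",
                writers[[j]]$uid, "' both ",
                if (excl == "sets") "set" else "update",
                " an overlapping region"
              )
            }
          }
        }
      }
    }
    add_edges(roles$sets, roles$incs)
    add_edges(roles$sets, roles$reads)
    add_edges(roles$sets, roles$updates)
    add_edges(roles$incs, roles$reads)
    add_edges(roles$incs, roles$updates)
    add_edges(roles$reads, roles$updates)
  }
  edges <- lapply(edges, function(e) sort(unique(e)))
  structure(
    list(vertices = uids, edges = edges, n_edges = sum(lengths(edges))),
    class = "nef_graph"
  )
}

#' Topologically sort a dependency graph
#'
#' Kahn's algorithm with deterministic tie-breaking: among ready vertices the
#' one earliest in the graph's vertex (declaration) order runs first, so the
#' schedule is stable across runs.
#'
#' @param g A `nef_graph`.
#' @return Character vector of vertices in a valid execution order (a linear
#'   extension of the graph's edges).
#' @export
toposort <- function(g) {
  stopifnot(inherits(g, "nef_graph"))
  verts <- g$vertices
  n <- length(verts)
  if (n == 0L) return(character())
  pos <- stats::setNames(seq_len(n), verts)
  indeg <- stats::setNames(integer(n), verts)
  for (v in verts) {
    for (s in g$edges[[v]]) indeg[[s]] <- indeg[[s]] + 1L
  }
  ready <- verts[indeg[verts] == 0L] # already in declaration order
  out <- character(n)
  k <- 0L
  while (length(ready) > 0L) {
    v <- ready[1L]
    ready <- ready[-1L]
    k <- k + 1L
    out[k] <- v
    newly <- character()
    for (s in g$edges[[v]]) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) newly <- c(newly, s)
    }
    if (length(newly)) {
      ready <- c(ready, newly)
      ready <- ready[order(pos[ready])]
    }
  }
  if (k < n) {
    stuck <- verts[indeg[verts] > 0L]
    cyc <- find_cycle(g, stuck)
    stop("dependency graph has a cycle: ", paste(cyc, collapse = " -> "))
  }
  out
}

# One concrete cycle among the stuck vertices, for error reporting.
find_cycle <- function(g, stuck) {
  if (length(stuck) == 0L) return(character())
  onpath <- character()
  seen <- character()
  res <- NULL
  dfs <- function(v) {
    if (!is.null(res)) return()
    if (v %in% onpath) {
      i <- match(v, onpath)
      res <<- c(onpath[i:length(onpath)], v)
      return()
    }
    if (v %in% seen) return()
    seen <<- c(seen, v)
    onpath <<- c(onpath, v)
    for (s in intersect(g$edges[[v]], stuck)) dfs(s)
    onpath <<- onpath[-length(onpath)]
  }
  for (v in stuck) {
    dfs(v)
    if (!is.null(res)) break
  }
  res
}

#' Transitive closure with interned reachable-sets
#'
#' Computes, for every vertex, the set of vertices reachable from it in any
#' number of steps, enabling dependence queries in (amortized) constant time.
#' In typical built networks many operators share exactly the same
#' reachable-set; each distinct set is therefore stored once in a
#' content-addressed intern table and vertices hold handles into it, keeping
#' memory far below one set instance per vertex.
#'
#' @param g An acyclic `nef_graph`.
#' @return An object of class `nef_reach` with fields `vertices`, `reach`
#'   (vertex -> intern key), `sets` (intern table), and `n_sets` (number of
#'   distinct stored sets).
#' @export
transitive_closure <- function(g) {
  order <- toposort(g) # errors on a cycle
  verts <- g$vertices
  n <- length(verts)
  if (n == 0L) {
    return(structure(
      list(vertices = character(), reach = character(), sets = list(),
           n_sets = 0L),
      class = "nef_reach"
    ))
  }
  idx <- stats::setNames(seq_len(n), verts)
  mat <- matrix(FALSE, n, n)
  for (v in rev(order)) {
    i <- idx[[v]]
    row <- mat[i, ]
    for (s in g$edges[[v]]) {
      j <- idx[[s]]
      row[j] <- TRUE
      row <- row | mat[j, ]
    }
    mat[i, ] <- row
  }
  sets <- list()
  reach <- stats::setNames(character(n), verts)
  for (v in verts) {
    members <- verts[mat[idx[[v]], ]]
    key <- paste0("k|", paste(members, collapse = "\036"))
    if (is.null(sets[[key]])) sets[[key]] <- members
    reach[[v]] <- key
  }
  structure(
    list(vertices = verts, reach = reach, sets = sets,
         n_sets = length(sets)),
    class = "nef_reach"
  )
}

#' @export
print.nef_reach <- function(x, ...) {
  cat(sprintf("<nef_reach: %d vertices, %d interned reachable-sets>\n",
              length(x$vertices), x$n_sets))
  invisible(x)
}

#' Reachable-set of a vertex
#' @param reach A `nef_reach`.
#' @param v Vertex identifier.
#' @return Character vector of vertices reachable from `v`.
#' @export
reach_set <- function(reach, v) {
  key <- reach$reach[[v]]
  if (is.null(key) || is.na(key)) stop("vertex '", v, "' not in closure")
  reach$sets[[key]]
}

#' Are two operators independent?
#'
#' Two operators may only be merged when the execution of one does not
#' depend on the other, i.e. neither is reachable from the other in the
#' dependency graph.
#'
#' @param a,b Vertex (operator) identifiers.
#' @param reach A `nef_reach` for the dependency graph.
#' @return Logical scalar.
#' @export
independent_ops <- function(a, b, reach) {
  !(b %in% reach_set(reach, a)) && !(a %in% reach_set(reach, b))
}
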