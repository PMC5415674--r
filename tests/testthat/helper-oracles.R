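# Independent oracles used across the suite. These deliberately use the
# dumbest correct algorithm available so they share no code path with the
# implementation they check.

# Per-vertex breadth-first reachability on a nef_graph.
bfs_reachable <- function(g, v) {
  seen <- character()
  frontier <- g$edges[[v]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    if (!length(new)) break
    seen <- c(seen, new)
    frontier <- unique(unlist(g$edges[new], use.names = FALSE))
  }
  sort(seen)
}

# Materialized block-diagonal matrix-vector product.
dense_block_diag_product <- function(blocks, x) {
  m <- vapply(blocks, nrow, integer(1L))
  n <- vapply(blocks, ncol, integer(1L))
  D <- matrix(0, sum(m), sum(n))
  ro <- 0L
  co <- 0L
  for (b in blocks) {
    D[ro + seq_len(nrow(b)), co + seq_len(ncol(b))] <- b
    ro <- ro + nrow(b)
    co <- co + ncol(b)
  }
  as.numeric(D %*% x)
}

# Micro model: a single constant-current LIF population, spikes probed.
lif_probe_model <- function(J, tau_rc = 0.02, tau_ref = 0.002, dt = 0.001) {
  m <- nef_model(dt = dt)
  m <- add_signal(m, nef_signal("J", initial = J))
  m <- add_signal(m, nef_signal("spk", shape = length(J)))
  m <- add_signal(m, nef_signal("vm", shape = length(J)))
  m <- add_signal(m, nef_signal("rf", shape = length(J)))
  m <- add_operator(m, op_sim_neurons("J", "spk", "vm", "rf",
                                      tau_rc = tau_rc, tau_ref = tau_ref))
  add_probe(m, "spk")
}

# Micro model wrapping one BsrDotInc over given blocks and input vector.
bsr_probe_model <- function(blocks, x) {
  m <- nef_model()
  ysize <- sum(vapply(blocks, nrow, integer(1L)))
  m <- add_signal(m, nef_signal("x", initial = x))
  m <- add_signal(m, nef_signal("y", shape = ysize))
  m <- add_operator(m, op_reset("y"))
  m <- add_operator(m, op_bsr_dot_inc(blocks, "x", "y"))
  add_probe(m, "y")
}

# Optimized-versus-unoptimized probe-trace discrepancy over n steps.
opt_discrepancy <- function(model, n_steps = 100L) {
  opt <- optimize_model(model)
  max_trace_diff(run_model(model, n_steps), run_model(opt$model, n_steps))
}
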