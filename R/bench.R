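#' Model specifications for benchmarking
#'
#' Lightweight descriptions of the generated benchmark families, consumed
#' by [bench()] and [gen_model_from_spec()].
#'
#' @param d Vector dimensionality.
#' @param n_per_d,n Neurons per dimension / per group.
#' @param s Number of splits (split-ensemble family).
#' @param n_ops Operator count (random family).
#' @param mode `"lif"` or `"direct"`.
#' @param seed RNG seed.
#' @return A list of class `nef_spec`.
#' @export
circconv_spec <- function(d, n_per_d = 10L, mode = "lif", seed = 1L) {
  structure(list(kind = "circconv", d = d, n_per_d = n_per_d, mode = mode,
                 seed = seed), class = "nef_spec")
}

#' @rdname circconv_spec
#' @export
split_spec <- function(d, s, n = 10L, mode = "lif", seed = 1L) {
  structure(list(kind = "split", d = d, s = s, n = n, mode = mode,
                 seed = seed), class = "nef_spec")
}

#' @rdname circconv_spec
#' @export
random_spec <- function(n_ops = 20L, seed = 1L) {
  structure(list(kind = "random", n_ops = n_ops, seed = seed),
            class = "nef_spec")
}

#' Build a model from a benchmark specification
#' @param spec A `nef_spec`.
#' @return A `nef_model`.
#' @export
gen_model_from_spec <- function(spec) {
  stopifnot(inherits(spec, "nef_spec"))
  switch(spec$kind,
    circconv = gen_circconv_model(spec$d, spec$n_per_d, spec$mode, spec$seed),
    split = gen_split_ensemble_model(spec$d, spec$s, spec$n, spec$mode,
                                     spec$seed),
    random = gen_random_model(spec$n_ops, spec$seed),
    order = gen_order_matters_model(spec$seed),
    stop("unknown model kind '", spec$kind, "'")
  )
}

#' Benchmark a model family
#'
#' Per trial: the model is built (and optionally optimized) under the clock
#' (build time), 10 warm-up steps pre-fill the memory buffers untimed, and
#' 1,000 further steps are timed as simulation time (one simulated second at
#' the default timestep). Reported times are means over trials. Operator
#' counts before/after optimization and instrumented step counters are
#' recorded; wall-clock numbers are hardware-dependent and informational.
#'
#' @param spec A `nef_spec` (see [circconv_spec()]).
#' @param optimize Run the graph optimizer as part of the build.
#' @param trials Number of trials averaged (>= 1).
#' @param n_steps Timed steps per trial.
#' @param warmup Untimed warm-up steps per trial.
#' @param keep_probes Keep the last trial's probe data (for equivalence
#'   checks).
#' @return An object of class `nef_bench`.
#' @export
bench <- function(spec, optimize = TRUE, trials = 5L, n_steps = 1000L,
                  warmup = 10L, keep_probes = FALSE) {
  stopifnot(trials >= 1L, n_steps >= 0L, warmup >= 0L)
  build_times <- numeric(trials)
  sim_times <- numeric(trials)
  warm_counts <- integer(trials)
  timed_counts <- integer(trials)
  ops_before <- NA_integer_
  ops_after <- NA_integer_
  probes <- NULL
  for (tr in seq_len(trials)) {
    t0 <- proc.time()[["elapsed"]]
    model <- gen_model_from_spec(spec)
    ops_before <- n_operators(model)
    if (optimize) {
      model <- optimize_model(model)$model
    }
    ops_after <- n_operators(model)
    compiled <- compile_plan(model)
    build_times[tr] <- proc.time()[["elapsed"]] - t0

    st <- init_state(model)
    for (i in seq_len(warmup)) sim_step(st, compiled)
    warm_counts[tr] <- st$step_index

    t1 <- proc.time()[["elapsed"]]
    pr <- run_model(model, n_steps, state = st)
    sim_times[tr] <- proc.time()[["elapsed"]] - t1
    timed_counts[tr] <- st$step_index - warm_counts[tr]
    if (keep_probes && tr == trials) probes <- pr
  }
  structure(
    list(
      spec = spec, optimize = optimize, trials = trials,
      n_steps = n_steps, warmup = warmup,
      build_time = mean(build_times), sim_time = mean(sim_times),
      build_times = build_times, sim_times = sim_times,
      warmup_steps_run = warm_counts, timed_steps_run = timed_counts,
      ops_before = ops_before, ops_after = ops_after,
      probes = probes
    ),
    class = "nef_bench"
  )
}

#' @export
print.nef_bench <- function(x, ...) {
  cat(sprintf(
    "<bench %s%s: build %.3fs, sim %.3fs (%d steps, %d trials), ops %d -> %d>\n",
    x$spec$kind, if (x$optimize) " optimized" else "",
    x$build_time, x$sim_time, x$n_steps, x$trials,
    x$ops_before, x$ops_after
  ))
  invisible(x)
}

#' Tabulate and serialize benchmark results
#'
#' @param results A list of `nef_bench` objects.
#' @param json Optional path; results are written as JSON.
#' @param csv Optional path; the summary table is written as CSV.
#' @return A data frame with one row per result (columns: kind, optimize,
#'   trials, n_steps, warmup, build_time, sim_time, ops_before, ops_after).
#' @export
bench_report <- function(results, json = NULL, csv = NULL) {
  stopifnot(is.list(results))
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "nef_bench"))
    data.frame(
      kind = r$spec$kind,
      optimize = r$optimize,
      trials = r$trials,
      n_steps = r$n_steps,
      warmup = r$warmup,
      build_time = r$build_time,
      sim_time = r$sim_time,
      ops_before = r$ops_before,
      ops_after = r$ops_after,
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
    kind = character(), optimize = logical(), trials = integer(),
    n_steps = integer(), warmup = integer(), build_time = numeric(),
    sim_time = numeric(), ops_before = integer(), ops_after = integer(),
    stringsAsFactors = FALSE
  )
  if (!is.null(json)) {
    payload <- lapply(results, function(r) {
      list(
        spec = unclass(r$spec), optimize = r$optimize, trials = r$trials,
        n_steps = r$n_steps, warmup = r$warmup,
        build_time = r$build_time, sim_time = r$sim_time,
        build_times = r$build_times, sim_times = r$sim_times,
        ops_before = r$ops_before, ops_after = r$ops_after
      )
    })
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  tab
}
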