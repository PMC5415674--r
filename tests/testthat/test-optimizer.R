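test_that("signal mergeability follows dtype and off-axis shape agreement", {
  s4 <- nef_signal("s4", shape = 4)
  s7 <- nef_signal("s7", shape = 7)
  expect_true(signals_mergeable(s4, s7)) # vectors always agree off-axis

  m34 <- nef_signal("m34", shape = c(3, 4))
  m54 <- nef_signal("m54", shape = c(5, 4))
  m35 <- nef_signal("m35", shape = c(3, 5))
  expect_true(signals_mergeable(m34, m54, axis = 1))
  expect_false(signals_mergeable(m34, m35, axis = 1))
  expect_false(signals_mergeable(s4, m34))

  v <- nef_view("v", "s4", 0L, 2L)
  expect_false(signals_mergeable(v, s4))
})

test_that("view mergeability requires one base and sequential memory", {
  a <- nef_view("a", "B", 0L, 4L)
  b <- nef_view("b", "B", 4L, 4L)
  gap <- nef_view("g", "B", 5L, 4L)
  other <- nef_view("o", "C", 4L, 4L)
  expect_true(views_mergeable(a, b))
  expect_false(views_mergeable(a, gap)) # gap breaks sequentiality
  expect_false(views_mergeable(b, a)) # order matters
  expect_false(views_mergeable(a, other)) # different bases: never
})

test_that("merge_signals concatenates memory and rewrites all references", {
  m <- nef_model()
  m <- add_signal(m, nef_signal("p", initial = c(1, 2)))
  m <- add_signal(m, nef_signal("q", initial = c(3, 4, 5)))
  m <- add_signal(m, nef_signal("dst", shape = 5))
  m <- add_view(m, "dst.lo", "dst", 0L, 2L)
  m <- add_view(m, "dst.hi", "dst", 2L, 3L)
  m <- add_operator(m, op_copy("p", "dst.lo", mode = "set"), name = "c1")
  m <- add_operator(m, op_copy("q", "dst.hi", mode = "set"), name = "c2")

  r <- merge_signals(m, c("p", "q"))
  base <- r$model$signals[[r$base]]
  expect_equal(base$initial, c(1, 2, 3, 4, 5))
  # operators now reference replacement views at cumulative offsets
  expect_equal(r$model$operators[["c1"]]$reads, unname(r$replacements["p"]))
  vq <- r$model$signals[[r$replacements[["q"]]]]
  expect_equal(vq$offset, 2L)
  # the rewritten model still runs and produces identical results
  m2 <- add_probe(m, "dst")
  r2 <- merge_signals(m2, c("p", "q"))
  expect_equal(run_model(r2$model, 2)$dst, run_model(m2, 2)$dst)

  # round-trip: every replacement view reads back the original initial
  set.seed(3)
  mm <- nef_model()
  vals <- lapply(1:5, function(i) rnorm(sample(2:5, 1)))
  for (i in 1:5) {
    mm <- add_signal(mm, nef_signal(sprintf("s%d", i), initial = vals[[i]]))
  }
  rr <- merge_signals(mm, sprintf("s%d", 1:5))
  st <- init_state(rr$model)
  for (i in 1:5) {
    ref <- rr$model$signals[[rr$replacements[[sprintf("s%d", i)]]]]
    buf <- get(ref$base, envir = st$buffers)
    expect_equal(buf[(ref$offset + 1):(ref$offset + ref$size)], vals[[i]])
  }

  expect_error(merge_signals(m, c("p", "p")), "itself")
})

test_that("merge_view_chain spans sequential views without copying", {
  m <- nef_model()
  m <- add_signal(m, nef_signal("B", initial = rnorm(8)))
  m <- add_view(m, "v1", "B", 0L, 4L)
  m <- add_view(m, "v2", "B", 4L, 4L)
  r <- merge_view_chain(m, c("v1", "v2"))
  sp <- r$model$signals[[r$view]]
  expect_equal(sp$offset, 0L)
  expect_equal(sp$size, 8L)
  expect_equal(sp$base, "B")

  # k consecutive unit views resolve to the same buffer elements
  m2 <- nef_model()
  m2 <- add_signal(m2, nef_signal("B", initial = rnorm(6)))
  for (i in 1:4) m2 <- add_view(m2, sprintf("u%d", i), "B", i - 1L, 1L)
  r2 <- merge_view_chain(m2, sprintf("u%d", 1:4))
  sp2 <- r2$model$signals[[r2$view]]
  st <- init_state(r2$model)
  buf <- get("B", envir = st$buffers)
  expect_equal(buf[(sp2$offset + 1):(sp2$offset + sp2$size)], buf[1:4])

  m3 <- add_view(m2, "gap", "B", 5L, 1L)
  expect_error(merge_view_chain(m3, c("u1", "gap")), "sequential")
})

test_that("can_merge enforces type, independence and slot compatibility", {
  m <- gen_ensemble_cluster_model(n_groups = 2, seed = 2)
  g <- build_dependency_graph(m)
  R <- transitive_closure(g)
  uid_of <- function(tag, k) {
    hits <- names(m$operators)[vapply(m$operators, function(o) o$tag,
                                      character(1)) == tag]
    hits[k]
  }
  # the two encoder products over unrelated signals merge
  expect_true(can_merge(m, uid_of("DotInc", 1), uid_of("DotInc", 2), R))
  # tag mismatch
  expect_false(can_merge(m, uid_of("Copy", 1), uid_of("DotInc", 1), R))
  # a dependent pair: the Copy feeding a DotInc through its input signal
  expect_false(independent_ops(uid_of("Copy", 1), uid_of("DotInc", 1), R))
  expect_false(can_merge(m, uid_of("Copy", 1), uid_of("DotInc", 1), R))

  # UserFunc operators never merge, even when structurally identical
  mu <- nef_model()
  mu <- add_signal(mu, nef_signal("x1", initial = 1))
  mu <- add_signal(mu, nef_signal("x2", initial = 2))
  mu <- add_signal(mu, nef_signal("y1", shape = 1))
  mu <- add_signal(mu, nef_signal("y2", shape = 1))
  mu <- add_operator(mu, op_user_func("identity", "y1", "x1"), name = "u1")
  mu <- add_operator(mu, op_user_func("identity", "y2", "x2"), name = "u2")
  expect_false(op_mergeable("UserFunc"))
  expect_false(can_merge(mu, "u1", "u2"))
})

test_that("merging two copies produces one copy with identical semantics", {
  m <- nef_model()
  m <- add_signal(m, nef_signal("s1", initial = c(1, 2)))
  m <- add_signal(m, nef_signal("s2", initial = c(3, 4, 5)))
  m <- add_signal(m, nef_signal("d1", shape = 2))
  m <- add_signal(m, nef_signal("d2", shape = 3))
  m <- add_operator(m, op_copy("s1", "d1"), name = "c1")
  m <- add_operator(m, op_copy("s2", "d2"), name = "c2")
  m <- add_probe(m, "d1")
  m <- add_probe(m, "d2")

  r <- merge_operators(m, c("c1", "c2"))
  expect_equal(n_operators(r$model), 1L)
  expect_equal(r$record$replaced, c("c1", "c2"))
  expect_identical(run_model(r$model, 1)$d1, run_model(m, 1)$d1)
  expect_identical(run_model(r$model, 1)$d2, run_model(m, 1)$d2)

  # degenerate chains and mixed tags are rejected
  expect_error(merge_operators(m, "c1"), "at least two")
  m2 <- add_operator(m, op_reset("d1"), name = "r1")
  expect_error(merge_operators(m2, c("c1", "r1")), "cannot be merged")
})

test_that("a DotInc chain merges into a BsrDotInc equal to the dense oracle", {
  set.seed(21)
  A1 <- matrix(rnorm(4), 2, 2)
  A2 <- matrix(rnorm(4), 2, 2)
  x1 <- rnorm(2)
  x2 <- rnorm(2)
  m <- nef_model()
  m <- add_signal(m, nef_signal("A1", initial = A1))
  m <- add_signal(m, nef_signal("A2", initial = A2))
  m <- add_signal(m, nef_signal("x1", initial = x1))
  m <- add_signal(m, nef_signal("x2", initial = x2))
  m <- add_signal(m, nef_signal("y1", shape = 2))
  m <- add_signal(m, nef_signal("y2", shape = 2))
  m <- add_operator(m, op_reset("y1"), name = "r1")
  m <- add_operator(m, op_reset("y2"), name = "r2")
  m <- add_operator(m, op_dot_inc("A1", "x1", "y1"), name = "d1")
  m <- add_operator(m, op_dot_inc("A2", "x2", "y2"), name = "d2")
  m <- add_probe(m, "y1")
  m <- add_probe(m, "y2")

  r <- merge_operators(m, c("d1", "d2"))
  merged <- Filter(function(o) o$tag == "BsrDotInc", r$model$operators)[[1]]
  expect_length(merged$params$blocks, 2L)
  expect_equal(bsr_storage_elements(merged), 8L)
  pr <- run_model(r$model, 1)
  expect_equal(c(pr$y1[1, ], pr$y2[1, ]),
               dense_block_diag_product(list(A1, A2), c(x1, x2)),
               tolerance = 1e-14)
  # the orphaned weight matrices were pruned from the registry
  expect_null(r$model$signals[["A1"]])
})

test_that("perform_merges implements the greedy sorted sweep", {
  # four copies over consecutive views collapse into one chain
  mk <- function(offsets, len = 2L) {
    m <- nef_model()
    m <- add_signal(m, nef_signal("src", initial = rnorm(8)))
    m <- add_signal(m, nef_signal("dst", shape = 8))
    for (i in seq_along(offsets)) {
      m <- add_view(m, sprintf("s.v%d", i), "src", offsets[i], len)
      m <- add_view(m, sprintf("d.v%d", i), "dst", offsets[i], len)
      m <- add_operator(m, op_copy(sprintf("s.v%d", i), sprintf("d.v%d", i),
                                   mode = "set"), name = sprintf("c%d", i))
    }
    add_probe(m, "dst")
  }
  m <- mk(c(0L, 2L, 4L, 6L))
  r <- perform_merges(m, sprintf("c%d", 1:4))
  expect_equal(r$n_merged, 3L)
  expect_equal(n_operators(r$model), 1L)
  expect_equal(run_model(r$model, 1)$dst, run_model(m, 1)$dst)

  # a gap stops the chain: nothing merges, both ops become never-mergeable
  m2 <- nef_model()
  m2 <- add_signal(m2, nef_signal("src", initial = rnorm(8)))
  m2 <- add_signal(m2, nef_signal("d1", shape = 2))
  m2 <- add_signal(m2, nef_signal("d2", shape = 2))
  m2 <- add_view(m2, "v0", "src", 0L, 2L)
  m2 <- add_view(m2, "v3", "src", 3L, 2L)
  m2 <- add_operator(m2, op_copy("v0", "d1"), name = "c1")
  m2 <- add_operator(m2, op_copy("v3", "d2"), name = "c2")
  r2 <- perform_merges(m2, c("c1", "c2"))
  expect_equal(r2$n_merged, 0L)
  expect_setequal(r2$excluded, c("c1", "c2"))

  # ten view-free independent elementwise increments collapse to one
  m3 <- nef_model()
  for (i in 1:10) {
    nm <- function(s) sprintf("%s%02d", s, i)
    m3 <- add_signal(m3, nef_signal(nm("a"), initial = rnorm(3)))
    m3 <- add_signal(m3, nef_signal(nm("x"), initial = rnorm(3)))
    m3 <- add_signal(m3, nef_signal(nm("y"), shape = 3))
    m3 <- add_operator(m3, op_reset(nm("y")), name = nm("r"))
    m3 <- add_operator(m3, op_elementwise_inc(nm("a"), nm("x"), nm("y")),
                       name = nm("e"))
    m3 <- add_probe(m3, nm("y"))
  }
  before <- run_model(m3, 1)
  r3 <- perform_merges(m3, sprintf("e%02d", 1:10))
  expect_equal(r3$n_merged, 9L)
  expect_identical(run_model(r3$model, 1), before)

  # group preconditions
  expect_error(perform_merges(m3, c("e01", "r01")), "mixes")
})

test_that("group_operators keys by type and first-view base, in heuristic order", {
  m <- nef_model()
  m <- add_signal(m, nef_signal("b1", initial = rnorm(4)))
  m <- add_signal(m, nef_signal("b2", initial = rnorm(4)))
  m <- add_signal(m, nef_signal("t1", shape = 2))
  m <- add_signal(m, nef_signal("t2", shape = 2))
  m <- add_signal(m, nef_signal("W", initial = matrix(rnorm(4), 2, 2)))
  m <- add_signal(m, nef_signal("z", shape = 2))
  m <- add_view(m, "b1.v", "b1", 0L, 2L)
  m <- add_view(m, "b2.v", "b2", 0L, 2L)
  m <- add_operator(m, op_dot_inc("W", "t1", "z"), name = "dot1")
  m <- add_operator(m, op_reset("z"), name = "rz")
  m <- add_operator(m, op_copy("b1.v", "t1"), name = "cp1")
  m <- add_operator(m, op_copy("b2.v", "t2"), name = "cp2")
  g <- group_operators(m)
  tags <- vapply(g, function(grp) m$operators[[grp[1]]]$tag, character(1))
  # Copy groups precede DotInc groups; Reset comes after the heuristic tags
  expect_equal(tags, c("Copy", "Copy", "DotInc", "Reset"))
  # the two copies have first views in different bases: separate groups
  expect_equal(sort(vapply(g[1:2], length, integer(1))), c(1L, 1L))
  expect_equal(group_operators(nef_model()), list())
})

test_that("optimize collapses the paired-group cluster to one op per tag", {
  m <- gen_ensemble_cluster_model(n_groups = 2, seed = 4)
  opt <- optimize_model(m)
  tags <- operator_tags(opt$model)
  expect_equal(sort(names(tags)),
               sort(c("Copy", "Reset", "BsrDotInc", "ElementwiseInc",
                      "SimNeurons")))
  expect_true(all(tags == 1L))
  expect_equal(opt$report$ops_before - opt$report$ops_after,
               sum(vapply(opt$report$merges, function(x) x$reduction,
                          integer(1))))
  expect_identical(run_model(m, 25), run_model(opt$model, 25))
})

test_that("optimization is a fixed point and counts are monotone", {
  m <- gen_circconv_model(4, mode = "lif", seed = 9)
  o1 <- optimize_model(m)
  expect_lte(n_operators(o1$model), n_operators(m))
  for (p in o1$report$passes) expect_gte(p$merges, 0L)
  o2 <- optimize_model(o1$model)
  expect_equal(o2$report$ops_before, o2$report$ops_after)
  expect_length(o2$report$merges, 0L)

  # graph stays valid after optimization
  expect_silent(validate_model(o1$model))

  # degenerate model passes through unchanged
  o0 <- optimize_model(nef_model())
  expect_equal(n_operators(o0$model), 0L)
})

test_that("the rate-based stop is active only when enabled, via a fake clock", {
  m <- gen_circconv_model(4, mode = "lif", seed = 10)
  # fake clock: every pass appears to take very long, so any pass rate
  # falls below 1% of the average and the loop stops early
  ticks <- new.env()
  ticks$i <- 0
  slow_clock <- function() {
    ticks$i <- ticks$i + 1
    ticks$i * 1e6
  }
  o_stop <- optimize_model(m, enable_rate_stop = TRUE, clock = slow_clock)
  o_full <- optimize_model(m, enable_rate_stop = FALSE)
  expect_lte(length(o_stop$report$passes), length(o_full$report$passes))
  # even when stopped early the result is a valid, equivalent model
  expect_silent(validate_model(o_stop$model))
  expect_identical(run_model(m, 10), run_model(o_stop$model, 10))

  # termination on fuzzed inputs, both settings
  for (seed in 1:5) {
    rm_ <- gen_random_model(15, seed = seed)
    fast <- optimize_model(rm_, enable_rate_stop = TRUE,
                           clock = function() 0)
    off <- optimize_model(rm_, enable_rate_stop = FALSE)
    expect_silent(validate_model(fast$model))
    expect_equal(n_operators(off$model), n_operators(fast$model))
  }
})

test_that("view-first policy wins where merge order matters", {
  m <- gen_order_matters_model(seed = 3)
  base <- run_model(m, 4)

  # default policy: the view-reading stage merges first, then the second
  # stage; two operators remain
  o <- optimize_model(m)
  expect_equal(n_operators(o$model), 2L)
  expect_identical(run_model(o$model, 4), base)

  # adversarial order: merging the second stage first as (b2, b1) flips the
  # b layout; the first stage can then never merge
  adv <- merge_operators(m, c("o2b", "o2a"))$model
  oadv <- optimize_model(adv)
  expect_gte(n_operators(oadv$model), 3L)
  expect_identical(run_model(oadv$model, 4), base)
})
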