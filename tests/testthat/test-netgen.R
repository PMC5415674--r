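test_that("the double-loop convolution oracle has the algebraic identities", {
  w <- c(5, 6, 7)
  expect_equal(circconv_oracle(c(1, 0, 0), w), w) # identity element
  expect_equal(circconv_oracle(c(0, 1), c(3, 9)), c(9, 3)) # cyclic shift
  expect_error(circconv_oracle(1:3, 1:4), "equal length")

  # transform-domain cross-check at n = 8
  set.seed(8)
  v <- rnorm(8)
  w <- rnorm(8)
  spectral <- Re(stats::fft(stats::fft(v) * stats::fft(w), inverse = TRUE)) / 8
  expect_equal(circconv_oracle(v, w), spectral, tolerance = 1e-12)
})

test_that("convolution transforms factorize the convolution exactly", {
  # d = 1 reduces to the scalar product
  tf1 <- convolution_transforms(1)
  expect_equal(as.numeric(tf1$C %*% ((tf1$A %*% 3) * (tf1$B %*% 4))), 12)

  # identity element survives the transform
  tf8 <- convolution_transforms(8)
  set.seed(2)
  w <- rnorm(8)
  e1 <- c(1, rep(0, 7))
  expect_equal(as.numeric(tf8$C %*% ((tf8$A %*% e1) * (tf8$B %*% w))), w,
               tolerance = 1e-12)

  # random pairs across dimensionalities, against the double-loop oracle
  for (d in c(2, 4, 16)) {
    tf <- convolution_transforms(d)
    expect_lte(tf$p, 2 * d + 2)
    for (i in 1:20) {
      v <- rnorm(d)
      w <- rnorm(d)
      got <- as.numeric(tf$C %*% ((tf$A %*% v) * (tf$B %*% w)))
      expect_equal(got, circconv_oracle(v, w), tolerance = 1e-9)
    }
  }
})

test_that("direct-mode convolution networks compute the oracle", {
  # d = 1: output is the scalar product of the (normalized) inputs
  m1 <- gen_circconv_model(1, mode = "direct", seed = 6)
  v <- m1$signals[["v"]]$initial
  w <- m1$signals[["w"]]$initial
  expect_equal(run_model(m1, 2)$out[2, ], v * w, tolerance = 1e-12)

  m8 <- gen_circconv_model(8, mode = "direct", seed = 6)
  v <- m8$signals[["v"]]$initial
  w <- m8$signals[["w"]]$initial
  pr <- run_model(m8, 3)
  expect_equal(pr$out[3, ], circconv_oracle(v, w), tolerance = 1e-9)
  # settled from the first step on
  expect_equal(pr$out[1, ], pr$out[3, ])
})

test_that("convolution operator counts are affine in dimensionality", {
  counts <- vapply(c(2L, 4L, 8L), function(d) {
    n_operators(gen_circconv_model(d, mode = "lif", seed = 1))
  }, integer(1))
  slopes <- diff(counts) / diff(c(2, 4, 8))
  expect_equal(slopes[1], slopes[2]) # one straight line through even d
  # model-family constants measured at d = 2, 4 predict d = 8
  c1 <- slopes[1]
  c0 <- counts[1] - c1 * 2
  expect_equal(counts[3], c0 + c1 * 8)
})

test_that("split-ensemble models scale operators with the split count", {
  n1 <- n_operators(gen_split_ensemble_model(16, 1, mode = "lif"))
  n4 <- n_operators(gen_split_ensemble_model(16, 4, mode = "lif"))
  n16 <- n_operators(gen_split_ensemble_model(16, 16, mode = "lif"))
  expect_lt(n1, n4)
  expect_lt(n4, n16) # s = d: one group per dimension, maximal count
  expect_error(gen_split_ensemble_model(16, 3), "divide")

  # optimized counts are nearly split-independent at fixed d
  o4 <- n_operators(optimize_model(
    gen_split_ensemble_model(16, 4, mode = "lif")
  )$model)
  o16 <- n_operators(optimize_model(
    gen_split_ensemble_model(16, 16, mode = "lif")
  )$model)
  expect_lte(max(o4, o16) / min(o4, o16), 2)

  # direct mode reconstructs the input exactly through the view slices
  md <- gen_split_ensemble_model(12, 3, mode = "direct", seed = 2)
  x <- md$signals[["input"]]$initial
  expect_equal(run_model(md, 1)$out[1, ], x, tolerance = 1e-12)
})

test_that("generated models satisfy the role invariants by construction", {
  for (seed in 1:8) {
    m <- gen_random_model(18, seed = seed)
    expect_silent(validate_model(m))
  }
  expect_silent(validate_model(gen_circconv_model(4, mode = "lif")))
  expect_silent(validate_model(gen_circconv_model(4, mode = "direct")))
  expect_silent(validate_model(gen_split_ensemble_model(8, 4)))
  expect_silent(validate_model(gen_order_matters_model()))
})

test_that("generators are reproducible under a seed", {
  expect_identical(gen_random_model(20, seed = 5),
                   gen_random_model(20, seed = 5))
  expect_identical(gen_circconv_model(4, seed = 3),
                   gen_circconv_model(4, seed = 3))
  expect_false(identical(gen_random_model(20, seed = 5),
                         gen_random_model(20, seed = 6)))
})

test_that("random DAG generation respects its edge-probability extremes", {
  g0 <- gen_random_dag(20, 0, seed = 1)
  expect_equal(g0$n_edges, 0L)
  g1 <- gen_random_dag(10, 1, seed = 1)
  expect_equal(g1$n_edges, 10L * 9L / 2L) # complete DAG
  R <- transitive_closure(g1)
  expect_setequal(reach_set(R, "v001"), sprintf("v%03d", 2:10))
  expect_identical(gen_random_dag(15, 0.3, seed = 2),
                   gen_random_dag(15, 0.3, seed = 2))
})

test_that("models round-trip through the JSON graph format", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))

  m <- gen_order_matters_model(seed = 2)
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(sort(names(m2$signals)), sort(names(m$signals)))
  expect_equal(names(m2$operators), names(m$operators))
  expect_equal(run_model(m2, 4), run_model(m, 4), tolerance = 1e-12)

  # a model with matrices, neurons and registered user functions
  md <- gen_circconv_model(4, mode = "direct", seed = 1)
  write_model_json(md, path)
  md2 <- read_model_json(path)
  expect_equal(run_model(md2, 3)$out, run_model(md, 3)$out,
               tolerance = 1e-12)

  # an optimized model (spanning views, merged bases, BsrDotInc) survives
  mo <- optimize_model(gen_circconv_model(4, mode = "lif", seed = 1))$model
  write_model_json(mo, path)
  mo2 <- read_model_json(path)
  expect_equal(run_model(mo2, 20), run_model(mo, 20), tolerance = 1e-12)

  # unregistered closures are flagged, not silently dropped
  mu <- nef_model()
  mu <- add_signal(mu, nef_signal("y", shape = 1))
  mu <- add_operator(mu, op_user_func(function(t) t, output = "y"))
  expect_error(write_model_json(mu, path), "unregistered")
})
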