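# Run code with a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Circular convolution by direct summation
#'
#' The binding operation of vector-symbolic architectures:
#' `u[i] = sum_j v[j] * w[(i - j) mod n]`. Evaluated by the literal double
#' loop -- this function is the package's ground-truth oracle for all
#' convolution claims and deliberately avoids transform tricks.
#'
#' @param v,w Numeric vectors of equal length `n >= 1`.
#' @return The circular convolution `v (*) w`, length `n`.
#' @export
#' @examples
#' circconv_oracle(c(1, 0, 0), c(5, 6, 7)) # identity element
circconv_oracle <- function(v, w) {
  n <- length(v)
  if (length(w) != n || n < 1L) {
    stop("circconv_oracle: v and w must have equal length >= 1")
  }
  u <- numeric(n)
  for (i in 0:(n - 1L)) {
    acc <- 0
    for (j in 0:(n - 1L)) {
      acc <- acc + v[j + 1L] * w[((i - j) %% n) + 1L]
    }
    u[i + 1L] <- acc
  }
  u
}

#' Real transform matrices factorizing circular convolution
#'
#' Builds real matrices `A` (p x d), `B` (p x d) and `C` (d x p) such that
#' `C %*% ((A %*% v) * (B %*% w))` equals the circular convolution of `v`
#' and `w` for all vectors, with `p <= 2d + 2`. The construction stacks the
#' real and imaginary parts of the discrete Fourier transform and uses the
#' three-multiplication complex-product identity per frequency, so only
#' elementwise products of linear images of `v` and `w` are needed -- the
#' form a network of product-computing neural populations can realize.
#'
#' @param d Vector dimensionality (>= 1).
#' @return List with matrices `A`, `B`, `C` and the product count `p`.
#' @export
convolution_transforms <- function(d) {
  stopifnot(d >= 1L)
  j <- 0:(d - 1L)
  rowsA <- list()
  rowsB <- list()
  colsC <- list() # output weights per product term, each length d
  push <- function(ar, br, cc) {
    rowsA[[length(rowsA) + 1L]] <<- ar
    rowsB[[length(rowsB) + 1L]] <<- br
    colsC[[length(colsC) + 1L]] <<- cc
  }
  # DC term: V_0 * W_0 contributes 1/d to every output element
  push(rep(1, d), rep(1, d), rep(1 / d, d))
  # Nyquist term (even d): real frequency with alternating signs
  if (d %% 2L == 0L && d >= 2L) {
    alt <- (-1)^j
    push(alt, alt, alt / d)
  }
  # generic complex frequencies: 3 products per frequency
  ks <- seq_len(ceiling(d / 2) - 1L)
  for (k in ks) {
    re <- cos(2 * pi * j * k / d)
    im <- -sin(2 * pi * j * k / d)
    cth <- cos(2 * pi * j * k / d)
    sth <- sin(2 * pi * j * k / d)
    # products m1 = Re(V)(Re(W)+Im(W)), m2 = (Re(V)+Im(V))Im(W),
    # m3 = (Im(V)-Re(V))Re(W); then Re(VW) = m1 - m2, Im(VW) = m1 + m3
    push(re, re + im, (2 / d) * (cth - sth))
    push(re + im, im, -(2 / d) * cth)
    push(im - re, re, -(2 / d) * sth)
  }
  A <- do.call(rbind, rowsA)
  B <- do.call(rbind, rowsB)
  C <- do.call(cbind, colsC)
  list(A = A, B = B, C = C, p = nrow(A))
}

# Append one scalar-or-vector ensemble to a model: routes a slice of
# `input_base` into a private input signal, computes input currents through
# random Gaussian encoders, simulates LIF neurons and decodes back into a
# slice of `out_base`. Direct mode replaces the neural population by an
# exact pass-through of the represented value. Weights are seeded Gaussian
# matrices: the optimizer's correctness is weight-independent, so no
# least-squares decoder solving is performed.
add_ensemble <- function(m, input_base, in_off, out_base, out_off, q,
                         n_neurons, mode, prefix,
                         tau_rc = 0.02, tau_ref = 0.002) {
  inv <- paste0(prefix, ".iv")
  outv <- paste0(prefix, ".ov")
  m <- add_view(m, inv, input_base, in_off, q)
  m <- add_view(m, outv, out_base, out_off, q)
  insig <- paste0(prefix, ".in")
  m <- add_signal(m, nef_signal(insig, shape = q))
  m <- add_operator(m, op_copy(inv, insig, mode = "set"))
  if (identical(mode, "direct")) {
    val <- paste0(prefix, ".val")
    dec <- paste0(prefix, ".dec")
    m <- add_signal(m, nef_signal(val, shape = q))
    m <- add_signal(m, nef_signal(dec, initial = diag(q)))
    m <- add_operator(m, op_user_func("identity", output = val, input = insig))
    m <- add_operator(m, op_dot_inc(dec, val, outv))
  } else {
    nm <- function(s) paste0(prefix, ".", s)
    m <- add_signal(m, nef_signal(nm("bias"), initial = runif(n_neurons, 1, 2)))
    m <- add_signal(m, nef_signal(nm("J"), shape = n_neurons))
    m <- add_signal(m, nef_signal(
      nm("enc"), initial = matrix(rnorm(n_neurons * q), n_neurons, q)
    ))
    m <- add_signal(m, nef_signal(nm("spk"), shape = n_neurons))
    m <- add_signal(m, nef_signal(nm("vm"), shape = n_neurons))
    m <- add_signal(m, nef_signal(nm("ref"), shape = n_neurons))
    m <- add_signal(m, nef_signal(
      nm("dec"),
      initial = matrix(rnorm(q * n_neurons, sd = 1 / n_neurons), q, n_neurons)
    ))
    m <- add_operator(m, op_copy(nm("bias"), nm("J"), mode = "set"))
    m <- add_operator(m, op_dot_inc(nm("enc"), insig, nm("J")))
    m <- add_operator(m, op_sim_neurons(nm("J"), nm("spk"), nm("vm"),
                                        nm("ref"), tau_rc, tau_ref))
    m <- add_operator(m, op_dot_inc(nm("dec"), nm("spk"), outv))
  }
  m
}

add_time_update <- function(m) {
  m <- add_signal(m, nef_signal("step", shape = 1L))
  m <- add_signal(m, nef_signal("time", shape = 1L))
  add_operator(m, op_time_update("step", "time"))
}

#' Generate a circular-convolution binding network
#'
#' Emits the operator/signal structure a NEF builder produces for circular
#' convolution: the two input vectors are mapped through fixed transform
#' matrices into product-space coefficients, one small neural population per
#' coefficient (and per operand side) represents its value, an elementwise
#' product pairs the decoded coefficients, and an output transform maps back
#' to the convolution. The unoptimized operator count grows linearly with
#' `d`; after optimization it is independent of `d`.
#'
#' @param d Vector dimensionality (>= 1).
#' @param n_per_d Neurons per represented dimension (LIF mode).
#' @param mode `"lif"` for spiking populations, `"direct"` for exact
#'   pass-through populations (the network output then equals
#'   [circconv_oracle()] at every step).
#' @param seed RNG seed for inputs and weights.
#' @param dt Timestep in seconds.
#' @return A `nef_model` with the convolution output probed as `"out"`.
#' @export
gen_circconv_model <- function(d, n_per_d = 10L, mode = c("lif", "direct"),
                               seed = 1L, dt = 0.001) {
  mode <- match.arg(mode)
  stopifnot(d >= 1L, n_per_d >= 1L)
  tf <- convolution_transforms(d)
  p <- tf$p
  with_seed(seed, {
    v <- rnorm(d)
    v <- v / sqrt(sum(v^2))
    w <- rnorm(d)
    w <- w / sqrt(sum(w^2))
    m <- nef_model(dt = dt)
    m <- add_time_update(m)
    m <- add_signal(m, nef_signal("v", initial = v))
    m <- add_signal(m, nef_signal("w", initial = w))
    m <- add_signal(m, nef_signal("tfA", initial = tf$A))
    m <- add_signal(m, nef_signal("tfB", initial = tf$B))
    m <- add_signal(m, nef_signal("tfC", initial = tf$C))
    for (s in c("a", "b", "ah", "bh")) {
      m <- add_signal(m, nef_signal(s, shape = p))
      m <- add_operator(m, op_reset(s))
    }
    m <- add_signal(m, nef_signal("prod", shape = p))
    m <- add_operator(m, op_reset("prod"))
    m <- add_signal(m, nef_signal("out", shape = d))
    m <- add_operator(m, op_reset("out"))
    m <- add_operator(m, op_dot_inc("tfA", "v", "a"))
    m <- add_operator(m, op_dot_inc("tfB", "w", "b"))
    for (side in c("a", "b")) {
      hat <- paste0(side, "h")
      for (i in seq_len(p)) {
        m <- add_ensemble(
          m, input_base = side, in_off = i - 1L,
          out_base = hat, out_off = i - 1L, q = 1L,
          n_neurons = n_per_d, mode = mode,
          prefix = sprintf("e.%s%03d", side, i)
        )
      }
    }
    m <- add_operator(m, op_elementwise_inc("ah", "bh", "prod"))
    m <- add_operator(m, op_dot_inc("tfC", "prod", "out"))
    m <- add_probe(m, "out")
    m
  })
}

#' Generate a split-ensemble representation model
#'
#' A `d`-dimensional vector is not represented by one neural group but by
#' `s` groups each representing a `d/s`-dimensional part, reading and
#' writing view slices of shared input/output vectors. Splitting improves
#' representational accuracy per neuron but multiplies the operator count --
#' the growth the graph optimizer counteracts.
#'
#' @param d Vector dimensionality.
#' @param s Number of splits; must divide `d`.
#' @param n Neurons per group (LIF mode).
#' @param mode `"lif"` or `"direct"`.
#' @param seed RNG seed.
#' @param dt Timestep in seconds.
#' @return A `nef_model` with the reconstructed output probed as `"out"`.
#' @export
gen_split_ensemble_model <- function(d, s, n = 10L, mode = c("lif", "direct"),
                                     seed = 1L, dt = 0.001) {
  mode <- match.arg(mode)
  stopifnot(d >= 1L, s >= 1L, n >= 1L)
  if (d %% s != 0L) stop("the split count s must divide d")
  q <- d %/% s
  with_seed(seed, {
    x <- rnorm(d)
    x <- x / sqrt(sum(x^2))
    m <- nef_model(dt = dt)
    m <- add_time_update(m)
    m <- add_signal(m, nef_signal("input", initial = x))
    m <- add_signal(m, nef_signal("out", shape = d))
    m <- add_operator(m, op_reset("out"))
    for (g in seq_len(s)) {
      m <- add_ensemble(
        m, input_base = "input", in_off = (g - 1L) * q,
        out_base = "out", out_off = (g - 1L) * q, q = q,
        n_neurons = n, mode = mode, prefix = sprintf("g%03d", g)
      )
    }
    m <- add_probe(m, "out")
    m
  })
}

#' Generate the input-current cluster of paired neural groups
#'
#' The canonical operator pattern for computing input currents to neural
#' groups: per group, a `Copy` routes the input, a `DotInc` applies the
#' encoders, an `ElementwiseInc` applies per-neuron gains, and `SimNeurons`
#' integrates -- each group touching unrelated memory. All per-group
#' operators are pairwise mergeable, so optimization collapses the model to
#' one operator per tag.
#'
#' @param n_groups Number of neural groups.
#' @param q Represented dimensions per group.
#' @param n Neurons per group.
#' @param seed RNG seed.
#' @return A `nef_model` probing each group's spike output.
#' @export
gen_ensemble_cluster_model <- function(n_groups = 2L, q = 2L, n = 8L,
                                       seed = 1L) {
  with_seed(seed, {
    m <- nef_model()
    for (g in seq_len(n_groups)) {
      nm <- function(s) sprintf("g%02d.%s", g, s)
      xin <- rnorm(q)
      m <- add_signal(m, nef_signal(nm("x"), initial = xin / sqrt(sum(xin^2))))
      m <- add_signal(m, nef_signal(nm("in"), shape = q))
      m <- add_signal(m, nef_signal(
        nm("enc"), initial = matrix(rnorm(n * q), n, q)
      ))
      m <- add_signal(m, nef_signal(nm("gain"), initial = runif(n, 0.5, 2)))
      m <- add_signal(m, nef_signal(nm("bias"), initial = runif(n, 1, 2)))
      m <- add_signal(m, nef_signal(nm("J"), shape = n))
      m <- add_signal(m, nef_signal(nm("spk"), shape = n))
      m <- add_signal(m, nef_signal(nm("vm"), shape = n))
      m <- add_signal(m, nef_signal(nm("ref"), shape = n))
      # J = gain * bias + enc %*% in; one operator per tag and group
      m <- add_operator(m, op_copy(nm("x"), nm("in"), mode = "set"))
      m <- add_operator(m, op_reset(nm("J")))
      m <- add_operator(m, op_elementwise_inc(nm("gain"), nm("bias"),
                                              nm("J")))
      m <- add_operator(m, op_dot_inc(nm("enc"), nm("in"), nm("J")))
      m <- add_operator(m, op_sim_neurons(nm("J"), nm("spk"), nm("vm"),
                                          nm("ref")))
      m <- add_probe(m, nm("spk"))
    }
    m
  })
}

#' Generate the merge-order sensitivity fixture
#'
#' Two first-stage operators read disjoint views of one signal `a` and
#' write `b1`/`b2`; two second-stage operators read the `b` signals and
#' write `c1`/`c2`. Merging the view-reading first stage first imposes the
#' memory order of `a` onto the `b` signals, after which the second stage
#' merges too (2 operators remain). Merging the second stage first in the
#' adverse order `(b2, b1)` lays the `b` signals out backwards, making the
#' first stage unmergeable (3 operators remain) -- the reason the optimizer
#' handles view-referencing operators first.
#'
#' @param seed RNG seed for the initial value of `a`.
#' @return A `nef_model` with operators named `o1a`, `o1b`, `o2a`, `o2b`.
#' @export
gen_order_matters_model <- function(seed = 1L) {
  with_seed(seed, {
    m <- nef_model()
    m <- add_signal(m, nef_signal("a", initial = rnorm(4)))
    m <- add_view(m, "a.v1", "a", 0L, 2L)
    m <- add_view(m, "a.v2", "a", 2L, 2L)
    for (s in c("b1", "b2", "c1", "c2")) {
      m <- add_signal(m, nef_signal(s, shape = 2L))
    }
    m <- add_operator(m, op_copy("a.v1", "b1", mode = "set"), name = "o1a")
    m <- add_operator(m, op_copy("a.v2", "b2", mode = "set"), name = "o1b")
    m <- add_operator(m, op_copy("b1", "c1", mode = "set"), name = "o2a")
    m <- add_operator(m, op_copy("b2", "c2", mode = "set"), name = "o2b")
    m <- add_probe(m, "c1")
    m <- add_probe(m, "c2")
    m
  })
}

#' Generate a random valid model
#'
#' Layered fuzzing surface for the optimizer and engine: constant input
#' signals feed a layer of reset-then-incremented accumulator signals
#' through randomly chosen `Copy` (often via contiguous views),
#' `ElementwiseInc` and `DotInc` operators, with a second accumulator layer
#' stacked on top. Construction guarantees the access-role invariants and
#' acyclicity; repeated calls with one seed produce identical models.
#'
#' @param n_ops Approximate number of randomly drawn operators (the
#'   scaffolding adds a `TimeUpdate` and one `Reset` per accumulator).
#' @param seed RNG seed.
#' @param dt Timestep in seconds.
#' @return A `nef_model` probing every accumulator signal.
#' @export
gen_random_model <- function(n_ops = 20L, seed = 1L, dt = 0.001) {
  stopifnot(n_ops >= 0L)
  with_seed(seed, {
    k <- sample(3:6, 1L) # common signal size for this model
    m <- nef_model(dt = dt)
    m <- add_time_update(m)
    n_in <- 3L
    n_mid <- 3L
    n_top <- 2L
    ins <- sprintf("in%02d", seq_len(n_in))
    mids <- sprintf("mid%02d", seq_len(n_mid))
    tops <- sprintf("top%02d", seq_len(n_top))
    for (s in ins) m <- add_signal(m, nef_signal(s, initial = rnorm(k)))
    for (s in c(mids, tops)) {
      m <- add_signal(m, nef_signal(s, shape = k))
      m <- add_operator(m, op_reset(s))
      m <- add_probe(m, s)
    }
    vseq <- 0L
    view_of <- function(base, off, len) {
      vseq <<- vseq + 1L
      nm <- sprintf("%s.v%03d", base, vseq)
      m <<- add_view(m, nm, base, off, len)
      nm
    }
    for (i in seq_len(n_ops)) {
      kind <- sample(c("ew", "dot", "cpv", "cp2", "dot2"), 1L)
      if (kind == "ew") {
        ab <- sample(ins, 2L)
        m <- add_operator(m, op_elementwise_inc(ab[1L], ab[2L],
                                                sample(mids, 1L)))
      } else if (kind == "dot") {
        a <- sprintf("W%03d", i)
        m <- add_signal(m, nef_signal(a, initial = matrix(rnorm(k * k), k, k)))
        m <- add_operator(m, op_dot_inc(a, sample(ins, 1L), sample(mids, 1L)))
      } else if (kind == "cpv") {
        len <- sample(seq_len(k - 1L), 1L)
        off1 <- sample(0:(k - len), 1L)
        off2 <- sample(0:(k - len), 1L)
        src <- view_of(sample(ins, 1L), off1, len)
        dst <- view_of(sample(mids, 1L), off2, len)
        m <- add_operator(m, op_copy(src, dst, mode = "inc"))
      } else if (kind == "cp2") {
        m <- add_operator(m, op_copy(sample(mids, 1L), sample(tops, 1L),
                                     mode = "inc"))
      } else {
        a <- sprintf("W%03d", i)
        m <- add_signal(m, nef_signal(a, initial = matrix(rnorm(k * k), k, k)))
        m <- add_operator(m, op_dot_inc(a, sample(mids, 1L),
                                        sample(tops, 1L)))
      }
    }
    m
  })
}

#' Generate a random DAG
#'
#' Vertices are ordered and each forward pair `(i, j)`, `i < j`, receives an
#' edge with probability `p` -- acyclicity is guaranteed by construction.
#'
#' @param n Number of vertices (>= 0).
#' @param p Edge probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return A `nef_graph`.
#' @export
gen_random_dag <- function(n, p, seed = 1L) {
  stopifnot(n >= 0L, p >= 0, p <= 1)
  with_seed(seed, {
    verts <- sprintf("v%03d", seq_len(n))
    edges <- list()
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        coin <- stats::runif(n - i) < p
        if (any(coin)) edges[[verts[i]]] <- verts[(i + 1L):n][coin]
      }
    }
    make_graph(verts, edges)
  })
}
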