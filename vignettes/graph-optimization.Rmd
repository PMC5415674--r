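---
title: "Operator merging in a NEF-style dataflow simulator: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operator merging in a NEF-style dataflow simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nefsim)
```

## The problem

Reference backends for NEF-style simulators interpret a built network as a
long list of small typed operators over scattered memory blocks and loop
over that list once per time step in a high-level language. For large
models the interpreter overhead and the cache-hostile memory layout — not
the arithmetic — dominate the simulation time. The remedy implemented here
is to rewrite the computation graph before simulation: operators of the
same type that do not depend on each other are fused into one operator
whose operands live in one contiguous block. `nefsim` implements that
rewrite together with a small but complete execution engine, so every
claim about the rewrite can be checked against actually simulated traces.

## Execution model and its assumptions

A model is a set of *signals* (named 1-D or 2-D float64 blocks; all
buffers are stored flat in row-major element order), *views* (windows into
a base signal given by a 0-based element offset and shape; always
contiguous over the viewed region), and *operators* with the four access
roles set / increment / read / update. The roles carry the semantics:

* a signal that is incremented each step must have exactly one setter
  (typically a `Reset` to 0), so increments start from a defined value —
  the generators follow this convention throughout;
* readers within a step see setter/incrementer results of the same step,
  but an *update* runs after all readers of overlapping memory, so updated
  state (e.g. membrane voltage) is carried into the next step;
* dependency edges are derived per overlapping memory *region* of a base
  block: set → inc → read → update, complete bipartite between role groups
  whose regions overlap. Whole-signal access spans the whole block, so for
  ordinary models this is exactly block-level ordering. We deliberately do
  not add edges between accesses to *disjoint* regions of one base: after
  the optimizer has concatenated formerly unrelated signals into one
  block, block-level edges would manufacture orderings (and, combined with
  further merges, even cycles) that no data flow justifies. Region
  granularity keeps exactly the orderings that a data dependence can
  justify, and together with chain-wide independence checking makes merges
  provably acyclicity-preserving.
* two setters (or two updaters) whose regions overlap are rejected when
  the graph is built; disjoint-region setters of one block are legal —
  they arise naturally from merging.

Scheduling is Kahn's algorithm with ties broken by declaration order, so a
model has one deterministic schedule. There is no parallel execution: the
engine models the single-threaded interpreter whose overhead motivates the
optimization in the first place.

## Merge rules

`can_merge(a, b)` requires: same tag and the tag supports merging
(`UserFunc` — arbitrary user code — never merges); mutual independence,
queried on the transitive closure; slot-wise signal mergeability (two
plain signals: same dtype, shapes agreeing off the concatenation axis, and
not the same signal twice; two views: same base, equal strides, second
offset = first offset + first size; a view never pairs with a non-view);
and per-tag extras — `DotInc` demands equal weight-matrix shapes so the
merged operator is a uniform-block BSR product (heterogeneous blocks are
rejected rather than zero-padded: standard BSR layout, no wasted memory),
`SimNeurons` equal time constants, `Reset` equal constants, `Copy` equal
modes.

Two additions beyond the pairwise rule proved necessary:

* **Chain-wide independence.** A chain is merged as a whole if adjacent
  pairs are mergeable, but a candidate must also be independent of every
  *interior* chain member: pairwise independence does not compose, and a
  dependence routed through an interior member would let the merged node
  close a cycle.
* **Cross-slot alias rejection.** Merging concatenates each non-view slot
  into a fresh block and rewrites all references. If one memory block
  appears at two different slot positions within the chain (e.g. the same
  vector read as both factors of different elementwise products), that
  rewrite would alias slots against each other; such chains are rejected.

`DotInc` chains become `BsrDotInc`: the dense weight blocks are copied
into the operator and applied block-by-block (`y_k += A_k x_k`) without
ever materializing the block-diagonal matrix — storage is the sum of block
sizes, linear in the number of merged operators. This treats weight
matrices as constants (no operator in any generated model writes them);
orphaned weight signals are pruned. The engine applies merged operators
with the same per-element arithmetic as the originals, which is why
optimized traces agree to floating-point reproducibility rather than
merely approximately.

## The pass loop

Operators are grouped by (tag, base of the first view in a fixed
sets–incs–reads–updates scan; view-free operators form one group per tag),
and groups are processed in the heuristic order `ElementwiseInc`, `Copy`,
`DotInc`, `SimNeurons`, then remaining tags alphabetically. Each group is
swept greedily after a stable sort by first-view offset (ties by
declaration index): candidates whose first view starts before the end of
the current operator's view are skipped, the scan breaks when views stop
being consecutive, chains of length ≥ 2 merge, and view operators that
merged with nothing are excluded from later passes.

Passes alternate polarities: only view-referencing operators are merged by
default, because plain signals impose no memory order — merging them first
can fix an operand order that makes later view merges impossible (the
package ships `gen_order_matters_model()`, a four-operator model where the
view-first policy ends at 2 operators and an adversarially ordered
view-free-first merge strands the first stage at 3). One view-free pass is
allowed whenever a pass yields no reduction; view passes resume if it
reduced the count. The loop ends when a view-free pass finds nothing.

Three deliberate deviations from a literal reading of the sweep:

* **Reconsidering excluded operators.** The permanent-exclusion argument
  ("an unmergeable view operator stays unmergeable") fails once *base
  signals* merge: rebasing turns views of different bases into views of
  one base, which may now be sequential. An excluded operator is therefore
  re-admitted whenever a signal merge rewrites or rebases any of its
  signals. Without this, `optimize_model()` was observably not a fixed
  point. Exclusions persist for untouched operators, keeping the intended
  scan savings.
* **Closure recomputation after every merge.** Reachability is recomputed
  not just before each group's sweep but after each merge within it: a
  stale closure cannot see dependences routed through an operator merged
  earlier in the same sweep, and two chained copies suffice to turn that
  blind spot into a cycle. Desk-scale graphs make recomputation cheap
  (dense boolean propagation in topological order, then set interning).
* **Rate-based stopping off by default.** The optional stop — end once a
  pass's merges-per-second fall below `rate_threshold` (default 0.01) of
  the average over all passes — references wall-clock time, which at desk
  scale is noise. It is implemented exactly, takes an injectable clock so
  tests exercise it deterministically, and is off by default so
  `optimize_model()` is reproducible run-to-run.

The transitive closure itself stores one instance per *distinct*
reachable-set in a content-addressed intern table; in built networks many
parallel branches share their downstream cone, so the number of stored
sets tracks the depth of the graph rather than its width (the fan-in tests
assert exactly this).

## Neuron model and numerical choices

The spiking neuron is the standard NEF leaky integrate-and-fire model:
`tau_rc * dv/dt = J − v` with threshold 1, integrated by the exact
exponential update (stable at the default `dt = 0.001 s`), refractory
clamp `tau_ref` after each spike, and sub-step spike-time correction so
the discretized rate matches the closed-form rate
`1/(tau_ref + tau_rc * log(1 + 1/(J − 1)))` closely (the tests demand 2%;
the correction leaves well under 0.1% at 1 ms). Defaults `tau_rc = 0.02 s`
and `tau_ref = 0.002 s` are the field's standard cortical values. Spikes
are impulses of amplitude `1/dt`, so a filtered spike train approximates a
rate in Hz; this convention is a choice, not a claim. `J = 1` exactly
produces an asymptotic approach and never a spike, since the threshold
test is strict. Non-finite input currents raise an error rather than
propagating.

Direct mode — populations replaced by exact pass-throughs of the
represented value — is realized at model-generation time by emitting a
`UserFunc` + identity-decoder cluster instead of the neural cluster, not
by a runtime engine flag: the engine then never needs to know which mode
it executes, and both variants flow through the optimizer identically.

## What the generators emulate (and what they do not)

`gen_circconv_model()` reproduces the operator *structure* of a built
circular-convolution binding network: input vectors mapped by fixed
transform matrices into product-space coefficients, one population per
coefficient and operand side (input routing via consecutive views of the
shared coefficient vector — the pattern that makes view merging
productive), an elementwise product pairing, and an output transform. The
transform factorization `C((Av) ∘ (Bw)) = v ⊛ w` stacks real/imaginary
DFT parts and uses the three-multiplication complex-product identity, so
`p = 3⌈d/2⌉ − 1` (even `d`) product terms suffice, within the `2d + 2`
budget. Encoder/decoder weights are *seeded Gaussian matrices, not
least-squares NEF solutions*: the optimizer's correctness is
weight-independent, and decoder solving is a different problem entirely.
Consequently the spiking networks do not compute an accurate convolution —
only the direct-mode networks do — and no test pretends otherwise.
Likewise `gen_split_ensemble_model()` reproduces the
split-representation pattern (s groups over d/s-dimensional slices) whose
operator growth the optimizer counteracts, and `gen_random_model()` is a
layered fuzzing surface that guarantees the role invariants and
acyclicity by construction. None of these reproduce a production
builder's exact operator inventory (probe plumbing, special-cased
passthroughs), so absolute operator counts of real built models are out
of reach by design; the *scaling shape* — affine in `d` before, constant
after — is the reproducible claim. Desk-scale defaults (`n_per_d = 10`,
`d ≤ 64`) keep every test in seconds; they are smaller than
production-scale networks but exercise identical code paths.

## Benchmark protocol

`bench()` follows the standard measurement protocol: per trial, a timed
build (including optimization when enabled), 10 untimed warm-up steps to
pre-fill buffers, then 1,000 timed steps (one simulated second at the
default `dt`), with means over 5 trials. Step counters are instrumented so
the protocol itself is testable; wall-clock numbers are reported but never
asserted against, since they are hardware-dependent.

## Known limitations

* No cross-tag fusion (e.g. folding a `Copy` into a `DotInc`) and no
  parallel scheduling of the merged graph — both are outside the model
  this package implements.
* Views are contiguous; strided or multi-level views (views of views) are
  rejected at construction.
* `float64` is the only dtype; per-signal dtypes would only add
  mergeability bookkeeping.
* Weight matrices read by `DotInc` are assumed constant; a learning rule
  that writes them would require keeping the weight signals live in the
  BSR rewrite.
* Set-only signals without readers are accepted (dead code) and simply
  ignored by the optimizer.
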