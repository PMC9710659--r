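---
title: "Assigning secondary structure from distances and dihedral cosines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning secondary structure from distances and dihedral cosines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Secondary-structure assignment normally leans on the primary sequence: the
assigner walks the chain residue by residue, finds backbone hydrogen-bond
patterns, and labels helices and strands. In many experimental situations that
walk is impossible — disordered regions are invisible in density maps, parts
of the chain are untraced, or a cryo-EM backbone tracer has produced nothing
but a cloud of Cα positions with no connectivity at all. **geosec** assigns
per-residue secondary-structure classes using only *geometry*: inter-atomic
distances and dihedral-angle cosines between spatially close residues,
whether or not they are consecutive in sequence.

Two ideas make this work:

1. **A sequence-agnostic residue graph.** Residues are nodes; edges connect
   residues that are spatially close (the distance between two residues is
   the minimum distance over their atoms). Two constructions are provided:
   a k-nearest-neighbour graph symmetrized by union (*method A*, default
   `k = 2`) and a strict distance-threshold graph (*method B*, default
   `tau = 3` Å). On realistic backbones the two produce very similar edge
   sets (the test suite reports their Jaccard overlap); method A is the
   default because it never leaves a residue disconnected.
2. **Distance-only dihedral cosines.** For an ordered atom quadruple the
   cosine of the dihedral angle ω follows from the six pairwise distances
   alone, via the trihedron cosine law
   `cos γ = cos α cos β + sin α sin β cos ω`, where α, β, γ are the planar
   angles at the second vertex, each given by the law of cosines. Only the
   cosine is recoverable — distances cannot distinguish a structure from its
   mirror image — so every downstream feature is a cosine, never a signed
   angle.

## Edge and node features

The classical backbone dihedrals φ and ψ are generalized to arbitrary residue
pairs (k, l): `phi_kl` is the dihedral over (C of k, N of l, CA of l, C of l)
and `psi_kl` over (N of k, CA of k, C of k, N of l). For sequence-adjacent
pairs these reduce exactly to the classical φ of l and ψ of k; for
non-adjacent pairs the same atom pattern is simply evaluated across space.
The atom convention for the non-adjacent case is not uniquely dictated by the
classical definition; we mirror the sequential one with k in the "previous
residue" role, and record this as a deliberate convention.

Each directed edge (w → v) carries `(d_wv, cos phi_wv, cos psi_wv)` oriented
toward the receiving node v; on Cα-only traces it carries `(d_ab, cos Phi_ab)`
where the pseudo-dihedral `Phi_ab` anchors the quadruple on the pair itself
plus the spatially nearest other Cα of each endpoint (distance ties broken by
the lower residue index, deterministically). Missing atoms or degenerate
(collinear) geometry never abort a run: the affected cosine is stored as a
sentinel 0 with a mask bit, and masked entries are excluded from every
average. Node features are the channel-wise means of the unmasked incoming
edge features, optionally concatenated with a 21-way residue-type one-hot
(20 amino acids + UNK).

Because every feature is a distance or a cosine, the whole featurization is
invariant under rigid-body motion, and because residue numbers are never
consulted, it is invariant under residue relabelling. Both properties are
enforced by property tests.

## The two classifiers

**FOS baseline.** The first-order-statistics baseline summarises each node by
the mean of its incident edge features (three values; a variant appends
variances for six) and classifies with a k-nearest-neighbour vote
(`k_classifier = 20` by default, the better noise-free setting; 60 is the
better choice on noisy inputs). Vote ties resolve to the smallest class id
and neighbour-distance ties to the smallest training index, so predictions
are fully deterministic. The intuition: a strand extends, a helix spirals,
and the neighbourhood means of `cos φ`/`cos ψ` separate those local shapes.

**Message-passing network.** The main classifier is a two-layer
edge-conditioned convolution. At layer t the message to node v is
`m_v = Σ_{w∈N(v)} N_t(e_wv) · h_w`, where the filter network `N_t` — a
four-layer perceptron with ReLU activations — maps the directed edge feature
vector to a (hidden × input) matrix. The vertex update is linear,
`h_v ← Θ_t h_v + m_v`, with one ReLU between the two layers, and the readout
is a two-layer perceptron composed with a softmax. The initial hidden state
is the aggregated-edge-feature node vector plus the residue one-hot; using
the aggregate (rather than the residue type alone) measurably helps, and the
one-hot can be dropped by flag.

Choices the architecture leaves open, and what this package does:

* *Widths*: hidden state 32, filter network 32-32-32, readout hidden 32.
  Width 32 keeps full training runs of the synthetic study comfortably on a
  single CPU core while saturating validation F1; doubling it changed
  nothing but the run time in our experiments. All widths are `mpn_config()`
  arguments.
* *Optimizer and loss*: full-batch Adam (rate 0.01) on an exact log-softmax
  cross-entropy (no probability clipping — the loss stays differentiable
  exactly where the softmax is, which the finite-difference gradient tests
  rely on). Optional inverse-frequency class weights for imbalanced schemes.
* *Split and early stopping*: proteins (never residues) are split 70/30 into
  train/validation with a seeded shuffle; training keeps the parameters of
  the best validation macro-F1 epoch and stops after 25 epochs without
  improvement.
* *ReLU placement*: after the first update only; the readout supplies its
  own nonlinearity.
* *Ablation augmentation*: optionally (`ablation_augment`), each training
  protein also contributes randomly ablated, re-featurized copies.
  Experimental training structures naturally contain chain breaks and
  unobserved residues; synthetic chains do not, and a model trained only on
  perfect chains never sees a gap-spanning edge. The augmentation
  reintroduces that heterogeneity. Validation proteins are never augmented.

## Noise model

Measurement imprecision enters the features through three channels:

1. **Distance noise.** Gaussian noise of standard deviation η1 (Å) added
   symmetrically to a distance matrix can make it non-Euclidean, in which
   case the dihedral reconstruction can divide by zero. The matrix is
   therefore projected back onto the cone of Euclidean distance matrices:
   square the entries, double-center (`G = −½ J D J`), clip negative Gram
   eigenvalues to zero, rebuild squared distances from the clipped Gram.
   The projection operates on *squared* distances — classical
   double-centering is only meaningful there — and is idempotent and the
   identity on valid inputs (both tested).
2. **Face-angle noise.** Gaussian noise on the trihedron angles α, β, γ
   (radians), propagated through the cosine law. Provided for comparison;
   not used by the main pipeline.
3. **Cosine noise.** Gaussian noise of standard deviation η2 added directly
   to dihedral cosines, clamped to [−1, 1] (arccos requires it; masked
   entries pass through untouched). This is the channel used for the
   robustness study, via `perturb_graph_cosines()`.

`monte_carlo_omega_error()` quantifies what cosine noise does to the
recovered angle: for each ω on a grid covering (0°, 180°) and each η2 it
draws perturbations, maps them back through `acos`, and reports the mean
absolute angular error mean |ω′ − ω| (the primary estimator) alongside the
RMS error. Near ω = 90° the delta method
gives `mean |error| ≈ η2 · (180/π) · √(2/π)`; toward 0° and 180° the error
inflates as 1/sin ω and the clamp folds the noise one-sidedly. The two
estimators differ by a constant-ish factor (√(π/2) ≈ 1.25 in the linear
regime) — both are reported so the reader can compare against whichever
convention an external account of this experiment used.

## Label schemes and evaluation

Reference labels are the eight DSSP states (H, G, I, E, B, T, S, -);
`map_labels()` collapses them into four tasks: α-vs-Other, β-vs-Other,
α/β/Other, or the full 8-state problem. By default only H counts as helix
and only E as strand (G, I, B go to Other); the collapse is configurable
because conventions differ between assigners.

Evaluation uses macro precision/recall/F1 with the 0 convention for empty
denominators and averaging over *all* d classes of the scheme, including
classes absent from the test set — deliberately conservative and comparable
across tasks. Beyond the scalar scores:

* `boundary_error_profile()` locates each misclassification inside a true
  helix/strand element by its distance to the nearer element extremity
  (`w = 1` for the first/last residue). Assignment errors concentrate at
  element limits, where backbone geometry deforms continuously while the
  discrete reference labelling jumps.
* `trim_element_limits()` relabels the w outermost residues of every element
  as Other (elements shorter than 2w + 1 dissolve), for re-scoring with the
  ambiguous limit residues excluded.
* `element_stats()` counts maximal-run elements and their mean lengths —
  useful for judging fragmentation when annotating traced Cα backbones.

## The synthetic generator

`build_backbone()` grows chains by sequential internal-coordinate (NeRF)
placement with ideal bond geometry (N–CA 1.46 Å, CA–C 1.52 Å, C–N 1.33 Å,
trans peptide ω = 180°) and per-segment dihedrals: α at −57°/−47°, β at
−139°/+135°, coil drawn per residue from φ ~ U(−100°, −75°),
ψ ~ U(−20°, 30°), all with optional Gaussian jitter. The coil basin is
deliberately placed so that it remains separated from the α and β basins *in
cosine space*: featurization only ever sees cosines, cosine is even, and a
coil basin at +57° would alias onto the helix basin. Residue types are
drawn uniformly and carry no label signal.

The default study conditions — 60 proteins of 45–75 residues, segment mix
α 0.4 / β 0.3 / coil 0.3, jitter 5° — are what the acceptance-level tests
train on; a full run (featurization, training with ablation augmentation,
and the robustness evaluations) completes in a few minutes on one CPU core.
Unit tests use 3–14 proteins of 20–30 residues.

What the generator does *not* emulate: tertiary packing (no compact folds,
so long-range contacts are rare and the k-NN graph is more chain-like than
in globular proteins), inter-strand hydrogen-bonded sheets, sidechains, and
real experimental noise (B-factors, resolution-dependent error). Passing the
synthetic study therefore demonstrates that the machinery learns and
separates local backbone geometry under controlled conditions — it does not
by itself certify performance on crystallographic data, which requires
user-supplied structures and DSSP references through the identical code
path (`read_structure()` → `featurize_structure()` → `predict()` →
`macro_prf()`).

## Numerical conventions, all in one place

* Dihedral cosines clamp to [−1, 1] only within 1e−9 of the boundary;
  larger violations raise a geometry-inconsistency error.
* Collinear triples are degenerate: an error in direct geometry calls, a
  masked feature during featurization.
* k-NN candidate ties break by the lower residue index; the threshold graph
  uses strict `<`; union symmetrization (an edge exists if either endpoint
  selects the other).
* Sequence-adjacent pairs are *not* excluded from k-NN candidates — nothing
  in the graph definition distinguishes them, which is the point.
* Prediction argmax ties resolve to the smallest class id, everywhere.
* The distance channels (edge `d`, node mean distance) are standardized with
  training-set statistics stored in the model; cosine and one-hot channels
  are already unit-scale.
* All randomness (generation, splits, initialisation, noise draws) is
  seeded, and seeded helpers restore the caller's RNG state.

## Known limitations

* The FOS feature definition admits two readings (means only, ℝ³, versus
  means + variances); the package defaults to the ℝ³ means of the full edge
  triple and exposes `include_variance` for the richer variant.
* Cosine features fold the dihedral sign, so conformations that differ only
  by mirror symmetry are indistinguishable — inherent to distance-only
  input.
* The 8-state task is markedly harder than the reduced ones on synthetic
  data simply because the generator only produces H/E/- letters; training
  the full task needs real DSSP references.
* Training is full-batch and in-memory; it is sized for thousands of
  residues per run, not millions.
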