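# geosec

Sequence-agnostic secondary-structure assignment for protein structures:
per-residue helix/strand/other classes computed from inter-atomic distances
and dihedral-angle cosines alone, with no use of primary-sequence
connectivity. Built for structural biologists working with partial models —
structures with unobserved regions, low-resolution models, or raw Cα traces
from cryo-EM backbone tracers — where classical assigners that walk the
sequence cannot run.

## The method in brief

Residues become nodes of a spatial graph: either the union-symmetrized
k-nearest-neighbour graph (*method A*, default `k = 2`) or a strict
distance-threshold graph (*method B*, default `τ = 3 Å`), with the distance
between residues defined as the minimum over their atom pairs. Each directed
edge (w → v) carries

- all-backbone mode: `x_wv = (d_wv, cos φ_wv, cos ψ_wv)` — the classical
  backbone dihedrals generalized to arbitrary residue pairs;
- Cα-only mode: `x_ab = (d_ab, cos Φ_ab)` — a pseudo-dihedral over four Cα
  atoms chosen by spatial proximity.

The cosines come from distances only, through the trihedron cosine law

```
cos γ = cos α cos β + sin α sin β cos ω
```

with the planar cosines α, β, γ given by the law of cosines — so the whole
featurization survives inputs where only distances are trustworthy, and a
PSD-cone projection (classical double-centering with eigenvalue clipping)
restores Euclidean consistency of noisy distance matrices.

Classification is a node-classification problem on this graph, solved two
ways:

- **FOS** (first-order statistics): neighbourhood means of the edge features
  plus a deterministic k-nearest-neighbour classifier — the baseline;
- **MPN**: a two-layer edge-conditioned message-passing network,
  `m_v = Σ_w N_t(e_wv)·h_w`, `h_v ← Θ_t h_v + m_v`, with a four-layer ReLU
  filter network `N_t`, softmax readout, and training by back-propagation
  (hand-derived gradients, full-batch Adam, protein-level 70/30 split).

Four labelling tasks are supported (α-Other, β-Other, α-β-Other, and the
eight DSSP states), with macro precision/recall/F1 evaluation,
boundary-error localisation, and element count/length statistics. A
synthetic backbone generator (ideal helix/strand/coil geometry built from
internal coordinates) makes the entire pipeline trainable and testable
without downloading any data.

## Worked example

```r
library(geosec)

# 1. synthesise a labelled dataset and featurize it
dataset <- generate_dataset(n_proteins = 14, length_range = c(30, 50),
                            jitter = 5, seed = 1) |>
  lapply(function(p) list(structure = p$structure,
                          graph = featurize_structure(p$structure, k = 2),
                          labels = p$labels))

# 2. train the message-passing classifier (3-class task)
model <- train_model(dataset, mpn_config(scheme = "alpha-beta-other",
                                         epochs = 60, seed = 1))
glance(model)
#> # A tibble: 1 × 8
#>   scheme           mode     hidden_dim epochs_run best_epoch best_val_macro_f1
#> 1 alpha-beta-other backbone         32         50         25             0.984

# 3. score one protein
pred <- predict(model, dataset[[10]]$graph)
macro_prf(dataset[[10]]$labels, pred)
#> # metrics_report (alpha-beta-other, 3 classes, n = 44)
#> #   macro P = 0.9697  R = 0.9444  F1 = 0.9569  accuracy = 0.9545
#>   class_id precision recall n_true n_assigned
#> 1        0     1      1         12         12
#> 2        1     0.909  1         20         22
#> 3        2     1      0.833     12         10

# 4. where do the errors sit relative to element boundaries?
boundary_error_profile(dataset[[10]]$labels, pred, w_max = 2)
#>   bucket   errors
#> 1 1             0
#> 2 2             0
#> 3 interior      0
#> 4 outside       2

# 5. element segmentation of the prediction
element_stats(pred)
#>   ss_class n_elements mean_length
#> 1 alpha             1       12
#> 2 beta              3        7.33
```

Reading the numbers: the trained network reaches validation macro F1 0.98 on
held-out proteins; on the protein shown, both misclassifications are coil
residues directly flanking a strand (`outside` bucket) — the classic
boundary ambiguity where backbone geometry deforms continuously while the
reference labelling jumps discretely. The angle-error question ("how much
does noise on `cos ω` corrupt ω?") is answered by
`monte_carlo_omega_error()`, which reports mean-absolute and RMS error in
degrees per ω-region and noise level.

Real structures run through the identical path: `read_structure("x.pdb")`
(all backbone atoms or `mode = "ca"` for traces), `featurize_structure()`,
`predict()`, and — when a DSSP reference exists — `read_dssp()`,
`align_labels()`, `map_labels()`, `macro_prf()`. Benchmarks against
experimental datasets therefore need user-supplied PDB/DSSP files; nothing
is downloaded by the package.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/geosec.R synth      --n-proteins 60 --seed 1 --out-dir run
Rscript inst/cli/geosec.R train      --scheme alpha-beta-other --out-dir run
Rscript inst/cli/geosec.R predict    --input run/synthetic_001.pdb --model-dir run/model --out-dir run
Rscript inst/cli/geosec.R evaluate   --input run/synthetic_001.pdb.labels.tsv \
                                     --reference run/synthetic_001_labels.tsv --out-dir run
Rscript inst/cli/geosec.R noise-sim  --seed 1 --out-dir run
```

Runs are reproducible: identical configuration and seed give byte-identical
label files.

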