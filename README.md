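# saxsfold

Small-angle X-ray scattering (SAXS) is one of the few solution-state
measurements cheap enough to run routinely, and its real-space form — the
pair distance distribution function P(r), the electron-weighted histogram of
all interatomic distances — is a global fingerprint of the conformations a
protein actually adopts in solution. saxsfold is an R toolkit for using that
fingerprint in structure modelling. It is aimed at structural
bioinformaticians who want to (a) synthesize SAXS observables from atomic
models, (b) score predicted structures against measured or reference
profiles, and (c) drive a frozen structure predictor toward profile-consistent
conformational ensembles at inference time.

## What it computes

**Forward model.** For point atoms with electron counts `Z_i`:

- P(r): histogram over unordered pairs with weight `2 Z_i Z_j`; the self
  term `sum(Z_i^2)` is carried separately so that the reciprocal-space
  transform `I(q) = sum(Z_i^2) + sum_k w_k sinc(q r_k)` is exact and
  `I(0) = (sum Z_i)^2` holds identically.
- I(q): the Debye sum `I(q) = sum_ij Z_i Z_j sin(q r_ij)/(q r_ij)`, with
  `q = (4*pi/lambda) * sin(theta)`.
- Rg and Dmax, from coordinates and from P(r) (second-moment relation with
  the self-term mass included, which makes it exact at any atom count).

**Differentiable path and losses.** A soft P(r) (integrated Gaussian kernel
per bin) with exact analytic gradients with respect to every coordinate; the
L1 profile loss `sum_k |p_k - t_k| * dr`; the six-term composite training
loss `0.5 L_FAPE + 0.5 L_aux + 0.3 L_dist + 2.0 L_msa + 0.01 L_conf +
2.0 L_SAXS`; and a chi-squared profile fit with a closed-form linear scale.

**Conditioning and inference-time optimization.** Cross-attention modules
that inject P(r) tokens into MSA (8 heads, c = 32) and pair (4 heads,
c = 32) representations, exact no-ops at their zero-initialized output
projections; and an optimization loop that trains a two-layer residual MLP
adapter between a frozen fold head and its output by Adam on the SAXS loss
(500-iteration budget, patience-50 early stopping, top-50 snapshot
retention).

**Curation and evaluation.** Multi-model (NMR-style) splitting, a
256-residue length filter, 70%-identity similarity exclusion
(Needleman-Wunsch, unit match / zero mismatch / gap -1), seeded contiguous
cropping with per-crop P(r) recomputation, apo-holo target selection (pair
RMSD > 4 A, per-conformer RMSD > 2.5 A, length <= 256); Kabsch CA-RMSD,
accuracy tiers (<= 1 A high, 1-5 A mid, > 5 A low), intra-ensemble
diversity, and the P(r)-divergence vs output-diversity Pearson correlation.

Everything is exercised end-to-end on deterministic synthetic fixtures
(helices, extended chains, globules, hinge open/closed pairs, multi-model
ensembles, noisy profiles) — no downloads, no trained weights.

## Worked example

```r
library(saxsfold)

# a 64-residue ideal helix, its P(r) and Debye intensity
helix <- make_chain("helix", n_res = 64, seed = 1)
pr <- compute_pr(helix, dr = 0.5, normalize = TRUE)
pr
#> pr_curve: 190 bins, dr = 0.5 A, Dmax = 94.6 A, normalized (unit area)
rg_from_coords(helix)   # 27.80 A
rg_from_pr(pr)          # 27.87 A -- second-moment relation, self term included
iq <- debye_intensity(helix, seq(0, 0.5, length.out = 101))
iq$intensity[1]         # 147456 == (sum Z_i)^2

# inference-time ensemble generation: start from a closed hinge conformer,
# target the P(r) of the open state
pair   <- make_hinge_pair(n_res = 64, angle_open = 10, angle_closed = 110, seed = 1)
target <- compute_pr(pair$open, dr = 0.5, normalize = TRUE)
fold   <- surrogate_fold_head(coords_matrix(pair$closed), feature_width = 32, seed = 1)
cfg    <- adapter_config(seed = 1, learning_rate = 0.05, max_iterations = 300)
trace  <- optimize_adapter(fold, target, cfg, bandwidth = 2)
trace
#> optimization_trace: 300 iteration(s), best loss 0.0222162 at iteration 300, stopped on budget
ensemble <- select_top_k(trace, 50)
intra_ensemble_rmsd(ensemble$structures)  # 0.59 A
```

The SAXS L1 falls from 0.472 to 0.022 while only the adapter's parameters
change (the fold head's checksum is verified before and after), the best
snapshot's radius of gyration lands within ~0.1 A of the open-state target
from an initial error of 18.9 A, and the retained 50-structure ensemble has
nonzero internal RMSD — distinct conformations, not duplicates.

The same pipeline is scriptable from a shell through the installed
`exec/saxsfold` entry point:

```sh
saxsfold simulate --kind hinge_pair --n-res 64 --seed 1 -o sim/
saxsfold profile sim/closed.pdb --dr 0.5 -o sim/closed
saxsfold optimize-demo --target sim/open_pr.out --n-res 64 --seed 1 -o run/
saxsfold evaluate --pred run/ensemble.pdb --refs sim/open.pdb sim/closed.pdb -o eval
```

## Package layout

- `R/` — structure container and element table, P(r)/I(q) math and
  gradients, losses, attention conditioning, adapter optimization, curation,
  evaluation, synthetic fixtures, IO (PDB/mmCIF via bio3d, ATSAS-style
  `.dat`, two-column P(r)), CLI dispatcher.
- `tests/testthat/` — oracle-backed unit and property tests plus an
  end-to-end acceptance suite.
- `vignettes/saxsfold-methods.Rmd` — the model, its assumptions, numerical
  choices, and what the synthetic fixtures do and do not demonstrate.
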