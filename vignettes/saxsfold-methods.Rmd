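---
title: "SAXS-guided structure modelling with saxsfold: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAXS-guided structure modelling with saxsfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsfold)
```

## What this package models

Small-angle X-ray scattering (SAXS) measures the orientation-averaged
intensity $I(q)$ of a protein in solution as a function of momentum transfer
$q = (4\pi/\lambda)\sin\theta$, where $2\theta$ is the scattering angle and
$\lambda$ the wavelength. Its real-space counterpart, the pair distance
distribution function $P(r)$, is the electron-weighted histogram of all
interatomic distances and acts as a global "shape fingerprint" of the
conformations present in solution. saxsfold implements the computational
machinery needed to use that fingerprint as a constraint on protein
structure prediction:

* forward synthesis of $P(r)$, $I(q)$, $R_g$ and $D_{max}$ from atomic
  coordinates (point-atom Debye model);
* a differentiable soft $P(r)$ with exact analytic coordinate gradients, an
  L1 profile loss, a weighted composite training loss and a $\chi^2$
  profile fit;
* cross-attention modules that inject $P(r)$ tokens into MSA and pair
  latent representations;
* an inference-time optimization loop that trains a small adapter between a
  frozen predictor and its structure head to generate SAXS-consistent
  conformational ensembles;
* dataset curation (multi-model splitting, length and similarity filters,
  random cropping, apo--holo target selection) and evaluation metrics
  (Kabsch RMSD, accuracy tiers, ensemble diversity, divergence--diversity
  correlation);
* deterministic synthetic structure generators so the whole pipeline is
  testable without any external data.

## Scattering model and conventions

Atoms are point scatterers with $q$-independent form factors $f_i = Z_i$,
the atomic number. Hydrogens missing from coordinate files are **not**
imputed by default; `united_atom()` optionally folds standard implicit
hydrogen counts into their bonded heavy atoms. Waters, alternate locations
beyond "A", and zero-occupancy atoms are dropped at parse time. These are
package conventions, fixed once for bit-reproducibility, not facts about
any particular experiment.

The cross-pair histogram uses bin centers at $(k + \tfrac12)\Delta r$ with
default $\Delta r = 0.5$ Å; a distance falling exactly on a bin boundary
goes to the upper bin. The self term $\sum_i Z_i^2$ is carried separately
from the histogram, never mixed into the $r = 0$ bin, which keeps the
real/reciprocal relation

$$I(q) = \sum_i Z_i^2 + \sum_k w_k\,\frac{\sin(q r_k)}{q r_k}$$

exact when all pair distances sit on bin centers, and makes
$I(0) = (\sum_i Z_i)^2$ hold identically. The residual binning error decays
as $\Delta r$ shrinks; at $\Delta r = 0.1$ Å it is below 1% for
$q \le 0.5$ Å$^{-1}$ on the packaged test fixtures.

$R_g$ from $P(r)$ uses the second-moment relation with the self-term mass
included in the denominator:
$R_g^2 = \int r^2 P \, dr \,/\, 2\,(\int P\,dr + \sum_i Z_i^2)$ on the raw
weight scale. Including the (momentless) self mass makes the relation exact
at any atom count — two equal atoms at separation $d$ give exactly $d/2$,
and the value agrees with the electron-weighted coordinate-space $R_g$ up to
binning — whereas the familiar continuum form, used as a fallback when a
normalized curve carries no absolute scale, omits the diagonal and is only
asymptotically correct.

## The differentiable P(r)

`compute_pr_soft()` replaces the hard bin assignment with an integrated
Gaussian kernel: the mass a pair at distance $d$ deposits into bin $k$ is
$\Phi\!\big(\frac{e_{k+1}-d}{h}\big) - \Phi\!\big(\frac{e_k - d}{h}\big)$,
where $e_k$ are bin edges and $h$ the bandwidth (default $\Delta r$).
Integrating the kernel across the bin, rather than sampling it at the bin
center, is what guarantees convergence to the hard histogram as
$h \to 0^+$: a center-sampled kernel loses pairs entirely once
$h \ll \Delta r$. The curve is renormalized to unit area, and
`pr_soft_vjp()` propagates the cotangent of any downstream scalar through
the renormalization and kernel analytically; tests verify agreement with
central differences to better than $10^{-4}$ relative (observed:
$\sim 10^{-8}$).

## Losses

`saxs_l1()` computes $\sum_k |p_k - t_k|\,\Delta r$ on the finer common
grid of two unit-area curves. The $\Delta r$ factor makes the value stable
under re-binning in the fine-grid limit and bounds it by 2 (the total
variation bound, attained for disjoint supports). `composite_loss()` forms
the six-term training objective with weights 0.5 (FAPE), 0.5 (auxiliary),
0.3 (distogram), 2.0 (masked MSA), 0.01 (confidence) and 2.0 (SAXS); the
five non-SAXS terms are consumed as scalars from the host network.
`chi2_fit()` fits one linear scale in closed form and reports the
per-point-averaged $\chi^2$, the convention of standard profile-fitting
tools. On synthetic profiles whose uncertainty column matches the injected
noise, $\chi^2$ lands near 1 (calibration checked over 20 seeds in the
tests).

## SAXS conditioning modules

`embed_pr()` turns each $P(r)$ bin into one token: a learned linear map of
the bin density concatenated with a sinusoidal encoding of the bin center.
`saxs_msa_attention()` (8 heads, $c = 32$) forms one query per (cluster,
residue) position of the MSA representation; `saxs_pair_attention()`
(4 heads, $c = 32$) forms one query per residue pair, with no weight
sharing between $(i,j)$ and $(j,i)$ because trunk pair activations are not
symmetric. Both modules return additive updates that the caller adds to the
Evoformer inputs. Design choices where the architecture was open:

* output projections are zero-initialized, so an untrained module is a
  strict no-op and cannot corrupt a pretrained trunk;
* token width defaults to $N_{heads} \cdot c$ of the consuming module,
  avoiding an extra projection;
* no gating and no internal layer normalization — the host trunk
  normalizes; the modules are attention plus residual add only;
* tokens encode $P(r)$ bins; an $I(q)$-token variant would be a drop-in
  replacement of `embed_pr()` but is not implemented.

## Inference-time ensemble generation

`optimize_adapter()` freezes the fold head and trains a two-layer residual
MLP adapter (`out = x + W2 tanh(W1 x + b1) + b2`, final layer
zero-initialized so iteration 0 reproduces the frozen prediction) by Adam
on the SAXS L1 between the soft $P(r)$ of the predicted CA trace and the
target curve, plus a small smooth bond-length penalty that keeps
consecutive CA near 3.8 Å. Defaults follow the protocol: at most 500
iterations, early stopping after 50 iterations without improvement of the
best loss (improvement means a decrease of at least $10^{-6}$ — an
exact-tie rule would be float-fragile), and retention of the 50
lowest-loss snapshots (no deduplication). Every iteration records the loss
and a CA-only snapshot; the frozen-trunk contract is checked by comparing a
parameter checksum before and after.

Two numerical choices matter here:

* **Matched smoothing.** The target histogram is smeared with the same
  Gaussian kernel as the model before the L1 is taken. Comparing a smoothed
  model against a sharp target moves the loss minimum to a structure that
  *compensates* for the smoothing — in development this showed up as $R_g$
  drifting away from the target while the loss decreased. With matched
  smoothing the minimum sits at the matching structure.
* **Optimization bandwidth.** The L1 gradient only reaches as far as the
  kernel overlaps; a bandwidth of a few Å (the demo uses 2 Å) gives the
  long-range signal needed to move mass across tens of Å, while profile
  *reporting* uses the sharp default.

`surrogate_fold_head()` provides the frozen predictor for desk-scale runs:
a fixed base conformation plus a linear basis of smooth sinusoidal
collective modes (random frequency, phase and direction per feature, in the
spirit of coarse normal modes). Smooth modes matter: an iid random
displacement basis cannot express hinge-scale collective motion, and the
recovery experiment below is then unreachable regardless of the optimizer.
The adapter acts on a single feature vector (the smallest faithful reading
of "between the trunk and the structure module"); perturbing the pair
representation as well is left out.

The packaged recovery experiment starts from a closed two-domain hinge
(64 residues, hinge angle 110°) and targets the $P(r)$ of the open state
(10°): with learning rate 0.05 and bandwidth 2 Å — the demo's settings;
the config default learning rate is $10^{-3}$ — the best loss falls from
0.47 to about 0.02 and the best snapshot's $R_g$ lands within a few tenths
of an Å of the open-state value from an initial error of 18.9 Å. The
retained top-50 ensemble has nonzero internal CA-RMSD: the trajectory
explores distinct conformations rather than emitting duplicates.

## Curation rules

`filter_length()` drops entries with more than 256 residues (strict `>`);
`exclude_similar()` removes a training entry when its identity to any test
sequence exceeds 70% (strict `>`); `crop_random()` takes a contiguous
256-residue window uniformly at random under the run seed, and
`build_training_records()` recomputes each model's $P(r)$ from exactly its
cropped coordinates so profiles always match crops;
`select_apo_holo_targets()` keeps pairs with length ≤ 256, pair RMSD
> 4 Å and each precomputed per-conformer baseline RMSD > 2.5 Å (the
per-conformer RMSDs come from the source benchmark as an input column and
are not recomputed here). Sequence identity is Needleman–Wunsch with unit
match, zero mismatch and linear gap −1; because co-optimal alignments can
differ in match count, the traceback applies a fixed tie-break and the
sequence pair is ordered canonically, making the measure deterministic and
symmetric. Whether the original "70% similarity" meant plain identity or a
clustering tool's score is not derivable from the protocol; plain
global-alignment identity with config-exposed parameters is this package's
recorded choice.

## Evaluation

`kabsch_rmsd()` is the SVD superposition with the determinant correction
that forbids reflections, computed over CA atoms. The accuracy tiers place
1.0 Å in "high" and 5.0 Å in "mid" (closed-left reading of "≤ 1.0" and
"1.0–5.0"). `unfavoured_conformer_rmsd()` reports the farther of the two
reference conformers, resolving exact ties to the first-listed reference
with a flag. The divergence–diversity statistic is the plain Pearson
coefficient (`stats::cor`).

## What the synthetic generators do and do not emulate

`make_chain()` produces CA traces: an ideal helix (rise 1.5 Å, 100° per
turn, radius 2.3 Å), an extended chain (rise 3.5 Å with a lateral zigzag
keeping consecutive CA at 3.8 Å) and a sphere-confined random walk
globule. `make_hinge_pair()` builds rigid two-domain open/closed conformer
pairs sharing one sequence; `make_nmr_ensemble()` perturbs a base
conformation into a multi-model entry; `make_noisy_profile()` adds
multiplicative Gaussian noise with a matching uncertainty column. All are
pure functions of their arguments and a seed, with a placeholder electron
count of 6 per CA.

These fixtures exercise every in-scope computation, but they are not real
data: no side chains, no solvation or excluded-volume scattering, no
buffer-subtraction artifacts, no inter-domain contact physics. Passing
tests therefore demonstrate the correctness of the *machinery* —
histograms, transforms, gradients, optimization control flow, filters,
metrics — not prediction accuracy on experimental SAXS profiles, which
additionally depends on trained network weights outside this package's
scope.

## Problem sizes and degenerate inputs

The test suite and the acceptance script use 30-atom fixtures for oracle
comparisons, 64 residues for the recovery experiment (300 optimization
iterations in the script; the config default budget is 500), and 20-model
ensembles for curation, sizes at which every check runs in seconds while
still exercising each code path. Degenerate inputs fail loudly rather than
silently: single-atom structures, zero-mass curves, non-positive
bandwidths, unnormalized curves where unit area is contractual, missing
uncertainty columns in $\chi^2$ fits, missing composite-loss components,
and non-finite optimization losses (which abort with a diagnostic
condition carrying the partial trace).

## Known limitations

Point-atom form factors and the absence of hydration-shell or
excluded-volume terms mean computed intensities are idealized vacuum
profiles; $q$-dependent form factors are a documented extension point.
mmCIF reading is single-model (multi-model splitting is implemented for
PDB). The attention and adapter components are forward-correct and
seed-deterministic but are not trained here; the package deliberately stops
at the machinery a training or inference pipeline would call.
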