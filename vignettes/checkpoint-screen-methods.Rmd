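---
title: "Methods: analysis of radiation-checkpoint RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of radiation-checkpoint RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g1screen)
```

## The assay and its readout

The package analyses high-content RNAi screens in which ionizing radiation
(IR) activates the G1 checkpoint of checkpoint-competent cells, read out as
loss of RB1 phosphorylation (serine 780) by quantitative immunofluorescence.
Each 96-well plate carries one siRNA pool per well plus in-plate triplicate
controls: a checkpoint-ablating positive control (p21 siRNA), mock
(lipid-only) and non-targeting (NT) wells. After IR, a large fraction of
control cells shift into a low-marker ("responder") population; knockdown
of a gene required for checkpoint activation suppresses that shift. The
per-well statistic is the percentage of responder cells (POS-LoRBPS780),
with analogous percentages for p21 nuclear positivity (POS-p21) and for a
nuclear/cytoplasmic G1 reporter ratio (POS-G1).

The pipeline starts from per-cell intensity tables; image acquisition and
segmentation are out of scope.

## Single-cell gating

Gates are derived per plate, from the plate's own control wells
(`derive_gate()`). The two pooled control samples are compared on the log
scale by kernel density estimation with a **common bandwidth** (mean of the
two `bw.nrd0` bandwidths), and the threshold is placed at the crossing of
the two densities. Two situations arise:

* Near-pure controls (one dominant population each): the crossing lies
  between the medians; for equal log-spreads it is the geometric midpoint
  of the medians.
* Realistic screen controls, which are *mixtures* of the same two
  intensity populations with different weights (NT after IR: ~45% low;
  positive control: ~5% low): the difference of two equal-bandwidth
  mixture estimates is proportional to the difference of the smoothed
  components, so the density crossing sits exactly at the component
  crossing — the statistically correct gate — even though it lies outside
  the interval between the mixture medians.

A common bandwidth matters: per-sample bandwidths smooth the bimodal NT
sample more than the unimodal positive control and shift the crossing by
roughly 0.15 log units, inflating responder fractions by about one
percentage point. When several density crossings survive the
low-density mask (tail artifacts), the crossing with the greatest shared
density height is used; if no crossing is found the gate falls back to the
midpoint of the log medians. Controls whose medians differ by less than a
configurable fold (default 1.2) raise a "no separation" error.

Gating direction is per metric: responders fall *below* the gate for
RB1-PS780 loss; p21 positivity gates *above* a background anchored on
TP53-knockdown wells. The G1 reporter uses a fixed nuclear:cytoplasmic
ratio threshold of 2, inclusive — the direction (nuclear high in G1)
follows the reporter's biology; both threshold and direction are
arguments. Wells below 1500 cells are reported but flagged unreliable, not
dropped, since the minimum is a quality criterion and silent deletion
would hide it.

On unirradiated counterscreen plates the positive-control and NT
histograms coincide (there is no responder shift to suppress), so those
plates carry no gating information of their own; each inherits the gate of
its paired irradiated plate (same plate index and replicate).

## Plate quality control

Plate quality is summarized by the Z-prime factor
\(Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|\) over the positive
(p21 siRNA) and negative (mock) control wells, with sample (n−1) standard
deviations and an absolute mean difference so the statistic survives
assays where the positive control reads low. A triplicate plate set is
rejected for rerun when any plate falls strictly below 0.2; exactly 0.2 is
accepted. The rejection rule applies to the irradiated assay plates only:
the counterscreen plates have no control window by construction, so their
Z-prime is reported but cannot gate them.

## Hit calling

Each target's triplicate mean POS is standardized against the mean and SD
of all library target means from the same run. The alternative reading of
"standard error" as the per-target SE of the mean would shrink the
denominator threefold and inflate all |z|, contradicting the expected
normal-tail behaviour of a null library (~6.7% of targets below z = −1.5);
the population-SD reading keeps the library calibrated so that a 779-target
null screen yields about `779 * pnorm(-1.5)` ≈ 52 targets below −1.5.

Targets with z < −1.5 are graded by fold reduction of the mean responder
percentage relative to the pooled mock (lipid-only) wells of the
irradiated plate set: strong ≥ 2-fold, average [1.6, 2), weak [1.4, 1.6),
boundaries closed on the left ("2-fold or greater" is inclusive; the
interior boundary side is a convention and configurable). The baseline is
switchable to NT wells or the library population mean. Hits whose
*unirradiated* z falls below −1.3 are flagged nonspecific and excluded
from the candidate list; hits missing from the counterscreen are flagged
untested but retained, because the counterscreen is a specificity check,
not a gate. Deconvolution treats a single oligonucleotide as active when
it meets the same criteria as a weak-or-better pool hit (z < −1.5, fold
≥ 1.4); a target validates with ≥ 2 active oligos. No multiple-testing
correction is applied to the primary screen.

## Interaction statistics

Checkpoint and viability phenotypes are normalized to their matched mock
or untreated reference (`normalize_relative()`), technical replicates are
averaged within biological replicate before any test (`bio_rep_means()`),
and paired Student's t-tests run across biological replicates
(df = n − 1). Degenerate difference vectors are resolved explicitly:
all-zero differences give t = 0, p = 1; constant nonzero differences give
the limiting p = 0.

The knockdown×treatment interaction index is
\((R_c/C_c)\cdot(C_{IR}/C_c) - (R_{IR}/C_c)\): the multiplicative
(Bliss-style) expectation of the combined response minus the observed
combined response, zero exactly for independent effects. Classification
is direction-aware: the IR-induced effect in the target arm is compared
with that in the mock arm, oriented by whether IR increases (p21, G1) or
decreases (viability) the readout; |index| below a configurable tolerance
(default 0.02, chosen as roughly the numerical noise of triplicate ratios
and stated with every classification) is reported as "none". The raw sign
of the index alone does not encode the rule for IR-increasing readouts,
which is why the classification is computed from the oriented effects.
`survival_curves()` applies the index per dose within each co-knockdown
background (NT vs CHK1- or TP53-perturbed), normalizing each arm to its
own untreated control.

## Phenotype-profile clustering

Per-target profiles of normalized assay means are clustered by
agglomerative hierarchical clustering on Euclidean distance with complete
linkage after row standardization — the defaults of the standard R
heatmap routine — and the tree is cut at k = 2, reflecting the
two-group structure of interest: knockdowns that suppress checkpoint
metrics *and* p21 induction versus those that suppress the checkpoint
with preserved p21 induction. Distance, linkage, scaling and k are all
arguments, since only the routine, not its parameters, is canonical.
Constant rows are an error before standardization. Dendrograms export as
newick via `ape`.

## The synthetic-screen generator

Every stage is exercised on `simulate_screen()`, which emulates the study
conditions: a 779-target library in 96-well triplicate plate sets (87
library wells per plate, triplicate positive/mock/NT controls in row A),
a 5 Gy run plus an unirradiated counterscreen, and Poisson cell counts
(mean 2500) that naturally dip below the 1500-cell QC floor.

Per-cell marker intensities are two-component log-normal mixtures —
fluorescence is positive and right-skewed — and knockdown acts only on the
mixture weight (the responder fraction), never on component locations,
because the assay's readout is a percentage of cells, not a mean
intensity. The true responder fraction of a well is
\(b + (ir - b)(1 - e)\) with baseline \(b = 0.05\), checkpoint-competent
IR response \(ir = 0.45\), and effect size \(e\) (positive control
\(e = 1\)); Gaussian well-to-well jitter (SD 0.015) models transfection
and plate effects. `effect_for_fold()` inverts this for a desired true
fold reduction; the default planted-hit set is 12 strong (fold 2.5), 18
average (1.8) and 11 weak (1.5) hits. Component centres sit 3 log-SD on
either side of the midpoint gate (`separation_sigma = 3` per side), so a
correctly placed gate misassigns only ~0.13% of cells per component; this
per-side convention is what makes the ±1-percentage-point gate-recovery
behaviour attainable at all. The G1 reporter draws independent nuclear
and cytoplasmic log-normals whose location ratio encodes cell-cycle
state — the simplest model producing a gateable ratio. Viability arms are
survival fractions per (arm, dose ∈ {0, 2, 5} Gy) with multiplicative
log-normal noise; the defaults emulate a target that sensitizes only in
the co-knockdown background. None of these distributional choices are
estimates of the real assay — the source screen reports no raw per-cell
distributions — so passing tests demonstrate correctness of the analysis
on data with the *assumed* structure, not performance on instrument data
with, e.g., spatial plate effects, illumination gradients or correlated
segmentation errors, none of which are modelled (or corrected for, since
the analysed screen applied no spatial normalization).

A fixed seed makes every generator output bit-identical; the fast
well-level path draws well responder counts binomially under the same
model (including the small analytic gate spill) and is cross-checked
against the per-cell path in the tests.

## Problem sizes and numerical conventions

The test suite runs screen-scale checks at the well level (20 planted
screens and 50 null screens of 779 targets in seconds) and reserves
per-cell simulation for gating checks (100 wells of 2×10⁴ cells, control
pools of 3×2×10⁴ cells) and a 40-target end-to-end pipeline run; these
sizes give Monte-Carlo error comfortably below the assertion tolerances.
Ties at gate thresholds have measure zero for continuous intensities; the
G1 ratio boundary is inclusive by convention. Fractions are carried as
percentages (0–100) throughout, matching the POS convention; ratios and
indices are dimensionless. All pipeline outputs embed an MD5 hash of the
resolved configuration, and a re-run reuses a stage output only when its
hash matches.

## Known limitations

* The generator does not model spatial (row/column/edge) plate effects,
  transfection chemistry, or radiation physics.
* DNA content is simulated for object identification only; no
  DNA-content cell-cycle gating is implemented.
* Dose–response analysis reports normalized points and interaction
  indices at 0/2/5 Gy; no survival-curve model fitting.
* The interaction "none" band and the deconvolution activity criteria are
  conventions made explicit and configurable rather than estimated.
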