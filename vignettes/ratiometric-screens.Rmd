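---
title: "Ratiometric analysis of split-luciferase interactome screens"
author: "RatioScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric analysis of split-luciferase interactome screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RatioScreen)
```

## The measurement model

Split-luciferase (NanoBiT-type) protein-fragment complementation assays
fuse the two engineered fragments of a luciferase to a bait and a prey
protein. Reconstitution of the enzyme — and hence luminescence — is
enhanced by bait–prey proximity, but the fragments also self-associate at
a low rate. The background luminescence produced by this self-association
grows with the abundance of the two tagged proteins and with their
colocalization, so abundant, colocalized but non-interacting pairs can
outshine weakly expressed genuine interaction partners. This is the
confounder the whole package is organized around.

RatioScreen models the latent (noise-free) luminescence of a bait–prey
strain as

$$ S = k_\mathrm{int}\, w \, \min(A_b, A_p) \;+\;
      k_\mathrm{self}\, c(b, p)\, A_b A_p $$

where $A_b$ and $A_p$ are the protein abundances (arbitrary copy-number
units), $w \ge 0$ the interaction strength, and $c(b,p) \in [0,1]$ a
colocalization factor (1 for proteins in the same compartment). The
interaction term scales with the scarcer partner because a complex cannot
outnumber either of its constituents; the background term follows
mass-action kinetics of two independently diffusing fragment pools, which
is why it scales with the *product* of the abundances. This asymmetry —
min for signal, product for background — is what makes abundant random
pairs light up while weak true pairs stay dim, and it is the property the
synthetic generator must reproduce for any downstream benchmarking to be
meaningful.

Full-length reporter (NanoLuc) strains carry a single tagged protein and
read out $S = k_\mathrm{int} A$: an abundance channel measured with the
same instrument and plate logistics.

## From raw plates to normalized signals

`normalizeScreen()` chains five steps, each available separately:

1. **Background subtraction** (`subtractBackground`). The instrument
   background of every plate read and channel is the median of its
   medium-only (`BLANK`) wells — a median rather than a mean so a few
   contaminated blanks cannot shift it. The detection floor is set at
   3 robust SDs (MAD) of the blanks above that median; readings below it
   are indistinguishable from instrument noise, are set *to* the floor
   (left-censoring, not removal) and flagged. Keeping censored wells at
   the floor keeps every downstream ratio computable and honestly bounded;
   the flag travels with the record so calls on censored data can be
   discounted.
2. **Cell-density correction** (`densityCorrect`). Luminescence is divided
   by the matched background-subtracted density reading (fluorescence or
   OD600) of the same well; wells whose density does not rise above its
   own blank level are excluded — a colony that did not grow has no
   meaningful luminescence either.
3. **log2 transform** (`log2Transform`), on values kept positive by the
   epsilon clamp upstream.
4. **Plate normalization** (`plateNormalize`). Day-to-day and
   plate-to-plate variation (substrate decay, temperature, detector
   drift) appears as an approximately linear distortion of the log2
   signals. Each plate read's values are regressed (OLS) against the
   cross-replicate median of the same strains, and the fitted map
   $y = m x + b$ is inverted: adjusted $= (y - b)/m$, so every plate read
   lands on the common median scale. Inversion (rather than residual
   subtraction) was chosen so the adjusted values have the units and scale
   of the median signal itself; residual subtraction is available via
   `method = "residual"`. Plates with $|m| < 0.1$ are left unadjusted and
   flagged — inverting a near-flat fit would amplify noise without bound.
   Fits need at least 10 wells (configurable); a single-replicate input
   passes through unchanged with a warning, since there is no median to
   regress against.
5. **Replicate aggregation** (`aggregateReplicates`) into a
   `PairSignalSet` (a `SummarizedExperiment`: strains × replicates), with
   per-strain means, censoring fractions, inter-replicate Pearson
   correlations and the plate fits kept as QC metadata.

## Ratiometric scores

Both scoring modes subtract, in log2 space, a control signal chosen to
carry the same abundance background as the scored pair:

* **Shared-partner mode** (`sharedPartnerRatio`), for reference-set
  benchmarking: the control for a pair is the *maximum* signal among
  random pairs containing either its bait or its prey. Pairs known to
  produce genuine signal can be excluded from control duty (the
  `exclusions` argument) while still being scored themselves.
* **Control-bait mode** (`controlBaitRatio`), for systematic screens: the
  control for a prey is its signal with one or more control baits,
  aggregated by max. The max is the conservative choice — a prey must beat
  *every* control to score — and degenerates to the single control value
  when only one is given; mean aggregation is available via
  `aggregate = "mean"`. Control baits should share localization and
  comparable abundance with the target and must not be known partners of
  the scored preys (the caller controls the list, e.g. excluding an
  F-box adaptor as control for its own cullin scaffold).

Because both the pair and its control carry the prey's (and bait's)
abundance term, adding any constant to a prey's log2 signal under target
and all controls cancels exactly — the mechanism by which the ratio
removes the abundance confounder. This invariance is enforced to 1e-9 in
the test suite.

Significance (`ratioSignificance`) is a two-sided Welch unequal-variance
t-test of the pair's log2 replicate values against the pooled replicates
of the selected control strain(s). The test is deliberately simple: with
3–4 replicates per side nothing more elaborate is identifiable. With
fewer than two replicates on a side the p-value is reported missing
rather than 1, so the downstream significance gate can distinguish
"untestable" from "tested and null". Per-pair p-values are *not*
multiplicity-corrected: the classification threshold is set on the ratio,
and the p < α gate is a secondary filter, mirroring common practice for
volcano-style displays of such screens.

## Classification benchmarking

`sweepThresholds()` enumerates every candidate threshold (the sorted
unique scores plus ±∞), counts TP/FP/TN/FN with ties counted positive
(score ≥ threshold), and computes

$$\mathrm{Sensitivity} = \frac{TP}{TP+FN},\quad
  \mathrm{Precision} = \frac{TP}{TP+FP},\quad
  \mathrm{Specificity} = \frac{TN}{TN+FP},$$
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

with MCC defined as 0 at degenerate margins and precision undefined (NA)
when nothing is called. ROC and precision–recall areas use the trapezoid
rule along the threshold path, the PR curve anchored at recall 0 with the
precision of the most stringent non-empty call (no convex interpolation —
PR areas are convention-sensitive and the convention is stated here).
Unlabeled pairs are excluded from counts but retained in score output.

`selectThreshold()` picks the threshold maximizing the *mean* MCC across
several classifications (e.g. two baits with independent reference sets),
re-evaluated on the union of all candidate thresholds; ties break toward
the more stringent threshold. The mean was chosen over the minimum
because the per-bait MCC curves are step functions on different grids and
the mean rewards thresholds good for both without being hostage to the
noisier curve; `combine = "min"` is available.

## Reference-set curation

Literature evidence arrives as PSI-MI-TAB-like rows (pair, interaction
type, detection method, publication, source database) from offline files —
reproducibility ruled out live database queries. `filterPPI()` keeps
records whose interaction type descends from the configured physical-
association root, removing genetic and protein–nucleic-acid records.
`deduplicateEvidence()` removes explicit duplicates and implicit ones —
the same observation annotated at different vocabulary granularity —
within each (pair, publication) group, using the ancestor–descendant
relation of the detection-method terms; each redundancy class keeps its
most specific record. Cross-publication records are never merged: the
same method in two papers is two pieces of evidence. `buildReference()`
then labels preys with ≥ 3 non-redundant pieces of evidence (default) as
positives; preys with *no* recorded evidence become negatives only if
they also lack annotations to the configured GO terms tied to the bait's
known functions (direct annotation by default, transitive through an
is_a DAG when one is supplied). Everything in between is unlabeled and
excluded from counting — absence of evidence with little study is not
evidence of absence.

## What the generator emulates — and what it does not

`simulateScreen()` reproduces: log-normal abundances (defaults
`meanlog = log(1000)`, `sdlog = 2`, a yeast-like spread over ~4 orders of
magnitude); the latent model above; per-plate-read linear effects in log2
space; replicate noise (log-normal, default SD 0.25 in log2 units, which
yields inter-replicate correlations comparable to well-run screens);
left-censoring at a jittered detection floor; additive instrument
background with noisy blank wells; and a matched density channel. The
default self-association coefficient `kSelf = 1e-7` was set so that, for
a log-normal abundance universe, a minority (roughly one pair in seven)
of random same-compartment pairs rises above the default detection limit
— background common enough to matter, rare enough not to swamp the
screen. It is a qualitative calibration: the dose–response of fragment
self-association is not quantified anywhere we could anchor it.

Not emulated: spatial within-plate gradients (edge effects), colony-size
carryover, substrate depletion kinetics, or any correlation between
abundance and interaction strength. Tests passing on this generator
therefore demonstrate correctness of the *analysis* under its stated
assumptions, not robustness of the assay to artifacts the model lacks.

## Numerical choices and degenerate inputs

* Censored values sit at the detection floor; flags are monotone (raising
  the floor never unflags a well).
* The epsilon clamp (`1e-3`) keeps background-subtracted values positive
  so the log2 transform is total.
* Welch p-values with zero variance on both sides return 1 for equal
  means, 0 otherwise; fewer than two replicates return NA.
* Clustering (`clusterProfiles`) is agglomerative with average linkage on
  Euclidean distances, missing fold changes imputed to 0 (no change) and
  flagged; dendrograms are exported as Newick via `ape`.
* All simulation draws come from one RNG stream seeded from the design;
  identical designs give bitwise-identical screens.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on generated
data: a 241-pair reference screen (35 interacting + 206 random pairs, 4
replicates) and two-bait systematic screens of 2,000 preys with 30
planted interactions spanning three orders of prey abundance, 3
replicates — sizes chosen to match the structure of real arrayed screens
while keeping a full run in minutes on one core. The
ratiometric-versus-intensity comparison repeats the 2,000-prey screen
over 100 seeds and asks the ratiometric AUPR to beat raw intensity in at
least 95 of them.

## Limitations

The package analyzes well-format screens with explicit blank wells; it
does not model colony arrays before pinning, nor vendor-binary reader
exports. Identifier namespaces are taken as given (no ortholog or alias
mapping). The significance gate assumes replicate-level, approximately
log-normal noise; systematic per-well artifacts would violate it.
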