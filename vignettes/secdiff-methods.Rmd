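---
title: "Differential SEC-MS analysis with secdiff: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential SEC-MS analysis with secdiff: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secdiff)
library(data.table)
```

## The measurement and the question

In cofractionation mass spectrometry (CoFrac-MS), a native cell extract is
separated by size-exclusion chromatography (SEC) into consecutive fractions,
and each fraction is quantified by bottom-up proteomics. A protein engaged in
a stable assembly elutes earlier (at higher apparent molecular weight) than
its monomer, so the elution profile of its peptides across fractions encodes
its assembly state. When the same experiment is run across several biological
conditions with replicates, three questions become statistically addressable:

1. **Global mass state** — has the balance between a protein's assembled and
   monomeric pools changed between conditions?
2. **Distinct assembly states** — which resolved coelution peak groups
   ("features") of a protein change in intensity, and is a change a
   redistribution between states (rewiring) or a plain expression change?
3. **Complexes** — do features matching prior complex hypotheses (CORUM
   entries, clusters of a scored PPI network) change as a unit?

`secdiff` implements this analysis chain for long-format peptide-level
intensity tables, with a seeded synthetic-data generator providing ground
truth for every statistical claim the package makes.

## Fraction calibration

SEC fraction number and apparent molecular weight follow a log-linear law.
Protein standards of known MW define an unweighted ordinary least-squares fit

$$\log_{10}(\mathrm{MW\ [kDa]}) = a \cdot f + b, \qquad a < 0 .$$

The fitting procedure is a package choice; the standards table decides which
x-coordinate (fraction midpoint or start) the user considers meaningful, and
the fit is agnostic to that. `mw_to_fraction()` may return fractional,
off-grid values; clamping to the measured grid happens only where a cutoff is
needed.

## Preprocessing

* **Imputation** (`impute_internal_gaps()`): only missing cells whose two
  immediate neighbours are measured are eligible, and are filled from a cubic
  interpolating spline (the standard smooth interpolant; the eligibility rule
  is the substantive constraint) fitted per peptide and sample, floored at
  zero. Traces with fewer than four measured points fall back to linear
  interpolation. Raw zeros on input are treated as *missing*, not as signal:
  downstream rules must distinguish "not detected" from a measured zero.
* **Normalization** (`cyclic_loess_normalize()`): repeated pairwise MA-plot
  loess correction on log2 intensities over the peptide-by-fraction cells
  measured in both samples of each pair, half of the fitted deviation
  subtracted from one sample and added to the other; three cycles with span
  0.7, the long-standing defaults of this normalization family. Samples
  sharing fewer than 100 measured cells with every other sample pass through
  unnormalized with a warning.
* **Filtering** (`filter_peptides()`), in order: (1) a peptide needs at
  least three *consecutive* detections in some single sample; (2) its best
  sibling-peptide Pearson correlation must reach 0.5 and (3) its mean
  sibling correlation 0.2, computed on full-grid traces concatenated across
  all samples with missing cells as 0 (a peptide absent where its siblings
  elute should be penalized, which NA-skipping correlations would not do);
  proteins retaining fewer than two peptides are removed. The correlations
  are computed after normalization, consistent with filtering the experiment
  as a whole.
* **Protein quantification** (`quantify_proteins()`): the two most intense
  peptides (by grand total over all samples), *the same two in every
  sample*, are summed fractionwise. Ties are broken by lexicographic peptide
  id so that runs are reproducible.

## Coelution feature detection

Feature finding runs on traces **integrated across all samples**, so that
boundaries are shared by every condition and the differential step compares
like with like. The detector is a deterministic reconstruction of
protein-centric peak-group picking:

1. smooth each member trace with a centred moving average
   (`smoothing_length = 7`);
2. slide a window (`window_size = 7`) and compute the mean pairwise Pearson
   correlation of the members inside it;
3. contiguous stretches with correlation at or above `corr_cutoff = 0.9`
   seed candidate regions;
4. apexes are peaks of the summed smoothed trace inside a region; peaks
   within `rt_height = 1` fraction of a higher peak merge into it;
5. boundaries extend from each apex to the nearest local minima of the
   summed smoothed trace (or the region edge);
6. the coelution score is recomputed on the *unsmoothed* traces inside the
   boundaries, greedily dropping the member least correlated with the rest
   until the score reaches the cutoff or fewer than two members remain.

The `perturb_cutoff` parameter is recorded in the parameter object for
provenance but has no effect on scoring in this implementation; decoy
scoring relies on random member reassignment alone. Smoothing uses partial
windows at the grid edges, which is why translation equivariance is only
exact away from the edges (and is tested there).

**Error control** is target–decoy: decoy "proteins" are assembled by drawing,
per target, the same number of peptides from that many distinct other
proteins; decoy complex queries are random protein sets whose member pairs
are at least `min_edge_distance = 3` apart in the supplied PPI graph (or
share no target complex when no graph is given). At score threshold $s$,

$$\widehat{\mathrm{FDR}}(s) = \frac{\#\{\text{decoys} \ge s\}}{\#\{\text{targets} \ge s\}},$$

and a feature's q-value is the minimum estimate over thresholds at or below
its own score. Complex features rank lexicographically by (completeness,
score), so that the most complete feature of each query drives acceptance.
If no decoy query produces any feature, the empirical null has no mass and
all target primaries receive q = 0 — a legitimate outcome on very clean
data rather than an error.

## Assembled mass fraction (AMF)

For a protein with monomeric weight $M$, the cutoff fraction is
`mw_to_fraction(cal, 2 M)`, clamped to the grid; fractions strictly earlier
than the cutoff are the assembled range (the tie rule at the exact cutoff is
a package convention — a peak *at* twice the monomer weight is compatible
with a dimer but also with an extended monomer, so it is counted as
monomeric). Then per sample

$$\mathrm{AMF} = \frac{\sum_{f < \mathrm{cutoff}} I_f}{\sum_f I_f} \in [0, 1],$$

using all fractions with no peak extraction. The condition effect is the
difference of condition means, $\Delta\mathrm{AMF} = \overline{\mathrm{AMF}}_A -
\overline{\mathrm{AMF}}_B$.

### Beta-regression likelihood-ratio test

AMF and FMF values are bounded proportions: a t test's normality assumption
fails near the boundaries. Values are first shrunk away from {0, 1} with

$$y' = \frac{y\,(n-1) + 0.5}{n}$$

($n$ = number of samples in the comparison), then modelled as
$y' \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with $\mathrm{logit}(\mu)$
linear in condition and a constant precision $\phi$. Both the full and the
intercept-only model are fitted by maximum likelihood (multi-start
quasi-Newton on $(\beta, \log\phi)$, with $\log\phi$ bounded in $[-10, 25]$
so that noiseless, zero-variance groups drive the statistic to a finite,
decisive value instead of a numerical overflow), and compared by a
likelihood-ratio test against $\chi^2_1$. Degenerate inputs with all
responses equal report p = 1 with a convergence flag rather than failing,
keeping the pipeline total.

**Known limitation.** The $\chi^2$ reference distribution is asymptotic. At
the very small replicate numbers typical of CoFrac-MS (3 vs 3), the test is
measurably anticonservative: in the package's own null simulations the
rejection rate at $\alpha = 0.05$ is about 0.12–0.14 (the package's
implementation and an independent maximum-likelihood fit agree on the
likelihoods to eight decimals, so this is a property of the method, not of
the optimizer). Calibration is restored in the asymptotic regime — at
15 vs 15 the measured rate is 0.048 with uniform p-values — which is what
the unit suite asserts. In practice the effect-size gate (below) dominates
the error rate of the final calls: on 1000-protein null-laden cohorts the
false call rate of the combined rule is ~0.

A protein is called significant only when **both** |ΔAMF| ≥ `min_diff`
(default 0.3, with 0.25 a common exploratory value exposed as the same
argument) **and** the Benjamini–Hochberg adjusted p ≤ 0.05.

## Feature-level, global and FMF differential testing

Within a feature's boundaries (or the whole gradient for the global test),
missing member cells are imputed uniformly on $(0, \text{member's minimum
detected intensity})$ — absence contributes a value below anything actually
measured — then per-member, per-sample sums are compared by a two-sided
Welch t test on replicate sums (a paired per-fraction t test when a
condition has a single replicate). The member log2 fold-change is
$\log_2(\bar{x}_A/\bar{x}_B)$.

The **FMF** (feature-specific mass fraction) of a member is the detected
signal inside the feature range over its total detected signal, per sample;
its condition difference is tested with the same beta-regression machinery
as the AMF. A protein whose FMF changes while its global intensity does not
has redistributed mass between assembly states — rewiring invisible to
conventional abundance proteomics.

**Aggregation to the parent** (peptides → protein, proteins → complex)
follows the order-statistic rule: the parent fold-change is the member
median; members whose sign opposes the parent median have p replaced by
1 − p (ties in sign count as concordant); the parent p is the
$\mathrm{Beta}(j, m - j + 1)$ CDF at the $j$-th smallest adjusted p with
$j = \lceil m/2 \rceil$ — the exact null distribution of that order
statistic for $m$ independent uniforms, so parent p-values are uniform
under the member-level null (verified by simulation in the suite). With
$m = 1$ the parent p is the member p exactly.

Significance thresholds are |log2FC| ≥ 1 with BH-adjusted p ≤ 0.05 for
intensity tests, and |ΔFMF| ≥ 0.3 with BH-adjusted p ≤ 0.05 for FMF.

## Complex-centric analysis

Complex hypotheses arrive as files (their construction from STRING/CORUM is
deliberately out of scope; any query set works). Per query, features found
over the subunit protein traces are first screened for **molecular-weight
plausibility**: the apex MW must exceed twice the heaviest subunit's
monomeric MW, otherwise the peak is compatible with free monomers. The most
complete feature per query (ties: higher score, then earlier apex) is its
primary; q-values are estimated across primaries against decoy primaries;
queries passing q ≤ 0.05 re-attach their remaining features with score
≥ 0.7 as secondary features (subcomplexes, variants).

Because overlapping queries find near-identical features, features whose
apexes lie within `distance_cutoff = 1.25` fractions *and* whose subunit
sets overlap (Jaccard > 0 — the minimal reading of "same composition and
position") are grouped by single linkage and represented by the largest
(then best-scoring) member. Collapsing is idempotent. The collapse
`rt_height = 0` means no extra peak-merge tolerance beyond the apex
distance.

Complex differential testing runs the peptide-level machinery inside the
complex feature range, aggregates peptides → protein and then proteins →
complex with the same order-statistic rule, and adjusts across complexes.

## The synthetic generator

`simulate_secms()` emulates exactly the structure the analysis assumes:
Gaussian elution peaks (σ = 1.5 fractions) positioned through the
calibration at the monomer MW and at the complex MW (set to
max(4 × heaviest subunit, sum of subunits), which keeps the assembled peak
well clear of every subunit's 2×MMW cutoff); per-condition assembled
fractions and abundance folds; peptide response factors drawn lognormal
(σ = 0.5) once per peptide so that sibling correlations are high, as the
filters assume; multiplicative lognormal cell noise (CV 0.1 by default,
matching the low replicate CVs of a well-behaved experiment);
intensity-dependent dropout, logistic in −log2(intensity) — low-abundance
cells vanish first, which is the realistic missingness mechanism for
intensity-dependent detection; and a hard detection floor. Defaults are
3 conditions × 3 replicates on 49 fractions.

What the generator does **not** emulate: retention-time drift between runs,
interference/co-fragmentation structure, heteroscedastic fraction-dependent
noise, shared (non-proteotypic) peptides, and partially overlapping
assembly states. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real chromatography; on real data the preprocessing steps carry
correspondingly more weight.

Ground truth records design AMF values, true apex positions, fold changes
and planted effect lists; the same seed reproduces the dataset bit for bit.

## Numerical choices and degenerate inputs

* Correlation of zero-variance trace pairs is undefined; it counts as 0
  inside window scoring (conservative) and fails the sibling filter.
* Welch t tests on two constant groups return p = 1 (flagged), which keeps
  noiseless fixtures total; the effect-size gate still reports their fold
  change.
* Peptide ranking, decoy assembly and differential imputation are seeded;
  all seeds are arguments, never global state (`with_seed` restores the
  caller's RNG).
* BH adjustment is `stats::p.adjust(method = "BH")`; order-statistic
  aggregation uses `stats::pbeta`. Re-deriving either would only add
  defect surface.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script validate on: 1000-protein
two-condition cohorts with 50 planted AMF shifts of 0.4; twenty seeds of
12-complex datasets with planted 4-fold changes at 10% CV; ten seeds of
50 planted + 450 null complex queries for FDR control; and a noiseless
9-protein round trip for apex recovery and the rewiring/expression
separation. These sizes make every claim recomputable on a laptop in
minutes while leaving the per-protein statistics at the paper-scale
replicate structure (3 vs 3).
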