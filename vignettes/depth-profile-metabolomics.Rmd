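---
title: "Region-discriminative metabolomics from SIMS depth profiles: methods and design"
author: "simsMetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-discriminative metabolomics from SIMS depth profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simsMetab)
```

# The experiment this package models

An OrbiSIMS depth profile is the sum of repeated sputter–analyse cycles at
one site of a tissue section: a single high-mass-accuracy peak list
(negative mode, m/z 75–1125, here a sum of 80 scans per profile). Profiling
several sites in each histological region of a tumour section — necrotic,
viable and non-cancerous — for several patients yields a small cohort in
which region-level metabolic differences can be tested. This vignette
documents the statistical procedure, the choices made where the design was
genuinely open, and what the synthetic benchmark does and does not
demonstrate.

# Preprocessing

The chain is fixed and logged on the object (`transformLog()`), in this
order: peak selection → alignment → missing-value filtering → imputation →
background removal → TIC normalization → Pareto scaling. Each step refuses
to run out of order on a matrix produced by the package's own alignment;
externally supplied matrices may run any single step.

**Peak selection.** Peaks below a fraction of the base-peak intensity are
discarded; the default `thresholdFraction = 0.001` (0.1%) mirrors the
automatic peak picking used on the instrument software's exports.

**Alignment** (`windowPpm = 5`). No consensus algorithm exists for aligning
sparse high-resolution peak lists; the package pools all peaks from all
spectra, sorts by m/z and sweeps once left-to-right, starting a new feature
when a peak's distance to the running intensity-weighted centroid of the
current cluster exceeds the window. A final merge pass joins adjacent
clusters whose centroids fall within the window, so the emitted centroids
are always separated by more than `windowPpm`. The sweep is deterministic
and O(n log n). When one sample contributes several peaks to a cluster they
are summed (the maximum would be defensible too; sum is the default because
the profile itself is already a sum of scans).

**Missing-value filtering** (`maxMissingFraction = 0.20`). "More than 20%"
is strict: a feature missing in exactly 20% of samples is retained.
Missing means *not detected* — the matrix stores `NA`, never zero, and the
serialized CSV uses empty fields.

**knn imputation** (`k = 5`). Donors are *samples* (replicate profiles of
the same region are the natural donors), compared by Euclidean distance
over jointly observed, per-feature standardized values, normalized by the
number of jointly observed features so pairs with different overlap are
comparable. Ties break by sample order; when fewer than k donors observe a
feature, all of them are used. Observed cells are never modified.

**Normalization and scaling.** TIC normalization divides each sample by its
total (rows sum to 1, idempotent). Pareto scaling centres each feature and
divides by the square root of its standard deviation (n−1 denominator
throughout), the usual compromise for intensity data spanning decades:
after scaling a feature's variance equals its pre-scaling sd. Constant
features are set to zero with a warning rather than dropped, so feature
indices remain aligned with annotation results. A second Pareto application
is refused via the transform log. The background-peak list is an optional
user-supplied m/z blacklist (default empty): instrument- and
embedding-specific contaminants are not knowable by the package.

# Multivariate models

**PCA** is the SVD of the centred matrix. Its Q² uses 7-fold venetian-blind
row exclusion with reconstruction PRESS — a choice the package makes
explicitly because no single convention exists for PCA cross-validation;
it is reported for orientation, not inference.

**OPLS-DA** follows the orthogonal-signal-corrected NIPALS formulation:
with w the PLS weight from the class dummy, each orthogonal component has
weight w_o ∝ p − (wᵀp)w, score t_o = Xw_o and loading p_o, and is deflated
from X; the single predictive component is then fitted on the filtered
matrix. Two consequences are exact and tested: the filtered matrix retains
no variation along any w_o, and t ⟂ t_o. With zero orthogonal components
the fit reduces to one-component NIPALS PLS1, which is the test oracle.
The class is encoded as a centred ±1 dummy with the decision threshold at
0. One orthogonal component is the default; up to 3 are supported.

**Cross-validation.** Q² for OPLS-DA is leave-one-out: the model —
including the centring statistics — is refit without the held-out sample.
TIC normalization is per-sample and cannot leak across folds; alignment,
imputation and the Pareto variance estimates are performed once upstream,
which is a known, documented source of mild optimism accepted here because
the alternative (re-aligning per fold) changes the feature space between
folds and makes Q² incomparable.

**VIP and S-plot.** With a single predictive component,
VIP_j = √J·|w_j|/‖w‖, so mean VIP² = 1 exactly — the familiar "VIP ≥ 1"
cut asks whether a feature carries more than the average share of the
predictive weight. The S-plot pairs cov(t, x_j) (magnitude) with
corr(t, x_j) (reliability) against the *original* centred data;
zero-variance features report correlation 0 with a warning.

**Permutation test.** Class labels are permuted `nPermutations` times
(default 999; 99 in the bundled pipeline config to keep runs short) and the
leave-one-out Q² recomputed each time;
p = (1 + #\{Q²_perm ≥ Q²_obs\}) / (n + 1), seeded and reproducible.

# Univariate statistics and selection predicates

Tests run on TIC-normalized (not Pareto-scaled) intensities: pooled-variance
Student's t (Welch behind a flag), two-sided, with Benjamini–Hochberg
q-values. Two predicates are exposed:

* *discriminative*: VIP ≥ 1 **and** q < 0.05 (the FDR-adjusted value, since
  the selection is applied across hundreds of features);
* *ubiquitous*: VIP ≥ 1 **and** p > 0.05 — a feature that matters to the
  model yet shows no significant two-region difference.

The ubiquitous predicate is internally surprising (high VIP with a
non-significant test usually reflects within-class structure picked up by
the orthogonal component); because the intent could equally have been
VIP < 1, `selectUbiquitous(..., highVip = FALSE)` provides the alternative
reading. The default follows the high-VIP form; the package does not guess
intent.

# Annotation and pathway coverage

Monoisotopic masses are sums of most-abundant-isotope atomic masses
(7-decimal values from the IUPAC/CIAAW tables, hard-coded). Deprotonation
subtracts the proton mass 1.0072765 Da — not a hydrogen atom — so
[M−H]⁻ = M − 1.0072765 and [M−H₂O−H]⁻ = M − 19.0178411. This convention,
and only this one, reproduces published negative-ion m/z values for
reference metabolites (indole 116.0506, phenylethanolamine water-loss
118.0662, phosphate 96.9696) at the printed precision.

Matching is a pure ppm-window query: every (compound, adduct) candidate
within `tolerancePpm` (default 5) of a feature centroid is reported with
its signed error, sorted by |ppm|; no arbitration is attempted because
accurate mass alone (level-3 identification) cannot distinguish isomers —
the bundled library deliberately contains isomer groups (leucine/isoleucine,
the hexoses) so downstream code must cope with multiplicity.

Pathway mapping works on *neutral* monoisotopic masses (convert observed
m/z with `neutralMass()` first) at a 2 ppm default against bundled
miniature membership tables (tryptophan, arginine/proline, tyrosine,
histidine metabolism). Coverage is simply matched members / members; no
topology or enrichment statistic is computed, and absolute coverage values
depend entirely on the pathway table used.

# The synthetic cohort generator

The generator is the package's test bed and reproduces the study design it
emulates: 4 patients × 3 regions × 5 sites, 80 scans, m/z 75–1125,
negative mode, 5 ppm-resolvable features. Where the design was open the
following were chosen once, on field-typical grounds:

* **Intensities** are log-normal: region effects act additively on the log
  scale, matching the positivity of ion counts and the variance structure
  Pareto scaling expects. Site noise has `intensityCv = 0.3`
  (sd(log) ≈ 0.29); a per-patient random effect (`patientSd = 0.2`) makes
  replicate sites within a patient correlated. The between-site versus
  between-patient variance ratio is deliberately a parameter, not a fixed
  constant.
* **Spiked effects** are calibrated in Cohen's d units on log-intensity:
  the shifted region differs from the rest by
  `effectSize × sqrt(sd_log² + patientSd²)`, so the *empirical*
  standardized difference converges to `effectSize` (tested at 50
  sites/region within 3 standard errors). With two regions there is one
  contrast; with k > 2, one-vs-rest per region.
* **Spiked abundance**: background compounds draw base abundance
  log-uniformly over three decades; spiked compounds draw from the top
  decade. A recovery benchmark must spike detectably — discriminative ions
  in real data are prominent ions — otherwise it measures the missing-value
  filter, not the model.
* **Mass error** is Gaussian per peak (`massJitterPpm = 1`, typical for an
  orbital-trap analyzer after calibration).
* **Missingness** is detection-limited by default: mask probability follows
  a logistic in standardized log-intensity (slope 1.5) with the intercept
  solved numerically so the marginal rate equals `missingRate`; a
  completely-at-random mechanism is available to test imputation under both.
* **Features** are theoretical adduct m/z values of library compounds
  (adduct drawn 0.7/0.3 for [M−H]⁻/[M−H₂O−H]⁻), greedily thinned to ≥15 ppm
  separation so alignment at 5 ppm is well-posed.

What the generator does **not** emulate: peak shape and centroiding,
isotope envelopes, matrix effects, detector saturation or dead-time,
chemical background, or real between-patient biology. Passing tests
therefore demonstrate the pipeline's statistical behaviour under its own
assumptions — calibrated effects in, calibrated recovery out — not
performance on real depth profiles.

# Numerical choices and degenerate inputs

* Standard deviations use the n−1 denominator everywhere.
* Duplicate m/z rows in a peak list are summed on ingestion; spectra are
  strictly increasing in m/z by construction.
* Zero-total samples abort TIC normalization with the sample named;
  constant features Pareto-scale to zero with a warning; zero pooled
  variance yields t = 0, p = 1 with a warning; zero-variance features get
  S-plot correlation 0.
* Feature matrices serialize at full double precision (`%.17g`), so
  write–read is a fixed point; display rounding happens only in reports.
* All cohort and permutation randomness is seeded; the pipeline derives
  per-stage seeds from the global seed so stages are independently
  reproducible.

# Problem sizes

The test suite and the acceptance script run two-class cohorts of 40
samples × 200 generated features (the study-design scale), 50 sites/region
for calibration checks, and permutation counts of 19–99; these sizes give
stable pass/fail behaviour for every property tested while keeping a full
run inside a few minutes on a laptop core. Users analysing larger cohorts
only pay in the leave-one-out and permutation loops, both linear in samples
× fits.

# Known limitations

* Patient is not modelled as a random effect in the univariate tests;
  sites are treated as exchangeable replicates within region. With N = 4
  patients a mixed model would be poorly identified, but the resulting
  pseudo-replication optimism should be kept in mind.
* One predictive component only (two-class OPLS-DA); no multi-class
  extension, no O2PLS.
* Level-3 annotation is by accurate mass only; identification confidence
  requires orthogonal MS/MS evidence outside this package's scope.
* Pathway coverage is descriptive, not inferential.
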