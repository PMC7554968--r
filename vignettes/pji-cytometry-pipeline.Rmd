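---
title: "Immune profiling of periprosthetic joint aspirates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune profiling of periprosthetic joint aspirates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Distinguishing septic from aseptic loosening of a hip or knee prosthesis
(periprosthetic joint infection, PJI) is clinically hard: cultures are slow
and often falsely negative, and the established MSIS rule set needs inputs
(histopathology, repeated cultures) that are frequently unavailable when a
decision must be made. `pjiFlow` implements a flow-cytometric alternative:
the immune cell composition of the aspirated joint fluid itself is used as
the diagnostic signal. The package covers the complete chain from raw
event-level cytometry data to a cross-validated infection classifier, and
ships a synthetic cohort generator so that every stage can be exercised and
validated with known ground truth.

# Hierarchical gating

Each aspirate sample is an event table: one row per acquired particle,
columns for four scatter channels and fourteen fluorescence channels
(viability dye, CD45, CD66b, CD16, CD3, CD19, CD56, CD4, CD8, CD14, HLA-DR,
CD11b, CD123, CD11c). Gating proceeds down a fixed tree:

1. **Pre-gates (QC):** debris and doublets are excluded on FSC-A/FSC-H and
   FSC-W/SSC-A, dead cells by the viability dye. A sample enters the
   analysis only if at least 400 single, living cells survive; the bound is
   inclusive (exactly 400 is accepted) by plain reading of the rule. The
   count is taken after the viability/singlet gates and before CD45
   selection.
2. **Leucocytes:** CD45+ events.
3. **Granulocytes:** CD66b splits the leucocytes; CD16 separates
   neutrophils (CD16+) from eosinophils (CD16-).
4. **Lymphoid branch:** CD3/CD19 separates T from B cells; the CD3+ gate is
   cleaned on side scatter; CD56 marks NKT cells; CD4/CD8 resolve T helper
   and T killer cells.
5. **Boolean pool:** the CD3- CD19- events and the events rejected by the
   SSC clean-up are pooled; CD56/CD14 yield NK cells and the monocytic
   branch; HLA-DR and CD16/CD11b split monocytes from monocytic
   myeloid-derived suppressor cells (mMDSCs, CD14+ HLA-DR- CD16+ CD11b+);
   HLA-DR/CD123 resolve basophils from dendritic-cell candidates, and CD11c
   separates myeloid from plasmacytoid DCs (reported as one combined DC
   type).

Unlike interactive gating software, in which batched gates receive manual
per-sample correction, the engine is fully declarative: every gate is a 1-D
threshold, a 2-D rectangle, or a Boolean combination of earlier gates, and
the whole tree serialises to JSON (`writeGateTree()`). We chose
reproducibility over fidelity to hand gating; the cost is that thresholds
must suit the data at hand. Defaults place every fluorescence threshold at
2.5 on the arcsinh scale, midway between the synthetic generator's negative
(1.0) and positive (4.0) population locations.

All fluorescence gating happens on `asinh(x / cofactor)` with cofactor 150
(configurable), the standard transform for conventional cytometers: linear
near zero, logarithmic for bright signals, so both negative and positive
populations are approximately Gaussian and threshold gates are well-posed.
Scatter channels stay on the acquisition scale.

Three invariants are enforced and tested: leaf gates are mutually disjoint,
so leaf counts plus the unassigned remainder partition the live singlets
exactly; every child count is bounded by its parent; and raising a
positivity threshold can only shrink the population at and below it.
Events that fail every leaf (for example CD4-CD8- conventional T cells or
HLA-DR+ CD11c- CD123- cells) stay unassigned: they are excluded from
numerators but never from denominators.

# Normalised proportions

Because the absolute cell yield varies enormously between samples, all
analysis uses ratios, in three families:

* `CD45.*` - each of the eleven leaf types over the CD45+ count;
* `NonGran.*` - each non-granulocytic subtype (including the combined CD3+
  population) over the CD66b- count;
* `Gran.*` - neutrophils, eosinophils and basophils over the granulocyte
  denominator.

Basophils are gated in the CD66b- branch (they are CD66b-low) yet belong
biologically with the granulocytes, and the granulocytic family reports
them against total granulocytes; we therefore define the granulocyte
denominator as the CD66b+ count plus the basophil count. This matches the
denominator naming of the granulocyte-family reporting and keeps the three
granulocytic ratios summing to at most one.

The optional 24th ratio, `CD45.nonGranulocyte`, is the fraction of
non-granulocytes among leucocytes. It is kept out of the default model
covariates: total granulocyte infiltration is essentially the clinical
PMN% and sits inside the MSIS definition of the response, so including it
moves the model toward circularity. `addNonGranulocytePredictor()` appends
it explicitly for the benchmark comparison.

Zero denominators produce `NA` ratios (flagged, never infinite), and
statistics drop missing values pairwise.

# The MSIS rule engine

The modified MSIS classification is a pure decision rule over a clinical
record: infected if at least one major criterion fires (joint-communicating
sinus tract; double-positive cultures with the same pathogen) or at least
three of five minors fire (synovial WBC > 3000/uL; synovial PMN% > 80;
serum CRP > 10 mg/L; a single positive culture or PCR; Morawietz grade
II/III histopathology). Decisions embedded in the implementation:

* thresholds are strict inequalities (WBC of exactly 3000/uL does not
  fire), following the printed `>` notation;
* missing fields never fire a criterion, so missingness can only lower the
  fired count (tested as a property);
* a double-positive culture fires the major criterion only - majors and
  minors are evaluated independently and one record cannot be both
  double- and single-positive;
* Morawietz grade IV does not fire the pathology minor (the rule names
  grades II and III only);
* the intraoperative surgeon's override for borderline cases exists only
  as an explicit `override` argument, never inferred.

`msisTruthTable()` enumerates all 2^7 = 128 fired/not-fired combinations
and is used as an exhaustive oracle; among the 32 all-major-negative
patterns exactly C(5,3)+C(5,4)+C(5,5) = 16 are infected.

# Group statistics, ROC and Youden ranking

Between-group comparison of each ratio uses the two-sided Mann-Whitney U
test: exact enumeration when the combined sample size is at most 20 with no
ties, otherwise the tie- and continuity-corrected normal approximation
(both modes are available explicitly, since either could be the convention
of a given analysis environment). Significance tiers are `*` p<0.05, `**`
p<0.01, `***` p<0.001, `****` p<0.0001. Tiers are reported per ratio
without multiple-testing correction, matching the per-ratio presentation
convention; a Benjamini-Hochberg column is emitted alongside so readers can
judge the family-wise picture.

Marker ranking follows the published procedure: one ROC curve per
significant non-granulocytic ratio, oriented by the observed group medians
(the orientation is recorded in the output, since a ratio such as the
mMDSC fraction runs higher in infection while NK runs lower); markers with
AUC below 0.8 are excluded; the remainder are ranked by the Youden index
J = sensitivity + specificity - 1. The AUC is computed as the concordance
probability with ties counted one half, which equals U/(n1 n2) exactly -
an identity the tests assert. Youden ties are broken toward the
higher-specificity threshold (the usual convention for diagnostic rules,
configurable in spirit by re-ranking the returned curve). Retained markers
are annotated with gating independence - whether two ratios' numerator
populations are nested in the gate tree - because only independently gated
markers make sense as joint additions to a rule set.

# The logistic infection model

The predictive model is ordinary logistic regression,
`logit p = b0 + b1 x1 + ... + bk xk`, on the nine default covariates (six
non-granulocytic subtype ratios and three granulocytic ones). The fitting
pipeline is:

1. **Univariate prescreen:** one covariate at a time; keep p < 0.25. The
   Wald p-value is used by default (configurable through the code path;
   the likelihood-ratio alternative behaves identically away from
   separation). One caveat the test suite documents deliberately: under
   complete univariate separation the Wald statistic collapses
   (Hauck-Donner effect) and a perfectly discriminating covariate can be
   screened out; real aspirate data live far from that regime.
2. **Forward-BIC selection:** greedy forward steps from the intercept-only
   model, adding at each step the covariate that lowers
   BIC = -2 log L + k log(n) the most (k counts the intercept), stopping
   when no addition lowers it. On simulated cohorts with planted strong
   effects the greedy path coincides with exhaustive all-subset BIC search,
   and under pure noise the null model wins - both properties are asserted
   at scale in the tests.
3. **Unpenalised ML fit:** IRLS to |change in deviance| < 1e-8, at most 100
   iterations. Quasi-separation is detected and flagged with a warning,
   never penalised away - the reference analysis used unpenalised `glm`,
   and the flag is part of the result object.

Covariates are raw fractions in [0,1], deliberately unstandardised: the
coefficients are then directly interpretable as log-odds per unit fraction
(which is why published coefficients of such models are large numbers).

Classification uses a strict `p > cutoff` rule (a probability exactly at
the cut-off is non-infected); the default operating point 0.5185 reflects
a calibrated borderline-case analysis, with 0.5 and 0.8 reported
alongside.

**Leave-one-sample-out cross-validation** repeats prescreen *and* forward
selection on every n-1 subset and predicts the held-out patient from the
resulting (possibly different) model. The held-out label is read only at
scoring time; the test suite proves this by poisoning: flipping a held-out
label leaves its predicted probability bit-identical.

# Classifier benchmark

`nestedCvMmce()` estimates the mean misclassification error (mmce) of five
classifier families - radial SVM, decision tree, LDA, random forest, and a
deviance-pruned classification tree - under nested 10x10 cross-validation:
the inner loop picks each classifier's hyperparameter row by inner-CV mmce,
the tuned model is refit on the outer training split and scored once on the
outer test fold. Outer folds are stratified by class (with 17 infected of
50, unstratified folds would regularly lose a class). Tuning grids are
small and fully explicit in `defaultClassifiers()` rather than inherited
from any framework's internal defaults, which are version-dependent. The
fifth family is a surrogate: no conditional-inference-tree implementation
is part of the package's dependency set, and a pruned classification tree
covers the same model class (axis-aligned recursive partitions) with an
explicit complexity control. Fold assignments are a deterministic function
of the seed, and a poisoning test (flipping outer-test labels with folds
held fixed) verifies that tuning decisions cannot see outer-test data.

# The synthetic cohort generator

Because no patient-level aspirate data are publicly deposited, the
generator is a first-class module, not a test fixture. It emulates:

* **Event-level structure:** each sample is a mixture over the eleven cell
  types; marker intensities are Gaussian on the arcsinh scale with
  location 4.0 for expressed markers, 1.0 otherwise, spread 0.35; debris
  has low scatter, dead cells carry a high viability-dye signal, doublets
  are sums of two live events' scatter (with height set by the larger
  cell) so the pre-gates act nontrivially. Every event keeps its true
  category as a hidden label - the oracle for all gating checks.
* **Cohort structure:** 17 infected and 33 non-infected patients by
  default. Per-patient compositions are Dirichlet draws around group means
  with concentration 60 (a moderate, realistic between-patient spread).
  The group mean compositions are package defaults chosen once: infection
  raises the neutrophil fraction (0.30 to 0.70 of CD45+) and the mMDSC
  fraction, and depresses T, NK and NKT fractions, matching the direction
  of the reported population shifts; the magnitudes are free parameters
  because no numeric per-group proportion table exists to anchor them.
* **Clinical records:** synovial WBC and serum CRP are log-normal with
  arithmetic group means 89,322.8 vs 669.1 cells/uL and 111.4 vs 17.2
  mg/L; PMN% is truncated-normal on [0,100] with means 81.0 vs 28.5;
  sinus-tract, microbiology, pathology and missingness rates follow the
  reported per-group counts. By default the MSIS label agrees with the
  generating group for every patient (`concordance = 1`); the enforcement
  adjusts only categorical fields or PMN/CRP draws and never touches the
  WBC draw, so the configured WBC group mean is preserved exactly - a
  law-of-large-numbers test asserts this.

What the generator does **not** emulate - and hence what passing tests do
not show about real data: spectral spillover and compensation artefacts,
batch effects between acquisition days, heavy-tailed or skewed marker
distributions, population-location drift that manual gating would correct,
blood contamination from intraoperative sampling, and continuous phenotype
gradients (every synthetic cell belongs cleanly to one type). The default
synthetic cohort is consequently close to separable: classifier error
rates near zero on it validate the machinery (no leakage, correct
bookkeeping), not clinical performance. Conclusions about real aspirates
must come from real aspirates.

# Numerical choices and degenerate inputs

* Arcsinh cofactor 150 everywhere, recorded on objects and in serialised
  trees.
* Exact Mann-Whitney enumeration switches to the corrected normal
  approximation above combined n = 20 or in the presence of ties; constant
  combined data returns p = 1.
* ROC thresholds are midpoints between distinct scores plus both
  infinities; AUC by pair concordance (ties half).
* GLM convergence: deviance tolerance 1e-8, 100 iterations; BIC
  comparisons use a 1e-10 slack so floating-point ties cannot add a
  variable.
* Empty event tables are excluded by QC with zero survivors; zero
  totalEvents is an error; zero denominators give `NA` ratios plus a
  warning; single-class inputs to ROC or group comparison are errors.
* LOOCV folds whose training split loses a class are skipped with a
  warning; the nested benchmark refuses fold counts its cohort cannot
  stratify.

# Problem sizes used by the test suite

The suite validates gating on 50,000-event samples, the statistic oracles
on 1,000 random instances each (exact enumeration up to 10 per group),
coefficient recovery on 200 simulated cohorts of n = 500, selection
correctness on 100 strong-effect and 100 null simulations (each checked
against exhaustive all-subset BIC), LOOCV integrity on 50-patient cohorts
with 100 permutation replicates, and end-to-end determinism on two full
pipeline runs at 4,000 events per sample. These sizes were chosen so the
whole suite runs in a few minutes on one CPU while keeping every
Monte-Carlo tolerance well above its standard error.

# Known limitations

* Gate thresholds are artifact-defined constants; real data would need
  per-panel calibration or the density-valley placement to be extended
  beyond the default midpoint convention.
* The feasible truth-table check covers 96 of 128 criterion patterns: a
  single record cannot be simultaneously double- and single-culture
  positive, so those 32 combinations are verified against the abstract
  rule only.
* Basophil-in-granulocyte-denominator is a reporting convention; other
  groups divide by CD66b+ only. The choice is localised in
  `granulocyteDenominator()`.
* The package deliberately does not model compensation/spillover, polygon
  or ellipse gates, cluster-based auto-gating, or batch normalisation
  across samples.
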