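---
title: "Methods and design notes for olivemet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for olivemet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivemet)
```

# Scope and data model

`olivemet` operates downstream of peak picking: its inputs are per-sample
feature tables (m/z, retention time in seconds, one intensity column per
sample, one table per ionization mode) and MS² peak lists in MGF form.
Raw-file conversion and chromatographic peak detection are upstream-tool
territory and deliberately out of scope, as are live spectral-database
queries: the library-match evidence used for confidence levels refers to
packaged, checksummed reference tables, so nothing in the package ever
downloads.

Retention times are seconds everywhere; concentrations are mg/L on
calibration curves, mg/g in products, and mg/day after dose conversion.

# The mass calculus

All annotation rests on exact monoisotopic arithmetic. Atomic masses are
IUPAC monoisotopic values to at least six decimals; the proton is
1.00727646 Da and the electron mass (0.00054858 Da) is included in the
mass delta of every charged species, which is what makes four-decimal
agreement with orbitrap-grade printed values possible. A registered
adduct with multimer count $k$, isotope shift $i$ and charge $z$ maps a
neutral mass $M$ to

$$ m/z = \frac{k\,M + i \cdot 1.003355 + \Delta}{|z|}. $$

The registry is closed: it contains exactly the bracketed species that
occur in the packaged annotation table (formate, chloride, ammonium,
sodium, potassium, dimethylammonium adducts; dimers and tetramers;
charges up to 3; first and second ¹³C isotopologues). Unknown species
are rejected rather than guessed, and the in-source-fragment search is
likewise restricted to a registered neutral-loss table (hexose, rhamnose,
H₂O, CO₂, CH₂O, CH₃OH, CO, C₂H₄O₂, the 136.0524 Da dehydrated
hydroxytyrosol moiety, caffeoyl). An open-ended loss search would
happily invent chemistry; a closed table cannot.

Printed-value comparisons use round-half-even at four decimals *and* a
5 ppm tolerance gate, the instrument's stated external-calibration
accuracy. The ppm gate is authoritative: a handful of printed observed
values differ from theory in the fourth decimal (the worst deprotonated /
protonated molecular ion in the shipped table deviates by 2.4 ppm), and
one printed potassium-acetate adduct appears to be off by ~1 Da, which we
treat as a printing artifact and exclude from invariants.

# Grouping into pseudo-spectra

Features are grouped per ionization mode when they co-elute and co-vary.
The tunables are:

* `rt_window` = **5 s**. The reference separation uses a 2.6 µm
  core-shell C18 column at 350 µL/min, giving peak widths of a few
  seconds; 5 s is common annotation practice for such gradients.
* `min_corr` = **0.8** Pearson correlation across samples, computed on
  `log10(intensity + 1)`. The log stabilizes heavy-tailed abundances;
  0.8 is strict enough to split co-eluting isomers with independent
  abundance patterns while tolerating detector noise.

The source description of this step says only "close RT" and "high
correlation"; the numeric defaults are our declared decisions, exposed in
the configuration, not facts inherited from the reference workflow.

The clustering itself is deliberately primitive and deterministic: seeds
are taken in decreasing order of maximum intensity, each feature joins
the first qualifying seed (ties by smaller ΔRT, then Δm/z), giving a
partition that is independent of input row order, idempotent on its own
output groups, and — on data whose within-group correlation is near 1 and
between-group correlation near 0 — monotone under tightening of
`min_corr`. On adversarial correlation structure the greedy assignment
cannot guarantee global monotonicity; the property is asserted on the
synthetic world where the assumption holds.

With fewer than three samples a correlation estimate is meaningless, so
the criterion is skipped with a warning and grouping degrades to an RT
window.

# Ion-role inference

Every member of a group proposes candidate neutral masses through every
base adduct; each candidate is scored by how many members it explains as
an adduct, an isotopologue, or an in-source fragment, at 5 ppm. Two
safeguards matter:

* an isotopologue is accepted only when its monoisotopic partner is
  present in the group *and more intense* — without this, the M+1 ion of
  an abundant compound can masquerade as a molecular ion;
* ties between equally-explaining hypotheses prefer the one whose
  (de)protonated ion is the group's base peak, then the smaller total
  |ppm|. This resolves the systematic dimer degeneracy: a group
  containing `[M-H]-` and `[2M-H]-` is explained equally well by a
  hypothetical compound of mass M/2 (reading the ions as `[2M'-H]-` and
  `[4M'-H]-`), but only the true M puts its molecular ion on the base
  peak.

Singleton groups are inverted through the default `[M-H]-` / `[M+H]+`
adduct and flagged, since nothing corroborates them. Hypotheses from
opposite polarities are merged when their masses agree within 5 ppm and
their RT centroids within 5 s.

# Formula enumeration and MS² classification

The formula enumerator replaces an external isotope-pattern tool with a
direct bounded search: all CHNOPS element vectors inside the user bounds
whose mass lands within the ppm tolerance, filtered by RDBE ≥ 0 and the
saturation rule H ≤ 2C + N + 2, ranked by |ppm|. Default bounds
(C ≤ 50, H ≤ 80, N ≤ 5, O ≤ 25, S ≤ 2, P ≤ 2) cover plant secondary
metabolites below ~800 Da; the grid is capped by the mass budget so the
search stays in the tens of milliseconds. Isotope-pattern scoring is
intentionally simplified away: at 4-decimal accuracy and these bounds,
accurate mass plus the plausibility filters recovers the true formula
for the entire 202-compound reference library at ≤5 ppm mass error
(asserted as a test), though generally among several candidates —
ranking, not uniqueness, is the claim.

Consensus MS² spectra are built by pooling peaks of up to three replicate
spectra, single-linkage clustering with a 0.005 Da gap, averaging
relative intensities over all input spectra (absence counts as zero),
renormalizing, and dropping fragments below 1 % relative intensity.

Class calls are rule-based. Each olive compound family is recognized by
its printed diagnostic set — e.g. hydroxytyrosol derivatives by the
−153.0557/−135.0452/−123.0452 or +155.0703/+137.0597 fragments or by a
136.0524 Da neutral loss; DEDA derivatives by the (de)protonated DEDA ion
*plus* a CO₂- or water-loss companion (`min_hits = 2`, because the DEDA
ion alone also appears in oleoside spectra). The fragment tolerance is
0.005 Da, the printing precision of the reference values, not a ppm
tolerance — diagnostic lists are transcriptions, so absolute precision is
the right model. Classification is multi-label by construction and
monotone: adding peaks can only add classes. Chemically related families
(elenolic acid within DEDA or oleoside spectra) genuinely share
fragments, so overlapping labels are expected behavior, and classifier
accuracy is defined as the planted class being *among* the returned
labels.

Confidence levels follow the Metabolomics Standards Initiative tiers:
I standard-confirmed (RT within ±5 s plus MS² agreement — the reference
RTs are printed as integer seconds), II library/literature MS² match,
III class-rule or in-silico only, IV formula only, V mass only. How
unannotated features lacking MS² split between IV and V is not fully
specified upstream; we assign IV exactly when a formula candidate exists.

# Quantification

Calibration is unweighted ordinary least squares — the reference method
states neither weighting nor an LOQ rule, so we chose the standard,
deterministic pair: the **linear dynamic range** is the widest contiguous
run of calibration levels whose back-calculated accuracy stays within
±20 %, the curve is then rebuilt on that run, and the **LOQ** is the
lowest level inside it. Back-calculation divides by the preparation
dilution (500 mg to 5 mL = 100 g/L, preferred; 2 g/L when the predicted
response leaves the LDR) and is conservatively censored: responses
mapping below the LOQ yield zero with a `below_loq` flag, non-positive
inversions yield `not_detected`.

One consequence worth knowing: with multiplicative detector noise the
unweighted fit is dominated by the top calibration level, so the slope
inherits roughly that level's relative noise. Under 5 % noise the median
slope error is ~3 % and about 96 % of fits land within 10 % — a "3 % in
95 % of runs" expectation is not achievable in this design, and our tests
assert the achievable bands plus exact agreement with an independent
`lm()` oracle on the LDR subset.

Compounds without their own standard are expressed through surrogates:
oleuropein for the secoiridoid catabolites, hydroxytyrosol for its
glucosides, verbascoside for hydroxy-verbascoside, isocitric acid for the
trihydroxyoctadecenoic acids.

# Dose assessment

Concentration ranges propagate as (lo, hi) intervals through all
arithmetic, with censored cells contributing zero — printed totals treat
unquantifiable values as absent, and this keeps totalling deterministic.
Cells of the form "LOQ–x" or "ND–x" (some replicates unquantifiable)
contribute (0, x). Pass criteria evaluate the **lower** bound: a product
passes only if even the pessimistic end of its range clears 5 mg/day.

Oleuropein counts toward the claim because it hydrolyses to
hydroxytyrosol in vivo. The reference text states no conversion factor;
we default to the molar-mass ratio 154.0630/540.1843 ≈ 0.2852 (one mole
of oleuropein yields one mole of hydroxytyrosol) and also provide the
mg-for-mg alternative. On the packaged tables the pass/fail sets are
identical under both conversions — four products pass directly and two
more with oleuropein — and that invariance is asserted as a test, so the
unknown upstream choice is immaterial here.

# Statistics

Abundance matrices are log10-transformed with an offset of 1 (abundances
are arbitrary detector units, so the offset merely guards zero), then
Pareto-scaled (mean-centered, divided by the square root of the column
standard deviation). Missing cells are imputed beforehand from a seeded
uniform draw in (0, min-positive/10) per column, emulating
"replace missing values by a random very low value" reproducibly; the
seed is exposed. PCA is SVD-based on the scaled matrix with no further
centering. Group differences use Kruskal–Wallis per feature with
Benjamini–Hochberg adjustment at 0.05, and heat-map rows are labelled by
the ordering of class medians (e.g. "F > L > B", with "=" for ties).

At the study's sample sizes (3–4 products per class) the smallest
achievable Kruskal–Wallis p-value for a single shifted class is about
0.018, so after multiplicity correction *no single feature* can be
declared significant on its own; detection requires the shift to be
pervasive across features, which is exactly the situation in these
products. Our power test therefore plants a class shift in all features
and asserts a high average detection rate, and the null test asserts the
type-I rate of the full pipeline.

The published two-component PCA variance figure (71 %) depends on
replicate-level data that were never released; we assert only the
qualitative property that replicates of a product sit closer to each
other than to other products' samples, in the full score space (the 2-D
projection of an 8-product synthetic design overlaps occasionally without
contradicting replicate clustering).

# The synthetic world

`simulate_feature_tables()` emulates the structure the pipeline assumes:
for each library compound, an ion cluster generated through the real
adduct registry, 1 ppm Gaussian mass noise (the instrument operates well
inside its 5 ppm specification), a shared retention time with 1 s
compound jitter and 0.2 s per-ion apex scatter, and log-normal abundances
(product-level geometric means with sd 1 on the log scale, 15 % replicate
scatter, 2 % per-ion residual noise) sharing one profile across all ions
of a compound. The default design is 14 products × 3 replicates, the
study layout. ¹³C abundances use the 1.1 % per-carbon rule so the
isotope-sanity constraint is physically meaningful.

What the generator does **not** emulate: chromatographic peak shapes
(grouping here sees only apex RTs and intensities, not shape
correlation), matrix effects, ion suppression, missing ions, or
between-compound intensity correlation from shared biosynthesis. A green
recovery test therefore establishes that the inference logic is correct
under the model's assumptions — not that real extracts, where those
assumptions erode, will be deciphered at 100 %.

`simulate_ms2()` plants each rule's diagnostic peaks plus decoys sampled
at least 0.02 Da away from every diagnostic value and every
precursor-minus-loss position; `simulate_calibration()` produces linear
responses with multiplicative noise. All generators flow from explicit
seeds and are byte-reproducible.

# Numerical choices, degenerate inputs, limitations

* Round-half-even (R's `round`) for all printed-precision comparisons.
* Grouping with < 3 samples: correlation skipped, warning.
* Singleton groups: default-adduct inversion, flagged.
* Empty formula: mass 0; enumeration outside bounds: empty result, not an
  error; empty MS² spectrum: kept with a warning, classifies to nothing.
* Constant columns Pareto-scale to zero rather than NaN.
* Fixtures are verified against MD5 checksums at load; a mismatch raises
  a dedicated condition that the CLI maps to exit code 3.
* The package consumes feature tables; it does not validate that a
  table's polarity flag matches how the data were acquired.
* Level-II calls are only as good as the transcribed reference evidence;
  no live database is consulted.
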