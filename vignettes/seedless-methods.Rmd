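---
title: "Models and methods behind seedless"
author: "seedless authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedless}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedless)
```

`seedless` analyzes miRNA target sites that pair to the guide 3′ region
(nucleotide 9 onward) with little or no seed pairing. This vignette is the
package's own account of its models: the assumptions, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generators do and do not emulate, and the places where a design decision
was genuinely open.

# The site grammar

A guide is indexed 1-based from its 5′ end; the seed is positions 2–7, the
subseed 2–5, and the 3′ region starts at position 9 by default
(`minThreePStart`; registers such as m9_20 are meaningful, so 9 rather
than a more conservative 10 or 11 is the operative bound). All
complementarity is strict Watson–Crick; a `wobble` flag admits G:U for
exploration but defaults off, because every site class is defined by
perfect pairing.

* **Canonical classes** need a contiguous match covering seed positions:
  2–7 (6mer), 2–8 (7mer-m8), 3–8 (6mer-m8), or 2–6/2–7/2–8 plus an
  adenosine in the target across from guide position 1 (6mer-A1, 7mer-A1,
  8mer). The A1 adenosine is a protein contact, not a base pair, so it is
  required to be A regardless of the guide's first nucleotide. Ranking:
  8mer > 7mer-m8 > 7mer-A1 > 6mer > 6mer-m8 > 6mer-A1.
* **3′ registers** `mX_Y` are maximal contiguous matches to guide
  positions X–Y with X ≥ `minThreePStart`. Maximality is relative to the
  3′ region: a full match to g11–g22 is one m11_22 site, not a family of
  sub-registers.
* **Compound sites** `mX_Y|±k|mA_B` have the 3′ match 5′ of the seed
  match on the target (the strands are antiparallel), with signed offset
  `k = bridge − (X − B)`: the number of target nucleotides bridging the
  two matched spans minus the corresponding guide distance. Positive
  offsets bulge the target. Example: m13_20 complementarity 8 nt upstream
  of m2_7 seed pairing gives 8 − (13 − 7) = +2, serialized
  `"m13_20|+2|m2_7"`. `parseSiteName()`/`siteName()` are exact inverses
  over this grammar.

Two presets bundle the remaining thresholds (`siteConfig()`):

| parameter | `rbns` | `survey` | meaning |
|---|---|---|---|
| `minThreePLen` | 8 | 10 | shortest reportable 3′ register |
| `maxSeedRun` | 1 | 2 | longest seed run a 3′-only call tolerates |
| offset window | [−8, +16] | [−4, +6] | compound-offset search range |
| `excludeOffset6mer` | no | yes | drop 6mer-m8/6mer-A1 calls |

The `rbns` values reflect the programmed bind-n-seq library (its minimal
programmed site is the 8-nt m13_20 of miR-155) and the strict "no more
than one nucleotide of contiguous seed pairing" definition of an
autonomous 3′-only site; the `survey` values reflect the endogenous-UTR
rules (≥10 nt of 3′ complementarity; a 3–5-nt seed run at offset −4..+6
upgrades the site to 3′+microseed; offset-6mers are excluded as marginal).

**Read assignment** (`assignSites()`) returns exactly one site per read
with precedence compound > longest 3′ register > canonical rank > none.
The underlying scanner walks antiparallel diagonals in C++ (the RBNS
simulator pushes millions of candidate molecules through it). Ties at the
top rank are broken deterministically — longer 3′ segment, longer seed
segment, left-most 3′ span, left-most seed span, smaller seed start,
smaller offset — and flagged `ambiguous` rather than dropped. The
minimum seed run that can join a compound site is `maxSeedRun + 1`
(2 nt under the RBNS preset): the compound and 3′-only definitions
partition the reads. The tests cross-check every rule against an
independent brute-force oracle that enumerates all guide segments by
string comparison.

# Relative Kd inference from AGO-RBNS

For input frequencies `f_j`, relative dissociation constants `κ_j`
(no-site ≡ 1) and a free-AGO scale `a_i` per bound sample (in units of
the no-site Kd), the equilibrium occupancy of site j in sample i is
`p_ij = a_i/(a_i + κ_j)` and the expected bound-read fraction is

```
g_ij = f_j p_ij / Σ_k f_k p_ik .
```

`fitRelativeKd()` maximizes the multinomial log-likelihood
`Σ_ij n_ij log g_ij` over `{log κ_j, log a_i}` with analytic gradients
(L-BFGS-B). Jointly scaling all κ and all a leaves every `g_ij`
unchanged — the model has one exact scale freedom — which is why the
no-site class is pinned at κ = 1: all reported values are *relative* Kd.

Choices a user may care about:

* `f_j` are plug-in estimates from the input sample with pseudocount 1
  (not co-fitted); a small bias is traded for stability.
* Sites with fewer than `minReads` (default 50) total bound reads are
  reported `notDetermined` and removed; the remaining classes form a
  conditional multinomial, which is statistically exact.
* Identifiability is a property of the *design*, not just the fit: a site
  with κ well below the smallest `a_i` is saturated in every sample, and
  the likelihood is flat below that point. Resolving κ ≈ 10⁻³ requires a
  free-AGO series extending to the same order, which is why the package's
  recovery experiments use a 1000-fold dilution series (a = 1 … 10⁻³),
  mirroring the wide concentration series of real bind-n-seq.
* Fits assume binding reached equilibrium; for the strongest 3′-only
  sites with very slow kinetics this assumption understates affinity, and
  no correction is applied.

`bootstrapCI()` resamples reads within each sample (multinomial over
classes), refits, and reports percentile 95% intervals; it is seeded and
drops failed replicates (at most 10%).

**Flanking-nucleotide stratification** (`stratifyByFlank()`) splits a
3′-only register mS_E by the target nucleotide opposite guide position
S−1 — in target coordinates the base immediately 3′ of the matched span.
Reads classified into the one-position-longer register m(S−1)_E *are* the
complementary-flank subclass by definition and are folded in; the two
sets count identical reads, which the tests assert by construction. This
is the analysis that explains why m9_20 sites of miR-155 look weak: they
are m10_20 sites forced to carry a disfavored U flank.

# The multiplicative compound-site model

Compound-site affinities decompose as
`−log10(κ) = A[3′ pattern] · B[seed pattern] · C[offset]`.
`fitMultiplicative()` takes logs, which turns the product into an
additive categorical model fitted by ordinary least squares (optionally
weighted). Two compensating scale freedoms (A→cA with C→C/c, likewise B)
are fixed by `max(A) = max(B) = 1`, absorbing the residual scale into C.
Because the absolute magnitudes carry no biochemical meaning, min-max
rescaled copies in [0, 1] are also reported for display. Sites with
κ ≥ 1 cannot enter a log fit and are returned in a rejects table.
Prediction refuses unseen levels — the model never extrapolates. A level
that never co-occurs with the others (a disconnected design) is an error
naming the level.

# Equilibrium binding and kinetics

`fitSaturation()` fits `θ_B = A/(A + Kd)` by nonlinear least squares
(Levenberg–Marquardt via minpack.lm). Bound reporting follows the assay
convention: if the maximum observed θ stays below `lowTheta` (default
0.2) the curve only supports a lower bound, reported as Kd = 10 nM; if θ
at the lowest tested concentration already exceeds `highTheta` (default
0.8) the curve is saturated and an upper bound of 5 pM is reported. Both
thresholds are configurable operationalizations of "negligible" and
"saturated".

`fitAssociation()` fits the pseudo-first-order integrated rate law
`AR(t) = AR_eq(1 − exp(−k_on A_T t))`, optionally pooling several AGO
concentrations that share one `k_on` (each series keeps its own
`AR_eq`); the pseudo-first-order guard requires every `A_T ≥ 80 pM`.
`deriveKoff()` applies `k_off = Kd · k_on` and propagates bound flags
rather than pretending a bound is a point estimate.

**Confidence intervals** for both fits use a case-resampling bootstrap
(within series for kinetics) and a t-interval on the log parameter. This
was a genuinely open choice; we calibrated candidates on the generator's
own noise process and found that the naive parametric percentile
bootstrap undercovers (≈ 0.84–0.89 at nominal 0.95) because clipping of
θ to [0, 1] and multiplicative kinetic noise shrink the residual-based
spread, whereas the case-resampling log-t interval covers at ≈ 0.91–0.95.

**Free energies.** `deltaGObserved()` is `RT ln κ` with
R = 1.9872×10⁻³ kcal/(mol·K) and T = 310.15 K (assays at 37 °C).
`deltaGPredictedNN()` scores the duplex of a segment with its perfect
complement as two free RNAs: Watson–Crick stack terms (a packaged
16-entry table of 37 °C Turner-style parameters, symmetric under duplex
reversal), a duplex-initiation term (+4.09) and a +0.45 terminal-AU
penalty per A:U helix end. Dangling ends and coaxial stacking are out of
scope; the contract is the summation rule, not a parameter vintage.
`compareDeltaG()` regresses observed on predicted ΔG° per site family,
excluding the A1 classes (8mer, 7mer-A1, 6mer-A1), whose position-1
adenosine is a non-pairing contact: seed-matched sites come out more
stable than the solution prediction (AGO pre-pays the entropic cost of
seed-helix formation) while 3′-only and compound sites come out less
stable with shallower slopes (3′ pairing must displace AGO–guide
contacts, including the PAZ-bound guide 3′ end).

# Chemical probing

`laneFractions()` converts band intensities to per-position signal
fractions; `relativeReactivity()` is `(S − Q)/(N − Q)` against the
pre-quenched baseline Q and the free-guide ceiling N. Positions where
the ceiling does not clear the baseline are not determined (`NA`), not
errors. Values outside [0, 1] — possible with noise — are reported as
computed and flagged, never clipped. Replicates aggregate as mean with
range (n = 2) or a t-based 95% interval (n ≥ 3).

# The MPRA module

`mpraSiteTable()`/`buildMpraDesign()` enumerate the reporter library:
6 canonical classes × 5 upstream sequences, a set of 3′-only registers,
the full compound grid (3 registers × 28 contiguous seed patterns of
2–8 nt × 2 offsets = 168), and 5 no-site controls — 223 sites for
miR-155, 218 for miR-124 (15 rather than 20 3′-only sites), each in 20
paired 50-nt flank contexts: 8,820 variants. Compound bridge fillers are
deterministic per-site pseudo-random sequences with salted collision
resolution, because two compound names differing by one seed nucleotide
can otherwise describe the same physical molecule; variant uniqueness is
verified at build time. No-site controls are per-guide rotations of a
pyrimidine set so the two libraries share no molecule.

`foldChanges()` computes counts-per-million, sums CPM per site across its
contexts, pairs miRNA and mock replicates, and normalizes each replicate
by the median fold change of the no-site sites (the median over the five
no-site architectures, for robustness). Sites with zero mock CPM are
flagged rather than silently infinite.

`fitOccupancyModel()` fits the biochemical repression model: fold
repression `1 + bN`, occupancy `N = a_free/(a_free + κ)`, predicted
`log2FC = −log2(1 + bN)` — the link from "repression" to steady-state
reporter mRNA is made explicit here. Neither b (unit repression per unit
occupancy) nor a_free (free AGO–miR in relative-Kd units) is measurable
directly, so both are fit globally by least squares over all sites with a
known κ, requiring ≥5 sites spanning a ≥100-fold κ range.
`occupancyModelCI()` fits each replicate separately and reports a
t-interval on the log scale: transfection replicates are the unit of
inference, and this captures the per-replicate normalization noise that
is shared across sites (a site-resampling bootstrap cannot see it and
undercovers badly — 0.5–0.8 in our calibration versus 0.93–0.95 for the
replicate interval).

`detectSlicing()` compares each zero-offset compound architecture with
its positive-offset counterpart: a positive offset bulges the target
between the seed and 3′ duplexes, which blocks slicing but tends to help
binding, so *greater* repression by the zero-offset variant is diagnostic
of slicing. Each pair is tested by one-way analysis of its replicate
log2 fold changes with Tukey's HSD, Bonferroni-corrected across tested
pairs (per-pair grouping; the joint-ANOVA alternative was the open
question, and per-architecture grouping keeps pairs independent); a call
requires the zero-offset mean lower and adjusted p < 0.05, strictly
one-directional.

# The targetome survey

`scanUtr()` applies the same grammar to 3′ UTRs under the `survey`
preset and reports *every* non-overlapping site: canonical classes
(offset-6mers excluded), 3′-only sites (≥10 nt contiguous 3′
complementarity, seed run < 3 nt at offsets −4..+6), and 3′+microseed
sites (same 3′ complementarity with a 3–5-nt in-window seed run). A
seed run of ≥6 nt at an in-window offset makes the site a canonical site
with supplementary 3′ pairing — recorded as a boolean, counted once as
canonical; canonical counting itself ignores 3′ pairing. Only the sense
strand is scanned (miRNA targeting is sense-strand by definition; the
tests confirm no strand leakage statistically). Overlaps are resolved
greedily left-most-first with category priority (3′ classes, then
canonical rank); survivors of a contested overlap are flagged ambiguous.
The paper's specific miRNA set and UTR database are inputs, not bundled;
`chanceRatio(6, 10) = 1/256` gives the rarity arithmetic, and the tests
verify empirical background rates on uniform sequence against the exact
register-sum expectation.

# Expression response

`leaveOneOutFC()` converts a log10 TPM matrix to per-gene log2 fold
changes for one transfected miRNA against the mean of all other samples
(× log2 10). `matchControls()` draws no-site controls matched to the
cohort's UTR-length distribution by decile stratification (seeded;
under-filled strata relax to nearest lengths with a warning).
`ksOneSided()` tests whether the cohort distribution is shifted toward
repression (cohort CDF above the control CDF; `alternative = "greater"`
with the cohort first), and `cohortResponse()` optionally aggregates
site-containing genes and controls across miRNAs before testing — the
device used to collect enough ≥10-nt 3′-only sites, at the cost of
diluting the signal by miRNAs whose sites are inert. Cohorts under ~10
genes are flagged low-power, not suppressed.

# Synthetic data

Every generator records a truth object (serializable with
`writeTruth()`) and is byte-deterministic given (configuration, seed).

* `genRbnsPools()` emulates the programmed library: 50% uniform random
  40-mers, 50% programmed molecules with a central 8-nt 3′-complementary
  segment (defaults: miR-155 positions 13–20), bound pools drawn under
  the equilibrium occupancy model at each free-AGO scale. For a ≥ 0.05
  this is per-molecule rejection sampling, so the grammar sees every raw
  candidate exactly as with real reads; for more dilute samples the cost
  grows as 1/a, and the generator instead classifies a fresh candidate
  pool and samples reads with probability proportional to occupancy —
  the same class distribution at fixed cost. Sequencing error, PCR
  duplicates and composition bias are not simulated, so passing recovery
  tests demonstrates correctness of the inference, not robustness to
  those artifacts.
* `genMpraCounts()` inverts the analysis model (mock ∝ abundance, miRNA
  ∝ abundance/(1 + bN)) with negative-binomial noise, default dispersion
  0.05 — typical reporter-assay overdispersion — and four replicates
  emulating two plates × two experiments. Defaults b = 3, a_free = 0.01.
* `genUtrs()` plants sites at recorded spans on uniform background that
  is rejection-sampled to be free of accidental sites of any surveyed
  category, and re-validates each plant's category *and* span, so
  plant-and-recover tests are exact.
* `genBindingData()` evaluates the saturation or rate equation forward
  and adds Gaussian noise; θ is clipped to [0, 1] with clip events
  counted, and sub-80 pM kinetics draw the pseudo-first-order warning.
* `genExpression()` draws gene baselines (log10 TPM ~ N(1.5, 0.5)),
  per-sample noise of 0.1 log10 units (≈ 0.33 in log2 — a realistic
  per-gene fold-change scatter for transfection experiments), and planted
  log2 shifts converted to log10.

# Problem sizes and numerics

The test suite runs the recovery experiments at the following scales,
chosen so each check has real statistical teeth while the whole suite
stays interactive: RBNS recovery at 10⁵ reads × 4 bound samples
(a = 1…10⁻³, κ spanning 10⁻³…1; read-by-read oracle agreement is checked
on 700 constructed and random reads); multiplicative-model recovery on
5,000 noisy sites; 200 seeded replicates each for saturation and
kinetics with bootstrap intervals; 100 noisy MPRA runs over the full
223-site design; survey background rates on 10⁶ nt; 1,000 null draws for
KS type-I and 200 for power.

Numerical conventions: optimization is always over log-parameters with
box bounds (κ, a ∈ [10⁻⁸, 10⁸]); the RBNS likelihood uses analytic
gradients (verified against finite differences); nonlinear curve fits
start from midpoint heuristics; the occupancy fit runs Nelder–Mead then
BFGS polish; degenerate inputs (all-zero θ lanes, empty enrichment
classes, zero mock CPM, n_free ≤ q probing positions) are flagged or
routed to bound paths rather than raised as failures, except where the
input is structurally invalid (all-zero lanes, malformed site names).

# Known limitations

* RBNS fits assume equilibrium; the strongest, slowest 3′-only sites are
  therefore understated.
* The single-best-site-per-read rule discards secondary sites on a read;
  the ambiguity flag marks where that mattered.
* The nearest-neighbor sum omits dangling ends and coaxial stacking.
* The MPRA design builder guarantees distinct variants but does not prove
  the absence of incidental short seed complementarity inside bridge
  fillers; the analysis keys on site names, not re-classification of
  designed sequences.
* The survey reports sites on representative UTR sequences only;
  conservation, isoform quantification and structural occlusion are out
  of scope.
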