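---
title: "Methods: disproportionality screening and drug-target MR in pvmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and drug-target MR in pvmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmr)
```

## The problem

Spontaneous-report databases such as FAERS record which adverse events are
*reported* with which drugs, not how often they *occur*. Disproportionality
analysis asks whether a drug–event pair is co-reported more often than the
database-wide reporting pattern predicts; it detects reporting signals and
is silent about causation. `pvmr` therefore pairs the screen with a
drug-target Mendelian randomization (MR) stage: if a drug's target protein
causally drives the adverse event, genetic variants that shift the
circulating protein level should shift the event risk too. The motivating
application is renal injury under CAR-T therapies, where an
acute-kidney-injury (AKI) reporting signal for the BCMA-directed product
idecabtagene vicleucel is not supported causally by MR on plasma BCMA — a
pattern consistent with the confounding-by-indication expected when the
treated disease (multiple myeloma) itself injures kidneys.

## Cleaning model for report streams

Reports are cleaned in a fixed cascade, mirroring the standard FAERS
workflow:

1. **Primary-suspect filter.** Only cases where a target drug is coded
   `PS` count as exposed; secondary-suspect, concomitant and interacting
   mentions are too confounded to use. Name matching is case-insensitive
   and whitespace-normalized, exact by default with an optional substring
   mode for free-text drug strings; the target name list (generic + brand)
   is user configuration, since no canonical list exists.
2. **Reporter occupation.** Only healthcare practitioners (`MD`, `HP`,
   `PH`, `RN`, `OT`) are retained, reducing reporting biases from consumer
   and legal reports. Missing occupation is removed, not imputed.
3. **Deduplication.** Within a `CASEID`, keep the record with the latest
   `fda_dt`; on ties, the higher `PRIMARYID` (numeric comparison when all
   ids are numeric). A missing date loses any tie — an undated version of
   a case should never displace a dated one.

The order is fixed (drug → occupation → dedup) because provenance counts
are reported per step; final case membership is order-invariant whenever a
case's occupation coding is internally consistent, and the suite checks
this property on random fixtures. Cases with no reaction rows are
*retained* and flagged: dropping them would silently shrink the
denominators b and d.

## The four algorithms

All four statistics are functions of one case-level 2×2 table. The unit of
counting is the deduplicated case — a case reporting the same PT twice
counts once. With s² = 1/a + 1/b + 1/c + 1/d:

| quantity | definition | threshold |
|---|---|---|
| ROR | ad/(bc), CI exp(ln ROR ± 1.96 s) | CI low > 1, a ≥ 3 |
| PRR, χ² | a(c+d)/(c(a+b)); Pearson χ², no continuity correction | PRR ≥ 2, χ² ≥ 4, a ≥ 3 |
| IC, IC025 | log₂(aN/((a+c)(a+b))); IC − 2√V, V = s²/ln²2 | IC025 > 0 |
| EBGM, EBGM05 | aN/((a+c)(a+b)); exp(ln EBGM − z·s) | EBGM05 > 2 |

Numerical choices worth stating:

* **EBGM05 quantile `z = 1.64`.** The published reference table this
  package reproduces is matched at 2 decimal places by z = 1.64 on every
  row, while the exact one-sided normal quantile 1.645 misses several rows
  at the second decimal. We default to the convention that reproduces the
  published values and expose `z05` for callers who prefer 1.645 or 1.96.
* **IC025 is the literal log-normal bound.** The bound IC − 2√V with
  V = s²/ln²2 reproduces published IC025 values for sparse cells (a = 3)
  but not for larger a, where published IC − IC025 gaps are nearly
  constant (≈1.67) and match no count-dependent variance we know of. We
  implement the literal formula and do not guess at an undocumented one;
  accordingly only the sparse-cell bounds are asserted against the
  reference table.
* **EBGM here is the closed-form relative reporting ratio**, identical to
  2^IC; the full DuMouchel gamma-mixture shrinkage model is deliberately
  out of scope. Consequently IC = log₂(EBGM) holds exactly and is
  property-tested.
* **Zero cells** make a statistic *undefined with a recorded reason*,
  never a silent `Inf`; undefined statistics can never flag.
* **Display rounding** is half-away-from-zero at 2 dp (matching published
  tables); all internal arithmetic is full precision.
* **No multiple-testing correction** across PTs: thresholds are applied
  per pair, as is conventional for these four criteria; the conservatism
  comes from requiring all four flags (the default combination; `"any"`
  is available).

The screen evaluates every PT observed for the target drug against a
background of all *other* cleaned cases from the same quarter range
(disjoint case keys are enforced — a shared key would be double counting).
SMQ-level screening is offered in both modes: PT-by-PT with scope
annotation, and pooled (all member PTs of the AKI or CKD narrow SMQ as one
composite event), since published analyses are ambiguous about which was
used; the reference AKI row is matched in PT mode.

## The renal SMQ dictionary

The bundled dictionary encodes the MedDRA 26.1 narrow-scope renal-injury
SMQs: 21 AKI PTs and 43 CKD PTs, six of which (Azotemia, Dialysis,
Hemodialysis, Hemofiltration, Peritoneal dialysis, Renal failure) belong
to both, so 21 + 43 = 64 with a distinct union of 58. Matching is exact
after trim/case-fold normalization — FAERS reaction strings are already
MedDRA PTs and fuzzy matching would inflate signals. The renal/urinary
system-organ-class list used for fallback presentation is user-suppliable;
the shipped demo list holds only the five SOC PTs that appear in the
reference results and is labelled incomplete.

## Drug-target MR

Instrument selection follows four criteria: cis location (within 500 kb of
the coding-region bounds, both flanks, 1-based inclusive), genome-wide
significance (p < 5×10⁻⁸, strict), independence (greedy LD clumping at
r² < 0.001, visiting variants by ascending p-value with rsID tie-break; a
missing LD entry is fatal rather than assumed zero), and strength
(F = (β/se)² > 10, the single-variant form of the first-stage F).

Validated instruments must additionally pass a **positive-control gate**:
MR against a disease the drug is known to treat must give a nominally
significant estimate (p < 0.05) in the configured direction. Without that,
the pipeline stops with status `instruments_not_validated` and produces no
primary estimate — an invalid-instrument answer, not a null answer.

Estimation: Wald ratio for one instrument (first-order delta se,
`se_out/|β_exp|`; a second-order option exists), fixed-effect IVW for
several, and for three or more also MR-Egger (weighted regression with
free intercept after orienting exposure effects positive; multiplicative
random-effects se floored at fixed-effect precision; t-based p-values),
the weighted median (cumulative-weight interpolation; parametric bootstrap
se, seeded), and the simple/weighted mode estimators (kernel density of
ratio estimates, bandwidth 0.9·min(sd, mad)·k^(−1/5) with multiplier
φ = 1; bootstrap MAD se). "Simple model"/"weighted model" in the
motivating analysis are interpreted as these standard mode estimators.
Heterogeneity is Cochran's Q on the ratio estimates; pleiotropy is the
Egger intercept. Nominal p-values throughout; no correction across
outcomes.

Degenerate inputs are errors with instructive messages: IVW on one pair
(use the Wald ratio), Egger on collinear exposure effects, a zero exposure
beta in a ratio.

## What the simulators emulate — and what they do not

`simulate_faers()` draws multinomial report streams: a target drug plus
comparator drugs, a PT vocabulary dominated by common
infusion/cytopenia-type events with renal PTs at a few per thousand,
1 + Poisson(0.8) PTs per report, reporter/sex/age/weight mixes with
realistic missingness, consumer reports for the occupation filter to
remove, and a configurable fraction of duplicated cases constructed to
exercise *both* deduplication tie rules. A planted signal (drug, PT, rate
ratio ρ) multiplies that drug's PT probability by ρ before
renormalization, so expected cell counts follow analytically from the
manifest: the defaults (2,000 target reports, 50,000 background, renal PT
background ≈ 0.5%) put a planted ρ = 5 signal comfortably above all four
thresholds while leaving the null stream clean. Calibration runs in the
suite and the acceptance script use 2,000 target / 20,000 background
reports per snapshot across 100 (null) and 50 (planted) seeds — sizes at
which the planted pair's expected a is ≈ 45 and detection is essentially
deterministic, chosen as the smallest snapshots that are still clearly in
the well-powered regime.

`simulate_gwas_pair()` works directly at the summary-statistic level — no
individual genotypes — which is exactly what two-sample MR consumes.
Exposure standard errors follow the quantitative-trait form
1/√(2p(1−p)n) at the proteomics-cohort scale (n = 35,559); outcome and
control standard errors use the *effective* sample size of a case-control
GWAS, 4/(1/cases + 1/controls), with defaults mirroring biobank-scale AKI
(1,415 cases) and multiple-myeloma (601 cases) GWAS. This matters: with
total-N precision the outcome noise would be implausibly small relative to
exposure noise and first-order MR standard errors would undercover.
Decoy variants (in-window nulls, out-of-window hits), optional LD blocks
(neighbours carry √r²-attenuated effects), and allele-label swaps in a
configurable fraction of outcome records exercise selection, clumping and
harmonization.

Neither generator attempts real FAERS marginal frequencies, real LD
panels, time trends, or notoriety effects. Passing calibration on these
streams shows the machinery is correct and calibrated under its stated
model; it does not certify performance on real reporting data, whose
biases (stimulated reporting, indication channeling) are exactly why the
MR stage exists.

## Simulation-calibration results asserted by the suite

Under the null stream, the fraction of drug–PT pairs flagged by all four
algorithms stays below 5% (empirically it is ~0 — the quadruple criterion
is very conservative); a planted ρ = 5 signal is detected in ≥ 90% of
seeds. IVW/Wald recovery runs at n_snp = 10 (and 1), θ ∈ {−0.3, 0, 0.3}:
absolute bias < 0.02, 95% CI coverage within [0.92, 0.98] over 200
replicates, and type-I error within [3.5%, 6.5%] over 1,000 null
replicates. These are properties of the estimators under the generator's
conditions, recomputed at run time — never stored constants.

## Known limitations

* The published IC025 convention for non-sparse cells is unknown and
  therefore not reproduced (see above).
* EBGM is the closed form, not gamma-Poisson shrinkage; for very sparse
  tables the shrinkage estimator would be smaller.
* The SOC fallback list ships as an incomplete demo subset.
* Exact report counts of any real FAERS analysis depend on the analyst's
  drug-name term lists and snapshot, which are not published; the package
  reproduces published *statistics from counts*, and validates the
  *count-building machinery* on synthetic streams.
* LD is consumed as a precomputed r² matrix; no reference-panel genotype
  processing is included.
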