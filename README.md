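# pvmr — pharmacovigilance signal detection and drug-target Mendelian randomization

`pvmr` is an R package for the two-stage safety question that spontaneous
adverse-event reporting keeps raising: a drug–event pair *disproportionately
reported* in FAERS is a signal, not a cause. The package (1) cleans
FAERS-style quarterly extracts and screens drug–event pairs with the four
standard disproportionality algorithms, and (2) follows a flagged signal up
with two-sample drug-target Mendelian randomization (MR) using cis-pQTL
instruments, so the correlational signal can be confronted with genetic
evidence for or against causality. It was built around the motivating case
of CAR-T cell therapies and renal injury — where idecabtagene vicleucel
shows an acute-kidney-injury reporting signal that drug-target MR on its
target protein BCMA does not support causally — but every component is
generic.

## What it computes

For a deduplicated case-level 2×2 table (a = target drug & target reaction,
b = drug & other reactions, c = other drugs & reaction, d = remainder,
N = a+b+c+d):

* **ROR** = ad/(bc), 95% CI = exp(ln ROR ± 1.96·s), s = √(1/a+1/b+1/c+1/d);
  flagged when CI lower bound > 1 and a ≥ 3.
* **PRR** = a(c+d)/(c(a+b)) with the Pearson χ² (no continuity
  correction); flagged when PRR ≥ 2, χ² ≥ 4, a ≥ 3.
* **BCPNN information component** IC = log₂(aN/((a+c)(a+b))), with
  IC025 = IC − 2√V, V = s²/(ln 2)²; flagged when IC025 > 0.
* **EBGM** = aN/((a+c)(a+b)) (the closed-form relative reporting ratio)
  with EBGM05 = exp(ln EBGM − z·s), z = 1.64 by default; flagged when
  EBGM05 > 2.

A pair is *positive* when all four algorithms flag it (configurable to
"any"). The MR half implements cis-window + significance instrument
selection, greedy LD clumping (r² < 0.001), the single-SNP F statistic
(β/se)², allele harmonization, a positive-control validation gate, and the
Wald-ratio / IVW / MR-Egger / weighted-median / mode estimators with
Cochran's Q and Egger-intercept diagnostics.

A synthetic-data module (`simulate_faers()`, `simulate_gwas_pair()`)
generates report streams and GWAS/pQTL summary statistics with known ground
truth, so the whole pipeline is testable without restricted data.

## Worked example

The bundled fixture `cart_renal_counts()` carries the eight published
(drug, PT) rows with their 2×2 counts. Reproducing the statistics of the
headline row:

```r
library(pvmr)
fit <- dpa(c(26, 1694, 37016, 8346665))   # idecabtagene vicleucel x AKI
print(fit)
#> Disproportionality analysis (a = 26 , N = 8,385,401 )
#>   ROR  3.46 (2.35-5.10)   PRR 3.42 (chi2 44.78)
#>   IC   1.77 (IC025 1.20)   EBGM 3.42 (EBGM05 2.47)
#>   flags: ROR=TRUE PRR=TRUE BCPNN=TRUE MGPS=TRUE | evaluable=TRUE positive=TRUE
```

Read: the drug–event pair is reported 3.4× more often than expected under
independence; every lower bound clears its threshold, so all four
algorithms call it a signal. `dpa_from_counts()` does this for the whole
counts table; `screen_signals()` does it for every PT of a cleaned case
set; `run_signal_report()` is the end-to-end wrapper from raw `$`-delimited
DEMO/DRUG/REAC files.

On the MR side, with summary statistics and an LD matrix (simulated here):

```r
cfg <- gwas_sim_config(seed = 5, theta = 0, theta_control = 0.5)
g   <- simulate_gwas_pair(cfg)
res <- run_mr_pipeline(g$exposure, g$outcome, g$control, cfg$region, g$ld)
res$status            # "ok": the positive control validated the instruments
res$primary_fit       # null causal estimate (theta = 0 was simulated)
```

A thin command-line wrapper lives at `inst/cli/pvmr.R`
(`signal`, `simulate`, `mr` subcommands).

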