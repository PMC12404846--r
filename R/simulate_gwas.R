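#' Configuration for the GWAS/pQTL summary-statistics simulator
#'
#' Defaults emulate a drug-target MR setting resembling a plasma-protein
#' exposure measured in a large proteomics cohort and binary-trait
#' outcome GWAS of biobank scale: a handful of strong cis instruments
#' inside a 500 kb window around the coding gene, decoy variants that
#' fail the window or significance criteria, optional LD-correlated
#' neighbours, a positive-control outcome with a real effect, and a
#' configurable true causal effect (and directional pleiotropy) on the
#' primary outcome.
#'
#' @param seed Integer RNG seed.
#' @param n_snps Number of independent instruments (LD-block leads).
#' @param region [gene_region] of the protein-coding gene.
#' @param beta_exp_range True per-allele instrument effects are drawn
#'   uniformly from this range.
#' @param maf_range Minor-allele frequencies drawn uniformly from this
#'   range.
#' @param n_exp,n_out,n_control GWAS sample sizes. The exposure is a
#'   quantitative protein level, so its standard errors follow
#'   `1/sqrt(2 p (1-p) n_exp)`; the outcomes are case-control traits, so
#'   their precision is driven by the effective sample size
#'   `4 / (1/cases + 1/controls)` implied by `n_out_cases` /
#'   `n_control_cases`.
#' @param n_out_cases,n_control_cases Case counts of the binary outcome
#'   and positive-control GWAS.
#' @param theta True causal effect of the exposure on the primary
#'   outcome.
#' @param delta Directional pleiotropy added to every outcome effect.
#' @param theta_control True effect on the positive-control outcome.
#' @param ld_block_size Variants per LD block (1 = independent
#'   instruments only).
#' @param ld_block_r2 Within-block r-squared.
#' @param n_null_snps In-window variants with no exposure effect (fail
#'   the p-value criterion).
#' @param n_flank_snps Significant variants outside the cis window (fail
#'   the window criterion).
#' @param swap_fraction Fraction of outcome/control records whose allele
#'   labels are swapped (beta negated) to exercise harmonization.
#' @return A validated list of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(seed = 1, n_snps = 10,
                            region = gene_region("TNFRSF17", "16",
                                                 11965000, 11975000),
                            beta_exp_range = c(0.15, 0.4),
                            maf_range = c(0.1, 0.5),
                            n_exp = 35559, n_out = 463010, n_control = 372617,
                            n_out_cases = 1415, n_control_cases = 601,
                            theta = 0, delta = 0, theta_control = 0.5,
                            ld_block_size = 1, ld_block_r2 = 0.8,
                            n_null_snps = 3, n_flank_snps = 2,
                            swap_fraction = 0.3) {
  stopifnot(inherits(region, "gene_region"))
  if (ld_block_r2 < 0 || ld_block_r2 > 1)
    stop_pv("invalid config field 'ld_block_r2': must be in [0, 1]")
  if (any(beta_exp_range <= 0) || any(maf_range <= 0) || any(maf_range > 0.5))
    stop_pv("invalid config field 'beta_exp_range'/'maf_range'")
  if (swap_fraction < 0 || swap_fraction > 1)
    stop_pv("invalid config field 'swap_fraction'")
  if (n_out_cases >= n_out || n_control_cases >= n_control)
    stop_pv("invalid config field 'n_out_cases'/'n_control_cases'")
  structure(list(seed = seed, n_snps = n_snps, region = region,
                 beta_exp_range = beta_exp_range, maf_range = maf_range,
                 n_exp = n_exp, n_out = n_out, n_control = n_control,
                 n_out_cases = n_out_cases, n_control_cases = n_control_cases,
                 theta = theta, delta = delta, theta_control = theta_control,
                 ld_block_size = ld_block_size, ld_block_r2 = ld_block_r2,
                 n_null_snps = n_null_snps, n_flank_snps = n_flank_snps,
                 swap_fraction = swap_fraction),
            class = "gwas_sim_config")
}

#' Simulate exposure / control / outcome summary statistics with LD
#'
#' Summary statistics are simulated directly at the summary level (no
#' individual genotypes): observed exposure effects are the true
#' instrument effects plus sampling noise at the analytic standard error;
#' outcome effects are `theta * b_true + delta + noise`; the control
#' outcome uses `theta_control`. LD-block neighbours carry attenuated
#' copies (`sqrt(r2)`) of their lead's effect and the returned r-squared
#' matrix is block-diagonal accordingly. The manifest records the ground
#' truth needed to verify recovery.
#'
#' @param config A [gwas_sim_config].
#' @param dir Optional directory: writes `exposure.tsv`, `control.tsv`,
#'   `outcome.tsv`, `ld.tsv`, `manifest.json`.
#' @return List with `exposure`, `control`, `outcome` data frames, `ld`
#'   matrix and `manifest`.
#' @export
simulate_gwas_pair <- function(config = gwas_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "gwas_sim_config"))
  with_seed(config$seed, simulate_gwas_impl(config, dir))
}

simulate_gwas_impl <- function(cfg, dir) {
  reg <- cfg$region
  n_iv_total <- cfg$n_snps * cfg$ld_block_size
  n_total <- n_iv_total + cfg$n_null_snps + cfg$n_flank_snps

  snp <- sprintf("rs%07d", sample.int(9999999, n_total))
  lo <- reg$start - reg$cis_window_bp
  hi <- reg$end + reg$cis_window_bp
  pos_iv <- sort(sample(seq(lo + 1000, hi - 1000), n_iv_total))
  pos_null <- sample(seq(reg$start, reg$end), max(cfg$n_null_snps, 0))
  pos_flank <- if (cfg$n_flank_snps > 0)
    lo - sample(seq(10000, 200000), cfg$n_flank_snps) else integer(0)
  pos <- c(pos_iv, pos_null, pos_flank)

  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G", "C", "A",
                    "G", "A", "C", "T", "G", "T"), ncol = 2, byrow = TRUE)
  al <- pairs[sample.int(nrow(pairs), n_total, replace = TRUE), , drop = FALSE]
  maf <- stats::runif(n_total, cfg$maf_range[1], cfg$maf_range[2])

  block <- c(rep(seq_len(cfg$n_snps), each = cfg$ld_block_size),
             rep(NA_integer_, cfg$n_null_snps + cfg$n_flank_snps))
  lead <- !duplicated(block) & !is.na(block)
  b_lead <- stats::runif(cfg$n_snps, cfg$beta_exp_range[1], cfg$beta_exp_range[2])
  b_true <- numeric(n_total)
  b_true[!is.na(block)] <- b_lead[block[!is.na(block)]] *
    ifelse(lead[!is.na(block)], 1, sqrt(cfg$ld_block_r2))
  is_flank <- seq_len(n_total) > n_iv_total + cfg$n_null_snps
  b_true[is_flank] <- mean(cfg$beta_exp_range)  # significant but out of window

  make_stats <- function(b_target, n_sample, n_eff = n_sample) {
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)
    beta <- stats::rnorm(n_total, b_target, se)
    pval <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(snp = snp, chr = reg$chrom, pos = pos,
               ea = al[, 1], oa = al[, 2], eaf = maf,
               beta = beta, se = se, pval = pval, n = n_sample,
               stringsAsFactors = FALSE)
  }
  n_eff_bin <- function(n, cases) 4 / (1 / cases + 1 / (n - cases))
  exposure <- make_stats(b_true, cfg$n_exp)
  control <- make_stats(cfg$theta_control * b_true, cfg$n_control,
                        n_eff_bin(cfg$n_control, cfg$n_control_cases))
  outcome <- make_stats(cfg$theta * b_true +
                          ifelse(b_true != 0, cfg$delta, 0), cfg$n_out,
                        n_eff_bin(cfg$n_out, cfg$n_out_cases))

  if (cfg$swap_fraction > 0) {
    swap <- stats::runif(n_total) < cfg$swap_fraction
    for (nm in c("control", "outcome")) {
      df <- get(nm)
      df$beta[swap] <- -df$beta[swap]
      df$eaf[swap] <- 1 - df$eaf[swap]
      tmp <- df$ea[swap]
      df$ea[swap] <- df$oa[swap]
      df$oa[swap] <- tmp
      assign(nm, df)
    }
  }

  ld <- diag(1, n_total)
  dimnames(ld) <- list(snp, snp)
  if (cfg$ld_block_size > 1) {
    for (bk in seq_len(cfg$n_snps)) {
      idx <- which(!is.na(block) & block == bk)
      ld[idx, idx] <- cfg$ld_block_r2
      ld[cbind(idx, idx)] <- 1
    }
  }

  manifest <- list(seed = cfg$seed, theta = cfg$theta, delta = cfg$delta,
                   theta_control = cfg$theta_control,
                   gene = reg$gene_symbol, n_instruments = cfg$n_snps,
                   true_beta_exp = stats::setNames(b_true, snp))
  out <- list(exposure = exposure, control = control, outcome = outcome,
              ld = ld, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_sumstats(exposure, file.path(dir, "exposure.tsv"))
    write_sumstats(control, file.path(dir, "control.tsv"))
    write_sumstats(outcome, file.path(dir, "outcome.tsv"))
    write_ld_matrix(ld, file.path(dir, "ld.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
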