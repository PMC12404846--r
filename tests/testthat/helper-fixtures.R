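# Shared fixtures and independent oracles used across the suite.

# Published 2x2 counts with the statistics they are known to yield
# (verified independently from the closed-form definitions at 2 dp;
# ic025 under the literal log-normal variance, defined only where the
# published bound follows that formula, i.e. the a = 3 rows).
golden_signal_rows <- function() {
  df <- cart_renal_counts()
  exp_stats <- rbind(
    c(5.67, 1.82, 17.64, 5.67, 11.48, 5.64, 2.18, 2.50, 0.83),
    c(12.70, 4.07, 39.64, 12.69, 31.92, 12.55, 4.84, 3.65, 1.97),
    c(13.51, 9.67, 18.87, 13.48, 397.96, 13.28, 10.04, 3.73, NA),
    c(3.32, 1.96, 5.61, 3.32, 22.55, 3.31, 2.13, 1.73, NA),
    c(21.32, 10.63, 42.76, 21.27, 153.68, 21.16, 11.82, 4.40, NA),
    c(58.63, 26.20, 131.20, 58.20, 335.33, 57.86, 29.49, 5.85, NA),
    c(3.46, 2.35, 5.10, 3.42, 44.78, 3.42, 2.47, 1.77, NA),
    c(18.43, 6.90, 49.26, 18.39, 65.55, 18.33, 8.05, 4.20, NA))
  colnames(exp_stats) <- c("ror", "ror_l", "ror_u", "prr", "chi2",
                           "ebgm", "ebgm05", "ic", "ic025")
  cbind(df, as.data.frame(exp_stats))
}

round2 <- function(x) pvmr:::round_half_up(x, 2)

# Random 2x2 tables with all-positive cells.
random_tables <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    contingency_counts(sample(1:80, 1), sample(1:5000, 1),
                       sample(1:5000, 1), sample(1000:2e6, 1))
  })
}

# Minimal demo/drug/reac builders.
make_demo <- function(primaryid, caseid = primaryid,
                      fda_dt = rep(20230101L, length(primaryid)),
                      occp_cod = rep("MD", length(primaryid)),
                      sex = rep("M", length(primaryid)),
                      age_yr = rep(60, length(primaryid)),
                      wt = rep(70, length(primaryid)),
                      quarter = rep("2023Q1", length(primaryid))) {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid), fda_dt = as.integer(fda_dt),
             occp_cod = occp_cod, sex = sex, age_yr = age_yr, wt = wt,
             quarter = quarter, stringsAsFactors = FALSE)
}

make_drug <- function(primaryid, drugname, role_cod = "PS") {
  data.frame(primaryid = as.character(primaryid),
             drugname = rep(drugname, length.out = length(primaryid)),
             role_cod = rep(role_cod, length.out = length(primaryid)),
             stringsAsFactors = FALSE)
}

make_reac <- function(primaryid, pt) {
  data.frame(primaryid = as.character(primaryid),
             pt = rep(pt, length.out = length(primaryid)),
             stringsAsFactors = FALSE)
}

# Write '$'-delimited FAERS-style files, returning their paths.
write_faers_files <- function(demo, drug, reac, dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(demo = file.path(dir, "demo.txt"),
            drug = file.path(dir, "drug.txt"),
            reac = file.path(dir, "reac.txt"))
  write.table(demo, p$demo, sep = "$", row.names = FALSE, quote = FALSE, na = "")
  write.table(drug, p$drug, sep = "$", row.names = FALSE, quote = FALSE, na = "")
  write.table(reac, p$reac, sep = "$", row.names = FALSE, quote = FALSE, na = "")
  p
}

# Independent greedy-clump oracle: visit by (pval, snp), test every pair
# against the full accepted set via the LD matrix directly.
clump_oracle <- function(candidates, ld, r2_threshold = 0.001, window_bp = 1e7) {
  ord <- order(candidates$pval, candidates$snp)
  cand <- candidates[ord, , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(cand))) {
    near <- accepted[abs(cand$pos[match(accepted, cand$snp)] - cand$pos[i]) <= window_bp]
    if (all(ld[cand$snp[i], near] < r2_threshold)) {
      accepted <- c(accepted, cand$snp[i])
    }
  }
  accepted
}

# Random summary statistics + LD matrix for clumping tests.
random_clump_instance <- function(n_snp, seed) {
  set.seed(seed)
  snp <- sprintf("rs%05d", sample.int(99999, n_snp))
  r <- matrix(runif(n_snp^2) * sample(c(0, 1), n_snp^2, TRUE, prob = c(0.7, 0.3)),
              n_snp, n_snp)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(snp, snp)
  stats <- data.frame(snp = snp, chr = "1",
                      pos = sort(sample.int(2e6, n_snp)),
                      ea = "A", oa = "G", eaf = runif(n_snp, 0.05, 0.95),
                      beta = rnorm(n_snp, 0, 0.2), se = runif(n_snp, 0.01, 0.05),
                      pval = runif(n_snp), n = 10000, stringsAsFactors = FALSE)
  list(stats = stats, ld = r)
}

# Simple harmonized-pair builder for the estimator tests.
make_pairs <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.05) {
  data.frame(beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out)
}
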