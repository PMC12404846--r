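#' Read / write GWAS-pQTL summary statistics
#'
#' Tab-delimited with header columns `snp`, `chr`, `pos`, `ea`, `oa`,
#' `eaf`, `beta`, `se`, `pval`, `n`.
#'
#' @param path File path.
#' @return Data frame of summary statistics.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop_pv("summary-statistics file not found: %s", path)
  check_sumstats(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sumstats
#' @param stats Summary-statistics data frame.
#' @export
write_sumstats <- function(stats, path) {
  check_sumstats(stats)
  utils::write.table(stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pairwise LD r-squared matrix
#'
#' Square matrix, rsIDs as header row and first column.
#'
#' @param path File path.
#' @return Numeric matrix with rsID dimnames.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_ld_matrix
#' @param ld Square r-squared matrix with rsID dimnames.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(cbind(snp = rownames(ld), as.data.frame(ld)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the drug-target MR pipeline with a positive-control gate
#'
#' Implements the instrument-validation workflow: (1) cis-pQTL selection
#' within the gene region, (2) LD clumping, (3) instrument-strength
#' filter (F > `f_min`), (4) harmonization against the positive-control
#' outcome and MR on the control; only if the control estimate is
#' nominally significant (`p < control_alpha`) in the expected direction
#' are the instruments considered validated, and (5) MR plus sensitivity
#' analyses run against the primary outcome (and an optional replication
#' outcome). Without control validation no primary estimate is produced.
#'
#' @param exposure pQTL summary statistics for the circulating target
#'   protein.
#' @param outcome Primary-outcome GWAS summary statistics.
#' @param control Positive-control GWAS summary statistics (a disease the
#'   drug is known to treat).
#' @param region [gene_region] of the protein-coding gene.
#' @param ld Pairwise r-squared matrix covering the candidates.
#' @param replication Optional replication-outcome summary statistics.
#' @param p_threshold,r2_threshold,f_min Instrument-selection criteria
#'   (defaults 5e-8, 0.001, 10).
#' @param control_direction Expected sign of the control effect (+1:
#'   target protein increases control-disease risk).
#' @param control_alpha Nominal significance for the gate (default 0.05).
#' @param seed Seed for the bootstrap-based estimators.
#' @return An object of class `mr_pipeline`: `status` (`"ok"`,
#'   `"instruments_not_validated"` or `"no_instruments"`), `instruments`
#'   (with F statistics), `control_fit`, `primary_fit`,
#'   `replication_fit`, `provenance`.
#' @export
run_mr_pipeline <- function(exposure, outcome, control, region, ld,
                            replication = NULL, p_threshold = 5e-8,
                            r2_threshold = 0.001, f_min = 10,
                            control_direction = 1, control_alpha = 0.05,
                            seed = 1) {
  prov <- list(n_exposure_snps = nrow(exposure))
  cand <- select_cis_pqtls(exposure, region, p_threshold = p_threshold)
  prov$n_cis_significant <- nrow(cand)
  if (nrow(cand) > 0) cand <- ld_clump(cand, ld, r2_threshold = r2_threshold)
  prov$n_after_clump <- nrow(cand)
  if (nrow(cand) > 0) {
    cand$f_stat <- f_statistic(cand)
    cand <- cand[cand$f_stat > f_min, , drop = FALSE]
  }
  prov$n_after_f <- nrow(cand)
  out <- list(status = "no_instruments", instruments = cand,
              control_fit = NULL, primary_fit = NULL, replication_fit = NULL,
              region = region, provenance = prov)
  class(out) <- "mr_pipeline"
  if (nrow(cand) == 0) return(out)

  fit_for <- function(outcome_stats) {
    pairs <- harmonize(cand, outcome_stats)
    if (nrow(pairs) == 0) return(NULL)
    mr_fit(pairs, seed = seed)
  }
  out$control_fit <- fit_for(control)
  if (is.null(out$control_fit)) {
    out$status <- "no_instruments"
    return(out)
  }
  head_est <- out$control_fit$results[1, ]
  validated <- head_est$pval < control_alpha &&
    sign(head_est$beta) == sign(control_direction)
  prov$control_pval <- head_est$pval
  prov$control_beta <- head_est$beta
  out$provenance <- prov
  if (!validated) {
    out$status <- "instruments_not_validated"
    return(out)
  }
  out$primary_fit <- fit_for(outcome)
  if (!is.null(replication)) out$replication_fit <- fit_for(replication)
  out$status <- "ok"
  out
}

#' @export
print.mr_pipeline <- function(x, ...) {
  p <- x$provenance
  cat("Drug-target MR pipeline:", x$region$gene_symbol, "\n")
  cat(sprintf("  instruments: %d cis-significant -> %d after clumping -> %d after F filter\n",
              p$n_cis_significant, p$n_after_clump, p$n_after_f))
  cat("  status:", x$status, "\n")
  if (!is.null(x$control_fit)) {
    cat("-- positive control --\n"); print(x$control_fit)
  }
  if (!is.null(x$primary_fit)) {
    cat("-- primary outcome --\n"); print(x$primary_fit)
  }
  if (!is.null(x$replication_fit)) {
    cat("-- replication outcome --\n"); print(x$replication_fit)
  }
  invisible(x)
}
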