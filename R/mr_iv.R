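#' Define a protein-coding gene region for cis-instrument selection
#'
#' @param gene_symbol Gene symbol (e.g. `"TNFRSF17"`, encoding BCMA).
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds of the coding region.
#' @param cis_window_bp Flank added on both sides when selecting
#'   cis-pQTLs (default 500 kb).
#' @return A list of class `gene_region`.
#' @export
gene_region <- function(gene_symbol, chrom, start, end, cis_window_bp = 5e5) {
  stopifnot(start <= end, cis_window_bp >= 0)
  structure(list(gene_symbol = gene_symbol, chrom = as.character(chrom),
                 start = start, end = end, cis_window_bp = cis_window_bp),
            class = "gene_region")
}

check_sumstats <- function(stats) {
  req <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  miss <- setdiff(req, names(stats))
  if (length(miss) > 0)
    stop_pv("summary statistics missing column(s): %s", paste(miss, collapse = ", "))
  if (any(stats$se <= 0, na.rm = TRUE)) stop_pv("summary statistics contain se <= 0")
  invisible(stats)
}

#' Select cis-pQTL instrument candidates
#'
#' Keeps variants lying within `cis_window_bp` of the coding-region
#' bounds on the region's chromosome whose association p-value is below
#' the genome-wide threshold. Both flanks count; coordinates are 1-based
#' inclusive. Caller is responsible for a consistent genome build.
#'
#' @param stats Summary-statistics data frame with columns `snp`, `chr`,
#'   `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param region A [gene_region].
#' @param p_threshold Significance threshold (default 5e-8, strict `<`).
#' @return The qualifying subset (possibly empty, with a warning).
#' @export
select_cis_pqtls <- function(stats, region, p_threshold = 5e-8) {
  stopifnot(inherits(region, "gene_region"))
  check_sumstats(stats)
  lo <- region$start - region$cis_window_bp
  hi <- region$end + region$cis_window_bp
  keep <- as.character(stats$chr) == region$chrom &
    stats$pos >= lo & stats$pos <= hi &
    stats$pval < p_threshold
  keep[is.na(keep)] <- FALSE
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warn_pv("no cis-pQTL passes the window/p-value criteria for %s", region$gene_symbol)
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Standard clumping: visit candidates by ascending p-value (ties broken
#' by rsID) and accept a variant only if its LD r-squared with every
#' already-accepted variant within `window_bp` is below `r2_threshold`.
#' A missing LD entry for a needed pair is a fatal error — independence
#' is never assumed.
#'
#' @param candidates Summary-statistics data frame (see
#'   [select_cis_pqtls()]).
#' @param ld Square pairwise r-squared matrix with rsID dimnames.
#' @param r2_threshold Maximum allowed r-squared (default 0.001).
#' @param window_bp Only pairs closer than this need an LD entry
#'   (default 10 Mb).
#' @return The retained subset, ordered by ascending p-value.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001, window_bp = 1e7) {
  if (nrow(candidates) == 0) return(candidates)
  check_sumstats(candidates)
  ord <- order(candidates$pval, candidates$snp)
  cand <- candidates[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (abs(cand$pos[i] - cand$pos[j]) > window_bp) next
      si <- cand$snp[i]; sj <- cand$snp[j]
      if (!(si %in% rownames(ld)) || !(sj %in% colnames(ld)) ||
          is.na(ld[si, sj]))
        stop_pv("missing LD entry for pair (%s, %s)", si, sj)
      if (ld[si, sj] >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-variant instrument-strength F statistic
#'
#' For one variant the first-stage F statistic reduces to the squared
#' Wald statistic, `(beta / se)^2`; F > 10 is the conventional
#' weak-instrument cutoff.
#'
#' @param beta Effect estimate(s), or a summary-statistics data frame.
#' @param se Standard error(s) (ignored when `beta` is a data frame).
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  stopifnot(all(se > 0))
  (beta / se)^2
}

is_palindromic <- function(ea, oa) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  toupper(oa) == unname(comp[toupper(ea)])
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effect to the exposure's effect allele for every
#' shared rsID. When the outcome's alleles are reversed, its beta is
#' negated and its EAF flipped (`action = "flipped"`). Palindromic
#' variants (A/T, C/G) are dropped when the exposure EAF lies in the
#' ambiguity window (default `[0.42, 0.58]`), otherwise they are resolved
#' by allele frequency; incompatible allele sets are dropped with a
#' logged reason.
#'
#' @param exposure,outcome Summary-statistics data frames.
#' @param eaf_window Ambiguity window for palindromic variants.
#' @return Data frame of class `harmonized_pairs` with exposure and
#'   outcome effects on a common allele, `action`, and attribute
#'   `dropped` (snp, reason).
#' @export
harmonize <- function(exposure, outcome, eaf_window = c(0.42, 0.58)) {
  check_sumstats(exposure)
  check_sumstats(outcome)
  m <- merge(exposure, outcome, by = "snp", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0) stop_pv("no shared rsIDs between exposure and outcome")
  up <- function(x) toupper(x)
  same <- up(m$ea_exp) == up(m$ea_out) & up(m$oa_exp) == up(m$oa_out)
  swapped <- up(m$ea_exp) == up(m$oa_out) & up(m$oa_exp) == up(m$ea_out)
  pal <- is_palindromic(m$ea_exp, m$oa_exp)
  ambiguous <- pal & m$eaf_exp >= eaf_window[1] & m$eaf_exp <= eaf_window[2]
  # palindromic outside the window: strand is resolved by frequency — the
  # outcome eaf must sit on the same side of 0.5 as the exposure eaf once
  # aligned; if not, the outcome record is on the other strand and the
  # allele match is effectively swapped.
  freq_mismatch <- pal & !ambiguous & same &
    (m$eaf_exp - 0.5) * (m$eaf_out - 0.5) < 0
  action <- rep(NA_character_, nrow(m))
  action[same] <- "none"
  action[swapped | freq_mismatch] <- "flipped"
  action[ambiguous] <- "palindromic_dropped"
  action[!same & !swapped & !ambiguous] <- "incompatible_alleles"

  flip <- action == "flipped"
  m$beta_out[flip] <- -m$beta_out[flip]
  m$eaf_out[flip] <- 1 - m$eaf_out[flip]
  tmp <- m$ea_out[flip]
  m$ea_out[flip] <- m$oa_out[flip]
  m$oa_out[flip] <- tmp
  m$action <- action

  dropped <- m[!(action %in% c("none", "flipped")), c("snp", "action")]
  out <- m[action %in% c("none", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("harmonized_pairs", class(out))
  out
}
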