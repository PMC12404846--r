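#' Bundled published disproportionality counts for CAR-T renal signals
#'
#' The eight (drug, PT) rows with their 2x2 counts from a published FAERS
#' screen of the six approved CAR-T therapies against renal
#' preferred terms (snapshot 2017Q1-2024Q1, cleaned as in
#' [assemble_case_set()]). Useful for exercising the statistics layer
#' without any report files.
#'
#' @return Data frame with columns `drug`, `pt`, `a`, `b`, `c`, `d`.
#' @export
cart_renal_counts <- function() {
  utils::read.delim(pvmr_extdata("cart_renal_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Run the four disproportionality algorithms over a counts table
#'
#' Entry point for precomputed 2x2 counts (columns `drug`, `pt`, `a`,
#' `b`, `c`, `d`): fits [dpa()] per row and returns the same decision
#' table as [screen_signals()].
#'
#' @param counts Data frame of counts, or a path to a delimited file of
#'   them; defaults to the bundled published counts.
#' @param thresholds A [signal_thresholds] object.
#' @param ... Passed to [dpa()].
#' @return A `signal_screen` data frame.
#' @export
dpa_from_counts <- function(counts = cart_renal_counts(),
                            thresholds = signal_thresholds(), ...) {
  if (is.character(counts)) counts <- utils::read.delim(counts, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "pt", "a", "b", "c", "d") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ct <- contingency_counts(counts$a[i], counts$b[i], counts$c[i], counts$d[i])
    fit <- dpa(ct, thresholds = thresholds, ...)
    e <- fit$estimates
    data.frame(drug = counts$drug[i], pt = counts$pt[i], scope = "",
               group = "pt", a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               ror = e[["ror"]], ror_l = e[["ror_l"]], ror_u = e[["ror_u"]],
               prr = e[["prr"]], chi2 = e[["chi2"]], ic = e[["ic"]],
               ic025 = e[["ic025"]], ebgm = e[["ebgm"]], ebgm05 = e[["ebgm05"]],
               flag_ror = fit$flags[["ror"]], flag_prr = fit$flags[["prr"]],
               flag_bcpnn = fit$flags[["bcpnn"]], flag_mgps = fit$flags[["mgps"]],
               evaluable = fit$evaluable, positive = fit$positive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "drug") <- "counts table"
  class(out) <- c("signal_screen", class(out))
  out
}

#' End-to-end signal report for one target drug
#'
#' Orchestrates the pharmacovigilance half of the pipeline: read the
#' quarterly tables, clean the snapshot, split target vs background,
#' screen every PT (plus pooled SMQ groups), summarize demographics, and
#' optionally write the decision table, forest-plot export, demographics
#' table and a provenance JSON.
#'
#' @param demo_path,drug_path,reac_path FAERS-style input files.
#' @param target_names Target drug name list.
#' @param dict `smq_dictionary` (default: bundled renal narrow SMQs plus
#'   the demo SOC list).
#' @param thresholds A [signal_thresholds].
#' @param dialect A [faers_dialect].
#' @param match Drug-name matching mode.
#' @param out_dir Optional output directory.
#' @return List with `screen`, `demographics`, `target`, `background`,
#'   `provenance`.
#' @export
run_signal_report <- function(demo_path, drug_path, reac_path, target_names,
                              dict = load_smq_dictionary(soc_path = "demo"),
                              thresholds = signal_thresholds(),
                              dialect = faers_dialect(), match = "exact",
                              out_dir = NULL) {
  raw <- read_faers_quarter(demo_path, drug_path, reac_path, dialect = dialect)
  split <- split_target_background(raw$demo, raw$drug, raw$reac,
                                   target_names, match = match)
  scr <- screen_signals(split$target, split$background, dict = dict,
                        thresholds = thresholds,
                        drug = paste(target_names, collapse = "/"))
  demog <- demographics_summary(split$target)
  prov <- list(parse_log = raw$log,
               target = split$target$provenance,
               background = split$background$provenance)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    forest_export(scr, file.path(out_dir, "signal_decisions.tsv"),
                  plot_path = file.path(out_dir, "forest_ror.png"))
    utils::write.table(demog, file.path(out_dir, "demographics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(screen = scr, demographics = demog, target = split$target,
       background = split$background, provenance = prov)
}
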