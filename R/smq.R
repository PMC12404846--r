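SMQ_SCOPES <- c("aki_smq_narrow", "ckd_smq_narrow", "soc_renal_urinary")

#' Load a PT-to-SMQ scope dictionary
#'
#' The dictionary maps MedDRA preferred terms (PTs) to renal-injury scope
#' labels: `aki_smq_narrow` (acute kidney injury SMQ, narrow search, 21
#' PTs in the bundled MedDRA 26.1 fixture), `ckd_smq_narrow` (chronic
#' kidney disease SMQ, narrow, 43 PTs), and `soc_renal_urinary` (the
#' renal and urinary disorders system organ class). A PT may carry several
#' labels (e.g. Azotemia and Dialysis sit in both SMQs).
#'
#' The bundled SOC list (`soc_renal_urinary_demo.tsv`) is a small demo
#' subset — the five SOC PTs that appear in published CAR-T renal signal
#' tables — not the full ~372-PT class; supply your own SOC file for
#' complete SOC fallback reporting.
#'
#' @param path Two-column delimited file (`pt`, `scope`); default is the
#'   bundled narrow renal SMQ fixture.
#' @param soc_path Optional additional file of SOC PTs in the same format;
#'   `NULL` (default) loads no SOC list, `"demo"` loads the bundled
#'   incomplete demo subset.
#' @param version_label Free-text provenance label.
#' @return An object of class `smq_dictionary`.
#' @examples
#' dict <- load_smq_dictionary()
#' smq_counts(dict)
#' @export
load_smq_dictionary <- function(path = NULL, soc_path = NULL,
                                version_label = "MedDRA 26.1 renal narrow-SMQ fixture") {
  path <- path %||% pvmr_extdata("smq_renal_narrow.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (identical(soc_path, "demo")) soc_path <- pvmr_extdata("soc_renal_urinary_demo.tsv")
  if (!is.null(soc_path)) {
    tab <- rbind(tab, utils::read.delim(soc_path, stringsAsFactors = FALSE))
  }
  if (nrow(tab) == 0) {
    warn_pv("empty SMQ dictionary loaded from '%s'", path)
    tab <- data.frame(pt = character(), scope = character())
  }
  if (!all(c("pt", "scope") %in% names(tab)))
    stop_pv("SMQ dictionary must have columns 'pt' and 'scope'")
  bad <- setdiff(unique(tab$scope), SMQ_SCOPES)
  if (length(bad) > 0)
    stop_pv("unknown scope label(s): %s", paste(bad, collapse = ", "))
  tab$pt <- norm_display(tab$pt)
  tab$pt_key <- norm_key(tab$pt)
  dup <- duplicated(tab[c("pt_key", "scope")])
  if (any(dup)) {
    warn_pv("%d duplicate (pt, scope) row(s) collapsed", sum(dup))
    tab <- tab[!dup, ]
  }
  structure(list(table = tab, version_label = version_label,
                 has_soc = any(tab$scope == "soc_renal_urinary")),
            class = "smq_dictionary")
}

#' Per-scope PT counts of a dictionary
#' @param dict An `smq_dictionary`.
#' @return Named integer vector of distinct PTs per scope label.
#' @export
smq_counts <- function(dict) {
  stopifnot(inherits(dict, "smq_dictionary"))
  vapply(SMQ_SCOPES, function(s)
    length(unique(dict$table$pt_key[dict$table$scope == s])), integer(1))
}

#' @export
print.smq_dictionary <- function(x, ...) {
  cnt <- smq_counts(x)
  cat("SMQ dictionary:", x$version_label, "\n")
  cat(sprintf("  AKI narrow: %d PTs | CKD narrow: %d PTs | SOC renal/urinary: %d PTs%s\n",
              cnt["aki_smq_narrow"], cnt["ckd_smq_narrow"], cnt["soc_renal_urinary"],
              if (x$has_soc) "" else " (no SOC list loaded)"))
  invisible(x)
}

#' PTs belonging to a scope
#' @param dict An `smq_dictionary`.
#' @param scope One of `"aki_smq_narrow"`, `"ckd_smq_narrow"`,
#'   `"soc_renal_urinary"`.
#' @return Character vector of PTs (display casing).
#' @export
smq_pts <- function(dict, scope) {
  stopifnot(inherits(dict, "smq_dictionary"))
  scope <- match.arg(scope, SMQ_SCOPES)
  unique(dict$table$pt[dict$table$scope == scope])
}

#' Classify a preferred term into SMQ/SOC scopes
#'
#' Matching is exact after normalization (trim, collapse whitespace,
#' case-fold) — never fuzzy: FAERS reaction strings are already MedDRA
#' PTs, and fuzzy matching would inflate signal counts. The function is
#' pure and total: an unmatched PT yields an empty character vector.
#'
#' @param pt Character vector of preferred terms.
#' @param dict An `smq_dictionary`.
#' @return For a single `pt`, a character vector of scope labels; for
#'   several, a named list of such vectors.
#' @examples
#' dict <- load_smq_dictionary()
#' classify_pt("Acute kidney injury", dict)
#' classify_pt("Azotemia", dict)
#' @export
classify_pt <- function(pt, dict) {
  stopifnot(inherits(dict, "smq_dictionary"))
  keys <- norm_key(pt)
  res <- lapply(keys, function(k)
    sort(unique(dict$table$scope[dict$table$pt_key == k])))
  if (length(pt) == 1) return(res[[1]])
  names(res) <- pt
  res
}

#' SOC fallback for positive PTs outside both renal SMQs
#'
#' Returns the subset of `positive_pts` that belong to the renal and
#' urinary disorders SOC but to neither narrow SMQ — the fallback
#' presentation used when a therapy has no SMQ-level positive signal.
#'
#' @param positive_pts Character vector of PTs flagged positive.
#' @param dict An `smq_dictionary`; if no SOC list was loaded the result
#'   is empty with an explicit warning.
#' @return Character vector (display casing of the input).
#' @export
soc_fallback_pts <- function(positive_pts, dict) {
  stopifnot(inherits(dict, "smq_dictionary"))
  if (!dict$has_soc) {
    warn_pv("no SOC renal/urinary list loaded; SOC fallback is empty")
    return(character(0))
  }
  keys <- norm_key(positive_pts)
  in_scope <- function(scope) keys %in% dict$table$pt_key[dict$table$scope == scope]
  keep <- in_scope("soc_renal_urinary") & !in_scope("aki_smq_narrow") &
    !in_scope("ckd_smq_narrow")
  norm_display(positive_pts)[keep]
}
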