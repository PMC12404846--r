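#' FAERS file-format dialect
#'
#' The modern public FAERS quarterly ASCII extracts are `$`-delimited with
#' a header row; column names drift across eras (`occp_cod` vs
#' `occp_code`, `isr` vs `primaryid`). A dialect bundles the delimiter,
#' header flag and a case-insensitive synonym table so one reader covers
#' the common variants.
#'
#' @param sep Field delimiter (default `"$"`).
#' @param header Logical, files carry a header row.
#' @param synonyms Named list mapping canonical column names to accepted
#'   header spellings.
#' @return A list of class `faers_dialect`.
#' @export
faers_dialect <- function(sep = "$", header = TRUE, synonyms = NULL) {
  default_syn <- list(
    primaryid = c("primaryid", "isr"),
    caseid    = c("caseid", "case", "case_num"),
    fda_dt    = c("fda_dt", "fda_date"),
    occp_cod  = c("occp_cod", "occp_code", "occupation_cod"),
    sex       = c("sex", "gndr_cod"),
    age       = c("age"),
    age_cod   = c("age_cod", "age_unit"),
    wt        = c("wt", "weight", "wt_kg"),
    quarter   = c("quarter", "period"),
    drugname  = c("drugname", "drug_name", "medicinalproduct"),
    role_cod  = c("role_cod", "role_code"),
    pt        = c("pt", "pt_name", "reac_pt")
  )
  if (!is.null(synonyms)) default_syn[names(synonyms)] <- synonyms
  structure(list(sep = sep, header = header, synonyms = default_syn),
            class = "faers_dialect")
}

map_columns <- function(df, dialect, required, file) {
  have <- tolower(names(df))
  out <- list()
  for (canon in names(dialect$synonyms)) {
    hit <- which(have %in% tolower(dialect$synonyms[[canon]]))
    if (length(hit) > 0) out[[canon]] <- df[[hit[1]]]
  }
  missing_req <- setdiff(required, names(out))
  if (length(missing_req) > 0)
    stop_pv("file '%s' is missing mandatory column(s): %s", file,
            paste(missing_req, collapse = ", "))
  as.data.frame(out, stringsAsFactors = FALSE)
}

parse_fda_dt <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]{8}$", x) &
    !is.na(suppressWarnings(as.Date(x, format = "%Y%m%d")))
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  n_bad <- sum(!ok & nzchar(x) & !is.na(x))
  list(value = out, n_unparseable = n_bad)
}

read_one <- function(path, dialect) {
  if (!file.exists(path)) stop_pv("input file not found: %s", path)
  utils::read.table(path, sep = dialect$sep, header = dialect$header,
                    quote = "", comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE)
}

#' Read one FAERS-style quarter (DEMO, DRUG, REAC tables)
#'
#' Parses the three case-level tables, standardizes column names through
#' the dialect's synonym map (case-insensitively), coerces receipt dates,
#' and normalizes reaction strings. Unparseable `fda_dt` values become
#' missing and are counted in the returned `log`; reaction rows whose PT
#' is empty after whitespace normalization are dropped and counted.
#'
#' @param demo_path,drug_path,reac_path Paths to the three tables.
#' @param dialect A [faers_dialect].
#' @return List with data frames `demo` (`primaryid`, `caseid`, `fda_dt`,
#'   `occp_cod`, `sex`, `age_yr`, `wt`, `quarter`), `drug` (`primaryid`,
#'   `drugname`, `role_cod`), `reac` (`primaryid`, `pt`), and a `log` of
#'   parse counters.
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path,
                               dialect = faers_dialect()) {
  logc <- list()
  demo_raw <- read_one(demo_path, dialect)
  drug_raw <- read_one(drug_path, dialect)
  reac_raw <- read_one(reac_path, dialect)
  for (nm in c("demo", "drug", "reac")) {
    raw <- get(paste0(nm, "_raw"))
    if (nrow(raw) == 0) warn_pv("%s file has no data rows", nm)
  }

  demo <- map_columns(demo_raw, dialect, c("primaryid", "caseid"), demo_path)
  dt <- parse_fda_dt(demo$fda_dt %||% rep(NA, nrow(demo)))
  logc$demo_unparseable_dates <- dt$n_unparseable
  demo <- data.frame(
    primaryid = trimws(demo$primaryid),
    caseid = trimws(demo$caseid),
    fda_dt = dt$value,
    occp_cod = toupper(trimws(demo$occp_cod %||% rep(NA_character_, nrow(demo)))),
    sex = toupper(trimws(demo$sex %||% rep(NA_character_, nrow(demo)))),
    age_yr = age_to_years(demo$age %||% rep(NA, nrow(demo)),
                          demo$age_cod %||% rep("YR", nrow(demo))),
    wt = suppressWarnings(as.numeric(demo$wt %||% rep(NA, nrow(demo)))),
    quarter = demo$quarter %||% rep(NA_character_, nrow(demo)),
    stringsAsFactors = FALSE)
  demo$occp_cod[!nzchar(demo$occp_cod) | demo$occp_cod == "NA"] <- NA_character_
  demo$sex[!demo$sex %in% c("F", "M")] <- NA_character_

  drug <- map_columns(drug_raw, dialect, c("primaryid", "drugname"), drug_path)
  role <- toupper(trimws(drug$role_cod %||% rep(NA_character_, nrow(drug))))
  bad_role <- !is.na(role) & nzchar(role) & !role %in% c("PS", "SS", "C", "I")
  logc$drug_unknown_roles <- sum(bad_role)
  role[bad_role | !nzchar(role)] <- NA_character_
  drug <- data.frame(primaryid = trimws(drug$primaryid),
                     drugname = norm_display(drug$drugname),
                     role_cod = role, stringsAsFactors = FALSE)

  reac <- map_columns(reac_raw, dialect, c("primaryid", "pt"), reac_path)
  reac <- data.frame(primaryid = trimws(reac$primaryid),
                     pt = norm_display(reac$pt), stringsAsFactors = FALSE)
  empty_pt <- !nzchar(reac$pt)
  logc$reac_empty_pts <- sum(empty_pt)
  reac <- reac[!empty_pt, , drop = FALSE]

  list(demo = demo, drug = drug, reac = reac, log = logc)
}

# Coerce an arbitrary demographics frame to the standard case schema
# (primaryid, caseid, fda_dt, occp_cod, sex, age_yr, wt, quarter), deriving
# age_yr from age/age_cod when needed.
normalize_demo <- function(demo) {
  if (!"primaryid" %in% names(demo)) stop_pv("demo table lacks 'primaryid'")
  n <- nrow(demo)
  if (is.null(demo$caseid)) demo$caseid <- demo$primaryid
  if (is.null(demo$fda_dt)) demo$fda_dt <- rep(NA_integer_, n)
  if (is.null(demo$occp_cod)) demo$occp_cod <- rep(NA_character_, n)
  if (is.null(demo$sex)) demo$sex <- rep(NA_character_, n)
  if (is.null(demo$wt)) demo$wt <- rep(NA_real_, n)
  if (is.null(demo$quarter)) demo$quarter <- rep(NA_character_, n)
  if (is.null(demo$age_yr)) {
    demo$age_yr <- if (!is.null(demo$age))
      age_to_years(demo$age, demo$age_cod %||% rep("YR", n))
    else rep(NA_real_, n)
  }
  demo[c("primaryid", "caseid", "fda_dt", "occp_cod", "sex", "age_yr",
         "wt", "quarter")]
}

age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  cod[is.na(cod) | !nzchar(cod)] <- "YR"
  div <- c(YR = 1, DEC = 0.1, MON = 12, WK = 52.1429, DY = 365.25, HR = 8766)
  f <- div[cod]
  f[is.na(f)] <- 1
  age / f
}

#' Deduplicate case reports by CASEID
#'
#' FDA de-duplication rule for spontaneous reports: among records sharing
#' a CASEID keep the one with the most recent FDA receipt date
#' (`fda_dt`); if dates tie, keep the higher PRIMARYID (numeric
#' comparison when all ids are numeric, lexicographic otherwise). Records
#' with a missing date lose ties to any dated record. Output rows are
#' sorted by `caseid`; the operation is idempotent.
#'
#' @param demo Demographics data frame with `primaryid`, `caseid`,
#'   `fda_dt`.
#' @return The deduplicated data frame (one row per `caseid`).
#' @export
deduplicate_cases <- function(demo) {
  if (nrow(demo) == 0) return(demo)
  dt <- ifelse(is.na(demo$fda_dt), -Inf, demo$fda_dt)
  pid <- demo$primaryid
  num <- suppressWarnings(as.numeric(pid))
  pid_rank <- if (!anyNA(num)) order(order(num)) else order(order(pid))
  ord <- order(demo$caseid, dt, pid_rank)
  demo <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Primary-suspect filter for a target drug
#'
#' Returns the case keys having at least one drug row that matches one of
#' the target names with role code `PS` (primary suspect). Secondary
#' suspect, concomitant and interacting mentions never qualify. Matching
#' is case-insensitive on whitespace-normalized names; with
#' `match = "substring"` a target name may occur anywhere inside the
#' verbatim drug string (useful for brand/generic free text).
#'
#' @param drug Drug data frame (`primaryid`, `drugname`, `role_cod`).
#' @param target_names Non-empty character vector of generic and brand
#'   names.
#' @param match `"exact"` (default) or `"substring"`.
#' @return Character vector of unique primaryids.
#' @export
filter_primary_suspect <- function(drug, target_names,
                                   match = c("exact", "substring")) {
  match <- match.arg(match)
  target_names <- target_names[nzchar(norm_display(target_names))]
  if (length(target_names) == 0)
    stop_pv("target_names must not be empty (refusing to match every drug)")
  keys <- unique(norm_key(target_names))
  name_key <- norm_key(drug$drugname)
  hit <- if (match == "exact") {
    name_key %in% keys
  } else {
    Reduce(`|`, lapply(keys, function(k) grepl(k, name_key, fixed = TRUE)))
  }
  ps <- !is.na(drug$role_cod) & drug$role_cod == "PS"
  unique(drug$primaryid[hit & ps])
}

#' Reporter-occupation filter
#'
#' Keeps reports filed by healthcare practitioners: physicians (MD),
#' health professionals (HP), pharmacists (PH), registered nurses (RN)
#' and other health professionals (OT). Consumer/lawyer/missing
#' occupations are removed; the removal count is attached as attribute
#' `n_removed`.
#'
#' @param demo Demographics data frame with `occp_cod`.
#' @param allowed Allowed occupation codes.
#' @return Filtered data frame.
#' @export
filter_reporter_occupation <- function(demo,
                                       allowed = c("MD", "HP", "PH", "RN", "OT")) {
  keep <- !is.na(demo$occp_cod) & demo$occp_cod %in% allowed
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assemble a cleaned case-level analysis set
#'
#' Applies the cleaning cascade in a fixed order — target-drug
#' primary-suspect filter (skipped when `target_names` is `NULL`, e.g.
#' for an all-drug background set), reporter-occupation filter, then
#' CASEID deduplication — and joins each surviving case's set of reaction
#' PTs. Cases with no reaction rows are retained (they belong in the
#' denominators) and flagged via `no_reaction`. Per-step removal counts
#' are recorded in `provenance`.
#'
#' @param demo,drug,reac Standardized tables as returned by
#'   [read_faers_quarter()].
#' @param target_names Target drug names for the PS filter, or `NULL` for
#'   no drug restriction.
#' @param match Name-matching mode, see [filter_primary_suspect()].
#' @param occupation_allowed Occupation allow-list.
#' @return An object of class `case_set`: `cases` (one row per case),
#'   `pts` (case-PT pairs), `provenance`, `quarter_range`.
#' @export
assemble_case_set <- function(demo, drug, reac, target_names = NULL,
                              match = "exact",
                              occupation_allowed = c("MD", "HP", "PH", "RN", "OT")) {
  demo <- normalize_demo(demo)
  prov <- list(n_input = nrow(demo))
  cur <- demo
  if (!is.null(target_names)) {
    ids <- filter_primary_suspect(drug, target_names, match = match)
    cur <- cur[cur$primaryid %in% ids, , drop = FALSE]
  }
  prov$removed_not_target_ps <- prov$n_input - nrow(cur)
  cur <- filter_reporter_occupation(cur, allowed = occupation_allowed)
  prov$removed_occupation <- attr(cur, "n_removed")
  n_before <- nrow(cur)
  cur <- deduplicate_cases(cur)
  prov$removed_duplicates <- n_before - nrow(cur)
  prov$n_final <- nrow(cur)
  if (nrow(cur) == 0) warn_pv("no cases survive the cleaning cascade")

  pts <- reac[reac$primaryid %in% cur$primaryid, c("primaryid", "pt"), drop = FALSE]
  pts$pt_key <- norm_key(pts$pt)
  pts <- unique(pts)
  rownames(pts) <- NULL
  cur$no_reaction <- !cur$primaryid %in% pts$primaryid
  prov$n_no_reaction <- sum(cur$no_reaction)
  qr <- if (all(is.na(cur$quarter))) c(NA_character_, NA_character_)
        else range(cur$quarter, na.rm = TRUE)
  structure(list(cases = cur, pts = pts, provenance = prov, quarter_range = qr),
            class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("case_set: %d cases (from %d records; -%d non-target/non-PS, -%d occupation, -%d duplicates)\n",
              p$n_final, p$n_input, p$removed_not_target_ps,
              p$removed_occupation, p$removed_duplicates))
  cat(sprintf("  %d distinct case-PT pairs; %d case(s) without reactions; quarters %s-%s\n",
              nrow(x$pts), p$n_no_reaction, x$quarter_range[1], x$quarter_range[2]))
  invisible(x)
}

# Subset a case_set to (or excluding) a set of primaryids.
subset_case_set <- function(cs, ids, exclude = FALSE) {
  keep <- cs$cases$primaryid %in% ids
  if (exclude) keep <- !keep
  cases <- cs$cases[keep, , drop = FALSE]
  pts <- cs$pts[cs$pts$primaryid %in% cases$primaryid, , drop = FALSE]
  rownames(cases) <- rownames(pts) <- NULL
  prov <- cs$provenance
  prov$n_final <- nrow(cases)
  structure(list(cases = cases, pts = pts, provenance = prov,
                 quarter_range = cs$quarter_range), class = "case_set")
}

#' Split a cleaned snapshot into target-drug and background case sets
#'
#' Cleans the full snapshot once (occupation filter + deduplication, no
#' drug restriction), then splits it by target-drug membership so the
#' background comparator contains every non-target case from the same
#' quarter range and the two sets never share a case key.
#'
#' @inheritParams assemble_case_set
#' @return List with `target` and `background` case sets.
#' @export
split_target_background <- function(demo, drug, reac, target_names,
                                    match = "exact",
                                    occupation_allowed = c("MD", "HP", "PH", "RN", "OT")) {
  all_cs <- assemble_case_set(demo, drug, reac, target_names = NULL,
                              occupation_allowed = occupation_allowed)
  ids <- filter_primary_suspect(drug, target_names, match = match)
  list(target = subset_case_set(all_cs, ids),
       background = subset_case_set(all_cs, ids, exclude = TRUE))
}

#' Serialize a case set
#'
#' Writes a tidy delimited table (one row per case-PT pair; reaction-free
#' cases get an empty PT) and a provenance JSON with per-step removal
#' counts.
#'
#' @param cs A `case_set`.
#' @param path Output path for the table; provenance goes to
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_case_set <- function(cs, path) {
  stopifnot(inherits(cs, "case_set"))
  merged <- merge(cs$cases, cs$pts[c("primaryid", "pt")],
                  by = "primaryid", all.x = TRUE, sort = TRUE)
  utils::write.table(merged, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cs$provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
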