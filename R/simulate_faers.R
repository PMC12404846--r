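default_pt_vocabulary <- function() {
  pt <- c("Pyrexia", "Cytokine release syndrome", "Fatigue", "Neutropenia",
          "Anaemia", "Headache", "Nausea", "Diarrhoea", "Hypotension",
          "Tremor", "Confusional state", "Thrombocytopenia",
          "Febrile neutropenia", "Hypoxia", "Encephalopathy", "Sepsis",
          "Pneumonia", "Vomiting", "Oedema peripheral", "Rash", "Dyspnoea",
          "Tachycardia", "Hypokalaemia", "Chills", "Aphasia", "Seizure",
          "Hypogammaglobulinaemia", "Device related infection",
          "Blood creatinine increased",
          "Acute kidney injury", "Renal failure", "Renal impairment",
          "Chronic kidney disease", "Dialysis", "Anuria", "Oliguria",
          "Azotemia", "Urinary incontinence", "Urinary hesitation",
          "Kidney enlargement", "Renal tubular necrosis")
  freq <- c(9, 8, 6, 5, 5, 5, 4, 4, 4, 3, 3, 3, 3, 2, 2, 2, 2, 2, 2, 2, 2,
            1.5, 1.5, 1, 1, 1, 1, 1, 0.4,
            0.5, 0.4, 0.3, 0.3, 0.2, 0.1, 0.2, 0.1, 0.3, 0.1, 0.05, 0.05) / 100
  data.frame(pt = pt, freq = freq / sum(freq), stringsAsFactors = FALSE)
}

#' Configuration for the FAERS-like report simulator
#'
#' Defaults emulate a moderate post-marketing surveillance window for one
#' CAR-T-like product: 2,000 target-drug reports against a 50,000-report
#' background spread over 6 comparator drugs, a PT vocabulary dominated by
#' common infusion/cytopenia events with renal PTs at background rates of
#' a few per thousand, 5% duplicated cases, and reporter/sex/age/weight
#' mixes resembling spontaneous-report data (including consumer reports
#' and missingness that the cleaning cascade must remove).
#'
#' @param seed Integer RNG seed (all randomness flows from it).
#' @param n_drugs Number of background comparator drugs.
#' @param n_background_reports,target_drug_reports Report counts.
#' @param target_drug Name of the simulated target drug.
#' @param pt_vocabulary Data frame (`pt`, `freq`); frequencies are
#'   normalized to sum to one.
#' @param planted_signals List of `list(drug=, pt=, rr=)`: within the
#'   named drug's reports the PT's probability is multiplied by the
#'   reporting-rate ratio `rr` and the vector renormalized.
#' @param duplicate_fraction Fraction of cases emitted twice (same
#'   CASEID; half the duplicates carry a later `fda_dt`, half the same
#'   date with a higher PRIMARYID, exercising both deduplication rules).
#' @param mean_extra_pts Mean number of additional PTs per report beyond
#'   the first (Poisson).
#' @param occupation_mix,sex_mix Named probability vectors (`"missing"`
#'   allowed as a level).
#' @param quarters Quarter labels covered by the snapshot.
#' @return A validated list of class `faers_sim_config`.
#' @export
faers_sim_config <- function(seed = 1, n_drugs = 6,
                             n_background_reports = 50000,
                             target_drug_reports = 2000,
                             target_drug = "TARGETLEUCEL",
                             pt_vocabulary = default_pt_vocabulary(),
                             planted_signals = list(),
                             duplicate_fraction = 0.05,
                             mean_extra_pts = 0.8,
                             occupation_mix = c(MD = 0.30, HP = 0.18, PH = 0.08,
                                                RN = 0.12, OT = 0.10, CN = 0.15,
                                                LW = 0.02, missing = 0.05),
                             sex_mix = c(F = 0.42, M = 0.53, missing = 0.05),
                             quarters = c("2023Q1", "2023Q2", "2023Q3",
                                          "2023Q4", "2024Q1")) {
  cfg <- list(seed = seed, n_drugs = n_drugs,
              n_background_reports = n_background_reports,
              target_drug_reports = target_drug_reports,
              target_drug = target_drug, pt_vocabulary = pt_vocabulary,
              planted_signals = planted_signals,
              duplicate_fraction = duplicate_fraction,
              mean_extra_pts = mean_extra_pts,
              occupation_mix = occupation_mix, sex_mix = sex_mix,
              quarters = quarters)
  if (!is.data.frame(pt_vocabulary) || !all(c("pt", "freq") %in% names(pt_vocabulary)))
    stop_pv("invalid config field 'pt_vocabulary': need columns pt, freq")
  if (any(pt_vocabulary$freq <= 0)) stop_pv("invalid config field 'pt_vocabulary': non-positive freq")
  cfg$pt_vocabulary$freq <- pt_vocabulary$freq / sum(pt_vocabulary$freq)
  if (duplicate_fraction < 0 || duplicate_fraction >= 1)
    stop_pv("invalid config field 'duplicate_fraction': must be in [0, 1)")
  for (ps in planted_signals) {
    if (!all(c("drug", "pt", "rr") %in% names(ps)) || ps$rr <= 0)
      stop_pv("invalid config field 'planted_signals': each needs drug, pt, rr > 0")
    if (!ps$pt %in% cfg$pt_vocabulary$pt)
      stop_pv("invalid config field 'planted_signals': pt '%s' not in vocabulary", ps$pt)
  }
  for (nm in c("occupation_mix", "sex_mix"))
    if (any(cfg[[nm]] < 0) || abs(sum(cfg[[nm]]) - 1) > 1e-6)
      stop_pv("invalid config field '%s': probabilities must sum to 1", nm)
  structure(cfg, class = "faers_sim_config")
}

quarter_dates <- function(q) {
  yr <- as.integer(substr(q, 1, 4))
  qu <- as.integer(substr(q, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", yr, (qu - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(start, end)
}

#' Simulate a FAERS-like quarterly snapshot with known ground truth
#'
#' Generates DEMO/DRUG/REAC tables in the dialect [read_faers_quarter()]
#' consumes. Target-drug reports carry the target drug as primary
#' suspect; background reports carry one of the comparator drugs.
#' Planted (drug, PT, rate-ratio) signals scale that drug's PT
#' probability before renormalization, so expected cell counts are
#' computable from the returned manifest. A configured fraction of cases
#' is emitted twice with the same CASEID (later date or same date +
#' higher PRIMARYID) to exercise deduplication, and a mix of consumer /
#' missing occupations exercises the reporter filter.
#'
#' @param config A [faers_sim_config].
#' @param dir Optional directory: writes `demo.txt`, `drug.txt`,
#'   `reac.txt` (`$`-delimited) and `manifest.json`.
#' @return List with `demo`, `drug`, `reac` data frames and `manifest`
#'   (ground truth: per-drug report counts and PT probability vectors,
#'   planted signals, seed).
#' @export
simulate_faers <- function(config = faers_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "faers_sim_config"))
  with_seed(config$seed, simulate_faers_impl(config, dir))
}

simulate_faers_impl <- function(cfg, dir) {
  bg_drugs <- sprintf("COMPARATOR_%02d", seq_len(cfg$n_drugs))
  n_bg <- cfg$n_background_reports
  n_tg <- cfg$target_drug_reports
  n <- n_bg + n_tg
  drug_of <- c(sample(bg_drugs, n_bg, replace = TRUE), rep(cfg$target_drug, n_tg))

  # per-drug PT probability vectors (planted signals renormalized in)
  vocab <- cfg$pt_vocabulary
  prob_for <- list(baseline = vocab$freq)
  for (ps in cfg$planted_signals) {
    p <- prob_for[[ps$drug]] %||% vocab$freq
    p[vocab$pt == ps$pt] <- p[vocab$pt == ps$pt] * ps$rr
    prob_for[[ps$drug]] <- p / sum(p)
  }

  ids <- as.character(100000000 + seq_len(n))
  quarter <- sample(cfg$quarters, n, replace = TRUE)
  dt <- vapply(cfg$quarters, function(q) {
    r <- quarter_dates(q)
    as.integer(r[1])
  }, integer(1))
  span <- vapply(cfg$quarters, function(q) {
    r <- quarter_dates(q)
    as.integer(r[2] - r[1])
  }, integer(1))
  date0 <- dt[quarter] + sample.int(90, n, replace = TRUE) %% (span[quarter] + 1)
  fda_dt <- as.integer(format(as.Date(date0, origin = "1970-01-01"), "%Y%m%d"))

  draw_mix <- function(mix, n) {
    lv <- names(mix)
    x <- sample(lv, n, replace = TRUE, prob = mix)
    x[x == "missing"] <- NA_character_
    x
  }
  occ <- draw_mix(cfg$occupation_mix, n)
  sex <- draw_mix(cfg$sex_mix, n)
  age_band <- sample(c("<18", "18-59", "60-69", "70-79", ">=80", "missing"), n,
                     replace = TRUE, prob = c(0.07, 0.30, 0.28, 0.20, 0.07, 0.08))
  age_lo <- c("<18" = 1, "18-59" = 18, "60-69" = 60, "70-79" = 70, ">=80" = 80)
  age_hi <- c("<18" = 17, "18-59" = 59, "60-69" = 69, "70-79" = 79, ">=80" = 94)
  age <- rep(NA_real_, n)
  known <- age_band != "missing"
  age[known] <- round(stats::runif(sum(known), age_lo[age_band[known]],
                                   age_hi[age_band[known]] + 1))
  wt <- round(stats::rnorm(n, 75, 15), 1)
  wt[wt < 30] <- 30
  wt[stats::runif(n) < 0.2] <- NA_real_

  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = fda_dt,
                     occp_cod = occ, sex = sex, age = age, age_cod = "YR",
                     wt = wt, quarter = quarter, stringsAsFactors = FALSE)

  # reactions: 1 + Poisson extra PTs per report, drug-specific PT probs
  n_pts <- 1L + stats::rpois(n, cfg$mean_extra_pts)
  reac_list <- lapply(unique(drug_of), function(g) {
    idx <- which(drug_of == g)
    p <- prob_for[[g]] %||% prob_for$baseline
    k <- n_pts[idx]
    data.frame(primaryid = rep(ids[idx], k),
               pt = sample(vocab$pt, sum(k), replace = TRUE, prob = p),
               stringsAsFactors = FALSE)
  })
  reac <- do.call(rbind, reac_list)

  # drug rows: own drug as PS; occasional concomitant mentions
  drug_rows <- data.frame(primaryid = ids, drugname = drug_of,
                          role_cod = "PS", stringsAsFactors = FALSE)
  conc_idx <- which(stats::runif(n) < 0.25)
  if (length(conc_idx) > 0) {
    conc_name <- ifelse(drug_of[conc_idx] == cfg$target_drug,
                        sample(bg_drugs, length(conc_idx), replace = TRUE),
                        ifelse(stats::runif(length(conc_idx)) < 0.1,
                               cfg$target_drug,
                               sample(bg_drugs, length(conc_idx), replace = TRUE)))
    drug_rows <- rbind(drug_rows,
                       data.frame(primaryid = ids[conc_idx], drugname = conc_name,
                                  role_cod = "C", stringsAsFactors = FALSE))
  }

  # duplicates: same caseid, higher primaryid; half later fda_dt, half tied
  n_dup <- floor(cfg$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    later <- rep(c(TRUE, FALSE), length.out = n_dup)
    dup_ids <- as.character(100000000 + n + seq_len(n_dup))
    dup_demo <- demo[dup_idx, , drop = FALSE]
    dup_demo$primaryid <- dup_ids
    new_dt <- as.integer(format(as.Date(as.character(dup_demo$fda_dt),
                                        "%Y%m%d") + 21, "%Y%m%d"))
    dup_demo$fda_dt <- ifelse(later, new_dt, dup_demo$fda_dt)
    demo <- rbind(demo, dup_demo)
    remap <- function(df) {
      sel <- df$primaryid %in% ids[dup_idx]
      dd <- df[sel, , drop = FALSE]
      dd$primaryid <- dup_ids[match(dd$primaryid, ids[dup_idx])]
      rbind(df, dd)
    }
    drug_rows <- remap(drug_rows)
    reac <- remap(reac)
  }
  rownames(demo) <- rownames(drug_rows) <- rownames(reac) <- NULL

  manifest <- list(seed = cfg$seed, target_drug = cfg$target_drug,
                   background_drugs = bg_drugs,
                   n_background_reports = n_bg, target_drug_reports = n_tg,
                   duplicate_fraction = cfg$duplicate_fraction,
                   n_duplicates = n_dup,
                   mean_extra_pts = cfg$mean_extra_pts,
                   planted_signals = cfg$planted_signals,
                   pt_probabilities = c(list(baseline = stats::setNames(
                     prob_for$baseline, vocab$pt)),
                     lapply(prob_for[setdiff(names(prob_for), "baseline")],
                            function(p) stats::setNames(p, vocab$pt))))
  out <- list(demo = demo, drug = drug_rows, reac = reac, manifest = manifest)
  if (!is.null(dir)) write_faers_sim(out, dir)
  out
}

#' Write a simulated snapshot as dialect-conformant files
#'
#' @param sim Result of [simulate_faers()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_faers_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) utils::write.table(
    df, file.path(dir, file), sep = "$", row.names = FALSE, quote = FALSE,
    na = "")
  w(sim$demo, "demo.txt")
  w(sim$drug, "drug.txt")
  w(sim$reac, "reac.txt")
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
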