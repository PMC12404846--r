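#' Screen every observed PT (and pooled SMQ groups) for a drug
#'
#' Builds a 2x2 table for each preferred term observed among the target
#' drug's cases against the background comparator, fits the four
#' disproportionality algorithms with [dpa()], and applies the decision
#' thresholds. When a dictionary is supplied, each PT is annotated with
#' its SMQ/SOC scope labels and, with `smq_pool = TRUE`, two additional
#' pooled rows screen the whole AKI-narrow and CKD-narrow PT sets as
#' single composite events.
#'
#' Rows are ordered positives first (descending ROR), then the remainder
#' alphabetically by PT.
#'
#' @param drug_cases,background Target-drug and comparator [case_set]s
#'   (disjoint case keys, same quarter range).
#' @param dict Optional `smq_dictionary` for scope annotation.
#' @param thresholds A [signal_thresholds] object.
#' @param smq_pool Also screen the pooled AKI/CKD SMQ groups.
#' @param drug Label used in the output.
#' @param ... Passed to [dpa()] (e.g. `z_ebgm05`).
#' @return A data frame of class `signal_screen` with counts, statistics,
#'   per-algorithm flags, `evaluable` and `positive` per row.
#' @export
screen_signals <- function(drug_cases, background, dict = NULL,
                           thresholds = signal_thresholds(), smq_pool = TRUE,
                           drug = "target drug", ...) {
  stopifnot(inherits(drug_cases, "case_set"), inherits(background, "case_set"))
  n_a <- nrow(drug_cases$cases)
  n_b <- nrow(background$cases)
  overlap <- intersect(drug_cases$cases$primaryid, background$cases$primaryid)
  if (length(overlap) > 0)
    stop_pv("drug cases and background share %d case key(s)", length(overlap))

  # one pass over the pair tables: distinct cases per pt_key
  count_by_pt <- function(cs) {
    if (nrow(cs$pts) == 0) return(integer(0))
    tab <- table(unique(cs$pts[c("primaryid", "pt_key")])$pt_key)
    stats::setNames(as.integer(tab), names(tab))
  }
  cnt_drug <- count_by_pt(drug_cases)
  cnt_bg <- count_by_pt(background)

  pt_tab <- unique(drug_cases$pts[c("pt", "pt_key")])
  rows <- lapply(seq_len(nrow(pt_tab)), function(i) {
    k <- pt_tab$pt_key[i]
    a <- unname(cnt_drug[k])
    c_ <- unname(cnt_bg[k]) %||% 0L
    if (is.na(c_)) c_ <- 0L
    list(pt = pt_tab$pt[i], pt_key = k, group = "pt",
         counts = contingency_counts(a, n_a - a, c_, n_b - c_))
  })

  if (smq_pool && !is.null(dict)) {
    for (scope in c("aki_smq_narrow", "ckd_smq_narrow")) {
      pts <- smq_pts(dict, scope)
      if (length(pts) == 0) next
      label <- if (scope == "aki_smq_narrow") "AKI (SMQ narrow, pooled)"
               else "CKD (SMQ narrow, pooled)"
      rows <- c(rows, list(list(pt = label, pt_key = NA_character_,
                                group = scope,
                                counts = build_contingency(drug_cases, background, pts))))
    }
  }
  if (length(rows) == 0) {
    out <- empty_screen_frame()
    attr(out, "drug") <- drug
    class(out) <- c("signal_screen", class(out))
    return(out)
  }

  recs <- lapply(rows, function(r) {
    fit <- dpa(r$counts, thresholds = thresholds, ...)
    scope <- if (!is.null(dict) && r$group == "pt") {
      paste(classify_pt(r$pt, dict), collapse = ";")
    } else if (r$group != "pt") r$group else ""
    e <- fit$estimates
    data.frame(drug = drug, pt = r$pt, scope = scope, group = r$group,
               a = r$counts$a, b = r$counts$b, c = r$counts$c, d = r$counts$d,
               ror = e[["ror"]], ror_l = e[["ror_l"]], ror_u = e[["ror_u"]],
               prr = e[["prr"]], chi2 = e[["chi2"]],
               ic = e[["ic"]], ic025 = e[["ic025"]],
               ebgm = e[["ebgm"]], ebgm05 = e[["ebgm05"]],
               flag_ror = fit$flags[["ror"]], flag_prr = fit$flags[["prr"]],
               flag_bcpnn = fit$flags[["bcpnn"]], flag_mgps = fit$flags[["mgps"]],
               evaluable = fit$evaluable, positive = fit$positive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  pos <- out$positive
  ord <- c(which(pos)[order(-out$ror[pos])], which(!pos)[order(out$pt[!pos])])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug") <- drug
  class(out) <- c("signal_screen", class(out))
  out
}

empty_screen_frame <- function() {
  data.frame(drug = character(), pt = character(), scope = character(),
             group = character(), a = numeric(), b = numeric(), c = numeric(),
             d = numeric(), ror = numeric(), ror_l = numeric(), ror_u = numeric(),
             prr = numeric(), chi2 = numeric(), ic = numeric(), ic025 = numeric(),
             ebgm = numeric(), ebgm05 = numeric(), flag_ror = logical(),
             flag_prr = logical(), flag_bcpnn = logical(), flag_mgps = logical(),
             evaluable = logical(), positive = logical(), stringsAsFactors = FALSE)
}

#' @export
print.signal_screen <- function(x, ...) {
  cat(sprintf("signal screen for %s: %d PT(s), %d positive under the %s\n",
              attr(x, "drug") %||% "drug", sum(x[["group"]] == "pt"),
              sum(x[["positive"]]), "configured combination rule"))
  want <- c("pt", "a", "ror", "ror_l", "ror_u", "prr", "chi2", "ic", "ic025",
            "ebgm", "ebgm05", "positive")
  df <- as.data.frame(x)[, intersect(want, names(x)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = 2)
  print(utils::head(df, 25), row.names = FALSE)
  if (nrow(df) > 25) cat("  ...", nrow(df) - 25, "more rows\n")
  invisible(x)
}

#' Export screen decisions as a forest-plot table (and optional plot)
#'
#' Writes a tidy delimited table (one row per decision: counts, the four
#' statistics with bounds, flags, positivity) and optionally a forest
#' plot of the ROR with its 95% CI per PT.
#'
#' @param decisions A `signal_screen` data frame (rows from several drugs
#'   may be concatenated).
#' @param path Output TSV path.
#' @param plot_path Optional PNG path for the forest plot.
#' @return `path`, invisibly.
#' @export
forest_export <- function(decisions, path, plot_path = NULL) {
  df <- as.data.frame(decisions)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(plot_path) && nrow(df) > 0) {
    grDevices::png(plot_path, width = 900, height = 160 + 40 * nrow(df), res = 110)
    on.exit(grDevices::dev.off())
    plot_forest(df)
  }
  invisible(path)
}

plot_forest <- function(df) {
  df <- df[rev(seq_len(nrow(df))), ]
  ok <- is.finite(df$ror)
  xlim <- range(c(df$ror_l[ok], df$ror_u[ok], 1), na.rm = TRUE)
  y <- seq_len(nrow(df))
  op <- graphics::par(mar = c(4, 16, 2, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(df$ror, y, log = "x", xlim = xlim, pch = 15,
                 col = ifelse(df$positive, "firebrick", "grey30"),
                 yaxt = "n", ylab = "", xlab = "ROR (95% CI, log scale)")
  graphics::segments(df$ror_l, y, df$ror_u, y)
  graphics::abline(v = 1, lty = 2, col = "grey60")
  graphics::axis(2, at = y, labels = paste(df$drug, df$pt, sep = ": "),
                 las = 1, cex.axis = 0.7)
}

#' Demographic summary of a cleaned case set
#'
#' Counts and proportions by sex, age band (<18, 18-59, 60-69, 70-79,
#' >=80 years), weight band (<60, 60-79, 80-99, >=100 kg) and reporter
#' occupation; missing values are tallied as their own level.
#' Proportions are computed over all cases, missing included.
#'
#' @param cs A `case_set`.
#' @return Data frame with columns `variable`, `level`, `n`, `prop`.
#' @export
demographics_summary <- function(cs) {
  stopifnot(inherits(cs, "case_set"))
  d <- cs$cases
  n <- nrow(d)
  band <- function(x, breaks, labels) {
    out <- as.character(cut(as.numeric(x), breaks = breaks, labels = labels,
                            right = FALSE))
    out[is.na(out)] <- "missing"
    out
  }
  lev <- list(
    sex = ifelse(is.na(d$sex), "missing", d$sex),
    age_band = band(d$age_yr, c(0, 18, 60, 70, 80, Inf),
                    c("<18", "18-59", "60-69", "70-79", ">=80")),
    weight_band = band(d$wt, c(0, 60, 80, 100, Inf),
                       c("<60", "60-79", "80-99", ">=100")),
    occupation = ifelse(is.na(d$occp_cod), "missing", d$occp_cod)
  )
  out <- do.call(rbind, lapply(names(lev), function(v) {
    tab <- table(lev[[v]])
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               prop = as.numeric(tab) / max(n, 1), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
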