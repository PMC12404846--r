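#' Signal-detection thresholds for the four disproportionality algorithms
#'
#' Defaults follow the conventional per-algorithm criteria: ROR lower 95%
#' bound > 1 with a >= 3; PRR >= 2 with chi-squared >= 4 and a >= 3;
#' IC025 > 0; EBGM05 > 2. A (drug, PT) pair is declared positive when the
#' configured combination of flags holds (`"all"` four by default, or
#' `"any"`).
#'
#' @param min_a Minimum case count `a` for a pair to be evaluable.
#' @param ror_ci_lower ROR is flagged when its CI lower bound exceeds this.
#' @param prr_min,chi2_min PRR flag requires PRR >= `prr_min` and
#'   chi-squared >= `chi2_min`.
#' @param ic025_min BCPNN flag requires IC025 > this.
#' @param ebgm05_min MGPS flag requires EBGM05 > this.
#' @param combination `"all"` (every algorithm must flag) or `"any"`.
#' @return A list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(min_a = 3, ror_ci_lower = 1, prr_min = 2,
                              chi2_min = 4, ic025_min = 0, ebgm05_min = 2,
                              combination = c("all", "any")) {
  combination <- match.arg(combination)
  structure(list(min_a = min_a, ror_ci_lower = ror_ci_lower,
                 prr_min = prr_min, chi2_min = chi2_min,
                 ic025_min = ic025_min, ebgm05_min = ebgm05_min,
                 combination = combination),
            class = "signal_thresholds")
}

undefined_stat <- function(reason, ...) {
  out <- list(...)
  out[] <- NA_real_
  out$defined <- FALSE
  out$reason <- reason
  out
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad / (bc); CI = exp(ln ROR +/- z * s) with
#' s = sqrt(1/a + 1/b + 1/c + 1/d). Undefined (with a reason, never a
#' silent infinity) when any cell is zero.
#'
#' @param t A [contingency_counts] object.
#' @param z Normal quantile for the two-sided CI (default 1.96).
#' @return List with `ror`, `ci_low`, `ci_high`, `defined`, `reason`.
#' @export
compute_ror <- function(t, z = 1.96) {
  stopifnot(inherits(t, "contingency_counts"))
  if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0)
    return(undefined_stat("zero cell", ror = NA, ci_low = NA, ci_high = NA))
  ror <- (t$a * t$d) / (t$b * t$c)
  s <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(ror = ror, ci_low = exp(log(ror) - z * s), ci_high = exp(log(ror) + z * s),
       defined = TRUE, reason = NA_character_)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' PRR = a(c+d) / (c(a+b)); the chi-squared statistic is the 2x2 Pearson
#' statistic without continuity correction,
#' (ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @inheritParams compute_ror
#' @return List with `prr`, `chi2`, `defined`, `reason`.
#' @export
compute_prr <- function(t) {
  stopifnot(inherits(t, "contingency_counts"))
  if (t$c == 0 || (t$a + t$b) == 0 || (t$c + t$d) == 0 || (t$a + t$c) == 0 ||
      (t$b + t$d) == 0)
    return(undefined_stat("zero margin", prr = NA, chi2 = NA))
  prr <- t$a * (t$c + t$d) / (t$c * (t$a + t$b))
  chi2 <- (t$a * t$d - t$b * t$c)^2 * t$N /
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d))
  list(prr = prr, chi2 = chi2, defined = TRUE, reason = NA_character_)
}

#' BCPNN information component with lower credible bound
#'
#' IC = log2( a N / ((a+c)(a+b)) ), the base-2 log of the relative
#' reporting ratio. IC025 = IC - 2 sqrt(V) with
#' V = (1/a + 1/b + 1/c + 1/d) / (ln 2)^2, i.e. the log-normal variance of
#' the observed/expected ratio transported to the log2 scale.
#'
#' @inheritParams compute_ror
#' @return List with `ic`, `ic025`, `e_ic`, `v_ic`, `defined`, `reason`.
#' @export
compute_bcpnn <- function(t) {
  stopifnot(inherits(t, "contingency_counts"))
  if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0)
    return(undefined_stat("zero cell", ic = NA, ic025 = NA, e_ic = NA, v_ic = NA))
  rr <- t$a * t$N / ((t$a + t$c) * (t$a + t$b))
  ic <- log2(rr)
  v_ic <- (1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d) / log(2)^2
  list(ic = ic, ic025 = ic - 2 * sqrt(v_ic), e_ic = ic, v_ic = v_ic,
       defined = TRUE, reason = NA_character_)
}

#' Empirical Bayes geometric mean with lower bound
#'
#' EBGM = a N / ((a+c)(a+b)), the relative reporting ratio (the closed
#' form, not the DuMouchel gamma-mixture shrinkage estimate). EBGM05 is
#' the one-sided lower bound exp(ln EBGM - z05 * s) with
#' s = sqrt(1/a + 1/b + 1/c + 1/d). The default `z05 = 1.64` is the
#' convention that matches published pharmacovigilance tables computed
#' this way; set 1.645 (or `qnorm(0.95)`) for the exact normal quantile.
#'
#' @inheritParams compute_ror
#' @param z05 Lower-bound quantile (default 1.64).
#' @return List with `ebgm`, `ebgm05`, `defined`, `reason`.
#' @export
compute_mgps <- function(t, z05 = 1.64) {
  stopifnot(inherits(t, "contingency_counts"))
  if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0)
    return(undefined_stat("zero cell", ebgm = NA, ebgm05 = NA))
  ebgm <- t$a * t$N / ((t$a + t$c) * (t$a + t$b))
  s <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(ebgm = ebgm, ebgm05 = exp(log(ebgm) - z05 * s),
       defined = TRUE, reason = NA_character_)
}

#' Fit the four disproportionality algorithms to a 2x2 table
#'
#' The single entry point for disproportionality analysis: computes ROR
#' (with 95% CI), PRR (with chi-squared), the BCPNN information component
#' (with IC025) and EBGM (with EBGM05), applies the per-algorithm
#' thresholds, and combines them into a signal decision. A pair is
#' evaluable only when `a >= min_a` (3 by default); non-evaluable pairs
#' are never positive regardless of effect size.
#'
#' @param counts A [contingency_counts] object, or the four counts
#'   `c(a, b, c, d)`.
#' @param thresholds A [signal_thresholds] object.
#' @param z_ror Quantile for the ROR 95% CI (default 1.96).
#' @param z_ebgm05 Quantile for the EBGM lower bound (default 1.64; see
#'   [compute_mgps]).
#' @return An object of class `dpa`: counts, full-precision estimates,
#'   per-algorithm flags, `evaluable` and `positive`.
#' @examples
#' fit <- dpa(c(26, 1694, 37016, 8346665))
#' summary(fit)
#' coef(fit)
#' @export
dpa <- function(counts, thresholds = signal_thresholds(), z_ror = 1.96,
                z_ebgm05 = 1.64) {
  if (!inherits(counts, "contingency_counts")) {
    stopifnot(is.numeric(counts), length(counts) == 4)
    counts <- contingency_counts(counts[1], counts[2], counts[3], counts[4])
  }
  ror <- compute_ror(counts, z = z_ror)
  prr <- compute_prr(counts)
  bcp <- compute_bcpnn(counts)
  mgp <- compute_mgps(counts, z05 = z_ebgm05)

  est <- c(ror = ror$ror, ror_l = ror$ci_low, ror_u = ror$ci_high,
           prr = prr$prr, chi2 = prr$chi2,
           ic = bcp$ic, ic025 = bcp$ic025, v_ic = bcp$v_ic,
           ebgm = mgp$ebgm, ebgm05 = mgp$ebgm05)
  flags <- c(
    ror  = isTRUE(ror$defined && ror$ci_low > thresholds$ror_ci_lower &&
                    counts$a >= thresholds$min_a),
    prr  = isTRUE(prr$defined && prr$prr >= thresholds$prr_min &&
                    prr$chi2 >= thresholds$chi2_min &&
                    counts$a >= thresholds$min_a),
    bcpnn = isTRUE(bcp$defined && bcp$ic025 > thresholds$ic025_min),
    mgps  = isTRUE(mgp$defined && mgp$ebgm05 > thresholds$ebgm05_min)
  )
  evaluable <- counts$a >= thresholds$min_a
  positive <- evaluable &&
    if (thresholds$combination == "all") all(flags) else any(flags)
  structure(list(counts = counts, estimates = est, flags = flags,
                 evaluable = evaluable, positive = positive,
                 thresholds = thresholds,
                 undefined = Filter(Negate(is.na),
                                    c(ror = ror$reason, prr = prr$reason,
                                      bcpnn = bcp$reason, mgps = mgp$reason))),
            class = "dpa")
}

#' @export
print.dpa <- function(x, digits = 2, ...) {
  e <- x$estimates
  r <- function(v) formatC(round_half_up(v, digits), format = "f", digits = digits)
  cat("Disproportionality analysis (a =", x$counts$a, ", N =",
      format(x$counts$N, big.mark = ","), ")\n")
  cat(sprintf("  ROR  %s (%s-%s)   PRR %s (chi2 %s)\n",
              r(e["ror"]), r(e["ror_l"]), r(e["ror_u"]), r(e["prr"]), r(e["chi2"])))
  cat(sprintf("  IC   %s (IC025 %s)   EBGM %s (EBGM05 %s)\n",
              r(e["ic"]), r(e["ic025"]), r(e["ebgm"]), r(e["ebgm05"])))
  cat(sprintf("  flags: ROR=%s PRR=%s BCPNN=%s MGPS=%s | evaluable=%s positive=%s\n",
              x$flags["ror"], x$flags["prr"], x$flags["bcpnn"], x$flags["mgps"],
              x$evaluable, x$positive))
  invisible(x)
}

#' @export
summary.dpa <- function(object, ...) {
  e <- object$estimates
  out <- data.frame(
    algorithm = c("ROR", "PRR", "BCPNN", "MGPS"),
    estimate = unname(e[c("ror", "prr", "ic", "ebgm")]),
    lower = unname(c(e["ror_l"], NA, e["ic025"], e["ebgm05"])),
    upper = unname(c(e["ror_u"], NA, NA, NA)),
    companion = unname(c(NA, e["chi2"], NA, NA)),
    flag = unname(object$flags))
  structure(list(table = out, counts = object$counts,
                 evaluable = object$evaluable, positive = object$positive),
            class = "summary.dpa")
}

#' @export
print.summary.dpa <- function(x, ...) {
  print(x$counts)
  df <- x$table
  df[2:5] <- lapply(df[2:5], function(v) round_half_up(v, 2))
  print(df, row.names = FALSE)
  cat("evaluable:", x$evaluable, " positive:", x$positive, "\n")
  invisible(x)
}

#' @export
coef.dpa <- function(object, ...) {
  object$estimates[c("ror", "prr", "ic", "ebgm")]
}

#' @export
confint.dpa <- function(object, parm, level = 0.95, ...) {
  e <- object$estimates
  m <- rbind(ror = c(e["ror_l"], e["ror_u"]),
             ic = c(e["ic025"], NA),
             ebgm = c(e["ebgm05"], NA))
  colnames(m) <- c("lower", "upper")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Evaluate signal thresholds for precomputed statistics
#'
#' Convenience wrapper mirroring the decision stage of [dpa()] for callers
#' holding a table of counts: returns the per-algorithm flags and the
#' combined decision.
#'
#' @param t A [contingency_counts] object.
#' @param thresholds A [signal_thresholds] object.
#' @param ... Passed to [dpa()].
#' @return A list with `flags`, `evaluable`, `positive`.
#' @export
evaluate_signal <- function(t, thresholds = signal_thresholds(), ...) {
  fit <- dpa(t, thresholds = thresholds, ...)
  list(flags = fit$flags, evaluable = fit$evaluable, positive = fit$positive)
}
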