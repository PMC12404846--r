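mr_estimate <- function(method, beta, se, n_snp, df = NULL) {
  pval <- if (is.null(df)) 2 * stats::pnorm(-abs(beta / se))
          else 2 * stats::pt(-abs(beta / se), df = df)
  data.frame(method = method, beta = beta, se = se,
             or = exp(beta), ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se), pval = pval, n_snp = n_snp,
             stringsAsFactors = FALSE)
}

ratio_estimates <- function(pairs) {
  if (any(pairs$beta_exp == 0))
    stop_pv("exposure beta of zero: Wald ratio undefined")
  theta <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  list(theta = theta, se = se)
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect of the exposure on the outcome through one variant:
#' `beta = beta_out / beta_exp`, with the first-order delta-method
#' standard error `se_out / |beta_exp|` (exposure uncertainty ignored;
#' `second_order = TRUE` adds the second-order term).
#'
#' @param pairs One-row harmonized pair (see [harmonize()]).
#' @param second_order Use the second-order delta standard error.
#' @return One-row estimate data frame (`method`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `pval`, `n_snp`).
#' @export
wald_ratio <- function(pairs, second_order = FALSE) {
  if (nrow(pairs) != 1) stop_pv("wald_ratio expects exactly one pair")
  r <- ratio_estimates(pairs)
  se <- r$se
  if (second_order) {
    se <- sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
                 pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  }
  mr_estimate("wald_ratio", r$theta, se, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effect pooling of per-variant Wald ratios with first-order
#' weights `1/se_i^2`: `beta = sum(w theta) / sum(w)`,
#' `se = sqrt(1 / sum(w))`. Requires at least two instruments; use
#' [wald_ratio()] for one.
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @return One-row estimate data frame.
#' @export
mr_ivw <- function(pairs) {
  if (nrow(pairs) < 2)
    stop_pv("IVW needs >= 2 instruments; use wald_ratio() for a single SNP")
  r <- ratio_estimates(pairs)
  w <- 1 / r$se^2
  beta <- sum(w * r$theta) / sum(w)
  mr_estimate("ivw", beta, sqrt(1 / sum(w)), nrow(pairs))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' a free intercept (weights `1/se_out^2`), after orienting every
#' exposure effect positive. The slope is the causal estimate; the
#' intercept estimates directional pleiotropy and its p-value is the
#' pleiotropy test. Standard errors use the multiplicative
#' random-effects convention (residual dispersion floored at 1); p-values
#' are t-based with `n_snp - 2` df.
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @return List with `estimate` (slope row) and `intercept`
#'   (`value`, `se`, `pval`).
#' @export
mr_egger <- function(pairs) {
  if (nrow(pairs) < 3) stop_pv("MR-Egger needs >= 3 instruments")
  s <- ifelse(pairs$beta_exp < 0, -1, 1)
  bx <- pairs$beta_exp * s
  by <- pairs$beta_out * s
  if (stats::sd(bx) < .Machine$double.eps^0.5)
    stop_pv("exposure effects are collinear; Egger slope unidentifiable")
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  infl <- 1 / min(1, sm$sigma)  # never report less than fixed-effect precision
  k <- nrow(pairs)
  slope <- mr_estimate("egger", sm$coefficients["bx", 1],
                       sm$coefficients["bx", 2] * infl, k, df = k - 2)
  intercept <- list(value = sm$coefficients["(Intercept)", 1],
                    se = sm$coefficients["(Intercept)", 2] * infl)
  intercept$pval <- 2 * stats::pt(-abs(intercept$value / intercept$se), df = k - 2)
  list(estimate = slope, intercept = intercept)
}

weighted_median_est <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(theta[1])
  if (p[length(p)] <= 0.5) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5, rule = 2)$y
}

#' Weighted-median estimate
#'
#' Median of the per-variant ratio estimates under cumulative normalized
#' inverse-variance weights; consistent when instruments carrying at
#' least half the weight are valid. The standard error comes from a
#' seeded parametric bootstrap (ratios resampled from
#' `N(theta_i, se_i)`).
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @param nboot Bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return One-row estimate data frame.
#' @export
mr_weighted_median <- function(pairs, nboot = 1000, seed = 1) {
  if (nrow(pairs) < 3) stop_pv("weighted median needs >= 3 instruments")
  r <- ratio_estimates(pairs)
  w <- 1 / r$se^2
  beta <- weighted_median_est(r$theta, w)
  boots <- with_seed(seed, vapply(seq_len(nboot), function(i) {
    th <- stats::rnorm(length(r$theta), r$theta, r$se)
    weighted_median_est(th, w)
  }, numeric(1)))
  mr_estimate("weighted_median", beta, stats::sd(boots), nrow(pairs))
}

mode_est <- function(theta, w, phi) {
  if (stats::sd(theta) < .Machine$double.eps^0.5) return(theta[1])
  s <- 0.9 * min(stats::sd(theta), stats::mad(theta)) * length(theta)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(theta) * length(theta)^(-1 / 5)
  d <- stats::density(theta, weights = w / sum(w), bw = phi * s)
  d$x[which.max(d$y)]
}

mr_mode <- function(pairs, weighted, phi = 1, nboot = 1000, seed = 1) {
  if (nrow(pairs) < 3) stop_pv("mode-based estimators need >= 3 instruments")
  r <- ratio_estimates(pairs)
  w <- if (weighted) 1 / r$se^2 else rep(1, length(r$theta))
  beta <- mode_est(r$theta, w, phi)
  boots <- with_seed(seed, vapply(seq_len(nboot), function(i) {
    th <- stats::rnorm(length(r$theta), r$theta, r$se)
    mode_est(th, w, phi)
  }, numeric(1)))
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, stats::mad(boots), nrow(pairs))
}

#' Simple-mode estimate
#'
#' Mode of the kernel-smoothed ratio-estimate distribution with equal
#' weights; bandwidth is the standard mode-estimator default
#' (`phi = 1` times `0.9 min(sd, mad) k^(-1/5)`), standard error by
#' seeded parametric bootstrap (MAD of bootstrap modes).
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return One-row estimate data frame.
#' @export
mr_simple_mode <- function(pairs, phi = 1, nboot = 1000, seed = 1) {
  mr_mode(pairs, weighted = FALSE, phi = phi, nboot = nboot, seed = seed)
}

#' Weighted-mode estimate
#'
#' As [mr_simple_mode()] but with inverse-variance weights in the kernel
#' density.
#'
#' @inheritParams mr_simple_mode
#' @return One-row estimate data frame.
#' @export
mr_weighted_mode <- function(pairs, phi = 1, nboot = 1000, seed = 1) {
  mr_mode(pairs, weighted = TRUE, phi = phi, nboot = nboot, seed = seed)
}

#' Cochran's Q heterogeneity test of the ratio estimates
#'
#' `Q = sum(w_i (theta_i - beta_ivw)^2)` with first-order weights,
#' compared to a chi-squared distribution on `n_snp - 1` df.
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @param beta_ivw Pooled estimate; recomputed with [mr_ivw()] when
#'   omitted.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, beta_ivw = NULL) {
  if (nrow(pairs) < 2) stop_pv("heterogeneity test needs >= 2 instruments")
  r <- ratio_estimates(pairs)
  if (is.null(beta_ivw)) beta_ivw <- mr_ivw(pairs)$beta
  w <- 1 / r$se^2
  q <- sum(w * (r$theta - beta_ivw)^2)
  df <- nrow(pairs) - 1
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Fit two-sample Mendelian randomization estimators
#'
#' The modelling front end for a harmonized exposure-outcome pair set.
#' With a single instrument only the Wald ratio is available; with two,
#' IVW; with three or more the full suite (IVW, MR-Egger, weighted
#' median, simple mode, weighted mode) plus heterogeneity (Cochran's Q)
#' and pleiotropy (Egger intercept) diagnostics.
#'
#' @param pairs A `harmonized_pairs` data frame from [harmonize()], or
#'   any data frame with `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param methods Methods to run; default all that the instrument count
#'   admits.
#' @param nboot,seed,phi Bootstrap and bandwidth controls for the median
#'   and mode estimators.
#' @return An object of class `mr_fit`: `results` (one row per method),
#'   `heterogeneity`, `pleiotropy`, and the input `pairs`.
#' @examples
#' pairs <- data.frame(beta_exp = c(0.3, 0.25, 0.4), se_exp = 0.02,
#'                     beta_out = c(0.09, 0.08, 0.11), se_out = 0.03)
#' fit <- mr_fit(pairs)
#' coef(fit)
#' @export
mr_fit <- function(pairs, methods = NULL, nboot = 1000, seed = 1, phi = 1) {
  k <- nrow(pairs)
  if (k == 0) stop_pv("no instruments")
  admissible <- if (k == 1) "wald_ratio"
    else if (k == 2) "ivw"
    else c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")
  methods <- methods %||% admissible
  bad <- setdiff(methods, admissible)
  if (length(bad) > 0)
    stop_pv("method(s) %s need more instruments than the %d supplied",
            paste(bad, collapse = ", "), k)
  pleio <- NULL
  res <- lapply(methods, function(m) {
    switch(m,
      wald_ratio = wald_ratio(pairs),
      ivw = mr_ivw(pairs),
      egger = {
        e <- mr_egger(pairs)
        pleio <<- e$intercept
        e$estimate
      },
      weighted_median = mr_weighted_median(pairs, nboot = nboot, seed = seed),
      simple_mode = mr_simple_mode(pairs, phi = phi, nboot = nboot, seed = seed),
      weighted_mode = mr_weighted_mode(pairs, phi = phi, nboot = nboot, seed = seed))
  })
  results <- do.call(rbind, res)
  het <- if (k >= 2) cochran_q(pairs, beta_ivw = results$beta[results$method == "ivw"][1])
         else NULL
  structure(list(results = results, heterogeneity = het, pleiotropy = pleio,
                 pairs = pairs), class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat("Two-sample MR fit (", x$results$n_snp[1], "instrument(s) )\n")
  df <- x$results
  df[c("beta", "se", "or", "ci_low", "ci_high")] <-
    lapply(df[c("beta", "se", "or", "ci_low", "ci_high")], round, digits = digits)
  df$pval <- signif(df$pval, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$heterogeneity))
    cat(sprintf("Heterogeneity: Q = %.3f on %d df, p = %.3g\n",
                f$heterogeneity$q, f$heterogeneity$df, f$heterogeneity$pval))
  if (!is.null(f$pleiotropy))
    cat(sprintf("Pleiotropy (Egger intercept): %.4f (se %.4f), p = %.3g\n",
                f$pleiotropy$value, f$pleiotropy$se, f$pleiotropy$pval))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(lower = object$results$beta - z * object$results$se,
             upper = object$results$beta + z * object$results$se)
  rownames(m) <- object$results$method
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$pairs
  s <- ifelse(p$beta_exp < 0, -1, 1)
  bx <- p$beta_exp * s
  by <- p$beta_out * s
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::arrows(bx, by - 1.96 * p$se_out, bx, by + 1.96 * p$se_out,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  ivw_b <- x$results$beta[x$results$method %in% c("ivw", "wald_ratio")][1]
  if (is.finite(ivw_b)) graphics::abline(0, ivw_b, col = "firebrick")
  invisible(x)
}
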