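#' Construct a 2x2 disproportionality contingency table
#'
#' The unit of counting is the deduplicated case report. For a target drug
#' and a target reaction (one preferred term or a pooled PT set):
#' `a` = cases with the drug and the reaction, `b` = cases with the drug but
#' not the reaction, `c` = other-drug cases with the reaction, `d` = the
#' remainder. `N = a + b + c + d`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `contingency_counts`: a list with elements
#'   `a`, `b`, `c`, `d` and the derived total `N`.
#' @examples
#' contingency_counts(26, 1694, 37016, 8346665)
#' @export
contingency_counts <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop_pv("contingency cells must be non-negative integers")
  out <- list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
              d = as.numeric(d), N = as.numeric(a + b + c + d))
  class(out) <- "contingency_counts"
  out
}

#' @export
print.contingency_counts <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target PT", "other PTs")))
  cat("2x2 disproportionality table (N =", format(x$N, big.mark = ","), ")\n")
  print(m)
  invisible(x)
}

#' Build a contingency table from cleaned case sets
#'
#' Counts cases, not reaction rows: a case reporting a PT from `pt_group`
#' several times contributes once to `a` (or `c`). The background set must
#' not share case keys with the target-drug set (that would double count).
#'
#' @param drug_cases A [case_set] of target-drug cases.
#' @param background A [case_set] of all other (comparator) cases covering
#'   the same quarter range.
#' @param pt_group Character vector of preferred terms defining the target
#'   reaction (a single PT, or a pooled SMQ term set).
#' @return A [contingency_counts] object.
#' @export
build_contingency <- function(drug_cases, background, pt_group) {
  stopifnot(inherits(drug_cases, "case_set"), inherits(background, "case_set"))
  if (length(pt_group) == 0 || all(!nzchar(norm_display(pt_group))))
    stop_pv("pt_group must contain at least one non-empty preferred term")
  overlap <- intersect(drug_cases$cases$primaryid, background$cases$primaryid)
  if (length(overlap) > 0)
    stop_pv("drug cases and background share %d case key(s); background must exclude the target drug's cases", length(overlap))
  keys <- unique(norm_key(pt_group))
  hit <- function(cs) {
    ids <- unique(cs$pts$primaryid[cs$pts$pt_key %in% keys])
    length(ids)
  }
  a <- hit(drug_cases)
  c_ <- hit(background)
  b <- nrow(drug_cases$cases) - a
  d <- nrow(background$cases) - c_
  contingency_counts(a, b, c_, d)
}
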