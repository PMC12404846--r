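#' @keywords internal
"_PACKAGE"

# Round half away from zero (presentation rounding for published tables);
# base round() is round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize a free-text term for display: trim and collapse whitespace.
norm_display <- function(x) {
  x <- gsub("\\s+", " ", as.character(x))
  trimws(x)
}

# Normalization key for matching: display form, case-folded.
norm_key <- function(x) tolower(norm_display(x))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_pv <- function(...) stop(sprintf(...), call. = FALSE)
warn_pv <- function(...) warning(sprintf(...), call. = FALSE)

pvmr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pvmr")
  if (!nzchar(path)) stop_pv("bundled file '%s' not found", file)
  path
}
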