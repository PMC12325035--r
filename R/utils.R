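#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Fixed-point rounding in which ties go away from zero (0.5 -> 1, -0.5 -> -1),
#' matching the convention of printed cohort summary tables. Base R's
#' \code{round()} uses banker's rounding and would print 33.25 as 33.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} decimals.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a stage-specific RNG seed from a global seed.  Deterministic, stays
# inside the 32-bit integer range required by set.seed().
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1009 * h) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is left untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Format a fraction as a percentage at 2 significant figures (e.g. 0.005882 ->
# 0.59). Used by the validation report.
pct2 <- function(x) signif(100 * x, 2)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
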