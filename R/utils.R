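# Small shared helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used when printing trial summary percentages (base R's [round()] rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_away(57.75, 1)  # 57.8, not 57.7 or banker's 57.8/57.7 ambiguity
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format an event count as a percentage of an arm N
#'
#' The percentage convention of trial event-summary tables: `100 * count / n`
#' rounded half-away-from-zero to one decimal.
#'
#' @param count integer event count (0 <= count <= n).
#' @param n arm size.
#' @param digits decimals to keep (default 1).
#' @return numeric percentage.
#' @examples
#' event_pct(1117, 1859)  # 60.1
#' @export
event_pct <- function(count, n, digits = 1) {
  if (any(n <= 0)) stop("arm N must be positive")
  if (any(count < 0 | count > n)) stop("count must lie in [0, N]")
  round_half_away(100 * count / n, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Comparison tolerance for the inclusive CID thresholds: absorbs double
# rounding (~1e-16 scale) while 1 mL (0.001 L) below the boundary never flags.
.cid_eps <- 1e-9

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Deterministic per-patient substream seed: cohorts are reproducible under
# re-ordering of the patient loop because each patient's draws depend only on
# (seed, global patient index). Kept inside 32-bit integer range.
.patient_seed <- function(seed, index) {
  as.integer(((seed %% 100003) * 20771 + index * 7919) %% 2147483629)
}
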