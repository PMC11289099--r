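# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed for a named pipeline stage
#'
#' A single user-level seed is fanned out to per-stage seeds by a fixed
#' counter scheme, so any stage can be regenerated independently of the
#' others while the whole run stays reproducible.
#'
#' @param seed integer master seed.
#' @param stage stage name (character) or a small integer counter.
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, stage) {
  if (is.character(stage)) {
    counter <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    counter <- as.integer(stage)
  }
  as.integer((as.numeric(seed) * 48271 + counter * 16807) %% 2147483647)
}

# log(sum(exp(x))) without overflow; -Inf inputs allowed
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference vanishes
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# -log10 of a two-sided normal p-value from a z statistic, underflow safe
neg_log10_p_from_z <- function(z) {
  -(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}

# -log10 of a two-sided t p-value, underflow safe
neg_log10_p_from_t <- function(t, df) {
  -(log(2) + stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)) / log(10)
}

stopifnot_scalar <- function(x, nm = deparse(substitute(x))) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", nm), call. = FALSE)
  invisible(x)
}

# strip a leading "chr" prefix so chr1 and 1 compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)
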