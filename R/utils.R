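#' Benjamini-Hochberg adjusted p-values
#'
#' Single source of truth for multiple-testing adjustment across the
#' package: differential expression and over-representation analysis both
#' route through this wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values (same length and order).
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

# Derive an independent sub-stream seed from a master seed. Each generator
# uses a fixed offset so that components stay reproducible when run alone.
# Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.double(seed) * 1103L + as.double(offset) * 12347L) %% 2147483629)
}

# INFO-level logging to stderr; quiet by default in tests via option.
cdr_log <- function(fmt, ...) {
  if (isTRUE(getOption("consensusDR.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(paste0("[consensusDR] ", fmt), ...))
}

# Invert the trigamma function by Newton iteration: find x > 0 with
# trigamma(x) = y. Used to estimate the prior degrees of freedom of the
# variance shrinkage model from the excess spread of log sample variances.
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1)
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}
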