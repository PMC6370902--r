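# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals (presentation rounding;
# base round() is round-half-even). A sqrt(eps) guard absorbs binary
# representation error in decimal sums so x.x5 values round up reliably.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp a numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Site key used to match truth sites and call records: (chrom, pos, ref);
# the alternate allele is compared separately (semantically).
site_key <- function(chrom, pos, ref) paste(chrom, pos, ref, sep = ":")

GENOTYPES <- c("RR", "RA", "AA")

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
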