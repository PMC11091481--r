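# Internal helpers: deterministic seed derivation and weighted summaries.

# Derive a child seed from a root seed and one or more indices.  Linear
# congruential folding modulo the Mersenne prime 2^31 - 1 keeps every derived
# seed a valid 32-bit R integer and makes streams reproducible from
# (root, index...) alone.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(x)
}

# Weighted mean with weights normalised internally.
wmean <- function(x, w) {
  sum(x * w) / sum(w)
}

# Weighted quantile of type "inverse weighted ECDF with interpolation".
# Used for equal-tailed posterior intervals of weighted ABC samples.
wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

# Genotype coding used throughout: the number of wildtype alleles carried,
# 2 = WT/WT, 1 = WT/ko (heterozygote), 0 = ko/ko.
GENOTYPE_LEVELS <- c("WT/WT", "WT/ko", "ko/ko")

genotype_label <- function(gt) GENOTYPE_LEVELS[3L - gt]

genotype_code <- function(label) {
  code <- c("WT/WT" = 2L, "WT/ko" = 1L, "ko/ko" = 0L)[label]
  if (anyNA(code)) {
    abort(paste0("unknown genotype label(s): ",
                 paste(unique(label[is.na(code)]), collapse = ", ")))
  }
  unname(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
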