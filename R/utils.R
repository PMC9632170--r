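# Shared constants and small helpers.

#' The 20-letter amino-acid alphabet used for CDR3 sequences
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Loci recognised by the package
#' @export
LOCI <- c("IGH", "TRB")

#' Cell subsets recognised by the package, split by chain
#' @export
CELL_SUBSETS <- list(
  IGH = c("naive_B", "memory_B"),
  TRB = c("naive_CD4", "memory_CD4", "naive_CD8", "memory_CD8")
)

is_valid_junction <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

check_locus <- function(locus) {
  if (length(locus) != 1L || !locus %in% LOCI) {
    abort(sprintf("`locus` must be one of %s", paste(LOCI, collapse = ", ")))
  }
  locus
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

clip_correlation <- function(r, limit = 0.999999) {
  out <- r
  hit <- !is.na(r) & abs(r) >= 1
  if (any(hit)) {
    warn(sprintf("%d correlation(s) at |r| = 1 clipped to +/-%g", sum(hit), limit))
    out[hit] <- sign(r[hit]) * limit
  }
  out
}

# Deterministic 31-bit stream seed from a key, so each simulated individual
# gets its own reproducible RNG stream independent of generation order.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h)
}

`%||%` <- rlang::`%||%`
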