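# Independent oracles and small in-code fixtures shared across tests.

# Brute-force RDI: explicit loop over codons, no vectorized shortcut.
bruteRdi <- function(v) {
  num <- 0
  den <- 0
  for (i in seq_along(v)) {
    num <- num + i * v[i]
    den <- den + v[i]
  }
  num / (length(v) * den)
}

# Brute-force Mann-Whitney: enumerate every labeling of the pooled sample,
# compute U (a > b counting, 1/2 per tie) directly from pairwise
# comparisons, and return the two-sided p = 2 * min(tail) capped at 1.
bruteMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  N <- length(pooled)
  uOf <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) {
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
    u
  }
  uObs <- uOf(a, b)
  labelings <- utils::combn(N, n1)
  us <- apply(labelings, 2L, function(idx)
    uOf(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  pl <- mean(us <= uObs + eps)
  pg <- mean(us >= uObs - eps)
  list(U = uObs, p = min(1, 2 * min(pl, pg)))
}

# Uniform codon-usage abundances for the 61 sense codons (+ stops at 0).
uniformUsage <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(ifelse(gc == "*", 0, 1), names(gc))
}

# A tiny two-condition, two-replicate profile set built in code.
tinyStudySet <- function() {
  counts <- list(
    c(4, 3, 2, 1), c(5, 3, 2, 2),   # txA control r1, r2
    c(4, 2, 1, 1), c(4, 3, 1, 0),   # txA treated r1, r2
    c(2, 2, 2, 2), c(2, 2, 1, 3),   # txB control r1, r2
    c(3, 2, 2, 1), c(2, 2, 2, 2))   # txB treated r1, r2
  CodonProfileSet(counts,
                  transcriptId = rep(c("txA", "txB"), each = 4),
                  condition = rep(rep(c("control", "treated"),
                                      each = 2), 2),
                  replicate = rep(c("r1", "r2"), 4))
}
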