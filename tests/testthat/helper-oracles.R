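# Independent oracles used against the package's implementations.

# Exact permutation p-value of the Mann-Whitney U test, computing U for every
# subset by direct pairwise comparison (no rank sums): the brute-force
# definition of the test.
oracle_exact_mw_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  n <- length(x)
  N <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- u_of(x, y)
  subsets <- utils::combn(N, n)
  Us <- apply(subsets, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  pg <- mean(Us >= U_obs - 1e-9)
  pl <- mean(Us <= U_obs + 1e-9)
  switch(alternative,
    greater = pg,
    two_sided = min(1, 2 * min(pg, pl))
  )
}

# Loop-based class frequency summation for one PSSM frequency row.
oracle_class_freq_row <- function(freq_row, scheme) {
  out <- numeric(length(scheme$classes))
  names(out) <- names(scheme$classes)
  for (cl in names(scheme$classes)) {
    s <- 0
    for (aa in scheme$classes[[cl]]) s <- s + freq_row[[aa]]
    out[cl] <- s
  }
  out
}

# Shannon-based information content of one frequency vector, in bits.
oracle_info <- function(p) {
  p <- p[p > 0]
  log2(20) - sum(-p * log2(p))
}
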