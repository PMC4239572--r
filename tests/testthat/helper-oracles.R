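# Independent oracles and small fixture builders used across the suite.

# exhaustive maximum compatible subset: try every subset of candidate rows
oracle_max_compatible <- function(cand) {
  m <- nrow(cand)
  if (m == 0L) return(0L)
  stopifnot(m <= 14L)
  best <- 0L
  for (mask in seq_len(2^m) - 1L) {
    idx <- which(bitwAnd(mask, 2L^(seq_len(m) - 1L)) > 0L)
    if (length(idx) <= best) next
    if (!anyDuplicated(as.vector(cand[idx, , drop = FALSE]))) {
      best <- length(idx)
    }
  }
  best
}

# term-by-term binomial upper tail, independent of pbinom
oracle_binom_tail <- function(n, theta) {
  p <- (1 - 2 * theta)^2
  m <- ceiling(theta * n - 1e-9)
  if (m <= 0) return(1)
  sum(vapply(m:n, function(x) {
    choose(n, x) * p^x * (1 - p)^(n - x)
  }, numeric(1)))
}

# enumerate all (2n-1)!! perfect matchings on ends 1..2n (tiny n only)
all_matchings <- function(n) {
  rec <- function(free) {
    if (!length(free)) return(list(matrix(integer(), 0L, 2L)))
    a <- free[1L]
    out <- list()
    for (b in free[-1L]) {
      rest <- setdiff(free, c(a, b))
      for (sub in rec(rest)) {
        out[[length(out) + 1L]] <- rbind(c(a, b), sub)
      }
    }
    out
  }
  rec(seq_len(2L * n))
}

random_trio <- function(n, seed) random_genomes(n, k = 3, seed = seed)

# Reference values for the normal-approximation success probability over the
# standard grid (rows n, columns theta), frozen to 4 decimals.  Two cells of
# the published grid -- (n=500, theta=0.24) and (n=50, theta=0.30) -- are
# internally inconsistent with the defining tail formula (their row/column
# neighbours all reproduce it to 4 d.p.); the values below are the formula's.
ref_table1 <- function() {
  theta <- c(0.10, 0.20, 0.24, 0.25, 0.26, 0.30, 1 / 3)
  n <- c(5, 10, 50, 100, 500, 1000, 2000, 10000)
  vals <- rbind(
    c(0.9798, 0.6101, 0.3630, 0.3028, 0.2457, 0.0716, 0.0109),
    c(0.9994, 0.7657, 0.4445, 0.3575, 0.2750, 0.0506, 0.0031),
    c(1,      0.9864, 0.6273, 0.4351, 0.2530, 0.0019, 0),
    c(1,      0.9994, 0.7163, 0.4540, 0.2056, 0,      0),
    c(1,      1,      0.9306, 0.4794, 0.0521, 0,      0),
    c(1,      1,      0.9834, 0.4854, 0.0119, 0,      0),
    c(1,      1,      0.9988, 0.4897, 0.0008, 0,      0),
    c(1,      1,      1,      0.4954, 0,      0,      0)
  )
  list(theta = theta, n = n, vals = vals)
}
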