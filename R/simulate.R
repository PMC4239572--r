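#' Simulate random genomes, optionally with shared adjacencies
#'
#' `random_genome()` draws a genome uniformly over all `(2n-1)!!` perfect
#' matchings on the `2n` gene ends, by shuffling the ends and pairing
#' consecutive entries.  Two independent draws share `n/(2n-1)` adjacencies
#' in expectation — about 0.5 for large `n` — which is why independent
#' random genomes are "random with respect to each other".
#'
#' `random_genomes()` generalizes to `k` genomes with prescribed
#' shared-adjacency structure: all `k` genomes contain a common core of
#' `floor(psi * n)` adjacencies, and (for `k = 3` only) each unordered pair
#' `(i, j)` shares `floor(omega[i, j] * n)` further adjacencies drawn on
#' ends free in both genomes.  Each genome is then completed independently
#' by a uniform matching of its remaining free ends, so realized sharing
#' counts are *at least* the prescribed counts (coincidental extra overlap,
#' of expectation O(1), is not rejected — rejection would bias the
#' distribution).  The admissibility constraint per genome `i` is
#' `psi + omega[i, j] + omega[i, h] <= 1`, and the realized counts must fit:
#' `floor(psi n) + sum_j floor(omega[i, j] n) <= n`.
#'
#' @param n Number of genes (>= 1).
#' @param k Number of genomes (>= 1; the construction needs >= 3).
#' @param psi Fraction in `[0, 1]` of adjacencies shared by all `k`
#'   genomes.
#' @param omega Optional `k x k` symmetric numeric matrix of additional
#'   pairwise-shared fractions (zero diagonal).  Only supported for
#'   `k = 3`; any non-zero `omega` with `k != 3` is an error.
#' @param seed Optional integer seed; when supplied the draw is made in a
#'   local RNG scope (via [withr::with_seed()]) and is reproducible.
#' @param label,labels Optional label(s) for the genomes.
#'
#' @return `random_genome()` a [genome()]; `random_genomes()` a list of
#'   `k` genomes in spec order.
#'
#' @examples
#' random_genomes(n = 20, k = 3, psi = 0.5, seed = 1)
#' @export
random_genome <- function(n, label = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  ends <- sample.int(2L * n)
  genome(matrix(ends, ncol = 2L, byrow = TRUE), n, label)
}

#' @rdname random_genome
#' @export
random_genomes <- function(n, k = 3L, psi = 0, omega = NULL, seed = NULL,
                           labels = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  stopifnot(length(n) == 1L, n >= 1L, length(k) == 1L, k >= 1L)
  spec <- validate_sharing(k, psi, omega, n)
  labels <- labels %||% paste0("genome_", seq_len(k))
  draw <- function() {
    core_ct <- spec$core_count
    w <- spec$pair_counts
    perm <- sample.int(2L * n)
    core <- if (core_ct > 0L) {
      matrix(perm[seq_len(2L * core_ct)], ncol = 2L, byrow = TRUE)
    } else {
      matrix(integer(), 0L, 2L)
    }
    used <- matrix(FALSE, 2L * n, k)
    if (core_ct > 0L) used[as.vector(core), ] <- TRUE
    own <- replicate(k, matrix(integer(), 0L, 2L), simplify = FALSE)
    for (i in seq_len(max(k - 1L, 1L))) {
      for (j in seq_len(k)) {
        if (j <= i || w[i, j] == 0L) next
        cand <- which(!used[, i] & !used[, j])
        if (length(cand) < 2L * w[i, j]) {
          abort(sprintf(
            "infeasible sharing spec: genomes %d and %d have only %d common free ends, need %d",
            i, j, length(cand), 2L * w[i, j]
          ), class = "nearmedian_infeasible")
        }
        sel <- cand[sample.int(length(cand), 2L * w[i, j])]
        pp <- matrix(sel, ncol = 2L, byrow = TRUE)
        own[[i]] <- rbind(own[[i]], pp)
        own[[j]] <- rbind(own[[j]], pp)
        used[sel, c(i, j)] <- TRUE
      }
    }
    lapply(seq_len(k), function(i) {
      free <- which(!used[, i])
      fill <- if (length(free)) {
        matrix(free[sample.int(length(free))], ncol = 2L, byrow = TRUE)
      } else {
        matrix(integer(), 0L, 2L)
      }
      genome(rbind(core, own[[i]], fill), n, labels[[i]])
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

validate_sharing <- function(k, psi, omega, n) {
  if (length(psi) != 1L || is.na(psi) || psi < 0 || psi > 1) {
    abort("psi must be a single fraction in [0, 1]")
  }
  if (is.null(omega)) {
    omega <- matrix(0, k, k)
  } else {
    omega <- as.matrix(omega)
    if (!all(dim(omega) == c(k, k))) {
      abort("omega must be a k x k matrix")
    }
    if (any(omega < 0) || any(diag(omega) != 0) ||
        !isTRUE(all.equal(omega, t(omega)))) {
      abort("omega must be symmetric with zero diagonal and non-negative entries")
    }
    if (any(omega > 0) && k != 3L) {
      abort("pairwise sharing fractions (omega) are only supported for k = 3",
            class = "nearmedian_unsupported")
    }
  }
  row_tot <- psi + rowSums(omega)
  if (any(row_tot > 1 + 1e-12)) {
    abort(sprintf(
      "infeasible sharing spec: psi + sum_j omega[i, j] = %.4g > 1 for genome %d",
      max(row_tot), which.max(row_tot)
    ), class = "nearmedian_infeasible")
  }
  core_count <- as.integer(floor(psi * n + 1e-9))
  pair_counts <- matrix(as.integer(floor(omega * n + 1e-9)), k, k)
  per_genome <- core_count + rowSums(pair_counts)
  if (any(per_genome > n)) {
    abort(sprintf(
      "infeasible sharing spec: genome %d is assigned %d shared adjacencies but has only %d",
      which.max(per_genome), max(per_genome), n
    ), class = "nearmedian_infeasible")
  }
  list(core_count = core_count, pair_counts = pair_counts,
       psi = psi, omega = omega)
}

#' Observed shared-adjacency structure of a genome set
#'
#' Counts, for each unordered pair of input genomes, the adjacencies they
#' share, and the number shared by all of them.  This is a descriptive
#' helper: [near_median()] does *not* estimate sharing fractions from the
#' data (the pairwise and all-shared components are confounded in pairwise
#' counts); declare `psi`/`omega` explicitly when known.
#'
#' @param genomes List of >= 2 genomes on the same gene universe.
#' @return A tibble with columns `i`, `j`, `shared`, `shared_fraction`,
#'   one row per unordered pair, with the all-`k` shared count in attribute
#'   `"all_shared"`.
#' @examples
#' gs <- random_genomes(50, k = 3, psi = 0.4, seed = 2)
#' observed_sharing(gs)
#' @export
observed_sharing <- function(genomes) {
  stopifnot(length(genomes) >= 2L)
  n <- check_same_universe(genomes)
  k <- length(genomes)
  pr <- which(upper.tri(diag(k)), arr.ind = TRUE)
  shared <- vapply(seq_len(nrow(pr)), function(r) {
    count_shared(genomes[[pr[r, 1L]]], genomes[[pr[r, 2L]]])
  }, numeric(1))
  all_shared <- length(Reduce(intersect, lapply(genomes, adj_keys)))
  out <- tibble(
    i = pr[, 1L], j = pr[, 2L],
    shared = as.integer(shared),
    shared_fraction = shared / n
  )
  attr(out, "all_shared") <- all_shared
  out
}
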