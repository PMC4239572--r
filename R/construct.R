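#' Stage-1 equal sampling of adjacencies
#'
#' Builds the partial set A' that underlies the near-median construction.
#' With `shared_first = TRUE` (the default, and the behaviour required
#' when the inputs share adjacencies), every adjacency present in at least
#' two input genomes is placed into A' first (for `k > 3`, where such
#' adjacencies can conflict, a maximum compatible subset is used).  Then,
#' processing genomes in input order, `floor(theta * n)` adjacencies are
#' sampled uniformly from each genome among those whose both ends are
#' still free relative to the current A'.  A genome's required count is
#' reduced by the number of its adjacencies already included (so three
#' identical genomes saturate immediately and owe nothing further).
#'
#' If a genome offers fewer two-free-end candidates than required, the
#' sampling *fails*: a classed error (`"nearmedian_stage1_error"`) is
#' thrown unless `allow_shortfall = TRUE`, in which case all available
#' candidates are taken and the shortfall is recorded.  [near_median()]
#' wraps this in a retry-then-fallback policy.
#'
#' @param genomes List of `k >= 3` genomes on the same `n` genes.
#' @param theta Sampling fraction; `floor(theta * n)` must be >= 1.
#' @param shared_first Pre-include all adjacencies shared by >= 2 inputs?
#' @param allow_shortfall Take all available candidates instead of
#'   failing when a genome cannot supply its quota?
#'
#' @return A list with elements `set` (the [adjacency_set()] A'),
#'   `sources` (tibble mapping each adjacency to `"shared"` or its source
#'   genome), `stage1_counts` (integer per genome), `shared_included`,
#'   `shortfall` (integer per genome), `m` (the per-genome quota),
#'   `theta`, and `success` (no shortfall anywhere).
#' @examples
#' gs <- random_genomes(100, k = 3, seed = 5)
#' s1 <- stage1_sample(gs, theta = 0.25)
#' s1$stage1_counts
#' @export
stage1_sample <- function(genomes, theta, shared_first = TRUE,
                          allow_shortfall = FALSE) {
  k <- length(genomes)
  if (k < 3L) abort("at least 3 input genomes are required")
  n <- check_same_universe(genomes)
  m <- as.integer(floor(theta * n + 1e-9))
  if (is.na(m) || m < 1L) {
    abort(sprintf("floor(theta * n) must be >= 1 (theta = %.4g, n = %d)",
                  theta, n))
  }
  used <- logical(2L * n)
  keys_list <- lapply(genomes, adj_keys)
  acc_pairs <- vector("list", k + 1L)
  acc_source <- vector("list", k + 1L)
  a_keys <- double(0)
  shared_included <- 0L

  if (shared_first) {
    allk <- unlist(keys_list)
    dup <- unique(allk[duplicated(allk)])
    if (length(dup)) {
      allp <- do.call(rbind, lapply(genomes, adjacencies))
      sh <- allp[match(dup, allk), , drop = FALSE]
      sh_set <- max_compatible_subset(sh, n)  # identity for k = 3
      sp <- adjacencies(sh_set)
      used[as.vector(sp)] <- TRUE
      acc_pairs[[1L]] <- sp
      acc_source[[1L]] <- rep("shared", nrow(sp))
      a_keys <- adj_keys(sh_set)
      shared_included <- nrow(sp)
    }
  }

  stage1_counts <- integer(k)
  shortfall <- integer(k)
  for (i in seq_len(k)) {
    p <- adjacencies(genomes[[i]])
    cand <- which(!used[p[, 1L]] & !used[p[, 2L]])
    included_i <- sum(keys_list[[i]] %in% a_keys)
    target <- min(m, n - included_i)
    if (length(cand) < target) {
      if (!allow_shortfall) {
        abort(sprintf(
          "insufficient two-free-end adjacencies in genome %d: %d available, %d required",
          i, length(cand), target
        ), class = "nearmedian_stage1_error")
      }
      shortfall[i] <- target - length(cand)
      target <- length(cand)
    }
    take <- cand[sample.int(length(cand), target)]
    tp <- p[take, , drop = FALSE]
    used[as.vector(tp)] <- TRUE
    acc_pairs[[i + 1L]] <- tp
    acc_source[[i + 1L]] <- rep(paste0("genome_", i), nrow(tp))
    a_keys <- c(a_keys, keys_list[[i]][take])
    stage1_counts[i] <- target
  }

  pairs <- do.call(rbind, acc_pairs)
  src <- unlist(acc_source) %||% character()
  sources <- tibble(
    end1 = format_gene_end(pairs[, 1L]),
    end2 = format_gene_end(pairs[, 2L]),
    source = src
  )
  list(
    set = adjacency_set(pairs, n),
    sources = sources,
    stage1_counts = stage1_counts,
    shared_included = shared_included,
    shortfall = shortfall,
    m = m,
    theta = theta,
    success = all(shortfall == 0L)
  )
}

#' Supplementary sampling of residual two-free-end adjacencies
#'
#' Scans every input genome for adjacencies not yet in the partial
#' construction whose *both* ends are still free, and returns them
#' de-duplicated.  These candidates may conflict with each other (share
#' an end); resolve them with [max_compatible_subset()].  All `k` genomes
#' are scanned — in expectation the last-processed genome contributes
#' nothing (all its two-free-end adjacencies were taken in stage 1), but
#' at finite `n` it may, and scanning it can only lower the score.
#'
#' @param genomes List of input genomes.
#' @param current A compatible [adjacency_set()] (e.g. A' from
#'   [stage1_sample()]).
#' @return Two-column integer matrix of candidate adjacencies with the
#'   gene-universe size attached as attribute `"n"`.
#' @examples
#' gs <- random_genomes(100, k = 3, seed = 5)
#' s1 <- stage1_sample(gs, theta = 0.25)
#' nrow(supplementary_sample(gs, s1$set))
#' @export
supplementary_sample <- function(genomes, current) {
  n <- check_same_universe(c(genomes, list(current)))
  used <- logical(2L * n)
  used[as.vector(adjacencies(current))] <- TRUE
  cand <- do.call(rbind, lapply(genomes, function(g) {
    p <- adjacencies(g)
    p[!used[p[, 1L]] & !used[p[, 2L]], , drop = FALSE]
  }))
  keys <- pair_keys(cand, n)
  cand <- cand[!duplicated(keys), , drop = FALSE]
  attr(cand, "n") <- n
  cand
}

#' Complete a partial adjacency set to a full genome
#'
#' Pairs the free gene ends (whose count is automatically even) into
#' filler adjacencies, producing a perfect matching.  By default the
#' pairing is deterministic — consecutive free ends in canonical order —
#' so a fixed seed upstream yields a bit-identical genome; set
#' `randomize = TRUE` for a uniform random pairing.
#'
#' @param partial A compatible [adjacency_set()].
#' @param randomize Shuffle the free ends before pairing?
#' @param label Optional label for the resulting genome.
#' @return A [genome()].
#' @examples
#' complete_genome(adjacency_set(c(1, 3), n = 2))
#' @export
complete_genome <- function(partial, randomize = FALSE, label = NULL) {
  stopifnot(inherits(partial, "adjacency_set"))
  free <- free_ends(partial)
  if (randomize && length(free)) free <- free[sample.int(length(free))]
  fill <- if (length(free)) {
    matrix(free, ncol = 2L, byrow = TRUE)
  } else {
    matrix(integer(), 0L, 2L)
  }
  genome(rbind(adjacencies(partial), fill), n_genes(partial),
         label %||% partial$label)
}

#' Construct a near-median genome
#'
#' End-to-end two-stage construction of a genome drawing equally on all
#' `k >= 3` inputs: stage-1 equal sampling ([stage1_sample()]) at
#' fraction `theta`, optionally the supplementary stage
#' ([supplementary_sample()] resolved by exact [max_compatible_subset()]),
#' and completion to a perfect matching ([complete_genome()]).
#'
#' With `theta = "auto"` (default) the optimal fraction for the *declared*
#' sharing level is used: [theta_max()] for random genomes,
#' [theta_max_shared()] when `psi > 0`, [theta_max_general()] when
#' pairwise fractions `omega` are declared (`k = 3` only), minus
#' `safety_margin`.  Sharing is never estimated from the data (see
#' [observed_sharing()]).  At the optimal `theta` stage 1 succeeds only
#' about half the time, so on failure the sampling is retried with fresh
#' randomness up to `max_retries` times, then falls back to taking all
#' available candidates for the deficient genome (the shortfall is
#' recorded in the diagnostics; `stage1_success` is then `FALSE`).
#'
#' @param genomes List of `k >= 3` genomes on the same `n` genes.
#' @param theta `"auto"` or a numeric sampling fraction.
#' @param psi Declared all-shared fraction (see [random_genomes()]).
#' @param omega Declared `k x k` pairwise-shared fraction matrix
#'   (`k = 3` only).
#' @param supplement Run the supplementary stage?
#' @param shared_first Pre-include adjacencies shared by >= 2 inputs?
#' @param safety_margin Amount subtracted from the automatic `theta`.
#' @param max_retries Stage-1 retries before the take-all fallback.
#' @param randomize_fill Randomize the filler matching (default:
#'   deterministic canonical pairing)?
#' @param seed Optional integer seed (local RNG scope; recorded in the
#'   result).
#'
#' @return An object of class `"near_median"`: a list with the
#'   constructed `genome`, `theta_used`, per-genome `stage1_counts`,
#'   `shared_included`, `supplementary_candidates`, `supplementary_added`,
#'   `filler_added`, `per_genome_distance`, `normalized_score`,
#'   `stage1_success`, `shortfall`, `retries`, `seed`, `k`, `n`.  The
#'   four count fields always sum to `n`.  Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#'
#' @examples
#' gs <- random_genomes(200, k = 3, seed = 11)
#' res <- near_median(gs, seed = 12)
#' glance(res)
#' @export
near_median <- function(genomes, theta = "auto", psi = 0, omega = NULL,
                        supplement = TRUE, shared_first = TRUE,
                        safety_margin = 0, max_retries = 20L,
                        randomize_fill = FALSE, seed = NULL) {
  k <- length(genomes)
  if (k < 3L) abort("at least 3 input genomes are required")
  n <- check_same_universe(genomes)
  if (identical(theta, "auto")) {
    omega_sum <- if (is.null(omega)) 0 else sum(omega[upper.tri(omega)])
    theta_val <- if (omega_sum > 0) {
      if (k != 3L) {
        abort("pairwise sharing (omega) is only supported for k = 3",
              class = "nearmedian_unsupported")
      }
      theta_max_general(psi, omega_sum)
    } else if (psi > 0) {
      theta_max_shared(k, psi)
    } else {
      theta_max(k)
    }
    theta_val <- theta_val - safety_margin
  } else {
    theta_val <- as.numeric(theta)
  }
  if (is.na(theta_val) || theta_val <= 0) {
    abort("effective theta must be positive")
  }

  run <- function() {
    s1 <- NULL
    retries <- 0L
    fell_back <- FALSE
    for (attempt in 0:max_retries) {
      r <- tryCatch(
        stage1_sample(genomes, theta_val, shared_first = shared_first),
        nearmedian_stage1_error = function(e) NULL
      )
      if (!is.null(r)) {
        s1 <- r
        retries <- attempt
        break
      }
    }
    if (is.null(s1)) {
      retries <- max_retries
      fell_back <- TRUE
      s1 <- stage1_sample(genomes, theta_val, shared_first = shared_first,
                          allow_shortfall = TRUE)
    }
    cur <- s1$set
    supp_cand <- 0L
    supp_added <- 0L
    if (supplement) {
      cand <- supplementary_sample(genomes, cur)
      supp_cand <- nrow(cand)
      add <- max_compatible_subset(cand, n)
      supp_added <- nrow(adjacencies(add))
      cur <- adjacency_set(rbind(adjacencies(cur), adjacencies(add)), n)
    }
    g <- complete_genome(cur, randomize = randomize_fill,
                         label = "near_median")
    dist <- vapply(genomes, function(x) breakpoint_distance(g, x), numeric(1))
    structure(list(
      genome = g,
      theta_used = theta_val,
      stage1_counts = s1$stage1_counts,
      shared_included = s1$shared_included,
      supplementary_candidates = supp_cand,
      supplementary_added = supp_added,
      filler_added = n - s1$shared_included - sum(s1$stage1_counts) -
        supp_added,
      per_genome_distance = as.integer(dist),
      normalized_score = sum(dist) / n,
      stage1_success = !fell_back,
      shortfall = s1$shortfall,
      retries = retries,
      seed = seed,
      k = k,
      n = n,
      input_labels = vapply(seq_len(k), function(i) {
        genomes[[i]]$label %||% paste0("genome_", i)
      }, character(1))
    ), class = "near_median")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.near_median <- function(x, ...) {
  cat(sprintf(
    "<near_median> k = %d genomes, n = %d genes, theta = %.5f\n",
    x$k, x$n, x$theta_used
  ))
  cat(sprintf(
    "  A: %d shared + %s stage-1 + %d supplementary + %d filler = %d\n",
    x$shared_included, paste(x$stage1_counts, collapse = "+"),
    x$supplementary_added, x$filler_added, x$n
  ))
  cat(sprintf(
    "  normalized score %.4f (distances: %s); stage 1 %s after %d retr%s\n",
    x$normalized_score, paste(x$per_genome_distance, collapse = ", "),
    if (x$stage1_success) "succeeded" else "fell back",
    x$retries, if (x$retries == 1L) "y" else "ies"
  ))
  invisible(x)
}

#' Exact breakpoint median by exhaustive enumeration
#'
#' Enumerates all `(2n - 1)!!` perfect matchings on the `2n` gene ends
#' (with branch-and-bound pruning) and returns a genome minimizing the
#' normalized score, ties broken by canonical pair order.  Only feasible
#' for tiny gene universes; `n > 7` is refused.  This is a test oracle —
#' the construction's score can never beat it.
#'
#' @param genomes List of genomes on the same `n <= 7` genes.
#' @return A list with elements `genome` (a median) and `score` (its
#'   normalized score).
#' @examples
#' gs <- random_genomes(4, k = 3, seed = 3)
#' brute_force_median(gs)$score
#' @export
brute_force_median <- function(genomes) {
  k <- length(genomes)
  if (k < 1L) abort("at least one genome is required")
  n <- check_same_universe(genomes)
  if (n > 7L) {
    abort(sprintf(
      "exhaustive median enumeration is limited to n <= 7 (got n = %d)", n
    ), class = "nearmedian_too_large")
  }
  nn <- 2L * n
  inc <- matrix(0L, nn, nn)
  for (g in genomes) {
    p <- adjacencies(g)
    inc[p] <- inc[p] + 1L  # canonical pairs: first < second
  }
  best_total <- -1L
  best_pairs <- NULL
  free <- rep(TRUE, nn)
  cur <- matrix(0L, n, 2L)
  rec <- function(depth, total) {
    if (depth > n) {
      if (total > best_total) {
        best_total <<- total
        best_pairs <<- cur[, , drop = FALSE]
      }
      return(invisible())
    }
    if (total + (n - depth + 1L) * k <= best_total) return(invisible())
    a <- which.max(free)
    free[a] <<- FALSE
    for (b in which(free)) {
      free[b] <<- FALSE
      cur[depth, 1L] <<- a
      cur[depth, 2L] <<- b
      rec(depth + 1L, total + inc[a, b])
      free[b] <<- TRUE
    }
    free[a] <<- TRUE
    invisible()
  }
  rec(1L, 0L)
  list(
    genome = genome(best_pairs, n, label = "median"),
    score = k - best_total / n
  )
}
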