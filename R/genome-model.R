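#' Breakpoint distance and the normalized score
#'
#' The breakpoint distance between two genomes on the same `n` genes is
#' `D = n - a`, where `a` is the number of adjacencies the genomes share.
#' It is symmetric, zero on identical genomes and at most `n`.
#' `count_shared()` returns `a` itself.  The *score* of a candidate genome
#' against `k` input genomes is the sum of normalized distances
#' `(1/n) * sum(D(candidate, G_i))`, which lies in `[0, k]`; the breakpoint
#' median minimizes it.
#'
#' @param a,b,candidate Genomes (see [genome()]).
#' @param inputs Non-empty list of genomes on the same gene universe.
#'
#' @return `breakpoint_distance()` and `count_shared()` a single
#'   non-negative integer; `breakpoint_score()` a single numeric value.
#'
#' @examples
#' g1 <- genome(c(1, 4, 3, 2), n = 2)
#' g2 <- genome(c(1, 2, 3, 4), n = 2)
#' breakpoint_distance(g1, g2)
#' breakpoint_score(g1, list(g1, g2, g2))
#' @export
breakpoint_distance <- function(a, b) {
  n <- check_same_universe(list(a, b))
  n - count_shared(a, b)
}

#' @rdname breakpoint_distance
#' @export
count_shared <- function(a, b) {
  check_same_universe(list(a, b))
  sum(adj_keys(a) %in% adj_keys(b))
}

#' @rdname breakpoint_distance
#' @export
breakpoint_score <- function(candidate, inputs) {
  if (!length(inputs)) abort("inputs must be a non-empty list of genomes")
  n <- check_same_universe(c(list(candidate), inputs))
  sum(vapply(inputs, function(g) breakpoint_distance(candidate, g),
             numeric(1))) / n
}

check_same_universe <- function(genomes) {
  ok <- vapply(genomes, inherits, logical(1), "adjacency_set")
  if (!all(ok)) abort("all inputs must be adjacency sets or genomes")
  ns <- vapply(genomes, n_genes, integer(1))
  if (length(unique(ns)) != 1L) {
    abort(
      sprintf("incomparable gene universes: n = %s",
              paste(unique(ns), collapse = ", ")),
      class = "nearmedian_universe_error"
    )
  }
  ns[[1L]]
}

#' Circular chromosome decomposition
#'
#' A genome (perfect matching on the `2n` gene ends) decomposes uniquely
#' into circular chromosomes: alternating traversal of gene edges
#' (head-tail of one gene) and adjacency edges yields disjoint cycles.
#' `chromosomes()` reports each cycle as a signed gene order in canonical
#' form — rotated so the smallest gene id comes first with positive sign —
#' with chromosomes ordered by their smallest gene.
#' `genome_from_chromosomes()` is the inverse: it encodes signed circular
#' gene orders as an adjacency matching (consecutive gene ends joined,
#' wrapping around).  The two functions round-trip exactly on canonical
#' forms.
#'
#' @param g A [genome()].
#' @param chroms List of signed integer vectors (or a single vector), one
#'   circular chromosome each; every gene `1..n` must appear exactly once
#'   across the list.
#' @param label Optional genome label.
#'
#' @return `chromosomes()` a list of signed integer vectors;
#'   `genome_from_chromosomes()` a [genome()].
#'
#' @examples
#' g <- genome_from_chromosomes(list(c(1, 2), 3))
#' chromosomes(g)
#' @export
chromosomes <- function(g) {
  stopifnot(inherits(g, "genome"))
  n <- g$n
  partner <- integer(2L * n)
  partner[g$pairs[, 1L]] <- g$pairs[, 2L]
  partner[g$pairs[, 2L]] <- g$pairs[, 1L]
  seen <- logical(n)
  out <- list()
  for (g0 in seq_len(n)) {
    if (seen[g0]) next
    chrom <- integer()
    cur <- g0
    sgn <- 1L
    repeat {
      seen[cur] <- TRUE
      chrom <- c(chrom, sgn * cur)
      # + genes are traversed tail -> head, - genes head -> tail
      exit <- if (sgn > 0L) 2L * cur - 1L else 2L * cur
      nxt_in <- partner[exit]
      nxt <- (nxt_in + 1L) %/% 2L
      if (nxt == g0) break
      cur <- nxt
      sgn <- if (nxt_in %% 2L == 0L) 1L else -1L
    }
    out[[length(out) + 1L]] <- chrom
  }
  out
}

#' @rdname chromosomes
#' @export
genome_from_chromosomes <- function(chroms, label = NULL) {
  if (is.numeric(chroms)) chroms <- list(chroms)
  genes <- unlist(chroms, use.names = FALSE)
  if (!length(genes)) abort("at least one gene is required")
  genes <- as.integer(genes)
  if (anyNA(genes) || any(genes == 0L)) {
    abort("chromosomes must contain non-zero signed integers")
  }
  ids <- sort(abs(genes))
  n <- length(ids)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate gene(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "nearmedian_format_error")
  }
  if (!identical(ids, seq_len(n))) {
    abort(sprintf("genes must cover 1..%d exactly once; missing: %s",
                  max(ids), paste(setdiff(seq_len(max(ids)), ids),
                                  collapse = ", ")),
          class = "nearmedian_format_error")
  }
  pairs <- do.call(rbind, lapply(chroms, function(ch) {
    ch <- as.integer(ch)
    nxt <- c(ch[-1L], ch[1L])
    # exit end of x, entry end of the following gene y
    out_end <- ifelse(ch > 0L, 2L * ch - 1L, -2L * ch)
    in_end <- ifelse(nxt > 0L, 2L * nxt, -2L * nxt - 1L)
    cbind(out_end, in_end)
  }))
  genome(pairs, n, label)
}
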