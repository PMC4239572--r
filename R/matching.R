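#' Maximum compatible subset of candidate adjacencies
#'
#' Candidate adjacencies gathered by [supplementary_sample()] may conflict
#' (share a gene end).  The largest number that can be added is the size
#' of a maximum-cardinality matching in the graph whose vertices are the
#' involved gene ends and whose edges are the candidates.  This solver is
#' exact, not greedy: the conflict graph is split into connected
#' components; pendant (degree-1) edges are repeatedly forced into the
#' matching — a safe reduction — and any remaining cyclic core (which for
#' the sparse conflict graphs arising here is tiny) is solved by
#' branch-and-bound on a minimum-degree vertex.  The result is
#' deterministic for a given candidate order.
#'
#' @param candidates Two-column integer matrix of end codes, one candidate
#'   adjacency per row (duplicates are removed), e.g. the output of
#'   [supplementary_sample()].
#' @param n Gene-universe size; defaults to the matrix's `"n"` attribute.
#' @return An [adjacency_set()] holding a maximum-cardinality compatible
#'   subset of the candidates.
#' @examples
#' # a path a-b, b-c, c-d: at most two of the three fit together
#' cand <- rbind(c(1, 2), c(2, 3), c(3, 4))
#' max_compatible_subset(cand, n = 2)
#' @export
max_compatible_subset <- function(candidates, n = attr(candidates, "n")) {
  if (is.null(n)) abort("n must be supplied (or attached as attr \"n\")")
  n <- as.integer(n)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(adjacency_set(NULL, n))
  }
  storage.mode(candidates) <- "integer"
  keys <- pair_keys(candidates, n)
  keep <- !duplicated(keys)
  candidates <- candidates[keep, , drop = FALSE]

  verts <- sort(unique(as.vector(candidates)))
  v1 <- match(candidates[, 1L], verts)
  v2 <- match(candidates[, 2L], verts)
  nv <- length(verts)

  # connected components via union-find on compressed vertices
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(v1)) {
    r1 <- find(v1[e]); r2 <- find(v2[e])
    if (r1 != r2) parent[r1] <- r2
  }
  comp_of_edge <- vapply(v1, find, integer(1))

  sel <- integer(0)
  for (cid in unique(comp_of_edge)) {
    eidx <- which(comp_of_edge == cid)
    sel <- c(sel, mm_component(eidx, v1, v2, nv))
  }
  adjacency_set(candidates[sel, , drop = FALSE], n)
}

# exact maximum matching on one component; returns selected edge indices
mm_component <- function(active, v1, v2, nv) {
  chosen <- integer(0)
  repeat {
    if (!length(active)) return(chosen)
    deg <- tabulate(c(v1[active], v2[active]), nv)
    pend <- deg[v1[active]] == 1L | deg[v2[active]] == 1L
    if (any(pend)) {
      # an edge at a degree-1 vertex always belongs to some maximum matching
      e <- active[which(pend)[1L]]
      chosen <- c(chosen, e)
      drop <- v1[active] == v1[e] | v2[active] == v1[e] |
        v1[active] == v2[e] | v2[active] == v2[e]
      active <- active[!drop]
      next
    }
    break
  }
  # cyclic core: branch on a minimum-degree vertex v — either v stays
  # unmatched or exactly one of its edges is used
  deg <- tabulate(c(v1[active], v2[active]), nv)
  vs <- unique(c(v1[active], v2[active]))
  v <- vs[which.min(deg[vs])]
  at_v <- v1[active] == v | v2[active] == v
  best <- mm_component(active[!at_v], v1, v2, nv)
  for (e in active[at_v]) {
    u <- if (v1[e] == v) v2[e] else v1[e]
    drop <- v1[active] == v | v2[active] == v |
      v1[active] == u | v2[active] == u
    cand <- c(e, mm_component(active[!drop], v1, v2, nv))
    if (length(cand) > length(best)) best <- cand
  }
  c(chosen, best)
}
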