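#' Adjacency sets and genomes
#'
#' An *adjacency* is an unordered pair of distinct gene ends; there are
#' `choose(2n, 2)` possible adjacencies over `n` genes (same-gene pairs
#' `{head(g), tail(g)}` are permitted and decode as single-gene circular
#' chromosomes).  An `adjacency_set` is a *compatible* collection of
#' adjacencies: no gene end occurs in more than one adjacency, so
#' `0 <= |set| <= n`.  A `genome` is an adjacency set of exactly `n`
#' adjacencies, i.e. a perfect matching on the `2n` ends; it decomposes into
#' circular chromosomes only (the model is circular-only: no telomeres).
#'
#' Pairs are stored canonically: within each pair the smaller end code
#' first, rows sorted by first then second end.  Construction validates
#' compatibility and rejects violating input with a classed error.
#'
#' @param pairs Two-column integer matrix of end codes (see [gene_end()]),
#'   one adjacency per row; or a plain integer vector of even length taken
#'   row-wise.  `NULL` gives the empty set.
#' @param n Gene-universe size (number of genes).
#' @param label Optional free-text label.
#' @param x An `adjacency_set` or `genome`.
#'
#' @return `adjacency_set()` returns an object of class `"adjacency_set"`;
#'   `genome()` of class `c("genome", "adjacency_set")`.  `adjacencies()`
#'   returns the canonical two-column matrix, `n_genes()` the universe
#'   size, `free_ends()` the sorted integer codes of ends not covered by
#'   any adjacency (of which there are `2n - 2|set|`).
#'
#' @examples
#' a <- adjacency_set(rbind(c(1, 4), c(3, 2)), n = 3)
#' free_ends(a)
#' g <- genome(rbind(c(1, 4), c(3, 2), c(5, 6)), n = 3, label = "toy")
#' as_tibble(g)
#' @export
adjacency_set <- function(pairs = NULL, n, label = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    abort("n must be a single positive integer")
  }
  pairs <- canonical_pairs(pairs)
  ends <- as.vector(pairs)
  if (length(ends)) {
    if (anyNA(ends) || any(ends < 1L) || any(ends > 2L * n)) {
      abort("gene-end codes must lie in 1..2n")
    }
    if (any(pairs[, 1L] == pairs[, 2L])) {
      abort("an adjacency must join two distinct gene ends")
    }
    if (anyDuplicated(ends)) {
      abort(
        "incompatible adjacencies: a gene end occurs in more than one adjacency",
        class = "nearmedian_compat_error"
      )
    }
  }
  structure(list(n = n, pairs = pairs, label = label),
            class = "adjacency_set")
}

#' @rdname adjacency_set
#' @export
genome <- function(pairs, n, label = NULL) {
  x <- adjacency_set(pairs, n, label)
  if (nrow(x$pairs) != x$n) {
    abort(sprintf(
      "a genome on %d genes needs exactly %d adjacencies (got %d): every gene end must be covered",
      x$n, x$n, nrow(x$pairs)
    ))
  }
  class(x) <- c("genome", "adjacency_set")
  x
}

# canonical form: min end first within pair, rows ordered by (first, second)
canonical_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) {
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("first", "second"))))
  }
  if (is.null(dim(pairs))) {
    if (length(pairs) %% 2L != 0L) {
      abort("pair vector must have even length")
    }
    pairs <- matrix(as.integer(pairs), ncol = 2L, byrow = TRUE)
  }
  if (ncol(pairs) != 2L) abort("pairs must have two columns")
  storage.mode(pairs) <- "integer"
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  o <- order(a, b)
  m <- cbind(first = a[o], second = b[o])
  rownames(m) <- NULL
  m
}

#' @rdname adjacency_set
#' @export
adjacencies <- function(x) {
  stopifnot(inherits(x, "adjacency_set"))
  x$pairs
}

#' @rdname adjacency_set
#' @export
n_genes <- function(x) {
  stopifnot(inherits(x, "adjacency_set"))
  x$n
}

#' @rdname adjacency_set
#' @export
free_ends <- function(x) {
  stopifnot(inherits(x, "adjacency_set"))
  used <- logical(2L * x$n)
  used[as.vector(x$pairs)] <- TRUE
  which(!used)
}

# unique numeric key per canonical adjacency; doubles are exact here
adj_keys <- function(x) pair_keys(x$pairs, x$n)

pair_keys <- function(pairs, n) {
  if (nrow(pairs) == 0L) return(double())
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  (as.double(a) - 1) * (2 * as.double(n)) + as.double(b)
}

#' @rdname adjacency_set
#' @param ... Passed on to methods (unused).
#' @method as_tibble adjacency_set
#' @export
as_tibble.adjacency_set <- function(x, ...) {
  p <- x$pairs
  tibble(
    end1 = format_gene_end(p[, 1L]),
    end2 = format_gene_end(p[, 2L]),
    end1_code = p[, 1L],
    end2_code = p[, 2L]
  )
}

#' @export
print.adjacency_set <- function(x, ...) {
  cat(sprintf("<adjacency_set> %d adjacencies over %d genes (%d free ends)\n",
              nrow(x$pairs), x$n, 2L * x$n - 2L * nrow(x$pairs)))
  if (nrow(x$pairs)) {
    shown <- utils::head(seq_len(nrow(x$pairs)), 8L)
    cat(" ", paste0("{", format_gene_end(x$pairs[shown, 1L]), ",",
                    format_gene_end(x$pairs[shown, 2L]), "}",
                    collapse = " "),
        if (nrow(x$pairs) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
print.genome <- function(x, ...) {
  chr <- chromosomes(x)
  cat(sprintf("<genome%s> %d genes, %d circular chromosome(s)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n, length(chr)))
  for (cc in utils::head(chr, 4L)) {
    cat("  (", paste(ifelse(cc > 0, paste0("+", cc), cc), collapse = " "),
        ")\n", sep = "")
  }
  if (length(chr) > 4L) cat("  ...\n")
  invisible(x)
}
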