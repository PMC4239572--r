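#' Gene-end (extremity) encoding
#'
#' A signed gene `g` in `1..n` has two extremities, its *head* and its *tail*.
#' The package encodes the `2n` gene ends of a genome as the integers
#' `1..2n`, with `head(g) = 2g - 1` and `tail(g) = 2g`.  This encoding gives
#' the canonical total order on ends used everywhere for deterministic
#' iteration and hashing: by gene, then side, with head before tail.
#'
#' `gene_end()` builds end codes from gene/side pairs; `end_gene()` and
#' `end_side()` invert it; `format_gene_end()` and `parse_gene_end()` convert
#' to and from the compact text form `"<gene><h|t>"` (for example `"12h"`)
#' used in adjacency TSV files.
#'
#' @param gene Integer vector of gene identifiers (>= 1).
#' @param side Character vector, `"head"` or `"tail"` (recycled against
#'   `gene`).
#' @param end Integer vector of end codes in `1..2n`.
#' @param x Character vector of end tokens such as `"3h"` or `"12T"`
#'   (case-insensitive).
#'
#' @return `gene_end()` and `parse_gene_end()` return integer end codes;
#'   `end_gene()` integer gene ids; `end_side()` a character vector of
#'   `"head"`/`"tail"`; `format_gene_end()` a character vector of tokens.
#'
#' @examples
#' gene_end(3, "head")
#' end_gene(6)
#' end_side(6)
#' format_gene_end(gene_end(c(1, 2), c("head", "tail")))
#' parse_gene_end("12h")
#' @export
gene_end <- function(gene, side) {
  gene <- as.integer(gene)
  if (any(is.na(gene)) || any(gene < 1L)) {
    abort("gene identifiers must be positive integers")
  }
  if (!all(side %in% c("head", "tail"))) {
    abort("side must be \"head\" or \"tail\"")
  }
  2L * gene - as.integer(side == "head")
}

#' @rdname gene_end
#' @export
end_gene <- function(end) (as.integer(end) + 1L) %/% 2L

#' @rdname gene_end
#' @export
end_side <- function(end) {
  ifelse(as.integer(end) %% 2L == 1L, "head", "tail")
}

#' @rdname gene_end
#' @export
format_gene_end <- function(end) {
  paste0(end_gene(end), ifelse(end_side(end) == "head", "h", "t"))
}

#' @rdname gene_end
#' @export
parse_gene_end <- function(x) {
  x <- tolower(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([0-9]+)([ht])$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(
      paste0("unparsable gene-end token(s): ",
             paste(utils::head(x[bad], 5L), collapse = ", ")),
      class = "nearmedian_parse_error"
    )
  }
  gene <- as.integer(vapply(m, `[`, character(1), 2L))
  side <- ifelse(vapply(m, `[`, character(1), 3L) == "h", "head", "tail")
  gene_end(gene, side)
}
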