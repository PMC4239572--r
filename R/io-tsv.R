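#' Read and write adjacency TSV files
#'
#' A flat tab-separated format for full genomes *and* partial adjacency
#' sets (useful for exporting the stage-1 set A' and diagnostics).
#' Columns: `genome_label`, `end1`, `end2`, with ends written as
#' `"<gene><h|t>"` tokens (e.g. `"12h"`; case-insensitive on read,
#' lowercase on write).  Compatibility is validated on read: two rows of
#' one record sharing a gene end are an error.
#'
#' @param path File path.
#' @param n Gene-universe size.  Defaults on read to the largest gene id
#'   seen in the file — supply it explicitly for partial sets whose
#'   largest gene is not covered.
#' @param sets An [adjacency_set()], [genome()], or (optionally named)
#'   list of them.
#' @return `read_adjacency_tsv()` a named list of [adjacency_set()]s;
#'   records with exactly `n` adjacencies are promoted to [genome()].
#'   `write_adjacency_tsv()` invisibly `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_adjacency_tsv(genome(c(1, 4, 3, 2), n = 2, label = "A"), tf)
#' read_adjacency_tsv(tf)
#' @export
read_adjacency_tsv <- function(path, n = NULL) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("genome_label", "end1", "end2")
  if (!all(need %in% names(d))) {
    abort(sprintf("adjacency TSV must have columns %s",
                  paste(need, collapse = ", ")),
          class = "nearmedian_format_error")
  }
  e1 <- parse_gene_end(d$end1)
  e2 <- parse_gene_end(d$end2)
  n <- as.integer(n %||% max(end_gene(c(e1, e2))))
  labels <- unique(d$genome_label)
  out <- lapply(labels, function(lb) {
    idx <- d$genome_label == lb
    s <- adjacency_set(cbind(e1[idx], e2[idx]), n, label = lb)
    if (nrow(s$pairs) == n) s <- genome(s$pairs, n, label = lb)
    s
  })
  names(out) <- labels
  out
}

#' @rdname read_adjacency_tsv
#' @export
write_adjacency_tsv <- function(sets, path) {
  if (inherits(sets, "adjacency_set")) sets <- list(sets)
  rows <- purrr::map(seq_along(sets), function(i) {
    s <- sets[[i]]
    stopifnot(inherits(s, "adjacency_set"))
    lbl <- s$label %||% names(sets)[i] %||% paste0("set_", i)
    if (!nzchar(lbl)) lbl <- paste0("set_", i)
    p <- adjacencies(s)
    tibble(
      genome_label = rep(lbl, nrow(p)),
      end1 = format_gene_end(p[, 1L]),
      end2 = format_gene_end(p[, 2L])
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
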