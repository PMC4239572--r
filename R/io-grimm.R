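#' Read and write GRIMM-style signed-permutation files
#'
#' The GRIMM dialect supported here: each genome starts with a header line
#' `">label"`, followed by whitespace-separated signed integers; each
#' circular chromosome is terminated by `"@"` (chromosomes may span
#' lines).  Genes `1..n` must each appear exactly once per genome, and all
#' genomes in a file share the same gene universe.  The model is
#' circular-only, so the linear terminator `"$"` is rejected loudly rather
#' than silently circularized.  Writing emits canonical chromosomes (see
#' [chromosomes()]), one `"@"`-terminated line each; `read_grimm()` and
#' `write_grimm()` round-trip exactly on canonical forms.
#'
#' @param path File path.
#' @param genomes A [genome()] or list of genomes.
#' @return `read_grimm()` a list of genomes (labelled from the headers);
#'   `write_grimm()` invisibly `path`.
#' @examples
#' tf <- tempfile(fileext = ".grimm")
#' write_grimm(genome_from_chromosomes(list(c(1, -2), 3), label = "A"), tf)
#' read_grimm(tf)
#' @export
read_grimm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  genomes <- list()
  cur_label <- NULL
  cur_chroms <- list()
  cur_tokens <- integer()
  flush_genome <- function() {
    if (is.null(cur_label)) return(invisible())
    if (length(cur_tokens)) {
      abort(sprintf("genome \"%s\": unterminated chromosome (missing \"@\")",
                    cur_label), class = "nearmedian_format_error")
    }
    if (!length(cur_chroms)) {
      abort(sprintf("genome \"%s\" has no chromosomes", cur_label),
            class = "nearmedian_format_error")
    }
    genomes[[length(genomes) + 1L]] <<-
      genome_from_chromosomes(cur_chroms, label = cur_label)
    invisible()
  }
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_label <- trimws(substring(line, 2L))
      cur_chroms <- list()
      cur_tokens <- integer()
      next
    }
    if (is.null(cur_label)) {
      abort("data before the first \">\" header",
            class = "nearmedian_format_error")
    }
    for (tok in strsplit(line, "[[:space:]]+")[[1L]]) {
      if (tok == "@") {
        if (!length(cur_tokens)) {
          abort("empty chromosome before \"@\"",
                class = "nearmedian_format_error")
        }
        cur_chroms[[length(cur_chroms) + 1L]] <- cur_tokens
        cur_tokens <- integer()
      } else if (tok == "$") {
        abort("linear chromosome terminator \"$\" is not supported: the model is circular-only",
              class = "nearmedian_format_error")
      } else {
        v <- suppressWarnings(as.integer(tok))
        if (is.na(v) || v == 0L) {
          abort(sprintf("malformed gene token \"%s\"", tok),
                class = "nearmedian_format_error")
        }
        cur_tokens <- c(cur_tokens, v)
      }
    }
  }
  flush_genome()
  if (!length(genomes)) {
    abort("no genomes found in file", class = "nearmedian_format_error")
  }
  ns <- vapply(genomes, n_genes, integer(1))
  if (length(unique(ns)) != 1L) {
    abort(sprintf("genomes in one file must share a gene universe (n = %s)",
                  paste(unique(ns), collapse = ", ")),
          class = "nearmedian_format_error")
  }
  genomes
}

#' @rdname read_grimm
#' @export
write_grimm <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  lines <- unlist(lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    stopifnot(inherits(g, "genome"))
    lbl <- g$label %||% paste0("genome_", i)
    c(paste0(">", lbl),
      vapply(chromosomes(g), function(ch) {
        paste(c(as.character(ch), "@"), collapse = " ")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
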