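#' Tidy a near-median construction result
#'
#' `tidy()` returns one row per input genome with its breakpoint distance
#' to the constructed genome and its stage-1 contribution; `glance()`
#' returns a one-row summary of the whole construction.
#'
#' @param x A `"near_median"` object from [near_median()].
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' res <- near_median(random_genomes(100, k = 3, seed = 1), seed = 2)
#' tidy(res)
#' glance(res)
#' @method tidy near_median
#' @export
tidy.near_median <- function(x, ...) {
  tibble(
    genome = x$input_labels,
    distance = x$per_genome_distance,
    normalized_distance = x$per_genome_distance / x$n,
    stage1_sampled = x$stage1_counts,
    shortfall = x$shortfall
  )
}

#' @rdname tidy.near_median
#' @method glance near_median
#' @export
glance.near_median <- function(x, ...) {
  tibble(
    k = x$k,
    n = x$n,
    theta = x$theta_used,
    shared_included = x$shared_included,
    stage1_total = sum(x$stage1_counts),
    supplementary_candidates = x$supplementary_candidates,
    supplementary_added = x$supplementary_added,
    filler_added = x$filler_added,
    normalized_score = x$normalized_score,
    stage1_success = x$stage1_success,
    retries = x$retries,
    seed = x$seed %||% NA_integer_
  )
}

#' @method autoplot near_median
#' @export
autoplot.near_median <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$genome, y = .data$normalized_distance)) +
    geom_col() +
    geom_hline(yintercept = object$normalized_score / object$k,
               linetype = "dashed") +
    labs(x = NULL, y = "normalized breakpoint distance",
         title = sprintf("Near-median score %.4f (theta = %.4f)",
                         object$normalized_score, object$theta_used),
         subtitle = "dashed line: score / k (perfect balance)")
}
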