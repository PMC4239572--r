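#' Optimal sampling fraction and score bounds
#'
#' In stage 1 of the construction, the same number `theta * n` of
#' adjacencies is sampled from each of `k` random input genomes.  After
#' `k - 1` genomes have contributed, the expected proportion of
#' adjacencies in the last genome with both ends still free is
#' `(1 - (k - 1) * theta)^2`, and sampling remains feasible (in
#' expectation) while this is at least `theta`.  The largest such
#' `theta` is
#' `theta*(k) = (2k - 1 - sqrt(4k - 3)) / (2 (k - 1)^2)`,
#' e.g. 1/4 for `k = 3`.  The resulting genome has normalized score at
#' most `k (1 - theta*(k))`, which exceeds the expected median score
#' `k - 1` of random genomes by a margin that vanishes as `k` grows.
#'
#' When all `k` genomes share a fraction `psi` of their adjacencies (which
#' are all pre-included in the construction), the feasibility condition
#' becomes `(1 - 2 theta - psi)^2 >= theta` for `k = 3` and analogously
#' for general `k`; `theta_max_shared()` returns the corresponding root
#' and `score_bound_shared()` the bound `k (1 - (theta + psi))`.  The
#' expected median score is then `median_score_shared() = (k - 1)(1 - psi)`.
#' For `k = 3` with additional pairwise-shared fractions `omega[i, j]`,
#' only the total `s = psi + sum_{i < j} omega[i, j]` matters:
#' `theta_max_general(psi, omega_sum)` returns
#' `(5 - 4s - sqrt(9 - 8s)) / 8` and `score_bound_general()` the bound
#' `3 (1 - (theta + s))`.
#'
#' All functions are vectorized over their first argument.
#'
#' @param k Number of input genomes (integer, >= 3).
#' @param psi Fraction in `[0, 1]` of adjacencies shared by all genomes.
#' @param omega_sum Sum of the pairwise-shared fractions over unordered
#'   pairs (`k = 3` semantics); `psi + omega_sum` must lie in `[0, 1]`.
#'
#' @return Numeric vector: a sampling fraction (`theta_*`) or a
#'   normalized-score value (`score_*`, `median_*`).
#'
#' @examples
#' theta_max(3)                   # 1/4
#' score_bound(4)                 # 3.24568
#' score_bound_shared(3, 0.625)   # 0.9375
#' median_score_shared(3, 0.625)  # 0.75
#' @export
theta_max <- function(k) {
  check_k(k)
  (2 * k - 1 - sqrt(4 * k - 3)) / (2 * (k - 1)^2)
}

#' @rdname theta_max
#' @export
score_bound <- function(k) k * (1 - theta_max(k))

#' @rdname theta_max
#' @export
theta_max_shared <- function(k, psi) {
  check_k(k)
  check_frac(psi, "psi")
  (2 * k + 2 * psi - 2 * k * psi - 1 - sqrt(4 * (k + psi - k * psi) - 3)) /
    (2 * (k - 1)^2)
}

#' @rdname theta_max
#' @export
score_bound_shared <- function(k, psi) {
  k * (1 - (theta_max_shared(k, psi) + psi))
}

#' @rdname theta_max
#' @export
median_score_shared <- function(k, psi) {
  check_k(k)
  check_frac(psi, "psi")
  (k - 1) * (1 - psi)
}

#' @rdname theta_max
#' @export
theta_max_general <- function(psi = 0, omega_sum = 0) {
  s <- psi + omega_sum
  check_frac(s, "psi + omega_sum")
  (5 - 4 * s - sqrt(9 - 8 * s)) / 8
}

#' @rdname theta_max
#' @export
score_bound_general <- function(psi = 0, omega_sum = 0) {
  s <- psi + omega_sum
  3 * (1 - (theta_max_general(psi, omega_sum) + s))
}

check_k <- function(k) {
  if (any(is.na(k)) || any(k < 3) || any(k != floor(k))) {
    abort("k must be an integer >= 3")
  }
  invisible(k)
}

check_frac <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(x)
}

#' Probability that stage-1 sampling can be completed
#'
#' After `theta * n` adjacencies have been drawn from each of the first
#' two (of three) genomes, the number `X` of adjacencies of the third
#' genome with two free ends is binomial with success probability
#' `p_theta = (1 - 2 theta)^2`; the construction succeeds when
#' `X >= theta * n`.  `success_prob_exact()` computes the exact binomial
#' upper tail `P(X >= ceiling(theta n))`.  `success_prob_normal()` uses
#' the standardized normal approximation with continuity correction,
#' `Z = (theta n + 0.5 - n p_theta) / sqrt(n p_theta (1 - p_theta))`,
#' returning `1 - pnorm(Z)`; the required count `theta * n` is kept
#' real-valued (not rounded) in this approximation.  The probability has a
#' sharp phase change at `theta = 1/4`: it tends to 1 with growing `n`
#' for `theta < 1/4` and to 0 for `theta > 1/4`.
#'
#' Both functions are vectorized and recycle `n` against `theta`.
#'
#' @param n Number of genes (>= 1).
#' @param theta Sampling fraction in `[0, 1/2]` (the construction itself
#'   needs `theta <= 1/3` for `k = 3`).
#' @return Probability in `[0, 1]`.
#' @examples
#' success_prob_normal(1000, 0.25)  # ~0.4854
#' success_prob_exact(5, 0.2)
#' @export
success_prob_exact <- function(n, theta) {
  check_theta_prob(theta)
  p <- (1 - 2 * theta)^2
  m <- ceiling(theta * n - 1e-9)
  out <- pbinom(m - 1, n, p, lower.tail = FALSE)
  out[theta == 0] <- 1
  out
}

#' @rdname success_prob_exact
#' @export
success_prob_normal <- function(n, theta) {
  check_theta_prob(theta)
  p <- (1 - 2 * theta)^2
  v <- n * p * (1 - p)
  z <- (theta * n + 0.5 - n * p) / sqrt(v)
  out <- 1 - pnorm(z)
  out[theta == 0] <- 1  # p = 1, zero required: certain success
  out[p == 0] <- 0      # theta = 1/2: no two-free-end adjacencies at all
  out
}

check_theta_prob <- function(theta) {
  if (any(is.na(theta)) || any(theta < 0) || any(theta > 0.5)) {
    abort("theta must lie in [0, 1/2]")
  }
  invisible(theta)
}

#' Reference tables for the construction's theory
#'
#' `theory_table1()` tabulates the normal-approximation success
#' probability of stage-1 sampling over a grid of genome sizes and
#' sampling fractions (long format; the default grid shows the phase
#' change at `theta = 1/4`).  `theory_table2()` tabulates the score bound
#' `k (1 - theta*(k))` against the median score `k - 1` for random
#' genomes.  `theory_table3()` does the same for genomes all sharing a
#' fraction `psi` of adjacencies, with the bound of
#' [score_bound_shared()], the expected median score of
#' [median_score_shared()], and their difference.
#'
#' @param n,k Integer vectors: grid of genome sizes / genome counts.
#' @param theta Numeric vector of sampling fractions.
#' @param psi All-shared fraction (single value).
#' @return A tibble (classed for [ggplot2::autoplot()]).
#' @examples
#' theory_table2(k = c(3, 4, 10))
#' @export
theory_table1 <- function(n = c(5, 10, 50, 100, 500, 1000, 2000, 10000),
                          theta = c(0.10, 0.20, 0.24, 0.25, 0.26, 0.30, 1 / 3)) {
  grid <- tidyr::expand_grid(n = as.integer(n), theta = theta)
  out <- mutate(grid,
                probability = success_prob_normal(.data$n, .data$theta))
  class(out) <- c("nm_table1", class(out))
  out
}

#' @rdname theory_table1
#' @export
theory_table2 <- function(k = c(3, 4, 5, 10, 50, 100, 500, 1000, 2000, 10000)) {
  k <- as.integer(k)
  out <- tibble(
    k = k,
    k_minus_1 = k - 1L,
    theta = theta_max(k),
    score_bound = score_bound(k),
    excess = score_bound(k) - (k - 1)
  )
  class(out) <- c("nm_table2", class(out))
  out
}

#' @rdname theory_table1
#' @export
theory_table3 <- function(k = c(3, 4, 5, 10, 50, 100, 500, 1000, 2000, 10000),
                          psi = 0.625) {
  k <- as.integer(k)
  out <- tibble(
    k = k,
    psi = psi,
    distance = score_bound_shared(k, psi),
    true_median = median_score_shared(k, psi),
    difference = score_bound_shared(k, psi) - median_score_shared(k, psi)
  )
  class(out) <- c("nm_table3", class(out))
  out
}

#' @method autoplot nm_table1
#' @export
autoplot.nm_table1 <- function(object, ...) {
  ggplot(object, aes(x = .data$n, y = .data$probability,
                     colour = factor(.data$theta),
                     group = factor(.data$theta))) +
    geom_line() +
    geom_point(size = 1) +
    scale_x_log10() +
    labs(x = "genome size n", y = "P(stage-1 sampling succeeds)",
         colour = expression(theta),
         title = expression("Phase change at" ~ theta == 0.25))
}

#' @method autoplot nm_table2
#' @export
autoplot.nm_table2 <- function(object, ...) {
  ggplot(object, aes(x = .data$k, y = .data$excess)) +
    geom_line() +
    geom_point(size = 1) +
    scale_x_log10() +
    labs(x = "number of genomes k",
         y = "score bound minus median score (k - 1)",
         title = "Approach of the construction to the median score")
}

#' @method autoplot nm_table3
#' @export
autoplot.nm_table3 <- function(object, ...) {
  ggplot(object, aes(x = .data$k, y = .data$difference)) +
    geom_line() +
    geom_point(size = 1) +
    scale_x_log10() +
    labs(x = "number of genomes k",
         y = "score bound minus expected median score",
         title = sprintf("Shared-adjacency case, psi = %.3g",
                         object$psi[[1]]))
}
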