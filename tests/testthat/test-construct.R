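test_that("stage-1 sampling draws equal quotas of two-free-end adjacencies", {
  gs <- random_genomes(1000, k = 3, seed = 31)
  withr::with_seed(32, {
    ok <- FALSE
    for (try in 1:20) {
      s1 <- tryCatch(stage1_sample(gs, theta = 0.25),
                     nearmedian_stage1_error = function(e) NULL)
      if (!is.null(s1)) { ok <- TRUE; break }
    }
    expect_true(ok)
  })
  expect_identical(s1$stage1_counts, c(250L, 250L, 250L))
  expect_gte(nrow(adjacencies(s1$set)), 750L)
  expect_true(s1$success)
  # every sampled adjacency belongs to its recorded source genome
  expect_identical(sort(unique(s1$sources$source[s1$sources$source != "shared"])),
                   c("genome_1", "genome_2", "genome_3"))
})

test_that("identical inputs saturate stage 1 through the shared set", {
  g <- random_genomes(40, k = 1, seed = 33)[[1]]
  s1 <- stage1_sample(list(g, g, g), theta = 0.25)
  expect_identical(s1$shared_included, 40L)
  expect_identical(s1$stage1_counts, c(0L, 0L, 0L))
  expect_true(s1$success)
})

test_that("stage-1 shortfall errors by default and is recorded under fallback", {
  # theta = 1/3 fails for large n with near certainty
  gs <- random_genomes(500, k = 3, seed = 34)
  withr::with_seed(35, {
    expect_error(stage1_sample(gs, theta = 1 / 3),
                 class = "nearmedian_stage1_error")
  })
  withr::with_seed(35, {
    s1 <- stage1_sample(gs, theta = 1 / 3, allow_shortfall = TRUE)
  })
  expect_false(s1$success)
  expect_gt(sum(s1$shortfall), 0L)
  expect_identical(sum(s1$stage1_counts) + s1$shared_included,
                   nrow(adjacencies(s1$set)))
})

test_that("supplementary sampling finds exactly the residual two-free-end adjacencies", {
  # hand-built: n = 4, A' of 3 adjacencies, one residual candidate left
  g1 <- genome_from_chromosomes(c(1, 2, 3, 4))   # contains {3h,4t} = (5, 8)
  g2 <- genome_from_chromosomes(c(1, -2, 3, -4))
  g3 <- genome_from_chromosomes(c(1, -3, 2, -4))
  aprime <- adjacency_set(c(1, 4, 3, 6, 2, 7), n = 4)  # frees ends 5 and 8
  cand <- supplementary_sample(list(g1, g2, g3), aprime)
  expect_identical(nrow(cand), 1L)
  expect_identical(as.vector(cand), c(5L, 8L))

  # a full genome leaves no candidates
  full <- complete_genome(aprime)
  expect_identical(nrow(supplementary_sample(list(g1, g2, g3), full)), 0L)

  # expected candidate volume after stage 1: (31/192) n for k = 3
  gs <- random_genomes(2000, k = 3, seed = 36)
  res <- near_median(gs, theta = 0.25, seed = 37)
  expect_lt(abs(res$supplementary_candidates - 31 / 192 * 2000),
            0.10 * 31 / 192 * 2000)
})

test_that("maximum compatible subset is exact on paths and random instances", {
  path <- rbind(c(1, 2), c(2, 3), c(3, 4))
  expect_identical(nrow(adjacencies(max_compatible_subset(path, n = 2))), 2L)
  expect_identical(nrow(adjacencies(max_compatible_subset(NULL, n = 2))), 0L)
  set.seed(38)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    cand <- matrix(sample(1:12, 2 * m, replace = TRUE), ncol = 2)
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    cand <- cand[!duplicated(nearmedian:::pair_keys(cand, 6)), , drop = FALSE]
    if (!nrow(cand)) next
    got <- nrow(adjacencies(max_compatible_subset(cand, n = 6)))
    expect_identical(got, oracle_max_compatible(cand))
  }
})

test_that("completion always yields a valid perfect matching", {
  set.seed(39)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    npairs <- sample(0:(n - 1), 1)
    ends <- sample(2 * n, 2 * npairs)
    partial <- adjacency_set(matrix(ends, ncol = 2), n)
    g <- complete_genome(partial)
    expect_s3_class(g, "genome")
    expect_identical(nrow(adjacencies(g)), n)
    expect_identical(free_ends(g), integer(0))
  }
  # a full genome passes through unchanged
  g0 <- random_genome(10)
  expect_identical(adjacencies(complete_genome(g0)), adjacencies(g0))
})

test_that("near_median diagnostics are consistent and reproducible", {
  gs <- random_genomes(600, k = 3, seed = 40)
  r1 <- near_median(gs, seed = 41)
  r2 <- near_median(gs, seed = 41)
  expect_identical(adjacencies(r1$genome), adjacencies(r2$genome))
  expect_identical(glance(r1), glance(r2))
  expect_identical(
    r1$shared_included + sum(r1$stage1_counts) + r1$supplementary_added +
      r1$filler_added,
    600L
  )
  expect_equal(r1$normalized_score,
               sum(r1$per_genome_distance) / r1$n, tolerance = 1e-12)
  expect_equal(r1$normalized_score,
               breakpoint_score(r1$genome, gs), tolerance = 1e-12)
  expect_error(near_median(gs[1:2]), "at least 3")

  d <- tidy(r1)
  expect_identical(nrow(d), 3L)
  expect_identical(d$distance, r1$per_genome_distance)
})

test_that("the supplementary stage never increases any per-genome distance", {
  for (s in 1:10) {
    gs <- random_genomes(400, k = 3, seed = 100 + s)
    base <- near_median(gs, supplement = FALSE, seed = 200 + s)
    supp <- near_median(gs, supplement = TRUE, seed = 200 + s)
    expect_lte(supp$normalized_score, base$normalized_score + 1e-12)
  }
})

test_that("auto theta honours the declared sharing level", {
  gs <- random_genomes(800, k = 3, psi = 0.5, seed = 42)
  r <- near_median(gs, psi = 0.5, seed = 43)
  expect_equal(r$theta_used, theta_max_shared(3, 0.5), tolerance = 1e-12)
  om <- matrix(0, 3, 3); om[1, 2] <- om[2, 1] <- 0.1
  r2 <- near_median(gs, psi = 0.3, omega = om, seed = 44)
  expect_equal(r2$theta_used, theta_max_general(0.3, 0.1), tolerance = 1e-12)
})

test_that("brute-force median is optimal and bounded by the construction", {
  g <- random_genomes(5, k = 1, seed = 45)[[1]]
  bf <- brute_force_median(list(g, g, g))
  expect_identical(adjacencies(bf$genome), adjacencies(g))
  expect_identical(bf$score, 0)

  # with a duplicated input genome at n = 2, the repeat is a median
  a <- genome(c(1, 4, 3, 2), n = 2)
  b <- genome(c(1, 2, 3, 4), n = 2)
  bf2 <- brute_force_median(list(a, a, b))
  expect_identical(adjacencies(bf2$genome), adjacencies(a))

  expect_error(brute_force_median(list(random_genome(8))),
               class = "nearmedian_too_large")

  set.seed(46)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    gs <- random_genomes(n, k = 3)
    bf <- brute_force_median(gs)
    nm <- near_median(gs, theta = 1 / n, seed = rep)
    expect_gte(nm$normalized_score, bf$score - 1e-12)
    # oracle cross-check at the smallest sizes: enumerate every matching
    if (n <= 5) {
      scores <- vapply(all_matchings(n), function(m) {
        breakpoint_score(genome(m, n), gs)
      }, numeric(1))
      expect_equal(bf$score, min(scores), tolerance = 1e-12)
    }
  }
})
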