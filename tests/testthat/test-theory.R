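test_that("the optimal sampling fraction solves its quadratic", {
  expect_equal(theta_max(3), 0.25, tolerance = 1e-12)
  expect_equal(theta_max(4), 0.18858, tolerance = 5e-6 / 0.18858)
  # root of 1 - 5 theta + 4 theta^2 at k = 3
  th <- theta_max(3)
  expect_equal(1 - 5 * th + 4 * th^2, 0, tolerance = 1e-12)
  # feasibility condition (1 - (k-1) theta)^2 = theta at equality
  for (k in c(3:10, 50, 1000)) {
    th <- theta_max(k)
    expect_equal((1 - (k - 1) * th)^2, th, tolerance = 1e-12)
  }
  expect_error(theta_max(2), "k must be")
})

test_that("score bounds exceed k - 1 and approach it as k grows", {
  expect_equal(score_bound(3), 2.25, tolerance = 1e-12)
  expect_equal(score_bound(4), 3.24568, tolerance = 5e-6)
  expect_equal(score_bound(10), 9.2026, tolerance = 5e-4)
  expect_equal(score_bound(2000), 1999.0216, tolerance = 5e-4)
  ks <- c(3:100, 1000, 10000)
  excess <- score_bound(ks) - (ks - 1)
  expect_true(all(excess > 0))
  expect_true(all(diff(score_bound(3:10000) - (3:10000 - 1)) < 0))
})

test_that("shared-adjacency theta and score bounds reproduce the reference values", {
  expect_equal(theta_max_shared(3, 0), theta_max(3), tolerance = 1e-12)
  expect_equal(theta_max_shared(5, 0), theta_max(5), tolerance = 1e-12)
  expect_equal(theta_max_shared(3, 0.625), 0.0625, tolerance = 1e-12)
  expect_equal(theta_max_shared(3, 1), 0, tolerance = 1e-12)
  expect_equal(theta_max_shared(7, 1), 0, tolerance = 1e-12)

  expect_equal(score_bound_shared(3, 0.625), 0.9375, tolerance = 5e-5)
  expect_equal(score_bound_shared(100, 0.625), 37.1785, tolerance = 5e-4)
  expect_equal(score_bound_shared(3, 0), 2.25, tolerance = 1e-12)

  expect_equal(median_score_shared(3, 0.625), 0.750, tolerance = 1e-12)
  expect_equal(median_score_shared(10, 0.625), 3.375, tolerance = 1e-12)
  expect_equal(median_score_shared(7, 0), 6, tolerance = 1e-12)

  # k = 3 feasibility condition (1 - 2 theta - psi)^2 = theta at equality
  for (psi in c(0, 0.2, 0.625, 0.9)) {
    th <- theta_max_shared(3, psi)
    expect_equal((1 - 2 * th - psi)^2, th, tolerance = 1e-12)
  }
})

test_that("the general k = 3 form depends only on psi + sum(omega)", {
  expect_equal(theta_max_general(0, 0), 0.25, tolerance = 1e-12)
  expect_equal(theta_max_general(0.625, 0), 0.0625, tolerance = 1e-12)
  expect_equal(theta_max_general(0.3, 0.325),
               theta_max_shared(3, 0.625), tolerance = 1e-12)
  expect_equal(score_bound_general(0, 0), 2.25, tolerance = 1e-12)
  expect_equal(score_bound_general(0.1, 0.2),
               score_bound_shared(3, 0.3), tolerance = 1e-12)
})

test_that("exact binomial tail matches term-by-term summation to 1e-12", {
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(1:30, 1)
    theta <- runif(1, 0.01, 0.45)
    expect_equal(success_prob_exact(n, theta), oracle_binom_tail(n, theta),
                 tolerance = 1e-12)
  }
  # direct 6-term check at n = 5, theta = 0.2
  expect_equal(success_prob_exact(5, 0.2), oracle_binom_tail(5, 0.2),
               tolerance = 1e-12)
  expect_equal(success_prob_exact(100, 0), 1)
})

test_that("exact and normal tails agree at large n away from the phase point", {
  expect_lt(abs(success_prob_exact(2000, 0.20) -
                  success_prob_normal(2000, 0.20)), 0.02)
})

test_that("normal approximation reproduces the full reference grid to 5e-4", {
  ref <- ref_table1()
  for (i in seq_along(ref$n)) {
    for (j in seq_along(ref$theta)) {
      got <- success_prob_normal(ref$n[i], ref$theta[j])
      expect_lt(abs(got - ref$vals[i, j]), 5e-4 + 1e-12,
                label = sprintf("|error| at n=%d theta=%.3f", ref$n[i],
                                ref$theta[j]))
    }
  }
})

test_that("success probability shows the phase change at theta = 1/4", {
  ns <- c(5, 10, 50, 100, 500, 1000, 2000, 10000, 1e5)
  below <- success_prob_normal(ns, 0.24)
  above <- success_prob_normal(ns, 0.26)
  at <- success_prob_normal(ns, 0.25)
  expect_true(all(diff(below) > 0))
  expect_gt(below[length(below)], 0.999)
  # decreasing from n = 10 on (the continuity correction lifts n = 5),
  # strictly until the tail underflows to zero
  above10 <- above[ns >= 10]
  expect_true(all(diff(above10) < 0 | above10[-1] == 0))
  expect_true(any(diff(above10) < 0))
  expect_lt(above[length(above)], 1e-4)
  expect_true(all(at > 0.30 & at < 0.51))
  expect_true(all(abs(at[ns >= 500] - 0.49) < 0.02))
  # monotone non-increasing in theta at fixed n
  tab <- theory_table1()
  for (nn in unique(tab$n)) {
    probs <- tab$probability[tab$n == nn][order(tab$theta[tab$n == nn])]
    expect_true(all(diff(probs) <= 1e-12))
  }
})

test_that("theory tables carry the printed headline cells", {
  t2 <- theory_table2()
  expect_equal(t2$score_bound[t2$k == 3], 2.25, tolerance = 1e-12)
  expect_equal(t2$score_bound[t2$k == 10], 9.2026, tolerance = 5e-4)
  expect_identical(t2$k_minus_1, t2$k - 1L)

  t3 <- theory_table3()
  r3 <- t3[t3$k == 3, ]
  expect_equal(r3$distance, 0.9375, tolerance = 5e-5)
  expect_equal(r3$true_median, 0.750, tolerance = 1e-12)
  expect_equal(r3$difference, 0.1875, tolerance = 5e-5)
  expect_equal(t3$distance[t3$k == 100], 37.1785, tolerance = 5e-4)
  # difference column strictly decreasing in k
  expect_true(all(diff(t3$difference) < 0))

  t1 <- theory_table1()
  expect_equal(t1$probability[t1$n == 1000 & abs(t1$theta - 0.25) < 1e-9],
               0.4854, tolerance = 5e-4)
})
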