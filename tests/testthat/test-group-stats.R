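test_that("the worked Mann-Whitney case gives U = 0 and exact p = 0.1", {
  cmp <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_two_sided, 0.1)
  expect_equal(cmp$method, "exact")
})

test_that("identical symmetric samples give U = n^2/2 and p = 1", {
  cmp <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(cmp$U, 4.5)
  expect_equal(cmp$p_two_sided, 1.0)
  expect_false(cmp$significant)
})

test_that("exact p equals the brute-force enumeration oracle", {
  set.seed(31)
  for (rep in 1:25) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    repeat {
      pooled <- round(rnorm(na + nb), 6)
      if (!anyDuplicated(pooled)) break
    }
    a <- pooled[seq_len(na)]; b <- pooled[-seq_len(na)]
    cmp <- mann_whitney_u(a, b)
    oracle <- oracle_mw_exact(a, b)
    expect_equal(cmp$U, oracle$U)
    expect_equal(cmp$p_two_sided, oracle$p, tolerance = 1e-12)
    # independent reference implementation agrees in the tie-free case
    expect_equal(cmp$p_two_sided,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the two one-sided statistics sum to n_a * n_b", {
  set.seed(32)
  for (rep in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    ua <- mann_whitney_u(a, b)$U
    ub <- mann_whitney_u(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("p is invariant under strictly monotone transforms", {
  set.seed(33)
  a <- rnorm(6); b <- rnorm(5, 0.8)
  p0 <- mann_whitney_u(a, b)$p_two_sided
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(mann_whitney_u(f(a), f(b))$p_two_sided, p0)
  }
  # also with the normal approximation
  a2 <- rnorm(20); b2 <- rnorm(20, 0.5)
  p1 <- mann_whitney_u(a2, b2)$p_two_sided
  expect_equal(mann_whitney_u(exp(a2), exp(b2))$p_two_sided, p1)
})

test_that("the normal approximation matches the reference implementation", {
  set.seed(34)
  a <- rnorm(25); b <- rnorm(30, 0.4)
  cmp <- mann_whitney_u(a, b)
  expect_equal(cmp$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(cmp$p_two_sided, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), b), "nonempty")
})

test_that("median CI uses the binomial order-statistic ranks", {
  ci <- median_with_ci(1:100)
  expect_equal(ci[["median"]], 50.5)
  expect_equal(ci[["ci_low"]], 40)
  expect_equal(ci[["ci_high"]], 61)
  expect_warning(ci1 <- median_with_ci(7), "coverage")
  expect_equal(unname(ci1), c(7, 7, 7))
  set.seed(35)
  for (rep in 1:20) {
    x <- rlnorm(sample(6:60, 1))
    ci <- median_with_ci(x)
    expect_lte(ci[["ci_low"]], ci[["median"]])
    expect_lte(ci[["median"]], ci[["ci_high"]])
    # claimed coverage actually reached by the chosen ranks
    n <- length(x)
    l <- match(ci[["ci_low"]], sort(x))
    u <- n + 1 - l
    expect_gte(pbinom(u - 1, n, 0.5) - pbinom(l - 1, n, 0.5), 0.95)
  }
})

test_that("cohort comparison covers all metrics with deterministic order", {
  cohort <- simulate_cohort(small_phantom(), n_per_group = 8L, base_seed = 4)
  cmp <- compare_cohorts(cohort$truth_table, c("control", "treated"))
  expect_equal(nrow(cmp), 8L)
  expect_equal(cmp$metric,
               c("tEDA", "tESA", "delta_pct_tA", "EDBA", "ESBA",
                 "SA", "EF", "MMI"))
  expect_error(compare_cohorts(cohort$truth_table, c("control", "mutant")),
               "unknown group")
})

test_that("comparing a cohort against itself finds nothing", {
  cohort <- simulate_cohort(small_phantom(), n_per_group = 6L, base_seed = 5)
  tab <- cohort$truth_table
  same <- rbind(
    transform(tab[tab$group == "control", ], group = "x"),
    transform(tab[tab$group == "control", ], group = "y"))
  cmp <- compare_cohorts(same, c("x", "y"))
  expect_true(all(cmp$p == 1))
  expect_true(all(!cmp$significant))
})

test_that("an impaired-emptying effect separates EF between cohorts", {
  cohort <- simulate_cohort(small_phantom(),
                            effect = list(blood_semi_axes_es = 1.15),
                            n_per_group = 30L, base_seed = 6)
  cmp <- compare_cohorts(cohort$truth_table, c("control", "treated"))
  ef <- cmp[cmp$metric == "EF", ]
  expect_lt(ef$p, 0.05)
  expect_lt(ef$median_b, ef$median_a)
})
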