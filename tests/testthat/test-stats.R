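test_that("signed-rank test reproduces enumerated exact p values", {
  w <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.25)                  # 2/8 sign patterns
  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p_value, 1)
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_equal(res$p_value, 1)
  # random continuous and tied inputs against brute-force enumeration
  set.seed(61)
  for (n in 3:8) {
    for (rep in 1:4) {
      d <- round(stats::rnorm(n), if (rep %% 2) 3 else 0)
      d <- d[d != 0]
      if (length(d) < 2) next
      expect_equal(wilcoxon_signed_rank(d)$p_value, brute_signrank_p(d),
                   tolerance = 1e-12, label = paste("n =", n))
    }
  }
})

test_that("Mann-Whitney test reproduces enumerated exact p values", {
  u <- mann_whitney_u(1:3, 4:6)
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 0.1)                   # 2/20 arrangements
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(63)
  for (n1 in 2:5) {
    for (n2 in 2:5) {
      x <- stats::rnorm(n1); y <- stats::rnorm(n2)
      expect_equal(mann_whitney_u(x, y)$p_value, brute_mwu_p(x, y),
                   tolerance = 1e-12, label = paste(n1, n2))
    }
  }
})

test_that("exact and approximate branches agree near the crossover", {
  set.seed(65)
  # signed rank at n = 25 (exact) vs the same data forced through normal
  for (rep in 1:10) {
    d <- stats::rnorm(25)
    pe <- wilcoxon_signed_rank(d, exact_max = 25)$p_value
    pn <- wilcoxon_signed_rank(d, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  for (rep in 1:10) {
    x <- stats::rnorm(10); y <- stats::rnorm(10)
    pe <- mann_whitney_u(x, y, exact_max = 20)$p_value
    pn <- mann_whitney_u(x, y, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(67)
  x <- stats::rnorm(12); y <- stats::rnorm(9)
  f <- function(v) exp(2 * v) - 1                # strictly increasing
  expect_equal(mann_whitney_u(x, y)$statistic,
               mann_whitney_u(f(x), f(y))$statistic)
  d <- stats::rnorm(10)
  g <- function(v) sign(v) * sqrt(abs(v))        # odd, increasing
  expect_equal(wilcoxon_signed_rank(d)$statistic,
               wilcoxon_signed_rank(g(d))$statistic)
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni(0.01, 6), 0.06)
  expect_equal(bonferroni(0.5, 6), 1)
  expect_equal(bonferroni(c(0.001, 0.2), 18), c(0.018, 1))
  expect_error(bonferroni(c(0.1, 0.2), 1), "family")
  # matches the base implementation on a family of its own size
  p <- c(0.001, 0.02, 0.3, 0.7)
  expect_equal(bonferroni(p), stats::p.adjust(p, "bonferroni"))
})

test_that("Hodges-Lehmann estimate is the pairwise-difference median", {
  hl <- suppressWarnings(hodges_lehmann(c(3, 5), c(1, 2)))
  expect_equal(hl$estimate, 2.5)                 # median of {1,2,3,4}
  # location equivariance
  set.seed(69)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  h0 <- hodges_lehmann(x, y)
  h1 <- hodges_lehmann(x + 3.25, y)
  expect_equal(h1$estimate, h0$estimate + 3.25)
  expect_equal(h1$ci_low, h0$ci_low + 3.25)
  # antisymmetry with reflected CI
  hxy <- hodges_lehmann(x, y); hyx <- hodges_lehmann(y, x)
  expect_equal(hxy$estimate, -hyx$estimate)
  expect_equal(hxy$ci_low, -hyx$ci_high)
  expect_equal(hxy$ci_high, -hyx$ci_low)
  # paired form: median of Walsh averages
  # n too small for a 95% interval: widest achievable CI, with a warning
  expect_warning(hp <- hodges_lehmann(c(1, 2, 6)), "widest achievable")
  expect_equal(hp$estimate, median(c(1, 1.5, 3.5, 2, 4, 6)))  # = 2.75
  expect_equal(c(hp$ci_low, hp$ci_high), c(1, 6))
})

test_that("Hedges' g matches its closed form and limits", {
  expect_equal(round(hedges_g(1.6, 0.3, 6, 1.2, 0.2, 6), 2), 1.45)
  expect_equal(hedges_g(5, 1, 10, 5, 1, 10), 0)
  # the correction factor vanishes asymptotically
  g_large <- hedges_g(1, 1, 1e6, 0, 1, 1e6)
  expect_equal(g_large, 1, tolerance = 1e-5)
  expect_error(hedges_g(1, 0, 5, 1, 0, 5), "zero")
})

test_that("sample-size and MDD formulas reproduce their worked examples", {
  g <- hedges_g(1.6, 0.3, 6, 1.2, 0.2, 6)
  expect_equal(sample_size_two_sample(g), 8L)
  expect_equal(sample_size_two_sample(0.5), 63L)   # 2*(2.8016/0.5)^2 = 62.8
  expect_equal(sample_size_two_sample(50), 1L)
  # the noncentral-t solver is one more conservative at this effect
  expect_equal(sample_size_two_sample(g, method = "t"), 9L)
  sp <- pooled_sd(0.3, 6, 0.2, 6)
  expect_equal(round(minimum_detectable_difference(15, sp), 2), 0.26)
  expect_equal(minimum_detectable_difference(15, 0), 0)
})

test_that("study analysis runs the plan and marks missing cells", {
  d <- two_group_cohort_design(n_per_group = 8, sites = c("top", "bottom"))
  coh <- generate_cohort(d, seed = 71)
  plan <- make_comparison_plan("G2", "velocity_m_s", sites = "pooled")
  res <- run_study_analysis(coh, plan)
  expect_equal(nrow(res), 1)
  expect_s3_class(res, "comparison_results")
  expect_true(res$hl_ci_low <= res$hl_estimate &
                res$hl_estimate <= res$hl_ci_high)
  # bit-reproducible on a seeded cohort
  res2 <- run_study_analysis(generate_cohort(d, seed = 71), plan)
  expect_identical(res, res2)
  # a cell with no data is marked, not an error
  plan_bad <- make_comparison_plan("G9", "velocity_m_s")
  res_bad <- run_study_analysis(coh, plan_bad)
  expect_true(is.na(res_bad$p_raw))
  expect_match(res_bad$note, "insufficient")
})

test_that("a true day-28 shift is detected with high power", {
  d <- two_group_cohort_design(n_per_group = 15)
  plan <- make_comparison_plan(c("G1", "G2"), "velocity_m_s",
                               between = list(c("G2", "G1")))
  hits <- vapply(1:60, function(s) {
    coh <- generate_cohort(d, seed = 500 + s)
    res <- run_study_analysis(coh, plan)
    res$p_adjusted[res$type == "paired" & res$group1 == "G2"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("the familywise error stays controlled under the null", {
  eff <- expand.grid(group = c("G1", "G2"), day = c(0, 28),
                     metric = c("velocity_m_s", "thickness_um"),
                     stringsAsFactors = FALSE)
  eff$mean <- ifelse(eff$metric == "velocity_m_s", 1.2, 500)
  eff$sd <- ifelse(eff$metric == "velocity_m_s", 0.2, 60)
  d <- list(effects = eff, n_per_group = 15)
  plan <- make_comparison_plan(c("G1", "G2"),
                               c("velocity_m_s", "thickness_um"),
                               between = list(c("G2", "G1")))
  any_hit <- vapply(1:400, function(s) {
    coh <- generate_cohort(d, seed = 2000 + s)
    res <- run_study_analysis(coh, plan)
    any(res$p_adjusted < 0.05, na.rm = TRUE)
  }, logical(1))
  # Bonferroni keeps the familywise rate at or below alpha (MC sd ~ 0.011)
  expect_lt(mean(any_hit), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
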