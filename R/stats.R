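# -- exact null distributions ------------------------------------------------

# distribution of twice the signed-rank statistic over all 2^n sign
# patterns, for arbitrary (mid)ranks; returns P(W2 = 0..sum(r2)) where
# r2 = 2 * ranks are integers even in the presence of ties
signrank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p
}

# counts of rank-sum arrangements for the Mann-Whitney U statistic
# (no ties): number of ways U = u over all choose(n1+n2, n1) arrangements
mwu_counts <- local({
  cache <- new.env(parent = emptyenv())
  function(n1, n2) {
    key <- paste(n1, n2)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # DP: c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1)
    tab <- vector("list", n1 + 1)
    for (m in 0:n1) tab[[m + 1]] <- vector("list", n2 + 1)
    for (n in 0:n2) tab[[1]][[n + 1]] <- 1          # m = 0: point mass at 0
    for (m in 1:n1) tab[[m + 1]][[1]] <- 1          # n = 0: point mass at 0
    if (n1 > 0 && n2 > 0) {
      for (m in 1:n1) {
        for (n in 1:n2) {
          a <- tab[[m]][[n + 1]]                    # c(u - n; m-1, n)
          b <- tab[[m + 1]][[n]]                    # c(u; m, n-1)
          len <- m * n + 1
          av <- c(numeric(n), a)[seq_len(len)]
          av[is.na(av)] <- 0
          bv <- c(b, numeric(len - length(b)))
          tab[[m + 1]][[n + 1]] <- av + bv
        }
      }
    }
    res <- tab[[n1 + 1]][[n2 + 1]]
    cache[[key]] <- res
    res
  }
})

# -- rank tests --------------------------------------------------------------

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment). For `n <= exact_max` differences the two-sided p value is
#' exact, computed from the null distribution of the statistic over all
#' 2^n sign patterns (midranks supported); for larger n a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for the exact branch (default 25).
#' @return A list: `statistic` (W = sum of ranks of positive differences),
#'   `p_value`, `n` (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "wilcoxon_signed_rank"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max) {
    p2 <- signrank_null(r)
    w2 <- as.integer(round(2 * W))
    lo <- sum(p2[seq_len(w2 + 1)])                 # P(W2 <= w2)
    hi <- sum(p2[(w2 + 1):length(p2)])             # P(W2 >= w2)
    p <- min(1, 2 * min(lo, hi))
    branch <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_term <- if (ties) {
      t_ <- table(abs(d)); sum(t_^3 - t_) / 48
    } else 0
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
    z <- (abs(W - mu) - 0.5) / sigma
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
    branch <- "normal"
  }
  list(statistic = W, p_value = p, n = n,
       method = paste0("wilcoxon_signed_rank_", branch))
}

#' Mann-Whitney U test for two independent samples
#'
#' U counts the pairs with `x > y` (ties contribute 1/2). For
#' `n1 + n2 <= exact_max` without ties the two-sided p value is exact,
#' from the null distribution of U over all rank arrangements; otherwise a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest n1 + n2 for the exact branch (default 20).
#' @return A list: `statistic` (U for x relative to y), `p_value`, `n1`,
#'   `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  comb <- c(x, y)
  r <- rank(comb)
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  ties <- any(duplicated(comb))
  if (n1 + n2 <= exact_max && !ties) {
    counts <- mwu_counts(n1, n2)
    tot <- sum(counts)
    u <- as.integer(round(U))
    lo <- sum(counts[seq_len(u + 1)]) / tot
    hi <- sum(counts[(u + 1):length(counts)]) / tot
    p <- min(1, 2 * min(lo, hi))
    branch <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_term <- if (ties) {
      t_ <- table(comb)
      n1 * n2 * sum(t_^3 - t_) / (12 * N * (N - 1))
    } else 0
    sigma <- sqrt(n1 * n2 * (N + 1) / 12 - tie_term)
    z <- max((abs(U - mu) - 0.5) / sigma, 0)
    p <- 2 * stats::pnorm(-z)
    branch <- "normal"
  }
  list(statistic = U, p_value = p, n1 = n1, n2 = n2,
       method = paste0("mann_whitney_u_", branch))
}

#' Bonferroni multiplicity correction
#'
#' `p_adj = min(1, m * p)` with `m` the family size (at least the number
#' of p values supplied).
#'
#' @param p vector of raw p values.
#' @param m family size (default `length(p)`).
#' @return Vector of adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m must be >= number of p values")
  pmin(1, m * p)
}

# largest k with P(T <= k) <= alpha2 under the exact null CDF given by
# cdf_fun; used to invert rank tests into order-statistic CIs
invert_rank_ci <- function(alpha2, qfun, pfun) {
  k <- qfun(alpha2)
  while (k > 0 && pfun(k) > alpha2) k <- k - 1
  if (pfun(k) > alpha2) k <- -1    # even k = 0 exceeds alpha2
  k
}

#' Hodges-Lehmann shift estimate with confidence interval
#'
#' Two-sample form (both `x` and `y` given): the estimate is the median of
#' all `n1 * n2` pairwise differences `x_i - y_j`; the CI comes from order
#' statistics of the sorted differences at ranks obtained by inverting the
#' Mann-Whitney null distribution (normal approximation for large
#' samples). Paired/one-sample form (`y = NULL`): the estimate is the
#' median of the Walsh averages `(x_i + x_j)/2, i <= j`, with signed-rank
#' inversion for the CI.
#'
#' @param x numeric sample (or paired differences when `y` is `NULL`).
#' @param y optional second sample.
#' @param conf confidence level (default 0.95).
#' @return A list: `estimate`, `ci_low`, `ci_high`, `conf`,
#'   `achieved_conf` (`NA` when the normal approximation was used).
#' @export
hodges_lehmann <- function(x, y = NULL, conf = 0.95) {
  alpha2 <- (1 - conf) / 2
  if (is.null(y)) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) stop("need at least 2 observations")
    idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    walsh <- sort((x[idx[, 1]] + x[idx[, 2]]) / 2)
    M <- length(walsh)
    est <- stats::median(walsh)
    if (n <= 50) {
      k <- invert_rank_ci(alpha2,
                          function(a) stats::qsignrank(a, n),
                          function(q) stats::psignrank(q, n))
      ach <- if (k >= 0) 1 - 2 * stats::psignrank(k, n) else NA_real_
    } else {
      k <- floor(n * (n + 1) / 4 -
                   stats::qnorm(1 - alpha2) *
                   sqrt(n * (n + 1) * (2 * n + 1) / 24))
      ach <- NA_real_
    }
    ci <- order_stat_ci(walsh, k)
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample")
    diffs <- sort(as.vector(outer(x, y, `-`)))
    est <- stats::median(diffs)
    if (n1 + n2 <= 60) {
      k <- invert_rank_ci(alpha2,
                          function(a) stats::qwilcox(a, n1, n2),
                          function(q) stats::pwilcox(q, n1, n2))
      ach <- if (k >= 0) 1 - 2 * stats::pwilcox(k, n1, n2) else NA_real_
    } else {
      k <- floor(n1 * n2 / 2 -
                   stats::qnorm(1 - alpha2) *
                   sqrt(n1 * n2 * (n1 + n2 + 1) / 12))
      ach <- NA_real_
    }
    ci <- order_stat_ci(diffs, k)
  }
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], conf = conf,
       achieved_conf = ach)
}

# CI from sorted values at ranks (k+1, M-k); falls back to the widest
# achievable interval with a warning when k is too small
order_stat_ci <- function(sorted_vals, k) {
  M <- length(sorted_vals)
  if (k < 0 || k + 1 > M - k) {
    warning("sample too small for the requested confidence; ",
            "returning the widest achievable interval")
    return(c(sorted_vals[1], sorted_vals[M]))
  }
  c(sorted_vals[k + 1], sorted_vals[M - k])
}

# -- effect size and power ---------------------------------------------------

#' Pooled standard deviation of two group summaries
#'
#' @param sd1,sd2 group SDs.
#' @param n1,n2 group sizes.
#' @return `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#' @export
pooled_sd <- function(sd1, n1, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Hedges' g standardized mean difference
#'
#' Cohen's d on the pooled SD, multiplied by the small-sample bias
#' correction `1 - 3 / (4 df - 1)` with `df = n1 + n2 - 2`. With group
#' summaries 1.6 (SD 0.3, n 6) vs 1.2 (SD 0.2, n 6) this gives g = 1.45.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return Hedges' g (signed).
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  sp <- pooled_sd(sd1, n1, sd2, n2)
  if (sp == 0) stop("pooled SD is zero")
  d <- (mean1 - mean2) / sp
  df <- n1 + n2 - 2
  d * (1 - 3 / (4 * df - 1))
}

#' Per-group sample size for a two-sample comparison
#'
#' Normal-approximation formula
#' \deqn{n = \lceil 2 ((z_{1-\alpha/2} + z_{power}) / g)^2 \rceil}
#' per group, at standardized effect size `g`. The optional noncentral-t
#' method solves the exact two-sample t power instead (it is slightly more
#' conservative: one more animal at moderate effects).
#'
#' @param effect_size_g standardized effect size (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power 1 - beta (default 0.80).
#' @param method `"normal"` (default) or `"t"`.
#' @return Integer sample size per group.
#' @export
sample_size_two_sample <- function(effect_size_g, alpha = 0.05,
                                   power = 0.80, method = c("normal", "t")) {
  if (effect_size_g <= 0) stop("effect size must be > 0")
  method <- match.arg(method)
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
    return(max(1L, as.integer(ceiling(2 * (z / effect_size_g)^2))))
  }
  pow_at <- function(n) {
    df <- 2 * (n - 1)
    ncp <- effect_size_g * sqrt(n / 2)
    q <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(q, df, ncp) + stats::pt(-q, df, ncp)
  }
  n <- 2L
  while (pow_at(n) < power && n < 1e6) n <- n + 1L
  n
}

#' Minimum detectable difference for a two-sample comparison
#'
#' \deqn{MDD = (z_{1-\alpha/2} + z_{power}) \, sd \, \sqrt{2/n}}
#' in the units of the measurement SD.
#'
#' @param n per-group sample size (>= 2).
#' @param sd measurement SD (typically the pooled SD of a pilot summary).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return MDD in the units of `sd`.
#' @export
minimum_detectable_difference <- function(n, sd, alpha = 0.05,
                                          power = 0.80) {
  if (n < 2) stop("need n >= 2")
  if (sd <= 0) {
    if (sd < 0) stop("sd must be >= 0")
    return(0)
  }
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * sd * sqrt(2 / n)
}

# -- study-level analysis ----------------------------------------------------

#' Build a comparison plan for a longitudinal study table
#'
#' One row per planned comparison cell. Within-group rows are paired
#' (baseline vs final day inside one group); between-group rows compare
#' two groups at the final day. The Bonferroni family is the whole plan.
#'
#' @param groups character vector of group labels for within-group rows.
#' @param metrics metrics to test.
#' @param sites `"top"`, `"bottom"` and/or `"pooled"` (per-animal mean of
#'   the two sites).
#' @param day_baseline,day_final the two days of the paired comparison.
#' @param between list of 2-vectors of group labels compared at
#'   `day_final`.
#' @return A data.frame with columns `metric`, `type`, `group1`, `group2`,
#'   `day1`, `day2`, `site`.
#' @export
make_comparison_plan <- function(groups, metrics, sites = "pooled",
                                 day_baseline = 0, day_final = 28,
                                 between = list()) {
  within <- expand.grid(metric = metrics, group1 = groups, site = sites,
                        stringsAsFactors = FALSE)
  within$type <- "paired"
  within$group2 <- NA_character_
  within$day1 <- day_baseline
  within$day2 <- day_final
  rows <- list(within[, c("metric", "type", "group1", "group2",
                          "day1", "day2", "site")])
  for (b in between) {
    bg <- expand.grid(metric = metrics, site = sites,
                      stringsAsFactors = FALSE)
    bg$type <- "between"
    bg$group1 <- b[1]
    bg$group2 <- b[2]
    bg$day1 <- day_final
    bg$day2 <- NA_real_
    rows <- c(rows, list(bg[, c("metric", "type", "group1", "group2",
                                "day1", "day2", "site")]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-animal values for one (group, day, metric, site) cell;
# site = "pooled" averages the sites per animal
cell_values <- function(cohort, group, day, metric, site) {
  sub <- cohort[cohort$group == group & cohort$day == day &
                  cohort$metric == metric, , drop = FALSE]
  if (site != "pooled") sub <- sub[sub$site == site, , drop = FALSE]
  if (!nrow(sub)) return(numeric(0))
  vapply(split(sub$value, sub$animal_id), mean, numeric(1))
}

#' Run the planned nonparametric analysis on a cohort table
#'
#' Executes each row of a comparison plan on a long-format cohort table:
#' paired rows use the Wilcoxon signed-rank test on per-animal day
#' differences with the paired Hodges-Lehmann estimate; between-group rows
#' use the Mann-Whitney U test with the two-sample Hodges-Lehmann
#' estimate. Site `"pooled"` averages the two sites per animal before
#' testing. The Bonferroni family is the full plan (one results table).
#'
#' @param cohort a `cohort_table` (columns `animal_id`, `group`, `site`,
#'   `day`, `metric`, `value`).
#' @param plan a plan data.frame from [make_comparison_plan()].
#' @param conf confidence level for the Hodges-Lehmann intervals.
#' @return A data.frame of class `comparison_results`, one row per plan
#'   cell: `metric`, `type`, `group1`, `group2`, `site`, `day1`, `day2`,
#'   `method`, `statistic`, `p_raw`, `p_adjusted`, `hl_estimate`,
#'   `hl_ci_low`, `hl_ci_high`, `n1`, `n2`, `note`. For paired rows
#'   `hl_estimate` is the day2 - day1 shift; for between rows it is
#'   group1 - group2.
#' @export
run_study_analysis <- function(cohort, plan, conf = 0.95) {
  stopifnot(is.data.frame(cohort), is.data.frame(plan))
  res <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pr <- plan[i, ]
    row <- data.frame(metric = pr$metric, type = pr$type,
                      group1 = pr$group1, group2 = pr$group2,
                      site = pr$site, day1 = pr$day1, day2 = pr$day2,
                      method = NA_character_, statistic = NA_real_,
                      p_raw = NA_real_, p_adjusted = NA_real_,
                      hl_estimate = NA_real_, hl_ci_low = NA_real_,
                      hl_ci_high = NA_real_, n1 = NA_integer_,
                      n2 = NA_integer_, note = "",
                      stringsAsFactors = FALSE)
    if (pr$type == "paired") {
      v1 <- cell_values(cohort, pr$group1, pr$day1, pr$metric, pr$site)
      v2 <- cell_values(cohort, pr$group1, pr$day2, pr$metric, pr$site)
      common <- intersect(names(v1), names(v2))
      if (length(common) < 2) {
        row$note <- "insufficient paired animals"
        res[[i]] <- row; next
      }
      d <- v2[common] - v1[common]
      tst <- wilcoxon_signed_rank(d)
      hl <- hodges_lehmann(d, conf = conf)
      row$n1 <- row$n2 <- length(common)
    } else {
      x <- cell_values(cohort, pr$group1, pr$day1, pr$metric, pr$site)
      y <- cell_values(cohort, pr$group2, pr$day1, pr$metric, pr$site)
      if (length(x) < 2 || length(y) < 2) {
        row$note <- "insufficient animals in a group"
        res[[i]] <- row; next
      }
      tst <- mann_whitney_u(x, y)
      hl <- hodges_lehmann(x, y, conf = conf)
      row$n1 <- length(x); row$n2 <- length(y)
    }
    row$method <- tst$method
    row$statistic <- tst$statistic
    row$p_raw <- tst$p_value
    row$hl_estimate <- hl$estimate
    row$hl_ci_low <- hl$ci_low
    row$hl_ci_high <- hl$ci_high
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- bonferroni(out$p_raw[ok], m = nrow(plan))
  rownames(out) <- NULL
  class(out) <- c("comparison_results", "data.frame")
  out
}
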