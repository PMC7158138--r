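test_that("rm-ANOVA matches a brute-force sums-of-squares oracle and aov()", {
  m <- matrix(c(3, 5, 4,
                6, 8, 9,
                2, 3, 5), nrow = 3, byrow = TRUE)
  res <- rm_anova_oneway(m)
  # brute-force two-way decomposition
  grand <- mean(m)
  ss_treat <- 3 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_treat - ss_subj
  f_oracle <- (ss_treat / 2) / (ss_err / 4)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$df, c(2, 4))

  # independent oracle: aov with subject stratum
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(1:3, times = 3)),
                   treatment = factor(rep(1:3, each = 3)))
  a <- summary(stats::aov(y ~ treatment + Error(subject), data = df))
  tab <- a[["Error: Within"]][[1]]
  expect_equal(res$statistic, tab["treatment", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, tab["treatment", "Pr(>F)"], tolerance = 1e-10)
})

test_that("rm-ANOVA at k = 2 equals the squared paired t statistic", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rnorm(20), ncol = 2)
    res <- rm_anova_oneway(m)
    tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("rm-ANOVA degenerate inputs", {
  # every subject identical across treatments: no effect, p = 1
  same <- matrix(rep(c(4, 7, 9), times = 3), nrow = 3)
  res <- rm_anova_oneway(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # strong effect, zero error: subjects shift in lockstep
  lock <- outer(c(0, 1, 2), c(10, 20, 30), "+")
  res2 <- rm_anova_oneway(lock)
  expect_equal(res2$p_value, 0)
  expect_true(res2$degenerate)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("Scheffe post hoc flags exactly the separated treatment", {
  set.seed(9)
  m <- matrix(rnorm(40, 10, 0.5), ncol = 4)
  expect_false(any(scheffe_posthoc(m)$significant))

  m2 <- m
  m2[, 3] <- m2[, 3] + 50  # one treatment far outside noise
  sp <- scheffe_posthoc(m2)
  involves3 <- sp$treatment_a == "3" | sp$treatment_b == "3"
  expect_true(all(sp$significant[involves3]))
  expect_false(any(sp$significant[!involves3]))
})

test_that("Scheffe is never significant when the omnibus F is below critical", {
  set.seed(13)
  for (i in 1:50) {
    m <- matrix(rnorm(30), ncol = 3)
    om <- rm_anova_oneway(m)
    crit <- stats::qf(0.95, om$df[1], om$df[2])
    if (om$statistic < crit)
      expect_false(any(scheffe_posthoc(m)$significant))
  }
})

test_that("Friedman statistic and exact permutation p on toy data", {
  same <- matrix(rep(c(5, 5, 5), times = 3), nrow = 3)
  expect_equal(friedman_test(same)$statistic, 0)

  consistent <- matrix(c(1, 2, 3,
                         10, 20, 30,
                         0.1, 0.2, 0.3), nrow = 3, byrow = TRUE)
  res <- friedman_test(consistent)
  expect_equal(res$statistic, 6)
  expect_equal(res$p_exact, 6 / 216)
  expect_equal(res$p_value, 6 / 216)

  # agreement with stats::friedman.test on untied data (chi-square route)
  set.seed(3)
  m <- matrix(rnorm(40), ncol = 4)
  mine <- friedman_test(m, exact_limit = 1)   # force chi-square
  ref <- stats::friedman.test(m)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)

  expect_error(friedman_test(matrix(1:3, ncol = 1)), "2 subjects and 2 treatments")
})

test_that("Steel-Dwass standardized rank sums match hand and oracle values", {
  # separated groups: W at its minimum, tie-free variance n1 n2 (N+1)/12
  sd1 <- steel_dwass_posthoc(list(a = c(1, 2, 3), b = c(10, 11, 12)))
  expect_equal(sd1$z, (6 - 10.5) / sqrt(5.25), tolerance = 1e-12)

  # identical groups within a pair -> z = 0, never significant
  sd2 <- steel_dwass_posthoc(list(a = c(4, 5, 6), b = c(4, 5, 6)))
  expect_equal(sd2$z, 0)
  expect_false(sd2$significant)

  # z agrees with an independent rank-sum computation before the
  # studentized-range referral, across random group sets
  set.seed(17)
  groups <- lapply(1:4, function(i) rnorm(8))
  res <- steel_dwass_posthoc(groups)
  for (j in seq_len(nrow(res))) {
    x <- groups[[as.integer(res$group_a[j])]]
    y <- groups[[as.integer(res$group_b[j])]]
    r <- rank(c(x, y))
    w <- sum(r[seq_along(x)])
    nn <- length(x) + length(y)
    ew <- length(x) * (nn + 1) / 2
    vw <- length(x) * length(y) * (nn + 1) / 12  # no ties here
    expect_equal(res$z[j], (w - ew) / sqrt(vw), tolerance = 1e-10)
  }
  # zero-spread group pair flagged degenerate
  sd3 <- steel_dwass_posthoc(list(a = c(2, 2), b = c(2, 2)))
  expect_true(sd3$degenerate)
})

test_that("Wilcoxon signed-rank exact enumeration and conventions", {
  res <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.25)  # 2/8 sign patterns reach W+ = 6

  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)

  allz <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(allz$p_value, 1)
  expect_true(allz$degenerate)

  # zeros dropped: same result as without them
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 0))$p_value,
               wilcoxon_signed_rank(c(1, 2, 3))$p_value)

  # matches stats::wilcox.test exact p on tie-free data
  set.seed(23)
  for (i in 1:10) {
    d <- round(rnorm(12), 2)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    mine <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Wilcoxon exact and normal-approximation p agree at n = 20", {
  set.seed(29)
  for (i in 1:20) {
    d <- rnorm(20)
    pe <- wilcoxon_signed_rank(d, method = "exact")$p_value
    pa <- wilcoxon_signed_rank(d, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("rank tests are shift- and monotone-invariant", {
  set.seed(37)
  m <- matrix(rnorm(30, 5, 1), ncol = 3)
  f1 <- friedman_test(m)
  expect_equal(friedman_test(m + 100)$statistic, f1$statistic)
  expect_equal(friedman_test(exp(m))$statistic, f1$statistic)
  a1 <- rm_anova_oneway(m)
  a2 <- rm_anova_oneway(m + 100)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-9)
  g <- lapply(1:3, function(i) rnorm(6))
  s1 <- steel_dwass_posthoc(g)
  s2 <- steel_dwass_posthoc(lapply(g, function(x) exp(x) + 3))
  expect_equal(s1$z, s2$z, tolerance = 1e-12)
})

test_that("familywise error of Steel-Dwass stays controlled under the null", {
  set.seed(41)
  n_rep <- 800L
  hits <- 0L
  for (i in seq_len(n_rep)) {
    g <- lapply(1:5, function(j) rnorm(10))
    if (any(steel_dwass_posthoc(g)$significant)) hits <- hits + 1L
  }
  expect_lte(hits / n_rep, 0.07)
})
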