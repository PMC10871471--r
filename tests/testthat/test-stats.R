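test_that("exact Wilcoxon p matches exhaustive enumeration", {
  # oracle: enumerate all C(6,3) = 20 labelings of the pooled sample
  pooled <- c(1, 2, 3, 4, 5, 6)
  obs <- sum(rank(pooled)[1:3])
  sums <- apply(utils::combn(6, 3), 2, function(i) sum(rank(pooled)[i]))
  mu <- mean(sums)
  p_enum <- mean(abs(sums - mu) >= abs(obs - mu))
  expect_equal(p_enum, 0.1)
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_true(w$exact)
  expect_equal(w$statistic, 6) # rank sum of the smaller-valued group
})

test_that("identical groups give p = 1", {
  w <- wilcoxon_rank_sum(c(2, 5, 9, 9), c(2, 5, 9, 9))
  expect_equal(w$p_value, 1.0)
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:5) {
    a <- stats::rnorm(8); b <- stats::rnorm(9, mean = 0.5)
    p0 <- wilcoxon_rank_sum(a, b)$p_value
    expect_equal(wilcoxon_rank_sum(exp(a), exp(b))$p_value, p0)
    expect_equal(wilcoxon_rank_sum(3 * a - 100, 3 * b - 100)$p_value, p0)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("exact enumeration agrees with a 1e6-draw permutation estimate", {
  a <- c(1.2, 2.9, 3.1, 4.5, 6.2)
  b <- c(2.1, 3.3, 5.0, 7.1, 8.4)
  p_exact <- wilcoxon_rank_sum(a, b)$p_value
  pooled <- c(a, b)
  combos <- utils::combn(10, 5)
  sums <- apply(combos, 2, function(i) sum(rank(pooled)[i]))
  obs <- sum(rank(pooled)[1:5])
  mu <- mean(sums)
  set.seed(12345)
  draw <- sums[sample.int(ncol(combos), 1e6, replace = TRUE)]
  p_mc <- mean(abs(draw - mu) >= abs(obs - mu))
  se <- sqrt(p_mc * (1 - p_mc) / 1e6)
  expect_lt(abs(p_mc - p_exact), 3 * se)
})

test_that("OLS matches closed-form formulas", {
  # perfect fit
  ages <- c(25, 35, 45, 55, 65)
  fit <- linreg_age(2 * ages + 1, ages)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  # hand-computed 3-point oracle: (1,1), (2,3), (3,2)
  f <- linreg_age(c(1, 3, 2), c(1, 2, 3))
  expect_equal(f$slope, 0.5)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 0.25)
  se <- sqrt((1.5 / 1) / 2) # sqrt(SSE/(n-2)/Sxx)
  expect_equal(f$p_value, 2 * stats::pt(-abs(0.5 / se), df = 1))
  # degenerate cases
  d <- linreg_age(c(5, 5, 5), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$r_squared, 0)
  expect_equal(d$p_value, 1)
  expect_error(linreg_age(c(1, 2, 3), c(4, 4, 4)), "ages")
  expect_error(linreg_age(c(1, 2), c(1, 2)), "3 points")
})

test_that("R^2 equals the squared correlation of fitted and observed", {
  set.seed(11)
  for (i in 1:5) {
    x <- stats::runif(12, 20, 70)
    y <- 0.3 * x + stats::rnorm(12, sd = 3)
    f <- linreg_age(y, x)
    expect_equal(f$r_squared, stats::cor(y, f$intercept + f$slope * x)^2,
                 tolerance = 1e-10)
  }
})

test_that("volume-contrast correlation handles exact and degenerate cases", {
  tab <- data.frame(
    subject_id = sprintf("s%d", 1:6),
    group = rep("non-smoker", 6), age = 30:35, region = "WholeBrain",
    mean_percent = c(1, 2, 3, 4, 5, 6),
    gm_fraction = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    wm_fraction = rep(0.4, 6), stringsAsFactors = FALSE)
  v <- volume_contrast_correlation(tab)
  expect_equal(v$r_squared[v$tissue == "gm"], 1)
  expect_true(is.na(v$r_squared[v$tissue == "wm"])) # zero-variance predictor
  # constant contrast: R^2 = 0 by the degenerate-response rule
  tab$mean_percent <- 5
  v2 <- volume_contrast_correlation(tab)
  expect_equal(v2$r_squared[v2$tissue == "gm"], 0)
})

test_that("results table covers the ten regions and both groups", {
  set.seed(3)
  subj <- data.frame(subject_id = sprintf("x%02d", 1:19),
                     group = rep(c("non-smoker", "smoker"), c(10, 9)),
                     age = sample(20:69, 19), stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(region_names(), function(r) {
    cbind(subj, region = r, mean_percent = stats::rnorm(19, 9),
          stringsAsFactors = FALSE)
  }))
  res <- build_results_table(tab)
  expect_equal(nrow(res$table1), 20)
  expect_setequal(unique(res$table1$region), region_names())
  expect_equal(nrow(res$age_regressions), 18) # 9 regions x 2 groups
  expect_true(all(res$table1$p_value >= 0 & res$table1$p_value <= 1))
  expect_true(all(res$age_regressions$r_squared >= 0 &
                    res$age_regressions$r_squared <= 1))
})

test_that("identical groups compare with p = 1", {
  set.seed(4)
  subj <- data.frame(subject_id = sprintf("y%02d", 1:18),
                     group = rep(c("non-smoker", "smoker"), each = 9),
                     age = rep(sample(20:69, 9), 2), stringsAsFactors = FALSE)
  vals <- stats::rnorm(9, 9)
  tab <- do.call(rbind, lapply(region_names(), function(r) {
    cbind(subj, region = r, mean_percent = rep(vals, 2),
          stringsAsFactors = FALSE)
  }))
  res <- build_results_table(tab)
  expect_true(all(res$table1$p_value == 1))
})

test_that("exact p-value null distribution is a proper distribution", {
  null <- wilcoxon_exact_p_null(10, 9)
  expect_equal(sum(null$prob), 1)
  expect_true(all(diff(null$p) > 0))
  expect_equal(max(null$p), 1)
  # super-uniformity at support points: P(p <= p_k) == p_k for exact tests
  expect_equal(cumsum(null$prob), null$p, tolerance = 1e-12)
  # PIT of null-simulated p-values is uniform
  set.seed(8)
  sim_p <- replicate(400, wilcoxon_rank_sum(stats::rnorm(10),
                                            stats::rnorm(9))$p_value)
  pit <- wilcoxon_p_pit(sim_p, 10, 9)
  expect_gt(stats::ks.test(pit, "punif")$p.value, 0.01)
  expect_error(wilcoxon_p_pit(0.123456, 10, 9), "support")
})
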