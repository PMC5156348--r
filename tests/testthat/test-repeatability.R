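test_that("one-way ANOVA matches the stats::aov oracle", {
  set.seed(31)
  for (trial in 1:20) {
    m <- anova_sim_matrix(k = sample(4:12, 1), n = sample(3:12, 1))
    if (trial > 10) m[sample(length(m), 5)] <- NA   # unbalanced cases
    an <- one_way_anova(m)
    d <- data.frame(y = as.vector(t(m)),
                    g = factor(rep(seq_len(nrow(m)), each = ncol(m))))
    d <- d[!is.na(d$y), ]
    ref <- summary(stats::aov(y ~ g, data = d))[[1]]
    expect_equal(an$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(an$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(an$df, c(ref$Df[1], ref$Df[2]))
    expect_equal(an$MS_A, ref$`Mean Sq`[1], tolerance = 1e-10)
    expect_equal(an$MS_W, ref$`Mean Sq`[2], tolerance = 1e-10)
  }
})

test_that("degenerate decompositions are reported, not hidden", {
  an0 <- one_way_anova(matrix(0.5, 4, 5))
  expect_true(is.na(an0$F))
  expect_match(an0$note, "not repeatable")
  expect_true(is.na(harper_r(an0)$r))
  an <- one_way_anova(rbind(c(0, 0), c(1, 1)))
  expect_equal(an$MS_W, 0)
  expect_equal(an$F, Inf)
  expect_equal(an$p, 0)
  expect_equal(harper_r(an)$r, 1)
  expect_error(one_way_anova(matrix(1, 1, 5)), "at least 2 groups")
})

test_that("balanced Harper identity r = (F-1)/(F+n-1) holds to 1e-12", {
  set.seed(37)
  for (trial in 1:50) {
    k <- sample(3:12, 1); n <- sample(3:12, 1)
    m <- anova_sim_matrix(k, n, sigma_a = runif(1, 0, 0.4))
    an <- one_way_anova(m)
    est <- harper_r(an)
    expect_equal(est$n0, n)
    expect_equal(est$r, (an$F - 1) / (an$F + n - 1), tolerance = 1e-12)
  }
})

test_that("unbalanced designs use Harper's effective group size", {
  m <- anova_sim_matrix(10, 12)
  set.seed(41); m[sample(length(m), 13)] <- NA
  an <- one_way_anova(m)
  est <- harper_r(an)
  n0_manual <- (an$N - sum(an$n_i^2) / an$N) / (an$k - 1)
  s2a <- (an$MS_A - an$MS_W) / n0_manual
  expect_equal(est$n0, n0_manual)
  expect_equal(est$r, s2a / (s2a + an$MS_W))
  expect_lt(est$n0, 12)
})

test_that("repeatability is invariant to affine transforms and r(F=1)=0", {
  set.seed(43)
  m <- anova_sim_matrix(8, 6)
  r0 <- harper_r(one_way_anova(m))$r
  for (trial in 1:10) {
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- runif(1, -3, 3)
    expect_equal(harper_r(one_way_anova(a * m + b))$r, r0, tolerance = 1e-10)
  }
  # F = 1 exactly: among-group variance equals within
  an1 <- structure(list(k = 10, N = 120, n_i = rep(12, 10), MS_A = 1,
                        MS_W = 1, F = 1, df = c(9, 110),
                        p = pf(1, 9, 110, lower.tail = FALSE), note = NULL),
                   class = "anova_decomposition")
  expect_equal(harper_r(an1)$r, 0)
})

test_that("negative estimates are flagged, not truncated", {
  set.seed(47)
  m <- matrix(rnorm(40), 4, 10)          # no group effect: r often < 0
  m[1, ] <- m[1, ] - mean(m[1, ]) + mean(m)  # force MS_A small
  m[2, ] <- m[2, ] - mean(m[2, ]) + mean(m)
  m[3, ] <- m[3, ] - mean(m[3, ]) + mean(m)
  m[4, ] <- m[4, ] - mean(m[4, ]) + mean(m)
  est <- harper_r(one_way_anova(m))
  expect_lt(est$r, 0)
  expect_true(est$negative)
})

test_that("parameter recovery: mean r-hat tracks sigma2_A/(sigma2_A+sigma2_W)", {
  set.seed(53)
  truth <- 0.04 / (0.04 + 0.04)
  rhat <- replicate(200, harper_r(one_way_anova(
    anova_sim_matrix(10, 12, sigma_a = 0.2, sigma_w = 0.2)))$r)
  expect_lt(abs(mean(rhat) - truth), 0.05)
})

test_that("repeatability_table gates display at alpha but always computes r", {
  set.seed(59)
  recs <- lapply(1:6, function(i) toy_recording(sprintf("N%02d", i)))
  mats <- lapply(c("male_care", "female_attendance"),
                 function(m) effort_matrix(recs, m, 1))
  tab <- repeatability_table(mats, alpha = 0.05)
  expect_equal(tab$metric, c("male_care", "female_attendance"))
  expect_true(all(!is.na(tab$r)))
  expect_equal(is.na(tab$r_displayed), !tab$significant)
  est <- harper_r(one_way_anova(mats[[1]]))
  expect_equal(tab$r[1], est$r)
})

test_that("paired t matches t.test and reproduces the published comparisons", {
  set.seed(61)
  for (trial in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    got <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter))
  }
  pw <- printed_width_pairs()
  d3 <- paired_t(pw$inc_d3$r1, pw$inc_d3$r3)
  expect_equal(round(d3$t, 2), -11.93)
  expect_equal(d3$df, 5L)
  d17 <- paired_t(pw$prov_d17$r1, pw$prov_d17$r3)
  expect_equal(round(d17$t, 2), -4.49)
  expect_equal(round(d17$p, 3), 0.011)
  expect_equal(paired_t(c(0, 1), c(1, 0))$t, 0)
  expect_error(paired_t(c(1, 2), c(2, 3)), "zero variance")
})

test_that("one-sample t matches the textbook formula", {
  x <- c(0.3, 0.5, 0.7)                  # symmetric around 0.5
  expect_equal(one_sample_t(x, 0.5)$t, 0)
  expect_error(one_sample_t(rep(0.5, 5), 0.5), "zero variance")
  set.seed(67)
  for (trial in 1:10) {
    x <- runif(sample(5:30, 1))
    got <- one_sample_t(x, 0.5)
    tt <- (mean(x) - 0.5) / (sd(x) / sqrt(length(x)))
    expect_equal(got$t, tt, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(tt), length(x) - 1), tolerance = 1e-12)
  }
})

test_that("width comparison rounds to 2 dp before summarizing", {
  wc <- window_width_comparison(c(0.231, 0.187, 0.362), c(0.451, 0.384, 0.492))
  expect_equal(wc$mean_1h, mean(c(0.23, 0.19, 0.36)))
  expect_equal(wc$mean_3h, mean(c(0.45, 0.38, 0.49)))
  expect_equal(wc$df, 2L)
})
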