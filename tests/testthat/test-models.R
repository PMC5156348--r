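# long-format diurnal fixture: value_ij = f(window) + nest_i + noise
diurnal_long <- function(n_nests = 10, k = 12, f = function(w) 0,
                         sigma_nest = 0.08, sigma_e = 0.08) {
  d <- expand.grid(nest_id = sprintf("N%02d", seq_len(n_nests)),
                   window_index = seq_len(k))
  d$value <- f(d$window_index) +
    rnorm(n_nests)[as.integer(factor(d$nest_id))] * sigma_nest +
    rnorm(nrow(d), 0, sigma_e)
  d
}

test_that("a quadratic diurnal signal selects degree 2 in most seeds", {
  hits <- 0L
  for (s in 1:25) {
    set.seed(400 + s)
    d <- diurnal_long(f = function(w) 0.5 - 0.02 * (w - 6.5)^2)
    fit <- fit_diurnal(d)
    if (fit$selected_degree == 2L) hits <- hits + 1L
    expect_gte(fit$chi2, 0)
    expect_equal(fit$df, fit$selected_degree)
  }
  expect_gt(hits, 12L)
})

test_that("pure-noise corpora rarely reach significance", {
  set.seed(97)
  ps <- replicate(60, fit_diurnal(diurnal_long())$p)
  # selection over 6 degrees inflates the nominal rate somewhat; the
  # type-I check only requires the rate to stay near alpha, not explode
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps > 0.3), 0.3)
})

test_that("per-nest constant effort yields a null diurnal trend", {
  set.seed(101)
  d <- diurnal_long(sigma_e = 1e-4)       # essentially nest-constant
  fit <- fit_diurnal(d)
  expect_lt(fit$p, Inf)
  expect_lt(fit$chi2, 15)
  expect_error(fit_diurnal(d[d$window_index < 3, ]), "at least 3")
})

test_that("fit_diurnal accepts an effort matrix and selects by AIC", {
  set.seed(103)
  recs <- lapply(1:8, function(i) toy_recording(sprintf("N%02d", i)))
  fit <- fit_diurnal(effort_matrix(recs, "male_care", 1))
  expect_s3_class(fit, "diurnal_fit")
  expect_equal(length(fit$aic_by_degree), 6L)
  expect_equal(unname(which.min(fit$aic_by_degree)), fit$selected_degree)
})

division_long <- function(male = 0.4, female = 0.4, trend = c(0, 0, 0),
                          sigma_nest = 0.05, sigma_e = 0.08, n_nests = 10) {
  d <- expand.grid(nest_id = sprintf("N%02d", seq_len(n_nests)),
                   parent = c("male", "female"),
                   stage_day = c(3, 8, 13))
  base <- ifelse(d$parent == "male", male, female)
  d$value <- base + trend[match(d$stage_day, c(3, 8, 13))] +
    rnorm(n_nests)[as.integer(factor(d$nest_id))] * sigma_nest +
    rnorm(nrow(d), 0, sigma_e)
  d
}

test_that("division LRT chi2 equals the lme4 anova oracle", {
  set.seed(107)
  d <- division_long(male = 0.4, female = 0.7, trend = c(0, 0.05, 0.1))
  fit <- fit_division(d)
  d$stage_f <- factor(d$stage_day)
  m_full <- lme4::lmer(value ~ parent * stage_f + (1 | nest_id / parent),
                       data = d, REML = FALSE)
  m_add <- lme4::lmer(value ~ parent + stage_f + (1 | nest_id / parent),
                      data = d, REML = FALSE)
  ref <- anova(m_add, m_full)
  expect_equal(fit$terms$chi2[fit$terms$term == "sex:stage"],
               ref$Chisq[2], tolerance = 1e-6)
  expect_equal(fit$terms$df, c(2, 1, 2))
  # deviance-difference identity from the returned log-likelihoods
  expect_equal(fit$terms$chi2[fit$terms$term == "sex"],
               2 * (fit$logLik[["additive"]] - fit$logLik[["stage_only"]]),
               tolerance = 1e-12)
})

test_that("a strong sex difference is detected at n = 10 nests", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(500 + s)
    fit <- fit_division(division_long(male = 0.4, female = 0.7))
    if (fit$terms$p[fit$terms$term == "sex"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 27L)                   # >= 90% power
})

test_that("identical sexes with no trend behave like the null", {
  set.seed(109)
  ps <- replicate(30, {
    fit <- fit_division(division_long())
    fit$terms$p[fit$terms$term == "sex"]
  })
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.25)
})

test_that("missing sexes are reported by nest", {
  d <- division_long()
  d <- d[!(d$nest_id == "N03" & d$parent == "male"), ]
  expect_error(fit_division(d), "N03")
})

test_that("at zero random-effect variance the ML deviance equals OLS", {
  set.seed(113)
  d <- division_long()
  d$stage_f <- factor(d$stage_day)
  dev_fun <- lme4::lmer(value ~ parent * stage_f + (1 | nest_id / parent),
                        data = d, REML = FALSE, devFunOnly = TRUE)
  ols <- stats::logLik(stats::lm(value ~ parent * stage_f, data = d))
  expect_equal(dev_fun(c(0, 0)), -2 * as.numeric(ols), tolerance = 1e-6)
  # and the free fit can only be at least as likely
  fit <- fit_division(d)
  expect_gte(fit$logLik[["full"]] + 1e-8, as.numeric(ols))
})
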