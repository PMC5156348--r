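test_that("config validation rejects impossible parameterizations", {
  expect_error(sim_config(sigma_individual = -1), "sigma_individual")
  expect_error(sim_config(joint_coupling = 0), "joint_coupling")
  bad <- preset_paperlike()$rates
  bad$male["off_care"] <- -1
  expect_error(sim_config(rates = bad), "positive")
  expect_s3_class(preset_paperlike(), "sim_config")
})

test_that("a fixed seed reproduces the event log bit for bit", {
  cfg <- preset_paperlike(n_nests = 2, seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  attr(a, "config") <- NULL; attr(b, "config") <- NULL
  expect_identical(a, b)
  cfg2 <- preset_paperlike(n_nests = 2, seed = 12)
  expect_false(identical(simulate_population(cfg2)[[1]], a[[1]]))
})

test_that("simulated recordings satisfy the ethogram invariants", {
  set.seed(131)
  cfg <- preset_paperlike()
  for (stage in c("incubation", "provisioning")) {
    rec <- simulate_nest(cfg, "X1", stage, 3)
    for (nm in names(rec$tracks)) {
      iv <- rec$tracks[[nm]]
      if (!nrow(iv)) next
      expect_true(all(iv[, 2] > iv[, 1]))
      expect_true(all(diff(as.vector(t(iv))) > 0))   # sorted, disjoint
      expect_gte(min(iv), 25200)
      expect_lte(max(iv), 68400)
    }
    # care and inside are mutually exclusive states of one parent
    for (p in c("male", "female"))
      expect_equal(iv_total(iv_intersect(rec$tracks[[paste0(p, ".care")]],
                                         rec$tracks[[paste0(p, ".inside")]])),
                   0)
    em <- effort_matrix(list(rec), "total_care", 1)
    expect_true(all(em$values <= 1 & em$values >= 0))
  }
  rec <- simulate_nest(cfg, "X2", "provisioning", 3)
  expect_gt(nrow(rec$feedings), 0)
  expect_true(all(rec$feedings$time >= 25200 & rec$feedings$time <= 68400))
  rec_inc <- simulate_nest(cfg, "X3", "incubation", 3)
  expect_equal(nrow(rec_inc$feedings), 0L)
})

test_that("homogeneous simulation matches the stationary-occupancy oracle", {
  cfg <- sim_config()                     # sigma 0, no diurnal, coupling 1
  set.seed(137)
  n <- 30
  occ <- t(vapply(seq_len(n), function(i) {
    rec <- simulate_nest(cfg, sprintf("S%02d", i), "incubation", 3)
    c(m = daily_effort(rec, "male_care"), f = daily_effort(rec, "female_care"))
  }, numeric(2)))
  for (sex in c("male", "female")) {
    target <- stationary_occupancy(cfg, sex)[["care"]]
    col <- occ[, substr(sex, 1, 1)]
    se <- sd(col) / sqrt(n)
    expect_lt(abs(mean(col) - target), 3 * se + 0.01)
  }
})

test_that("uncoupled parents have independent care occupancy", {
  cfg <- sim_config()                     # joint_coupling = 1
  set.seed(139)
  n <- 30
  d <- t(vapply(seq_len(n), function(i) {
    rec <- simulate_nest(cfg, sprintf("S%02d", i), "incubation", 3)
    c(j = daily_effort(rec, "joint_care"),
      p = daily_effort(rec, "male_care") * daily_effort(rec, "female_care"))
  }, numeric(2)))
  diff <- d[, "j"] - d[, "p"]
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(n) + 0.005)
  # coupling > 1 produces a joint-care excess
  cfgc <- sim_config(joint_coupling = 3)
  set.seed(141)
  dc <- t(vapply(seq_len(10), function(i) {
    rec <- simulate_nest(cfgc, sprintf("S%02d", i), "incubation", 3)
    c(j = daily_effort(rec, "joint_care"),
      p = daily_effort(rec, "male_care") * daily_effort(rec, "female_care"))
  }, numeric(2)))
  expect_gt(mean(dc[, "j"] - dc[, "p"]), 0)
})

test_that("study-design arithmetic reproduces the footage totals", {
  expect_equal(scheduled_hours(10, "actual"), 570)
  expect_equal(scheduled_hours(10, "all12h"), 840)
  expect_equal(scheduled_hours(1, "actual"), 57)
})

test_that("the population mirrors the recording design", {
  cfg <- preset_paperlike(n_nests = 3, seed = 17)
  recs <- simulate_population(cfg)
  expect_length(recs, 3 * 3 + 3 * 4)
  keys <- table(vapply(recs, function(r)
    sprintf("%s_d%d", r$stage, r$stage_day), ""))
  expect_equal(unname(keys["incubation_d8"]), 6L)  # both nest groups
  expect_equal(unname(keys["provisioning_d3"]), 3L)
  spans <- vapply(recs, function(r) r$record_end - r$record_start, numeric(1))
  expect_equal(sum(spans) / 3600, scheduled_hours(3, "actual"))
})

test_that("stronger individual effects raise expected repeatability", {
  sigmas <- c(0, 0.45, 0.9)
  means <- vapply(seq_along(sigmas), function(si) {
    set.seed(600 + si)
    cfg <- sim_config(sigma_individual = sigmas[si])
    mean(replicate(8, {
      recs <- lapply(1:8, function(i)
        simulate_nest(cfg, sprintf("S%02d", i), "incubation", 3))
      harper_r(one_way_anova(effort_matrix(recs, "female_care", 3)))$r
    }))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
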