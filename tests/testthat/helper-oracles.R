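# Independent brute-force oracles and fixture builders. Oracles use a 1-second
# rasterization (exact for integer endpoints) and never call the interval
# algebra they check.

raster_covered <- function(iv, t) {
  if (NROW(iv) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv)))
    out <- out | (t >= iv[i, 1] & t < iv[i, 2])
  out
}

# occupied/observable seconds of `iv` in `window` outside `gaps`, counted on a
# 1 s grid (integer endpoints assumed)
raster_duration <- function(iv, window, gaps = NULL) {
  t <- seq(window[1], window[2] - 1)
  obs <- !raster_covered(gaps, t)
  c(occupied = sum(raster_covered(iv, t) & obs), observable = sum(obs))
}

rand_iv <- function(n, lo = 0, hi = 3600) {
  s <- sample(lo:(hi - 1), n, replace = TRUE)
  len <- sample(1:600, n, replace = TRUE)
  cbind(s, pmin(s + len, hi))
}

# a hand-built recording: integer-second tracks for both parents
toy_recording <- function(nest_id = "N1", stage = "incubation", stage_day = 3,
                          span = c(25200, 68400), n_per_track = 20,
                          gaps = NULL, feedings = NULL) {
  rows <- list()
  for (p in c("male", "female")) for (s in c("care", "inside")) {
    iv <- rand_iv(n_per_track, span[1], span[2])
    rows[[paste(p, s)]] <- data.frame(parent = p, state = s,
                                      start = iv[, 1], end = iv[, 2])
  }
  nest_recording(nest_id, stage, stage_day, span[1], span[2],
                 intervals = do.call(rbind, rows), gaps = gaps,
                 feedings = feedings)
}

# fully covering care for both parents: every effort cell must be exactly 1
saturated_recording <- function(nest_id, stage = "incubation", stage_day = 3,
                                span = c(25200, 68400)) {
  nest_recording(nest_id, stage, stage_day, span[1], span[2],
                 intervals = data.frame(parent = c("male", "female"),
                                        state = "care",
                                        start = span[1], end = span[2]))
}

# small per-group effort simulator for ANOVA-level tests: value_ij = mu + a_i + e_ij
anova_sim_matrix <- function(k = 10, n = 12, sigma_a = 0.2, sigma_w = 0.1,
                             mu = 0.5) {
  a <- rnorm(k, 0, sigma_a)
  matrix(mu + rep(a, each = n) + rnorm(k * n, 0, sigma_w),
         nrow = k, byrow = TRUE)
}

# printed repeatability tables (r and F, 2 dp) used by the reproduction tests:
# duration metrics only; the feeding-ratio rows of the provisioning tables had
# unbalanced effective group sizes not recoverable from the printed F.
printed_day_tables <- function() {
  list(
    inc_d3 = data.frame(
      metric = c("male_care", "male_attendance", "female_care",
                 "female_attendance", "joint_care", "total_care"),
      r1 = c(0.23, 0.19, 0.18, 0.18, 0.36, 0.19),
      F1 = c(4.68, 3.83, 3.64, 3.68, 7.84, 3.86),
      r3 = c(0.45, 0.38, 0.32, 0.34, 0.49, 0.39),
      F3 = c(4.29, 3.44, 2.93, 3.08, 4.78, 3.55)),
    inc_d13 = data.frame(
      metric = c("male_care", "male_attendance", "female_care",
                 "female_attendance", "joint_care", "joint_attendance",
                 "total_care", "total_attendance"),
      r1 = c(0.47, 0.15, 0.27, 0.16, 0.58, 0.13, 0.73, 0.43),
      F1 = c(11.85, 3.07, 5.44, 3.22, 17.44, 2.80, 33.14, 10.00),
      r3 = c(0.75, 0.34, 0.57, 0.43, 0.75, 0.28, 0.85, 0.56),
      F3 = c(13.06, 3.02, 6.27, 4.00, 12.81, 2.57, 24.27, 6.00)),
    prov_d3 = data.frame(
      metric = c("male_care", "female_care", "joint_care", "total_care"),
      r1 = c(0.54, 0.27, 0.62, 0.39),
      F1 = c(15.18, 5.50, 20.47, 8.67),
      r3 = c(0.78, 0.58, 0.86, 0.62),
      F3 = c(15.57, 6.46, 24.95, 7.50)),
    prov_d17 = data.frame(
      metric = c("male_care", "female_care", "joint_care", "total_care"),
      r1 = c(0.48, 0.54, 0.25, 0.49),
      F1 = c(12.03, 15.26, 4.91, 12.72),
      r3 = c(0.57, 0.69, 0.28, 0.60),
      F3 = c(6.23, 9.77, 2.57, 7.05)))
}

# the four published 1h-vs-3h paired summaries: repeatability vectors include
# the feeding-ratio rows where the day's summary did (provisioning days)
printed_width_pairs <- function() {
  list(
    inc_d3 = list(r1 = c(0.23, 0.19, 0.18, 0.18, 0.36, 0.19),
                  r3 = c(0.45, 0.38, 0.32, 0.34, 0.49, 0.39),
                  mean1 = 0.22, mean3 = 0.40, t = -11.93, df = 5),
    inc_d13 = list(r1 = c(0.47, 0.15, 0.27, 0.16, 0.58, 0.13, 0.73, 0.43),
                   r3 = c(0.75, 0.34, 0.57, 0.43, 0.75, 0.28, 0.85, 0.56),
                   mean1 = 0.37, mean3 = 0.57, t = -7.93, df = 7),
    prov_d3 = list(r1 = c(0.54, 0.27, 0.62, 0.39, 0.48),
                   r3 = c(0.78, 0.58, 0.86, 0.62, 0.64),
                   mean1 = 0.46, mean3 = 0.70, t = -9.92, df = 4),
    prov_d17 = list(r1 = c(0.48, 0.54, 0.25, 0.49, 0.40),
                    r3 = c(0.57, 0.69, 0.28, 0.60, 0.57),
                    mean1 = 0.43, mean3 = 0.54, t = -4.49, df = 4))
}
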