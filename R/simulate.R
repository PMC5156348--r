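#' Configuration of the two-parent behavioural simulator
#'
#' Each parent moves among three states -- `off` (away from the nest box),
#' `inside` (in the box but not on eggs/young) and `care` (incubating or
#' brooding) -- as a continuous-time jump process with piecewise-constant
#' hazards updated on a 1-minute grid. Log-hazards of the two care-entry
#' transitions (`off -> care`, `inside -> care`) are modulated by a diurnal
#' polynomial, a per-(stage, day) shift and a per-parent random intercept;
#' the same shift and intercept are subtracted from the two care-exit
#' transitions so that individual and stage effects move care occupancy in
#' one direction. While the partner is in `care`, both care-entry hazards
#' are multiplied by `joint_coupling` (1 = independent parents). Feeding
#' bouts are a Poisson process at `feed_rate` per hour while the parent is in
#' the nest (inside or care), emitted only for provisioning-stage recordings.
#'
#' @param n_nests nests per reproductive-stage group (10 in the reference
#'   design).
#' @param rates list with elements `male` and `female`, each a named numeric
#'   vector of per-hour baseline hazards: `off_inside`, `off_care`,
#'   `inside_care`, `inside_off`, `care_inside`, `care_off`.
#' @param diurnal_coefficients numeric vector `c(c1, c2, ...)` adding
#'   `sum(c_j * u^j)` to care-entry log-hazards, where `u` maps 07:00-19:00
#'   to `[-1, 1]`.
#' @param stage_effects list with elements `incubation` and `provisioning`,
#'   each a named numeric vector of additive log-hazard shifts per stage day.
#' @param sigma_individual SD of the per-parent normal random intercept on
#'   care log-hazards (between-individual consistency).
#' @param joint_coupling multiplier on care-entry hazard while the partner is
#'   in care.
#' @param feed_rate feeding bouts per hour while in the nest (provisioning).
#' @param seed integer seed used by [simulate_population()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_nests = 10,
                       rates = preset_paperlike()$rates,
                       diurnal_coefficients = c(0, 0),
                       stage_effects = list(
                         incubation = c("3" = 0, "8" = 0, "13" = 0),
                         provisioning = c("3" = 0, "10" = 0, "17" = 0)),
                       sigma_individual = 0,
                       joint_coupling = 1,
                       feed_rate = 5,
                       seed = 1L) {
  need <- c("off_inside", "off_care", "inside_care", "inside_off",
            "care_inside", "care_off")
  for (sex in c("male", "female")) {
    if (!all(need %in% names(rates[[sex]])))
      stop("rates$", sex, " must name all of: ", paste(need, collapse = ", "))
    if (any(rates[[sex]][need] <= 0)) stop("all rates must be positive")
  }
  if (sigma_individual < 0) stop("sigma_individual must be >= 0")
  if (joint_coupling <= 0) stop("joint_coupling must be positive")
  if (feed_rate < 0) stop("feed_rate must be >= 0")
  structure(list(n_nests = as.integer(n_nests), rates = rates,
                 diurnal_coefficients = diurnal_coefficients,
                 stage_effects = stage_effects,
                 sigma_individual = sigma_individual,
                 joint_coupling = joint_coupling,
                 feed_rate = feed_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Reference simulator preset
#'
#' A documented default calibrated once so that the simulated corpus shows
#' the qualitative structure the real study population shows: female-biased
#' incubation (female care share exceeding the male's by well over 0.15),
#' brooding that declines over the provisioning stage, a nonlinear (quadratic)
#' diurnal trend, within-day repeatabilities of roughly 0.15-0.5 for 1 h and
#' 0.3-0.8 for 3 h windows, and feeding split evenly between the sexes.
#'
#' @param n_nests nests per stage group; default 10.
#' @param seed integer seed; default 1.
#' @return a [sim_config()].
#' @export
preset_paperlike <- function(n_nests = 10, seed = 1L) {
  rates <- list(
    male = c(off_inside = 2.0, off_care = 1.6, inside_care = 3.0,
             inside_off = 7.0, care_inside = 1.0, care_off = 2.4),
    female = c(off_inside = 2.0, off_care = 6.0, inside_care = 8.0,
               inside_off = 7.0, care_inside = 0.8, care_off = 1.2))
  structure(list(n_nests = as.integer(n_nests), rates = rates,
                 diurnal_coefficients = c(0.25, -0.9),
                 stage_effects = list(
                   incubation = c("3" = 0, "8" = 0.15, "13" = 0.3),
                   provisioning = c("3" = 0.3, "10" = -0.5, "17" = -1.3)),
                 sigma_individual = 0.45,
                 joint_coupling = 1.5,
                 feed_rate = 5,
                 seed = as.integer(seed)),
            class = "sim_config")
}

TRANSITIONS <- matrix(c(1L, 2L,   # off    -> inside
                        1L, 3L,   # off    -> care
                        2L, 3L,   # inside -> care
                        2L, 1L,   # inside -> off
                        3L, 2L,   # care   -> inside
                        3L, 1L),  # care   -> off
                      ncol = 2, byrow = TRUE,
                      dimnames = list(c("off_inside", "off_care",
                                        "inside_care", "inside_off",
                                        "care_inside", "care_off"), NULL))
CARE_ENTRY <- c("off_care", "inside_care")
CARE_EXIT  <- c("care_inside", "care_off")

# per-minute log-hazard modifier on care entries (diurnal poly + stage + indiv)
diurnal_term <- function(t_sec, coefs) {
  if (!length(coefs)) return(0 * t_sec)
  u <- (t_sec / 3600 - 13) / 6
  out <- 0
  for (j in seq_along(coefs)) out <- out + coefs[j] * u^j
  out
}

stage_shift <- function(config, stage, stage_day) {
  v <- config$stage_effects[[stage]]
  key <- as.character(stage_day)
  if (!is.null(v) && key %in% names(v)) unname(v[key]) else 0
}

# rate table: minutes x 6 transitions, one per parent
rate_table <- function(config, sex, stage, stage_day, minutes, indiv) {
  base <- log(config$rates[[sex]][rownames(TRANSITIONS)])
  shift <- stage_shift(config, stage, stage_day) + indiv
  tab <- matrix(rep(base, each = length(minutes)), nrow = length(minutes),
                dimnames = list(NULL, rownames(TRANSITIONS)))
  dt <- diurnal_term(minutes * 60, config$diurnal_coefficients)
  tab[, CARE_ENTRY] <- tab[, CARE_ENTRY] + shift + dt
  tab[, CARE_EXIT] <- tab[, CARE_EXIT] - shift
  exp(tab)   # per-hour hazards
}

# stationary distribution of the 3-state generator built from a rate row
stationary_state_dist <- function(r) {
  q <- matrix(0, 3, 3)
  for (nm in rownames(TRANSITIONS))
    q[TRANSITIONS[nm, 1], TRANSITIONS[nm, 2]] <- r[[nm]]
  diag(q) <- -rowSums(q)
  a <- rbind(t(q), rep(1, 3))
  pi <- stats::setNames(as.vector(qr.solve(a, c(0, 0, 0, 1))),
                        c("off", "inside", "care"))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Closed-form stationary care occupancy of the homogeneous process
#'
#' Solves the 3-state generator built from one parent's baseline rates for
#' its stationary distribution; the oracle for the simulator's long-run care
#' occupancy when diurnal, stage and individual effects are off.
#'
#' @param config a [sim_config()].
#' @param sex `"male"` or `"female"`.
#' @return named numeric of stationary probabilities `off`, `inside`, `care`.
#' @export
stationary_occupancy <- function(config, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stationary_state_dist(as.list(config$rates[[sex]]))
}

#' Simulate one nest recording
#'
#' Event-driven simulation of the coupled two-parent process over
#' `span + burn-in`: exponential competing clocks with hazards held constant
#' between events and 1-minute grid points, which is exact for the
#' piecewise-constant hazard model. Initial states are drawn from each
#' parent's baseline stationary distribution and the first `burn_in` seconds
#' are discarded.
#'
#' @param config a [sim_config()].
#' @param nest_id nest identifier.
#' @param stage `"incubation"` or `"provisioning"`.
#' @param stage_day integer day within stage.
#' @param span numeric length-2 recording span in seconds since midnight;
#'   default the canonical full day 07:00-19:00.
#' @param indiv named numeric `c(male=, female=)` of individual log-hazard
#'   intercepts; `NULL` draws fresh ones from
#'   `Normal(0, sigma_individual^2)`.
#' @param burn_in seconds simulated before `span[1]` and discarded.
#' @return a [nest_recording()].
#' @export
simulate_nest <- function(config, nest_id, stage, stage_day,
                          span = c(25200, 68400), indiv = NULL,
                          burn_in = 3600) {
  stage <- match.arg(stage, STAGES)
  if (is.null(indiv))
    indiv <- c(male = stats::rnorm(1, 0, config$sigma_individual),
               female = stats::rnorm(1, 0, config$sigma_individual))
  t0 <- span[1] - burn_in
  minute0 <- floor(t0 / 60)
  minutes <- minute0:ceiling(span[2] / 60)
  tabs <- list(
    male = rate_table(config, "male", stage, stage_day, minutes, indiv["male"]),
    female = rate_table(config, "female", stage, stage_day, minutes,
                        indiv["female"]))
  state <- c(
    male = sample.int(3, 1, prob = stationary_state_dist(
      as.list(tabs$male[1, ]))),
    female = sample.int(3, 1, prob = stationary_state_dist(
      as.list(tabs$female[1, ]))))
  state0 <- state
  # event log: time, parent (1 male / 2 female), new state
  ev_t <- numeric(512); ev_p <- integer(512); ev_s <- integer(512); ne <- 0L
  gamma <- config$joint_coupling
  t <- t0
  end <- span[2]
  from_rows <- list(`1` = c("off_inside", "off_care"),
                    `2` = c("inside_care", "inside_off"),
                    `3` = c("care_inside", "care_off"))
  while (t < end) {
    row <- floor(t / 60) - minute0 + 1L
    rm_names <- from_rows[[state[["male"]]]]
    rf_names <- from_rows[[state[["female"]]]]
    rm <- tabs$male[row, rm_names]
    rf <- tabs$female[row, rf_names]
    if (gamma != 1) {
      if (state[["female"]] == 3L)
        rm[rm_names %in% CARE_ENTRY] <- rm[rm_names %in% CARE_ENTRY] * gamma
      if (state[["male"]] == 3L)
        rf[rf_names %in% CARE_ENTRY] <- rf[rf_names %in% CARE_ENTRY] * gamma
    }
    rates <- c(rm, rf)                     # per hour
    total <- sum(rates) / 3600             # per second
    boundary <- min((floor(t / 60) + 1) * 60, end)
    dt <- stats::rexp(1, total)
    if (t + dt < boundary) {
      t <- t + dt
      which_tr <- sample.int(length(rates), 1, prob = rates)
      parent <- if (which_tr <= length(rm)) 1L else 2L
      nm <- c(rm_names, rf_names)[which_tr]
      new_state <- TRANSITIONS[nm, 2]
      state[[parent]] <- new_state
      ne <- ne + 1L
      if (ne > length(ev_t)) {
        ev_t <- c(ev_t, numeric(length(ev_t)))
        ev_p <- c(ev_p, integer(length(ev_p)))
        ev_s <- c(ev_s, integer(length(ev_s)))
      }
      ev_t[ne] <- t; ev_p[ne] <- parent; ev_s[ne] <- new_state
    } else {
      t <- boundary
    }
  }
  # reconstruct per-parent state intervals over [t0, end), clip to span
  iv_rows <- list()
  for (pi in 1:2) {
    sel <- seq_len(ne)[ev_p[seq_len(ne)] == pi]
    times <- c(t0, ev_t[sel], end)
    st <- c(state0[[pi]], ev_s[sel])       # state holding on [times_j, times_j+1)
    for (j in seq_along(st)) {
      s <- st[j]
      if (s == 1L) next
      lo <- max(times[j], span[1]); hi <- min(times[j + 1], span[2])
      if (hi > lo)
        iv_rows[[length(iv_rows) + 1L]] <- data.frame(
          parent = c("male", "female")[pi],
          state = c("off", "inside", "care")[s],
          start = lo, end = hi)
    }
  }
  intervals <- if (length(iv_rows)) do.call(rbind, iv_rows) else NULL
  rec <- nest_recording(nest_id, stage, stage_day, span[1], span[2],
                        intervals = intervals)
  if (stage == "provisioning" && config$feed_rate > 0) {
    feeds <- list()
    for (p in PARENTS) {
      innest <- iv_union(rec$tracks[[paste(p, "care", sep = ".")]],
                         rec$tracks[[paste(p, "inside", sep = ".")]])
      dur <- iv_total(innest)
      if (dur <= 0) next
      n <- stats::rpois(1, config$feed_rate * dur / 3600)
      if (n == 0) next
      u <- stats::runif(n) * dur
      lens <- innest[, 2] - innest[, 1]
      cum <- cumsum(lens)
      seg <- findInterval(u, cum, left.open = TRUE) + 1L
      tt <- innest[seg, 1] + (u - c(0, cum)[seg])
      feeds[[p]] <- data.frame(parent = p, time = tt)
    }
    if (length(feeds)) {
      fd <- do.call(rbind, feeds)
      fd <- fd[order(fd$time), ]
      rec <- nest_recording(rec$nest_id, rec$stage, rec$stage_day,
                            rec$record_start, rec$record_end,
                            intervals = intervals, feedings = fd)
    }
  }
  rec
}

#' Simulate the full study corpus
#'
#' Mirrors the reference recording design: `n_nests` incubation nests
#' recorded on days 3 and 13 (full day, 07:00-19:00) and day 8 (10:00-13:00);
#' a second set of `n_nests` provisioning nests recorded on post-hatching
#' days 3 and 17 (full day) and day 10 (10:00-13:00), plus a 3 h
#' incubation-day-8 recording of the provisioning nests. Per-parent random
#' intercepts are drawn once per nest and shared across that nest's
#' recordings, which is what makes effort repeatable across days.
#'
#' @param config a [sim_config()]; `config$seed` seeds the whole corpus.
#' @return list of [nest_recording()] objects with the config attached as
#'   attribute `config`.
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  full <- c(25200, 68400); mid <- c(36000, 46800)
  recs <- list()
  for (i in seq_len(config$n_nests)) {
    id <- sprintf("I%02d", i)
    indiv <- c(male = stats::rnorm(1, 0, config$sigma_individual),
               female = stats::rnorm(1, 0, config$sigma_individual))
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "incubation", 3,
                                               full, indiv)
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "incubation", 8,
                                               mid, indiv)
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "incubation", 13,
                                               full, indiv)
  }
  for (i in seq_len(config$n_nests)) {
    id <- sprintf("P%02d", i)
    indiv <- c(male = stats::rnorm(1, 0, config$sigma_individual),
               female = stats::rnorm(1, 0, config$sigma_individual))
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "incubation", 8,
                                               mid, indiv)
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "provisioning", 3,
                                               full, indiv)
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "provisioning", 10,
                                               mid, indiv)
    recs[[length(recs) + 1L]] <- simulate_nest(config, id, "provisioning", 17,
                                               full, indiv)
  }
  attr(recs, "config") <- config
  recs
}

#' Scheduled footage of the recording design
#'
#' Total hours of video the design schedules: the actual mixed design (12 h on
#' early/late days, 3 h mid-stage, plus the provisioning nests' 3 h
#' mid-incubation recording) against the all-12 h alternative.
#'
#' @param n_nests nests per stage group.
#' @param design `"actual"` or `"all12h"`.
#' @return total scheduled hours.
#' @export
scheduled_hours <- function(n_nests = 10, design = c("actual", "all12h")) {
  design <- match.arg(design)
  per_inc <- if (design == "actual") 12 + 3 + 12 else 12 * 3
  per_prov <- if (design == "actual") 3 + 12 + 3 + 12 else 12 * 4
  n_nests * (per_inc + per_prov)
}
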