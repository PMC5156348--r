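#' Diurnal trend in window effort: AIC-selected polynomial mixed model
#'
#' Fits, by maximum likelihood, linear mixed models of window effort on an
#' orthogonal polynomial of window index (degrees 1..6) with a random
#' intercept per nest, selects the degree minimizing AIC (ties broken toward
#' the lower degree), and reports a likelihood-ratio test of the selected
#' model against the intercept-only null (degree 0).
#'
#' @param em an [effort_matrix()] of 1 h windows over a full-day corpus, or a
#'   long data frame with columns `nest_id`, `window_index`, `value`.
#' @param degrees polynomial degrees to try; default `1:6`.
#' @return object of class `diurnal_fit`: `metric`, `selected_degree`,
#'   `chi2`, `df`, `p`, `aic_by_degree`, `singular` (TRUE when the selected
#'   fit had a singular random-effect variance).
#' @export
fit_diurnal <- function(em, degrees = 1:6) {
  if (inherits(em, "effort_matrix")) {
    d <- effort_long(em)
    metric <- em$metric
  } else {
    d <- em
    metric <- if (!is.null(d$metric)) as.character(d$metric[1]) else NA_character_
  }
  d <- d[!is.na(d$value), c("nest_id", "window_index", "value")]
  if (length(unique(d$window_index)) < 3L)
    stop("need at least 3 distinct windows to fit a diurnal trend")
  d$nest_id <- factor(d$nest_id)

  fit_deg <- function(deg) {
    form <- if (deg == 0)
      value ~ 1 + (1 | nest_id)
    else
      stats::as.formula(sprintf("value ~ poly(window_index, %d) + (1 | nest_id)",
                                deg))
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  }
  null_fit <- fit_deg(0)
  fits <- lapply(degrees, fit_deg)
  aic <- vapply(fits, stats::AIC, numeric(1))
  best <- which(aic <= min(aic) + 1e-6)[1]   # ties -> lower degree
  sel <- fits[[best]]
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(sel)) -
                        as.numeric(stats::logLik(null_fit))))
  df <- degrees[best]
  structure(list(metric = metric, selected_degree = degrees[best],
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 aic_by_degree = stats::setNames(aic, paste0("d", degrees)),
                 singular = lme4::isSingular(sel)),
            class = "diurnal_fit")
}

#' @export
print.diurnal_fit <- function(x, ...) {
  cat(sprintf("<diurnal_fit> %s: degree %d, chi2(%d) = %.2f, p = %.4g%s\n",
              x$metric, x$selected_degree, x$df, x$chi2, x$p,
              if (x$singular) " [singular RE]" else ""))
  invisible(x)
}

#' Division-of-labour mixed model with likelihood-ratio tests
#'
#' Models per-recording effort of each parent as a function of parental sex,
#' time in the reproductive stage (factor: early/middle/late, i.e. the stage
#' day) and their interaction, with parent nested in nest as random
#' intercepts, fitted by maximum likelihood. Each term is tested by a
#' likelihood-ratio test between nested models: interaction (full vs
#' additive, df 2), sex (additive vs stage-only, df 1), stage (additive vs
#' sex-only, df 2).
#'
#' @param d data frame with columns `nest_id`, `parent` (`male`/`female`),
#'   `stage_day`, `value`; typically one 3 h mid-day effort value per parent
#'   per stage day.
#' @return object of class `division_fit`: data frame `terms` with `term`,
#'   `chi2`, `df`, `p`, plus log-likelihoods of the fitted models.
#' @export
fit_division <- function(d) {
  need <- c("nest_id", "parent", "stage_day", "value")
  if (!all(need %in% names(d))) stop("missing columns: need ",
                                     paste(need, collapse = ", "))
  d <- d[!is.na(d$value), ]
  tab <- table(d$nest_id, d$parent)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r == 0))]
  if (length(bad))
    stop("nests missing one sex entirely: ", paste(bad, collapse = ", "))
  d$nest_id <- factor(d$nest_id)
  d$parent <- factor(d$parent, levels = c("male", "female"))
  d$stage_f <- factor(d$stage_day)
  if (nlevels(d$stage_f) < 2L) stop("need at least 2 stage days")

  fit <- function(form) {
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  }
  m_full <- fit(value ~ parent * stage_f + (1 | nest_id / parent))
  m_add  <- fit(value ~ parent + stage_f + (1 | nest_id / parent))
  m_sex  <- fit(value ~ parent + (1 | nest_id / parent))
  m_stg  <- fit(value ~ stage_f + (1 | nest_id / parent))
  ll <- function(m) as.numeric(stats::logLik(m))
  lrt <- function(big, small, df) {
    chi2 <- max(0, 2 * (ll(big) - ll(small)))
    c(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
  }
  n_stage_df <- nlevels(d$stage_f) - 1L
  terms <- rbind(
    data.frame(term = "sex:stage", t(lrt(m_full, m_add, n_stage_df))),
    data.frame(term = "sex",       t(lrt(m_add, m_stg, 1))),
    data.frame(term = "stage",     t(lrt(m_add, m_sex, n_stage_df))))
  structure(list(terms = terms,
                 logLik = c(full = ll(m_full), additive = ll(m_add),
                            sex_only = ll(m_sex), stage_only = ll(m_stg))),
            class = "division_fit")
}

#' @export
print.division_fit <- function(x, ...) {
  cat("<division_fit> LRTs (ML, parent nested in nest):\n")
  print(transform(x$terms, chi2 = round(chi2, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Assemble the per-parent division-of-labour data set
#'
#' Extracts one effort value per parent per recording (the 10:00-13:00 window
#' in the reference design) for an individual metric across recordings of one
#' stage, ready for [fit_division()].
#'
#' @param recs recordings of one stage over several stage days.
#' @param kind `"care"` or `"attendance"`.
#' @param window numeric length-2 window; default the whole recording span of
#'   each recording (use `c(36000, 46800)` for the canonical mid-day window).
#' @return data frame `nest_id`, `parent`, `stage_day`, `value`.
#' @export
division_data <- function(recs, kind = c("care", "attendance"), window = NULL) {
  kind <- match.arg(kind)
  rows <- list()
  for (rec in recs) {
    w <- if (is.null(window)) c(rec$record_start, rec$record_end) else window
    for (p in PARENTS) {
      iv <- metric_intervals(rec, paste(p, kind, sep = "_"))
      dd <- duration_in_window(iv, w, rec$gaps)
      rows[[length(rows) + 1L]] <- data.frame(
        nest_id = rec$nest_id, parent = p, stage_day = rec$stage_day,
        value = if (dd["observable"] > 0)
          unname(dd["occupied"] / dd["observable"]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
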