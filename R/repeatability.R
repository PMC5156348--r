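#' One-way ANOVA on an effort matrix
#'
#' Rows (nests, or parents nested in nests) are the groups; columns (sampling
#' windows, or days within a stage) are the repeated observations. Missing
#' cells are excluded, giving the unbalanced decomposition. This is the
#' significance test for repeatability: a significantly larger
#' between-individual than within-individual variance.
#'
#' @param x an [effort_matrix()] or a plain numeric matrix (rows = groups).
#' @return object of class `anova_decomposition`: `k`, `N`, `n_i`, `MS_A`,
#'   `MS_W`, `F`, `df` (length 2), `p`. When all values are identical both
#'   mean squares are 0, `F` is `NA` and a `note` explains the degeneracy.
#' @export
one_way_anova <- function(x) {
  m <- if (inherits(x, "effort_matrix")) x$values else as.matrix(x)
  keep <- rowSums(!is.na(m)) >= 1L      # singleton groups still inform SS_A
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L || sum(!is.na(m)) - nrow(m) < 1L)
    stop("need at least 2 groups and positive within-group df")
  vals <- lapply(seq_len(nrow(m)), function(i) m[i, !is.na(m[i, ])])
  n_i <- lengths(vals)
  k <- length(vals)
  N <- sum(n_i)
  gm <- sum(unlist(vals)) / N
  means <- vapply(vals, mean, numeric(1))
  ss_a <- sum(n_i * (means - gm)^2)
  ss_w <- sum(vapply(seq_len(k), function(i) sum((vals[[i]] - means[i])^2),
                     numeric(1)))
  df <- c(k - 1L, N - k)
  ms_a <- ss_a / df[1]
  ms_w <- ss_w / df[2]
  if (ms_a == 0 && ms_w == 0) {
    f <- NA_real_; p <- NA_real_
    note <- "all values identical: F undefined, not repeatable"
  } else {
    f <- ms_a / ms_w                       # +Inf when MS_W == 0
    p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
    note <- NULL
  }
  structure(list(k = k, N = N, n_i = unname(n_i), MS_A = ms_a, MS_W = ms_w,
                 F = f, df = df, p = p, note = note),
            class = "anova_decomposition")
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf("<one-way ANOVA> F(%d,%d) = %.3f, p = %.4g (k=%d, N=%d)\n",
              x$df[1], x$df[2], x$F, x$p, x$k, x$N))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Intraclass repeatability from a one-way ANOVA (Harper's method)
#'
#' Variance-component estimate of the intraclass correlation: with effective
#' group size `n0 = (N - sum(n_i^2)/N) / (k - 1)`, the among-group variance
#' component is `s2_A = (MS_A - MS_W) / n0` and
#' `r = s2_A / (s2_A + MS_W)`. In a balanced design (`n_i = n`) this reduces
#' algebraically to `r = (F - 1) / (F + n - 1)`. A negative estimate
#' (`MS_A < MS_W`) is returned as-is and flagged, not truncated.
#'
#' @param anova an `anova_decomposition` from [one_way_anova()].
#' @param alpha significance level gating the `significant` flag.
#' @return object of class `repeatability_estimate`: the decomposition plus
#'   `n0`, `r`, `significant`, `negative`.
#' @export
harper_r <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_decomposition"))
  n0 <- (anova$N - sum(anova$n_i^2) / anova$N) / (anova$k - 1)
  if (is.na(anova$F)) {
    r <- NA_real_
  } else if (is.infinite(anova$F)) {
    r <- 1
  } else {
    s2_a <- (anova$MS_A - anova$MS_W) / n0
    r <- s2_a / (s2_a + anova$MS_W)
  }
  structure(list(anova = anova, n0 = n0, r = r,
                 significant = !is.na(anova$p) && anova$p < alpha,
                 negative = !is.na(r) && r < 0),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability> r = %.3f (n0 = %.2f), F(%d,%d) = %.3f, p = %.4g%s\n",
              x$r, x$n0, x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p,
              if (x$negative) " [negative estimate]" else ""))
  invisible(x)
}

#' Balanced Harper conversion from a printed F ratio
#'
#' Reconstructs the repeatability implied by a published balanced one-way
#' ANOVA with `k` groups, `n` observations per group and variance ratio `F`,
#' by rebuilding the decomposition (`MS_W = 1`, `MS_A = F`) and applying the
#' variance-component path of [harper_r()]. Equals `(F - 1) / (F + n - 1)`.
#'
#' @param f F ratio (vectorized).
#' @param k number of groups.
#' @param n observations per group.
#' @return repeatability estimate(s), unrounded.
#' @export
harper_r_from_f <- function(f, k, n) {
  vapply(f, function(fi) {
    an <- structure(list(k = k, N = k * n, n_i = rep(n, k),
                         MS_A = fi, MS_W = 1, F = fi,
                         df = c(k - 1L, k * n - k),
                         p = stats::pf(fi, k - 1, k * n - k, lower.tail = FALSE),
                         note = NULL),
                    class = "anova_decomposition")
    harper_r(an)$r
  }, numeric(1))
}

#' Repeatability table over a set of effort matrices
#'
#' Computes the one-way ANOVA and Harper repeatability for each metric's
#' effort matrix. `r` is always computed; `r_displayed` is blanked for
#' metrics that are not significantly repeatable at `alpha`, emulating the
#' published-table convention.
#'
#' @param mats named list of [effort_matrix()] objects (names = metrics), or
#'   unnamed (metric taken from each object).
#' @param alpha significance level (default 0.05).
#' @return data frame: `metric`, `width_h`, `r`, `r_displayed`, `F`, `df1`,
#'   `df2`, `p`, `significant`.
#' @export
repeatability_table <- function(mats, alpha = 0.05) {
  rows <- lapply(mats, function(em) {
    est <- harper_r(one_way_anova(em), alpha = alpha)
    data.frame(metric = em$metric, width_h = em$width_h,
               r = est$r,
               r_displayed = if (est$significant) est$r else NA_real_,
               F = est$anova$F, df1 = est$anova$df[1], df2 = est$anova$df[2],
               p = est$anova$p, significant = est$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test on two estimate vectors
#'
#' Classical paired t on the differences `x - y`; used to compare 1 h and 3 h
#' sampling-window repeatability estimates metric by metric.
#'
#' @param x,y paired numeric vectors (equal length, >= 2 pairs).
#' @return list `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       mean_diff = mean(d))
}

#' One-sample t-test against a reference mean
#'
#' Used for the proportion-of-male-feedings test against an even split (0.5).
#'
#' @param x numeric vector.
#' @param mu reference mean.
#' @return list `t`, `df`, `p` (two-sided), `mean`, `se`.
#' @export
one_sample_t <- function(x, mu = 0.5) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: t undefined")
  se <- s / sqrt(n)
  t <- (mean(x) - mu) / se
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       mean = mean(x), se = se)
}

#' Compare 1h and 3h repeatability estimates as in the published summaries
#'
#' Rounds both estimate vectors to 2 decimals (published tables print 2 dp
#' and the published means and t statistics derive from those), then reports
#' means, standard errors and the paired t-test.
#'
#' @param r_1h,r_3h paired repeatability vectors (same metrics, both widths).
#' @param digits rounding applied before summarizing; default 2.
#' @return list `mean_1h`, `mean_3h`, `se_1h`, `se_3h`, `t`, `df`, `p`.
#' @export
window_width_comparison <- function(r_1h, r_3h, digits = 2) {
  keep <- !is.na(r_1h) & !is.na(r_3h)
  a <- round(r_1h[keep], digits); b <- round(r_3h[keep], digits)
  tt <- paired_t(a, b)
  list(mean_1h = mean(a), mean_3h = mean(b),
       se_1h = stats::sd(a) / sqrt(length(a)),
       se_3h = stats::sd(b) / sqrt(length(b)),
       t = tt$t, df = tt$df, p = tt$p)
}
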