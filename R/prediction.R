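#' Simple OLS of daily effort on a single window's effort
#'
#' Least-squares regression of per-nest daily effort on per-nest effort in
#' one sampling window; `R2 = 1 - SS_res / SS_tot` and a two-sided t-test on
#' the slope. For simple regression R-squared equals the squared Pearson
#' correlation; the implementation uses the normal equations directly.
#'
#' @param x per-nest effort in the window.
#' @param y per-nest daily effort.
#' @return list `R2`, `slope`, `intercept`, `p`, `n`, `flag` (`NULL`,
#'   `"zero_x_variance"` with everything `NA`, or `"zero_y_variance"` with
#'   `R2 = 0`).
#' @export
ols_r2 <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0)
    return(list(R2 = NA_real_, slope = NA_real_, intercept = NA_real_,
                p = NA_real_, n = n, flag = "zero_x_variance"))
  if (syy == 0)
    return(list(R2 = 0, slope = 0, intercept = mean(y), p = NA_real_,
                n = n, flag = "zero_y_variance"))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- syy - slope * sxy
  r2 <- 1 - ss_res / syy
  df <- n - 2L
  if (ss_res <= .Machine$double.eps * syy) {
    p <- 0                                 # exact collinearity
  } else {
    se <- sqrt(ss_res / df / sxx)
    p <- 2 * stats::pt(-abs(slope / se), df)
  }
  list(R2 = r2, slope = slope, intercept = intercept, p = p, n = n,
       flag = NULL)
}

#' Percentile bootstrap CI for a simple-regression R-squared
#'
#' Resamples nests (the independent unit) with replacement `B` times,
#' recomputes R-squared, and returns percentile bounds. Resamples with zero
#' x-variance are discarded and redrawn; a warning is issued if more than 1%
#' of draws were redrawn. Deterministic for a fixed `seed`.
#'
#' @param x,y paired per-nest vectors as in [ols_r2()].
#' @param B bootstrap replicates; default `1e4`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param conf confidence level; default 0.95.
#' @return list `low`, `high`, `B`, `redrawn`.
#' @export
bootstrap_r2_ci <- function(x, y, B = 1e4, seed = NULL, conf = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  r2 <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xv <- x[idx]
      if (stats::var(xv) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * B) stop("cannot draw a resample with x-variance")
    }
    yv <- y[idx]
    r2[b] <- if (stats::var(yv) == 0) 0 else stats::cor(xv, yv)^2
  }
  if (redrawn > 0.01 * B)
    warning(sprintf("%d of %d bootstrap draws redrawn for zero x-variance",
                    redrawn, B))
  qs <- stats::quantile(r2, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(low = qs[1], high = qs[2], B = B, redrawn = redrawn)
}

#' Window-versus-daily prediction table
#'
#' For each metric and window width, regresses overall daily effort on the
#' effort observed in each single window across nests, with bootstrap CI for
#' R-squared: the machinery behind the published prediction-accuracy tables.
#'
#' @param recs recordings of one stage/day (full-day in the reference design).
#' @param metrics character vector of metric names.
#' @param widths window widths in hours; default `c(1, 3)`.
#' @param B bootstrap replicates per window; default `1e4`.
#' @param seed integer seed for the bootstrap (one stream per window, derived
#'   deterministically).
#' @param alpha significance threshold for the `significant` column.
#' @return data frame: `metric`, `width_h`, `window_index`, `window_start_s`,
#'   `R2`, `ci_low`, `ci_high`, `p`, `n`, `significant`.
#' @export
prediction_table <- function(recs, metrics, widths = c(1, 3), B = 1e4,
                             seed = 1, alpha = 0.05) {
  rows <- list()
  for (metric in metrics) {
    y <- vapply(recs, daily_effort, numeric(1), metric = metric)
    for (w in widths) {
      em <- effort_matrix(recs, metric, w)
      for (j in seq_len(ncol(em$values))) {
        x <- em$values[, j]
        fit <- tryCatch(ols_r2(x, y), error = function(e) NULL)
        if (is.null(fit) || !is.null(fit$flag) && fit$flag == "zero_x_variance") {
          r2 <- NA_real_; ci <- list(low = NA_real_, high = NA_real_)
          p <- NA_real_; n <- sum(!is.na(x) & !is.na(y))
        } else {
          r2 <- fit$R2; p <- fit$p; n <- fit$n
          ci <- bootstrap_r2_ci(x, y, B = B,
                                seed = seed + 7919L * j + 104729L * match(w, widths))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, width_h = w, window_index = j,
          window_start_s = em$windows$start[j],
          R2 = r2, ci_low = ci$low, ci_high = ci$high, p = p, n = n,
          significant = !is.na(p) && p < alpha)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
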