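#' Chi-square periodogram (Sokolove-Bulla)
#'
#' The series is summed into \code{bin_min}-minute bins; for each candidate
#' period P the bins are folded at P and grouped into K = round(P /
#' bin_width) phase columns with means M_h. The statistic is
#' \deqn{Q_P = N \sum_h n_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2,}
#' which under the null of no rhythm is chi-square with K - 1 degrees of
#' freedom; the per-period significance line is the chi-square quantile at
#' level \code{alpha}, Bonferroni-divided by the number of candidate
#' periods by default so that the whole scan has family-wise level alpha.
#' The reported peak is the candidate maximizing \eqn{Q_P} minus its
#' significance line.
#'
#' @param a an \code{\link{activity_series}} (>= 2 days; circadian use
#'   assumes 14+ days of constant darkness).
#' @param period_range candidate period range in hours.
#' @param step_h candidate period step in hours.
#' @param bin_min binning of the series in minutes.
#' @param alpha significance level of the chi-square line.
#' @param adjust "bonferroni" (default) corrects the line for the number
#'   of candidate periods; "none" uses the pointwise quantile.
#' @return object of class \code{chi2_periodogram}: \code{spectrum}
#'   (data.frame period_h, Q, threshold, df), \code{peak_period_h},
#'   \code{peak_Q}, \code{significant}.
#' @export
chi2_periodogram <- function(a, period_range = c(14, 34), step_h = 0.1,
                             bin_min = 30, alpha = 0.01,
                             adjust = c("bonferroni", "none")) {
  stopifnot(inherits(a, "activity_series"))
  adjust <- match.arg(adjust)
  x <- bin_series(a$counts, bin_min)
  N <- length(x)
  if (N < 2L) stop("series too short for a periodogram")
  constant <- stats::var(x) == 0
  periods <- seq(period_range[1], period_range[2], by = step_h)
  a_eff <- if (adjust == "bonferroni") alpha / length(periods) else alpha
  denom <- sum((x - mean(x))^2)
  Q <- numeric(length(periods)); df <- integer(length(periods))
  t_bin <- (seq_len(N) - 1) * (bin_min / 60)  # hours
  for (j in seq_along(periods)) {
    P <- periods[j]
    K <- max(2L, as.integer(round(P / (bin_min / 60))))
    phase <- as.integer(floor((t_bin %% P) / (P / K)))
    phase[phase >= K] <- K - 1L
    n_h <- tabulate(phase + 1L, nbins = K)
    s_h <- numeric(K)
    sums <- rowsum(x, phase)
    s_h[as.integer(rownames(sums)) + 1L] <- sums[, 1]
    occ <- n_h > 0L
    M_h <- s_h[occ] / n_h[occ]
    Q[j] <- if (constant) 0 else
      N * sum(n_h[occ] * (M_h - mean(x))^2) / denom
    df[j] <- sum(occ) - 1L
  }
  thr <- stats::qchisq(1 - a_eff, df)
  excess <- Q - thr
  peak <- which.max(excess)
  if (constant) {
    warning("constant series: no periodogram peak")
    peak_period <- NA_real_
  } else {
    peak_period <- periods[peak]
  }
  structure(list(spectrum = data.frame(period_h = periods, Q = Q,
                                       threshold = thr, df = df),
                 peak_period_h = peak_period,
                 peak_Q = if (constant) NA_real_ else Q[peak],
                 significant = !constant && excess[peak] > 0,
                 alpha = alpha, adjust = adjust),
            class = "chi2_periodogram")
}

# sum a 1-min series into bin_min-minute bins, dropping any remainder
bin_series <- function(counts, bin_min) {
  n <- (length(counts) %/% bin_min) * bin_min
  if (n < bin_min) stop("series shorter than one bin")
  colSums(matrix(counts[seq_len(n)], nrow = bin_min))
}

#' @export
print.chi2_periodogram <- function(x, ...) {
  cat("chi-square periodogram: peak",
      if (is.na(x$peak_period_h)) "none" else
        sprintf("%.1f h (Q = %.1f, %ssignificant at alpha = %g)",
                x$peak_period_h, x$peak_Q,
                if (x$significant) "" else "not ", x$alpha), "\n")
  invisible(x)
}

#' @export
plot.chi2_periodogram <- function(x, ...) {
  graphics::plot(x$spectrum$period_h, x$spectrum$Q, type = "l",
                 xlab = "period (h)", ylab = expression(Q[P]), ...)
  graphics::lines(x$spectrum$period_h, x$spectrum$threshold, lty = 2,
                  col = "red")
  if (!is.na(x$peak_period_h))
    graphics::abline(v = x$peak_period_h, col = "grey60", lty = 3)
  invisible(x)
}

#' FFT rhythm-power value
#'
#' Relative spectral power of rhythmicity: the series is summed into
#' \code{bin_min}-minute bins and mean-subtracted; the value is the power
#' at the strongest frequency whose period falls in \code{band} divided by
#' the total power over all positive frequencies, hence in [0, 1]. A
#' constant series scores 0.
#'
#' @param a an \code{\link{activity_series}}.
#' @param band period band in hours to search for the circadian peak.
#' @param bin_min binning in minutes.
#' @return relative power in [0, 1].
#' @export
fft_value <- function(a, band = c(18, 30), bin_min = 30) {
  stopifnot(inherits(a, "activity_series"))
  x <- bin_series(a$counts, bin_min)
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  N <- length(x)
  pw <- Mod(stats::fft(x))^2
  k <- seq_len(floor(N / 2))           # positive frequencies
  period_h <- (N / k) * (bin_min / 60)
  in_band <- period_h >= band[1] & period_h <= band[2]
  if (!any(in_band)) return(0)
  max(pw[1 + k][in_band]) / sum(pw[1 + k])
}

#' Classify rhythmicity
#'
#' Default rule: arrhythmic if the periodogram peak is below its
#' significance line OR the FFT value is below \code{t_low}; rhythmic if
#' the peak is significant AND the FFT value reaches \code{t_high};
#' otherwise weakly rhythmic. The two FFT cutoffs are documented
#' surrogates for proprietary analysis-suite defaults and are emitted with
#' every report.
#'
#' @param pg \code{\link{chi2_periodogram}} result.
#' @param fft \code{\link{fft_value}} result for the same fly.
#' @param t_low,t_high FFT-value cutoffs for arrhythmic / rhythmic.
#' @return one of "rhythmic", "weak", "arrhythmic".
#' @export
classify_rhythmicity <- function(pg, fft, t_low = 0.01, t_high = 0.03) {
  stopifnot(inherits(pg, "chi2_periodogram"))
  if (!isTRUE(pg$significant) || fft < t_low) return("arrhythmic")
  if (fft >= t_high) "rhythmic" else "weak"
}

#' Full circadian analysis of one fly
#'
#' @param a an \code{\link{activity_series}}.
#' @param ... passed to \code{\link{chi2_periodogram}}.
#' @param t_low,t_high cutoffs for \code{\link{classify_rhythmicity}}.
#' @return object of class \code{rhythm_result}: \code{fly_id},
#'   \code{period_h} (NA when arrhythmic), \code{fft_value}, \code{class},
#'   \code{periodogram}.
#' @export
rhythm_analysis <- function(a, ..., t_low = 0.01, t_high = 0.03) {
  pg <- chi2_periodogram(a, ...)
  fv <- fft_value(a)
  cls <- classify_rhythmicity(pg, fv, t_low, t_high)
  structure(list(fly_id = a$fly_id,
                 period_h = if (cls == "arrhythmic") NA_real_
                            else pg$peak_period_h,
                 fft_value = fv, class = cls, periodogram = pg,
                 thresholds = c(t_low = t_low, t_high = t_high)),
            class = "rhythm_result")
}

#' @export
print.rhythm_result <- function(x, ...) {
  cat(sprintf("%s: %s%s, FFT value %.3f (cutoffs %g/%g)\n", x$fly_id,
              x$class,
              if (is.na(x$period_h)) "" else
                sprintf(", period %.1f h", x$period_h),
              x$fft_value, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Group rhythmicity summary table
#'
#' One row per group: N, rhythmic/weak/arrhythmic counts, FFT value mean
#' +/- SEM and period mean +/- SEM, both computed over the rhythmic and
#' weakly rhythmic flies only (arrhythmic flies have no meaningful period
#' or rhythm power).
#'
#' @param results list of \code{\link{rhythm_analysis}} results.
#' @param groups character vector assigning each result to a group.
#' @return data.frame, one row per group.
#' @export
rhythm_table <- function(results, groups) {
  stopifnot(length(results) == length(groups))
  cls <- vapply(results, `[[`, "", "class")
  per <- vapply(results, `[[`, 0, "period_h")
  fft <- vapply(results, `[[`, 0, "fft_value")
  out <- lapply(unique(groups), function(g) {
    sel <- groups == g
    rw <- sel & cls != "arrhythmic"
    sem <- function(v) if (sum(!is.na(v)) > 1)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else NA_real_
    data.frame(group = g, N = sum(sel),
               rhythmic = sum(sel & cls == "rhythmic"),
               weak = sum(sel & cls == "weak"),
               arrhythmic = sum(sel & cls == "arrhythmic"),
               fft_mean = if (any(rw)) mean(fft[rw]) else NA_real_,
               fft_sem = sem(fft[rw]),
               period_mean = if (any(rw)) mean(per[rw], na.rm = TRUE)
                             else NA_real_,
               period_sem = sem(per[rw]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fisher's exact comparison of rhythmicity between two groups
#'
#' Tests rhythmic-or-weak versus arrhythmic counts in a 2x2 table via
#' \code{\link{fisher_exact}}.
#'
#' @param results,groups as in \code{\link{rhythm_table}}.
#' @param group_a,group_b the two groups to compare.
#' @return \code{\link{fisher_exact}} result plus the \code{table}.
#' @export
rhythmicity_test <- function(results, groups, group_a, group_b) {
  cls <- vapply(results, `[[`, "", "class")
  tab <- vapply(c(group_a, group_b), function(g)
    c(sum(groups == g & cls != "arrhythmic"),
      sum(groups == g & cls == "arrhythmic")), numeric(2))
  tab <- t(tab)
  colnames(tab) <- c("rhythmic_or_weak", "arrhythmic")
  ft <- fisher_exact(tab)
  ft$table <- tab
  ft
}

#' Actogram matrix
#'
#' Day-by-day activity raster; when double-plotted, row i concatenates day
#' i and day i + 1 (so a d-day series gives d - 1 rows), the standard
#' display for spotting free-running drift.
#'
#' @param a an \code{\link{activity_series}} with >= 1 full day.
#' @param double_plot TRUE for the conventional 48-h rows.
#' @return numeric matrix of class \code{actogram}, one row per plotted
#'   day, 1440 or 2880 minute columns.
#' @export
actogram <- function(a, double_plot = TRUE) {
  stopifnot(inherits(a, "activity_series"))
  n_days <- floor(length(a$counts) / 1440)
  if (n_days < (if (double_plot) 2L else 1L))
    stop("too few full days for an actogram")
  day_mat <- matrix(a$counts[seq_len(n_days * 1440L)],
                    nrow = n_days, byrow = TRUE)
  m <- if (double_plot)
    cbind(day_mat[-n_days, , drop = FALSE], day_mat[-1, , drop = FALSE])
  else day_mat
  rownames(m) <- paste0("day", seq_len(nrow(m)))
  class(m) <- c("actogram", class(m))
  m
}

#' @export
plot.actogram <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::grey.colors(32, start = 1, end = 0),
                  axes = FALSE, xlab = "time of day (h)", ylab = "day", ...)
  graphics::axis(1, at = seq(0, 1, length.out = 5),
                 labels = round(seq(0, ncol(m) / 60, length.out = 5)))
  invisible(x)
}
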