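#' A single courtship observation
#'
#' One male's timed courting intervals in one session. The effective
#' observation window is the nominal window truncated at successful
#' copulation; intervals must be sorted, non-overlapping and contained in
#' the effective window.
#'
#' @param intervals data.frame with \code{start,end} in seconds.
#' @param window_s nominal observation window (default 600 s).
#' @param copulation_s time of successful copulation, or NA.
#' @param male_id,genotype,condition,session identifiers (condition is
#'   trained/sham; session is initial/final/test/sham).
#' @return object of class \code{courtship_record}.
#' @export
courtship_record <- function(intervals, window_s = 600, copulation_s = NA,
                             male_id = "m1", genotype = NA_character_,
                             condition = NA_character_,
                             session = NA_character_) {
  eff <- if (is.na(copulation_s)) window_s else min(window_s, copulation_s)
  if (eff <= 0) stop("empty observation: effective window is 0")
  if (nrow(intervals) > 0) {
    intervals <- intervals[order(intervals$start), , drop = FALSE]
    if (any(intervals$end <= intervals$start))
      stop("intervals must have end > start")
    if (any(intervals$start < 0) || any(intervals$end > eff + 1e-9))
      stop("intervals must lie within [0, effective window]")
    if (nrow(intervals) > 1 &&
        any(intervals$start[-1] < intervals$end[-nrow(intervals)] - 1e-9))
      stop("intervals overlap")
  }
  structure(list(intervals = intervals, window_s = window_s,
                 copulation_s = copulation_s, effective_window = eff,
                 male_id = male_id, genotype = genotype,
                 condition = condition, session = session),
            class = "courtship_record")
}

#' Courtship index
#'
#' Fraction of the effective observation window (10 minutes, or until
#' successful copulation) a male spends in active courtship.
#'
#' @param r a \code{\link{courtship_record}}.
#' @return CI in [0, 1].
#' @export
courtship_index <- function(r) {
  stopifnot(inherits(r, "courtship_record"))
  sum(r$intervals$end - r$intervals$start) / r$effective_window
}

#' Learning contrast: within-fly courtship decrement
#'
#' Learning in courtship conditioning is the decline from a fly's initial
#' to its final courtship index during training, analyzed as a paired t
#' test on the per-fly decrements.
#'
#' @param initial,final per-fly CI vectors, same flies in the same order.
#' @param paired paired (default, the within-fly design) or unpaired.
#' @return list with \code{decrement_mean}, \code{decrement_se}, \code{p}.
#' @export
learning_test <- function(initial, final, paired = TRUE) {
  st <- student_t(initial, final, paired = paired)
  d <- if (paired) initial - final else NULL
  list(decrement_mean = mean(initial) - mean(final),
       decrement_se = if (paired) stats::sd(d) / sqrt(length(d))
                      else NA_real_,
       p = st$p)
}

#' Cross-genotype comparison of learning decrements
#'
#' One-way ANOVA with Tukey HSD on per-fly decrements (CI initial - CI
#' final), the test used to compare learning capacity across genotypes.
#'
#' @param decrements named list of per-fly decrement vectors by genotype.
#' @return \code{\link{anova_tukey}} result.
#' @export
learning_comparison <- function(decrements) anova_tukey(decrements)

#' Short-term memory contrast: trained vs naive males
#'
#' Unpaired Student t of CI test (trained males, tested on a virgin after
#' a rest) against CI sham (separate naive males). Memory is called only
#' when the difference is significant AND in the suppressive direction; a
#' significant increase is flagged instead.
#'
#' @param test,sham per-fly CI vectors for the trained and naive groups.
#' @param alpha significance cutoff for the memory call.
#' @return list with \code{ratio} (test mean / sham mean), \code{p},
#'   \code{memory} (logical), \code{flag} ("" or "increase").
#' @export
memory_test <- function(test, sham, alpha = 0.05) {
  st <- student_t(test, sham)
  ratio <- mean(test) / mean(sham)
  suppressed <- mean(test) < mean(sham)
  list(ratio = ratio, p = st$p,
       memory = st$p < alpha && suppressed,
       flag = if (st$p < alpha && !suppressed) "increase" else "")
}

#' Read courtship records from long-format TSV
#'
#' Columns: male_id, genotype, condition, session, window_s, copulation_s
#' (empty or NA for none), interval_start_s, interval_end_s; one row per
#' courting interval, and a single row with empty interval fields for a
#' male that never courted.
#'
#' @param path TSV file.
#' @return list of \code{\link{courtship_record}}.
#' @export
read_courtship_records <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("male_id", "genotype", "condition", "session", "window_s",
            "copulation_s", "interval_start_s", "interval_end_s")
  if (!all(need %in% names(df))) stop("missing courtship record columns")
  key <- paste(df$male_id, df$session)
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    iv <- g[!is.na(g$interval_start_s),
            c("interval_start_s", "interval_end_s")]
    names(iv) <- c("start", "end")
    courtship_record(iv, window_s = g$window_s[1],
                     copulation_s = g$copulation_s[1],
                     male_id = g$male_id[1], genotype = g$genotype[1],
                     condition = g$condition[1], session = g$session[1])
  })
}

#' Write courtship records to long-format TSV
#'
#' @param records list of \code{\link{courtship_record}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_courtship_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    iv <- r$intervals
    if (nrow(iv) == 0) iv <- data.frame(start = NA_real_, end = NA_real_)
    data.frame(male_id = r$male_id, genotype = r$genotype,
               condition = r$condition, session = r$session,
               window_s = r$window_s, copulation_s = r$copulation_s,
               interval_start_s = iv$start, interval_end_s = iv$end,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
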