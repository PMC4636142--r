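#' Configuration for the courtship-conditioning simulator
#'
#' Defaults emulate a conditioning experiment in which controls court
#' vigorously at first (CI ~ 0.8), suppress courtship strongly by the end
#' of training, and retain roughly half their naive courtship when tested
#' an hour later -- the canonical learning/short-term-memory pattern.
#'
#' @param n_males males per condition.
#' @param window_s observation window in seconds.
#' @param ci_means named numeric: target mean CI per session
#'   (initial, final, test, sham), each in [0, 1].
#' @param ci_sd SD of the per-male target CI (truncated to [0, 1]).
#' @param copulation_prob probability of successful copulation in the
#'   test/sham sessions (virgin females); training females are pre-mated
#'   and never copulate.
#' @param seed RNG seed.
#' @return list of class \code{courtship_sim_config}.
#' @export
courtship_sim_config <- function(n_males = 20, window_s = 600,
                                 ci_means = c(initial = 0.8, final = 0.4,
                                              test = 0.3, sham = 0.6),
                                 ci_sd = 0.15, copulation_prob = 0,
                                 seed = 1) {
  stopifnot(n_males >= 1, window_s > 0,
            all(c("initial", "final", "test", "sham") %in% names(ci_means)),
            all(ci_means >= 0), all(ci_means <= 1), ci_sd >= 0,
            copulation_prob >= 0, copulation_prob <= 1)
  structure(as.list(environment()), class = "courtship_sim_config")
}

#' Simulate courtship-conditioning records with known truth
#'
#' Each trained male gets an initial and final training CI and a test CI;
#' a disjoint naive cohort gets sham CIs. Courting time equal to the
#' target CI times the effective window is split into non-overlapping
#' intervals placed in order; copulation (test/sham only) truncates the
#' window and the intervals with it.
#'
#' @param cfg a \code{\link{courtship_sim_config}}.
#' @return list of class \code{courtship_sim}: \code{records} (list of
#'   \code{\link{courtship_record}}), \code{truth} (target session means).
#' @export
gen_courtship <- function(cfg) {
  stopifnot(inherits(cfg, "courtship_sim_config"))
  set.seed(cfg$seed)
  records <- list()
  for (sess in c("initial", "final", "test", "sham")) {
    cond <- if (sess == "sham") "sham" else "trained"
    cop_ok <- sess %in% c("test", "sham")
    for (i in seq_len(cfg$n_males)) {
      id <- sprintf("%s%02d", if (cond == "sham") "n" else "t", i)
      ci <- min(1, max(0, stats::rnorm(1, cfg$ci_means[[sess]], cfg$ci_sd)))
      cop <- if (cop_ok && stats::runif(1) < cfg$copulation_prob)
        stats::runif(1, 0.2, 1) * cfg$window_s else NA
      eff <- if (is.na(cop)) cfg$window_s else min(cfg$window_s, cop)
      records[[paste(id, sess)]] <- courtship_record(
        place_intervals(ci, eff), window_s = cfg$window_s,
        copulation_s = cop, male_id = id, genotype = "sim",
        condition = cond, session = sess)
    }
  }
  truth <- data.frame(session = names(cfg$ci_means),
                      target_ci = unname(cfg$ci_means),
                      stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, config = cfg),
            class = "courtship_sim")
}

# split courting time ci * window into non-overlapping ordered intervals
place_intervals <- function(ci, window) {
  total <- ci * window
  if (total <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (total >= window - 1e-9)
    return(data.frame(start = 0, end = window))
  k <- 1L + stats::rpois(1, 2)
  seg <- stats::rexp(k); seg <- seg / sum(seg) * total
  gap <- stats::rexp(k + 1L); gap <- gap / sum(gap) * (window - total)
  start <- cumsum(gap)[seq_len(k)] + c(0, cumsum(seg))[seq_len(k)]
  data.frame(start = start, end = start + seg)
}

#' Summarize a set of courtship records per session
#'
#' @param records list of \code{\link{courtship_record}}.
#' @param min_n warn when a session has fewer than this many males (the
#'   conventional minimum cohort is 18).
#' @return data.frame with session, n, mean CI, SE.
#' @export
courtship_summary <- function(records, min_n = 18) {
  sess <- vapply(records, `[[`, "", "session")
  ci <- vapply(records, courtship_index, 0)
  out <- lapply(unique(sess), function(s) {
    v <- ci[sess == s]
    ms <- suppressWarnings(mean_se(v))
    data.frame(session = s, n = length(v), ci_mean = ms$mean,
               ci_se = ms$se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$n < min_n))
    warning("session(s) below the conventional n >= ", min_n, ": ",
            paste(out$session[out$n < min_n], collapse = ", "))
  out
}
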