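# Independent oracles used to cross-check the package implementations.
# Each is a direct textbook formula, enumeration or brute-force loop kept
# deliberately separate from the code paths it validates.

# pooled two-sample t from the textbook formula
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# two-sided Fisher p by explicit enumeration over all tables with the
# observed margins: sum hypergeometric probabilities <= P(observed)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- pr[ks == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# per-base brute force: expand a strand track into a depth array and sum
# depth over the union of each gene's exon bases (0-based half-open)
oracle_exon_union <- function(tracks, models) {
  glen <- max(models$end) + 10L
  out <- setNames(numeric(length(unique(models$gene_id))),
                  unique(models$gene_id))
  for (str in c("+", "-")) {
    depth <- numeric(glen)
    tr <- tracks[[str]]
    if (!is.null(tr)) for (i in seq_len(nrow(tr)))
      depth[(tr$start[i] + 1):tr$end[i]] <-
        depth[(tr$start[i] + 1):tr$end[i]] + tr$score[i]
    sel <- models$strand == str
    for (g in unique(models$gene_id[sel])) {
      rows <- which(models$gene_id == g & sel)
      bases <- unique(unlist(lapply(rows, function(r)
        (models$start[r] + 1):models$end[r])))
      out[g] <- sum(depth[bases])
    }
  }
  out
}

# brute-force run scanner for sleep bouts (runs of zeros >= min_bout)
oracle_sleep_bouts <- function(counts, min_bout = 5) {
  starts <- integer(0); durs <- integer(0)
  i <- 1L; n <- length(counts)
  while (i <= n) {
    if (counts[i] == 0L) {
      j <- i
      while (j < n && counts[j + 1L] == 0L) j <- j + 1L
      if (j - i + 1L >= min_bout) {
        starts <- c(starts, i); durs <- c(durs, j - i + 1L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, duration = durs)
}

# total-coverage normalization: the standard-method control used only to
# demonstrate why the pipeline anchors to histones instead
total_coverage_normalize <- function(tab, offset = 1) {
  sc <- setdiff(names(tab), c("gene_id", "gene_class"))
  totals <- colSums(tab[, sc, drop = FALSE])
  f <- mean(totals) / totals
  for (s in sc) tab[[s]] <- (tab[[s]] + offset) * f[[s]]
  tab
}

# group sample columns of the simulated coverage experiment
sim_groups <- function(sim) {
  split(sim$samples$sample_id, sim$samples$group)
}
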