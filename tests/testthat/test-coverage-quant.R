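# hand-built two-gene fixture: one exon of 100 bp at depth 2, and a gene
# whose two exons overlap by 50 bp at depth 1
tiny_models <- data.frame(
  gene_id = c("gA", "gB", "gB"),
  gene_class = "protein_coding",
  seqname = "chr1", strand = c("+", "+", "+"),
  start = c(0L, 300L, 350L), end = c(100L, 400L, 450L),
  stringsAsFactors = FALSE)

test_that("exon-union coverage sums depth once per union base", {
  track <- list("+" = data.frame(seqname = "chr1", start = 0L, end = 500L,
                                 score = c(1), stringsAsFactors = FALSE))
  cov <- exon_union_coverage(track, tiny_models)
  expect_equal(unname(cov["gB"]), 150)  # 100 + 100 - 50 overlap
  track2 <- list("+" = data.frame(seqname = "chr1", start = 0L, end = 100L,
                                  score = 2, stringsAsFactors = FALSE))
  expect_equal(unname(exon_union_coverage(track2, tiny_models)["gA"]), 200)
})

test_that("opposite-strand and missing-contig coverage is not counted", {
  minus_track <- list("-" = data.frame(seqname = "chr1", start = 0L,
                                       end = 500L, score = 3,
                                       stringsAsFactors = FALSE))
  expect_warning(cov <- exon_union_coverage(minus_track, tiny_models),
                 "no track coverage")
  expect_true(all(cov == 0))
  far <- tiny_models; far$seqname <- "chrZ"
  track <- list("+" = data.frame(seqname = "chr1", start = 0L, end = 500L,
                                 score = 1, stringsAsFactors = FALSE))
  expect_warning(cov <- exon_union_coverage(track, far), "no track")
  expect_true(all(cov == 0))
})

test_that("exon-union coverage equals the per-base brute-force oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 40
    models <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      st <- sort(sample(0:1800, k))
      data.frame(gene_id = sprintf("g%02d", i),
                 gene_class = "protein_coding", seqname = "chr1",
                 strand = sample(c("+", "-"), 1),
                 start = st, end = st + sample(20:200, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    tracks <- lapply(c("+", "-"), function(s) {
      brk <- sort(sample(0:2100, 25))
      data.frame(seqname = "chr1", start = brk[-25], end = brk[-1],
                 score = rpois(24, 3), stringsAsFactors = FALSE)
    })
    names(tracks) <- c("+", "-")
    got <- exon_union_coverage(tracks, models)
    want <- oracle_exon_union(tracks, models)
    expect_equal(got[names(want)], want)
  }
})

test_that("contaminant stripping removes exactly the labeled classes", {
  tab <- data.frame(gene_id = paste0("g", 1:14),
                    gene_class = c(rep("protein_coding", 3), "histone",
                                   rep("rRNA", 5), rep("small_ncRNA", 5)),
                    s1 = 1:14, s2 = 14:1, stringsAsFactors = FALSE)
  out <- strip_contaminants(tab)
  expect_equal(nrow(out), 4)
  expect_identical(out$s1, tab$s1[1:4])
  clean <- tab[1:4, ]; rownames(clean) <- NULL
  expect_identical(strip_contaminants(clean), clean)
})

test_that("histone factors equalize the anchor totals exactly", {
  tab <- data.frame(gene_id = c("h1", "g1"),
                    gene_class = c("histone", "protein_coding"),
                    a = c(100, 7), b = c(50, 7), stringsAsFactors = FALSE)
  nf <- histone_norm_factors(tab)
  expect_equal(nf$mean_total, 75)
  expect_equal(unname(nf$factors), c(0.75, 1.5))
  # definitional identity on arbitrary input
  set.seed(8)
  tab2 <- data.frame(gene_id = paste0("g", 1:20),
                     gene_class = c(rep("histone", 4), rep("other", 16)),
                     r1 = runif(20, 1, 100), r2 = runif(20, 1, 100),
                     r3 = runif(20, 1, 100), stringsAsFactors = FALSE)
  nf2 <- histone_norm_factors(tab2)
  expect_equal(unname(nf2$factors * nf2$histone_totals),
               rep(nf2$mean_total, 3))
  tab2$r1[tab2$gene_class == "histone"] <- 0
  expect_error(histone_norm_factors(tab2), "anchor absent")
})

test_that("normalization applies the offset before scaling", {
  tab <- data.frame(gene_id = c("h", "g0"), gene_class = c("histone", "pc"),
                    a = c(10, 0), b = c(10, 0), stringsAsFactors = FALSE)
  nf <- list(factors = c(a = 0.75, b = 1.5))
  out <- normalize_coverage(tab, nf, offset = 1)
  expect_equal(out$a, c(11 * 0.75, 0.75))
  expect_equal(out$b, c(11 * 1.5, 1.5))   # zero-coverage gene stays positive
  ident <- normalize_coverage(tab, list(factors = c(a = 1, b = 1)),
                              offset = 0)
  expect_equal(ident, tab)
})

test_that("post-normalization histone totals agree within the offset bound", {
  set.seed(77)
  s <- gen_coverage(coverage_sim_config(n_genes = 300, n_histone = 10,
                                        seed = 4))
  tab <- strip_contaminants(s$table)
  nf <- histone_norm_factors(tab)
  sc <- setdiff(names(tab), c("gene_id", "gene_class"))
  # offset = 0: anchored totals are exactly equal
  n0 <- normalize_coverage(tab, nf, offset = 0)
  tot0 <- colSums(n0[n0$gene_class == "histone", sc])
  expect_equal(unname(tot0), rep(nf$mean_total, length(sc)))
  # offset = 1: totals differ by at most n_histone * max factor spread
  n1 <- normalize_coverage(tab, nf, offset = 1)
  tot1 <- colSums(n1[n1$gene_class == "histone", sc])
  bound <- 10 * max(dist(nf$factors))
  expect_lte(max(dist(tot1)), bound + 1e-9)
})

test_that("the active-gene filter is a strict mean threshold", {
  norm <- data.frame(gene_id = c("at", "below", "above"),
                     gene_class = "protein_coding",
                     s1 = c(500, 400, 501), s2 = c(500, 400, 501),
                     stringsAsFactors = FALSE)
  expect_identical(active_genes(norm), "above")
  # the filter averages over all samples of both groups jointly
  norm2 <- data.frame(gene_id = "g", gene_class = "pc",
                      a = 1000, b = 2, stringsAsFactors = FALSE)
  expect_identical(active_genes(norm2), "g")  # mean 501 > 500
})

test_that("per-gene statistics match the t-formula oracle and truth", {
  s <- gen_coverage(coverage_sim_config(seed = 1))
  res <- quantify_expression(s$table, sim_groups(s)$control,
                             sim_groups(s)$mutant)
  st <- res$stats
  # identical groups give log2fc 0, p 1
  dup <- res$normalized
  same <- per_gene_stats(dup, sim_groups(s)$control, sim_groups(s)$control)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$p == 1))
  # p values agree with the independent pooled-t oracle
  set.seed(6)
  idx <- sample(nrow(st), 20)
  a <- as.matrix(dup[, sim_groups(s)$control])
  b <- as.matrix(dup[, sim_groups(s)$mutant])
  for (i in idx)
    expect_equal(st$p[i], oracle_pooled_t(b[i, ], a[i, ])$p,
                 tolerance = 1e-9)
  # the global down-shift is recovered in the median of true-down genes
  down <- s$truth$gene_id[s$truth$true_log2fc < 0]
  expect_lt(abs(median(st$log2fc[st$gene_id %in% down]) - log2(0.8)), 0.03)
})

test_that("fold-change densities integrate to one and sit where expected", {
  s <- gen_coverage(coverage_sim_config(seed = 2))
  res <- quantify_expression(s$table, sim_groups(s)$control,
                             sim_groups(s)$mutant)
  d <- fc_density(res$stats)
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
  expect_lt(d$x[which.max(d$y)], 0)      # shifted simulation: mode below 0
  # near-delta input peaks at the common value
  st0 <- res$stats[1:50, ]; st0$log2fc <- 0.7 + rnorm(50, 0, 1e-4)
  d0 <- fc_density(st0)
  expect_equal(d0$x[which.max(d0$y)], 0.7, tolerance = 0.01)
  # null simulation: mode within 0.05 of zero
  s0 <- gen_coverage(coverage_sim_config(global_fc = 1, seed = 3))
  r0 <- quantify_expression(s0$table, sim_groups(s0)$control,
                            sim_groups(s0)$mutant)
  dn <- fc_density(r0$stats)
  expect_lt(abs(dn$x[which.max(dn$y)]), 0.05)
})

test_that("replicate correlation matrices behave like Fig-style reports", {
  s <- gen_coverage(coverage_sim_config(seed = 9))
  res <- quantify_expression(s$table, sim_groups(s)$control,
                             sim_groups(s)$mutant)
  m <- res$correlations
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, ncol(m)))
  expect_true(all(m[lower.tri(m)] > 0.9))   # 10% CV, 2000 genes
  dup <- res$normalized
  dup$copy <- dup$ctrl_1
  m2 <- replicate_correlations(dup)
  expect_equal(m2["ctrl_1", "copy"], 1)
})

test_that("histone anchoring beats total-coverage normalization on a
           global shift", {
  s <- gen_coverage(coverage_sim_config(seed = 14))
  res <- quantify_expression(s$table, sim_groups(s)$control,
                             sim_groups(s)$mutant)
  nh <- res$stats$gene_class != "histone"
  anchored <- median(res$stats$log2fc[nh])
  tot <- total_coverage_normalize(strip_contaminants(s$table))
  mt <- log2(rowMeans(tot[, sim_groups(s)$mutant]) /
             rowMeans(tot[, sim_groups(s)$control]))
  biased <- median(mt[tot$gene_class != "histone"])
  true_shift <- log2(0.8)
  expect_lt(abs(anchored - true_shift), 0.03)
  expect_gte(abs(biased - true_shift), 0.5 * abs(true_shift))
})

test_that("the pipeline wrapper enforces the stage order", {
  s <- gen_coverage(coverage_sim_config(n_genes = 200, n_histone = 10,
                                        seed = 10))
  res <- quantify_expression(s$table, sim_groups(s)$control,
                             sim_groups(s)$mutant)
  stripped <- strip_contaminants(s$table)
  nf <- histone_norm_factors(stripped)
  expect_equal(res$norm_factors$factors, nf$factors)
  norm <- normalize_coverage(stripped, nf, 1)
  expect_equal(res$normalized, norm)
  expect_identical(res$active, active_genes(norm, 500))
  expect_false(any(res$normalized$gene_class %in%
                     c("rRNA", "small_ncRNA")))
})

test_that("expression report tabs partition active genes by direction", {
  s <- gen_coverage(coverage_sim_config(n_genes = 300, n_histone = 10,
                                        seed = 12))
  res <- quantify_expression(s$table, sim_groups(s)$control,
                             sim_groups(s)$mutant)
  dir <- withr::local_tempdir()
  paths <- write_expression_tabs(res$stats, res$active, res$correlations,
                                 dir)
  expressed <- read.delim(paths$EXPRESSED)
  down <- read.delim(paths$DOWN)
  up <- read.delim(paths$UP)
  expect_setequal(expressed$gene_id, res$active)
  expect_true(all(down$p <= 0.05) && all(down$log2fc < 0))
  expect_true(all(up$p <= 0.05) && all(up$log2fc > 0))
  expect_true(all(c(down$gene_id, up$gene_id) %in% expressed$gene_id))
})
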