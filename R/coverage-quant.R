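#' Sum per-base coverage over each gene's exon union
#'
#' For each gene, overlapping exons are merged first so every base is
#' counted once, then per-base depth from the strand-matched track is
#' summed over the union. Tracks and models both use the package-internal
#' 0-based half-open convention (bedGraph is native; GFF is converted by
#' \code{\link{read_gene_models}}).
#'
#' @param tracks named list with components \code{"+"} and \code{"-"}, each
#'   a bedGraph-style data.frame (\code{seqname,start,end,score}) for one
#'   sample. A missing strand component is treated as zero coverage.
#' @param models exon table as returned by \code{\link{read_gene_models}}.
#' @return named numeric vector: summed nucleotide coverage per gene.
#'   Genes whose contig is absent from the matching track get 0 with a
#'   warning.
#' @export
exon_union_coverage <- function(tracks, models) {
  stopifnot(is.list(tracks))
  gr <- GenomicRanges::GRanges(
    models$seqname, IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand)
  red <- GenomicRanges::reduce(S4Vectors::split(gr, models$gene_id))
  gene_ids <- names(red)
  gene_strand <- vapply(seq_along(red), function(i)
    as.character(GenomicRanges::strand(red[[i]])[1]), "")
  out <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  missing_contig <- character(0)
  for (str in c("+", "-")) {
    sel <- gene_strand == str
    if (!any(sel)) next
    tr <- tracks[[str]]
    exons <- unlist(red[sel], use.names = FALSE)
    exon_gene <- rep(gene_ids[sel], S4Vectors::elementNROWS(red[sel]))
    if (is.null(tr) || nrow(tr) == 0L) {
      missing_contig <- c(missing_contig, unique(exon_gene))
      next
    }
    tgr <- GenomicRanges::GRanges(
      tr$seqname, IRanges::IRanges(tr$start + 1L, tr$end))
    GenomicRanges::strand(exons) <- "*"
    absent <- !(as.character(GenomicRanges::seqnames(exons)) %in%
                  unique(tr$seqname))
    if (any(absent))
      missing_contig <- c(missing_contig, unique(exon_gene[absent]))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(exons, tgr))
    if (length(hits) > 0L) {
      ov <- IRanges::pintersect(
        IRanges::ranges(exons)[S4Vectors::queryHits(hits)],
        IRanges::ranges(tgr)[S4Vectors::subjectHits(hits)])
      contrib <- IRanges::width(ov) * tr$score[S4Vectors::subjectHits(hits)]
      sums <- tapply(contrib, exon_gene[S4Vectors::queryHits(hits)], sum)
      out[names(sums)] <- out[names(sums)] + as.numeric(sums)
    }
  }
  if (length(missing_contig) > 0L)
    warning("no track coverage for contigs of gene(s): ",
            paste(unique(missing_contig), collapse = ", "),
            "; coverage set to 0")
  out
}

#' Build a GeneCoverageTable from per-sample strand tracks
#'
#' @param track_list named list (one element per sample) of per-strand
#'   track lists as accepted by \code{\link{exon_union_coverage}}.
#' @param models exon table (\code{\link{read_gene_models}}).
#' @return data.frame with \code{gene_id}, \code{gene_class} and one
#'   coverage column per sample.
#' @export
exon_union_coverage_table <- function(track_list, models) {
  stopifnot(is.list(track_list), length(track_list) > 0L,
            !is.null(names(track_list)))
  cov <- lapply(track_list, exon_union_coverage, models = models)
  gene_ids <- names(cov[[1]])
  cls <- models$gene_class[match(gene_ids, models$gene_id)]
  out <- data.frame(gene_id = gene_ids, gene_class = cls,
                    stringsAsFactors = FALSE)
  for (s in names(cov)) out[[s]] <- unname(cov[[s]][gene_ids])
  rownames(out) <- NULL
  validate_coverage_table(out)
  out
}

#' Remove contaminant gene classes before normalization
#'
#' Drops ribosomal RNA (incompletely removed by depletion) and small
#' non-coding RNAs (not quantitatively removed during library size
#' selection). Must run before \code{\link{histone_norm_factors}}.
#'
#' @param tab GeneCoverageTable data.frame.
#' @param classes gene classes to drop.
#' @return the table with contaminant rows removed, others untouched.
#' @export
strip_contaminants <- function(tab, classes = c("rRNA", "small_ncRNA")) {
  validate_coverage_table(tab)
  out <- tab[!(tab$gene_class %in% classes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histone-anchored normalization factors
#'
#' Each sample's total coverage over the histone gene class is computed
#' from the raw (pre-offset) table; the factor for sample s is the mean of
#' those totals across ALL samples of both genotypes divided by sample s's
#' total, so that factor x histone total is identical across samples.
#' Replication-coupled histone mRNA output tracks DNA content, making this
#' anchor immune to global shifts in transcription that defeat
#' total-coverage normalization.
#'
#' @param tab GeneCoverageTable (after \code{\link{strip_contaminants}}).
#' @param histone_class class label of the anchor genes.
#' @return list of class \code{norm_factors}: \code{factors} (named per
#'   sample), \code{histone_totals}, \code{mean_total}.
#' @export
histone_norm_factors <- function(tab, histone_class = "histone") {
  validate_coverage_table(tab)
  sc <- sample_columns(tab)
  hist_rows <- tab$gene_class == histone_class
  if (!any(hist_rows)) stop("no genes of class '", histone_class, "'")
  totals <- colSums(tab[hist_rows, sc, drop = FALSE])
  if (any(totals == 0))
    stop("histone anchor absent in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  mean_total <- mean(totals)
  structure(list(factors = mean_total / totals,
                 histone_totals = totals,
                 mean_total = mean_total),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("Histone-anchored normalization factors\n")
  cat("  mean histone total:", format(x$mean_total, digits = 6), "\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Apply normalization factors with a pseudocount offset
#'
#' Every remaining gene's raw coverage (histones included) becomes
#' \code{(raw + offset) x factor}; the offset is added BEFORE scaling and
#' guarantees strictly positive values, so downstream log2 ratios are
#' always finite.
#'
#' @param tab GeneCoverageTable.
#' @param nf \code{\link{histone_norm_factors}} result (or any list with a
#'   named \code{factors} element covering all samples).
#' @param offset pseudocount in nucleotides (default 1).
#' @return data.frame in the same layout with normalized values.
#' @export
normalize_coverage <- function(tab, nf, offset = 1) {
  validate_coverage_table(tab)
  sc <- sample_columns(tab)
  f <- nf$factors
  if (!all(sc %in% names(f))) stop("factors missing for some samples")
  out <- tab
  for (s in sc) out[[s]] <- (tab[[s]] + offset) * f[[s]]
  out
}

#' Active-gene filter
#'
#' A gene is active when its normalized coverage, averaged over ALL samples
#' of both genotypes, strictly exceeds the threshold (default 500
#' nucleotides).
#'
#' @param norm normalized table (\code{\link{normalize_coverage}}).
#' @param threshold coverage threshold in nucleotides.
#' @return character vector of active gene ids.
#' @export
active_genes <- function(norm, threshold = 500) {
  validate_coverage_table(norm)
  sc <- sample_columns(norm)
  m <- rowMeans(norm[, sc, drop = FALSE])
  norm$gene_id[m > threshold]
}

#' Per-gene group statistics
#'
#' For each gene: group means and standard errors, the log2 ratio of group
#' B over group A means, and a two-tailed pooled-variance Student t p value
#' (via \code{\link{student_t}}). Direction labels follow the p <= alpha
#' rule used for the DOWN/UP report tabs.
#'
#' @param norm normalized table.
#' @param group_a,group_b character vectors of sample column names
#'   (A = control/reference; the log2 ratio is B over A).
#' @param alpha significance cutoff for the direction label.
#' @return data.frame of class \code{gene_stats} with columns
#'   \code{gene_id, gene_class, mean_a, mean_b, se_a, se_b, log2fc, t, p,
#'   direction}.
#' @export
per_gene_stats <- function(norm, group_a, group_b, alpha = 0.05) {
  validate_coverage_table(norm)
  sc <- sample_columns(norm)
  stopifnot(all(group_a %in% sc), all(group_b %in% sc),
            length(group_a) >= 2L, length(group_b) >= 2L)
  a <- as.matrix(norm[, group_a, drop = FALSE])
  b <- as.matrix(norm[, group_b, drop = FALSE])
  res <- t(vapply(seq_len(nrow(norm)), function(i) {
    st <- suppressWarnings(student_t(b[i, ], a[i, ]))
    c(st$t, st$p)
  }, numeric(2)))
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  out <- data.frame(
    gene_id = norm$gene_id, gene_class = norm$gene_class,
    mean_a = mean_a, mean_b = mean_b,
    se_a = apply(a, 1, stats::sd) / sqrt(ncol(a)),
    se_b = apply(b, 1, stats::sd) / sqrt(ncol(b)),
    log2fc = log2(mean_b / mean_a),
    t = res[, 1], p = res[, 2],
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$p > alpha, "ns",
                          ifelse(out$log2fc < 0, "down", "up"))
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' @export
print.gene_stats <- function(x, ...) {
  cat(nrow(x), "genes;",
      sum(x$direction == "down"), "down and",
      sum(x$direction == "up"), "up at p <= 0.05;",
      "median log2FC", round(stats::median(x$log2fc), 3), "\n")
  NextMethod()
}

#' Kernel density of per-gene log2 fold-changes
#'
#' @param stats \code{\link{per_gene_stats}} result.
#' @param subset "all" genes or only "significant" ones (p <= alpha).
#' @param alpha cutoff used when \code{subset = "significant"}.
#' @param ... passed to \code{\link[stats]{density}}.
#' @return a \code{density} object (integrates to 1 over its grid).
#' @export
fc_density <- function(stats, subset = c("all", "significant"),
                       alpha = 0.05, ...) {
  subset <- match.arg(subset)
  v <- if (subset == "significant")
    stats$log2fc[stats$p <= alpha] else stats$log2fc
  if (length(v) < 2L) stop("too few genes for a density estimate")
  d <- stats::density(v, ...)
  # renormalize so the curve integrates to exactly 1 over its own grid
  area <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  d$y <- d$y / area
  d
}

#' Pairwise Pearson correlations between samples
#'
#' Computed on the normalized values of all quantified genes (i.e. before
#' the active-gene filter).
#'
#' @param norm normalized table.
#' @return symmetric sample x sample correlation matrix with unit diagonal.
#' @export
replicate_correlations <- function(norm) {
  validate_coverage_table(norm)
  sc <- sample_columns(norm)
  m <- stats::cor(as.matrix(norm[, sc, drop = FALSE]), method = "pearson")
  diag(m) <- 1
  m
}

#' Run the full coverage-quantification pipeline
#'
#' Enforces the stage order: contaminant stripping, then histone-anchored
#' factors (computed on the stripped raw table), then offset
#' normalization, then the active filter and per-gene statistics.
#'
#' @param tab raw GeneCoverageTable.
#' @param group_a,group_b sample columns of the two genotypes (A is the
#'   reference).
#' @param histone_class,offset,active_threshold,alpha stage parameters.
#' @return list with \code{norm_factors}, \code{normalized}, \code{active},
#'   \code{stats} (all genes), \code{active_stats},
#'   \code{correlations}.
#' @export
quantify_expression <- function(tab, group_a, group_b,
                                histone_class = "histone", offset = 1,
                                active_threshold = 500, alpha = 0.05) {
  stripped <- strip_contaminants(tab)
  nf <- histone_norm_factors(stripped, histone_class)
  norm <- normalize_coverage(stripped, nf, offset)
  act <- active_genes(norm, active_threshold)
  st <- per_gene_stats(norm, group_a, group_b, alpha)
  list(norm_factors = nf, normalized = norm, active = act,
       stats = st,
       active_stats = st[st$gene_id %in% act, , drop = FALSE],
       correlations = replicate_correlations(norm))
}
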