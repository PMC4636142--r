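#' Read gene models from GFF3
#'
#' Reads exon features and converts them, once and at this boundary, from
#' GFF3's 1-based inclusive coordinates to the package-internal 0-based
#' half-open convention. Features need \code{gene_id} and (optionally)
#' \code{gene_class} attributes; a missing class defaults to "other".
#'
#' @param path GFF3 file.
#' @return exon-level data.frame with columns
#'   \code{gene_id, gene_class, seqname, strand, start, end}
#'   (start 0-based, end exclusive).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  cls <- if (!is.null(gr$gene_class)) as.character(gr$gene_class)
         else rep("other", length(gr))
  cls[is.na(cls)] <- "other"
  data.frame(gene_id = as.character(gr$gene_id),
             gene_class = cls,
             seqname = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# internal: write the exon table as GFF3 (converting back to 1-based
# inclusive at the boundary)
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf(
    "%s\tflypheno\texon\t%d\t%d\t.\t%s\t.\tgene_id=%s;gene_class=%s",
    models$seqname, models$start + 1L, models$end, models$strand,
    models$gene_id, models$gene_class)
  writeLines(lines, con)
}

#' Read a bedGraph coverage track
#'
#' bedGraph is consumed natively as 0-based half-open; no coordinate shift
#' is applied.
#'
#' @param path bedGraph file (4 columns: seqname, start, end, score).
#' @return data.frame with columns \code{seqname, start, end, score}.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seqname", "start", "end", "score"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"),
                          comment.char = "#")
  if (any(df$end <= df$start)) stop("malformed bedGraph intervals in ", path)
  df
}

# internal bedGraph writer (full precision scores)
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(track) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%.12g", track$seqname, track$start,
                       track$end, track$score), con)
}

#' Read a precomputed per-gene coverage table
#'
#' @param path TSV with columns \code{gene_id}, \code{gene_class}, then one
#'   numeric column per sample.
#' @return data.frame in GeneCoverageTable layout.
#' @export
read_coverage_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "gene_class") %in% names(df)))
    stop("coverage table needs gene_id and gene_class columns")
  validate_coverage_table(df)
  df
}

# internal: structural checks shared by readers and pipeline stages
validate_coverage_table <- function(tab) {
  sc <- sample_columns(tab)
  if (length(sc) == 0L) stop("coverage table has no sample columns")
  vals <- as.matrix(tab[, sc, drop = FALSE])
  if (any(is.na(vals))) stop("coverage table has missing cells")
  if (any(vals < 0)) stop("coverage must be non-negative")
  invisible(tab)
}

# names of the per-sample numeric columns of a coverage/expression table
sample_columns <- function(tab) {
  setdiff(names(tab), c("gene_id", "gene_class"))
}

#' Write per-gene statistics in spreadsheet-tab layout
#'
#' Writes the per-gene statistics table split the way the study's
#' supplementary workbook is organized: ALL_GENES, EXPRESSED (active
#' genes), DOWN and UP (active genes changing with p <= alpha), plus the
#' replicate correlation matrix.
#'
#' @param stats result of \code{\link{per_gene_stats}}.
#' @param active character vector of active gene ids
#'   (\code{\link{active_genes}}).
#' @param correlations matrix from \code{\link{replicate_correlations}}.
#' @param dir output directory.
#' @param alpha significance cutoff for the DOWN/UP tabs.
#' @return invisibly, named list of written paths.
#' @export
write_expression_tabs <- function(stats, active, correlations, dir,
                                  alpha = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expressed <- stats[stats$gene_id %in% active, , drop = FALSE]
  tabs <- list(
    ALL_GENES = stats,
    EXPRESSED = expressed,
    DOWN = expressed[expressed$p <= alpha & expressed$log2fc < 0, ],
    UP = expressed[expressed$p <= alpha & expressed$log2fc > 0, ])
  paths <- list()
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[nm]] <- p
  }
  p <- file.path(dir, "REPLICATE_CORRELATIONS.tsv")
  utils::write.table(data.frame(sample_id = rownames(correlations),
                                correlations, check.names = FALSE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$REPLICATE_CORRELATIONS <- p
  invisible(paths)
}
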