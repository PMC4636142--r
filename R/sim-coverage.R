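#' Configuration for the RNA-seq coverage simulator
#'
#' Describes a two-genotype, replicated wing-disc-style RNA-seq experiment
#' quantified as per-gene summed nucleotide coverage. The defaults emulate
#' the study conditions the pipeline was built for: four replicates per
#' genotype, a global modest down-shift (0.8x) of non-histone transcription
#' in the mutant, constant replication-coupled histone output (the
#' normalization anchor), heavy residual ribosomal RNA contamination, and
#' unequal library depths that any per-sample normalization must undo.
#'
#' @param n_genes number of protein-coding genes.
#' @param n_histone number of replication-dependent histone gene copies
#'   (the anchor set; the Drosophila histone locus is a tandem repeat with
#'   on the order of 100 annotated copies of the five core genes, so the
#'   anchor total is a sum over many loci and its relative measurement
#'   noise is small).
#' @param n_rrna number of ribosomal RNA genes (contaminants).
#' @param n_small_ncrna number of small non-coding RNA genes (snoRNA/tRNA
#'   class contaminants, removed before normalization).
#' @param replicates_per_group replicates per genotype.
#' @param baseline_meanlog,baseline_sdlog log-normal location/scale of the
#'   per-gene baseline coverage (nucleotides).
#' @param global_fc multiplier applied to every non-histone gene's true
#'   output in the mutant group (0.8 = global 20% down-shift).
#' @param fc_jitter_sd per-gene SD (log2 units) of the fold-change around
#'   \code{global_fc}.
#' @param depth_multipliers optional numeric vector, one per sample
#'   (controls first), of library-depth multipliers applied to ALL genes;
#'   default NULL draws them from Unif(0.6, 1.4).
#' @param rrna_fraction fraction of each library's coverage that is
#'   ribosomal contamination (0 disables the rRNA genes' signal).
#' @param cv multiplicative per-gene, per-sample measurement noise
#'   (coefficient of variation of a log-normal with mean 1).
#' @param histone_level true coverage of each histone gene (identical in
#'   both groups).
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return list of class \code{coverage_sim_config}.
#' @export
coverage_sim_config <- function(n_genes = 2000, n_histone = 100, n_rrna = 8,
                                n_small_ncrna = 30, replicates_per_group = 4,
                                baseline_meanlog = log(2000),
                                baseline_sdlog = 1.3,
                                global_fc = 0.8, fc_jitter_sd = 0.1,
                                depth_multipliers = NULL,
                                rrna_fraction = 0.5, cv = 0.1,
                                histone_level = 5e3, seed = 1) {
  stopifnot(n_genes > 0, n_histone > 0, n_rrna >= 0, n_small_ncrna >= 0,
            replicates_per_group > 0, global_fc > 0, fc_jitter_sd >= 0,
            rrna_fraction >= 0, rrna_fraction < 1, cv >= 0,
            histone_level > 0)
  n_samples <- 2L * replicates_per_group
  if (!is.null(depth_multipliers)) {
    stopifnot(length(depth_multipliers) == n_samples,
              all(depth_multipliers > 0))
  }
  structure(list(n_genes = n_genes, n_histone = n_histone, n_rrna = n_rrna,
                 n_small_ncrna = n_small_ncrna,
                 replicates_per_group = replicates_per_group,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 global_fc = global_fc, fc_jitter_sd = fc_jitter_sd,
                 depth_multipliers = depth_multipliers,
                 rrna_fraction = rrna_fraction, cv = cv,
                 histone_level = histone_level, seed = seed),
            class = "coverage_sim_config")
}

#' Simulate a replicated coverage-quantified RNA-seq experiment
#'
#' Generates gene models, a per-gene x per-sample raw coverage table, and a
#' truth table of per-gene fold-changes. Histone genes have identical true
#' output in both groups; every other gene is scaled by
#' \code{global_fc x 2^jitter} in the mutant; per-sample depth multipliers
#' are then applied to all genes alike, so only an anchor-based
#' normalization can recover the global shift.
#'
#' @param cfg a \code{\link{coverage_sim_config}}.
#' @return list of class \code{coverage_sim} with elements \code{models}
#'   (exon table: gene_id, gene_class, seqname, strand, start, end in
#'   0-based half-open coordinates), \code{table} (the raw
#'   GeneCoverageTable: gene_id, gene_class, one column per sample),
#'   \code{samples} (sample_id, group, replicate, depth), \code{truth}
#'   (gene_id, gene_class, base_level, true_fc, true_log2fc), \code{config}.
#' @export
gen_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "coverage_sim_config"))
  set.seed(cfg$seed)
  classes <- c(rep("protein_coding", cfg$n_genes),
               rep("histone", cfg$n_histone),
               rep("rRNA", cfg$n_rrna),
               rep("small_ncRNA", cfg$n_small_ncrna))
  n_all <- length(classes)
  gene_id <- sprintf("G%05d", seq_len(n_all))

  base <- stats::rlnorm(n_all, cfg$baseline_meanlog, cfg$baseline_sdlog)
  base[classes == "histone"] <- cfg$histone_level
  # rRNA contamination: scale the rRNA genes so they carry rrna_fraction of
  # the expected library signal
  non_rrna_total <- sum(base[classes != "rRNA"])
  if (cfg$n_rrna > 0) {
    if (cfg$rrna_fraction > 0) {
      rr_total <- cfg$rrna_fraction / (1 - cfg$rrna_fraction) * non_rrna_total
      w <- stats::runif(cfg$n_rrna)
      base[classes == "rRNA"] <- rr_total * w / sum(w)
    } else {
      base[classes == "rRNA"] <- 0
    }
  }

  true_fc <- rep(1, n_all)
  shifted <- classes != "histone"
  true_fc[shifted] <- cfg$global_fc *
    2 ^ stats::rnorm(sum(shifted), 0, cfg$fc_jitter_sd)

  n_rep <- cfg$replicates_per_group
  samples <- data.frame(
    sample_id = c(paste0("ctrl_", seq_len(n_rep)),
                  paste0("mut_", seq_len(n_rep))),
    group = rep(c("control", "mutant"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L),
    stringsAsFactors = FALSE)
  depth <- cfg$depth_multipliers
  if (is.null(depth)) depth <- stats::runif(nrow(samples), 0.6, 1.4)
  samples$depth <- depth

  sdl <- sqrt(log(1 + cfg$cv^2))
  tab <- matrix(0, n_all, nrow(samples),
                dimnames = list(gene_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu <- base * (if (samples$group[s] == "mutant") true_fc else 1) * depth[s]
    noise <- if (cfg$cv > 0)
      stats::rlnorm(n_all, -sdl^2 / 2, sdl) else rep(1, n_all)
    tab[, s] <- mu * noise
  }

  models <- make_gene_models(gene_id, classes)
  table <- data.frame(gene_id = gene_id, gene_class = classes,
                      tab, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(table) <- NULL
  truth <- data.frame(gene_id = gene_id, gene_class = classes,
                      base_level = base, true_fc = true_fc,
                      true_log2fc = log2(true_fc),
                      stringsAsFactors = FALSE)
  structure(list(models = models, table = table, samples = samples,
                 truth = truth, config = cfg),
            class = "coverage_sim")
}

# Lay genes end to end on one synthetic contig, alternating strands.
# Each gene gets 1-3 exons; every third multi-exon gene gets a pair of
# overlapping exons so union merging is exercised. Coordinates are 0-based
# half-open (the package's internal convention).
make_gene_models <- function(gene_id, classes) {
  n <- length(gene_id)
  n_ex <- sample(1:3, n, replace = TRUE)
  rows <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    starts <- integer(n_ex[i]); ends <- integer(n_ex[i])
    p <- pos
    for (e in seq_len(n_ex[i])) {
      len <- sample(80:400, 1L)
      starts[e] <- p
      ends[e] <- p + len
      p <- ends[e] + sample(20:100, 1L)
    }
    if (n_ex[i] >= 2L && i %% 3L == 0L) {
      # force an overlap between the first two exons
      starts[2] <- ends[1] - sample(10:60, 1L)
      if (starts[2] < starts[1] + 1L) starts[2] <- starts[1] + 1L
    }
    rows[[i]] <- data.frame(gene_id = gene_id[i], gene_class = classes[i],
                            seqname = "chrS", strand = strand,
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
    pos <- max(ends) + 200L
  }
  do.call(rbind, rows)
}

#' Expand a coverage simulation to per-base coverage tracks
#'
#' Distributes each gene's raw coverage uniformly over its merged exon
#' union, giving one bedGraph-style interval track per strand per sample
#' (0-based half-open, real-valued depth). Summing depth over the exon
#' union recovers the raw table entry, so these tracks exercise the
#' interval-summation code path with exact truth.
#'
#' @param sim a \code{\link{gen_coverage}} result.
#' @return named list (one element per sample) of lists with components
#'   \code{"+"} and \code{"-"}, each a data.frame with columns
#'   \code{seqname,start,end,score}.
#' @export
sim_tracks <- function(sim) {
  stopifnot(inherits(sim, "coverage_sim"))
  mod <- sim$models
  # merged exon union per gene
  gr <- GenomicRanges::GRanges(mod$seqname,
                               IRanges::IRanges(mod$start + 1L, mod$end),
                               strand = mod$strand)
  red <- GenomicRanges::reduce(S4Vectors::split(gr, mod$gene_id))
  ulen <- sum(GenomicRanges::width(red))
  gene_ids <- names(red)
  flat <- unlist(red, use.names = FALSE)
  flat_gene <- rep(gene_ids, S4Vectors::elementNROWS(red))
  flat_strand <- as.character(GenomicRanges::strand(flat))
  out <- list()
  for (s in sim$samples$sample_id) {
    raw <- sim$table[[s]][match(flat_gene, sim$table$gene_id)]
    depth <- raw / ulen[match(flat_gene, gene_ids)]
    df <- data.frame(seqname = as.character(GenomicRanges::seqnames(flat)),
                     start = GenomicRanges::start(flat) - 1L,
                     end = GenomicRanges::end(flat),
                     score = depth, stringsAsFactors = FALSE)
    out[[s]] <- list("+" = df[flat_strand == "+", , drop = FALSE],
                     "-" = df[flat_strand == "-", , drop = FALSE])
  }
  out
}

#' Write a coverage simulation to disk
#'
#' Writes GFF3 gene models (1-based inclusive, with a \code{gene_class}
#' attribute), one bedGraph per strand per sample (0-based half-open), the
#' raw coverage table, the truth table and a manifest recording the seed.
#'
#' @param sim a \code{\link{gen_coverage}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
write_coverage_files <- function(sim, dir) {
  stopifnot(inherits(sim, "coverage_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(models = file.path(dir, "gene_models.gff3"),
                table = file.path(dir, "coverage_table.tsv"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  write_gene_models_gff3(sim$models, paths$models)
  utils::write.table(sim$table, paths$table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tracks <- sim_tracks(sim)
  for (s in names(tracks)) {
    for (str in c("+", "-")) {
      tag <- if (str == "+") "plus" else "minus"
      p <- file.path(dir, sprintf("%s_%s.bedGraph", s, tag))
      paths[[paste0(s, "_", tag)]] <- p
      write_bedgraph(tracks[[s]][[str]], p)
    }
  }
  utils::write.table(
    data.frame(key = c("generator", "seed"),
               value = c("gen_coverage", sim$config$seed)),
    paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
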