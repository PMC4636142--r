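#' Cell density from a sampled wing region
#'
#' Each wing epithelial cell produces exactly one trichome (hair), so the
#' hair count in a sampled region divided by its area gives cells per mm2.
#'
#' @param hair_count hairs counted in the region.
#' @param region_area sampled region area in mm2 (> 0).
#' @return cells per mm2.
#' @export
cell_density <- function(hair_count, region_area) {
  stopifnot(region_area > 0, hair_count >= 0)
  hair_count / region_area
}

#' Mean apical cell area from cell density
#'
#' 10^6 / density converts cells per mm2 to um2 per cell. Full precision
#' is returned; reports round to 1 decimal.
#'
#' @param density cells per mm2 (> 0).
#' @return um2 per cell.
#' @export
cell_area <- function(density) {
  stopifnot(density > 0)
  1e6 / density
}

#' Total cells per wing
#'
#' @param wing_area wing blade area in mm2.
#' @param density cells per mm2.
#' @return integer cell count (rounded).
#' @export
cells_per_wing <- function(wing_area, density) {
  stopifnot(wing_area >= 0, density >= 0)
  round(wing_area * density)
}

#' Ratio of mutant to matched control means
#'
#' @param mutant,control numeric measurement vectors.
#' @return list with \code{ratio} (mean(mutant)/mean(control), full
#'   precision; reports round to 2 decimals) and \code{p} (pooled
#'   two-tailed Student t).
#' @export
genotype_ratio <- function(mutant, control) {
  st <- suppressWarnings(student_t(mutant, control))
  list(ratio = mean(mutant) / mean(control), p = st$p)
}

#' Count wing hairs in a high-magnification image
#'
#' Semi-automated trichome counting: the image is binarized at a
#' percentile intensity threshold (illumination-invariant), a 3x3
#' morphological opening suppresses salt noise that a fixed-fraction
#' threshold necessarily marks, 8-connected components are labeled, and
#' components smaller than \code{min_spot_px} are dropped. Touching hairs
#' merge into one component and are counted once (a documented
#' limitation of this class of counter).
#'
#' @param image single-channel numeric matrix.
#' @param intensity_threshold percentile (0-100) for binarization.
#' @param min_spot_px minimum component size in pixels.
#' @return integer hair count; a blank or saturated image returns 0 with
#'   a warning.
#' @export
count_hairs <- function(image, intensity_threshold = 90, min_spot_px = 4) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (diff(range(image)) < 1e-8) {
    warning("blank or saturated image: no hairs counted")
    return(0L)
  }
  thr <- stats::quantile(image, intensity_threshold / 100, names = FALSE)
  mask <- EBImage::Image(image > thr)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  sum(sizes >= min_spot_px)
}

#' Per-fly weight summaries from batch weighings
#'
#' Flies are weighed in batches (default 20 per batch); per-fly mass is
#' batch mass over batch size, and statistics are computed over batches
#' (n = number of batches).
#'
#' @param batches data.frame with columns \code{genotype, sex, food_level,
#'   batch_mass} (mg) and optionally \code{flies_per_batch} (default 20).
#' @return data.frame per genotype/sex/food: n_batches, mean and SE of mg
#'   per fly.
#' @export
weight_summary <- function(batches) {
  need <- c("genotype", "sex", "food_level", "batch_mass")
  stopifnot(all(need %in% names(batches)), all(batches$batch_mass > 0))
  if (is.null(batches$flies_per_batch)) batches$flies_per_batch <- 20L
  stopifnot(all(batches$flies_per_batch >= 1))
  per_fly <- batches$batch_mass / batches$flies_per_batch
  key <- interaction(batches$genotype, batches$sex, batches$food_level,
                     drop = TRUE)
  out <- lapply(split(seq_len(nrow(batches)), key), function(idx) {
    ms <- mean_se(per_fly[idx])
    data.frame(genotype = batches$genotype[idx[1]],
               sex = batches$sex[idx[1]],
               food_level = batches$food_level[idx[1]],
               n_batches = length(idx),
               mg_per_fly = ms$mean, se = ms$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Developmental timing curves
#'
#' Cumulative pupariation and eclosion curves from daily counts, with
#' median transition days (first day the cumulative count reaches half
#' its final value; the median is robust to the long right tail of
#' eclosion curves) and survival fractions.
#'
#' @param counts data.frame with columns \code{day}, \code{new_pupae},
#'   \code{new_adults} (daily increments, one row per day).
#' @param initial_larvae number of larvae seeded.
#' @return list with \code{curves} (day, cum_pupae, cum_adults),
#'   \code{median_pupariation}, \code{median_eclosion} (NA, with a
#'   warning, if nothing survived), \code{survival_pupae},
#'   \code{survival_adults}.
#' @export
timing_curves <- function(counts, initial_larvae) {
  need <- c("day", "new_pupae", "new_adults")
  stopifnot(all(need %in% names(counts)), initial_larvae >= 1)
  counts <- counts[order(counts$day), , drop = FALSE]
  cum_p <- cumsum(counts$new_pupae)
  cum_a <- cumsum(counts$new_adults)
  if (max(cum_p) > initial_larvae || max(cum_a) > initial_larvae)
    stop("cumulative counts exceed the initial larvae count")
  med <- function(cum) {
    tot <- cum[length(cum)]
    if (tot == 0) return(NA_real_)
    counts$day[which(cum >= tot / 2)[1]]
  }
  mp <- med(cum_p); me <- med(cum_a)
  if (is.na(mp) || is.na(me))
    warning("zero survivors in a stage: median day undefined")
  list(curves = data.frame(day = counts$day, cum_pupae = cum_p,
                           cum_adults = cum_a),
       median_pupariation = mp, median_eclosion = me,
       survival_pupae = max(cum_p) / initial_larvae,
       survival_adults = max(cum_a) / initial_larvae)
}

#' Compare apoptotic-cell counts per disc across genotypes
#'
#' Boxplot-style five-number summaries per genotype plus pairwise pooled
#' Student t tests on the per-disc counts.
#'
#' @param counts named list of per-disc apoptotic-cell counts by genotype.
#' @return list with \code{summary} (data.frame: genotype, n, median, q1,
#'   q3, mean) and \code{pairwise} (data.frame: pair, p).
#' @export
apoptosis_compare <- function(counts) {
  stopifnot(is.list(counts), length(counts) >= 2L,
            !is.null(names(counts)))
  if (any(lengths(counts) == 0)) stop("empty group")
  summ <- do.call(rbind, lapply(names(counts), function(g) {
    q <- stats::quantile(counts[[g]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(genotype = g, n = length(counts[[g]]), median = q[2],
               q1 = q[1], q3 = q[3], mean = mean(counts[[g]]),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(counts), 2)
  pw <- data.frame(
    pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
    p = apply(pairs, 2, function(pr)
      suppressWarnings(student_t(counts[[pr[1]]], counts[[pr[2]]]))$p),
    stringsAsFactors = FALSE)
  list(summary = summ, pairwise = pw)
}
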