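#' Configuration for the wing-morphometry simulator
#'
#' Defaults emulate a wild-type female wing cohort: blade area ~1.74 mm2,
#' ~5971 cells per mm2, and a 0.02 mm2 sampled region (so the expected
#' hair count per region is near 120), with 40 wings per genotype.
#'
#' @param n_wings wings per genotype.
#' @param genotype label carried into the records.
#' @param wing_area_mean,wing_area_sd wing blade area (mm2).
#' @param density_mean,density_sd cell density (cells per mm2).
#' @param region_area sampled region area (mm2); must be below the wing
#'   area.
#' @param img_size side length (pixels) of generated hair images.
#' @param spot_radius hair spot radius in pixels.
#' @param spot_intensity spot brightness (background is 0.2).
#' @param noise_sd Gaussian background noise SD.
#' @param seed RNG seed.
#' @return list of class \code{wing_sim_config}.
#' @export
wing_sim_config <- function(n_wings = 40, genotype = "control",
                            wing_area_mean = 1.74, wing_area_sd = 0.06,
                            density_mean = 5971, density_sd = 150,
                            region_area = 0.02, img_size = 256,
                            spot_radius = 2, spot_intensity = 1,
                            noise_sd = 0.05, seed = 1) {
  stopifnot(n_wings >= 1, wing_area_mean > 0, density_mean > 0,
            density_sd >= 0, region_area > 0,
            region_area < wing_area_mean, img_size >= 32,
            spot_radius >= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "wing_sim_config")
}

#' Simulate wing records (and optionally hair images) with known truth
#'
#' Per wing: area and cell density are drawn from the configured normals,
#' and the hair count in the sampled region is Poisson(density x region
#' area). With \code{images = TRUE} each wing also gets a synthetic
#' high-magnification image containing exactly \code{hair_count}
#' well-separated bright spots on a noisy background, so the image
#' counter has construction-level truth.
#'
#' @param cfg a \code{\link{wing_sim_config}}.
#' @param images generate per-wing images (slower; off by default).
#' @return list of class \code{wing_sim}: \code{records} (wing_id,
#'   genotype, wing_area, sampled_region_area, hair_count),
#'   \code{truth} (per-wing true density), \code{images} (list of
#'   matrices or NULL), \code{config}.
#' @export
gen_wings <- function(cfg, images = FALSE) {
  stopifnot(inherits(cfg, "wing_sim_config"))
  set.seed(cfg$seed)
  area <- stats::rnorm(cfg$n_wings, cfg$wing_area_mean, cfg$wing_area_sd)
  area <- pmax(area, cfg$region_area * 2)
  dens <- pmax(1, stats::rnorm(cfg$n_wings, cfg$density_mean,
                               cfg$density_sd))
  hairs <- stats::rpois(cfg$n_wings, dens * cfg$region_area)
  records <- data.frame(
    wing_id = sprintf("%s_w%03d", cfg$genotype, seq_len(cfg$n_wings)),
    genotype = cfg$genotype, wing_area = area,
    sampled_region_area = cfg$region_area, hair_count = hairs,
    stringsAsFactors = FALSE)
  imgs <- NULL
  if (images)
    imgs <- lapply(hairs, function(n)
      gen_hair_image(n, size = cfg$img_size, radius = cfg$spot_radius,
                     intensity = cfg$spot_intensity,
                     noise_sd = cfg$noise_sd))
  structure(list(records = records,
                 truth = data.frame(wing_id = records$wing_id,
                                    true_density = dens,
                                    stringsAsFactors = FALSE),
                 images = imgs, config = cfg),
            class = "wing_sim")
}

#' Synthetic wing-hair image with an exact spot count
#'
#' Draws \code{n_spots} bright disks on a noisy background. Spot centers
#' sit on a jittered grid whose pitch keeps every pair separated by more
#' than three spot radii, so spots never touch and the construction is
#' its own counting oracle.
#'
#' @param n_spots number of spots (hairs).
#' @param size image side length in pixels.
#' @param radius spot radius in pixels.
#' @param intensity spot brightness; background mean is 0.2.
#' @param noise_sd background Gaussian noise SD.
#' @return numeric matrix in [0, 1].
#' @export
gen_hair_image <- function(n_spots, size = 256, radius = 2, intensity = 1,
                           noise_sd = 0.05) {
  stopifnot(n_spots >= 0, size >= 16, radius >= 1)
  pitch <- 3L * radius + 4L
  cells_per_side <- (size - 2L * radius - 2L) %/% pitch
  if (n_spots > cells_per_side^2)
    stop("too many spots for non-touching placement at this image size")
  img <- matrix(pmin(1, pmax(0, stats::rnorm(size * size, 0.2, noise_sd))),
                size, size)
  if (n_spots == 0) return(img)
  cells <- sample(cells_per_side^2, n_spots)
  jit <- (pitch - 2L * radius - 2L) %/% 2L
  cx <- ((cells - 1L) %% cells_per_side) * pitch + radius + 2L +
    sample(-jit:jit, n_spots, replace = TRUE)
  cy <- ((cells - 1L) %/% cells_per_side) * pitch + radius + 2L +
    sample(-jit:jit, n_spots, replace = TRUE)
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  for (i in seq_len(n_spots)) {
    xs <- cx[i] + off$dx; ys <- cy[i] + off$dy
    ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    img[cbind(xs[ok], ys[ok])] <- intensity
  }
  img
}

#' Wing morphometry summary for one genotype
#'
#' Derives, per wing, the cell density from the sampled region, then the
#' genotype's mean area, density, cell area and cells per wing (the
#' latter two from the means, as in the standard reporting chain).
#'
#' @param records wing record data.frame (see \code{\link{gen_wings}}).
#' @return one-row data.frame: genotype, n, mean wing area (+SE), mean
#'   density, cell area (um2), cells per wing.
#' @export
wing_morphometry <- function(records) {
  stopifnot(all(c("genotype", "wing_area", "sampled_region_area",
                  "hair_count") %in% names(records)))
  dens <- cell_density_vec(records$hair_count,
                           records$sampled_region_area)
  area_ms <- suppressWarnings(mean_se(records$wing_area))
  mean_dens <- mean(dens)
  data.frame(genotype = records$genotype[1], n = nrow(records),
             wing_area = area_ms$mean, wing_area_se = area_ms$se,
             cells_per_mm2 = mean_dens,
             cell_area_um2 = cell_area(mean_dens),
             cells_per_wing = cells_per_wing(area_ms$mean, mean_dens),
             stringsAsFactors = FALSE)
}

# vectorized helper for per-wing densities
cell_density_vec <- function(hair_count, region_area) {
  stopifnot(all(region_area > 0), all(hair_count >= 0))
  hair_count / region_area
}
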