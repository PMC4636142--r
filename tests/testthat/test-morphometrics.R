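test_that("the cell-size arithmetic chain holds exactly", {
  expect_equal(cell_density(100, 0.01), 10000)
  expect_equal(cell_density(0, 0.02), 0)
  expect_equal(cell_area(1e6), 1)
  # pre-rounding identity: cell_area x density = 1e6
  for (d in c(137.5, 5971, 6163, 12000.4))
    expect_equal(cell_area(d) * d, 1e6)
  expect_equal(cells_per_wing(0, 5971), 0)
  # monotone in both arguments
  expect_true(cells_per_wing(1.8, 5971) > cells_per_wing(1.6, 5971))
  expect_true(cells_per_wing(1.74, 6200) > cells_per_wing(1.74, 5900))
})

test_that("genotype ratios and their t tests are wired together", {
  same <- c(1.7, 1.8, 1.75)
  r <- genotype_ratio(same, same)
  expect_equal(r$ratio, 1); expect_equal(r$p, 1)
  set.seed(15)
  mut <- rnorm(40, 1.61, 0.06); ctl <- rnorm(40, 1.74, 0.06)
  r2 <- genotype_ratio(mut, ctl)
  expect_equal(r2$ratio, mean(mut) / mean(ctl))
  expect_equal(r2$p, oracle_pooled_t(mut, ctl)$p, tolerance = 1e-12)
})

test_that("hair counting recovers constructed spot counts exactly", {
  set.seed(25)
  img0 <- gen_hair_image(0)
  expect_equal(count_hairs(img0), 0)
  img250 <- gen_hair_image(250)
  expect_equal(count_hairs(img250), 250)
  for (n in c(1, 40, 120)) {
    img <- gen_hair_image(n)
    expect_equal(count_hairs(img), n)
  }
  expect_warning(cnt <- count_hairs(matrix(1, 64, 64)), "blank")
  expect_equal(cnt, 0)
})

test_that("touching spots merge into a single counted component", {
  img <- matrix(rnorm(128 * 128, 0.2, 0.03), 128, 128)
  disk <- function(cx, cy, r = 3) {
    for (dx in -r:r) for (dy in -r:r)
      if (dx^2 + dy^2 <= r^2) img[cx + dx, cy + dy] <<- 1
  }
  disk(40, 40); disk(44, 40)     # overlapping pair
  disk(90, 90)                    # isolated spot
  expect_equal(count_hairs(img), 2)
})

test_that("simulated hair counts follow the Poisson density model", {
  cfg <- wing_sim_config(n_wings = 500, density_mean = 5971,
                         density_sd = 0, region_area = 0.02, seed = 33)
  s <- gen_wings(cfg)
  lambda <- 5971 * 0.02                     # 119.42 expected hairs
  se <- sqrt(lambda / 500)
  expect_lt(abs(mean(s$records$hair_count) - lambda), 2 * se)
  # per-wing density estimates recover the generating truth
  dens <- s$records$hair_count / s$records$sampled_region_area
  expect_lt(abs(mean(dens) - 5971), 2 * sd(dens) / sqrt(500))
  # per-image counts equal the recorded hair counts (construction oracle)
  s2 <- gen_wings(wing_sim_config(n_wings = 4, seed = 2), images = TRUE)
  expect_equal(vapply(s2$images, count_hairs, 0L),
               s2$records$hair_count)
})

test_that("wing summaries reproduce the reporting chain from records", {
  s <- gen_wings(wing_sim_config(n_wings = 60, seed = 6))
  w <- wing_morphometry(s$records)
  expect_equal(w$n, 60)
  md <- mean(s$records$hair_count / 0.02)
  expect_equal(w$cells_per_mm2, md)
  expect_equal(w$cell_area_um2, 1e6 / md)
  expect_equal(w$cells_per_wing, round(mean(s$records$wing_area) * md))
})

test_that("batch weighings give per-fly means over batches", {
  b <- data.frame(genotype = "ctl", sex = "m", food_level = 100,
                  batch_mass = c(17.6, 17.8))
  w <- weight_summary(b)
  expect_equal(w$mg_per_fly, 0.885)
  expect_equal(w$n_batches, 2)
  expect_warning(w1 <- weight_summary(b[1, ]), "single")
  expect_equal(w1$se, 0)
  # ratio layout: a 5% lighter mutant is recovered
  set.seed(55)
  ctl <- data.frame(genotype = "ctl", sex = "f", food_level = 100,
                    batch_mass = rnorm(10, 0.88 * 20, 0.3))
  mut <- data.frame(genotype = "mut", sex = "f", food_level = 100,
                    batch_mass = rnorm(10, 0.836 * 20, 0.3))
  r <- genotype_ratio(mut$batch_mass / 20, ctl$batch_mass / 20)
  expect_lt(abs(r$ratio - 0.95), 0.02)
})

test_that("timing curves report medians, survival and flag extinction", {
  counts <- data.frame(day = 1:15,
                       new_pupae = c(rep(0, 9), 80, rep(0, 5)),
                       new_adults = c(rep(0, 11), 75, rep(0, 3)))
  tc <- timing_curves(counts, initial_larvae = 100)
  expect_equal(tc$median_pupariation, 10)
  expect_equal(tc$median_eclosion, 12)
  expect_equal(tc$survival_adults, 0.75)
  expect_true(all(diff(tc$curves$cum_pupae) >= 0))
  # starvation-style doubling of development time doubles the median
  slow <- counts; slow$day <- counts$day * 2
  ts <- timing_curves(slow, 100)
  expect_equal(ts$median_eclosion / tc$median_eclosion, 2)
  dead <- data.frame(day = 1:5, new_pupae = 0, new_adults = 0)
  expect_warning(td <- timing_curves(dead, 100), "zero survivors")
  expect_true(is.na(td$median_eclosion))
  expect_equal(td$survival_adults, 0)
  bad <- data.frame(day = 1:2, new_pupae = c(60, 60), new_adults = 0)
  expect_error(timing_curves(bad, 100), "exceed")
})

test_that("apoptotic-count comparisons summarize and test per genotype", {
  same <- list(a = c(10, 12, 14, 11), b = c(10, 12, 14, 11))
  r <- apoptosis_compare(same)
  expect_equal(r$pairwise$p, 1)
  expect_equal(r$summary$median, c(11.5, 11.5))
  expect_error(apoptosis_compare(list(a = 1:3, b = numeric(0))), "empty")
  # a 1.7-fold increase at n = 20 per disc group is reliably detected
  set.seed(65)
  hits <- 0L
  for (i in 1:200) {
    ctl <- pmax(0, rnorm(20, 20, 7))
    mut <- pmax(0, rnorm(20, 34, 10))
    if (apoptosis_compare(list(c = ctl, m = mut))$pairwise$p < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})
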