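test_that("the courtship index is time courting over the effective window", {
  full <- courtship_record(data.frame(start = 0, end = 600))
  expect_equal(courtship_index(full), 1)
  some <- courtship_record(data.frame(start = c(10, 300),
                                      end = c(100, 390)))
  expect_equal(courtship_index(some), 0.3)
  # copulation truncates the window: courting 0-120 then copulation
  trunc <- courtship_record(data.frame(start = 0, end = 120),
                            copulation_s = 120)
  expect_equal(courtship_index(trunc), 1)
  expect_error(courtship_record(data.frame(start = numeric(0),
                                           end = numeric(0)),
                                copulation_s = 0), "empty observation")
})

test_that("the index is invariant to interval subdivision and obeys the
           complement partition", {
  iv <- data.frame(start = c(0, 200, 450), end = c(150, 380, 600))
  r <- courtship_record(iv)
  split_iv <- data.frame(start = c(0, 75, 200, 290, 450),
                         end = c(75, 150, 290, 380, 600))
  expect_equal(courtship_index(courtship_record(split_iv)),
               courtship_index(r))
  comp <- data.frame(start = c(150, 380), end = c(200, 450))
  expect_equal(courtship_index(courtship_record(comp)),
               1 - courtship_index(r))
  expect_error(courtship_record(data.frame(start = c(0, 50),
                                           end = c(100, 150))), "overlap")
})

test_that("the simulator hits its target indices and round-trips", {
  s <- gen_courtship(courtship_sim_config(n_males = 20, seed = 7))
  summ <- courtship_summary(s$records)
  for (i in seq_len(nrow(s$truth))) {
    row <- summ[summ$session == s$truth$session[i], ]
    expect_lt(abs(row$ci_mean - s$truth$target_ci[i]), 2 * row$ci_se + 1e-9)
  }
  path <- withr::local_tempfile()
  write_courtship_records(s$records, path)
  back <- read_courtship_records(path)
  expect_equal(vapply(back, courtship_index, 0),
               vapply(s$records, courtship_index, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  # deterministic per seed
  s2 <- gen_courtship(courtship_sim_config(n_males = 20, seed = 7))
  expect_equal(vapply(s2$records, courtship_index, 0),
               vapply(s$records, courtship_index, 0))
  expect_warning(courtship_summary(s$records[1:10]), "n >= 18")
})

test_that("degenerate extremes produce exact single-interval records", {
  s <- gen_courtship(courtship_sim_config(n_males = 5, ci_sd = 0,
                                          ci_means = c(initial = 1,
                                                       final = 1,
                                                       test = 1, sham = 1),
                                          seed = 3))
  for (r in s$records) {
    expect_equal(nrow(r$intervals), 1)
    expect_equal(courtship_index(r), 1)
  }
})

test_that("learning is the paired decrement and matches the t machinery", {
  expect_equal(
    suppressWarnings(learning_test(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)))$p, 1)
  set.seed(19)
  ini <- pmin(1, pmax(0, rnorm(20, 0.8, 0.1)))
  fin <- pmin(1, pmax(0, ini - rnorm(20, 0.4, 0.1)))
  lt <- learning_test(ini, fin)
  expect_equal(lt$decrement_mean, mean(ini) - mean(fin))
  expect_lt(lt$p, 0.001)
  # two-genotype Tukey equals the pooled t on decrements
  d1 <- ini - fin; d2 <- rnorm(20, 0.2, 0.1)
  cmp <- learning_comparison(list(control = d1, mutant = d2))
  expect_equal(cmp$pairwise$p_adj[1], oracle_pooled_t(d1, d2)$p,
               tolerance = 1e-6)
})

test_that("a halved learning decrement is detected in most simulations", {
  set.seed(29)
  hits <- 0L
  for (i in 1:200) {
    d_ctrl <- rnorm(20, 0.4, 0.2)
    d_mut <- rnorm(20, 0.2, 0.2)
    cmp <- learning_comparison(list(control = d_ctrl, mutant = d_mut))
    if (cmp$pairwise$p_adj[1] < 0.05) hits <- hits + 1L
  }
  # unpaired power at this effect size (d = 1, n = 20) is 0.87
  expect_gte(hits / 200, 0.8)
})

test_that("memory calls require both significance and suppression", {
  set.seed(37)
  same <- rnorm(18, 0.5, 0.1)
  r0 <- memory_test(same, same)
  expect_equal(r0$p, 1); expect_false(r0$memory)
  up <- memory_test(rnorm(18, 0.9, 0.05), rnorm(18, 0.3, 0.05))
  expect_false(up$memory); expect_equal(up$flag, "increase")
})

test_that("a 50% courtship reduction is detected at the conventional n", {
  set.seed(47)
  hits <- 0L
  for (i in 1:200) {
    sham <- rnorm(18, 0.6, 0.15)
    test <- rnorm(18, 0.3, 0.15)
    if (memory_test(test, sham)$memory) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})
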