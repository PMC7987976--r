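# screen_simulator: transduction, aliquot sampling, bottleneck, outgrowth,
# sequencing, and whole-screen bookkeeping.

test_that("transduction follows the Poisson zero-class", {
  lib <- tiny_library()
  zero <- assign_guides_by_transduction(1e5, 0, lib, seed = 1)
  expect_true(all(zero == 0))

  counts <- assign_guides_by_transduction(1e6, 0.3, lib, seed = 1)
  frac <- sum(counts) / 1e6
  p <- 1 - exp(-0.3)
  expect_lt(abs(frac - p), 5 * sqrt(p * (1 - p) / 1e6))

  single <- guide_library(data.frame(guide_id = "g1", gene = "G1",
                                     protospacer = "ACGTACGTACGT",
                                     is_control = FALSE))
  one <- assign_guides_by_transduction(1000, 0.3, single, seed = 1)
  expect_equal(sum(one), unname(one["g1"]))
  expect_error(assign_guides_by_transduction(10, 0.3, tiny_library(0, 1, 0)),
               "empty library")
})

test_that("control aliquots are exact without-replacement draws", {
  pool <- stats::setNames(rep(1000L, 11225), sprintf("g%05d", 1:11225))
  # exhaustive draw returns the pool itself
  all_of_it <- sample_control_aliquot(pool, sum(pool), seed = 1)
  expect_identical(unname(all_of_it), unname(as.integer(pool)))
  expect_true(all(sample_control_aliquot(pool, 0, seed = 1) == 0))
  expect_error(sample_control_aliquot(pool, sum(pool) + 1, seed = 1),
               "cannot draw")

  draw <- sample_control_aliquot(pool, 5.5e6, seed = 2)
  expect_equal(sum(draw), 5.5e6)
  # per-guide mean 490; hypergeometric sd ~ 15.8, allow 5 sd
  m <- 5.5e6 * 1000 / sum(pool)
  v <- 5.5e6 * (1000 / sum(pool)) * (1 - 1000 / sum(pool)) *
    (sum(pool) - 5.5e6) / (sum(pool) - 1)
  expect_lt(max(abs(draw - m)), 5.5 * sqrt(v))
})

test_that("simulate_mouse: bottleneck edge cases and proportionality", {
  lib <- tiny_library(40, 5, 10, 12)
  ids <- lib$guides$guide_id
  pool <- stats::setNames(rep(500L, length(ids)), ids)
  design <- screen_design(n_mice_per_group = 1, dose_cells = 20000,
                          read_depth = 2e5, growth_days = 0,
                          control_replicates = c(cells_500x_a = 1000,
                                                 cells_500x_b = 1000))

  sel0 <- selection_profile(lib, survival_prob = 0)
  res0 <- simulate_mouse(pool, design, sel0, "t19d", seed = 3)
  expect_identical(res0$founders, character())
  expect_true(all(res0$counts == 0))

  # p = 1, days = 0, dispersion = 0: reads multinomial on the dose
  sel1 <- selection_profile(lib, survival_prob = 1, dispersion = 0)
  res1 <- simulate_mouse(pool, design, sel1, "t19d", seed = 3)
  expect_equal(sum(res1$counts), design$read_depth)
  expect_setequal(res1$founders, ids)
  # counts ~ read_depth * dose_i / dose_total: combine the multinomial read
  # variance with the (scaled) hypergeometric dose variance
  expected <- design$read_depth / length(ids)
  m <- 20000 / length(ids)
  N <- sum(pool)
  v_dose <- 20000 * (500 / N) * (1 - 500 / N) * (N - 20000) / (N - 1)
  v <- expected * (1 - 1 / length(ids)) + (design$read_depth / 20000)^2 * v_dose
  expect_lt(max(abs(res1$counts - expected)), 6 * sqrt(v))
})

test_that("founder sets are nested in the survival probability", {
  lib <- tiny_library(40, 5, 10, 12)
  pool <- stats::setNames(rep(500L, nrow(lib$guides)), lib$guides$guide_id)
  design <- screen_design(n_mice_per_group = 1, dose_cells = 20000,
                          read_depth = 1e4,
                          control_replicates = c(a = 1000, b = 1000))
  lo <- simulate_mouse(pool, design, selection_profile(lib, survival_prob = 0.002),
                       "t4h", seed = 9)
  hi <- simulate_mouse(pool, design, selection_profile(lib, survival_prob = 0.006),
                       "t4h", seed = 9)
  expect_true(all(lo$founders %in% hi$founders))
  expect_true(all(lo$n_founders <= hi$n_founders))
})

test_that("per-mouse representation matches the Poisson-thinning closed form", {
  lib <- build_synthetic_library(2195, 5, 250, 20, seed = 2)
  frac <- simulate_representation(40, lib, seed = 4)
  lambda <- 550000 / 11225
  p <- -log(0.8) / 49
  closed <- 1 - exp(-lambda * p)
  expect_lt(abs(mean(frac) - closed), 3 * sd(frac) / sqrt(length(frac)))
})

test_that("simulate_screen bookkeeping, read conservation and determinism", {
  fx <- small_screen()
  cm <- fx$sim$counts
  samples <- cm$samples
  expect_equal(sum(samples$group == "cells_500x"), 2)
  expect_equal(sum(samples$group == "lung_4h"), 6)
  expect_equal(sum(samples$group == "lung_19d"), 6)
  # read conservation: columns sum to read_depth whenever founders exist
  totals <- colSums(cm$counts)
  lungs <- samples$sample_id[samples$group != "cells_500x"]
  for (s in lungs) {
    if (length(fx$sim$truth$founders[[s]])) {
      expect_equal(unname(totals[s]), fx$design$read_depth)
    } else {
      expect_equal(unname(totals[s]), 0)
    }
  }
  expect_true(all(totals[samples$group == "cells_500x"] == fx$design$read_depth))
  # truth founder sets are library guides
  expect_true(all(unlist(fx$sim$truth$founders) %in% rownames(cm$counts)))
  # byte-identical rerun
  again <- simulate_screen(fx$design, fx$sel, fx$lib, seed = 42)
  expect_identical(again$counts$counts, cm$counts)
  expect_identical(again$sample_sheet, fx$sim$sample_sheet)
  expect_identical(again$truth, fx$sim$truth)
})

test_that("cohort mode emits per-cohort controls and mice", {
  lib <- tiny_library(10, 3, 5, 12)
  design <- screen_design(dose_cells = 2000, read_depth = 2e4,
                          cohorts = c(A = 2, B = 2, C = 3),
                          controls_per_cohort = 3, control_cells = 20000,
                          n_cells_transduced = 2e5, n_cells_expanded = 5e5)
  sim <- simulate_screen(design, selection_profile(lib, survival_prob = 0.05),
                         lib, seed = 6)
  grp <- sim$sample_sheet$group
  expect_equal(sum(grp == "cells_500x"), 9)
  expect_equal(sum(grp %in% c("A", "B", "C")), 7)
  expect_equal(ncol(sim$counts$counts), 16)
})

test_that("selection sanity and null calibration of recurrence", {
  # planted guides' mean late count share exceeds the NTC share
  fx <- small_screen(hit_genes = c("gene0003", "gene0007"), beta = 0.5)
  cm <- fx$sim$counts
  late <- cm$samples$sample_id[cm$samples$group == "lung_19d"]
  shares <- sweep(cm$counts[, late, drop = FALSE], 2,
                  colSums(cm$counts[, late, drop = FALSE]), "/")
  planted <- cm$gene %in% c("gene0003", "gene0007")
  ntc <- cm$gene == "NTC"
  expect_gt(mean(shares[planted, ]), mean(shares[ntc, ]))

  # no planted effects: recurrence of targeting guides indistinguishable
  # from NTC recurrence
  lib <- build_synthetic_library(200, 5, 100, 14, seed = 21)
  design <- screen_design(n_mice_per_group = 8, dose_cells = 20000,
                          control_replicates = c(cells_500x_a = 1e5,
                                                 cells_500x_b = 1e5),
                          read_depth = 2e5, n_cells_transduced = 1e6,
                          n_cells_expanded = 5e6)
  sel <- selection_profile(lib, survival_prob = 0.02)
  sim <- simulate_screen(design, sel, lib, seed = 31)
  cmn <- drop_absent_guides(total_normalize(
    filter_by_control_minimum(sim$counts, c("cells_500x_a", "cells_500x_b"),
                              min_reads = 1)))
  zm <- compute_zscores(cmn, compute_group_stats(cmn))
  sets <- percentile_sets(zm)
  late <- cmn$samples$sample_id[cmn$samples$group == "lung_19d"]
  ht <- recurrence(sets[late], zm, cmn$gene, 2)
  rec <- stats::setNames(rep(0L, nrow(cmn$counts)), rownames(cmn$counts))
  rec[ht$guides$guide_id] <- ht$guides$n_samples
  is_ntc <- cmn$gene[names(rec)] == "NTC"
  wt <- suppressWarnings(stats::wilcox.test(rec[!is_ntc], rec[is_ntc]))
  expect_gt(wt$p.value, 0.01)
})
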