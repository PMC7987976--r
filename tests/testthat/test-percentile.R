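# percentile_hits: group statistics, z-scores, nearest-rank percentile sets,
# recurrence.

stats_matrix <- function(values, groups) {
  m <- matrix(values, nrow = 1, dimnames = list("g1", names(groups)))
  count_matrix(m, c(g1 = "G1"),
               data.frame(sample_id = names(groups), group = unname(groups)),
               normalized = TRUE)
}

test_that("group statistics follow the SEM = sd/sqrt(group count) definition", {
  cm <- stats_matrix(c(80, 120), c(a1 = "t19d", a2 = "t19d"))
  st <- compute_group_stats(cm)$groups$t19d
  expect_equal(unname(st$mean), 100)
  expect_equal(unname(st$sd), sqrt(800))
  expect_equal(unname(st$k), 2)
  expect_equal(unname(st$sem), sqrt(800) / sqrt(2))

  # zeros count toward the moments but not the group count (p1)
  cm2 <- stats_matrix(c(0, 0, 0, 10, 10),
                      stats::setNames(rep("t19d", 5), paste0("s", 1:5)))
  st2 <- compute_group_stats(cm2)$groups$t19d
  expect_equal(unname(st2$k), 2)
  expect_equal(unname(st2$mean), 4)
  expect_equal(unname(st2$sd), sqrt(30))
  expect_equal(unname(st2$sem), sqrt(30) / sqrt(2))

  # present-only alternative
  st3 <- compute_group_stats(cm2, present_only = TRUE)$groups$t19d
  expect_equal(unname(st3$mean), 10)
  expect_equal(unname(st3$sd), 0)

  # degenerate: identical values
  cm4 <- stats_matrix(c(7, 7), c(a = "t19d", b = "t19d"))
  st4 <- compute_group_stats(cm4)$groups$t19d
  expect_equal(unname(st4$sd), 0)
  expect_equal(unname(st4$sem), 0)

  expect_error(compute_group_stats(stats_matrix(5, c(only = "t19d"))),
               "fewer than 2")
})

test_that("z-scores centre on the control mean and mask degenerate entries", {
  m <- rbind(g1 = c(100, 100, 100, 130), g2 = c(50, 50, 8, 8))
  colnames(m) <- c("c1", "c2", "l1", "l2")
  cm <- count_matrix(m, stats::setNames(c("G1", "G2"), rownames(m)),
                     data.frame(sample_id = colnames(m),
                                group = c("cells_500x", "cells_500x",
                                          "lung_19d", "lung_19d")),
                     normalized = TRUE)
  st <- compute_group_stats(cm)
  zm <- compute_zscores(cm, st)
  # g1: ctrl mean 100; 19d sem = sd(c(100,130))/sqrt(2)
  sem1 <- sd(c(100, 130)) / sqrt(2)
  expect_equal(zm$z["g1", "l1"], (100 - 100) / sem1)
  expect_equal(zm$z["g1", "l2"], (130 - 100) / sem1)
  # g2: identical lung values -> sem 0 -> masked, never infinite
  expect_true(all(is.na(zm$z["g2", ])))
  expect_error(compute_zscores(cm, st, control = "nope"), "not present")
})

test_that("z-scores match the brute-force oracle on random matrices", {
  groups <- list(cells_500x = c("ctrl_1", "ctrl_2"),
                 lung_4h = paste0("l4_", 1:3),
                 lung_19d = paste0("l19_", 1:3))
  for (i in 1:5) {
    cm <- random_count_matrix(seed = 900 + i, normalized = TRUE)
    zm <- compute_zscores(cm, compute_group_stats(cm))
    oracle <- bf_zscores(cm$counts, groups, "cells_500x")
    expect_identical(is.na(zm$z), is.na(oracle[, colnames(zm$z)]))
    d <- abs(zm$z - oracle[, colnames(zm$z)])
    expect_lt(max(d / pmax(abs(oracle[, colnames(zm$z)]), 1), na.rm = TRUE), 1e-12)
  }
})

test_that("percentile sets use the nearest-rank definition", {
  z <- matrix(1:100, 100, 1, dimnames = list(sprintf("g%03d", 1:100), "s1"))
  zm <- structure(list(z = z, control = "cells_500x",
                       group = c(s1 = "lung_19d")), class = "z_matrix")
  expect_setequal(percentile_sets(zm, 98)$s1, c("g098", "g099", "g100"))

  # all ties -> everyone is a member
  z2 <- matrix(5, 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  zm2 <- structure(list(z = z2, control = "cells_500x",
                        group = c(s1 = "lung_19d")), class = "z_matrix")
  expect_length(percentile_sets(zm2, 98)$s1, 10)

  # single defined guide is the set; all-NA sample warns and is empty
  z3 <- matrix(c(3, NA), 2, 1, dimnames = list(c("a", "b"), "s1"))
  zm3 <- structure(list(z = z3, control = "cells_500x",
                        group = c(s1 = "lung_19d")), class = "z_matrix")
  expect_identical(percentile_sets(zm3, 98)$s1, "a")
  z4 <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "s1"))
  zm4 <- structure(list(z = z4, control = "cells_500x",
                        group = c(s1 = "lung_19d")), class = "z_matrix")
  expect_warning(out <- percentile_sets(zm4, 98), "no defined")
  expect_length(out$s1, 0)

  # |set| = m - ceiling(pct/100 * m) + 1 for distinct values
  set.seed(1)
  for (i in 1:10) {
    m <- sample(5:400, 1)
    pct <- runif(1, 50, 99)
    zi <- matrix(sample(seq_len(10 * m), m), m, 1,
                 dimnames = list(paste0("g", 1:m), "s1"))
    zmi <- structure(list(z = zi, control = "cells_500x",
                          group = c(s1 = "lung_19d")), class = "z_matrix")
    expect_length(percentile_sets(zmi, pct)$s1,
                  m - ceiling(pct / 100 * m) + 1)
  }
})

test_that("recurrence counts, ordering, and permutation invariance", {
  z <- matrix(c(9, 5, 1,
                8, NA, 2,
                7, NA, 1), 3, 3, byrow = FALSE,
              dimnames = list(c("gA_1", "gB_1", "NTC_1"),
                              c("s1", "s2", "s3")))
  zm <- structure(list(z = z, control = "cells_500x",
                       group = stats::setNames(rep("lung_19d", 3),
                                               colnames(z))), class = "z_matrix")
  gene <- c(gA_1 = "gA", gB_1 = "gB", NTC_1 = "NTC")
  sets <- list(s1 = c("gA_1", "gB_1"), s2 = c("gA_1"), s3 = c("gA_1", "NTC_1"))
  ht <- recurrence(sets, zm, gene, min_samples = 2)
  expect_equal(ht$guides$n_samples[ht$guides$guide_id == "gA_1"], 3)
  expect_equal(ht$guides$max_z[ht$guides$guide_id == "gA_1"], 9)
  expect_identical(ht$guides$guide_id[1], "gA_1")
  expect_identical(ht$guides$hit, c(TRUE, FALSE, FALSE))
  expect_equal(ht$genes$best_recurrence[ht$genes$gene == "gA"], 3)

  perm <- recurrence(sets[c(3, 1, 2)], zm, gene, min_samples = 2)
  expect_identical(perm$guides, ht$guides)

  none <- recurrence(list(s1 = "gA_1", s2 = "gB_1"), zm, gene, min_samples = 2)
  expect_false(any(none$guides$hit))
})

test_that("planted genes surface in the hit list of a selective screen", {
  fx <- small_screen(hit_genes = c("gene0003", "gene0007"), seed = 42)
  cm <- fx$sim$counts
  cmn <- drop_absent_guides(total_normalize(
    filter_by_control_minimum(cm, c("cells_500x_a", "cells_500x_b"),
                              min_reads = 5)))
  zm <- compute_zscores(cmn, compute_group_stats(cmn))
  sets <- percentile_sets(zm, 90)
  late <- cmn$samples$sample_id[cmn$samples$group == "lung_19d"]
  ht <- recurrence(sets[late], zm, cmn$gene, 2)
  hit_genes <- unique(ht$guides$gene[ht$guides$hit])
  expect_true(all(c("gene0003", "gene0007") %in% hit_genes))
  expect_true(ht$genes$gene[1] %in% c("gene0003", "gene0007"))
})
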