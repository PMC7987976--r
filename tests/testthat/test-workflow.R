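# workflow_qc: representation / enrichment reports and the end-to-end
# pipeline (all three entry points).

test_that("representation fractions and union coverage", {
  lib <- tiny_library(4, 2, 2, 12)
  ids <- lib$guides$guide_id
  m <- cbind(full = rep(5L, 10), empty = rep(0L, 10),
             half = c(rep(3L, 5), rep(0L, 5)))
  rownames(m) <- ids
  cm <- count_matrix(m, stats::setNames(lib$guides$gene, ids),
                     data.frame(sample_id = colnames(m),
                                group = c("lung_19d", "lung_19d", "lung_19d")))
  rep <- representation_fraction(cm, lib)
  fr <- stats::setNames(rep$per_sample$fraction, rep$per_sample$sample_id)
  expect_equal(unname(fr[c("full", "empty", "half")]), c(1, 0, 0.5))
  expect_equal(rep$per_group$union_fraction, 1)
  expect_true(all(rep$per_group$union_fraction >=
                    max(rep$per_sample$fraction)))
  expect_error(representation_fraction(cm, tiny_library(0, 1, 0)), "empty")
})

test_that("bottlenecked lungs sit far below control representation", {
  fx <- small_screen(survival_prob = 0.01)
  rep <- representation_fraction(fx$sim$counts, fx$lib)
  pg <- rep$per_group
  ctrl <- pg$mean_fraction[pg$group == "cells_500x"]
  lungs <- pg$mean_fraction[pg$group != "cells_500x"]
  expect_gt(ctrl, 0.99)
  expect_true(all(lungs < ctrl))
})

test_that("top-k abundance share flags clonal enrichment", {
  m <- cbind(uniform = rep(10L, 20),
             clonal = c(9900L, rep(5L, 19)))
  rownames(m) <- paste0("g", 1:20)
  cm <- count_matrix(m, stats::setNames(paste0("G", 1:20), rownames(m)),
                     data.frame(sample_id = colnames(m),
                                group = c("lung_4h", "lung_19d")))
  ep <- enrichment_profile(cm, k = 4)
  sh <- stats::setNames(ep$per_sample$top_k_share, ep$per_sample$sample_id)
  expect_equal(unname(sh["uniform"]), 4 / 20)
  expect_gte(unname(sh["clonal"]), 0.99)
  expect_equal(enrichment_profile(cm, k = 100)$per_sample$top_k_share[1], 1)

  fx <- small_screen()
  eps <- enrichment_profile(fx$sim$counts, k = 10)$per_group
  expect_gt(eps$mean_share[eps$group == "lung_19d"],
            eps$mean_share[eps$group == "lung_4h"])
})

pipeline_config <- function(seed = 5, outdir = NULL) {
  lib <- build_synthetic_library(20, 5, 10, 20, seed = 3)
  list(
    seed = seed, outdir = outdir, library = lib,
    simulate = list(
      design = list(n_mice_per_group = 6, dose_cells = 5000,
                    control_replicates = c(cells_500x_a = 50000,
                                           cells_500x_b = 50000),
                    read_depth = 1e5, n_cells_transduced = 5e5,
                    n_cells_expanded = 1e6),
      profile = list(hit_genes = c("gene0003", "gene0007"),
                     survival_prob = 0.05)
    ),
    min_reads = 5, pct = 90, top_n = 5
  )
}

test_that("pipeline recovers a planted hit in both methods and concords", {
  out1 <- withr::local_tempdir()
  bundle <- suppressMessages(run_pipeline(pipeline_config(outdir = out1)))
  expect_s3_class(bundle, "screen_report")
  # dimension bookkeeping
  expect_lte(nrow(bundle$counts_processed$counts),
             nrow(bundle$counts_raw$counts))
  expect_equal(ncol(bundle$counts_raw$counts), 14)
  # planted genes in both top lists and hence in the concordance section
  hit_genes <- unique(bundle$hits$guides$gene[bundle$hits$guides$hit])
  expect_true(all(c("gene0003", "gene0007") %in% hit_genes))
  expect_true(all(c("gene0003", "gene0007") %in%
                    utils::head(bundle$gene_ranking$gene, 5)))
  expect_true(all(c("gene0003", "gene0007") %in% bundle$concordance))
  # artifacts written
  expect_true(all(file.exists(file.path(
    out1, c("report.json", "report.md", "hits_guides.tsv", "hits_genes.tsv",
            "gene_ranking.tsv", "counts_processed.tsv", "zscores.tsv")))))
  # rerun is byte-identical
  out2 <- withr::local_tempdir()
  suppressMessages(run_pipeline(pipeline_config(outdir = out2)))
  for (f in c("report.json", "counts_raw.tsv", "hits_guides.tsv",
              "gene_ranking.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("counts-TSV and FASTQ entry points agree with the simulator", {
  cfg <- pipeline_config()
  bundle <- suppressMessages(run_pipeline(cfg))
  lib <- cfg$library
  sheet <- bundle$sample_sheet

  counts_path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(bundle$counts_raw, counts_path)
  cfg_counts <- cfg
  cfg_counts$counts <- counts_path
  cfg_counts$sample_sheet <- sheet
  b2 <- suppressMessages(run_pipeline(cfg_counts))
  expect_equal(b2$counts_raw$counts, bundle$counts_raw$counts)
  expect_identical(b2$hits$guides, bundle$hits$guides)

  # FASTQ entry point on simulator-generated reads: downscale depth so the
  # FASTQ stays small, then demand exact equality of the two paths
  small_cfg <- pipeline_config()
  small_cfg$simulate$design$read_depth <- 5000
  b3 <- suppressMessages(run_pipeline(small_cfg))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_screen_fastq(b3$counts_raw, lib, b3$sample_sheet, fq, seed = 2)
  cfg_fq <- small_cfg
  cfg_fq$fastq <- fq
  cfg_fq$sample_sheet <- b3$sample_sheet
  b4 <- suppressMessages(run_pipeline(cfg_fq))
  expect_equal(b4$counts_raw$counts[rownames(b3$counts_raw$counts),
                                    colnames(b3$counts_raw$counts)],
               b3$counts_raw$counts)
  expect_identical(b4$hits$guides, b3$hits$guides)
})

test_that("pipeline accepts a JSON config file", {
  cfg <- list(seed = 2,
              simulate = list(design = list(
                n_mice_per_group = 3, dose_cells = 2000,
                control_replicates = c(cells_500x_a = 20000,
                                       cells_500x_b = 20000),
                read_depth = 2e4, n_cells_transduced = 2e5,
                n_cells_expanded = 5e5),
                profile = list(survival_prob = 0.05)),
              library = NULL, min_reads = 2, pct = 90)
  # library built from seed; keep it tiny via a library path instead
  lib <- build_synthetic_library(8, 3, 4, 14, seed = 4)
  lib_path <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, lib_path)
  cfg$library <- lib_path
  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  bundle <- suppressMessages(run_pipeline(cfg_path))
  expect_s3_class(bundle, "screen_report")
  expect_equal(nrow(bundle$counts_raw$counts), 28)
})
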