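# End-to-end orchestration: entry points (simulate | counts TSV | FASTQ),
# count hygiene, both hit callers, QC, and the cross-method concordance
# report.

default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = NULL,
    library = NULL,          # path to a library table, a guide_library, or NULL
    counts = NULL,           # count matrix TSV entry point
    sample_sheet = NULL,     # path or data.frame (required for counts/fastq)
    fastq = NULL,            # FASTQ path(s) entry point
    barcode_start = 1,
    spacer_start = 9,
    simulate = NULL,         # list(design = ..., profile = ...) or TRUE
    min_reads = 30,
    pct = 98,
    min_samples = 2,
    alpha = 0.5,
    control_group = "cells_500x",
    top_n = 10,
    qc_min_reads = 1,
    top_k = 10
  )
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full screen-analysis pipeline
#'
#' Resolves the guide library and a raw count matrix (from, in order of
#' precedence: a counts TSV, FASTQ input, or the simulator), then applies the
#' canonical pipeline: control-minimum filter, total normalization, removal of
#' absent guides, percentile-rank hit calling, the joint effect model (when
#' both the early and late timepoints are present), representation/enrichment
#' QC, and a concordance section listing the genes top-ranked by both methods.
#' Deterministic given (config, seed). With \code{outdir} set, all tables plus
#' \code{report.json} and \code{report.md} are written.
#'
#' @param config named list overriding the defaults (see
#'   \code{crisprascreen:::default_pipeline_config()}), or the path to a JSON
#'   file holding one.
#' @return a report bundle (class \code{screen_report}): library, raw and
#'   processed matrices, group stats, z-matrix, percentile sets, hit table,
#'   joint fit and gene ranking (when applicable), QC reports, concordance,
#'   and the resolved config.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  seed <- cfg$seed

  # --- library ---------------------------------------------------------
  lib <- if (inherits(cfg$library, "guide_library")) {
    cfg$library
  } else if (is.character(cfg$library)) {
    read_library(cfg$library)
  } else {
    build_synthetic_library(seed = derive_seed(seed, 11))
  }
  ct <- library_counts(lib)
  log_stage("library", "%d guides (%d genes, %d controls)",
            ct$n_total, ct$n_genes, ct$n_control)

  sheet <- cfg$sample_sheet
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.data.frame(sheet)) sheet <- sample_sheet(sheet)

  # --- counts ----------------------------------------------------------
  truth <- NULL
  quant_summary <- NULL
  if (!is.null(cfg$counts)) {
    if (is.null(sheet)) stop("a sample sheet is required with the counts entry point",
                             call. = FALSE)
    cm_raw <- read_count_matrix(cfg$counts, samples = as.data.frame(sheet))
    log_stage("counts", "loaded %d x %d from %s",
              nrow(cm_raw$counts), ncol(cm_raw$counts), cfg$counts)
  } else if (!is.null(cfg$fastq)) {
    if (is.null(sheet)) stop("a sample sheet is required with the FASTQ entry point",
                             call. = FALSE)
    reads <- unlist(lapply(cfg$fastq, read_fastq_seqs))
    dmx <- demultiplex(reads, sheet, barcode_start = cfg$barcode_start)
    cols <- lapply(names(dmx$reads), function(sid)
      count_guides(dmx$reads[[sid]], lib, spacer_start = cfg$spacer_start,
                   sample_id = sid))
    quant_summary <- quantification_summary(cols)
    cm_raw <- merge_columns(cols, sheet, lib = lib)
    log_stage("quantify", "%d reads; %d unassigned at demultiplexing",
              length(reads), dmx$n_unassigned)
  } else {
    sim_cfg <- if (isTRUE(cfg$simulate) || is.null(cfg$simulate)) list() else cfg$simulate
    design <- if (inherits(sim_cfg$design, "screen_design")) sim_cfg$design else
      do.call(screen_design, sim_cfg$design %||% list())
    profile <- if (inherits(sim_cfg$profile, "selection_profile")) sim_cfg$profile else
      do.call(selection_profile, c(list(lib = lib), sim_cfg$profile %||% list()))
    sim <- simulate_screen(design, profile, lib, seed = derive_seed(seed, 13))
    cm_raw <- sim$counts
    sheet <- sim$sample_sheet
    truth <- sim$truth
    log_stage("simulate", "%d x %d simulated (%d planted hit gene(s))",
              nrow(cm_raw$counts), ncol(cm_raw$counts), length(truth$hit_genes))
  }

  # --- QC on raw counts ------------------------------------------------
  representation <- representation_fraction(cm_raw, lib, min_reads = cfg$qc_min_reads)
  enrichment <- enrichment_profile(cm_raw, k = cfg$top_k)

  # --- count hygiene: filter (raw) -> normalize -> drop absent ---------
  zero_tot <- colSums(cm_raw$counts) == 0
  if (any(zero_tot)) {
    warning("dropping zero-total sample(s): ",
            paste(colnames(cm_raw$counts)[zero_tot], collapse = ", "))
    keep <- !zero_tot
    cm_raw <- count_matrix(cm_raw$counts[, keep, drop = FALSE], cm_raw$gene,
                           cm_raw$samples[keep, , drop = FALSE])
  }
  control_ids <- cm_raw$samples$sample_id[cm_raw$samples$group == cfg$control_group]
  if (!length(control_ids)) {
    stop("no samples in control group \"", cfg$control_group, "\"", call. = FALSE)
  }
  cm_f <- filter_by_control_minimum(cm_raw, control_ids, min_reads = cfg$min_reads)
  log_stage("filter", "%d -> %d guides (removed %d below %d reads in a control)",
            nrow(cm_raw$counts), nrow(cm_f$counts),
            length(removed_guides(cm_f)), cfg$min_reads)
  cm_n <- total_normalize(cm_f)
  cm_n <- drop_absent_guides(cm_n)
  log_stage("normalize", "%d guides after dropping all-zero rows",
            nrow(cm_n$counts))

  # --- percentile method ----------------------------------------------
  stats <- compute_group_stats(cm_n)
  zm <- compute_zscores(cm_n, stats, control = cfg$control_group)
  sets <- percentile_sets(zm, pct = cfg$pct)
  groups_present <- unique(cm_n$samples$group)
  late_groups <- if ("lung_19d" %in% groups_present) "lung_19d" else
    setdiff(groups_present, c(cfg$control_group, "lung_4h"))
  late_ids <- cm_n$samples$sample_id[cm_n$samples$group %in% late_groups]
  hits <- recurrence(sets[intersect(names(sets), late_ids)], zm, cm_n$gene,
                     min_samples = cfg$min_samples)
  log_stage("percentile", "%d guides in any late-sample set; %d hits",
            nrow(hits$guides), sum(hits$guides$hit))

  # --- joint model (both timepoints required) --------------------------
  fit <- NULL
  ranking <- NULL
  if (all(c("lung_4h", "lung_19d") %in% groups_present)) {
    lfm <- compute_log_ratios(cm_n, control = cfg$control_group, alpha = cfg$alpha)
    fit <- fit_joint_model(lfm, lib, seed = derive_seed(seed, 17))
    ranking <- rank_genes(fit)
    log_stage("joint", "fit %s in %d iterations",
              if (fit$converged) "converged" else "did NOT converge",
              fit$iterations)
  } else {
    log_stage("joint", "skipped (needs both lung_4h and lung_19d groups)")
  }

  # --- concordance ------------------------------------------------------
  concordance <- NULL
  if (!is.null(ranking)) {
    top_pct <- utils::head(setdiff(hits$genes$gene, "NTC"), cfg$top_n)
    top_jnt <- utils::head(ranking$gene, cfg$top_n)
    concordance <- sort(intersect(top_pct, top_jnt))
    log_stage("concordance", "%d gene(s) in both top-%d lists: %s",
              length(concordance), cfg$top_n,
              paste(concordance, collapse = ", "))
  }

  bundle <- structure(
    list(library = lib, sample_sheet = sheet, counts_raw = cm_raw,
         counts_processed = cm_n, removed_by_filter = removed_guides(cm_f),
         group_stats = stats, z = zm, percentile_sets = sets, hits = hits,
         joint_fit = fit, gene_ranking = ranking,
         representation = representation, enrichment = enrichment,
         concordance = concordance, quantification = quant_summary,
         truth = truth, config = cfg),
    class = "screen_report"
  )
  if (!is.null(cfg$outdir)) write_report_bundle(bundle, cfg$outdir)
  bundle
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report\n")
  cat(sprintf("  guides: %d raw -> %d processed; samples: %d\n",
              nrow(x$counts_raw$counts), nrow(x$counts_processed$counts),
              ncol(x$counts_raw$counts)))
  cat(sprintf("  percentile hits (recurrence >= %d): %d\n",
              x$hits$min_samples, sum(x$hits$guides$hit)))
  if (!is.null(x$concordance)) {
    cat("  concordant top genes:", paste(x$concordance, collapse = ", "), "\n")
  }
  invisible(x)
}

write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_library(bundle$library, file.path(outdir, "library.csv"))
  write_count_matrix(bundle$counts_raw, file.path(outdir, "counts_raw.tsv"))
  write_count_matrix(bundle$counts_processed,
                     file.path(outdir, "counts_processed.tsv"))
  zdf <- data.frame(sgRNA = rownames(bundle$z$z), bundle$z$z,
                    check.names = FALSE)
  tsv(zdf, "zscores.tsv")
  sets_long <- data.frame(
    sample_id = rep(names(bundle$percentile_sets),
                    lengths(bundle$percentile_sets)),
    guide_id = unlist(bundle$percentile_sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(sets_long)) {
    sets_long$z <- bundle$z$z[cbind(sets_long$guide_id, sets_long$sample_id)]
  }
  tsv(sets_long, "percentile_sets.tsv")
  tsv(bundle$hits$guides, "hits_guides.tsv")
  tsv(bundle$hits$genes, "hits_genes.tsv")
  tsv(bundle$representation$per_sample, "representation_per_sample.tsv")
  tsv(bundle$representation$per_group, "representation_per_group.tsv")
  tsv(bundle$enrichment$per_sample, "enrichment_per_sample.tsv")
  if (!is.null(bundle$gene_ranking)) {
    tsv(as.data.frame(bundle$gene_ranking), "gene_ranking.tsv")
    guide_table <- data.frame(guide_id = names(bundle$joint_fit$x),
                              gene = unname(bundle$joint_fit$gene),
                              x = unname(bundle$joint_fit$x),
                              sd_x = unname(bundle$joint_fit$x_sd),
                              stringsAsFactors = FALSE)
    tsv(guide_table, "guide_efficacies.tsv")
  }
  if (!is.null(bundle$quantification)) tsv(bundle$quantification, "demux_summary.tsv")
  report <- list(
    n_guides_raw = nrow(bundle$counts_raw$counts),
    n_guides_processed = nrow(bundle$counts_processed$counts),
    n_samples = ncol(bundle$counts_raw$counts),
    n_removed_by_filter = length(bundle$removed_by_filter),
    n_hits = sum(bundle$hits$guides$hit),
    top_genes_percentile = utils::head(setdiff(bundle$hits$genes$gene, "NTC"),
                                       bundle$config$top_n),
    top_genes_joint = if (!is.null(bundle$gene_ranking))
      utils::head(bundle$gene_ranking$gene, bundle$config$top_n),
    concordance = bundle$concordance,
    joint_converged = if (!is.null(bundle$joint_fit)) bundle$joint_fit$converged,
    representation = bundle$representation$per_group,
    enrichment = bundle$enrichment$per_group,
    seed = bundle$config$seed
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  md <- c(
    "# Screen analysis report", "",
    sprintf("- guides: %d raw, %d after processing", report$n_guides_raw,
            report$n_guides_processed),
    sprintf("- samples: %d", report$n_samples),
    sprintf("- percentile hits (recurrence >= %d): %d",
            bundle$hits$min_samples, report$n_hits),
    sprintf("- top genes (percentile): %s",
            paste(report$top_genes_percentile, collapse = ", ")),
    if (!is.null(report$top_genes_joint))
      sprintf("- top genes (joint model): %s",
              paste(report$top_genes_joint, collapse = ", ")),
    if (!is.null(bundle$concordance))
      sprintf("- concordant genes (both methods, top %d): %s",
              bundle$config$top_n, paste(bundle$concordance, collapse = ", "))
  )
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}
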