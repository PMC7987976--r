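# Representation / bottleneck QC: detected library fraction per sample and
# group, union coverage across a cohort, and top-k abundance shares.

#' Library representation per sample and group
#'
#' Per sample: the fraction of library guides detected at \code{min_reads} or
#' more. Per group: mean and SD of the per-sample fractions and the cumulative
#' (union) fraction covered by any sample in the group. In a bottlenecked in
#' vivo screen, lung samples carry only a small fraction each while the union
#' over the cohort approaches 1.
#'
#' @param cm a \code{count_matrix} whose guides are a subset of \code{lib}.
#' @param lib the \code{guide_library} defining the denominator.
#' @param min_reads detection threshold (default 1 read).
#' @return object of class \code{representation_report}: list with
#'   \code{per_sample} (sample_id, group, fraction) and \code{per_group}
#'   (group, n_samples, mean_fraction, sd_fraction, union_fraction).
#' @export
representation_fraction <- function(cm, lib, min_reads = 1) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "guide_library"))
  n_lib <- nrow(lib$guides)
  if (n_lib == 0) stop("empty library", call. = FALSE)
  extra <- setdiff(rownames(cm$counts), lib$guides$guide_id)
  if (length(extra)) {
    stop("matrix contains guides absent from the library: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  det <- cm$counts >= min_reads
  per_sample <- data.frame(
    sample_id = colnames(cm$counts),
    group = cm$samples$group,
    fraction = colSums(det) / n_lib,
    stringsAsFactors = FALSE
  )
  rownames(per_sample) <- NULL
  groups <- split(per_sample$sample_id, per_sample$group)
  per_group <- data.frame(
    group = names(groups),
    n_samples = lengths(groups),
    mean_fraction = vapply(groups, function(ids)
      mean(per_sample$fraction[match(ids, per_sample$sample_id)]), numeric(1)),
    sd_fraction = vapply(groups, function(ids)
      stats::sd(per_sample$fraction[match(ids, per_sample$sample_id)]), numeric(1)),
    union_fraction = vapply(groups, function(ids)
      sum(rowSums(det[, ids, drop = FALSE]) > 0) / n_lib, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_group) <- NULL
  structure(list(per_sample = per_sample, per_group = per_group,
                 min_reads = min_reads),
            class = "representation_report")
}

#' @export
print.representation_report <- function(x, ...) {
  cat(sprintf("representation_report (detection >= %s read(s)):\n", x$min_reads))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Top-k abundance share per sample
#'
#' The share of each sample's reads carried by its k most abundant guides; a
#' high share in late samples relative to early ones indicates clonal
#' enrichment (positive selection). When \code{k} exceeds the number of guides
#' the share is 1 by definition; zero-total samples give NA.
#'
#' @param cm a \code{count_matrix} (raw or normalized).
#' @param k number of top guides.
#' @return list with \code{per_sample} (sample_id, group, top_k_share) and
#'   \code{per_group} (group, mean_share).
#' @export
enrichment_profile <- function(cm, k = 10) {
  stopifnot(inherits(cm, "count_matrix"), k >= 1)
  totals <- colSums(cm$counts)
  share <- vapply(seq_len(ncol(cm$counts)), function(j) {
    if (totals[j] == 0) return(NA_real_)
    v <- sort(cm$counts[, j], decreasing = TRUE)
    sum(v[seq_len(min(k, length(v)))]) / totals[j]
  }, numeric(1))
  per_sample <- data.frame(sample_id = colnames(cm$counts),
                           group = cm$samples$group,
                           top_k_share = share, stringsAsFactors = FALSE)
  groups <- split(per_sample$top_k_share, per_sample$group)
  per_group <- data.frame(group = names(groups),
                          mean_share = vapply(groups, mean, numeric(1)),
                          stringsAsFactors = FALSE)
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group, k = k)
}
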