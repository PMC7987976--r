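# Percentile-rank hit calling: per-guide group statistics, z-scores against
# the pre-injection cell controls, per-sample 98th-percentile membership, and
# cross-mouse recurrence.

#' Per-guide per-group summary statistics
#'
#' For every guide and sample group computes the mean and (n-1) standard
#' deviation over ALL samples in the group (zeros included), the group count
#' \code{k} (number of samples in which the guide is present, value > 0) and
#' the standard error of the mean \code{sem = sd / sqrt(k)}. \code{sem} is
#' undefined (NA) when \code{k = 0}; guides with zero spread are flagged
#' degenerate (\code{sem = 0}).
#'
#' Set \code{present_only = TRUE} to compute the moments over present samples
#' only (alternative reading; the group count is unchanged).
#'
#' @param cm normalized \code{count_matrix}.
#' @param groups named list group -> sample ids; defaults to splitting the
#'   matrix columns by the sample annotation \code{group}.
#' @param present_only compute mean/sd over positive values only.
#' @return object of class \code{group_stats}: per group a list with
#'   \code{mean}, \code{sd}, \code{k}, \code{sem} (named by guide).
#' @export
compute_group_stats <- function(cm, groups = NULL, present_only = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(groups)) {
    groups <- split(cm$samples$sample_id, cm$samples$group)
  }
  out <- list()
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    missing <- setdiff(ids, colnames(cm$counts))
    if (length(missing)) {
      stop("group ", gname, " references unknown sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    n <- length(ids)
    if (n < 2) {
      stop("group ", gname, " has fewer than 2 samples", call. = FALSE)
    }
    X <- cm$counts[, ids, drop = FALSE]
    k <- rowSums(X > 0)
    if (present_only) {
      pos <- X > 0
      s1 <- rowSums(X * pos)
      s2 <- rowSums(X^2 * pos)
      mu <- ifelse(k >= 1, s1 / k, NA_real_)
      sd <- ifelse(k >= 2, sqrt(pmax((s2 - k * mu^2) / (k - 1), 0)), NA_real_)
    } else {
      mu <- rowMeans(X)
      sd <- sqrt(pmax(rowSums((X - mu)^2) / (n - 1), 0))
    }
    sem <- ifelse(k >= 1 & !is.na(sd), sd / sqrt(k), NA_real_)
    out[[gname]] <- list(mean = mu, sd = sd, k = k, sem = sem, n_samples = n)
  }
  structure(list(groups = out, guide_ids = rownames(cm$counts),
                 present_only = present_only),
            class = "group_stats")
}

#' Per-guide per-sample z-scores against the control mean
#'
#' \code{z[g, s] = (value[g, s] - mean_control[g]) / sem[g, group(s)]}, for
#' every non-control sample \code{s}. Entries where the group SEM is zero or
#' undefined (group count 0, or a degenerate guide) are masked (NA) rather
#' than allowed to become infinite.
#'
#' @param cm normalized \code{count_matrix} (same matrix the stats came from).
#' @param stats a \code{group_stats} object containing the control group.
#' @param control control group label (default \code{"cells_500x"}).
#' @return object of class \code{z_matrix}: list with \code{z} (guides x
#'   non-control samples, NA-masked), \code{control}, and \code{group} (named
#'   group label per sample).
#' @export
compute_zscores <- function(cm, stats, control = "cells_500x") {
  stopifnot(inherits(cm, "count_matrix"), inherits(stats, "group_stats"))
  if (!control %in% names(stats$groups)) {
    stop("control group \"", control, "\" not present in stats", call. = FALSE)
  }
  if (!identical(stats$guide_ids, rownames(cm$counts))) {
    stop("stats were computed on a different guide set", call. = FALSE)
  }
  grp <- stats::setNames(cm$samples$group, cm$samples$sample_id)
  lung <- names(grp)[grp != control & grp %in% names(stats$groups)]
  if (!length(lung)) stop("no non-control samples with group statistics", call. = FALSE)
  mu_ctrl <- stats$groups[[control]]$mean
  z <- matrix(NA_real_, nrow(cm$counts), length(lung),
              dimnames = list(rownames(cm$counts), lung))
  for (s in lung) {
    st <- stats$groups[[grp[[s]]]]
    ok <- !is.na(st$sem) & st$sem > 0
    z[ok, s] <- (cm$counts[ok, s] - mu_ctrl[ok]) / st$sem[ok]
  }
  structure(list(z = z, control = control, group = grp[lung]),
            class = "z_matrix")
}

#' Per-sample percentile membership sets
#'
#' For each sample, ranks its defined z-scores and returns the guides at or
#' above the nearest-rank \code{pct}-th percentile (the smallest defined z
#' with at least \code{pct}\% of defined values <= it). Ties share membership.
#'
#' @param zm a \code{z_matrix}.
#' @param pct percentile in (0, 100); default 98.
#' @return named list sample_id -> character vector of member guide ids.
#' @export
percentile_sets <- function(zm, pct = 98) {
  stopifnot(inherits(zm, "z_matrix"), pct > 0, pct < 100)
  out <- stats::setNames(vector("list", ncol(zm$z)), colnames(zm$z))
  for (s in colnames(zm$z)) {
    v <- zm$z[, s]
    def <- !is.na(v)
    m <- sum(def)
    if (m == 0) {
      warning("sample ", s, " has no defined z-scores; empty percentile set")
      out[[s]] <- character()
    } else {
      sorted <- sort(v[def])
      threshold <- sorted[ceiling(pct / 100 * m)]
      out[[s]] <- names(v)[def & v >= threshold]
    }
  }
  out
}

#' Cross-sample recurrence of percentile membership
#'
#' Counts, for each guide, the number of samples whose percentile set contains
#' it; hits are guides recurring in at least \code{min_samples} samples
#' ("multiple mice"). Also aggregates per gene: the best guide recurrence and
#' the number of distinct guides of that gene ever appearing in any set.
#'
#' @param sets per-sample guide sets from \code{\link{percentile_sets}}
#'   (restricted by the caller to the samples of one timepoint, conventionally
#'   the late one).
#' @param zm the \code{z_matrix} the sets were derived from (for max z).
#' @param gene named character vector guide id -> gene symbol.
#' @param min_samples recurrence threshold defining a hit.
#' @return object of class \code{hit_table}: list with \code{guides} (columns
#'   guide_id, gene, n_samples, max_z, samples, hit), \code{genes} (gene,
#'   best_recurrence, n_guides_in_sets, max_z), \code{min_samples}. Both
#'   tables are sorted by (recurrence desc, max z desc, id).
#' @export
recurrence <- function(sets, zm, gene, min_samples = 2) {
  stopifnot(inherits(zm, "z_matrix"))
  long <- data.frame(
    sample_id = rep(names(sets), lengths(sets)),
    guide_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(long) == 0) {
    guides <- data.frame(guide_id = character(), gene = character(),
                         n_samples = integer(), max_z = numeric(),
                         samples = character(), hit = logical(),
                         stringsAsFactors = FALSE)
    genes <- data.frame(gene = character(), best_recurrence = integer(),
                        n_guides_in_sets = integer(), max_z = numeric(),
                        stringsAsFactors = FALSE)
    return(structure(list(guides = guides, genes = genes,
                          min_samples = min_samples), class = "hit_table"))
  }
  long$z <- zm$z[cbind(long$guide_id, long$sample_id)]
  split_g <- split(long, long$guide_id)
  guides <- data.frame(
    guide_id = names(split_g),
    gene = unname(gene[names(split_g)]),
    n_samples = vapply(split_g, nrow, integer(1)),
    max_z = vapply(split_g, function(d) max(d$z), numeric(1)),
    samples = vapply(split_g, function(d)
      paste(sort(d$sample_id), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  guides <- guides[order(-guides$n_samples, -guides$max_z, guides$guide_id), ,
                   drop = FALSE]
  guides$hit <- guides$n_samples >= min_samples
  rownames(guides) <- NULL
  split_gene <- split(guides, guides$gene)
  genes <- data.frame(
    gene = names(split_gene),
    best_recurrence = vapply(split_gene, function(d) max(d$n_samples), integer(1)),
    n_guides_in_sets = vapply(split_gene, nrow, integer(1)),
    max_z = vapply(split_gene, function(d) max(d$max_z), numeric(1)),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(-genes$best_recurrence, -genes$max_z, genes$gene), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(guides = guides, genes = genes, min_samples = min_samples),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  hits <- x$guides[x$guides$hit, , drop = FALSE]
  cat(sprintf("hit_table: %d guides in any percentile set; %d hits (recurrence >= %d)\n",
              nrow(x$guides), nrow(hits), x$min_samples))
  if (nrow(hits)) {
    print(utils::head(hits[c("guide_id", "gene", "n_samples", "max_z")], 10))
  }
  invisible(x)
}
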