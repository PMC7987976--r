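# CountMatrix container and the pre-analysis count hygiene:
# control-minimum filter -> total normalization -> drop absent guides
# (applied in exactly that order).

#' Construct a guide-by-sample count matrix
#'
#' @param counts numeric matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample ids); nonnegative.
#' @param gene character vector of gene symbols, named by guide id (or
#'   unnamed, aligned with the rows).
#' @param samples data.frame of sample annotations with at least
#'   \code{sample_id} and \code{group}; defaults to ungrouped samples.
#' @param normalized logical: raw integer counts (\code{FALSE}) or
#'   total-normalized reals.
#' @param size_factors per-sample divisors recorded by
#'   \code{\link{total_normalize}}.
#' @return object of class \code{count_matrix}: a list with fields
#'   \code{counts}, \code{gene}, \code{samples}, \code{normalized},
#'   \code{size_factors}.
#' @export
count_matrix <- function(counts, gene, samples = NULL, normalized = FALSE,
                         size_factors = NULL) {
  counts <- as.matrix(counts)
  # a zero-row matrix (everything filtered away) legitimately has no rownames
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      is.null(colnames(counts))) {
    stop("`counts` must have guide rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(names(gene))) {
    if (length(gene) != nrow(counts)) {
      stop("`gene` length does not match the number of guides", call. = FALSE)
    }
    names(gene) <- rownames(counts)
  }
  if (anyNA(match(rownames(counts), names(gene)))) {
    stop("some guides have no gene annotation", call. = FALSE)
  }
  gene <- gene[rownames(counts)]
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts), group = NA_character_,
                          stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("`samples` must have sample_id and group columns", call. = FALSE)
  }
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id)) {
    stop("`samples$sample_id` must match the matrix columns one-to-one", call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(counts = counts, gene = gene, samples = samples,
         normalized = isTRUE(normalized), size_factors = size_factors),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  grp <- table(x$samples$group, useNA = "ifany")
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname count_matrix
guide_ids <- function(cm) rownames(cm$counts)

#' @export
#' @rdname count_matrix
sample_ids <- function(cm) colnames(cm$counts)

subset_cm_guides <- function(cm, keep) {
  count_matrix(cm$counts[keep, , drop = FALSE], cm$gene[keep], cm$samples,
               normalized = cm$normalized, size_factors = cm$size_factors)
}

#' Guides removed by a filtering step
#'
#' Filtering operations attach the removed-guide list to their result as an
#' audit artifact; this accessor retrieves it.
#'
#' @param cm a filtered \code{count_matrix}.
#' @return character vector of removed guide ids (possibly empty).
#' @export
removed_guides <- function(cm) attr(cm, "removed_guides") %||% character()

#' Remove guides underrepresented in the control replicates
#'
#' A guide is removed iff its raw count is strictly below \code{min_reads} in
#' at least one of the named control samples (the pre-injection cell
#' aliquots). The default of 30 reads reproduces the screen's "fewer than 30
#' reads in either cell replicate" rule; counts of exactly 30 are retained.
#'
#' @param cm raw \code{count_matrix}.
#' @param control_ids sample ids of the control replicates.
#' @param min_reads strict lower bound.
#' @return the reduced \code{count_matrix}; the removed guide ids are attached
#'   and retrievable with \code{\link{removed_guides}}.
#' @export
filter_by_control_minimum <- function(cm, control_ids, min_reads = 30) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$normalized) stop("filter applies to raw counts only", call. = FALSE)
  if (!length(control_ids)) stop("`control_ids` must be non-empty", call. = FALSE)
  missing <- setdiff(control_ids, colnames(cm$counts))
  if (length(missing)) {
    stop("control sample(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- cm$counts[, control_ids, drop = FALSE]
  low <- rowSums(ctrl < min_reads) > 0
  out <- subset_cm_guides(cm, !low)
  attr(out, "removed_guides") <- rownames(cm$counts)[low]
  out
}

#' Total-count normalization
#'
#' Scales every sample to the mean raw column total (the MAGeCK "total"
#' method): normalized value = raw / size factor, with size factor =
#' column total / mean total. After normalization all column totals are equal.
#'
#' @param cm raw \code{count_matrix} with strictly positive column totals.
#' @return normalized \code{count_matrix} carrying its \code{size_factors}.
#' @export
total_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$normalized) stop("matrix is already normalized", call. = FALSE)
  totals <- colSums(cm$counts)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(cm$counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sf <- totals / mean(totals)
  count_matrix(sweep(cm$counts, 2, sf, "/"), cm$gene, cm$samples,
               normalized = TRUE, size_factors = sf)
}

#' Drop guides with no reads in any sample
#'
#' Applied after normalization: a guide is removed iff its value is zero in
#' every sample. Guides missing from some lungs but present elsewhere are
#' retained (they still inform the other samples' z-scores).
#'
#' @param cm \code{count_matrix}.
#' @return reduced matrix; removed ids via \code{\link{removed_guides}}.
#' @export
drop_absent_guides <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  absent <- rowSums(cm$counts > 0) == 0
  out <- subset_cm_guides(cm, !absent)
  attr(out, "removed_guides") <- rownames(cm$counts)[absent]
  out
}

#' Read a count matrix TSV
#'
#' Dialect: first column \code{sgRNA} (guide id), second \code{gene}, one
#' column per sample; tab-separated, gzip-transparent.
#'
#' @param path file path.
#' @param samples optional sample annotation data.frame (sample_id, group,
#'   ...); defaults to ungrouped.
#' @param normalized whether the stored values are normalized.
#' @return a \code{count_matrix}.
#' @export
read_count_matrix <- function(path, samples = NULL, normalized = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "sgRNA" || names(df)[2] != "gene") {
    stop("count matrix must start with columns sgRNA, gene", call. = FALSE)
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$sgRNA
  count_matrix(m, stats::setNames(df$gene, df$sgRNA), samples,
               normalized = normalized)
}

#' Write a count matrix TSV
#'
#' @param cm a \code{count_matrix}.
#' @param path output path (\code{.gz} writes gzip).
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(sgRNA = rownames(cm$counts), gene = unname(cm$gene),
                   cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}
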