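# Guide library data model: the catalogue of guides every other module
# references (guide_id, gene, protospacer, control flag).

required_library_columns <- c("guide_id", "gene", "protospacer", "is_control")

#' Construct a guide library
#'
#' A guide library is the catalogue of sgRNAs in a pooled CRISPRa screen:
#' targeting guides carry a gene symbol, non-targeting controls carry the
#' sentinel gene \code{"NTC"}. Protospacers are DNA strings of one fixed
#' length, unique within the library (exact-match quantification depends on
#' this), and are upper-cased on construction.
#'
#' @param guides data.frame with columns \code{guide_id}, \code{gene},
#'   \code{protospacer}, \code{is_control}.
#' @param protospacer_length declared spacer length; inferred from the first
#'   guide when \code{NULL}.
#' @return an object of class \code{guide_library}.
#' @export
guide_library <- function(guides, protospacer_length = NULL) {
  if (!is.data.frame(guides)) stop("`guides` must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(required_library_columns, names(guides))
  if (length(missing_cols)) {
    stop("library table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  guides <- guides[required_library_columns]
  guides$guide_id <- as.character(guides$guide_id)
  guides$gene <- as.character(guides$gene)
  guides$protospacer <- toupper(as.character(guides$protospacer))
  guides$is_control <- parse_flag(guides$is_control)
  rownames(guides) <- NULL
  if (is.null(protospacer_length)) {
    protospacer_length <- if (nrow(guides)) nchar(guides$protospacer[[1]]) else 20L
  }
  lib <- structure(
    list(guides = guides, protospacer_length = as.integer(protospacer_length)),
    class = "guide_library"
  )
  validate_guide_library(lib)
}

validate_guide_library <- function(lib) {
  g <- lib$guides
  if (nrow(g) == 0) return(lib)
  dup <- unique(g$guide_id[duplicated(g$guide_id)])
  if (length(dup)) {
    stop("duplicate guide_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGT]", g$protospacer)
  if (any(bad)) {
    stop("non-ACGT protospacer at row(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  len <- nchar(g$protospacer)
  if (any(len != lib$protospacer_length)) {
    stop("protospacer length inconsistent with declared length ",
         lib$protospacer_length, " at row(s): ",
         paste(which(len != lib$protospacer_length), collapse = ", "), call. = FALSE)
  }
  dup_sp <- unique(g$protospacer[duplicated(g$protospacer)])
  if (length(dup_sp)) {
    stop("duplicate protospacer(s): ", paste(dup_sp, collapse = ", "), call. = FALSE)
  }
  mismatch <- g$is_control != (g$gene == "NTC")
  if (any(mismatch)) {
    stop("is_control flag inconsistent with gene == \"NTC\" at row(s): ",
         paste(which(mismatch), collapse = ", "), call. = FALSE)
  }
  lib
}

#' Derived composition counts of a guide library
#'
#' @param lib a \code{guide_library}.
#' @return list with \code{n_total}, \code{n_targeting}, \code{n_control} and
#'   \code{n_genes} (distinct targeted genes, controls excluded).
#' @export
library_counts <- function(lib) {
  stopifnot(inherits(lib, "guide_library"))
  g <- lib$guides
  list(
    n_total = nrow(g),
    n_targeting = sum(!g$is_control),
    n_control = sum(g$is_control),
    n_genes = length(unique(g$gene[!g$is_control]))
  )
}

#' @export
print.guide_library <- function(x, ...) {
  ct <- library_counts(x)
  cat(sprintf(
    "guide_library: %d guides (%d targeting %d genes, %d non-targeting controls), %d-nt protospacers\n",
    ct$n_total, ct$n_targeting, ct$n_genes, ct$n_control, x$protospacer_length))
  invisible(x)
}

#' Generate a synthetic guide library
#'
#' Builds a library matching the layout of a subpooled CRISPRa library:
#' \code{n_genes} genes with \code{guides_per_gene} guides each (ids
#' \code{<gene>_g<j>}) plus \code{n_controls} non-targeting controls (ids
#' \code{NTC_<j>}, gene \code{"NTC"}). Protospacers are distinct random DNA
#' sequences; generation is seed-deterministic. The defaults reproduce the
#' m6 membrane-protein design: 2195 genes x 5 guides + 250 controls = 11,225.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per gene.
#' @param n_controls number of non-targeting control guides.
#' @param protospacer_length spacer length in nt (>= 8).
#' @param seed RNG seed.
#' @return a \code{guide_library} in canonical order (targeting guides sorted
#'   by gene then guide id, controls last).
#' @export
build_synthetic_library <- function(n_genes = 2195, guides_per_gene = 5,
                                    n_controls = 250, protospacer_length = 20,
                                    seed = 1) {
  stopifnot(n_genes >= 0, guides_per_gene >= 0, n_controls >= 0)
  if (protospacer_length < 8) {
    stop("protospacer_length must be >= 8", call. = FALSE)
  }
  n_targeting <- n_genes * guides_per_gene
  n_total <- n_targeting + n_controls
  if (4^protospacer_length < n_total) {
    stop("impossible uniqueness: 4^", protospacer_length, " < ", n_total, call. = FALSE)
  }
  width <- max(4L, nchar(as.character(max(n_genes, 1L))))
  genes <- sprintf(paste0("gene%0", width, "d"), seq_len(n_genes))
  gene_col <- c(rep(genes, each = guides_per_gene), rep("NTC", n_controls))
  id_col <- c(
    if (n_targeting) paste0(rep(genes, each = guides_per_gene), "_g",
                            rep(seq_len(guides_per_gene), times = n_genes)),
    if (n_controls) paste0("NTC_", seq_len(n_controls))
  )
  spacers <- with_seed(seed, random_dna(n_total, protospacer_length))
  guide_library(
    data.frame(
      guide_id = if (n_total) id_col else character(),
      gene = if (n_total) gene_col else character(),
      protospacer = spacers,
      is_control = if (n_total) gene_col == "NTC" else logical(),
      stringsAsFactors = FALSE
    ),
    protospacer_length = protospacer_length
  )
}

canonical_guide_order <- function(guides) {
  targ <- guides[!guides$is_control, , drop = FALSE]
  ctrl <- guides[guides$is_control, , drop = FALSE]
  targ <- targ[order(targ$gene, targ$guide_id), , drop = FALSE]
  ctrl <- ctrl[order(ctrl$guide_id), , drop = FALSE]
  out <- rbind(targ, ctrl)
  rownames(out) <- NULL
  out
}

#' Read a guide library table
#'
#' Accepts CSV or TSV (auto-detected from the header line) with the exact
#' header \code{guide_id,gene,protospacer,is_control}. Protospacers are
#' upper-cased; \code{is_control} accepts 0/1/true/false. Duplicate guide ids,
#' non-ACGT spacers (reported with their line number) and inconsistent spacer
#' lengths are rejected.
#'
#' @param path file path.
#' @return a \code{guide_library}.
#' @export
read_library <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty library file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df), required_library_columns)) {
    stop("library header must be exactly: ",
         paste(required_library_columns, collapse = ","),
         " (got: ", paste(names(df), collapse = ","), ")", call. = FALSE)
  }
  sp <- toupper(df$protospacer)
  bad <- grepl("[^ACGT]", sp)
  if (any(bad)) {
    stop("non-ACGT protospacer at line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  guide_library(df)
}

#' Write a guide library table
#'
#' Writes in canonical order (targeting guides by gene then id, controls
#' last), so output is byte-stable. The delimiter follows the file extension:
#' tab for \code{.tsv}, comma otherwise. \code{read_library()} round-trips the
#' result field-for-field.
#'
#' @param lib a \code{guide_library}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "guide_library"))
  g <- canonical_guide_order(lib$guides)
  g$is_control <- as.integer(g$is_control)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(g, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
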