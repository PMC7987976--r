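# Guide quantification from amplicon reads: barcode demultiplexing and
# exact-match protospacer counting, plus FASTQ generation for simulated
# screens (the round-trip oracle for the quantifier).

#' Construct / validate a sample sheet
#'
#' One record per sequencing sample: id, 8-mer demultiplexing barcode, group
#' label (e.g. \code{cells_500x}, \code{lung_4h}, \code{lung_19d}, or a cohort
#' label), optional mouse id and run. Barcodes must be exact 8-mer DNA and
#' unique within a run.
#'
#' @param x data.frame with columns \code{sample_id}, \code{barcode},
#'   \code{group} (optional \code{mouse_id}, \code{run}).
#' @return the validated data.frame (class \code{sample_sheet} prepended).
#' @export
sample_sheet <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample_id", "barcode", "group")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"mouse_id" %in% names(x)) x$mouse_id <- NA_character_
  if (!"run" %in% names(x)) x$run <- NA_character_
  x$sample_id <- as.character(x$sample_id)
  x$barcode <- toupper(as.character(x$barcode))
  x$group <- as.character(x$group)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(x$barcode) != 8) || any(grepl("[^ACGT]", x$barcode))) {
    stop("barcodes must be exact 8-mers over ACGT", call. = FALSE)
  }
  for (r in unique(x$run)) {
    b <- x$barcode[is.na(x$run) == is.na(r) & (is.na(r) | x$run == r)]
    if (anyDuplicated(b)) {
      stop("duplicate barcode within run ", ifelse(is.na(r), "<NA>", r), ": ",
           paste(unique(b[duplicated(b)]), collapse = ", "), call. = FALSE)
    }
  }
  if (!inherits(x, "sample_sheet")) class(x) <- c("sample_sheet", class(x))
  x
}

#' Read a sample sheet (CSV or TSV, auto-detected)
#' @param path file path.
#' @return a validated \code{sample_sheet}.
#' @export
read_sample_sheet <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  sample_sheet(utils::read.table(path, header = TRUE, sep = sep,
                                 colClasses = "character", check.names = FALSE,
                                 stringsAsFactors = FALSE))
}

read_fastq_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    as.character(Biostrings::readDNAStringSet(x, format = "fastq"))
  } else {
    as.character(x)
  }
}

#' Demultiplex reads by exact 8-mer barcode
#'
#' Routes each read to the unique sample whose barcode equals the read's
#' 8-mer at \code{barcode_start}. Matching is exact (no error correction);
#' reads with any mismatch, or too short to contain the barcode, are counted
#' as unassigned.
#'
#' @param fastq FASTQ(.gz) path or a character vector of read sequences.
#' @param sheet a \code{sample_sheet}; barcodes must be unique across it.
#' @param barcode_start 1-based position of the barcode in the read.
#' @return list with \code{reads} (named list sample_id -> character vector of
#'   full read sequences) and \code{n_unassigned}.
#' @export
demultiplex <- function(fastq, sheet, barcode_start = 1) {
  sheet <- sample_sheet(as.data.frame(sheet))
  if (anyDuplicated(sheet$barcode)) {
    stop("duplicate barcodes in sheet: ",
         paste(unique(sheet$barcode[duplicated(sheet$barcode)]), collapse = ", "),
         call. = FALSE)
  }
  reads <- read_fastq_seqs(fastq)
  bc <- substr(reads, barcode_start, barcode_start + 7L)
  m <- match(bc, sheet$barcode)
  out <- stats::setNames(vector("list", nrow(sheet)), sheet$sample_id)
  for (i in seq_len(nrow(sheet))) out[[i]] <- character()
  hit <- !is.na(m)
  if (any(hit)) {
    assigned <- split(reads[hit], sheet$sample_id[m[hit]])
    out[names(assigned)] <- assigned
  }
  list(reads = out, n_unassigned = sum(!hit))
}

#' Count guides by exact protospacer match
#'
#' Extracts the L-mer at \code{spacer_start} from each read (L = the library's
#' protospacer length) and looks it up in the protospacer-to-guide index.
#' Exact hits increment the guide; anything else (including reads too short
#' for the extraction window) increments \code{n_unmatched}. The accounting
#' identity \code{sum(counts) + n_unmatched == n_total_reads} always holds.
#'
#' @param reads FASTQ(.gz) path or character vector of read sequences.
#' @param lib a \code{guide_library} (unique protospacers enforced).
#' @param spacer_start 1-based position of the protospacer in the read.
#' @param sample_id optional id stored on the column.
#' @return object of class \code{count_column}: list with \code{sample_id},
#'   \code{counts} (named over all library guides), \code{n_unmatched},
#'   \code{n_total_reads}.
#' @export
count_guides <- function(reads, lib, spacer_start = 9, sample_id = NA_character_) {
  stopifnot(inherits(lib, "guide_library"))
  if (anyDuplicated(lib$guides$protospacer)) {
    stop("ambiguous index: duplicate protospacers in library", call. = FALSE)
  }
  reads <- read_fastq_seqs(reads)
  L <- lib$protospacer_length
  sp <- toupper(substr(reads, spacer_start, spacer_start + L - 1L))
  m <- match(sp, lib$guides$protospacer)
  hit <- !is.na(m) & nchar(sp) == L
  counts <- tabulate(m[hit], nbins = nrow(lib$guides))
  structure(
    list(sample_id = sample_id,
         counts = stats::setNames(as.integer(counts), lib$guides$guide_id),
         n_unmatched = length(reads) - sum(hit),
         n_total_reads = length(reads)),
    class = "count_column"
  )
}

#' Assemble count columns into a count matrix
#'
#' Columns sharing a \code{sample_id} are technical sequencing re-runs; by
#' default they are summed after a concordance check (Pearson r of
#' log2(count + 1) between the duplicates). Modes \code{keep_first} and
#' \code{keep_both} are provided for audit.
#'
#' @param columns list of \code{count_column} objects over the same library.
#' @param sheet a \code{sample_sheet} covering all column sample ids.
#' @param lib optional \code{guide_library} supplying gene annotations.
#' @param duplicate_mode how to treat re-runs of one sample id.
#' @return raw \code{count_matrix}; the duplicate concordance report (columns
#'   \code{sample_id}, \code{r}) is attached as attribute
#'   \code{"concordance"}.
#' @export
merge_columns <- function(columns, sheet, lib = NULL,
                          duplicate_mode = c("sum", "keep_first", "keep_both")) {
  duplicate_mode <- match.arg(duplicate_mode)
  sheet <- sample_sheet(as.data.frame(sheet))
  stopifnot(length(columns) > 0)
  ref <- names(columns[[1]]$counts)
  for (col in columns) {
    if (!inherits(col, "count_column") || !identical(names(col$counts), ref)) {
      stop("all columns must be count_column objects over the same library",
           call. = FALSE)
    }
  }
  ids <- vapply(columns, function(c) c$sample_id, character(1))
  unknown <- setdiff(ids, sheet$sample_id)
  if (length(unknown)) {
    stop("column sample id(s) absent from sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  concordance <- data.frame(sample_id = character(), r = numeric(),
                            stringsAsFactors = FALSE)
  for (sid in unique(ids[duplicated(ids)])) {
    reps <- columns[ids == sid]
    for (i in seq_len(length(reps) - 1)) {
      r <- stats::cor(log2(reps[[i]]$counts + 1), log2(reps[[i + 1]]$counts + 1))
      concordance <- rbind(concordance,
                           data.frame(sample_id = sid, r = r,
                                      stringsAsFactors = FALSE))
    }
  }
  if (duplicate_mode == "keep_both") {
    out_ids <- stats::ave(ids, ids, FUN = function(v) {
      if (length(v) > 1) paste0(v, "_", seq_along(v)) else v
    })
    mat <- vapply(columns, function(c) as.numeric(c$counts), numeric(length(ref)))
    colnames(mat) <- out_ids
    ann <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
    ann$sample_id <- out_ids
  } else {
    keep_ids <- unique(ids)
    mat <- vapply(keep_ids, function(sid) {
      reps <- columns[ids == sid]
      if (duplicate_mode == "keep_first") {
        as.numeric(reps[[1]]$counts)
      } else {
        rowSums(vapply(reps, function(c) as.numeric(c$counts),
                       numeric(length(ref))))
      }
    }, numeric(length(ref)))
    colnames(mat) <- keep_ids
    ann <- sheet[match(keep_ids, sheet$sample_id), , drop = FALSE]
  }
  rownames(mat) <- ref
  ann <- as.data.frame(ann)
  class(ann) <- "data.frame"
  gene <- if (!is.null(lib)) {
    stats::setNames(lib$guides$gene, lib$guides$guide_id)[ref]
  } else {
    stats::setNames(rep(NA_character_, length(ref)), ref)
  }
  out <- count_matrix(mat, gene, samples = ann, normalized = FALSE)
  attr(out, "concordance") <- concordance
  out
}

# Constant downstream of the protospacer in the amplicon (sgRNA scaffold
# homology arm); used to pad generated reads to the read length.
scaffold_constant <- "GTTTAAGAGCTAAGCTGGAAACAGCATAGCAAGTTTAAATAAGGCTAGTCCG"

#' Write a FASTQ file realising a count matrix
#'
#' Inverse of demultiplex + count: emits, for every sample and guide,
#' \code{count} reads laid out as \code{[8-mer barcode][protospacer][scaffold
#' padding]} truncated to \code{read_length}, shuffled across samples
#' (seeded), with constant quality. Used as the round-trip oracle for the
#' quantification path and to exercise the FASTQ entry point on simulated
#' screens.
#'
#' @param cm raw \code{count_matrix} (integer counts).
#' @param lib the \code{guide_library}.
#' @param sheet \code{sample_sheet} with barcodes for every sample in
#'   \code{cm}.
#' @param path output FASTQ path (\code{.gz} supported).
#' @param barcode_start,spacer_start 1-based read layout (defaults: barcode at
#'   1-8, protospacer from 9).
#' @param read_length total read length.
#' @param seed RNG seed for the read shuffle.
#' @return \code{path}, invisibly.
#' @export
write_screen_fastq <- function(cm, lib, sheet, path, barcode_start = 1,
                               spacer_start = 9, read_length = 50, seed = 1) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "guide_library"))
  sheet <- sample_sheet(as.data.frame(sheet))
  if (barcode_start != 1) {
    stop("read generation supports barcode_start = 1 only", call. = FALSE)
  }
  if (spacer_start < 9) stop("spacer_start must be >= 9 (after the barcode)", call. = FALSE)
  if (spacer_start + lib$protospacer_length - 1L > read_length) {
    stop("protospacer does not fit in the read at spacer_start ", spacer_start,
         call. = FALSE)
  }
  counts <- round(cm$counts)
  seqs <- character()
  pad <- paste(rep(scaffold_constant, 3), collapse = "")
  stuffer <- substr(pad, 1L, spacer_start - 9L)
  for (sid in colnames(counts)) {
    bc <- sheet$barcode[match(sid, sheet$sample_id)]
    if (is.na(bc)) stop("sample ", sid, " missing from sheet", call. = FALSE)
    nz <- counts[, sid] > 0
    if (!any(nz)) next
    template <- paste0(bc, stuffer,
                       lib$guides$protospacer[match(rownames(counts)[nz],
                                                    lib$guides$guide_id)])
    template <- substr(paste0(template, pad), 1L, read_length)
    seqs <- c(seqs, rep.int(template, counts[nz, sid]))
  }
  seqs <- with_seed(seed, sample(seqs))
  qual <- strrep("I", read_length)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    writeLines(paste0("@read_", seq_along(seqs), "\n", seqs, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Demultiplexing / quantification summary
#'
#' @param columns list of \code{count_column} objects.
#' @return data.frame with \code{sample_id}, \code{n_reads}, \code{n_matched},
#'   \code{n_unmatched}.
#' @export
quantification_summary <- function(columns) {
  data.frame(
    sample_id = vapply(columns, function(c) c$sample_id, character(1)),
    n_reads = vapply(columns, function(c) c$n_total_reads, numeric(1)),
    n_matched = vapply(columns, function(c) sum(c$counts), numeric(1)),
    n_unmatched = vapply(columns, function(c) c$n_unmatched, numeric(1)),
    stringsAsFactors = FALSE
  )
}
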