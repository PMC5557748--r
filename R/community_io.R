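# Readers/writers and validators for the standard study inputs:
# OTU count tables (TSV), aligned representative sequences (FASTA),
# pedigrees (CSV) and sample metadata (CSV).

VALID_BASES <- c("A", "C", "G", "T", "N", "-")

#' Validate an OTU count table
#'
#' A count table is a numeric matrix with OTUs in rows and samples in
#' columns (amplicon-pipeline convention), unique row and column names,
#' non-negative integral entries, and a positive total for every sample.
#'
#' @param counts Numeric matrix, OTUs x samples, with dimnames.
#' @return The validated matrix (storage mode double, integral values).
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_symh2("count table must be a numeric matrix (OTUs x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_symh2("count table must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop_symh2(sprintf("duplicate otu_id: %s",
                       paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                             collapse = ", ")))
  if (anyDuplicated(colnames(counts)))
    stop_symh2(sprintf("duplicate sample_id: %s",
                       paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                             collapse = ", ")))
  if (any(!is.finite(counts)) || any(counts < 0) || !is_wholenumber(counts))
    stop_symh2("count table entries must be non-negative integers")
  empty <- colSums(counts) == 0
  if (any(empty))
    stop_symh2(sprintf("sample(s) with zero total counts: %s",
                       paste(colnames(counts)[empty], collapse = ", ")))
  storage.mode(counts) <- "double"
  counts
}

#' Read an OTU count table from TSV
#'
#' Expects a tab-delimited file whose first column is `otu_id` and whose
#' remaining columns are per-sample integer counts; row and column order
#' are preserved.
#'
#' @param path Path to the TSV file.
#' @return Validated counts matrix (OTUs x samples).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "otu_id")
    stop_symh2("count table TSV must start with an 'otu_id' column followed by sample columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop_symh2("count table entries must be non-negative integers")
  rownames(m) <- ids
  validate_count_table(m)
}

#' Write an OTU count table to TSV
#'
#' @param counts Counts matrix (OTUs x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned OTU sequences from FASTA
#'
#' Sequences are uppercased and must be of equal length (an alignment),
#' over the alphabet `A C G T N -`; `.` gaps are rejected.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_aligned_seqs(seqs)
}

#' Validate a set of aligned sequences
#'
#' @param seqs Named character vector of nucleotide strings.
#' @return The validated, uppercased vector.
#' @export
validate_aligned_seqs <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_symh2("sequences must have unique names")
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    off <- names(seqs)[widths != widths[1L]]
    stop_symh2(sprintf("sequences are not aligned (unequal lengths): %s",
                       paste(off, collapse = ", ")))
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad <- setdiff(chars, VALID_BASES)
  if (length(bad))
    stop_symh2(sprintf("invalid character(s) in sequences: %s",
                       paste(bad, collapse = " ")))
  seqs
}

#' Write aligned sequences to FASTA
#'
#' @param seqs Named character vector of aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  seqs <- validate_aligned_seqs(seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Columns: `sample_id,individual_id,life_stage,group_id,cohort`, with
#' `life_stage` one of adult, juvenile, egg. If a count table and/or
#' pedigree are given, membership is cross-checked.
#'
#' @param path Path to metadata CSV.
#' @param counts Optional counts matrix; every `sample_id` must be a column.
#' @param ped Optional [pedigree()]; every `individual_id` must be present.
#' @return data.frame of metadata.
#' @export
read_sample_metadata <- function(path, counts = NULL, ped = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "life_stage", "group_id", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_symh2(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    stop_symh2("duplicate sample_id in metadata")
  if (!all(df$life_stage %in% c("adult", "juvenile", "egg")))
    stop_symh2("life_stage must be one of adult, juvenile, egg")
  if (!is.null(counts)) {
    miss <- setdiff(df$sample_id, colnames(counts))
    if (length(miss))
      stop_symh2(sprintf("metadata sample(s) absent from count table: %s",
                         paste(miss, collapse = ", ")))
  }
  if (!is.null(ped)) {
    miss <- setdiff(df$individual_id, ped$id)
    if (length(miss))
      stop_symh2(sprintf("metadata individual(s) absent from pedigree: %s",
                         paste(miss, collapse = ", ")))
  }
  df
}

#' Write sample metadata to CSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
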