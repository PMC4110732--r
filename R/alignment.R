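#' Read an aligned set of mitochondrial genomes
#'
#' Reads a multi-FASTA of pre-aligned full mitochondrial genomes (e.g. a
#' ClustalW or MAFFT alignment exported as FASTA) into an alignment object.
#' One record must be the reference genome (an rCRS-like sequence); the
#' reference row defines the coordinate system used for variant naming.
#' Columns where the reference carries a gap are insertion columns and are
#' mapped to "insertion after position p".
#'
#' @param fasta_path Path to a multi-FASTA file. Records may be line-wrapped.
#' @param reference_id Identifier of the reference record.
#' @return An object of class `"mt_alignment"`: a list with elements
#'   `ids`, `seqs` (named uppercase character vector, one string per record),
#'   `reference_id`, `ref_pos` (integer vector over alignment columns;
#'   1-based reference position, `NA` at insertion columns) and `ins_after`
#'   (integer vector; for insertion columns, the reference position the
#'   column follows, `NA` elsewhere).
#' @seealso [extract_variants()], [write_mt_alignment()]
#' @export
read_mt_alignment <- function(fasta_path, reference_id) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", fasta_path)
  }
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  mt_alignment(ids, seqs, reference_id)
}

#' Construct an alignment object from in-memory sequences
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of equal-length aligned sequences over
#'   `{A,C,G,T,N,-}`.
#' @param reference_id Identifier of the reference row.
#' @return An `"mt_alignment"` object; see [read_mt_alignment()].
#' @export
mt_alignment <- function(ids, seqs, reference_id) {
  seqs <- toupper(seqs)
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers in alignment")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(range(widths), collapse = "-"), ")")
  }
  if (!reference_id %in% ids) {
    stop("reference record '", reference_id, "' not found in alignment")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("sequences contain characters outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "))
  }
  ref_chars <- strsplit(seqs[[reference_id]], "", fixed = TRUE)[[1]]
  is_ref_base <- ref_chars != "-"
  ref_pos <- ifelse(is_ref_base, cumsum(is_ref_base), NA_integer_)
  # insertion columns follow the last reference base seen (0 = before start)
  ins_after <- ifelse(is_ref_base, NA_integer_, cumsum(is_ref_base))
  structure(
    list(ids = ids, seqs = seqs, reference_id = reference_id,
         ref_pos = as.integer(ref_pos), ins_after = as.integer(ins_after),
         reference_length = sum(is_ref_base)),
    class = "mt_alignment"
  )
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mtDNA alignment: ", length(x$ids), " sequences, ",
      nchar(x$seqs[[1]]), " columns, reference '", x$reference_id,
      "' (", x$reference_length, " bp)\n", sep = "")
  invisible(x)
}

#' Write an alignment to multi-FASTA
#'
#' @param aln An `"mt_alignment"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mt_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "mt_alignment"))
  set <- Biostrings::DNAStringSet(aln$seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Reference sequence of an alignment, gaps removed
#'
#' @param aln An `"mt_alignment"` object.
#' @return The ungapped reference sequence as a single string.
#' @export
reference_sequence <- function(aln) {
  gsub("-", "", aln$seqs[[aln$reference_id]], fixed = TRUE)
}
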