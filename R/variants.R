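## Variant extraction, canonical labelling and re-application.
##
## Coordinates are 1-based reference positions on a linear rCRS-like
## reference (variants are named on linear coordinates; no origin-spanning
## features). Indels are left-aligned within homopolymer context so that a
## haplotype's identity -- its set of variant labels -- is well defined.

#' Build the canonical label for a variant
#'
#' SNVs are labelled `m.<pos><ref>><alt>` (e.g. `m.263A>G`), deletions
#' `m.del<start>` or `m.del<start>-<end>`, insertions `m.<pos>ins<SEQ>`
#' (the inserted bases follow reference position `<pos>`).
#'
#' @param kind One of `"SNV"`, `"deletion"`, `"insertion"`.
#' @param start,end 1-based reference positions (closed interval; `end ==
#'   start` for SNVs; for insertions `start` is the base the insertion
#'   follows).
#' @param ref,alt Reference / alternate allele strings (empty where the
#'   kind implies it).
#' @return A single label string.
#' @export
variant_label <- function(kind, start, end = start, ref = "", alt = "") {
  switch(kind,
    SNV = paste0("m.", start, ref, ">", alt),
    deletion = if (end > start) paste0("m.del", start, "-", end)
               else paste0("m.del", start),
    insertion = paste0("m.", start, "ins", alt),
    stop("unknown variant kind: ", kind)
  )
}

#' Parse a canonical variant label
#'
#' Inverse of [variant_label()]: recovers kind, coordinates and alleles
#' (the deleted reference bases are not encoded in a deletion label and are
#' returned empty).
#'
#' @param label Character vector of labels.
#' @return A data frame with columns `label`, `kind`, `start`, `end`,
#'   `ref`, `alt`.
#' @export
parse_variant_label <- function(label) {
  n <- length(label)
  kind <- character(n); start <- integer(n); end <- integer(n)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    lab <- label[i]
    if (grepl("^m\\.del[0-9]+(-[0-9]+)?$", lab)) {
      body <- sub("^m\\.del", "", lab)
      parts <- strsplit(body, "-", fixed = TRUE)[[1]]
      kind[i] <- "deletion"
      start[i] <- as.integer(parts[1])
      end[i] <- if (length(parts) == 2L) as.integer(parts[2]) else start[i]
      if (end[i] < start[i]) stop("malformed deletion label: ", lab)
    } else if (grepl("^m\\.[0-9]+ins[ACGT]+$", lab)) {
      kind[i] <- "insertion"
      start[i] <- as.integer(sub("^m\\.([0-9]+)ins.*$", "\\1", lab))
      end[i] <- start[i]
      alt[i] <- sub("^m\\.[0-9]+ins", "", lab)
    } else if (grepl("^m\\.[0-9]+[ACGT]>[ACGT]$", lab)) {
      kind[i] <- "SNV"
      start[i] <- as.integer(sub("^m\\.([0-9]+).*$", "\\1", lab))
      end[i] <- start[i]
      ref[i] <- sub("^m\\.[0-9]+([ACGT])>.*$", "\\1", lab)
      alt[i] <- sub("^.*>", "", lab)
      if (ref[i] == alt[i]) stop("SNV label with identical alleles: ", lab)
    } else {
      stop("unparseable variant label: ", lab)
    }
  }
  data.frame(label = label, kind = kind, start = start, end = end,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

## Left-align a deletion of ref[start..end] within its homopolymer context.
## Shifting by one is valid iff ref[start-1] == ref[end].
normalize_deletion <- function(ref_chars, start, end) {
  while (start > 1L && ref_chars[start - 1L] == ref_chars[end]) {
    start <- start - 1L
    end <- end - 1L
  }
  c(start, end)
}

## Left-align an insertion of `seq` after reference position `pos`.
## Shifting by one is valid iff the last inserted base equals ref[pos].
normalize_insertion <- function(ref_chars, pos, seq) {
  n <- nchar(seq)
  while (pos >= 1L && substr(seq, n, n) == ref_chars[pos]) {
    seq <- paste0(ref_chars[pos], substr(seq, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

empty_variant_table <- function() {
  data.frame(label = character(), kind = character(), start = integer(),
             end = integer(), ref = character(), alt = character(),
             stringsAsFactors = FALSE)
}

#' Extract variants of one sample against the reference
#'
#' Scans the aligned sample row against the reference row and reports all
#' differences as canonical variants. Maximal runs of sample gaps over
#' consecutive reference positions become one deletion; maximal runs of
#' sample bases over reference gap columns become one insertion. `N` is
#' treated as missing and never produces a variant (an insertion run
#' containing `N` is dropped entirely). Indels are left-aligned.
#'
#' @param aln An `"mt_alignment"` object.
#' @param sample_id Identifier of the sample row.
#' @return A variant table: data frame with columns `label`, `kind`,
#'   `start`, `end`, `ref`, `alt`, ordered by position.
#' @export
extract_variants <- function(aln, sample_id) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (!sample_id %in% aln$ids) {
    stop("sample '", sample_id, "' not found in alignment")
  }
  ref_row <- strsplit(aln$seqs[[aln$reference_id]], "", fixed = TRUE)[[1]]
  smp <- strsplit(aln$seqs[[sample_id]], "", fixed = TRUE)[[1]]
  ref_chars <- ref_row[ref_row != "-"]   # ungapped reference
  rp <- aln$ref_pos

  out <- list()

  ## SNVs: reference base columns where both carry a (different) base
  idx <- which(!is.na(rp) & smp != "-" & smp != "N" &
                 ref_row != "N" & smp != ref_row)
  if (length(idx)) {
    pos <- rp[idx]
    out$snv <- data.frame(
      label = paste0("m.", pos, ref_row[idx], ">", smp[idx]),
      kind = "SNV", start = pos, end = pos,
      ref = ref_row[idx], alt = smp[idx], stringsAsFactors = FALSE)
  }

  ## Deletions: runs over consecutive reference positions where sample is gap
  del_pos <- rp[!is.na(rp) & smp == "-"]
  if (length(del_pos)) {
    del_pos <- sort(del_pos)
    run_id <- cumsum(c(1L, diff(del_pos) != 1L))
    dels <- lapply(split(del_pos, run_id), function(p) {
      se <- normalize_deletion(ref_chars, min(p), max(p))
      data.frame(
        label = variant_label("deletion", se[1], se[2]),
        kind = "deletion", start = se[1], end = se[2],
        ref = paste(ref_chars[se[1]:se[2]], collapse = ""), alt = "",
        stringsAsFactors = FALSE)
    })
    out$del <- do.call(rbind, dels)
  }

  ## Insertions: runs of insertion columns sharing an anchor position where
  ## the sample carries bases
  ins_cols <- which(is.na(rp) & smp != "-")
  if (length(ins_cols)) {
    anchors <- aln$ins_after[ins_cols]
    ## split by anchor; columns with the same anchor form one insertion event
    by_anchor <- split(ins_cols, anchors)
    ins <- lapply(by_anchor, function(cols) {
      bases <- smp[sort(cols)]
      if (any(bases == "N")) return(NULL)     # ambiguous insertion: missing
      pos <- aln$ins_after[cols[1]]
      nrm <- normalize_insertion(ref_chars, pos, paste(bases, collapse = ""))
      data.frame(
        label = variant_label("insertion", nrm$pos, alt = nrm$seq),
        kind = "insertion", start = nrm$pos, end = nrm$pos,
        ref = "", alt = nrm$seq, stringsAsFactors = FALSE)
    })
    ins <- ins[!vapply(ins, is.null, logical(1))]
    if (length(ins)) out$ins <- do.call(rbind, ins)
  }

  res <- if (length(out)) do.call(rbind, out) else empty_variant_table()
  res <- res[order(res$start, res$kind, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply a variant set to a reference sequence
#'
#' Edits the (ungapped) reference according to a set of non-overlapping
#' variants and returns the implied sample sequence with gaps removed.
#' This is the inverse of [extract_variants()] up to alignment gaps, and is
#' used both by the synthetic-data generator and as a testing oracle.
#'
#' @param reference_seq Reference sequence as a single string.
#' @param variants A variant table (as returned by [extract_variants()]) or
#'   a character vector of canonical labels.
#' @return The edited sequence as a single string.
#' @export
apply_variants <- function(reference_seq, variants) {
  ref_chars <- strsplit(toupper(reference_seq), "", fixed = TRUE)[[1]]
  L <- length(ref_chars)
  if (is.character(variants)) variants <- parse_variant_label(variants)
  if (nrow(variants) == 0L) return(paste(ref_chars, collapse = ""))

  v <- variants
  if (any(v$start < ifelse(v$kind == "insertion", 0L, 1L)) ||
      any(v$end > L)) {
    stop("variant position out of reference range [1, ", L, "]")
  }
  ## fill deleted reference allele if absent (labels do not encode it)
  fix <- which(v$kind == "deletion" & (is.na(v$ref) | v$ref == ""))
  for (i in fix) v$ref[i] <- paste(ref_chars[v$start[i]:v$end[i]], collapse = "")

  ## order by edit location; insertions after pos p sit at p + 0.5
  key <- v$start + ifelse(v$kind == "insertion", 0.5, 0)
  v <- v[order(key), , drop = FALSE]
  key <- sort(key)
  lo <- ifelse(v$kind == "insertion", v$start + 0.5, v$start)
  hi <- ifelse(v$kind == "insertion", v$start + 0.5, v$end)
  if (nrow(v) > 1L && any(lo[-1] <= hi[-nrow(v)])) {
    stop("overlapping variants in reference coordinates")
  }

  ## consistency of stated reference alleles
  snv <- v$kind == "SNV"
  if (any(snv & v$ref != ref_chars[v$start])) {
    bad <- v$label[snv & v$ref != ref_chars[v$start]][1]
    stop("reference allele mismatch for ", bad)
  }
  for (i in which(v$kind == "deletion")) {
    have <- paste(ref_chars[v$start[i]:v$end[i]], collapse = "")
    if (v$ref[i] != have) stop("reference allele mismatch for ", v$label[i])
  }

  pieces <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "insertion") {
      upto <- v$start[i]
      if (upto >= cur) pieces <- c(pieces, paste(ref_chars[cur:upto], collapse = ""))
      pieces <- c(pieces, v$alt[i])
      cur <- upto + 1L
    } else {
      if (v$start[i] > cur) {
        pieces <- c(pieces, paste(ref_chars[cur:(v$start[i] - 1L)], collapse = ""))
      }
      if (v$kind[i] == "SNV") pieces <- c(pieces, v$alt[i])
      cur <- v$end[i] + 1L
    }
  }
  if (cur <= L) pieces <- c(pieces, paste(ref_chars[cur:L], collapse = ""))
  paste(pieces, collapse = "")
}

#' Write a per-individual variant table to TSV
#'
#' @param variant_sets Named list mapping individual id to a variant table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variant_sets, path) {
  rows <- lapply(names(variant_sets), function(id) {
    v <- variant_sets[[id]]
    if (is.character(v)) v <- parse_variant_label(v)
    if (nrow(v) == 0L) return(NULL)
    cbind(individual = id, v)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- cbind(individual = character(0), empty_variant_table())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
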