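## Haplotype collapsing with matrilineal imputation.
##
## A haplotype is identified by its set of called variant labels relative to
## the reference; missing calls never split haplotypes. Individuals without a
## sequenced genome join the haplotype of their matrilineal representative
## (mtDNA is maternally inherited, so matrilineal relatives share it barring
## de novo mutation).

hap_key <- function(labels) paste(sort(unique(labels)), collapse = ";")

#' Collapse individuals into haplotypes
#'
#' Groups sequenced individuals with identical variant sets into haplotypes
#' and attaches matrilineally imputed individuals to their representative's
#' haplotype.
#'
#' @param variant_sets Named list mapping each sequenced individual to its
#'   variant set (a character vector of canonical labels, or a variant table
#'   with a `label` column).
#' @param matrilineage_map Optional data frame with columns `individual`
#'   and `representative`. Every representative must be sequenced;
#'   representatives may map to themselves. Individuals absent from the map
#'   but present in `variant_sets` stand for themselves.
#' @return An object of class `"haplotype_table"`: a list with
#'   `tab` (data frame: `haplotype_id`, `n_sequenced`, `n_imputed`,
#'   `n_total`), `variants` (named list of label vectors per haplotype),
#'   `members` (named list with `sequenced` and `imputed` id vectors per
#'   haplotype) and totals `n_sequenced`, `n_total`.
#' @export
collapse_haplotypes <- function(variant_sets, matrilineage_map = NULL) {
  if (length(variant_sets) == 0L) stop("no sequenced individuals supplied")
  sets <- lapply(variant_sets, function(v) {
    if (is.data.frame(v)) v <- v$label
    sort(unique(as.character(v)))
  })
  seq_ids <- names(sets)
  if (is.null(seq_ids) || any(seq_ids == "")) {
    stop("variant_sets must be a named list keyed by individual id")
  }

  rep_of <- stats::setNames(seq_ids, seq_ids)
  if (!is.null(matrilineage_map)) {
    mm <- as.data.frame(matrilineage_map)
    stopifnot(all(c("individual", "representative") %in% names(mm)))
    missing_rep <- setdiff(unique(mm$representative), seq_ids)
    if (length(missing_rep)) {
      stop("matrilineage representatives without a sequenced genome: ",
           paste(utils::head(missing_rep, 5), collapse = ", "))
    }
    conflict <- mm$individual %in% seq_ids & mm$individual != mm$representative
    if (any(conflict)) {
      ## a sequenced individual mapped to a different representative is only
      ## acceptable when both carry the same variant set
      for (i in which(conflict)) {
        a <- hap_key(sets[[mm$individual[i]]])
        b <- hap_key(sets[[mm$representative[i]]])
        if (!identical(a, b)) {
          stop("individual '", mm$individual[i], "' is sequenced but mapped ",
               "to representative '", mm$representative[i],
               "' with a different variant set")
        }
      }
    }
    extra <- stats::setNames(mm$representative, mm$individual)
    rep_of <- c(rep_of[setdiff(names(rep_of), names(extra))], extra)
  }

  keys <- vapply(sets, hap_key, character(1))
  uniq <- unique(keys)

  members_seq <- vector("list", length(uniq))
  members_imp <- vector("list", length(uniq))
  for (ind in names(rep_of)) {
    h <- match(keys[[rep_of[[ind]]]], uniq)
    if (ind %in% seq_ids) {
      members_seq[[h]] <- c(members_seq[[h]], ind)
    } else {
      members_imp[[h]] <- c(members_imp[[h]], ind)
    }
  }
  members_seq <- lapply(members_seq, function(x) sort(unique(x)))
  members_imp <- lapply(members_imp, function(x) sort(unique(x)))

  n_seq <- lengths(members_seq)
  n_imp <- lengths(members_imp)
  n_tot <- n_seq + n_imp

  ## deterministic ids: by decreasing total membership, ties by variant key
  ord <- order(-n_tot, uniq)
  ids <- sprintf("H%03d", seq_along(ord))
  variants <- lapply(uniq[ord], function(k) {
    if (k == "") character(0) else strsplit(k, ";", fixed = TRUE)[[1]]
  })
  names(variants) <- ids
  members <- Map(function(s, i) list(sequenced = s, imputed = i),
                 members_seq[ord], members_imp[ord])
  names(members) <- ids

  structure(
    list(
      tab = data.frame(haplotype_id = ids,
                       n_sequenced = n_seq[ord],
                       n_imputed = n_imp[ord],
                       n_total = n_tot[ord],
                       stringsAsFactors = FALSE),
      variants = variants,
      members = members,
      n_sequenced = sum(n_seq),
      n_total = sum(n_tot)
    ),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table: ", nrow(x$tab), " haplotypes, ",
      x$n_sequenced, " sequenced / ", x$n_total, " total individuals\n",
      sep = "")
  print(utils::head(x$tab, 10))
  if (nrow(x$tab) > 10) cat("...\n")
  invisible(x)
}

#' Map every individual to its haplotype id
#'
#' @param haplotypes A `"haplotype_table"`.
#' @return Named character vector: individual id -> haplotype id.
#' @export
haplotype_of <- function(haplotypes) {
  out <- character(0)
  for (h in names(haplotypes$members)) {
    m <- haplotypes$members[[h]]
    ids <- c(m$sequenced, m$imputed)
    out[ids] <- h
  }
  out
}

#' Read a matrilineage map TSV
#'
#' Expects a header line `individual<TAB>representative`.
#'
#' @param path TSV file path.
#' @return Data frame with columns `individual`, `representative`.
#' @export
read_matrilineage_map <- function(path) {
  mm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("individual", "representative") %in% names(mm)))
  mm
}

#' Write a haplotype table to TSV
#'
#' One row per haplotype with its variant labels and member ids collapsed
#' into comma-separated fields.
#'
#' @param haplotypes A `"haplotype_table"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(haplotypes, path) {
  tab <- haplotypes$tab
  tab$variants <- vapply(haplotypes$variants[tab$haplotype_id],
                         paste, character(1), collapse = ",")
  tab$members_sequenced <- vapply(haplotypes$members[tab$haplotype_id],
                                  function(m) paste(m$sequenced, collapse = ","),
                                  character(1))
  tab$members_imputed <- vapply(haplotypes$members[tab$haplotype_id],
                                function(m) paste(m$imputed, collapse = ","),
                                character(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
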