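## Pedigree kinship and the familial adjustment score covariate.
##
## f(i,j) is the probability that one allele drawn at random from i and one
## from j are identical by descent. Founders are assumed non-inbred and
## mutually unrelated; a missing parent is treated as a unique unrelated
## founder.

#' Read a pedigree TSV
#'
#' Expects columns `id`, `father`, `mother`, `sex`, `age`; unknown parents
#' are coded `0`, `NA` or an empty field; sex is coded `F`/`M` (or 0/1).
#'
#' @param path TSV file path.
#' @return A data frame with character `id`/`father`/`mother` (`NA` for
#'   unknown parents), character `sex` and numeric `age`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          father = "character",
                                          mother = "character"),
                           na.strings = c("NA", ""))
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  ped$father[ped$father %in% "0"] <- NA_character_
  ped$mother[ped$mother %in% "0"] <- NA_character_
  ped
}

#' Write a pedigree TSV
#'
#' @param ped Pedigree data frame (see [read_pedigree()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Topological order (parents before children); errors on cycles or
## references to absent parents.
pedigree_order <- function(ped) {
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree")
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ids)
    if (any(bad)) {
      stop("pedigree refers to unknown ", col, " id(s): ",
           paste(utils::head(unique(ref[bad]), 5), collapse = ", "))
    }
  }
  idx <- stats::setNames(seq_along(ids), ids)
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  indeg <- integer(length(ids))
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) {
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  }
  out
}

#' Kinship matrix from a pedigree
#'
#' Recursive (tabular) kinship: processing individuals with parents before
#' children, `f(i,i) = 0.5 * (1 + f(father_i, mother_i))` and for j earlier
#' in the order `f(i,j) = 0.5 * (f(father_i, j) + f(mother_i, j))`, with
#' missing parents contributing 0. The result is invariant to the input
#' order of individuals.
#'
#' @param ped Pedigree data frame with columns `id`, `father`, `mother`
#'   (`NA`/`"0"` for unknown).
#' @return Symmetric numeric matrix with dimnames equal to `ped$id` in input
#'   order; diagonal entries are at least 0.5.
#' @export
kinship_matrix <- function(ped) {
  ped <- as.data.frame(ped)
  ped$father[!is.na(ped$father) & ped$father == "0"] <- NA_character_
  ped$mother[!is.na(ped$mother) & ped$mother == "0"] <- NA_character_
  ord <- pedigree_order(ped)
  ids <- ped$id[ord]
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father[ord]]
  mo <- idx[ped$mother[ord]]

  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fi <- fa[i]; mi <- mo[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row_f <- if (!is.na(fi)) K[fi, prev] else 0
      row_m <- if (!is.na(mi)) K[mi, prev] else 0
      v <- 0.5 * (row_f + row_m)
      K[i, prev] <- v
      K[prev, i] <- v
    }
    fpm <- if (!is.na(fi) && !is.na(mi)) K[fi, mi] else 0
    K[i, i] <- 0.5 * (1 + fpm)
  }
  dimnames(K) <- list(ids, ids)
  K[ped$id, ped$id, drop = FALSE]
}

#' Familial adjustment scores
#'
#' Per-individual covariate absorbing phenotype variance due to
#' relatedness: for focal individual i,
#' \deqn{FAS_i = \sum_{j \ne i} y_j f(i,j) / (N y_i)}
#' where the sum runs over the other phenotype-measured individuals, N is
#' the number of phenotype-measured individuals and y is the phenotype
#' (mtDNA copy number). The self term is excluded by default (the sum runs
#' over "each of the other individuals"); set `include_self = TRUE` to add
#' `y_i f(i,i)` to the numerator instead.
#'
#' Individuals with a missing phenotype contribute nothing to other
#' individuals' sums and receive `NA`. A focal individual with phenotype 0
#' is a domain error (the score divides by it).
#'
#' @param phenotype Named numeric vector: individual id -> copy number
#'   (`NA` for missing).
#' @param kin Kinship matrix covering at least the phenotyped individuals
#'   (as from [kinship_matrix()]).
#' @param include_self Include the j = i term of the sum? Default `FALSE`.
#' @return Named numeric vector of scores, `NA` where the phenotype is
#'   missing.
#' @export
familial_adjustment_scores <- function(phenotype, kin, include_self = FALSE) {
  ids <- names(phenotype)
  if (is.null(ids)) stop("phenotype must be a named vector of copy numbers")
  absent <- setdiff(ids, rownames(kin))
  if (length(absent)) {
    stop("phenotyped individuals missing from kinship matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  measured <- ids[!is.na(phenotype)]
  if (any(phenotype[measured] == 0)) {
    stop("familial adjustment score undefined for zero copy number")
  }
  N <- length(measured)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (N == 0L) return(out)
  Km <- kin[measured, measured, drop = FALSE]
  y <- phenotype[measured]
  num <- as.vector(Km %*% y)
  if (!include_self) num <- num - diag(Km) * y
  out[measured] <- num / (N * y)
  out
}

#' Write kinship coefficients to long-format TSV
#'
#' @param kin Kinship matrix.
#' @param path Output TSV path.
#' @param lower_only Emit each unordered pair once (including the
#'   diagonal)? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path, lower_only = TRUE) {
  ids <- rownames(kin)
  pairs <- which(if (lower_only) lower.tri(kin, diag = TRUE)
                 else matrix(TRUE, nrow(kin), ncol(kin)), arr.ind = TRUE)
  tab <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                    f = kin[pairs], stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
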