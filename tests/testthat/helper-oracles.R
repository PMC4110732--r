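## Shared fixtures and independent oracles for the test suite.

## ---- alignment fixtures ---------------------------------------------------

## Tiny hand-built alignment: reference plus samples with an SNV, a
## deletion, an insertion and an N.
toy_alignment <- function() {
  mt_alignment(
    ids = c("REF", "S1", "S2", "S3", "S4"),
    seqs = c(
      REF = "ACGTACGTACGT--ACGTACGT",
      S1  = "ACGTACGTACGT--ACGTACGT",  # identical to reference
      S2  = "ACGTACGGACGT--ACGTACGT",  # SNV at reference position 8 (T>G)
      S3  = "ACGT----ACGTGGACGTACGT",  # deletion 5-8 + insertion after 12
      S4  = "ACGTACNTACGT--ACGTACGT"), # N at position 7: missing
    reference_id = "REF")
}

random_reference <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

## Random non-overlapping variant set on a reference, already canonical
## (left-aligned) so that apply -> extract round-trips exactly.
random_variant_set <- function(ref, n = 5) {
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  L <- length(ref_chars)
  anchors <- sort(sample(seq(5, L - 12, by = 12), n))
  rows <- lapply(anchors, function(a) {
    kind <- sample(c("SNV", "deletion", "insertion"), 1,
                   prob = c(0.7, 0.15, 0.15))
    if (kind == "SNV") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[a]), 1)
      data.frame(label = variant_label("SNV", a, ref = ref_chars[a], alt = alt),
                 kind = "SNV", start = a, end = a,
                 ref = ref_chars[a], alt = alt, stringsAsFactors = FALSE)
    } else if (kind == "deletion") {
      len <- sample(1:3, 1)
      se <- mitoscan:::normalize_deletion(ref_chars, a, a + len - 1L)
      data.frame(label = variant_label("deletion", se[1], se[2]),
                 kind = "deletion", start = se[1], end = se[2],
                 ref = paste(ref_chars[se[1]:se[2]], collapse = ""), alt = "",
                 stringsAsFactors = FALSE)
    } else {
      alt <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                          replace = TRUE), collapse = "")
      nrm <- mitoscan:::normalize_insertion(ref_chars, a, alt)
      data.frame(label = variant_label("insertion", nrm$pos, alt = nrm$seq),
                 kind = "insertion", start = nrm$pos, end = nrm$pos,
                 ref = "", alt = nrm$seq, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

## ---- network oracles ------------------------------------------------------

## Haplotype table straight from a named list of label sets, one member per
## haplotype.
hap_table_from_sets <- function(sets) {
  collapse_haplotypes(sets)
}

## Brute force: enumerate every spanning tree of the complete Hamming graph
## (via all (h-1)-subsets of edges), find the MST weight, and return the
## union of all minimum spanning trees as a canonical edge matrix.
brute_force_msn <- function(sets) {
  ids <- names(sets)
  h <- length(ids)
  pairs <- t(utils::combn(h, 2))
  w <- apply(pairs, 1, function(p)
    hamming_distance(sets[[p[1]]], sets[[p[2]]]))
  m <- nrow(pairs)
  tree_sets <- utils::combn(m, h - 1)
  best_w <- Inf
  in_some_mst <- logical(m)
  for (j in seq_len(ncol(tree_sets))) {
    es <- tree_sets[, j]
    ## connectivity check by union-find
    parent <- seq_len(h)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in es) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    tw <- sum(w[es])
    if (tw < best_w - 1e-9) {
      best_w <- tw
      in_some_mst <- logical(m)
      in_some_mst[es] <- TRUE
    } else if (abs(tw - best_w) < 1e-9) {
      in_some_mst[es] <- TRUE
    }
  }
  edges <- cbind(ids[pairs[in_some_mst, 1]], ids[pairs[in_some_mst, 2]])
  sw <- edges[, 1] > edges[, 2]
  edges[sw, ] <- edges[sw, c(2, 1)]
  list(edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
       mst_weight = best_w,
       n_msts = NA)
}

## Count minimum spanning trees by brute force.
brute_force_n_mst <- function(sets) {
  ids <- names(sets)
  h <- length(ids)
  pairs <- t(utils::combn(h, 2))
  w <- apply(pairs, 1, function(p)
    hamming_distance(sets[[p[1]]], sets[[p[2]]]))
  m <- nrow(pairs)
  tree_sets <- utils::combn(m, h - 1)
  weights <- c(); count <- 0; best <- Inf
  for (j in seq_len(ncol(tree_sets))) {
    es <- tree_sets[, j]
    parent <- seq_len(h)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in es) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    tw <- sum(w[es])
    if (tw < best - 1e-9) { best <- tw; count <- 1 }
    else if (abs(tw - best) < 1e-9) count <- count + 1
  }
  count
}

## Random label sets over a small variant alphabet (distinct sets only).
random_hap_sets <- function(h, n_vars = 6) {
  vars <- paste0("m.", seq(100, 100 + n_vars - 1), "A>G")
  repeat {
    sets <- lapply(seq_len(h), function(i)
      sort(sample(vars, sample(0:n_vars, 1))))
    keys <- vapply(sets, paste, character(1), collapse = ";")
    if (!anyDuplicated(keys)) break
  }
  names(sets) <- sprintf("X%02d", seq_len(h))
  sets
}

## ---- pedigree fixtures and kinship oracle ---------------------------------

## Three-generation toy pedigree: grandparents GF/GM, their children A,B
## (full sibs), C unrelated spouse, D spouse; cousins K1, K2.
toy_pedigree <- function() {
  data.frame(
    id     = c("GF", "GM", "A",  "B",  "C",  "D",  "K1", "K2"),
    father = c(NA,   NA,   "GF", "GF", NA,   NA,   "C",  "D"),
    mother = c(NA,   NA,   "GM", "GM", NA,   NA,   "A",  "B"),
    sex    = c("M",  "F",  "F",  "F",  "M",  "M",  "F",  "M"),
    age    = c(NA, NA, NA, NA, NA, NA, 70, 72),
    stringsAsFactors = FALSE)
}

## Gene-dropping Monte-Carlo kinship: drop two independent alleles down the
## pedigree n_drop times; f(i,j) = P(random allele of i IBD to random
## allele of j). Vectorised over drops.
gene_drop_kinship <- function(ped, n_drop = 200000) {
  ord <- mitoscan:::pedigree_order(ped)
  ids <- ped$id[ord]
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father[ord]]
  mo <- idx[ped$mother[ord]]
  ## allele matrices: n x n_drop, unique founder allele ids
  A1 <- matrix(0L, n, n_drop); A2 <- matrix(0L, n, n_drop)
  counter <- 0L
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      A1[i, ] <- counter + 1L; counter <- counter + 1L
    } else {
      pick <- stats::runif(n_drop) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa[i], ], A2[fa[i], ])
    }
    if (is.na(mo[i])) {
      A2[i, ] <- counter + 1L; counter <- counter + 1L
    } else {
      pick <- stats::runif(n_drop) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo[i], ], A2[mo[i], ])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      f <- 0.25 * (mean(A1[i, ] == A1[j, ]) + mean(A1[i, ] == A2[j, ]) +
                     mean(A2[i, ] == A1[j, ]) + mean(A2[i, ] == A2[j, ]))
      K[i, j] <- f; K[j, i] <- f
    }
  }
  K[ped$id, ped$id]
}

## Random valid pedigree of n individuals: founders plus random matings of
## previously created individuals.
random_pedigree <- function(n, p_founder = 0.4) {
  id <- sprintf("P%02d", seq_len(n))
  father <- rep(NA_character_, n); mother <- rep(NA_character_, n)
  sex <- character(n)
  sex[1:2] <- c("M", "F")
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) > p_founder) {
      males <- which(sex[seq_len(i - 1)] == "M")
      females <- which(sex[seq_len(i - 1)] == "F")
      if (length(males) && length(females)) {
        father[i] <- id[males[sample.int(length(males), 1)]]
        mother[i] <- id[females[sample.int(length(females), 1)]]
      }
    }
    if (i > 2) sex[i] <- sample(c("M", "F"), 1)
  }
  data.frame(id = id, father = father, mother = mother, sex = sex,
             age = 70, stringsAsFactors = FALSE)
}

## ---- regression / permutation oracles -------------------------------------

## Partial F via two explicit lm() fits.
lm_partial_F <- function(y, X, allele) {
  d0 <- if (is.null(X)) data.frame(y = y) else data.frame(y = y, X)
  f0 <- stats::lm(y ~ ., data = d0)
  d1 <- cbind(d0, allele = allele)
  f1 <- stats::lm(y ~ ., data = d1)
  a <- stats::anova(f0, f1)
  a$F[2]
}

## Exact permutation p for a single branch with no covariates: the F
## statistic depends on the labelling only through which individuals carry
## allele 1, so enumerate all subsets of the same size.
exact_perm_p <- function(y, allele) {
  n <- length(y)
  k <- sum(allele)
  obs <- branch_statistic(y, NULL, allele)
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, function(ix) {
    a <- integer(n); a[ix] <- 1L
    branch_statistic(y, NULL, a)
  })
  mean(stats >= obs - 1e-10)
}

## Small synthetic cohort for scan tests.
small_cohort <- function(seed = 1, n = 300L, m = 40L, gamma = 1.1,
                         s2g = 0.05, missing = 0.1, ...) {
  cfg <- sim_config(n_individuals = n, n_matrilineages = m,
                    gamma_clade = gamma, sigma2_g = s2g,
                    missing_frac = missing, ...)
  simulate_mt_cohort(cfg, seed = seed, sequences = FALSE)
}

## Build a 2-row alignment (REF, S) that realises a variant table as
## alignment columns directly, independently of apply_variants().
alignment_from_variants <- function(ref, v) {
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  smp <- ref_chars
  for (i in which(v$kind == "SNV")) smp[v$start[i]] <- v$alt[i]
  for (i in which(v$kind == "deletion")) smp[v$start[i]:v$end[i]] <- "-"
  refrow <- as.list(ref_chars); smprow <- as.list(smp)
  ins <- v[v$kind == "insertion", , drop = FALSE]
  for (i in order(ins$start, decreasing = TRUE)) {
    p <- ins$start[i]
    alt <- strsplit(ins$alt[i], "", fixed = TRUE)[[1]]
    refrow <- append(refrow, as.list(rep("-", length(alt))), after = p)
    smprow <- append(smprow, as.list(alt), after = p)
  }
  mt_alignment(c("REF", "S"),
               c(paste(unlist(refrow), collapse = ""),
                 paste(unlist(smprow), collapse = "")),
               "REF")
}
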