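## Synthetic cohort generator with a truth record.
##
## Emulates the statistical structure the analysis assumes: a matrilineal
## haplotype genealogy with infinite-sites mutations on a 16,569-bp circular
## reference treated as linear, long-tailed matrilineage sizes, a
## multi-generation pedigree whose maternal lines realise the matrilineages,
## and a continuous phenotype with age/sex effects, a kinship-structured
## familial component and an optional clade effect on a branch of the
## reconstructed network.

#' Simulation configuration
#'
#' Default values emulate the cohort scale the analysis is designed for:
#' 1007 individuals in 274 matrilineages, ~900 segregating variants over a
#' 16,569-bp reference (SNVs with small insertion/deletion fractions),
#' ages uniform on 65-95 years, 44% male, background phenotype mean 2.7
#' with total residual SD 0.9 (kinship-structured variance
#' `sigma2_g = 0.05` plus i.i.d. `sigma2_e = 0.76`), a clade effect of
#' +1.1 phenotype units on a 10-17-member clade, and 19% missing
#' phenotypes.
#'
#' @param n_individuals Cohort size.
#' @param n_matrilineages Number of maternal lineages (each contributes one
#'   sequenced representative).
#' @param reference_length Reference length in bp.
#' @param mutation_mean Poisson mean mutation count per genealogy branch
#'   (default 3.3: with 274 lineages this yields roughly 900 segregating
#'   variants and, through zero-mutation branches, around 250-265 unique
#'   haplotypes).
#' @param p_insertion,p_deletion Per-mutation probabilities of the event
#'   being an insertion / deletion (otherwise an SNV).
#' @param max_sibship Maximum cohort sibship size in the pedigree.
#' @param p_cross_father Probability a sibship's father is drawn from
#'   another matrilineage's pedigree (creates cross-family kinship).
#' @param p_pool_son Probability a matrilineage contributes a marriageable
#'   (non-cohort) son to the father pool.
#' @param p_male Probability a cohort member is male.
#' @param age_range Cohort age range (years), sampled uniformly.
#' @param beta_age,beta_sex Covariate effects (phenotype units per year /
#'   for male sex).
#' @param gamma_clade Clade effect in phenotype units.
#' @param sigma2_g Kinship-structured variance component; the familial
#'   deviation g is multivariate normal with covariance `2 sigma2_g K`
#'   (the additive-relationship convention), so `var(g_i) = sigma2_g` for a
#'   non-inbred individual.
#' @param sigma2_e Residual variance.
#' @param target_mean Intended background phenotype mean; the intercept is
#'   derived from it and the covariate effects.
#' @param clade_size_range Complete-cohort size range from which the target
#'   clade is selected among the network's branch bipartitions.
#' @param gamma_subclade,subclade_size_range Optional nested effect on a
#'   sub-clade inside the target clade (for round-2 heterogeneity
#'   scenarios); `gamma_subclade = 0` disables it.
#' @param missing_frac Fraction of phenotypes set missing at random.
#' @return A list of class `"mt_sim_config"`.
#' @export
sim_config <- function(n_individuals = 1007L,
                       n_matrilineages = 274L,
                       reference_length = 16569L,
                       mutation_mean = 3.3,
                       p_insertion = 26 / 945,
                       p_deletion = 20 / 945,
                       max_sibship = 4L,
                       p_cross_father = 0.3,
                       p_pool_son = 0.5,
                       p_male = 0.44,
                       age_range = c(65, 95),
                       beta_age = -0.01,
                       beta_sex = -0.10,
                       gamma_clade = 1.1,
                       sigma2_g = 0.05,
                       sigma2_e = 0.76,
                       target_mean = 2.7,
                       clade_size_range = c(10L, 17L),
                       gamma_subclade = 0,
                       subclade_size_range = c(5L, 20L),
                       missing_frac = 0.19) {
  cfg <- as.list(environment())
  if (cfg$n_matrilineages < 2L) stop("need at least 2 matrilineages")
  if (cfg$n_individuals < cfg$n_matrilineages) {
    stop("n_individuals must be at least n_matrilineages")
  }
  if (cfg$sigma2_g < 0 || cfg$sigma2_e < 0) stop("variances must be >= 0")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    stop("missing_frac must lie in [0, 1)")
  }
  if (cfg$mutation_mean < 0) stop("mutation_mean must be >= 0")
  structure(cfg, class = "mt_sim_config")
}

## ---- genealogy ------------------------------------------------------------

## Matrilineal haplotype genealogy with persisting ancestors: the first
## matrilineage derives from the reference (node 0), every later one buds
## from a uniformly chosen existing matrilineage, acquiring a
## Poisson-distributed number of mutations placed at unique reference
## positions (infinite sites: no recurrence, no back-mutation). Pairwise
## Hamming distances therefore equal path sums of mutation counts on the
## budding tree, and -- because every ancestral haplotype is carried by an
## extant lineage -- the minimum spanning tree of the Hamming graph is the
## budding tree itself (observed interior nodes, as in real mtDNA
## haplotype networks).
sim_genealogy <- function(cfg, ref_chars) {
  M <- cfg$n_matrilineages
  L <- cfg$reference_length
  edges_parent <- integer(M)
  edges_child <- seq_len(M)
  edges_parent[1] <- 0L
  for (m in seq_len(M)[-1]) {
    edges_parent[m] <- sample.int(m - 1L, 1L)
  }
  n_edges <- M
  n_mut <- stats::rpois(n_edges, cfg$mutation_mean)
  total <- sum(n_mut)

  ## unique, well-separated anchors: infinite-sites plus room for indel
  ## left-alignment so canonical labels never collide
  candidates <- seq(10L, L - 20L, by = 16L)
  if (total > length(candidates)) {
    stop("mutation demand (", total, ") exceeds reference capacity (",
         length(candidates), " sites)")
  }
  anchors <- if (total > 0) sample(candidates, total) else integer(0)

  bases <- c("A", "C", "G", "T")
  mk_variant <- function(anchor) {
    u <- stats::runif(1)
    if (u < cfg$p_insertion) {
      len <- sample.int(4L, 1L, prob = c(.5, .25, .15, .1))
      seqs <- paste(sample(bases, len, replace = TRUE), collapse = "")
      nrm <- normalize_insertion(ref_chars, anchor, seqs)
      data.frame(label = variant_label("insertion", nrm$pos, alt = nrm$seq),
                 kind = "insertion", start = nrm$pos, end = nrm$pos,
                 ref = "", alt = nrm$seq, stringsAsFactors = FALSE)
    } else if (u < cfg$p_insertion + cfg$p_deletion) {
      len <- sample.int(6L, 1L, prob = c(.4, .25, .15, .1, .06, .04))
      se <- normalize_deletion(ref_chars, anchor, anchor + len - 1L)
      data.frame(label = variant_label("deletion", se[1], se[2]),
                 kind = "deletion", start = se[1], end = se[2],
                 ref = paste(ref_chars[se[1]:se[2]], collapse = ""), alt = "",
                 stringsAsFactors = FALSE)
    } else {
      ref <- ref_chars[anchor]
      alt <- sample(setdiff(bases, ref), 1L)
      data.frame(label = variant_label("SNV", anchor, ref = ref, alt = alt),
                 kind = "SNV", start = anchor, end = anchor,
                 ref = ref, alt = alt, stringsAsFactors = FALSE)
    }
  }
  variants <- if (total > 0) {
    do.call(rbind, lapply(anchors, mk_variant))
  } else empty_variant_table()

  edge_labels <- split(variants$label,
                       factor(rep(seq_len(n_edges), n_mut),
                              levels = seq_len(n_edges)))

  ## accumulate labels root -> tips; a lineage's parent always has a
  ## smaller index, so a single forward pass suffices
  hap <- vector("list", M)
  for (m in seq_len(M)) {
    inherited <- if (edges_parent[m] == 0L) character(0) else
      hap[[edges_parent[m]]]
    hap[[m]] <- c(inherited, edge_labels[[m]])
  }
  list(edges = data.frame(parent = edges_parent, child = edges_child,
                          n_mut = n_mut),
       tip_haplotypes = hap,
       variants = variants)
}

## Long-tailed matrilineage sizes summing exactly to the cohort size.
sim_matrilineage_sizes <- function(cfg) {
  M <- cfg$n_matrilineages
  n <- cfg$n_individuals
  p <- min(0.9, M / n)
  sizes <- 1L + stats::rgeom(M, p)
  while (sum(sizes) > n) {
    big <- which(sizes > 1L)
    i <- big[sample.int(length(big), 1L)]
    sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < n) {
    i <- sample.int(M, 1L)
    sizes[i] <- sizes[i] + 1L
  }
  sizes
}

## ---- pedigree -------------------------------------------------------------

## Multi-generation pedigree realising the matrilineage assignment: each
## matrilineage is founded by an ancestor couple whose daughters mother the
## cohort sibships; fathers are new unrelated founders or, with probability
## p_cross_father, non-cohort sons of other matrilineages' founder couples.
## Parents always precede children in the emitted order.
sim_pedigree <- function(cfg, members_by_lineage) {
  rows <- list()
  add <- function(id, father, mother, sex, age) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex, age = age,
      stringsAsFactors = FALSE)
  }
  pool <- character(0)        # marriageable non-cohort males
  pool_lineage <- integer(0)
  M <- length(members_by_lineage)
  cohort_sex <- list()
  for (m in seq_len(M)) {
    members <- members_by_lineage[[m]]
    s <- length(members)
    fid <- sprintf("AF%04d", m)   # founder female (matrilineage ancestor)
    mid <- sprintf("AM%04d", m)   # her husband, founder male
    add(fid, NA, NA, "F", NA)
    add(mid, NA, NA, "M", NA)
    ## split cohort members into sibships
    sib_sizes <- integer(0)
    left <- s
    while (left > 0L) {
      k <- min(left, sample.int(cfg$max_sibship, 1L))
      sib_sizes <- c(sib_sizes, k)
      left <- left - k
    }
    start <- 1L
    for (k in seq_along(sib_sizes)) {
      mom <- sprintf("DF%04d_%d", m, k)  # daughter of the founder couple
      add(mom, mid, fid, "F", NA)
      use_pool <- length(pool) > 0L &&
        any(pool_lineage != m) &&
        stats::runif(1) < cfg$p_cross_father
      if (use_pool) {
        ok <- which(pool_lineage != m)
        j <- ok[sample.int(length(ok), 1L)]
        dad <- pool[j]
        pool <- pool[-j]; pool_lineage <- pool_lineage[-j]
      } else {
        dad <- sprintf("EM%04d_%d", m, k)
        add(dad, NA, NA, "M", NA)
      }
      sib <- members[start:(start + sib_sizes[k] - 1L)]
      for (ind in sib) {
        sex <- if (stats::runif(1) < cfg$p_male) "M" else "F"
        age <- round(stats::runif(1, cfg$age_range[1], cfg$age_range[2]), 1)
        add(ind, dad, mom, sex, age)
        cohort_sex[[ind]] <- sex
      }
      start <- start + sib_sizes[k]
    }
    if (stats::runif(1) < cfg$p_pool_son) {
      son <- sprintf("SM%04d", m)
      add(son, mid, fid, "M", NA)
      pool <- c(pool, son); pool_lineage <- c(pool_lineage, m)
    }
  }
  do.call(rbind, rows)
}

## ---- phenotypes -----------------------------------------------------------

## y_i = mu + beta_age age_i + beta_sex sex_i + gamma 1[target] (+ nested
## effect) + g_i + eps_i with g ~ MVN(0, 2 sigma2_g K) over the cohort.
sim_phenotypes <- function(cfg, ped, cohort_ids, target_members,
                           subclade_members) {
  n <- length(cohort_ids)
  cohort <- ped[match(cohort_ids, ped$id), ]
  sex01 <- as.integer(cohort$sex == "M")
  age <- cohort$age
  mu <- cfg$target_mean - cfg$beta_age * mean(cfg$age_range) -
    cfg$beta_sex * cfg$p_male

  g <- rep(0, n)
  if (cfg$sigma2_g > 0) {
    K <- kinship_matrix(ped)[cohort_ids, cohort_ids]
    V <- 2 * cfg$sigma2_g * K
    R <- chol(V + diag(1e-8, n))
    g <- as.numeric(crossprod(R, stats::rnorm(n)))
  }
  eps <- if (cfg$sigma2_e > 0) stats::rnorm(n, 0, sqrt(cfg$sigma2_e)) else rep(0, n)
  y <- mu + cfg$beta_age * age + cfg$beta_sex * sex01 +
    cfg$gamma_clade * (cohort_ids %in% target_members) +
    cfg$gamma_subclade * (cohort_ids %in% subclade_members) +
    g + eps
  if (cfg$missing_frac > 0) {
    n_miss <- floor(cfg$missing_frac * n)
    if (n_miss > 0) y[sample.int(n, n_miss)] <- NA_real_
  }
  data.frame(id = cohort_ids, copy_number = y, age = age, sex = sex01,
             stringsAsFactors = FALSE)
}

## ---- top-level generator --------------------------------------------------

#' Simulate a synthetic mitochondrial cohort
#'
#' Generates a full synthetic study -- reference genome, matrilineal
#' genealogy with infinite-sites mutations, matrilineage map, pedigree,
#' phenotypes with a known clade effect -- together with the truth record
#' needed to validate every pipeline stage. Fully deterministic given
#' `(config, seed)`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed.
#' @param sequences Build the aligned sequences (`"mt_alignment"`)? Set
#'   `FALSE` to skip the (comparatively slow) sequence materialisation when
#'   only the statistical structure is needed, e.g. in simulation studies.
#' @return An object of class `"mt_cohort"`: list with `config`, `seed`,
#'   `reference` (string), `alignment` (or `NULL`), `rep_variant_sets`
#'   (variant labels per sequenced representative), `haplotypes`
#'   (`"haplotype_table"`), `network` (`NULL` if fewer than 2 haplotypes),
#'   `matrilineage_map`, `pedigree`, `phenotype` (data frame `id`,
#'   `copy_number`, `age`, `sex`) and `truth` (target clade signature,
#'   member ids, effect sizes, genealogy, familial component).
#' @export
simulate_mt_cohort <- function(config = sim_config(), seed = 1L,
                               sequences = TRUE) {
  stopifnot(inherits(config, "mt_sim_config"))
  set.seed(seed)
  cfg <- config
  L <- cfg$reference_length
  ref_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  reference <- paste(ref_chars, collapse = "")

  gen <- sim_genealogy(cfg, ref_chars)
  sizes <- sim_matrilineage_sizes(cfg)

  ids <- sprintf("I%04d", seq_len(cfg$n_individuals))
  lineage_of <- rep(seq_len(cfg$n_matrilineages), sizes)
  members_by_lineage <- split(ids, lineage_of)
  reps <- vapply(members_by_lineage, `[`, character(1), 1L)

  rep_variant_sets <- stats::setNames(
    lapply(seq_len(cfg$n_matrilineages),
           function(m) sort(gen$tip_haplotypes[[m]])),
    reps)
  matrilineage_map <- data.frame(
    individual = ids,
    representative = reps[lineage_of],
    stringsAsFactors = FALSE)

  haplotypes <- collapse_haplotypes(rep_variant_sets, matrilineage_map)
  network <- if (nrow(haplotypes$tab) >= 2L) {
    build_haplotype_network(haplotypes)
  } else NULL

  ## target clade: a branch bipartition of the first loop resolution whose
  ## complete-cohort clade size is closest to the configured range
  hap_of <- haplotype_of(haplotypes)
  target <- list(signature = NA_character_, clade = character(0),
                 members = character(0), size = NA_integer_)
  subclade <- list(signature = NA_character_, members = character(0))
  branches <- NULL
  if (!is.null(network)) {
    res1 <- enumerate_resolutions(network)[[1]]
    branches <- enumerate_branches(network, res1, resolution_id = 1L)
    cl_sizes <- vapply(branches$clade,
                       function(cl) sum(hap_of[ids] %in% cl), integer(1))
    lo <- cfg$clade_size_range[1]; hi <- cfg$clade_size_range[2]
    mid <- (lo + hi) / 2
    pen <- ifelse(cl_sizes >= lo & cl_sizes <= hi, 0, 1e6) +
      abs(cl_sizes - mid)
    b <- which.min(pen)
    target$clade <- branches$clade[[b]]
    target$signature <- bipartition_signature(target$clade)
    target$members <- ids[hap_of[ids] %in% target$clade]
    target$size <- cl_sizes[b]
    target$in_range <- cl_sizes[b] >= lo && cl_sizes[b] <= hi
    if (cfg$gamma_subclade != 0) {
      nested <- which(vapply(branches$clade, function(cl) {
        length(cl) < length(target$clade) && all(cl %in% target$clade)
      }, logical(1)))
      if (length(nested)) {
        ns <- cl_sizes[nested]
        lo2 <- cfg$subclade_size_range[1]; hi2 <- cfg$subclade_size_range[2]
        pen2 <- ifelse(ns >= lo2 & ns <= hi2, 0, 1e6) +
          abs(ns - (lo2 + hi2) / 2)
        b2 <- nested[which.min(pen2)]
        subclade$signature <- bipartition_signature(branches$clade[[b2]])
        subclade$members <- ids[hap_of[ids] %in% branches$clade[[b2]]]
      }
    }
  }

  pedigree <- sim_pedigree(cfg, members_by_lineage)
  phenotype <- sim_phenotypes(cfg, pedigree, ids, target$members,
                              subclade$members)

  alignment <- if (sequences) {
    build_cohort_alignment(ref_chars, rep_variant_sets, gen$variants)
  } else NULL

  structure(
    list(config = cfg, seed = seed,
         reference = reference,
         alignment = alignment,
         rep_variant_sets = rep_variant_sets,
         haplotypes = haplotypes,
         network = network,
         matrilineage_map = matrilineage_map,
         pedigree = pedigree,
         phenotype = phenotype,
         truth = list(target = target, subclade = subclade,
                      genealogy = gen$edges,
                      tip_haplotypes = gen$tip_haplotypes,
                      variants = gen$variants,
                      lineage_of = stats::setNames(lineage_of, ids),
                      gamma_clade = cfg$gamma_clade,
                      gamma_subclade = cfg$gamma_subclade,
                      beta_age = cfg$beta_age, beta_sex = cfg$beta_sex)),
    class = "mt_cohort"
  )
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat("Synthetic mtDNA cohort: ", x$config$n_individuals, " individuals, ",
      x$config$n_matrilineages, " matrilineages, ",
      nrow(x$haplotypes$tab), " haplotypes, ",
      nrow(x$truth$variants), " variants (seed ", x$seed, ")\n", sep = "")
  if (!is.na(x$truth$target$signature)) {
    cat("  target clade: ", x$truth$target$size, " members, effect ",
        x$config$gamma_clade, "\n", sep = "")
  }
  invisible(x)
}

## Aligned multi-FASTA rows (reference + one row per sequenced
## representative) from the variant truth. Insertion events add gap columns
## to the reference row; deletions become gaps in carrier rows.
build_cohort_alignment <- function(ref_chars, rep_variant_sets, variants) {
  L <- length(ref_chars)
  ins <- variants[variants$kind == "insertion", , drop = FALSE]
  ins <- ins[order(ins$start), , drop = FALSE]

  base_row <- function(labels) {
    v <- variants[variants$label %in% labels & variants$kind != "insertion", ,
                  drop = FALSE]
    row <- ref_chars
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] == "SNV") {
        row[v$start[i]] <- v$alt[i]
      } else {
        row[v$start[i]:v$end[i]] <- "-"
      }
    }
    row
  }

  weave <- function(row, labels) {
    if (nrow(ins) == 0L) return(paste(row, collapse = ""))
    pieces <- character(0)
    cur <- 1L
    for (i in seq_len(nrow(ins))) {
      p <- ins$start[i]
      if (p >= cur) {
        pieces <- c(pieces, paste(row[cur:p], collapse = ""))
        cur <- p + 1L
      }
      block <- if (ins$label[i] %in% labels) ins$alt[i] else
        strrep("-", nchar(ins$alt[i]))
      pieces <- c(pieces, block)
    }
    if (cur <= L) pieces <- c(pieces, paste(row[cur:L], collapse = ""))
    paste(pieces, collapse = "")
  }

  ids <- c("REF", names(rep_variant_sets))
  seqs <- c(weave(ref_chars, character(0)),
            vapply(rep_variant_sets,
                   function(labs) weave(base_row(labs), labs), character(1)))
  mt_alignment(ids, seqs, "REF")
}

#' Write a synthetic cohort to the pipeline's input formats
#'
#' Emits the aligned multi-FASTA (reference row included), the matrilineage
#' map, the pedigree, the phenotype table and a machine-readable truth
#' record. Byte-identical across runs for the same `(config, seed)`.
#'
#' @param cohort An `"mt_cohort"` (generated with `sequences = TRUE`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mt_cohort"))
  if (is.null(cohort$alignment)) {
    stop("cohort was generated with sequences = FALSE; no alignment to write")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genomes.fasta"),
    matrilineage = file.path(dir, "matrilineage.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.json"))
  write_mt_alignment(cohort$alignment, paths[["fasta"]])
  utils::write.table(cohort$matrilineage_map, paths[["matrilineage"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pedigree(cohort$pedigree, paths[["pedigree"]])
  utils::write.table(cohort$phenotype, paths[["phenotype"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed,
         config = unclass(cohort$config),
         target = cohort$truth$target,
         subclade = cohort$truth$subclade,
         haplotype_of = as.list(haplotype_of(cohort$haplotypes))),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
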