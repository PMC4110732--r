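test_that("simulation is fully deterministic given (config, seed)", {
  cfg <- sim_config(n_individuals = 120L, n_matrilineages = 15L,
                    missing_frac = 0.1)
  c1 <- simulate_mt_cohort(cfg, seed = 5)
  c2 <- simulate_mt_cohort(cfg, seed = 5)
  expect_identical(c1$reference, c2$reference)
  expect_identical(c1$rep_variant_sets, c2$rep_variant_sets)
  expect_identical(c1$pedigree, c2$pedigree)
  expect_identical(c1$phenotype, c2$phenotype)
  expect_identical(c1$alignment$seqs, c2$alignment$seqs)
  c3 <- simulate_mt_cohort(cfg, seed = 6)
  expect_false(identical(c1$phenotype$copy_number, c3$phenotype$copy_number))
})

test_that("zero mutation rate collapses everyone onto one haplotype", {
  cfg <- sim_config(n_individuals = 50L, n_matrilineages = 8L,
                    mutation_mean = 0, missing_frac = 0)
  co <- simulate_mt_cohort(cfg, seed = 2)
  expect_equal(nrow(co$haplotypes$tab), 1L)
  expect_equal(co$haplotypes$n_total, 50L)
  expect_null(co$network)
  ## all emitted representative rows equal the reference row
  expect_true(all(co$alignment$seqs == co$alignment$seqs[["REF"]]))
})

test_that("pairwise Hamming distances equal path sums on the genealogy", {
  cfg <- sim_config(n_individuals = 60L, n_matrilineages = 20L,
                    mutation_mean = 3, missing_frac = 0)
  co <- simulate_mt_cohort(cfg, seed = 9, sequences = FALSE)
  edges <- co$truth$genealogy
  tips <- co$truth$tip_haplotypes
  ## path-sum oracle on the budding tree (parent 0 = reference root)
  parent <- c(edges$parent)
  depth_muts <- function(m) {
    path <- integer(0)
    while (m != 0L) { path <- c(path, m); m <- parent[m] }
    path
  }
  for (a in c(1L, 5L, 11L)) {
    for (b in c(3L, 8L, 17L)) {
      pa <- depth_muts(a); pb <- depth_muts(b)
      sym <- c(setdiff(pa, pb), setdiff(pb, pa))
      expect_equal(hamming_distance(tips[[a]], tips[[b]]),
                   sum(edges$n_mut[sym]))
    }
  }
})

test_that("matrilineage sizes are long-tailed and sum to the cohort", {
  cfg <- sim_config(n_individuals = 500L, n_matrilineages = 80L)
  co <- simulate_mt_cohort(cfg, seed = 4, sequences = FALSE)
  sizes <- table(co$truth$lineage_of)
  expect_equal(sum(sizes), 500L)
  expect_equal(length(sizes), 80L)
  expect_gte(max(sizes), 10)   # long tail
  expect_equal(min(sizes), 1L)
})

test_that("pedigree is topologically ordered and maternal lines realise matrilineages", {
  cfg <- sim_config(n_individuals = 150L, n_matrilineages = 20L)
  co <- simulate_mt_cohort(cfg, seed = 12, sequences = FALSE)
  ped <- co$pedigree
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  ## children always follow their parents in emitted order
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    ok <- is.na(ref) | pos[ref] < pos[ped$id]
    expect_true(all(ok))
  }
  ## tracing mother links upward reaches the same founder female for all
  ## members of a matrilineage, and different founders across matrilineages
  founder_of <- function(id) {
    repeat {
      m <- ped$mother[match(id, ped$id)]
      if (is.na(m)) return(id)
      id <- m
    }
  }
  cohort <- co$phenotype$id
  fl <- vapply(cohort, founder_of, character(1))
  lineage <- co$truth$lineage_of[cohort]
  expect_equal(length(unique(paste(fl, lineage))), length(unique(lineage)))
  ## map agrees: same representative <=> same maternal founder
  mm <- co$matrilineage_map
  rep_founder <- vapply(mm$representative, founder_of, character(1))
  ind_founder <- vapply(mm$individual, founder_of, character(1))
  expect_equal(unname(rep_founder), unname(ind_founder))
})

test_that("the mtvar pipeline on emitted files recovers the simulated truth", {
  cfg <- sim_config(n_individuals = 80L, n_matrilineages = 12L,
                    mutation_mean = 4, missing_frac = 0)
  co <- simulate_mt_cohort(cfg, seed = 33)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  aln <- read_mt_alignment(paths[["fasta"]], "REF")
  mm <- read_matrilineage_map(paths[["matrilineage"]])
  samples <- setdiff(aln$ids, "REF")
  vs <- lapply(samples, function(s) extract_variants(aln, s)$label)
  names(vs) <- samples
  ## extracted variant sets equal the generator's truth per representative
  for (s in samples) {
    expect_setequal(vs[[s]], co$rep_variant_sets[[s]])
  }
  ht <- collapse_haplotypes(vs, mm)
  expect_identical(ht$tab, co$haplotypes$tab)
  expect_identical(ht$members, co$haplotypes$members)
  ## grouping equals the generator's truth record
  hof <- haplotype_of(ht)
  truth_hof <- haplotype_of(co$haplotypes)
  expect_identical(hof[order(names(hof))], truth_hof[order(names(truth_hof))])
})

test_that("emitted files are byte-identical across runs", {
  cfg <- sim_config(n_individuals = 40L, n_matrilineages = 8L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(simulate_mt_cohort(cfg, seed = 77), d1)
  p2 <- write_cohort(simulate_mt_cohort(cfg, seed = 77), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
})

test_that("noiseless null phenotypes are constant at the intercept", {
  cfg <- sim_config(n_individuals = 40L, n_matrilineages = 8L,
                    gamma_clade = 0, sigma2_g = 0, sigma2_e = 0,
                    beta_age = 0, beta_sex = 0, missing_frac = 0)
  co <- simulate_mt_cohort(cfg, seed = 3, sequences = FALSE)
  mu <- cfg$target_mean
  expect_equal(co$phenotype$copy_number, rep(mu, 40), tolerance = 1e-12)
})

test_that("age and sex effects are recovered by regression", {
  cfg <- sim_config(n_individuals = 2000L, n_matrilineages = 250L,
                    mutation_mean = 1, gamma_clade = 0, sigma2_g = 0,
                    missing_frac = 0)
  co <- simulate_mt_cohort(cfg, seed = 8, sequences = FALSE)
  fit <- stats::lm(copy_number ~ age + sex, data = co$phenotype)
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf["age", 1] - cfg$beta_age), 2 * cf["age", 2])
  expect_lt(abs(cf["sex", 1] - cfg$beta_sex), 2 * cf["sex", 2])
})

test_that("the familial component has covariance 2 sigma2_g K", {
  ## small cohort, many replicates: empirical covariance of g against the
  ## theoretical kinship covariance
  cfg <- sim_config(n_individuals = 30L, n_matrilineages = 4L,
                    gamma_clade = 0, sigma2_g = 0.5, sigma2_e = 0,
                    beta_age = 0, beta_sex = 0, missing_frac = 0)
  set.seed(1)
  co1 <- simulate_mt_cohort(cfg, seed = 1, sequences = FALSE)
  K <- kinship_matrix(co1$pedigree)[co1$phenotype$id, co1$phenotype$id]
  mu <- cfg$target_mean
  G <- sapply(1:400, function(s) {
    co <- simulate_mt_cohort(cfg, seed = 10000 + s, sequences = FALSE)
    co$phenotype$copy_number - mu
  })
  emp <- tcrossprod(G - rowMeans(G)) / (ncol(G) - 1)
  theo <- 2 * cfg$sigma2_g * K
  ## entrywise agreement within Monte-Carlo error: check average absolute
  ## deviation is small relative to the diagonal scale
  expect_lt(mean(abs(emp - theo)), 0.08 * max(diag(theo)))
  ## diagonal specifically: var(g_i) = sigma2_g
  expect_equal(mean(diag(emp)), cfg$sigma2_g, tolerance = 0.15)
})

test_that("target clade respects the configured size range when possible", {
  cfg <- sim_config(n_individuals = 400L, n_matrilineages = 60L,
                    clade_size_range = c(10L, 17L), missing_frac = 0)
  for (s in 1:3) {
    co <- simulate_mt_cohort(cfg, seed = 50 + s, sequences = FALSE)
    tgt <- co$truth$target
    expect_false(is.na(tgt$signature))
    expect_equal(length(tgt$members), tgt$size)
    if (isTRUE(tgt$in_range)) {
      expect_gte(tgt$size, 10L)
      expect_lte(tgt$size, 17L)
    }
    ## members carry exactly the clade's haplotypes
    hof <- haplotype_of(co$haplotypes)
    expect_setequal(unique(hof[tgt$members]), tgt$clade)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_individuals = 5, n_matrilineages = 10),
               "at least")
  expect_error(sim_config(sigma2_g = -1), "variances")
  expect_error(sim_config(missing_frac = 1), "missing_frac")
  expect_error(sim_config(n_matrilineages = 1), "matrilineages")
  ## mutation demand beyond reference capacity
  cfg <- sim_config(n_individuals = 60L, n_matrilineages = 50L,
                    reference_length = 600L, mutation_mean = 20)
  expect_error(simulate_mt_cohort(cfg, seed = 1), "capacity")
})

test_that("full-scale defaults produce the expected cohort shape", {
  co <- simulate_mt_cohort(sim_config(), seed = 1, sequences = FALSE)
  ## ~250-270 unique haplotypes from 274 matrilineages
  expect_gt(nrow(co$haplotypes$tab), 230)
  expect_lte(nrow(co$haplotypes$tab), 274)
  ## ~900 segregating variants
  expect_gt(nrow(co$truth$variants), 750)
  expect_lt(nrow(co$truth$variants), 1100)
  ## background mean near 2.7, missing fraction near 19%
  expect_equal(mean(co$phenotype$copy_number, na.rm = TRUE), 2.7,
               tolerance = 0.08)
  expect_equal(mean(is.na(co$phenotype$copy_number)), 0.19, tolerance = 0.01)
  ## network loop-free by construction of the budding genealogy
  expect_equal(co$network$n_cycles, 0L)
})
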