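## Fit-level behaviour of treescan() on small synthetic cohorts.

fit_cohort <- function(co, n_perm = 200, seed = 7, ...) {
  kin <- kinship_matrix(co$pedigree)
  treescan(copy_number ~ age + sex, data = co$phenotype,
           network = co$network, kinship = kin,
           n_perm = n_perm, seed = seed, ...)
}

test_that("same seed and inputs give a bit-identical scan", {
  co <- small_cohort(seed = 101, n = 200L, m = 25L)
  f1 <- fit_cohort(co)
  f2 <- fit_cohort(co)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("an injected clade effect is recovered as significant", {
  hits <- 0L
  for (s in 1:5) {
    co <- small_cohort(seed = 200 + s, n = 350L, m = 35L, gamma = 1.3,
                       missing = 0.1)
    fit <- fit_cohort(co, round2 = FALSE, condition = FALSE)
    if (co$truth$target$signature %in% fit$significant) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("null cohorts rarely produce significant branches", {
  any_sig <- logical(8)
  for (s in 1:8) {
    co <- small_cohort(seed = 300 + s, n = 250L, m = 30L, gamma = 0)
    fit <- fit_cohort(co, round2 = FALSE, condition = FALSE)
    any_sig[s] <- length(fit$significant) > 0
  }
  expect_lte(sum(any_sig), 2L)
})

test_that("conditioning on a significant branch removes its own signal", {
  co <- small_cohort(seed = 401, n = 350L, m = 35L, gamma = 1.3,
                     missing = 0.1)
  fit <- fit_cohort(co, round2 = FALSE, condition = FALSE)
  sig <- co$truth$target$signature
  expect_true(sig %in% fit$significant)
  ## re-scan with the branch's own indicator among the covariates: its
  ## conditional nominal p should be large (the indicator absorbs the
  ## effect and the branch allele is collinear with it)
  fit2 <- treescan(copy_number ~ age + sex, data = co$phenotype,
                   network = co$network,
                   kinship = kinship_matrix(co$pedigree),
                   n_perm = 200, seed = 7, round2 = FALSE,
                   condition = FALSE, condition_on = sig)
  row <- fit2$summary[fit2$summary$signature == sig, ]
  expect_equal(row$F, 0)
  expect_equal(row$nominal_p, 1)
})

test_that("conditional nominal p is near-uniform after conditioning", {
  ## under repeated simulation, conditioning on the true effect should
  ## leave the branch's conditional p without systematic enrichment at
  ## small values
  ps <- numeric(10)
  for (s in 1:10) {
    co <- small_cohort(seed = 500 + s, n = 250L, m = 25L, gamma = 1.2,
                       missing = 0)
    ## condition on the truth; scan the remaining branches
    fit <- treescan(copy_number ~ age + sex, data = co$phenotype,
                    network = co$network,
                    kinship = kinship_matrix(co$pedigree),
                    n_perm = 100, seed = s, round2 = FALSE,
                    condition = FALSE,
                    condition_on = co$truth$target$signature)
    other <- fit$summary[fit$summary$signature != co$truth$target$signature, ]
    ps[s] <- min(other$corrected_p)
  }
  ## family-wise corrected minimum p below 0.05 should stay rare
  expect_lte(sum(ps < 0.05), 3L)
})

test_that("round-2 subdivides a significant clade and respects min_class", {
  co <- small_cohort(seed = 601, n = 400L, m = 30L, gamma = 1.4,
                     missing = 0)
  fit <- fit_cohort(co, round2 = TRUE, condition = FALSE)
  if (length(fit$significant)) {
    r2 <- fit$round2
    expect_true(!is.null(r2) && nrow(r2) > 0)
    ## subdivisions below the class minimum are flagged untestable with NA p
    small <- r2$n_sub_a < 5 | r2$n_sub_b < 5
    expect_true(all(!r2$testable[small]))
    expect_true(all(is.na(r2$corrected_p[small])))
    ok <- r2$testable
    if (any(ok)) {
      expect_true(all(r2$corrected_p[ok] >= r2$nominal_p[ok] - 1e-12))
      ## sub-classes partition the side they subdivide
      expect_true(all(r2$n_sub_a[ok] + r2$n_sub_b[ok] <=
                        fit$n_complete))
    }
  } else {
    succeed("no significant branch at this seed; round-2 covered elsewhere")
  }
})

test_that("round-2 detects an injected nested heterogeneity", {
  ## a large significant clade containing a shifted sub-clade: the
  ## defining sub-branch should reach the smallest round-2 p in most runs
  wins <- 0L; tried <- 0L
  for (s in 1:6) {
    cfg <- sim_config(n_individuals = 500L, n_matrilineages = 25L,
                      gamma_clade = 1.0, sigma2_g = 0.02,
                      missing_frac = 0,
                      clade_size_range = c(120L, 220L),
                      gamma_subclade = 1.0,
                      subclade_size_range = c(30L, 90L))
    co <- simulate_mt_cohort(cfg, seed = 700 + s, sequences = FALSE)
    if (is.na(co$truth$subclade$signature)) next
    fit <- fit_cohort(co, n_perm = 150, seed = s, round2 = TRUE,
                      condition = FALSE)
    if (!co$truth$target$signature %in% fit$significant) next
    r2 <- fit$round2[fit$round2$parent_signature ==
                       co$truth$target$signature &
                       fit$round2$side == "clade" &
                       fit$round2$testable, ]
    if (is.null(r2) || nrow(r2) == 0) next
    tried <- tried + 1L
    ## the permutation p floors and ties at 1/(B+1), and branches nested
    ## one haplotype away carry nearly the same contrast; require the
    ## defining sub-branch among the top 2 by the continuous statistic
    tm <- sort(strsplit(co$truth$subclade$signature, "|", fixed = TRUE)[[1]])
    top2 <- r2$sub_signature[order(r2$F, decreasing = TRUE)][1:2]
    hit <- any(vapply(top2, function(ss)
      identical(sort(strsplit(ss, "|", fixed = TRUE)[[1]]), tm), logical(1)))
    if (hit) wins <- wins + 1L
    ## and the sub-branch must itself be strongly significant in round 2
    truth_p <- r2$nominal_p[vapply(r2$sub_signature, function(ss)
      identical(sort(strsplit(ss, "|", fixed = TRUE)[[1]]), tm), logical(1))]
    if (length(truth_p)) expect_lt(truth_p[1], 0.2)
  }
  expect_gte(tried, 3L)
  expect_gte(wins, ceiling(0.6 * tried))
})

test_that("missing phenotypes are excluded from tests but kept in membership", {
  co <- small_cohort(seed = 801, n = 250L, m = 30L, missing = 0.2)
  fit <- fit_cohort(co, round2 = FALSE, condition = FALSE)
  n_missing_true <- sum(is.na(co$phenotype$copy_number))
  expect_equal(fit$n_missing, n_missing_true)
  expect_equal(fit$n_complete, 250L - n_missing_true)
  ## network membership counts include everyone
  expect_equal(sum(co$network$nodes$n_total), 250L)
  ## test ns only count complete data
  expect_true(all(fit$summary$n_a + fit$summary$n_b == fit$n_complete))
})

test_that("summary, print, plot and residuals methods work", {
  co <- small_cohort(seed = 901, n = 200L, m = 25L)
  fit <- fit_cohort(co)
  s <- summary(fit)
  expect_s3_class(s, "summary.treescan")
  expect_output(print(fit), "TreeScan")
  expect_output(print(s), "Branch association scan")
  r <- residuals(fit)
  expect_length(r, fit$n_complete)
  expect_equal(unname(sum(r)), 0, tolerance = 1e-8)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("treescan validates its inputs", {
  co <- small_cohort(seed = 1001, n = 120L, m = 15L)
  expect_error(fit_cohort(co, alpha = 1.2), "alpha")
  bad <- co$phenotype; bad$id[1] <- "UNKNOWN"
  expect_error(treescan(copy_number ~ age + sex, data = bad,
                        network = co$network), "haplotype assignment")
  expect_error(treescan(copy_number ~ age + sex,
                        data = within(co$phenotype, rm(id)),
                        network = co$network), "id column")
})
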