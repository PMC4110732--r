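## Branch association statistics and permutation machinery.
##
## Statistic: partial F for adding the branch's allelic-class indicator to
## the covariate-only linear model (1 numerator df). Null distribution:
## Freedman-Lane residual permutation -- residuals of the covariate-only fit
## are permuted, added back to the fitted values, and all branch statistics
## are recomputed on the same permutation, preserving the inter-branch
## correlation that the step-down minP/maxT correction exploits.

.F_TOL <- 1e-10

## Partial F for each column of MA given projected response columns MY.
## MA: n x k covariate-projected allele indicators; MY: n x B projected
## responses; dfres: residual df of the full model.
partial_F_matrix <- function(MA, MY, dfres) {
  sa <- colSums(MA^2)
  rss0 <- colSums(MY^2)
  C <- crossprod(MA, MY)                       # k x B
  expl <- C^2 / ifelse(sa > .F_TOL, sa, Inf)   # zero when allele is collinear
  rss1 <- sweep(-expl, 2, rss0, "+")           # rss0 - expl, columnwise
  Fmat <- expl / (pmax(rss1, 0) / dfres)
  ## 0/0 (collinear allele) -> no evidence -> F = 0
  Fmat[!is.finite(Fmat) & expl < .F_TOL] <- 0
  Fmat[is.nan(Fmat)] <- 0
  ## an (effectively) constant response carries no evidence either
  if (any(zero <- rss0 <= .F_TOL)) Fmat[, zero] <- 0
  Fmat
}

#' Partial F statistic for one branch
#'
#' F statistic (1 numerator df) for adding a binary allelic-class indicator
#' to a linear model already containing the covariates (and an intercept).
#'
#' @param y Numeric phenotype vector, no missing values.
#' @param covariates Numeric matrix of covariates (columns; may be `NULL`
#'   for an intercept-only baseline). An intercept is always included.
#' @param allele 0/1 vector with both classes present.
#' @return Non-negative scalar F.
#' @export
branch_statistic <- function(y, covariates = NULL, allele) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (length(allele) != n) stop("allele and y lengths differ")
  if (length(unique(allele)) < 2L) {
    stop("allele indicator has a single class")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient")
  dfres <- n - ncol(X) - 1L
  if (dfres < 1L) stop("not enough observations for the model")
  MY <- qr.resid(qrX, matrix(y, ncol = 1))
  MA <- qr.resid(qrX, matrix(as.numeric(allele), ncol = 1))
  as.numeric(partial_F_matrix(MA, MY, dfres))
}

## Partial F for each allele column given the fixed covariates plus ONE
## extra covariate column that differs per permutation (e.g. a recomputed
## familial adjustment score). A0 (n x k) and the columns of E (n x B) and
## Phi (n x B) are already residualised on the fixed covariates; the extra
## column enters via a rank-one update.
partial_F_one_extra <- function(A0, sa0, E, Phi, dfres) {
  su <- colSums(Phi^2)
  scale <- ifelse(su > .F_TOL, 1 / sqrt(su), 0)   # drop degenerate column
  U <- sweep(Phi, 2, scale, "*")
  CU <- crossprod(A0, U)                          # k x B
  CE <- crossprod(A0, E)                          # k x B
  uE <- colSums(U * E)                            # B
  C <- CE - sweep(CU, 2, uE, "*")
  SA <- sa0 - CU^2
  RSS0 <- colSums(E^2) - uE^2
  expl <- C^2 / ifelse(SA > .F_TOL, SA, Inf)
  RSS1 <- sweep(-expl, 2, RSS0, "+")
  Fmat <- expl / (pmax(RSS1, 0) / dfres)
  Fmat[!is.finite(Fmat) & expl < .F_TOL] <- 0
  Fmat[is.nan(Fmat)] <- 0
  if (any(zero <- RSS0 <= .F_TOL)) Fmat[, zero] <- 0
  Fmat
}

#' Permutation scan over a set of branches
#'
#' Computes the observed partial F for every allele column and a
#' branches-by-permutations null matrix under Freedman-Lane residual
#' permutation (residuals of the covariate-only model are permuted, added
#' back to the fitted values, and all branch statistics recomputed on the
#' same permutation, preserving inter-branch correlation), plus add-one
#' nominal p-values `(1 + #\{T* >= T_obs\}) / (n_perm + 1)`.
#'
#' A covariate that is itself a function of the phenotype -- the familial
#' adjustment score -- must not be held fixed while the phenotype is
#' permuted; supply it through `recompute`, and it is re-derived from each
#' permuted pseudo-phenotype so that observed and null statistics treat it
#' symmetrically.
#'
#' @param y Numeric phenotype vector (complete cases only).
#' @param covariates Fixed covariate matrix or `NULL`; an intercept is
#'   always included.
#' @param alleles n x k matrix of 0/1 allelic-class indicators, one column
#'   per branch.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param perm_within Optional integer/factor of length n: permutations
#'   shuffle residuals only within levels of this grouping (used by the
#'   conditional round-2 scan). Default: one global group.
#' @param recompute Optional function taking an n x B matrix of
#'   (pseudo-)phenotype columns and returning an n x B matrix of a
#'   phenotype-derived covariate, re-evaluated per permutation.
#' @param familial Optional whitening transform from [familial_transform()]:
#'   the phenotype, covariates (including the intercept) and allele
#'   indicators are all rotated into the whitened space `Winv %*% .`, where
#'   residuals are exchangeable under the familial null; the statistic
#'   becomes the generalised-least-squares partial F and permutation
#'   operates on the whitened residuals. This keeps the null valid under
#'   kinship-structured noise without inflating it when the variance
#'   components are over-estimated (observed and null statistics shrink
#'   together).
#' @return List with `F_obs` (length k), `F_null` (k x n_perm),
#'   `p_nominal` (length k), `n_perm`, `seed`.
#' @export
permutation_scan <- function(y, covariates = NULL, alleles,
                             n_perm = 10000L, seed = 1L,
                             perm_within = NULL, recompute = NULL,
                             familial = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  n <- length(y)
  alleles <- as.matrix(alleles)
  stopifnot(nrow(alleles) == n)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  A <- alleles
  yy <- y
  if (!is.null(familial)) {                   # rotate into whitened space
    X <- familial$Winv %*% X
    A <- familial$Winv %*% A
    yy <- as.numeric(familial$Winv %*% y)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient")
  dfres <- n - ncol(X) - 1L - (!is.null(recompute))
  if (dfres < 1L) stop("not enough observations for the model")

  MA <- qr.resid(qrX, A)
  e <- qr.resid(qrX, matrix(yy, ncol = 1))    # whitened-model residuals
  fitted <- yy - as.numeric(e)

  ## permutation index matrix (optionally stratified)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  groups <- if (is.null(perm_within)) rep(1L, n) else as.integer(as.factor(perm_within))
  idx_by_group <- split(seq_len(n), groups)
  P <- matrix(seq_len(n), nrow = n, ncol = n_perm)
  for (b in seq_len(n_perm)) {
    for (g in idx_by_group) {
      if (length(g) > 1L) P[g, b] <- g[sample.int(length(g))]
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  Eperm <- matrix(e[P], nrow = n)             # permuted (whitened) residuals
  MEperm <- qr.resid(qrX, Eperm)              # re-project (Freedman-Lane)

  if (is.null(recompute)) {
    F_obs <- as.numeric(partial_F_matrix(MA, e, dfres))
    F_null <- partial_F_matrix(MA, MEperm, dfres)
  } else {
    ## the recomputed covariate is a function of the RAW phenotype; map
    ## pseudo-phenotypes back before evaluating it, then rotate the column
    sa0 <- colSums(MA^2)
    raw_of <- function(Ym) if (is.null(familial)) Ym else familial$W %*% Ym
    rotate <- function(Fm) if (is.null(familial)) Fm else familial$Winv %*% Fm
    phi_obs <- qr.resid(qrX, rotate(recompute(matrix(y, ncol = 1))))
    F_obs <- as.numeric(partial_F_one_extra(MA, sa0, e, phi_obs, dfres))
    Ystar_raw <- raw_of(fitted + Eperm)       # pseudo-phenotypes, raw scale
    Phi <- qr.resid(qrX, rotate(recompute(Ystar_raw)))
    F_null <- partial_F_one_extra(MA, sa0, MEperm, Phi, dfres)
  }
  if (is.null(dim(F_null))) F_null <- matrix(F_null, nrow = ncol(alleles))

  p_nominal <- (1 + rowSums(F_null >= F_obs - .F_TOL)) / (n_perm + 1)
  list(F_obs = F_obs, F_null = F_null, p_nominal = p_nominal,
       n_perm = n_perm, seed = seed)
}

#' Step-down minP/maxT corrected p-values
#'
#' Permutation analogue of the sequential step-down Bonferroni: branches are
#' ordered by decreasing observed statistic; the branch of rank r is
#' compared against the permutation distribution of the maximum statistic
#' over all branches of rank >= r, and monotonicity
#' (corrected p non-decreasing in rank) is enforced.
#'
#' @param F_obs Observed statistics (length k).
#' @param F_null k x n_perm null matrix, rows aligned with `F_obs`.
#' @return Corrected p-values aligned with `F_obs`; always at least the
#'   add-one nominal p-value.
#' @export
stepdown_correction <- function(F_obs, F_null) {
  F_null <- as.matrix(F_null)
  k <- length(F_obs)
  if (nrow(F_null) != k) {
    stop("F_null must have one row per observed statistic (",
         nrow(F_null), " rows for ", k, " statistics)")
  }
  B <- ncol(F_null)
  ord <- order(F_obs, decreasing = TRUE)      # rank 1 = most significant
  corrected <- numeric(k)
  running_max <- rep(-Inf, B)
  for (r in rev(seq_len(k))) {                # least significant first
    i <- ord[r]
    running_max <- pmax(running_max, F_null[i, ])
    corrected[i] <- (1 + sum(running_max >= F_obs[i] - .F_TOL)) / (B + 1)
  }
  ## enforce monotone non-decreasing corrected p along decreasing rank
  for (r in seq_len(k)[-1]) {
    corrected[ord[r]] <- max(corrected[ord[r]], corrected[ord[r - 1]])
  }
  corrected
}

#' Familial whitening transform for permutation under related samples
#'
#' Residuals of related individuals are not exchangeable: the familial
#' component induces covariance `V = sigma2_g * 2K + sigma2_e * I`.
#' This estimates the variance components by REML (one-dimensional profile
#' likelihood after rotating into the eigenbasis of `2K`) and returns the
#' symmetric square roots `W = V^{1/2}` and `Winv = V^{-1/2}` (up to an
#' irrelevant scale): permuting the whitened residuals `Winv e` and
#' re-colouring with `W` yields pseudo-residuals with the correct familial
#' covariance, so the permutation null is valid under kinship-structured
#' noise. With `sigma2_g = 0` the transform is the identity and the scheme
#' reduces to plain residual permutation.
#'
#' @param y Phenotype vector (complete cases).
#' @param covariates Fixed covariate matrix (or `NULL`); an intercept is
#'   always included in the null model.
#' @param kinship Kinship matrix over the same individuals, in the same
#'   order.
#' @return List with `W`, `Winv`, `h2` (estimated share of familial
#'   variance) and `sigma2` (total variance estimate).
#' @export
familial_transform <- function(y, covariates = NULL, kinship) {
  n <- length(y)
  stopifnot(nrow(kinship) == n)
  A <- 2 * kinship
  eig <- eigen(A, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  Xr <- crossprod(U, cbind(1, covariates))
  yr <- as.numeric(crossprod(U, y))
  p <- ncol(Xr)

  reml_crit <- function(h) {
    w <- (1 - h) + h * lam
    sw <- 1 / w
    XtWX <- crossprod(Xr, Xr * sw)
    beta <- solve(XtWX, crossprod(Xr, yr * sw))
    r <- yr - as.numeric(Xr %*% beta)
    s2 <- sum(r^2 * sw) / (n - p)
    as.numeric(0.5 * ((n - p) * log(s2) + sum(log(w)) +
                        determinant(XtWX, logarithm = TRUE)$modulus))
  }
  opt <- stats::optimize(reml_crit, c(1e-6, 1 - 1e-6))
  h <- opt$minimum
  w <- (1 - h) + h * lam
  sw <- 1 / w
  XtWX <- crossprod(Xr, Xr * sw)
  beta <- solve(XtWX, crossprod(Xr, yr * sw))
  r <- yr - as.numeric(Xr %*% beta)
  s2 <- sum(r^2 * sw) / (n - p)
  list(W = U %*% (sqrt(w) * t(U)),
       Winv = U %*% (t(U) / sqrt(w)),
       h2 = h, sigma2 = s2)
}

#' Allelic-class membership matrix for a set of branches
#'
#' For each branch, individuals whose haplotype lies in the branch's clade
#' (`side_a`) get 1, all others 0.
#'
#' @param branches Branch data frame from [enumerate_branches()].
#' @param hap_of Named vector individual id -> haplotype id (see
#'   [haplotype_of()]).
#' @param ids Individual ids (rows of the returned matrix).
#' @return Length(ids) x nrow(branches) 0/1 matrix.
#' @export
branch_membership <- function(branches, hap_of, ids) {
  A <- matrix(0L, nrow = length(ids), ncol = nrow(branches),
              dimnames = list(ids, NULL))
  hap <- hap_of[ids]
  for (b in seq_len(nrow(branches))) {
    A[, b] <- as.integer(hap %in% branches$clade[[b]])
  }
  A
}

#' Filter branches to testable contrasts
#'
#' A branch is testable when both of its allelic classes contain at least
#' `min_class` individuals with complete phenotype data.
#'
#' @param branches Branch data frame.
#' @param hap_of Named vector individual id -> haplotype id.
#' @param complete_ids Ids of individuals with complete phenotype data.
#' @param min_class Minimum class size (default 5).
#' @return `branches` with added columns `n_a`, `n_b`, `testable`, keeping
#'   only testable rows.
#' @export
filter_testable <- function(branches, hap_of, complete_ids, min_class = 5L) {
  A <- branch_membership(branches, hap_of, complete_ids)
  n_a <- colSums(A)
  n_b <- length(complete_ids) - n_a
  branches$n_a <- as.integer(n_a)
  branches$n_b <- as.integer(n_b)
  branches$testable <- n_a >= min_class & n_b >= min_class
  branches[branches$testable, , drop = FALSE]
}
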