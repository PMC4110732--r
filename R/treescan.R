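## The user-facing model fit: scan every branch of the haplotype network for
## association between its bipartition and a continuous phenotype, adjusted
## for covariates.

#' TreeScan a haplotype network for phenotype association
#'
#' Tests every branch bipartition of a haplotype network for association
#' with a continuous phenotype (e.g. relative mtDNA copy number), adjusted
#' for covariates such as age, sex and the familial adjustment score.
#' Nominal p-values come from Freedman-Lane residual permutations; a
#' step-down minP/maxT permutation correction controls the family-wise error
#' over branches; branches with corrected p below `alpha` are declared
#' significant. Optionally, each significant branch is (a) re-scanned with
#' the other significant branches' indicators as additional covariates to
#' label statistically separate effects, and (b) subjected to a conditional
#' second scanning round that looks for phenotypic heterogeneity inside each
#' of its two allelic classes (a three-allele system: one class held
#' constant, the other subdivided by each branch interior to it, with
#' permutations restricted to the subdivided class).
#'
#' Networks with unresolved loops are scanned once per loop resolution; the
#' cross-resolution summary reports, for each distinct bipartition, the
#' maximum corrected p-value over the resolutions in which it occurs
#' (conservative).
#'
#' @param formula Model formula, phenotype on the left, fixed covariates on
#'   the right, e.g. `copy_number ~ age + sex`.
#' @param data Data frame containing the model variables and an id column
#'   linking rows to individuals in the haplotype table. Rows with a missing
#'   value in any model variable are excluded listwise.
#' @param network A `"haplotype_network"` from [build_haplotype_network()].
#' @param kinship Optional kinship matrix (from [kinship_matrix()]) covering
#'   the individuals in `data`. When supplied, the test adjusts for
#'   familial relationships by whitening: the variance components of
#'   `V = sigma2_g 2K + sigma2_e I` are estimated by REML (with the
#'   strongest pre-scan branches in the mean model, so a genuine clade
#'   effect does not masquerade as familial variance) and phenotype,
#'   covariates and allele indicators are rotated by `V^{-1/2}` before the
#'   permutation scan; see [familial_transform()].
#' @param fas_covariate Also include the familial adjustment score as a
#'   covariate (requires `kinship`)? Because the score is a function of the
#'   phenotype it is recomputed from each permuted pseudo-phenotype rather
#'   than held fixed (holding it fixed invalidates the permutation null).
#'   Default `FALSE`: the score partially absorbs genuine clade effects --
#'   mtDNA effects are themselves matrilineally structured -- and the
#'   whitened permutation already accounts for relatedness.
#' @param id_col Name of the individual-id column in `data` (default
#'   `"id"`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed; the same seed, inputs and options give a
#'   bit-identical result.
#' @param min_class Minimum complete-data individuals per allelic class for
#'   a branch to be testable (default 5).
#' @param alpha Family-wise significance level on corrected p (default
#'   0.05).
#' @param max_resolutions Cap on loop resolutions (default 64).
#' @param log_transform Scan `log(phenotype)` instead of the raw phenotype?
#'   Default `FALSE`.
#' @param condition Re-scan each significant branch conditioning on the
#'   other significant branches? Default `TRUE`.
#' @param round2 Run the conditional second round inside significant
#'   branches? Default `TRUE`.
#' @param condition_on Optional character vector of bipartition signatures
#'   (or a logical/0-1 indicator matrix over individuals) added to the
#'   covariates of every test, e.g. to condition the whole scan on an
#'   already-established branch.
#' @return An object of class `"treescan"`; see [summary.treescan()].
#' @export
treescan <- function(formula, data, network, kinship = NULL, id_col = "id",
                     n_perm = 10000L, seed = 1L, min_class = 5L,
                     alpha = 0.05, max_resolutions = 64L,
                     log_transform = FALSE, fas_covariate = FALSE,
                     condition = TRUE, round2 = TRUE,
                     condition_on = NULL) {
  stopifnot(inherits(network, "haplotype_network"))
  if (!id_col %in% names(data)) stop("id column '", id_col, "' not in data")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  ids_all <- as.character(data[[id_col]])
  hap_of <- haplotype_of(network$haplotypes)
  unknown <- setdiff(ids_all, names(hap_of))
  if (length(unknown)) {
    stop("individuals in data without a haplotype assignment: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  complete <- stats::complete.cases(mf)
  ids <- ids_all[complete]
  y <- stats::model.response(mf)[complete]
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires a strictly positive phenotype")
    y <- log(y)
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                           mf[complete, , drop = FALSE])
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]

  extra <- NULL
  if (!is.null(condition_on)) {
    extra <- condition_matrix(condition_on, hap_of, ids, network)
    X <- cbind(X, extra)
  }

  if (fas_covariate && is.null(kinship)) {
    stop("fas_covariate = TRUE requires a kinship matrix")
  }

  resolutions <- enumerate_resolutions(network, max_resolutions)

  recompute <- NULL
  familial <- NULL
  if (!is.null(kinship)) {
    if (fas_covariate) recompute <- fas_recompute_fn(kinship, ids, y)
    ## two-stage variance components: a quick unadjusted pre-scan picks the
    ## strongest branches, whose indicators enter the REML mean model so a
    ## real clade effect is not mistaken for familial variance
    pre_br <- enumerate_branches(network, resolutions[[1]], resolution_id = 1L)
    pre_br <- filter_testable(pre_br, hap_of, ids, min_class)
    Xlead <- NULL
    if (nrow(pre_br)) {
      Apre <- branch_membership(pre_br, hap_of, ids)
      Fpre <- vapply(seq_len(ncol(Apre)), function(b)
        tryCatch(branch_statistic(y, X, Apre[, b]), error = function(e) 0),
        numeric(1))
      top <- order(Fpre, decreasing = TRUE)[seq_len(min(3L, ncol(Apre)))]
      Xlead <- Apre[, top, drop = FALSE]
    }
    familial <- familial_transform(y, drop_dependent_columns(cbind(X, Xlead)),
                                   kinship[ids, ids, drop = FALSE])
  }

  res_list <- vector("list", length(resolutions))
  for (r in seq_along(resolutions)) {
    branches <- enumerate_branches(network, resolutions[[r]], resolution_id = r)
    branches <- filter_testable(branches, hap_of, ids, min_class)
    res_list[[r]] <- scan_one_resolution(branches, y, X, hap_of, ids,
                                         n_perm, seed + r - 1L, recompute,
                                         familial)
  }

  summary_tab <- summarise_resolutions(res_list, y, hap_of, ids)
  significant <- summary_tab$signature[summary_tab$corrected_p < alpha]

  conditional <- NULL
  if (condition && length(significant) > 1L) {
    conditional <- condition_rescan(summary_tab, significant, res_list,
                                    y, X, hap_of, ids, n_perm, seed, alpha,
                                    recompute, familial)
  } else if (condition && length(significant) == 1L) {
    conditional <- data.frame(signature = significant,
                              conditional_corrected_p =
                                summary_tab$corrected_p[
                                  summary_tab$signature == significant],
                              separate = TRUE, stringsAsFactors = FALSE)
  }

  round2_res <- NULL
  if (round2 && length(significant)) {
    round2_res <- do.call(rbind, lapply(significant, function(sig) {
      scan_round2(sig, summary_tab, res_list, network, y, X, hap_of, ids,
                  n_perm, seed, min_class, kinship)
    }))
  }

  structure(
    list(call = match.call(), formula = formula,
         results = res_list, summary = summary_tab,
         significant = significant, conditional = conditional,
         round2 = round2_res,
         n_resolutions = length(resolutions),
         n_perm = n_perm, seed = seed, alpha = alpha,
         min_class = min_class, log_transform = log_transform,
         n_individuals = length(ids_all), n_complete = length(ids),
         n_missing = length(ids_all) - length(ids),
         ids = ids, y = y, X = X, hap_of = hap_of[ids]),
    class = "treescan"
  )
}

## The familial adjustment score of the complete-case cohort as a function
## of a (pseudo-)phenotype matrix, for per-permutation recomputation.
## Denominators are floored at 2% of the observed mean so a permuted
## pseudo-phenotype straying to ~0 cannot produce an unbounded covariate.
fas_recompute_fn <- function(kinship, ids, y_obs) {
  absent <- setdiff(ids, rownames(kinship))
  if (length(absent)) {
    stop("individuals missing from kinship matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  Km <- kinship[ids, ids, drop = FALSE]
  d <- diag(Km)
  N <- length(ids)
  floor_val <- 0.02 * abs(mean(y_obs))
  function(Y) {
    Y <- as.matrix(Y)
    num <- Km %*% Y - d * Y         # exclude the self term
    num / (N * pmax(Y, floor_val))
  }
}

## Scan the testable branches of one resolution.
scan_one_resolution <- function(branches, y, X, hap_of, ids, n_perm, seed,
                                recompute = NULL, familial = NULL) {
  if (nrow(branches) == 0L) {
    branches$F <- numeric(0); branches$nominal_p <- numeric(0)
    branches$corrected_p <- numeric(0)
    branches$mean_a <- numeric(0); branches$mean_b <- numeric(0)
    branches$signature <- character(0)
    return(list(branches = branches, F_null = NULL))
  }
  A <- branch_membership(branches, hap_of, ids)
  scan <- permutation_scan(y, X, A, n_perm = n_perm, seed = seed,
                           recompute = recompute, familial = familial)
  corrected <- stepdown_correction(scan$F_obs, scan$F_null)
  branches$F <- scan$F_obs
  branches$nominal_p <- scan$p_nominal
  branches$corrected_p <- corrected
  branches$mean_a <- vapply(seq_len(ncol(A)),
                            function(b) mean(y[A[, b] == 1L]), numeric(1))
  branches$mean_b <- vapply(seq_len(ncol(A)),
                            function(b) mean(y[A[, b] == 0L]), numeric(1))
  branches$signature <- vapply(branches$clade, bipartition_signature,
                               character(1))
  list(branches = branches, F_null = scan$F_null)
}

## A bipartition is identified by the sorted clade haplotype ids.
bipartition_signature <- function(clade) paste(sort(clade), collapse = "|")

## Cross-resolution summary: one row per distinct bipartition; corrected p
## is the maximum over the resolutions in which the bipartition occurs.
summarise_resolutions <- function(res_list, y, hap_of, ids) {
  all_b <- do.call(rbind, lapply(res_list, function(r)
    r$branches[, c("signature", "resolution_id", "branch_id", "n_variants",
                   "n_a", "n_b", "mean_a", "mean_b", "F",
                   "nominal_p", "corrected_p")]))
  if (is.null(all_b) || nrow(all_b) == 0L) {
    return(data.frame(signature = character(0), branch_id = integer(0),
                      resolution_id = integer(0), n_resolutions = integer(0),
                      n_variants = integer(0), n_a = integer(0),
                      n_b = integer(0), mean_a = numeric(0),
                      mean_b = numeric(0), F = numeric(0),
                      nominal_p = numeric(0), corrected_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sigs <- unique(all_b$signature)
  rows <- lapply(sigs, function(s) {
    sub <- all_b[all_b$signature == s, , drop = FALSE]
    worst <- which.max(sub$corrected_p)
    data.frame(signature = s,
               branch_id = sub$branch_id[1],
               resolution_id = sub$resolution_id[1],
               n_resolutions = nrow(sub),
               n_variants = sub$n_variants[1],
               n_a = sub$n_a[1], n_b = sub$n_b[1],
               mean_a = sub$mean_a[1], mean_b = sub$mean_b[1],
               F = sub$F[1],
               nominal_p = max(sub$nominal_p),
               corrected_p = sub$corrected_p[worst],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$corrected_p, -out$F), , drop = FALSE]
}

## Indicator columns over `ids` for bipartition signatures (or pass-through
## numeric matrix).
condition_matrix <- function(condition_on, hap_of, ids, network) {
  if (is.matrix(condition_on) || is.data.frame(condition_on)) {
    m <- as.matrix(condition_on)
    stopifnot(nrow(m) == length(ids))
    return(m)
  }
  sapply(condition_on, function(sig) {
    clade <- strsplit(sig, "|", fixed = TRUE)[[1]]
    as.integer(hap_of[ids] %in% clade)
  })
}

## Re-scan every branch conditioning, for each significant bipartition, on
## the indicators of the other significant bipartitions; an effect is
## "statistically separate" when it stays significant.
condition_rescan <- function(summary_tab, significant, res_list, y, X,
                             hap_of, ids, n_perm, seed, alpha,
                             recompute = NULL, familial = NULL) {
  rows <- lapply(seq_along(significant), function(s) {
    sig <- significant[s]
    others <- setdiff(significant, sig)
    Xc <- cbind(X, condition_matrix(others, hap_of, ids, NULL))
    ## re-run each resolution containing this bipartition; take max corrected p
    ps <- c()
    for (r in seq_along(res_list)) {
      br <- res_list[[r]]$branches
      if (!nrow(br) || !sig %in% br$signature) next
      A <- branch_membership(br, hap_of, ids)
      sc <- permutation_scan(y, Xc, A, n_perm = n_perm,
                             seed = seed + 1000L + r,
                             recompute = recompute, familial = familial)
      corr <- stepdown_correction(sc$F_obs, sc$F_null)
      ps <- c(ps, corr[br$signature == sig])
    }
    data.frame(signature = sig,
               conditional_corrected_p = max(ps),
               separate = max(ps) < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Conditional second round for one significant bipartition: for each of its
## two allelic classes, every branch lying strictly inside that class
## subdivides it into two sub-alleles; the other class is held constant and
## permutations shuffle residuals only within the subdivided class.
## Step-down correction is applied within each (branch, side) family.
scan_round2 <- function(sig, summary_tab, res_list, network, y, X,
                        hap_of, ids, n_perm, seed, min_class,
                        kinship = NULL) {
  clade <- strsplit(sig, "|", fixed = TRUE)[[1]]
  all_haps <- network$nodes$haplotype_id
  sides <- list(clade = clade, other = setdiff(all_haps, clade))

  out <- list()
  for (r in seq_along(res_list)) {
    br <- res_list[[r]]$branches
    if (!nrow(br) || !sig %in% br$signature) next
    full_br <- enumerate_branches(network,
                                  resolution = attr_resolution(res_list, r, network),
                                  resolution_id = r)
    for (side_name in names(sides)) {
      side <- sides[[side_name]]
      in_side <- ids[hap_of[ids] %in% side]
      ## branches strictly interior to this side: their clade is a proper
      ## non-empty subset of the side's haplotypes
      interior <- vapply(full_br$clade, function(cl) {
        sub <- intersect(cl, side)
        length(sub) > 0L && length(sub) < length(side) &&
          (all(cl %in% side) || all(setdiff(all_haps, cl) %in% side))
      }, logical(1))
      cand <- full_br[interior, , drop = FALSE]
      if (!nrow(cand)) next
      ## sub-allele membership within the side
      A <- matrix(0L, nrow = length(in_side), ncol = nrow(cand))
      keep <- logical(nrow(cand))
      n_sub_a <- integer(nrow(cand)); n_sub_b <- integer(nrow(cand))
      for (b in seq_len(nrow(cand))) {
        cl <- cand$clade[[b]]
        sub <- if (all(cl %in% side)) cl else setdiff(all_haps, cl)
        sub <- intersect(sub, side)
        A[, b] <- as.integer(hap_of[in_side] %in% sub)
        n_sub_a[b] <- sum(A[, b]); n_sub_b[b] <- length(in_side) - n_sub_a[b]
        keep[b] <- n_sub_a[b] >= min_class && n_sub_b[b] >= min_class
      }
      res_rows <- data.frame(parent_signature = sig, side = side_name,
                             resolution_id = r,
                             branch_id = cand$branch_id,
                             n_sub_a = n_sub_a, n_sub_b = n_sub_b,
                             testable = keep,
                             F = NA_real_, nominal_p = NA_real_,
                             corrected_p = NA_real_,
                             stringsAsFactors = FALSE)
      res_rows$sub_signature <- vapply(seq_len(nrow(cand)), function(b) {
        cl <- cand$clade[[b]]
        sub <- if (all(cl %in% side)) cl else setdiff(all_haps, cl)
        bipartition_signature(intersect(sub, side))
      }, character(1))
      ## collapse duplicate subdivisions (the same sub-clade can be induced
      ## by the edge on either side of a latent chain only once; but two
      ## tree edges can induce complementary cuts of the side)
      dup <- duplicated(res_rows$sub_signature)
      res_rows <- res_rows[!dup, , drop = FALSE]
      A <- A[, !dup, drop = FALSE]
      keep <- res_rows$testable
      if (any(keep)) {
        side_idx <- match(in_side, ids)
        yy <- y[side_idx]
        XX <- drop_dependent_columns(X[side_idx, , drop = FALSE])
        rc <- if (!is.null(kinship)) {
          ## the score is defined over the whole cohort; only the permuted
          ## class's rows of the pseudo-phenotype vary
          base <- fas_recompute_fn(kinship, ids, y)
          function(Ys) {
            Ys <- as.matrix(Ys)
            Yfull <- matrix(y, nrow = length(ids), ncol = ncol(Ys))
            Yfull[side_idx, ] <- Ys
            base(Yfull)[side_idx, , drop = FALSE]
          }
        } else NULL
        fam_side <- if (!is.null(kinship)) {
          ## two-stage as in round 1: strongest sub-branches join the REML
          ## mean model so within-class heterogeneity is not soaked up as
          ## familial variance
          Fpre <- vapply(which(keep), function(b)
            tryCatch(branch_statistic(yy, XX, A[, b]), error = function(e) 0),
            numeric(1))
          lead <- which(keep)[order(Fpre, decreasing = TRUE)]
          lead <- lead[seq_len(min(3L, length(lead)))]
          familial_transform(yy,
                             drop_dependent_columns(
                               cbind(XX, A[, lead, drop = FALSE])),
                             kinship[in_side, in_side, drop = FALSE])
        } else NULL
        sc <- permutation_scan(yy, XX, A[, keep, drop = FALSE],
                               n_perm = n_perm,
                               seed = seed + 5000L + 10L * r +
                                 as.integer(side_name == "other"),
                               recompute = rc, familial = fam_side)
        corr <- stepdown_correction(sc$F_obs, sc$F_null)
        res_rows$F[keep] <- sc$F_obs
        res_rows$nominal_p[keep] <- sc$p_nominal
        res_rows$corrected_p[keep] <- corr
      }
      out[[length(out) + 1L]] <- res_rows
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## Drop covariate columns that are constant or linearly dependent (given an
## intercept) on a subset of individuals, e.g. inside a small clade.
drop_dependent_columns <- function(X) {
  if (is.null(X) || ncol(X) == 0L) return(NULL)
  Xi <- cbind(1, X)
  q <- qr(Xi)
  keep <- sort(q$pivot[seq_len(q$rank)])
  keep <- setdiff(keep, 1L) - 1L    # drop the intercept slot
  if (!length(keep)) return(NULL)
  X[, keep, drop = FALSE]
}

## Recover the retained edge-index vector of resolution r. Stored branches
## only keep testable rows, so re-derive from the network when loop-free,
## otherwise re-enumerate.
attr_resolution <- function(res_list, r, network) {
  if (network$n_cycles == 0L) return(seq_len(nrow(network$edges)))
  enumerate_resolutions(network)[[r]]
}
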