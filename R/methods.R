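#' @export
print.treescan <- function(x, ...) {
  cat("TreeScan of a haplotype network\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  individuals: ", x$n_individuals, " (", x$n_missing,
      " with missing phenotype data)\n", sep = "")
  cat("  resolutions: ", x$n_resolutions,
      "; permutations: ", x$n_perm, "; seed: ", x$seed, "\n", sep = "")
  cat("  testable bipartitions: ", nrow(x$summary), "\n", sep = "")
  if (length(x$significant)) {
    cat("  significant (corrected p < ", x$alpha, "): ",
        length(x$significant), "\n", sep = "")
    sig <- x$summary[x$summary$signature %in% x$significant, ]
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    branch %d (res %d): n=%d vs %d, means %.2f vs %.2f, corrected p=%.2g\n",
                  sig$branch_id[i], sig$resolution_id[i], sig$n_a[i],
                  sig$n_b[i], sig$mean_a[i], sig$mean_b[i],
                  sig$corrected_p[i]))
    }
  } else {
    cat("  no significant branches at corrected p < ", x$alpha, "\n", sep = "")
  }
  invisible(x)
}

#' Summarise a TreeScan fit
#'
#' @param object A `"treescan"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.treescan"` wrapping the
#'   cross-resolution branch table, the significant set, the conditioning
#'   re-scan and the round-2 results.
#' @export
summary.treescan <- function(object, ...) {
  structure(
    list(branches = object$summary,
         significant = object$significant,
         conditional = object$conditional,
         round2 = object$round2,
         alpha = object$alpha, n_perm = object$n_perm,
         n_individuals = object$n_individuals,
         n_missing = object$n_missing,
         n_resolutions = object$n_resolutions),
    class = "summary.treescan")
}

#' @export
print.summary.treescan <- function(x, ...) {
  cat("Branch association scan (", x$n_resolutions, " resolution(s), ",
      x$n_perm, " permutations)\n", sep = "")
  cat(x$n_individuals, " individuals, ", x$n_missing,
      " excluded for missing data\n\n", sep = "")
  tab <- x$branches
  show <- tab[, c("branch_id", "resolution_id", "n_variants", "n_a", "n_b",
                  "mean_a", "mean_b", "F", "nominal_p", "corrected_p")]
  print(utils::head(show, 15), row.names = FALSE, digits = 4)
  if (nrow(show) > 15) cat("... (", nrow(show) - 15, " more branches)\n", sep = "")
  cat("\nSignificant bipartitions: ", length(x$significant), "\n", sep = "")
  if (!is.null(x$conditional) && nrow(x$conditional)) {
    cat("\nConditioning re-scan (each significant branch adjusted for the others):\n")
    print(x$conditional, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$round2) && nrow(x$round2)) {
    cat("\nRound-2 conditional scan (within-class heterogeneity):\n")
    show2 <- x$round2[, c("parent_signature", "side", "branch_id",
                          "n_sub_a", "n_sub_b", "testable",
                          "F", "nominal_p", "corrected_p")]
    show2$parent_signature <- substr(show2$parent_signature, 1, 24)
    print(utils::head(show2, 15), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Residuals of the covariate-only model underlying a TreeScan
#'
#' @param object A `"treescan"` fit.
#' @param ... Unused.
#' @return Named numeric vector of residuals of the phenotype on the
#'   covariates (complete cases only), the quantities the permutation null
#'   shuffles.
#' @export
residuals.treescan <- function(object, ...) {
  X <- cbind(1, object$X)
  stats::setNames(as.numeric(qr.resid(qr(X), matrix(object$y, ncol = 1))),
                  object$ids)
}

#' Plot phenotype distributions for significant clades
#'
#' Box plots of the phenotype inside each significant clade against the rest
#' of the cohort, mirroring the usual presentation of TreeScan contrasts.
#'
#' @param x A `"treescan"` fit.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.treescan <- function(x, ...) {
  groups <- rep("rest", length(x$y))
  if (length(x$significant)) {
    for (i in seq_along(x$significant)) {
      clade <- strsplit(x$significant[i], "|", fixed = TRUE)[[1]]
      sig_row <- x$summary[x$summary$signature == x$significant[i], ]
      lab <- paste0("branch ", sig_row$branch_id[1])
      groups[x$hap_of %in% clade] <- lab
    }
  }
  graphics::boxplot(x$y ~ factor(groups),
                    xlab = "clade", ylab = "phenotype", ...)
  invisible(x)
}
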