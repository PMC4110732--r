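## End-to-end orchestration: alignment -> variants -> haplotypes -> network
## -> kinship/FAS -> branch scan -> report files.

#' Run the full association pipeline
#'
#' Reads the aligned genomes, matrilineage map, pedigree and phenotype
#' table (or takes them from an in-memory synthetic cohort), extracts
#' variants, collapses haplotypes, builds the network, computes kinship and
#' familial adjustment scores, scans every branch (round 1, conditioning
#' re-scan, round 2 inside significant branches) and writes the result
#' files plus a run manifest.
#'
#' @param config A list (or path to a YAML file) with entries: either
#'   `fasta`, `reference_id`, `matrilineage`, `pedigree`, `phenotype`
#'   (file paths), or `cohort` (an `"mt_cohort"` object); and the options
#'   `n_perm` (default 10000), `seed` (1), `min_class` (5), `alpha`
#'   (0.05), `max_resolutions` (64), `log_transform` (FALSE), `outdir`
#'   (optional output directory; nothing is written when absent).
#' @return A list of class `"treescan_run"` with elements `fit` (the
#'   `"treescan"` object), `haplotypes`, `network`, `kinship`, `fas`,
#'   `data` (the assembled per-individual analysis table), `counts` (stage
#'   bookkeeping) and `files` (written paths, if any).
#' @export
run_treescan_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(n_perm = 10000L, seed = 1L, min_class = 5L, alpha = 0.05,
                   max_resolutions = 64L, log_transform = FALSE,
                   outdir = NULL, reference_id = "REF")
  cfg <- utils::modifyList(defaults, config)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0,1)")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")

  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) message("[mitoscan] ", ...)

  input_files <- character(0)
  if (!is.null(cfg$cohort)) {
    stopifnot(inherits(cfg$cohort, "mt_cohort"))
    co <- cfg$cohort
    aln <- co$alignment
    mm <- co$matrilineage_map
    ped <- co$pedigree
    pheno <- co$phenotype
    variant_sets <- co$rep_variant_sets
    log_stage("using in-memory synthetic cohort (seed ", co$seed, ")")
  } else {
    for (f in c("fasta", "matrilineage", "pedigree", "phenotype")) {
      if (is.null(cfg[[f]])) stop("config entry '", f, "' is required")
      if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
    }
    input_files <- c(fasta = cfg$fasta, matrilineage = cfg$matrilineage,
                     pedigree = cfg$pedigree, phenotype = cfg$phenotype)
    aln <- read_mt_alignment(cfg$fasta, cfg$reference_id)
    mm <- read_matrilineage_map(cfg$matrilineage)
    ped <- read_pedigree(cfg$pedigree)
    pheno <- utils::read.table(cfg$phenotype, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = c(id = "character"))
    sample_ids <- setdiff(aln$ids, aln$reference_id)
    log_stage("alignment: ", length(sample_ids), " genomes + reference")
    variant_sets <- lapply(sample_ids, function(s) extract_variants(aln, s))
    names(variant_sets) <- sample_ids
  }

  if (!is.null(cfg$cohort)) {
    varsets_labels <- variant_sets
  } else {
    varsets_labels <- lapply(variant_sets, function(v) v$label)
  }
  n_variants <- length(unique(unlist(varsets_labels, use.names = FALSE)))

  haplotypes <- collapse_haplotypes(varsets_labels, mm)
  log_stage("haplotypes: ", nrow(haplotypes$tab), " (",
            haplotypes$n_sequenced, " sequenced / ",
            haplotypes$n_total, " total individuals)")
  network <- build_haplotype_network(haplotypes)
  log_stage("network: ", nrow(network$edges), " edges, ",
            network$n_cycles, " loop(s)")

  kin <- kinship_matrix(ped)
  cn <- stats::setNames(pheno$copy_number, pheno$id)
  fas <- familial_adjustment_scores(cn, kin)
  dat <- data.frame(id = pheno$id,
                    copy_number = pheno$copy_number,
                    age = pheno$age, sex = pheno$sex,
                    fas = fas[pheno$id],
                    stringsAsFactors = FALSE)

  fit <- treescan(copy_number ~ age + sex, data = dat,
                  network = network, kinship = kin, id_col = "id",
                  n_perm = cfg$n_perm, seed = cfg$seed,
                  min_class = cfg$min_class, alpha = cfg$alpha,
                  max_resolutions = cfg$max_resolutions,
                  log_transform = cfg$log_transform)
  log_stage("scan: ", nrow(fit$summary), " testable bipartitions, ",
            length(fit$significant), " significant")

  counts <- list(n_haplotypes = nrow(haplotypes$tab),
                 n_variants = n_variants,
                 n_individuals = haplotypes$n_total,
                 n_sequenced = haplotypes$n_sequenced,
                 n_missing_phenotype = fit$n_missing,
                 n_branches_testable = nrow(fit$summary),
                 n_significant = length(fit$significant),
                 elapsed_s = proc.time()[["elapsed"]] - t0)

  run <- structure(
    list(fit = fit, haplotypes = haplotypes, network = network,
         kinship = kin, fas = fas, data = dat,
         variant_sets = varsets_labels, counts = counts,
         config = cfg[setdiff(names(cfg), "cohort")],
         input_files = input_files, files = character(0)),
    class = "treescan_run")

  if (!is.null(cfg$outdir)) {
    run$files <- write_scan_report(run, cfg$outdir)
  }
  run
}

#' @export
print.treescan_run <- function(x, ...) {
  cat("mitoscan pipeline run\n")
  cat("  haplotypes: ", x$counts$n_haplotypes,
      ", variants: ", x$counts$n_variants,
      ", individuals: ", x$counts$n_individuals, "\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' Write the result files of a pipeline run
#'
#' Emits the per-branch results TSV (class sizes, group means, F, nominal
#' and corrected p, round), the haplotype and branch tables, network
#' exports (GraphML + JSON), a machine-readable JSON report and a manifest
#' recording the seed, permutation count, filters, input file hashes and
#' package version.
#'
#' @param run A `"treescan_run"` from [run_treescan_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Named vector of written file paths, invisibly.
#' @export
write_scan_report <- function(run, outdir) {
  stopifnot(inherits(run, "treescan_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fit <- run$fit

  results <- scan_results_table(fit)
  paths <- c(results = file.path(outdir, "results.tsv"),
             haplotypes = file.path(outdir, "haplotypes.tsv"),
             variants = file.path(outdir, "variants.tsv"),
             branches = file.path(outdir, "branches.tsv"),
             graphml = file.path(outdir, "network.graphml"),
             network_json = file.path(outdir, "network.json"),
             report = file.path(outdir, "report.json"),
             manifest = file.path(outdir, "manifest.json"))
  utils::write.table(results, paths[["results"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_haplotype_table(run$haplotypes, paths[["haplotypes"]])
  write_variant_table(run$variant_sets, paths[["variants"]])
  all_branches <- do.call(rbind, lapply(fit$results, `[[`, "branches"))
  write_branch_table(all_branches, paths[["branches"]])
  network_to_graphml(run$network, paths[["graphml"]])
  network_to_json(run$network, paths[["network_json"]])

  report <- list(
    n_perm = fit$n_perm, seed = fit$seed, alpha = fit$alpha,
    min_class = fit$min_class, n_resolutions = fit$n_resolutions,
    n_individuals = fit$n_individuals, n_missing = fit$n_missing,
    results = results,
    summary = fit$summary,
    significant = as.list(fit$significant),
    conditional = fit$conditional,
    round2 = fit$round2)
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  manifest <- list(
    package = "mitoscan",
    version = as.character(utils::packageVersion("mitoscan")),
    seed = fit$seed, n_perm = fit$n_perm, alpha = fit$alpha,
    min_class = fit$min_class,
    log_transform = fit$log_transform,
    counts = run$counts[setdiff(names(run$counts), "elapsed_s")],
    input_md5 = if (length(run$input_files)) {
      as.list(tools::md5sum(run$input_files))
    } else NULL)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

## Flat per-branch results table across resolutions and rounds.
scan_results_table <- function(fit) {
  rows <- lapply(fit$results, function(r) {
    br <- r$branches
    if (!nrow(br)) return(NULL)
    data.frame(resolution_id = br$resolution_id,
               branch_id = br$branch_id,
               variants = vapply(br$variants, paste, character(1),
                                 collapse = ","),
               n_a = br$n_a, n_b = br$n_b,
               mean_a = br$mean_a, mean_b = br$mean_b,
               F = br$F, nominal_p = br$nominal_p,
               corrected_p = br$corrected_p,
               testable = br$testable, round = 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(fit$round2) && nrow(fit$round2)) {
    r2 <- fit$round2
    out <- rbind(out, data.frame(
      resolution_id = r2$resolution_id, branch_id = r2$branch_id,
      variants = paste0("within:", substr(r2$parent_signature, 1, 20),
                        ":", r2$side),
      n_a = r2$n_sub_a, n_b = r2$n_sub_b,
      mean_a = NA_real_, mean_b = NA_real_,
      F = r2$F, nominal_p = r2$nominal_p, corrected_p = r2$corrected_p,
      testable = r2$testable, round = 2L, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Read a machine-readable scan report back
#'
#' Inverse of the JSON report written by [write_scan_report()]; restores
#' the per-branch results, summary, significant set, conditioning and
#' round-2 tables.
#'
#' @param path Path to `report.json`.
#' @return A list mirroring the written report, with data frames restored.
#' @export
read_scan_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$significant <- as.character(unlist(rep$significant))
  rep
}
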