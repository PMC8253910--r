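#' Default run configuration for the end-to-end pipeline
#'
#' @param n_proteins,de_fraction,effect_size_log2,missing_target_fraction
#'   Generator settings (see [generator_config()]).
#' @param n_replicates Imputation ensemble size.
#' @param alpha DE significance threshold on pooled q-values.
#' @param k Number of protein clusters.
#' @param seed Master seed for every stochastic stage.
#' @param pep_max,min_samples,min_unique_peptides Filter thresholds.
#' @return A `run_config` list, serializable losslessly to JSON.
#' @export
run_config <- function(n_proteins = 200, de_fraction = 0.05,
                       effect_size_log2 = 2,
                       missing_target_fraction = 0.15,
                       n_replicates = 10, alpha = 0.05, k = 4,
                       seed = 1L, pep_max = 0.05, min_samples = 5,
                       min_unique_peptides = 2) {
  structure(list(n_proteins = as.integer(n_proteins),
                 de_fraction = de_fraction,
                 effect_size_log2 = effect_size_log2,
                 missing_target_fraction = missing_target_fraction,
                 n_replicates = as.integer(n_replicates),
                 alpha = alpha, k = as.integer(k), seed = as.integer(seed),
                 pep_max = pep_max, min_samples = as.integer(min_samples),
                 min_unique_peptides = as.integer(min_unique_peptides)),
            class = "run_config")
}

#' Run the full synthetic-to-DE pipeline
#'
#' Orchestrates simulate -> filter -> impute -> differential expression ->
#' clustering on a synthetic dataset, writing every stage output plus a
#' manifest (parameters, seeds, stage counts, file checksums) to a run
#' directory. Rerunning with the same config reproduces all outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen_cfg <- generator_config(
    n_proteins = config$n_proteins,
    de_fraction = config$de_fraction,
    effect_size_log2 = config$effect_size_log2,
    missing_target_fraction = config$missing_target_fraction,
    seed = config$seed)
  sim <- simulate_proteomics(gen_cfg, out_dir = out_dir)

  pg <- read_protein_groups(file.path(out_dir, "proteinGroups.txt"),
                            sim$design)
  if (nrow(pg$records) == 0) {
    stop("pipeline halted at filter stage: empty protein table",
         call. = FALSE)
  }
  flt <- filter_cascade(pg, pep_max = config$pep_max,
                        min_samples = config$min_samples,
                        min_unique_peptides = config$min_unique_peptides)
  write_intensity_matrix(flt$matrix, file.path(out_dir, "matrix.tsv"))
  jsonlite::write_json(
    flt$report[c("n_input", "n_after_decoy_contaminant_annotation",
                 "n_after_pep", "n_quantified_min_samples",
                 "n_after_min_peptides")],
    file.path(out_dir, "filter_report.json"), auto_unbox = TRUE)

  ens <- build_ensemble(flt$matrix, n_replicates = config$n_replicates,
                        master_seed = derive_seed(config$seed, 104729L))
  de <- call_de(ens, alpha = config$alpha)
  de$gene <- flt$records$gene[match(de$protein_id,
                                    flt$records$protein_id)]
  write_de_table(de, file.path(out_dir, "de_table.tsv"))

  truth <- sim$truth[match(de$protein_id, sim$truth$protein_id), ]
  recovery <- list(
    n_true_de = sum(truth$is_de, na.rm = TRUE),
    n_called = sum(de$significant),
    true_positives = sum(de$significant & truth$is_de, na.rm = TRUE),
    false_positives = sum(de$significant & !truth$is_de, na.rm = TRUE))
  recovery$sensitivity <- if (recovery$n_true_de > 0)
    recovery$true_positives / recovery$n_true_de else NA
  jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)

  sig <- de[de$significant, , drop = FALSE]
  clusters <- NULL
  if (nrow(sig) >= 2) {
    m1 <- ens$replicates[[1]][sig$protein_id, , drop = FALSE]
    kk <- min(config$k, nrow(sig))
    clusters <- cluster_heatmap(m1, k = kk)
    utils::write.table(
      data.frame(protein_id = names(clusters$cluster),
                 cluster = clusters$cluster),
      file.path(out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pc <- pca(ens$replicates[[1]])
  utils::write.table(
    data.frame(sample_id = pc$sample_id, pc$scores[, 1:2, drop = FALSE]),
    file.path(out_dir, "pca_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    config = unclass(config),
    seeds = list(master = config$seed,
                 censoring = derive_seed(config$seed, 7919L),
                 ensemble = derive_seed(config$seed, 104729L)),
    stage_counts = flt$report[c("n_input",
                                "n_after_decoy_contaminant_annotation",
                                "n_after_pep", "n_quantified_min_samples",
                                "n_after_min_peptides")],
    n_significant = sum(de$significant),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, filter = flt, ensemble = ens, de = de,
                 clusters = clusters, pca = pc, recovery = recovery,
                 manifest = manifest))
}

#' Read the packaged table of study DE proteins
#'
#' Loads the machine-readable transcription of the emulated study's
#' published differential-expression table (70 proteins with peptide
#' counts, time point of significance, direction, and interaction
#' q-value), shipped under `extdata`.
#'
#' @param path Path to a TSV in the same layout; defaults to the packaged
#'   fixture.
#' @return Data frame with columns `protein_id`, `pig_gene`, `human_gene`,
#'   `n_peptides`, `timepoint_of_significance`, `increased_in`,
#'   `q_interaction`.
#' @export
read_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "study_de_proteins.tsv",
                        package = "miprot", mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Audit a published-style DE table
#'
#' Tallies a DE table in the published layout: total rows, rows per
#' direction (`increased_in`) and rows per time point of significance.
#'
#' @param de_table Data frame with `increased_in` and
#'   `timepoint_of_significance` columns (e.g. [read_table1()]).
#' @return List: `total`, `by_direction` (named counts), `by_timepoint`.
#' @export
table1_audit <- function(de_table) {
  needed <- c("increased_in", "timepoint_of_significance")
  missing_cols <- setdiff(needed, names(de_table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  list(total = nrow(de_table),
       by_direction = c(table(de_table$increased_in)),
       by_timepoint = c(table(de_table$timepoint_of_significance)))
}
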