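#' Configuration for the synthetic proteomics generator
#'
#' Collects the knobs of the synthetic proteinGroups generator. Defaults
#' describe the emulated study: ~5000 quantified proteins on a log2 LFQ
#' scale centred near 25, a small fraction of proteins carrying a
#' treatment-by-time interaction effect on the (NEVKP, POD3) cell, ~15%
#' intensity-dependent (MNAR) missingness, and a sprinkling of decoy and
#' contaminant rows plus records violating the identification filters.
#'
#' @param n_proteins Number of genuine (non-decoy, non-contaminant) proteins.
#' @param n_animals_per_group Animals per arm (design has 3 timepoints).
#' @param dropout Sample ids removed from the full design (default: the
#'   28-of-30 pattern, one NEVKP baseline and one NEVKP R30 biopsy).
#' @param de_fraction Fraction of proteins carrying a nonzero effect.
#' @param effect_size_log2 Log2 effect placed on the interaction cell.
#' @param interaction_cell `"group:timepoint"` cell receiving the effect.
#' @param base_mean,base_sd Mean/SD of per-protein baseline log2 abundance.
#' @param noise_sd Residual log2 SD within a (group, timepoint) cell.
#' @param missing_target_fraction Overall fraction of values censored.
#' @param censor_scale Logistic scale (log2 units) of the censoring curve.
#' @param contaminant_count,reverse_count Numbers of flagged extra rows.
#' @param pep_violation_fraction Fraction of proteins given PEP > 0.05.
#' @param single_peptide_fraction Fraction given a single unique peptide.
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_proteins = 200,
                             n_animals_per_group = 5,
                             dropout = c("NEVKP4_BL", "NEVKP4_R30"),
                             de_fraction = 0.05,
                             effect_size_log2 = 2,
                             interaction_cell = "NEVKP:POD3",
                             base_mean = 25,
                             base_sd = 2,
                             noise_sd = 0.5,
                             missing_target_fraction = 0.15,
                             censor_scale = 0.5,
                             contaminant_count = 0,
                             reverse_count = 0,
                             pep_violation_fraction = 0,
                             single_peptide_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_animals_per_group = as.integer(n_animals_per_group),
              dropout = as.character(dropout),
              de_fraction = de_fraction,
              effect_size_log2 = effect_size_log2,
              interaction_cell = interaction_cell,
              base_mean = base_mean, base_sd = base_sd,
              noise_sd = noise_sd,
              missing_target_fraction = missing_target_fraction,
              censor_scale = censor_scale,
              contaminant_count = as.integer(contaminant_count),
              reverse_count = as.integer(reverse_count),
              pep_violation_fraction = pep_violation_fraction,
              single_peptide_fraction = single_peptide_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_proteins >= 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$missing_target_fraction >= 0,
            cfg$missing_target_fraction < 1,
            cfg$noise_sd > 0, cfg$censor_scale > 0)
  parts <- strsplit(cfg$interaction_cell, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% GROUPS ||
      !parts[2] %in% TIMEPOINTS) {
    stop("interaction_cell must be \"<group>:<timepoint>\"", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a complete synthetic protein dataset with known truth
#'
#' Draws a complete latent log2 intensity matrix
#' `base + group effect + time effect + interaction + N(0, noise_sd)` for
#' every protein and sample, plus per-protein annotation (gene names,
#' unique peptide counts, posterior error probabilities, decoy and
#' contaminant flags). A `de_fraction` of proteins carry
#' `effect_size_log2` on the configured interaction cell. The returned
#' truth table records every effect so recovery can be scored exactly.
#'
#' @param config A [generator_config()].
#' @param design A [generate_design()] table; defaults to the config's.
#' @return List with `latent` (proteins x samples complete log2 matrix,
#'   decoy/contaminant rows included), `annotations` (data frame),
#'   `truth` (`synthetic_truth` data frame, genuine proteins only) and
#'   `design`.
#' @export
generate_dataset <- function(config, design = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(design)) {
    design <- generate_design(config$n_animals_per_group, config$dropout)
  }
  validate_design(design)
  set.seed(config$seed)
  p <- config$n_proteins
  n <- nrow(design)

  n_de <- round(config$de_fraction * p)
  is_de <- rep(FALSE, p)
  if (n_de > 0) is_de[seq_len(n_de)] <- TRUE

  base <- stats::rnorm(p, config$base_mean, config$base_sd)
  group_effect <- rep(0, p)
  time_R30 <- rep(0, p)
  time_POD3 <- rep(0, p)
  interaction_effect <- ifelse(is_de, config$effect_size_log2, 0)

  cell <- strsplit(config$interaction_cell, ":", fixed = TRUE)[[1]]
  in_cell <- design$group == cell[1] & design$timepoint == cell[2]

  latent <- matrix(base, nrow = p, ncol = n) +
    outer(group_effect, as.integer(design$group == "NEVKP")) +
    outer(time_R30, as.integer(design$timepoint == "R30")) +
    outer(time_POD3, as.integer(design$timepoint == "POD3")) +
    outer(interaction_effect, as.integer(in_cell)) +
    matrix(stats::rnorm(p * n, 0, config$noise_sd), nrow = p)

  protein_id <- sprintf("PROT%05d", seq_len(p))
  gene <- sprintf("GENE%05d", seq_len(p))
  unique_peptides <- 1L + stats::rpois(p, 8)
  n_single <- round(config$single_peptide_fraction * p)
  if (n_single > 0) {
    unique_peptides[sample.int(p, n_single)] <- 1L
  }
  pep <- stats::rbeta(p, 1, 200)  # bulk well under the 0.05 cutoff
  pep <- pmin(pep, 0.049)
  n_peprej <- round(config$pep_violation_fraction * p)
  if (n_peprej > 0) {
    pep[sample.int(p, n_peprej)] <- stats::runif(n_peprej, 0.051, 0.5)
  }
  annotations <- data.frame(
    protein_id = protein_id, gene = gene,
    unique_peptides = unique_peptides, pep = pep,
    is_reverse = FALSE, is_contaminant = FALSE,
    stringsAsFactors = FALSE
  )

  n_extra <- config$reverse_count + config$contaminant_count
  if (n_extra > 0) {
    extra_lat <- matrix(stats::rnorm(n_extra * n, config$base_mean,
                                     config$base_sd),
                        nrow = n_extra)
    latent <- rbind(latent, extra_lat)
    rev_ids <- if (config$reverse_count > 0)
      sprintf("REV__PROT%05d", seq_len(config$reverse_count)) else character()
    con_ids <- if (config$contaminant_count > 0)
      sprintf("CON__PROT%05d", seq_len(config$contaminant_count)) else character()
    extra <- data.frame(
      protein_id = c(rev_ids, con_ids),
      gene = "",
      unique_peptides = 1L + stats::rpois(n_extra, 4),
      pep = pmin(stats::rbeta(n_extra, 1, 200), 0.049),
      is_reverse = rep(c(TRUE, FALSE),
                       c(config$reverse_count, config$contaminant_count)),
      is_contaminant = rep(c(FALSE, TRUE),
                           c(config$reverse_count, config$contaminant_count)),
      stringsAsFactors = FALSE
    )
    annotations <- rbind(annotations, extra)
  }
  rownames(latent) <- annotations$protein_id
  colnames(latent) <- design$sample_id

  censor_location <- calibrate_censor_location(
    latent[seq_len(p), , drop = FALSE],
    config$missing_target_fraction, config$censor_scale)

  truth <- data.frame(
    protein_id = protein_id, base_log2 = base,
    group_effect = group_effect,
    time_R30 = time_R30, time_POD3 = time_POD3,
    interaction_effect = interaction_effect,
    is_de = is_de, noise_sd = config$noise_sd,
    censor_location = censor_location,
    censor_scale = config$censor_scale,
    stringsAsFactors = FALSE
  )
  attr(truth, "interaction_cell") <- config$interaction_cell
  class(truth) <- c("synthetic_truth", "data.frame")

  list(latent = latent, annotations = annotations, truth = truth,
       design = design)
}

#' Calibrate the censoring location for a target missing fraction
#'
#' Solves for the logistic location L such that the expected censored
#' fraction `mean(plogis((L - x) / scale))` over the supplied values equals
#' `target`. With `target = 0` returns `-Inf` (nothing censored).
#'
#' @param values Numeric matrix or vector of complete log2 intensities.
#' @param target Desired overall missing fraction in `[0, 1)`.
#' @param scale Logistic scale (> 0).
#' @return The location, in log2 units.
#' @export
calibrate_censor_location <- function(values, target, scale = 1) {
  stopifnot(scale > 0, target >= 0, target < 1)
  if (target == 0) return(-Inf)
  x <- as.numeric(values)
  f <- function(loc) mean(stats::plogis((loc - x) / scale)) - target
  rng <- range(x)
  stats::uniroot(f, lower = rng[1] - 50 * scale,
                 upper = rng[2] + 50 * scale, tol = 1e-8)$root
}

#' Apply intensity-dependent (MNAR) left-censoring
#'
#' Each value `x` is set missing independently with probability
#' `plogis((location - x) / scale)` (logistic mode), so low-abundance
#' values are preferentially lost -- the missingness mechanism assumed by
#' left-censored imputation. A hard-threshold mode (`x < location` always
#' censored, others never) is available.
#'
#' @param matrix Complete numeric matrix of log2 intensities.
#' @param truth Optional `synthetic_truth`; supplies location/scale.
#' @param seed Integer seed.
#' @param censor_location,censor_scale Explicit parameters (override truth).
#' @param mode `"logistic"` or `"threshold"`.
#' @return The matrix with censored entries set to `NA`.
#' @export
apply_mnar_censoring <- function(matrix, truth = NULL, seed = 1L,
                                 censor_location = NULL,
                                 censor_scale = NULL,
                                 mode = c("logistic", "threshold")) {
  mode <- match.arg(mode)
  if (!is.null(truth)) {
    if (is.null(censor_location)) censor_location <- truth$censor_location[1]
    if (is.null(censor_scale)) censor_scale <- truth$censor_scale[1]
  }
  stopifnot(!is.null(censor_location), !is.null(censor_scale))
  if (censor_scale <= 0) stop("censor_scale must be > 0", call. = FALSE)
  if (anyNA(matrix)) stop("matrix must be complete", call. = FALSE)
  set.seed(seed)
  if (mode == "logistic") {
    pmiss <- stats::plogis((censor_location - matrix) / censor_scale)
    drop <- stats::runif(length(matrix)) < pmiss
  } else {
    drop <- matrix < censor_location
  }
  matrix[drop] <- NA_real_
  matrix
}

#' Assemble and write a proteinGroups-style table
#'
#' `assemble_protein_groups` binds annotations and a (possibly censored)
#' log2 matrix into the MaxQuant proteinGroups dialect: one
#' `"LFQ intensity <sample>"` column per sample on the raw intensity scale
#' with missing encoded as 0, and `"+"`-flagged Reverse / Potential
#' contaminant columns. `write_protein_groups` serializes it as
#' tab-separated text; the file round-trips losslessly through
#' [read_protein_groups()].
#'
#' @param annotations Annotation data frame (see [generate_dataset()]).
#' @param log2_matrix Proteins x samples log2 matrix, `NA` = missing.
#' @return A data frame in proteinGroups layout.
#' @export
assemble_protein_groups <- function(annotations, log2_matrix) {
  stopifnot(nrow(annotations) == nrow(log2_matrix))
  lfq <- 2^log2_matrix
  lfq[is.na(lfq)] <- 0
  tab <- data.frame(
    `Majority protein IDs` = annotations$protein_id,
    `Gene names` = annotations$gene,
    `Unique peptides` = annotations$unique_peptides,
    PEP = annotations$pep,
    Reverse = ifelse(annotations$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(annotations$is_contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  lfq_df <- as.data.frame(lfq)
  names(lfq_df) <- paste("LFQ intensity", colnames(log2_matrix))
  cbind(tab, lfq_df)
}

#' @rdname assemble_protein_groups
#' @param table A proteinGroups-layout data frame.
#' @param path Output file path.
#' @export
write_protein_groups <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Simulate a full study: design, dataset, censoring, files
#'
#' Convenience wrapper running the generator end to end and, optionally,
#' writing the proteinGroups table, design CSV and truth JSON to a
#' directory.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory.
#' @return List with `table`, `design`, `truth`, `matrix` (censored log2,
#'   genuine proteins and extras), and file paths if written.
#' @export
simulate_proteomics <- function(config, out_dir = NULL) {
  ds <- generate_dataset(config)
  censored <- apply_mnar_censoring(
    ds$latent, seed = derive_seed(config$seed, 7919L),
    censor_location = ds$truth$censor_location[1],
    censor_scale = ds$truth$censor_scale[1])
  table <- assemble_protein_groups(ds$annotations, censored)
  out <- list(table = table, design = ds$design, truth = ds$truth,
              matrix = censored, latent = ds$latent)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- c(
      protein_groups = write_protein_groups(
        table, file.path(out_dir, "proteinGroups.txt")),
      design = write_design(ds$design, file.path(out_dir, "design.csv")),
      truth = {
        p <- file.path(out_dir, "truth.json")
        jsonlite::write_json(as.data.frame(ds$truth), p, digits = NA)
        p
      })
  }
  out
}
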