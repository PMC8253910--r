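# Shared fixtures, all built in code.

study_design <- function() generate_design(5)

# Hand-built 10-protein table exercising every filter stage on the
# 28-sample design: 2 reverse + 1 contaminant, one PEP violation, one
# single-peptide protein, one protein too sparse for the min-samples rule.
# Expected cascade: 10 -> 7 -> 6 -> 5 -> 4.
ten_protein_fixture <- function(design = study_design()) {
  n <- nrow(design)
  ann <- data.frame(
    protein_id = sprintf("P%02d", 1:10),
    gene = c(sprintf("G%02d", 1:7), "G08", "G09", "G10"),
    unique_peptides = c(5L, 8L, 3L, 2L, 4L, 6L, 7L, 9L, 1L, 6L),
    pep = c(rep(0.01, 7), 0.2, 0.01, 0.01),
    is_reverse = c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 4)),
    is_contaminant = c(rep(FALSE, 6), TRUE, rep(FALSE, 3)),
    stringsAsFactors = FALSE
  )
  m <- matrix(25 + seq_len(10 * n) / 100, nrow = 10,
              dimnames = list(ann$protein_id, design$sample_id))
  # P10: observed in only 4 samples at every timepoint (fails stage 4)
  for (tp in levels(design$timepoint)) {
    cols <- which(design$timepoint == tp)
    m[10, cols[-seq_len(4)]] <- NA
  }
  list(annotations = ann, log2 = m, design = design)
}

write_ten_protein_fixture <- function(path, design = study_design()) {
  fx <- ten_protein_fixture(design)
  write_protein_groups(assemble_protein_groups(fx$annotations, fx$log2),
                       path)
  fx
}

# Small imputation-ready matrix with a known censoring pattern.
small_censored_matrix <- function(n_proteins = 120, seed = 42) {
  cfg <- generator_config(n_proteins = n_proteins, de_fraction = 0,
                          seed = seed)
  sim <- simulate_proteomics(cfg)
  intensity_matrix(sim$matrix[sim$truth$protein_id, , drop = FALSE],
                   sim$design)
}
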