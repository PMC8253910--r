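#' Read a proteinGroups-dialect table
#'
#' Parses a MaxQuant-style tab-separated protein table and binds its LFQ
#' columns to a sample design. LFQ intensities of 0 are parsed as missing
#' (the MaxQuant on-disk convention); Reverse and Potential contaminant
#' flags follow the `"+"` convention.
#'
#' @param path Path to the tab-separated file.
#' @param design A `sample_design`; every design sample must have a
#'   matching `"LFQ intensity <sample_id>"` column.
#' @return List with `records` (data frame: protein_id, gene,
#'   unique_peptides, pep, is_reverse, is_contaminant), `lfq` (proteins x
#'   samples raw-intensity matrix, `NA` = missing) and `design`.
#' @export
read_protein_groups <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_design(design)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  required <- c("Majority protein IDs", "Gene names", "Unique peptides",
                "PEP", "Reverse", "Potential contaminant")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lfq_cols <- paste("LFQ intensity", design$sample_id)
  absent <- setdiff(lfq_cols, names(tab))
  if (length(absent)) {
    stop("no LFQ column for design sample(s): ",
         paste(sub("^LFQ intensity ", "", absent), collapse = ", "),
         call. = FALSE)
  }
  extra_lfq <- setdiff(grep("^LFQ intensity ", names(tab), value = TRUE),
                       lfq_cols)
  if (length(extra_lfq)) {
    stop("LFQ column(s) with no design entry: ",
         paste(extra_lfq, collapse = ", "), call. = FALSE)
  }
  flag <- function(x) {
    x <- as.character(x)          # an all-empty column reads as logical NA
    x[is.na(x)] <- ""
    trimws(x) == "+"
  }
  records <- data.frame(
    protein_id = as.character(tab[["Majority protein IDs"]]),
    gene = as.character(tab[["Gene names"]]),
    unique_peptides = as.integer(tab[["Unique peptides"]]),
    pep = as.numeric(tab[["PEP"]]),
    is_reverse = flag(tab[["Reverse"]]),
    is_contaminant = flag(tab[["Potential contaminant"]]),
    stringsAsFactors = FALSE
  )
  if (nrow(records)) {
    records$gene[is.na(records$gene)] <- ""
    assert_probability(records$pep, "PEP values")
  }
  lfq <- as.matrix(tab[, lfq_cols, drop = FALSE])
  if (nrow(lfq)) {
    storage.mode(lfq) <- "double"
    lfq[lfq == 0] <- NA_real_
  }
  rownames(lfq) <- records$protein_id
  colnames(lfq) <- design$sample_id
  list(records = records, lfq = lfq, design = design)
}

#' Construct an intensity matrix bound to a design
#'
#' @param values Proteins x samples numeric matrix of log2 intensities
#'   (`NA` = missing), columns ordered as `design$sample_id`.
#' @param design A `sample_design`.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, design) {
  validate_design(design)
  stopifnot(is.matrix(values), ncol(values) == nrow(design))
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), design$sample_id)) {
    stop("column order must match design$sample_id", call. = FALSE)
  }
  colnames(values) <- design$sample_id
  structure(list(values = values, design = design),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Apply the identification/quantification filter cascade
#'
#' Reproduces the standard protein-level quality cascade for label-free
#' data, in order: (1) drop reverse decoys, contaminants and unannotated
#' rows (no gene name and no usable accession); (2) drop proteins with
#' posterior error probability above `pep_max`; (3) log2-transform the
#' observed intensities; (4) keep proteins quantified in at least
#' `min_samples` samples within at least one timepoint (both treatment
#' arms pooled); (5) keep proteins identified with at least
#' `min_unique_peptides` unique peptides.
#'
#' @param pg Output of [read_protein_groups()], or a list with `records`,
#'   `lfq`, `design` in that layout.
#' @param pep_max PEP cutoff (exclusive), default 0.05.
#' @param min_samples Minimum quantified samples within some timepoint.
#' @param min_unique_peptides Minimum unique peptides (default 2,
#'   i.e. "more than one peptide").
#' @param min_samples_scope `"timepoint"` pools both groups within a
#'   timepoint; `"cell"` requires the count within a (group, timepoint)
#'   cell.
#' @return List with `matrix` (an [intensity_matrix()]) and `report`
#'   (a `filter_report`: per-stage retained counts and dropped ids).
#' @export
filter_cascade <- function(pg, pep_max = 0.05, min_samples = 5,
                           min_unique_peptides = 2,
                           min_samples_scope = c("timepoint", "cell")) {
  min_samples_scope <- match.arg(min_samples_scope)
  records <- pg$records
  lfq <- pg$lfq
  design <- pg$design
  validate_design(design)

  strata <- if (min_samples_scope == "timepoint") {
    split(seq_len(nrow(design)), design$timepoint)
  } else {
    split(seq_len(nrow(design)),
          interaction(design$group, design$timepoint, drop = TRUE))
  }
  if (min_samples > max(lengths(strata))) {
    stop("filter unsatisfiable: min_samples exceeds every stratum size",
         call. = FALSE)
  }

  ids <- records$protein_id
  dropped <- list()

  # stage 1: decoys, contaminants, unannotated
  unannotated <- records$gene == "" & !grepl("[A-Za-z0-9]", ids)
  keep1 <- !(records$is_reverse | records$is_contaminant | unannotated)
  dropped$decoy_contaminant_annotation <- ids[!keep1]

  # stage 2: PEP
  keep2 <- keep1 & records$pep <= pep_max
  dropped$pep <- ids[keep1 & !keep2]

  # stage 3: log2 transform (observed cells only; NA pattern preserved)
  logm <- log2(lfq)

  # stage 4: quantified in >= min_samples within some stratum
  enough <- rep(FALSE, nrow(logm))
  if (nrow(logm)) {
    for (idx in strata) {
      cnt <- rowSums(!is.na(logm[, idx, drop = FALSE]))
      enough <- enough | cnt >= min_samples
    }
  }
  keep4 <- keep2 & enough
  dropped$min_samples <- ids[keep2 & !keep4]

  # stage 5: unique peptides
  keep5 <- keep4 & records$unique_peptides >= min_unique_peptides
  dropped$min_peptides <- ids[keep4 & !keep5]

  report <- structure(list(
    n_input = length(ids),
    n_after_decoy_contaminant_annotation = sum(keep1),
    n_after_pep = sum(keep2),
    n_quantified_min_samples = sum(keep4),
    n_after_min_peptides = sum(keep5),
    dropped = dropped,
    parameters = list(pep_max = pep_max, min_samples = min_samples,
                      min_unique_peptides = min_unique_peptides,
                      min_samples_scope = min_samples_scope)
  ), class = "filter_report")

  mat <- logm[keep5, , drop = FALSE]
  list(matrix = intensity_matrix(mat, design), report = report,
       records = records[keep5, , drop = FALSE])
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter cascade:",
      x$n_input, "->", x$n_after_decoy_contaminant_annotation,
      "(decoy/contaminant/annotation) ->", x$n_after_pep, "(PEP) ->",
      x$n_quantified_min_samples, "(min samples) ->",
      x$n_after_min_peptides, "(min peptides)\n")
  invisible(x)
}

#' Read/write an intensity matrix as TSV
#'
#' Missing values are written as `NA`; the first column holds protein ids.
#'
#' @param x An [intensity_matrix()].
#' @param path File path.
#' @param design Design to bind on read.
#' @return `read_intensity_matrix` returns an `intensity_matrix`.
#' @export
write_intensity_matrix <- function(x, path) {
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_matrix
#' @export
read_intensity_matrix <- function(path, design) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  intensity_matrix(m[, design$sample_id, drop = FALSE], design)
}
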