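#' Generate the two-arm, three-timepoint biopsy design
#'
#' Builds the sample layout of a porcine kidney preservation experiment:
#' two treatment arms (normothermic ex-vivo perfusion, NEVKP, versus static
#' cold storage, SCS), each animal biopsied at baseline (BL), 30 minutes
#' post-reperfusion (R30) and post-operative day 3 (POD3). Individual
#' samples can be dropped to emulate biopsies excluded for insufficient
#' protein yield; the default reproduces the 28-of-30 layout with one
#' NEVKP baseline and one NEVKP R30 sample missing.
#'
#' @param n_per_group Number of animals per treatment arm (>= 2).
#' @param dropout Character vector of sample ids to remove. Sample ids have
#'   the form `"<GROUP><animal>_<TIMEPOINT>"`, e.g. `"NEVKP4_BL"`.
#' @return A `sample_design` data frame with columns `sample_id`,
#'   `animal_id`, `group` and `timepoint` (factors with levels
#'   NEVKP/SCS and BL/R30/POD3).
#' @examples
#' d <- generate_design(5)
#' table(d$group, d$timepoint)
#' @export
generate_design <- function(n_per_group = 5,
                            dropout = c("NEVKP4_BL", "NEVKP4_R30")) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) == 1L,
            n_per_group >= 2, n_per_group == round(n_per_group))
  grid <- expand.grid(animal = seq_len(n_per_group),
                      timepoint = TIMEPOINTS,
                      group = GROUPS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  animal_id <- paste0(grid$group, grid$animal)
  design <- data.frame(
    sample_id = paste(animal_id, grid$timepoint, sep = "_"),
    animal_id = animal_id,
    group = factor(grid$group, levels = GROUPS),
    timepoint = factor(grid$timepoint, levels = TIMEPOINTS),
    stringsAsFactors = FALSE
  )
  dropout <- as.character(dropout)
  if (length(dropout)) {
    unknown <- setdiff(dropout, design$sample_id)
    if (length(unknown)) {
      stop("dropout ids not in the generated design: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    design <- design[!design$sample_id %in% dropout, , drop = FALSE]
  }
  rownames(design) <- NULL
  validate_design(design)
  class(design) <- c("sample_design", "data.frame")
  design
}

#' Validate a sample design table
#'
#' Checks the structural invariants of a design: unique sample ids, at most
#' one sample per (animal, timepoint), a constant group per animal, and no
#' empty (group, timepoint) cell. With `strict = TRUE` additionally requires
#' at least two samples in every cell, the minimum for a cell-means ANOVA.
#'
#' @param design A data frame with columns `sample_id`, `animal_id`,
#'   `group`, `timepoint`.
#' @param strict Require >= 2 samples per (group, timepoint) cell.
#' @return The design, invisibly; errors on violation.
#' @export
validate_design <- function(design, strict = FALSE) {
  needed <- c("sample_id", "animal_id", "group", "timepoint")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  if (anyDuplicated(design[, c("animal_id", "timepoint")])) {
    stop("more than one sample for an (animal_id, timepoint) pair",
         call. = FALSE)
  }
  grp_per_animal <- tapply(as.character(design$group), design$animal_id,
                           function(g) length(unique(g)))
  if (any(grp_per_animal > 1)) {
    stop("group must be constant within animal_id", call. = FALSE)
  }
  cells <- table(design$group, design$timepoint)
  if (any(cells == 0)) stop("degenerate cell", call. = FALSE)
  if (strict && any(cells < 2)) {
    stop("every (group, timepoint) cell needs >= 2 samples", call. = FALSE)
  }
  invisible(design)
}

#' Read/write a design table as CSV
#'
#' @param design A `sample_design` data frame.
#' @param path File path.
#' @return `read_design` returns a validated `sample_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$group <- factor(d$group, levels = GROUPS)
  d$timepoint <- factor(d$timepoint, levels = TIMEPOINTS)
  validate_design(d)
  class(d) <- c("sample_design", "data.frame")
  d
}
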