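#' Map query genes through a two-column ortholog table
#'
#' Applies a one-to-one species mapping (e.g. pig to human symbols) to a
#' query gene list. Genes without a mapping are returned in `unmapped`,
#' never silently dropped. One-to-many mappings are an error unless
#' `tie_break = "first"`, which keeps the first listed target.
#'
#' @param query_genes Character vector.
#' @param mapping_table Data frame whose first two columns are
#'   (source gene, target gene), or a path to such a TSV.
#' @param tie_break `"error"` (default) or `"first"`.
#' @return List with `mapped` (named character vector, names = source),
#'   and `unmapped`.
#' @export
map_orthologs <- function(query_genes, mapping_table,
                          tie_break = c("error", "first")) {
  tie_break <- match.arg(tie_break)
  if (is.character(mapping_table) && length(mapping_table) == 1) {
    mapping_table <- utils::read.delim(mapping_table,
                                       stringsAsFactors = FALSE)
  }
  stopifnot(ncol(mapping_table) >= 2)
  src <- as.character(mapping_table[[1]])
  dst <- as.character(mapping_table[[2]])
  dup <- unique(src[duplicated(src)])
  if (length(dup)) {
    if (tie_break == "error") {
      stop("one-to-many mapping for: ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    keep <- !duplicated(src)
    src <- src[keep]; dst <- dst[keep]
  }
  idx <- match(query_genes, src)
  mapped <- dst[idx[!is.na(idx)]]
  names(mapped) <- query_genes[!is.na(idx)]
  list(mapped = mapped, unmapped = query_genes[is.na(idx)])
}

#' Hypergeometric overlap between a query set and a signature
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' (e.g. the differentially expressed proteins) and an external signature
#' drawn from a universe of `universe` genes:
#' `p = P(X >= n_overlap)`, `X ~ Hypergeometric(universe, n_signature,
#' n_query)`.
#'
#' @param query,signature Character vectors of gene symbols.
#' @param universe Universe size (>= size of the union of the sets).
#' @return An `overlap_result` list: `n_query`, `n_signature`,
#'   `n_universe`, `n_overlap`, `p_hypergeometric`, `overlap_genes`.
#' @export
hypergeometric_overlap <- function(query, signature, universe) {
  query <- unique(as.character(query))
  signature <- unique(as.character(signature))
  n_union <- length(unique(c(query, signature)))
  if (universe < n_union) {
    stop("universe smaller than the union of the sets", call. = FALSE)
  }
  ov <- intersect(query, signature)
  k <- length(ov)
  p <- stats::phyper(k - 1, length(signature),
                     universe - length(signature), length(query),
                     lower.tail = FALSE)
  structure(list(n_query = length(query),
                 n_signature = length(signature),
                 n_universe = as.integer(universe),
                 n_overlap = k,
                 p_hypergeometric = p,
                 overlap_genes = sort(ov)),
            class = "overlap_result")
}

#' Classify direction concordance with an external injury signature
#'
#' Labels each differentially expressed gene by whether its treatment-arm
#' direction opposes or mirrors the external injury signature. Under the
#' default polarity, the perfusion arm (NEVKP) is the putatively
#' protective one: a protein increased in NEVKP whose gene is decreased in
#' injury is `opposing` (the treatment reverses the injury change), as is
#' a protein increased in SCS whose gene is increased in injury (SCS
#' mirrors injury, hence NEVKP opposes it). Matching directions are
#' `concordant`; genes absent from the signature or lacking a direction
#' are `undirected`. Flipping `polarity` swaps opposing and concordant
#' exactly.
#'
#' @param de_table A `de_result` (or data frame with `gene` and
#'   `direction` columns, direction in the design's group labels).
#' @param signature Data frame with columns `gene` and `direction`
#'   (values `up_in_injury` / `down_in_injury`), or a path to such a TSV.
#' @param polarity Which arm opposes injury: `"NEVKP"` (default) or
#'   `"SCS"`.
#' @return Data frame `gene`, `de_direction`, `injury_direction`, `label`.
#' @export
classify_concordance <- function(de_table, signature,
                                 polarity = c("NEVKP", "SCS")) {
  polarity <- match.arg(polarity)
  if (is.character(signature) && length(signature) == 1) {
    signature <- utils::read.delim(signature, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "direction") %in% names(signature)))
  genes <- as.character(de_table$gene)
  dir_de <- as.character(de_table$direction)
  idx <- match(genes, signature$gene)
  dir_inj <- as.character(signature$direction)[idx]
  protective <- polarity
  label <- ifelse(
    is.na(dir_inj) | is.na(dir_de), "undirected",
    ifelse((dir_de == protective) == (dir_inj == "down_in_injury"),
           "opposing", "concordant"))
  data.frame(gene = genes, de_direction = dir_de,
             injury_direction = dir_inj, label = label,
             stringsAsFactors = FALSE)
}

#' Overlap a DE table with a directional external signature
#'
#' Convenience combining [hypergeometric_overlap()] on the gene sets with
#' [classify_concordance()] on the overlapping genes, filling the
#' `n_opposing` / `n_concordant` tallies (genes lacking a direction are
#' excluded from both).
#'
#' @inheritParams classify_concordance
#' @param universe Universe size for the hypergeometric test.
#' @return An `overlap_result` with added `n_opposing`, `n_concordant`
#'   and `concordance` (the per-gene label table).
#' @export
signature_overlap <- function(de_table, signature, universe,
                              polarity = c("NEVKP", "SCS")) {
  polarity <- match.arg(polarity)
  if (is.character(signature) && length(signature) == 1) {
    signature <- utils::read.delim(signature, stringsAsFactors = FALSE)
  }
  ov <- hypergeometric_overlap(de_table$gene, signature$gene, universe)
  cls <- classify_concordance(
    de_table[de_table$gene %in% ov$overlap_genes, , drop = FALSE],
    signature, polarity)
  ov$n_opposing <- sum(cls$label == "opposing")
  ov$n_concordant <- sum(cls$label == "concordant")
  ov$concordance <- cls
  ov
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: per line, set name, description, then member
#'   genes, tab-separated.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in GMT", call. = FALSE)
  }
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  class(sets) <- "gene_set_collection"
  sets
}

#' Over-representation analysis against a gene-set collection
#'
#' One upper-tail hypergeometric test per set ([hypergeometric_overlap()])
#' with BH adjustment across the collection. The gene ratio is
#' hits / query size, as conventionally plotted for enrichment dot plots.
#'
#' @param query Character vector of query genes.
#' @param collection A [read_gmt()] collection or named list of sets.
#' @param universe Universe size (an explicit choice; typically the number
#'   of quantified proteins after filtering).
#' @param alpha Threshold on the adjusted p for the `enriched` flag.
#' @return Data frame: `set`, `n_set`, `n_overlap`, `gene_ratio`, `p`,
#'   `q`, `enriched`, ordered by `p`.
#' @export
ora <- function(query, collection, universe, alpha = 0.05) {
  query <- unique(as.character(query))
  if (length(collection) == 0) {
    return(data.frame(set = character(), n_set = integer(),
                      n_overlap = integer(), gene_ratio = numeric(),
                      p = numeric(), q = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  res <- lapply(collection, function(s) {
    hypergeometric_overlap(query, s, universe)
  })
  p <- vapply(res, `[[`, numeric(1), "p_hypergeometric")
  k <- vapply(res, `[[`, integer(1), "n_overlap")
  out <- data.frame(set = names(collection),
                    n_set = vapply(res, `[[`, integer(1), "n_signature"),
                    n_overlap = k,
                    gene_ratio = k / length(query),
                    p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out$enriched <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}
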