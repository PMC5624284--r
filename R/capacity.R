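## LPS acylation and SCFA biosynthetic capacity profiling: classify taxa by
## lipid-A pathway gene carriage, sum class abundances and the hexa:penta
## log-ratio per sample, and score SCFA capacity from terminal-enzyme gene
## abundances selected by homology-hit filters.

#' The configured lipid-A pathway gene set
#'
#' The nine-gene Raetz pathway (lipid A biosynthesis), ending in the terminal
#' acyltransferase LpxM that distinguishes hexa- from penta-acylated LPS.
#'
#' @return Character vector of gene names.
#' @export
lipid_a_genes <- function() {
  c("LpxA", "LpxC", "LpxD", "LpxH", "LpxB", "LpxK", "WaaA", "LpxL", "LpxM")
}

#' Classify taxa by LPS acylation capacity
#'
#' A pure function of the lipid-A gene presence vector: no genes present ->
#' `gram_positive`; all present -> `hexa_producer`; all except LpxM ->
#' `penta_producer`; any other pattern -> `unclassified` (counted and
#' logged).
#'
#' @param annotation A `taxon_annotation` with presence columns for the
#'   configured gene set.
#' @param gene_set Lipid-A gene names (default [lipid_a_genes()]).
#' @return data.frame: `taxon_id`, `cls`.
#' @export
classify_lps <- function(annotation, gene_set = lipid_a_genes()) {
  stopifnot(is.data.frame(annotation), "taxon_id" %in% names(annotation))
  missing <- setdiff(gene_set, names(annotation))
  if (length(missing)) stop("classify_lps: annotation lacks gene column(s): ",
                            paste(missing, collapse = ", "))
  pres <- as.matrix(annotation[, gene_set, drop = FALSE])
  if (!all(pres %in% c(0L, 1L))) stop("classify_lps: presence flags must be 0/1")
  cls <- apply(pres, 1L, function(v) classify_lps_pattern(v, gene_set))
  n_uncl <- sum(cls == "unclassified")
  if (n_uncl) log_msg(n_uncl, " taxa with partial lipid-A pathways (unclassified)",
                      level = "debug")
  data.frame(taxon_id = annotation$taxon_id, cls = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Classification of a single 0/1 presence pattern over the gene set.
classify_lps_pattern <- function(v, gene_set = lipid_a_genes()) {
  stopifnot(length(v) == length(gene_set))
  if (all(v == 0L)) return("gram_positive")
  if (all(v == 1L)) return("hexa_producer")
  if (all(v == as.integer(gene_set != "LpxM"))) return("penta_producer")
  "unclassified"
}

#' Per-sample LPS class abundances and hexa:penta ratio
#'
#' Sums relative abundance per LPS class; Gram-negative mass is the penta +
#' hexa + (optionally) partial-pathway unclassified mass, and the ratio is
#' `log10((hexa + eps) / (penta + eps))`. Samples with zero mass on both
#' hexa and penta producers get ratio 0 and a `no_mass` flag.
#'
#' @param abund Relative-mode `abundance_table` over taxa.
#' @param classes Output of [classify_lps()] covering the table's taxa.
#' @param eps Pseudocount (default 1e-6).
#' @param include_unclassified Count partial-lipid-A "unclassified" taxa in
#'   the Gram-negative mass (default TRUE).
#' @return data.frame per sample: class masses, `gram_negative`,
#'   `hexa_penta_log_ratio`, `no_mass`.
#' @export
class_abundances <- function(abund, classes, eps = 1e-6,
                             include_unclassified = TRUE) {
  stopifnot(inherits(abund, "abundance_table"))
  v <- abund$values
  missing <- setdiff(colnames(v), classes$taxon_id)
  if (length(missing)) stop("class_abundances: unclassified taxa absent from 'classes': ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  cl <- stats::setNames(classes$cls, classes$taxon_id)[colnames(v)]
  mass <- function(which_cls) {
    idx <- which(cl %in% which_cls)
    if (!length(idx)) return(numeric(nrow(v)))
    rowSums(v[, idx, drop = FALSE])
  }
  gp <- mass("gram_positive")
  pe <- mass("penta_producer")
  he <- mass("hexa_producer")
  un <- mass("unclassified")
  gn <- pe + he + if (include_unclassified) un else 0
  no_mass <- (pe == 0 & he == 0)
  data.frame(sample_id = rownames(v), gram_positive = gp,
             penta_producer = pe, hexa_producer = he, unclassified = un,
             gram_negative = gn,
             hexa_penta_log_ratio = ifelse(no_mass, 0, log10((he + eps) / (pe + eps))),
             no_mass = no_mass, stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter homology hits and assign genes to enzymes
#'
#' Keeps hits with identity strictly above `min_identity`, score strictly
#' above `min_score` and E-value strictly below `max_evalue` (the printed
#' BLASTP best-match convention), then keeps the best-scoring surviving hit
#' per gene.
#'
#' @param hits data.frame with `gene_id`, `enzyme_id`, `identity`, `score`,
#'   `evalue`.
#' @param min_identity,min_score,max_evalue Thresholds
#'   (defaults 35, 60, 1e-3).
#' @return data.frame `gene_id` -> `enzyme_id` (one row per gene; possibly
#'   empty).
#' @export
filter_homology_hits <- function(hits, min_identity = 35, min_score = 60,
                                 max_evalue = 1e-3) {
  stopifnot(is.data.frame(hits),
            all(c("gene_id", "enzyme_id", "identity", "score", "evalue") %in% names(hits)))
  keep <- hits$identity > min_identity & hits$score > min_score &
    hits$evalue < max_evalue
  surv <- hits[keep, , drop = FALSE]
  if (!nrow(surv)) {
    return(data.frame(gene_id = character(), enzyme_id = character(),
                      stringsAsFactors = FALSE))
  }
  surv <- surv[order(surv$gene_id, -surv$score, surv$enzyme_id), , drop = FALSE]
  best <- surv[!duplicated(surv$gene_id), c("gene_id", "enzyme_id"), drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Per-sample SCFA biosynthetic capacity
#'
#' Sums the relative abundance of genes assigned to each SCFA's terminal
#' enzymes (fixed map: CO dehydrogenase and the acetyl-CoA synthase complex
#' for acetate; propionyl-CoA transferase and propionyl-CoA/succinyl-CoA
#' transferase for propionate; butyryl-CoA transferase for butyrate).
#'
#' @param gene_abund Samples x genes numeric matrix (or `abundance_table`)
#'   of gene relative abundances.
#' @param gene_map data.frame `gene_id` -> `enzyme_id`
#'   (see [filter_homology_hits()]). Enzyme ids outside the fixed map are an
#'   error.
#' @param eps Pseudocount for the log10 view columns (default 1e-6).
#' @return data.frame per sample: `acetate`, `propionate`, `butyrate` plus
#'   `log10_*` views.
#' @export
scfa_capacity <- function(gene_abund, gene_map, eps = 1e-6) {
  v <- if (inherits(gene_abund, "abundance_table")) gene_abund$values else as.matrix(gene_abund)
  emap <- scfa_enzyme_map()
  known <- unlist(emap, use.names = FALSE)
  bad <- setdiff(unique(gene_map$enzyme_id), known)
  if (length(bad)) stop("scfa_capacity: enzyme id(s) outside the fixed map: ",
                        paste(bad, collapse = ", "))
  out <- data.frame(sample_id = rownames(v), stringsAsFactors = FALSE)
  for (s in names(emap)) {
    genes <- intersect(gene_map$gene_id[gene_map$enzyme_id %in% emap[[s]]],
                       colnames(v))
    out[[s]] <- if (length(genes)) rowSums(v[, genes, drop = FALSE]) else numeric(nrow(v))
    out[[paste0("log10_", s)]] <- log10(out[[s]] + eps)
  }
  out
}
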