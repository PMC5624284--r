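## Microbial dysbiosis index: per-sample log10 ratio of the summed abundance
## of disease-increased taxa over disease-decreased taxa.

#' Compute the microbial dysbiosis index per sample
#'
#' `md = log10((up_mass + eps) / (down_mass + eps))`, where `up_mass` and
#' `down_mass` are the summed abundances of the disease-increased and
#' disease-decreased taxon sets.
#'
#' @param abund Relative-mode `abundance_table`.
#' @param up_set,down_set Disjoint, non-empty feature-id sets.
#' @param eps Pseudocount guarding empty masses (default 1e-6).
#' @return data.frame: `sample_id`, `md`, `up_mass`, `down_mass`.
#' @export
md_index <- function(abund, up_set, down_set, eps = 1e-6) {
  stopifnot(inherits(abund, "abundance_table"))
  if (!length(up_set)) stop("md_index: up_set is empty")
  if (!length(down_set)) stop("md_index: down_set is empty")
  ov <- intersect(up_set, down_set)
  if (length(ov)) stop("md_index: sets overlap: ", paste(ov, collapse = ", "))
  unknown <- setdiff(c(up_set, down_set), colnames(abund$values))
  if (length(unknown)) stop("md_index: unknown taxon/taxa: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  up <- rowSums(abund$values[, up_set, drop = FALSE])
  dn <- rowSums(abund$values[, down_set, drop = FALSE])
  data.frame(sample_id = rownames(abund$values),
             md = log10((up + eps) / (dn + eps)),
             up_mass = up, down_mass = dn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive disease-increased/decreased taxon sets from biomarkers
#'
#' Maps each biomarker's enriched group to a disease polarity: features
#' enriched in CD-associated groups form the `up` set, features enriched in
#' CT-associated groups the `down` set. Biomarkers enriched in groups with no
#' polarity mapping are excluded with a warning.
#'
#' @param biomarkers A `biomarker_records` data.frame
#'   (see [discover_biomarkers()]).
#' @param cd_groups,ct_groups Group names considered CD- and CT-associated.
#' @return List with `up_set` and `down_set` (both non-empty, else error).
#' @export
derive_md_sets <- function(biomarkers, cd_groups, ct_groups) {
  stopifnot(is.data.frame(biomarkers), "enriched_group" %in% names(biomarkers))
  up <- biomarkers$feature_id[biomarkers$enriched_group %in% cd_groups]
  dn <- biomarkers$feature_id[biomarkers$enriched_group %in% ct_groups]
  unmapped <- !(biomarkers$enriched_group %in% c(cd_groups, ct_groups))
  if (any(unmapped)) {
    warning("derive_md_sets: excluding ", sum(unmapped),
            " biomarker(s) enriched in unmapped group(s): ",
            paste(unique(biomarkers$enriched_group[unmapped]), collapse = ", "))
  }
  if (!length(up)) stop("derive_md_sets: no CD-associated biomarkers")
  if (!length(dn)) stop("derive_md_sets: no CT-associated biomarkers")
  list(up_set = unique(up), down_set = unique(dn))
}
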