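## Reporter-score enrichment of KEGG pathways/modules: per-KO two-group
## Wilcoxon p-values are converted to signed normal quantiles, aggregated per
## pathway as sum(z)/sqrt(k), and standardized against the mean/SD of random
## same-size KO sets.

#' Per-KO signed z-scores between two groups
#'
#' Two-sided Wilcoxon rank-sum p per KO, signed by the direction of the
#' median difference (group B minus group A):
#' `z = sign * qnorm(1 - p/2)`, with p clipped to \[1e-15, 1 - 1e-15\].
#' KOs absent in all samples are dropped.
#'
#' @param ko_table `abundance_table` over KOs.
#' @param group_a,group_b Sample-id vectors, each of size >= 3.
#' @return data.frame: `ko_id`, `p`, `direction`, `z`.
#' @export
ko_zscores <- function(ko_table, group_a, group_b) {
  stopifnot(inherits(ko_table, "abundance_table"))
  if (length(group_a) < 3L || length(group_b) < 3L) {
    stop("ko_zscores: each group needs >= 3 samples")
  }
  v <- ko_table$values
  missing <- setdiff(c(group_a, group_b), rownames(v))
  if (length(missing)) stop("ko_zscores: unknown sample(s): ",
                            paste(utils::head(missing, 3L), collapse = ", "))
  present <- colSums(v[c(group_a, group_b), , drop = FALSE]) > 0
  v <- v[, present, drop = FALSE]
  p <- vapply(seq_len(ncol(v)), function(j)
    wilcox_p(v[group_a, j], v[group_b, j]), numeric(1L))
  dir <- sign(apply(v[group_b, , drop = FALSE], 2L, stats::median) -
                apply(v[group_a, , drop = FALSE], 2L, stats::median))
  p_cl <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  z <- dir * stats::qnorm(1 - p_cl / 2)
  data.frame(ko_id = colnames(v), p = p, direction = dir, z = z,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reporter scores per pathway
#'
#' For each pathway with `k` scored member KOs, `raw_z = sum(z) / sqrt(k)`;
#' the background mean and SD for size `k` come from `n_background` random KO
#' sets of size `k` drawn without replacement from all scored KOs, and
#' `score = (raw_z - mu_k) / sigma_k`. Pathways whose |score| exceeds 1.9
#' (the display threshold used for reporting) are flagged.
#'
#' @param kostats Output of [ko_zscores()].
#' @param pathway_map data.frame with columns `pathway` and `ko`.
#' @param n_background Random background sets per pathway size
#'   (default 1000, minimum 100).
#' @param seed Integer seed.
#' @return data.frame: `pathway_id`, `k`, `raw_z`, `mu_k`, `sigma_k`,
#'   `score`, `significant`.
#' @export
reporter_scores <- function(kostats, pathway_map, n_background = 1000L, seed = 1L) {
  stopifnot(is.data.frame(kostats), all(c("ko_id", "z") %in% names(kostats)),
            is.data.frame(pathway_map),
            all(c("pathway", "ko") %in% names(pathway_map)))
  if (n_background < 100L) stop("reporter_scores: n_background must be >= 100")
  z <- stats::setNames(kostats$z, kostats$ko_id)
  pw <- split(pathway_map$ko, pathway_map$pathway)
  ks <- vapply(pw, function(m) sum(m %in% names(z)), integer(1L))
  skipped <- names(pw)[ks == 0L]
  if (length(skipped)) {
    warning("reporter_scores: skipping pathway(s) with no scored KOs: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  }
  pw <- pw[ks > 0L]
  ks <- ks[ks > 0L]
  raw <- vapply(names(pw), function(p) {
    zz <- z[pw[[p]][pw[[p]] %in% names(z)]]
    sum(zz) / sqrt(length(zz))
  }, numeric(1L))
  bg <- with_seed(derive_seed(seed, "reporter-bg"), {
    out <- list()
    for (k in sort(unique(ks))) {
      draws <- vapply(seq_len(n_background), function(i)
        sum(z[sample.int(length(z), k)]) / sqrt(k), numeric(1L))
      out[[as.character(k)]] <- c(mu = mean(draws), sigma = stats::sd(draws))
    }
    out
  })
  mu <- vapply(as.character(ks), function(k) bg[[k]][["mu"]], numeric(1L))
  sg <- vapply(as.character(ks), function(k) bg[[k]][["sigma"]], numeric(1L))
  if (any(sg <= 0)) stop("reporter_scores: degenerate background SD")
  score <- (raw - mu) / sg
  data.frame(pathway_id = names(pw), k = as.integer(ks), raw_z = unname(raw),
             mu_k = unname(mu), sigma_k = unname(sg), score = unname(score),
             significant = abs(unname(score)) > 1.9,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a reporter-score table for reporting
#'
#' Excludes pathways with |score| <= threshold (default 1.9, the display
#' convention for reporter-score heatmaps).
#'
#' @param scores Output of [reporter_scores()].
#' @param threshold Absolute-score threshold (default 1.9).
#' @return The filtered data.frame, ordered by decreasing |score|.
#' @export
significant_pathways <- function(scores, threshold = 1.9) {
  out <- scores[abs(scores$score) > threshold, , drop = FALSE]
  out[order(-abs(out$score)), , drop = FALSE]
}
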