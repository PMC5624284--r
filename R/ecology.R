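## Diversity, ordination, association, and multivariate statistics shared
## across the pipeline: Shannon index, gene counts, Bray-Curtis /
## Jensen-Shannon / Gower distances, PCoA, one-way PERMANOVA, bioenv-style
## covariate subset search, Fisher's exact metacommunity-disease association
## with BH, and per-feature Wilcoxon + BH with the four-tier q scheme.

#' Shannon alpha-diversity of a relative-abundance profile
#'
#' `H = -sum over p > 0 of p * ln p` (natural log).
#'
#' @param profile Non-negative vector summing to 1 (tolerance 1e-8).
#' @return Numeric.
#' @export
shannon_index <- function(profile) {
  if (any(profile < 0)) stop("shannon_index: negative entries")
  if (abs(sum(profile) - 1) > 1e-8) stop("shannon_index: profile must sum to 1")
  p <- profile[profile > 0]
  -sum(p * log(p))
}

#' Gene count of a sample (features with at least one mapped read)
#'
#' @param counts_row Non-negative counts vector.
#' @return Integer number of features with value >= 1.
#' @export
gene_count <- function(counts_row) {
  if (any(counts_row < 0)) stop("gene_count: negative counts")
  sum(counts_row >= 1)
}

# Shared two-group Wilcoxon p-value: exact for combined n <= 25 without
# ties, normal approximation with tie/continuity correction otherwise;
# constant pooled data gives p = 1.
wilcox_p <- function(x, y) {
  if (max(c(x, y)) == min(c(x, y))) return(1)
  exact <- (length(x) + length(y) <= 25L) && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Pairwise sample distances
#'
#' Bray-Curtis (`sum|x-y| / sum(x+y)`) and Jensen-Shannon distance
#' (`sqrt(JSD)`, natural log, metric form) on relative abundances; Gower on
#' a mixed covariate data.frame (numeric covariates standardized to zero
#' mean/unit variance, then range-normalized absolute differences;
#' categorical mismatch indicators; missing pairs ignored in the mean).
#'
#' @param x Relative-mode `abundance_table` (bray_curtis, jensen_shannon) or
#'   covariate data.frame (gower).
#' @param metric One of `"bray_curtis"`, `"jensen_shannon"`, `"gower"`.
#' @return List of class `mc_dist`: `ids`, `D` (symmetric matrix, zero
#'   diagonal), `metric`.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "jensen_shannon", "gower")) {
  metric <- match.arg(metric)
  if (metric %in% c("bray_curtis", "jensen_shannon")) {
    if (!inherits(x, "abundance_table") || !startsWith(x$mode, "relative")) {
      stop("distance_matrix: ", metric, " requires a relative-mode abundance_table")
    }
    v <- x$values
    D <- switch(metric,
      bray_curtis = as.matrix(vegan::vegdist(v, method = "bray")),
      jensen_shannon = jsd_matrix(v))
    dimnames(D) <- list(rownames(v), rownames(v))
    ids <- rownames(v)
  } else {
    if (!is.data.frame(x)) stop("distance_matrix: gower requires a covariate data.frame")
    D <- gower_matrix(x)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  structure(list(ids = ids, D = D, metric = metric), class = "mc_dist")
}

jsd_matrix <- function(v) {
  n <- nrow(v)
  D <- matrix(0, n, n)
  kl <- function(p, m) {
    i <- p > 0
    sum(p[i] * log(p[i] / m[i]))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- (v[i, ] + v[j, ]) / 2
      D[i, j] <- D[j, i] <- sqrt(pmax(0, 0.5 * kl(v[i, ], m) + 0.5 * kl(v[j, ], m)))
    }
  }
  D
}

# Gower on standardized numerics (range-normalized) and categorical
# mismatches; NA pairs dropped from the per-pair mean.
gower_matrix <- function(df, standardize = TRUE) {
  n <- nrow(df)
  num <- vapply(df, is.numeric, logical(1L))
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (j in seq_along(df)) {
    v <- df[[j]]
    ok <- !is.na(v)
    pair_ok <- outer(ok, ok, "&")
    if (num[j]) {
      z <- v
      if (standardize && stats::sd(v, na.rm = TRUE) > 0) {
        z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
      }
      rg <- diff(range(z, na.rm = TRUE))
      d <- if (rg > 0) abs(outer(z, z, "-")) / rg else matrix(0, n, n)
    } else {
      d <- outer(as.character(v), as.character(v), "!=") * 1
    }
    d[!pair_ok] <- 0
    acc <- acc + d
    cnt <- cnt + pair_ok
  }
  D <- ifelse(cnt > 0, acc / cnt, 0)
  diag(D) <- 0
  D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared-distance Gram matrix and extracts the top
#' eigenpairs. Axes come from positive eigenvalues (negative eigenvalues are
#' reported); the sign convention makes each axis's largest-magnitude
#' loading positive.
#'
#' @param D An `mc_dist` (or distance matrix).
#' @param n_axes Number of axes requested (truncated with a warning if it
#'   exceeds the positive eigenvalue count).
#' @return List: `coordinates` (samples x axes), `eigenvalues` (all),
#'   `var_explained` (relative, over positive eigenvalues).
#' @export
pcoa <- function(D, n_axes = 2L) {
  ids <- NULL
  if (inherits(D, "mc_dist")) {
    ids <- D$ids
    D <- D$D
  }
  n <- nrow(D)
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are reported to the caller instead
  cm <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1L, eig = TRUE))
  eig <- cm$eig
  npos <- sum(eig > 1e-9)
  if (n_axes > npos) {
    warning("pcoa: requested ", n_axes, " axes but only ", npos,
            " positive eigenvalues; truncating")
    n_axes <- npos
  }
  coords <- cm$points[, seq_len(n_axes), drop = FALSE]
  for (a in seq_len(ncol(coords))) {
    sgn <- sign(coords[which.max(abs(coords[, a])), a])
    if (sgn < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- ids %||% rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       var_explained = pmax(eig, 0)[seq_len(max(1L, n_axes))] / sum(pmax(eig, 0)))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from the within/total squared-distance decomposition
#' (`SS_total = sum d^2 / N`, `SS_within = sum over groups of within-group
#' d^2 / n_g`), with the p-value from seeded label permutations:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param D `mc_dist` or distance matrix.
#' @param labels Group labels (>= 2 groups, each >= 2 samples).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `permanova_result`: `pseudo_F`, `p`,
#'   `n_permutations`, `group_sizes`.
#' @export
permanova <- function(D, labels, n_permutations = 999L, seed = 1L) {
  if (inherits(D, "mc_dist")) D <- D$D
  labels <- as.character(labels)
  N <- nrow(D)
  stopifnot(length(labels) == N)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("permanova: at least 2 groups required")
  if (any(sizes < 2L)) stop("permanova: singleton group(s): ",
                            paste(names(sizes)[sizes < 2L], collapse = ", "))
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / N
  a <- length(sizes)
  fstat <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  }
  f_obs <- fstat(labels)
  exceed <- with_seed(derive_seed(seed, "permanova"), {
    sum(vapply(seq_len(n_permutations), function(b)
      fstat(sample(labels)) >= f_obs, logical(1L)))
  })
  structure(list(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 group_sizes = as.integer(sizes)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p, x$n_permutations))
  invisible(x)
}

#' bioenv: covariate subsets best correlated with community dissimilarity
#'
#' Exhaustive search over non-empty covariate subsets up to
#' `max_subset_size`; each subset is scored by the Pearson correlation
#' between its Gower distances (numeric covariates standardized first) and
#' the community dissimilarities. Ties report the lexicographically smallest
#' subset.
#'
#' @param community_d `mc_dist` or distance matrix over samples.
#' @param covariates data.frame of covariates (rows = samples, matching
#'   order).
#' @param max_subset_size Largest subset searched; required when more than
#'   20 covariates are supplied (combinatorial guard).
#' @return List of class `bioenv_result`: `best_subset`, `best_r`, `table`
#'   (subset, size, r).
#' @export
bioenv <- function(community_d, covariates, max_subset_size = NULL) {
  if (inherits(community_d, "mc_dist")) community_d <- community_d$D
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(community_d))
  p <- ncol(covariates)
  if (p < 1L) stop("bioenv: at least one covariate required")
  if (is.null(max_subset_size)) {
    if (p > 20L) stop("bioenv: > 20 covariates requires max_subset_size")
    max_subset_size <- p
  }
  max_subset_size <- min(max_subset_size, p)
  dcomm <- community_d[upper.tri(community_d)]
  nm <- sort(names(covariates))
  rows <- list()
  best <- list(r = -Inf, subset = NULL)
  for (k in seq_len(max_subset_size)) {
    for (sub in utils::combn(nm, k, simplify = FALSE)) {
      G <- gower_matrix(covariates[, sub, drop = FALSE])
      r <- suppressWarnings(stats::cor(G[upper.tri(G)], dcomm, method = "pearson"))
      if (is.na(r)) r <- -Inf
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(sub, collapse = "+"), size = k, r = r,
        stringsAsFactors = FALSE)
      if (r > best$r) best <- list(r = r, subset = sub)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(best_subset = best$subset, best_r = best$r,
                 table = tab[order(-tab$r), , drop = FALSE]),
            class = "bioenv_result")
}

#' Fisher's exact association between membership groups and disease
#'
#' Per membership group, a 2x2 table (in group vs not, CD vs CT) is tested
#' two-sided by Fisher's exact test; BH adjustment across groups yields
#' q-values. Empty margins give p = 1 with a warning.
#'
#' @param membership Group labels per sample.
#' @param disease Disease labels (`CT`/`CD`), same length.
#' @return data.frame: `group`, `n_in_cd`, `n_in_ct`, `odds_ratio`, `p`, `q`.
#' @export
fisher_association <- function(membership, disease) {
  stopifnot(length(membership) == length(disease))
  disease <- as.character(disease)
  if (!all(disease %in% c("CT", "CD"))) stop("disease labels must be CT/CD")
  groups <- sort(unique(as.character(membership)))
  if (length(groups) < 2L) stop("fisher_association: >= 2 membership groups required")
  rows <- lapply(groups, function(g) {
    tab <- matrix(c(sum(membership == g & disease == "CD"),
                    sum(membership == g & disease == "CT"),
                    sum(membership != g & disease == "CD"),
                    sum(membership != g & disease == "CT")), 2L, 2L)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      warning("fisher_association: empty margin for group ", g, "; p = 1")
      return(data.frame(group = g, n_in_cd = tab[1L, 1L], n_in_ct = tab[2L, 1L],
                        odds_ratio = NA_real_, p = 1, stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(group = g, n_in_cd = tab[1L, 1L], n_in_ct = tab[2L, 1L],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-feature Wilcoxon tests with BH correction and significance tiers
#'
#' Two-sided rank-sum per feature between two sample groups, BH-adjusted
#' across features, with the four-tier scheme:
#' `*` q < 0.2, `**` q < 0.1, `***` q < 0.05, `****` q < 0.001.
#'
#' @param abund `abundance_table` (any mode) or numeric matrix.
#' @param group_a,group_b Sample-id vectors, each >= 3.
#' @return data.frame: `feature_id`, `median_a`, `median_b`, `p`, `q`,
#'   `tier`.
#' @export
wilcoxon_bh <- function(abund, group_a, group_b) {
  v <- if (inherits(abund, "abundance_table")) abund$values else as.matrix(abund)
  if (length(group_a) < 3L || length(group_b) < 3L) {
    stop("wilcoxon_bh: each group needs >= 3 samples")
  }
  p <- vapply(seq_len(ncol(v)), function(j)
    wilcox_p(v[group_a, j], v[group_b, j]), numeric(1L))
  q <- stats::p.adjust(p, method = "BH")
  tier <- q_tier(q)
  data.frame(feature_id = colnames(v),
             median_a = apply(v[group_a, , drop = FALSE], 2L, stats::median),
             median_b = apply(v[group_b, , drop = FALSE], 2L, stats::median),
             p = p, q = q, tier = tier, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Map q-values to the four-tier significance scheme
#'
#' @param q Numeric q-values.
#' @return Character: `"****"` (q < 0.001), `"***"` (q < 0.05),
#'   `"**"` (q < 0.1), `"*"` (q < 0.2), `""` otherwise.
#' @export
q_tier <- function(q) {
  ifelse(q < 0.001, "****",
         ifelse(q < 0.05, "***",
                ifelse(q < 0.1, "**",
                       ifelse(q < 0.2, "*", ""))))
}
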