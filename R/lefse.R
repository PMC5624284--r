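## Adapted LEfSe biomarker discovery: a "less stringent" screen keeping any
## feature that differs in at least one declared group comparison (two-sided
## rank-sum, unadjusted alpha), followed by a bootstrapped log10 linear
## discriminant effect size; biomarkers are features with score >= threshold.

#' Declare groups and pairwise comparisons
#'
#' @param groups Named list of sample-id vectors (e.g. metacommunities A, B, C
#'   and subgroups B-CT, B-CD).
#' @param comparisons List of length-2 character vectors naming group pairs to
#'   test; defaults to all pairs of `groups`.
#' @return An object of class `comparison_scheme`.
#' @export
comparison_scheme <- function(groups, comparisons = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(groups), 2L, simplify = FALSE)
  }
  for (cp in comparisons) {
    if (length(cp) != 2L || !all(cp %in% names(groups))) {
      stop("comparison references undefined group(s): ", paste(cp, collapse = " vs "))
    }
  }
  structure(list(groups = groups, comparisons = comparisons),
            class = "comparison_scheme")
}

#' Build the study's default comparison scheme
#'
#' Metacommunity groups from hard DMM labels plus disease subgroups within
#' the mixed metacommunity, compared as: every metacommunity pair plus the
#' within-mixed CT-vs-CD subgroup pair.
#'
#' @param metadata `sample_metadata`.
#' @param labels Integer metacommunity labels named by sample id
#'   (see [assign_metacommunities()]).
#' @param mixed Which metacommunity (letter) holds both disease groups;
#'   defaults to the one with the most balanced CT/CD split.
#' @return A `comparison_scheme`.
#' @export
default_scheme <- function(metadata, labels, mixed = NULL) {
  stopifnot(all(names(labels) %in% metadata$sample_id))
  letter <- LETTERS[labels]
  groups <- split(names(labels), letter)
  disease <- stats::setNames(metadata$disease_status, metadata$sample_id)[names(labels)]
  if (is.null(mixed)) {
    bal <- vapply(names(groups), function(g) {
      d <- disease[groups[[g]]]
      min(sum(d == "CT"), sum(d == "CD"))
    }, numeric(1L))
    mixed <- names(groups)[which.max(bal)]
  }
  comparisons <- utils::combn(names(groups), 2L, simplify = FALSE)
  for (d in c("CT", "CD")) {
    sub <- groups[[mixed]][disease[groups[[mixed]]] == d]
    if (length(sub) >= 3L) groups[[paste0(mixed, "-", d)]] <- sub
  }
  sub_names <- paste0(mixed, "-", c("CT", "CD"))
  if (all(sub_names %in% names(groups))) {
    comparisons <- c(comparisons, list(sub_names))
  }
  structure(list(groups = groups, comparisons = comparisons),
            class = "comparison_scheme")
}

#' Screen features differing in at least one comparison
#'
#' A feature passes iff its two-sided Wilcoxon rank-sum p-value is below
#' `alpha` (unadjusted) in at least one declared comparison.
#'
#' @param abund Relative-mode `abundance_table`.
#' @param scheme A `comparison_scheme`; every compared group needs >= 3
#'   samples.
#' @param alpha Screen level (default 0.05).
#' @return List with `pass` (named logical) and `p` (features x comparisons
#'   matrix of p-values).
#' @export
screen_features <- function(abund, scheme, alpha = 0.05) {
  stopifnot(inherits(abund, "abundance_table"), inherits(scheme, "comparison_scheme"))
  if (!startsWith(abund$mode, "relative")) {
    stop("screen_features: relative abundances required")
  }
  v <- abund$values
  for (g in names(scheme$groups)) {
    ids <- scheme$groups[[g]]
    if (length(ids) < 3L) stop("group with < 3 samples: ", g)
    missing <- setdiff(ids, rownames(v))
    if (length(missing)) stop("group ", g, " references unknown sample(s): ",
                              paste(utils::head(missing, 3L), collapse = ", "))
  }
  cmp_names <- vapply(scheme$comparisons, paste, character(1L), collapse = "_vs_")
  p <- matrix(NA_real_, ncol(v), length(scheme$comparisons),
              dimnames = list(colnames(v), cmp_names))
  for (j in seq_along(scheme$comparisons)) {
    cp <- scheme$comparisons[[j]]
    xa <- v[scheme$groups[[cp[1L]]], , drop = FALSE]
    xb <- v[scheme$groups[[cp[2L]]], , drop = FALSE]
    p[, j] <- vapply(seq_len(ncol(v)), function(f)
      wilcox_p(xa[, f], xb[, f]), numeric(1L))
  }
  list(pass = apply(p < alpha, 1L, any), p = p)
}

# Two-class LDA direction: ridge-regularized pooled-covariance solve of
# Sigma_w^-1 (m1 - m2); proportional to the MASS::lda scaling for two classes.
lda_direction <- function(X, cl) {
  m1 <- colMeans(X[cl == 1L, , drop = FALSE])
  m2 <- colMeans(X[cl == 2L, , drop = FALSE])
  S <- (crossprod(scale(X[cl == 1L, , drop = FALSE], center = m1, scale = FALSE)) +
          crossprod(scale(X[cl == 2L, , drop = FALSE], center = m2, scale = FALSE))) /
    (nrow(X) - 2L)
  lam <- 1e-6 * mean(diag(S))
  if (!is.finite(lam) || lam <= 0) lam <- 1e-8
  w <- tryCatch(solve(S + diag(lam, ncol(X)), m1 - m2),
                error = function(e) {
                  log_msg("singular within-class scatter; increasing ridge",
                          level = "info")
                  solve(S + diag(mean(diag(S)) * 1e-2 + 1e-8, ncol(X)), m1 - m2)
                })
  nw <- sqrt(sum(w^2))
  if (nw <= 0 || !is.finite(nw)) w else w / nw
}

#' Bootstrapped logarithmic LDA effect sizes for one group pair
#'
#' Per bootstrap: subsample `boot_fraction` of each group without
#' replacement, fit a two-class linear discriminant on the feature matrix
#' (abundances rescaled to "per ten thousand"; see Details), and record per
#' feature the mean of the absolute raw class-mean difference and the
#' absolute LDA-axis contribution. The reported score is
#' `log10(1 + mean over bootstraps of 0.5 * (|d_raw| + |d_lda|))`.
#'
#' @details The abundance rescaling constant (`scale`, default 1e4) pins the
#' log10 effect-size scale: a score of 2 corresponds to a combined class
#' difference of about 1 percent absolute relative abundance. All thresholds
#' in this package refer to this pinned construction.
#'
#' @param abund Relative-mode `abundance_table`.
#' @param group_a,group_b Sample-id vectors of the two classes.
#' @param features Feature ids to score.
#' @param n_boot Bootstrap count (default 30).
#' @param boot_fraction Per-class subsample fraction (default 2/3, without
#'   replacement).
#' @param seed Integer seed.
#' @param scale Abundance rescaling constant (default 1e4).
#' @return data.frame: `feature_id`, `lda_score`, `enriched_group`, `n_boot`.
#' @export
lda_effect_size <- function(abund, group_a, group_b, features = NULL,
                            n_boot = 30L, boot_fraction = 2 / 3, seed = 1L,
                            scale = 1e4) {
  stopifnot(inherits(abund, "abundance_table"))
  v <- abund$values
  if (is.null(features)) features <- colnames(v)
  Xa <- v[group_a, features, drop = FALSE] * scale
  Xb <- v[group_b, features, drop = FALSE] * scale
  na <- nrow(Xa); nb <- nrow(Xb)
  ka <- max(2L, ceiling(boot_fraction * na))
  kb <- max(2L, ceiling(boot_fraction * nb))
  eff <- matrix(0, n_boot, length(features))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      ia <- sample.int(na, ka)
      ib <- sample.int(nb, kb)
      X <- rbind(Xa[ia, , drop = FALSE], Xb[ib, , drop = FALSE])
      cl <- rep(c(1L, 2L), c(ka, kb))
      keep <- which(apply(X, 2L, stats::sd) > 0)
      d_raw <- abs(colMeans(Xa[ia, , drop = FALSE]) - colMeans(Xb[ib, , drop = FALSE]))
      d_lda <- numeric(length(features))
      if (length(keep) >= 1L) {
        w <- lda_direction(X[, keep, drop = FALSE], cl)
        ld <- X[, keep, drop = FALSE] %*% w
        sep <- abs(mean(ld[cl == 1L]) - mean(ld[cl == 2L]))
        d_lda[keep] <- abs(w) * sep
      }
      eff[b, ] <- 0.5 * (d_raw + d_lda)
    }
  })
  score <- log10(1 + colMeans(eff))
  med_a <- apply(Xa, 2L, stats::median)
  med_b <- apply(Xb, 2L, stats::median)
  enr <- ifelse(med_a == med_b,
                ifelse(colMeans(Xa) >= colMeans(Xb), "A", "B"),
                ifelse(med_a > med_b, "A", "B"))
  data.frame(feature_id = features, lda_score = as.numeric(score),
             enriched_group = enr, n_boot = as.integer(n_boot),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Discover biomarkers: screen, score, rank
#'
#' Runs the screen, computes bootstrapped LDA effect sizes for every declared
#' comparison over the screened features, takes each feature's final score as
#' the maximum over comparisons, and retains features with score at least
#' `lda_threshold` (default 2), ranked in descending order.
#'
#' @param abund Relative-mode `abundance_table`.
#' @param scheme A `comparison_scheme`.
#' @param alpha Screen level (default 0.05, unadjusted).
#' @param lda_threshold Reporting threshold on the log10 LDA score (default 2).
#' @param n_boot,boot_fraction,seed,scale Passed to [lda_effect_size()].
#' @return data.frame of class `biomarker_records`: `feature_id`,
#'   `enriched_group`, `lda_score`, `best_comparison`, `n_boot`,
#'   `passed_screen`, `p_min`; attribute `screen` holds the full screen
#'   output.
#' @export
discover_biomarkers <- function(abund, scheme, alpha = 0.05, lda_threshold = 2,
                                n_boot = 30L, boot_fraction = 2 / 3, seed = 1L,
                                scale = 1e4) {
  scr <- screen_features(abund, scheme, alpha = alpha)
  passed <- names(which(scr$pass))
  empty <- data.frame(feature_id = character(), enriched_group = character(),
                      lda_score = numeric(), best_comparison = character(),
                      n_boot = integer(), passed_screen = logical(),
                      p_min = numeric(), stringsAsFactors = FALSE)
  if (!length(passed) || identical(lda_threshold, Inf)) {
    attr(empty, "screen") <- scr
    class(empty) <- c("biomarker_records", "data.frame")
    return(empty)
  }
  best_score <- stats::setNames(rep(-Inf, length(passed)), passed)
  best_cmp <- stats::setNames(rep(NA_character_, length(passed)), passed)
  best_grp <- stats::setNames(rep(NA_character_, length(passed)), passed)
  for (j in seq_along(scheme$comparisons)) {
    cp <- scheme$comparisons[[j]]
    es <- lda_effect_size(abund, scheme$groups[[cp[1L]]], scheme$groups[[cp[2L]]],
                          features = passed, n_boot = n_boot,
                          boot_fraction = boot_fraction,
                          seed = derive_seed(seed, paste(cp, collapse = "|")),
                          scale = scale)
    better <- es$lda_score > best_score
    best_score[better] <- es$lda_score[better]
    best_cmp[better] <- paste(cp, collapse = "_vs_")
    best_grp[better] <- ifelse(es$enriched_group[better] == "A", cp[1L], cp[2L])
  }
  keep <- which(best_score >= lda_threshold)
  out <- data.frame(feature_id = passed[keep],
                    enriched_group = unname(best_grp[keep]),
                    lda_score = unname(best_score[keep]),
                    best_comparison = unname(best_cmp[keep]),
                    n_boot = rep(as.integer(n_boot), length(keep)),
                    passed_screen = rep(TRUE, length(keep)),
                    p_min = vapply(keep, function(i) min(scr$p[passed[i], ]),
                                   numeric(1L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$lda_score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen") <- scr
  class(out) <- c("biomarker_records", "data.frame")
  out
}
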