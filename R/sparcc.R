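## SparCC compositional correlation inference: Dirichlet-resampled fractions,
## log-ratio variances t_ij = Var(log x_i/x_j), the sparsity-approximation
## linear system for basis variances, iterative exclusion of the strongest
## correlated pair, averaging over resampling rounds, and permutation-based
## empirical p-values; plus thresholded network construction and two-network
## comparison.

# Basis-variance solve with an exclusion mask. t_mat is the T x T log-ratio
# variance matrix; excl a logical matrix of excluded pairs. Under the sparse-
# correlation assumption, rowSums over included pairs of t satisfy
# M omega = t_rowsum with M = diag(d_i) + A (A = included-pair adjacency).
sparcc_basis <- function(t_mat, excl = NULL) {
  Tn <- nrow(t_mat)
  adj <- matrix(TRUE, Tn, Tn)
  diag(adj) <- FALSE
  if (!is.null(excl)) adj[excl] <- FALSE
  d <- rowSums(adj)
  M <- diag(d) + adj * 1
  t_sum <- rowSums(t_mat * adj)
  omega <- solve(M, t_sum)
  if (any(omega <= 0)) {
    log_msg("negative basis variance(s) clipped to 1e-8", level = "debug")
    omega <- pmax(omega, 1e-8)
  }
  so <- sqrt(omega)
  rho <- (outer(omega, omega, "+") - t_mat) / (2 * outer(so, so))
  diag(rho) <- 1
  list(omega = omega, rho = rho)
}

# One SparCC inference pass on a fraction matrix (samples x taxa):
# log-ratio variances, basis solve, then iterative exclusion of the
# strongest pair above the exclusion threshold.
sparcc_once <- function(frac, exclusion_threshold = 0.25,
                        max_exclusion_rounds = 10L) {
  lf <- log(frac)
  V <- stats::cov(lf)
  t_mat <- outer(diag(V), diag(V), "+") - 2 * V
  Tn <- ncol(frac)
  excl <- matrix(FALSE, Tn, Tn)
  res <- sparcc_basis(t_mat, excl)
  for (round in seq_len(max_exclusion_rounds)) {
    r <- abs(res$rho)
    r[excl] <- 0
    r[lower.tri(r, diag = TRUE)] <- 0
    m <- max(r)
    if (m <= exclusion_threshold) break
    ij <- which(r == m, arr.ind = TRUE)[1L, ]
    excl[ij[1L], ij[2L]] <- TRUE
    excl[ij[2L], ij[1L]] <- TRUE
    res <- sparcc_basis(t_mat, excl)
  }
  res
}

#' SparCC correlations from a count table
#'
#' Per inference iteration, sample fractions are Dirichlet-resampled from the
#' posterior with unit pseudocounts, log-ratio variances are computed, the
#' sparsity-approximation linear system yields basis variances, correlations
#' follow, and the most strongly correlated pair above `exclusion_threshold`
#' is iteratively excluded and the system re-solved. The final correlation
#' matrix is the element-wise mean over `n_iterations`.
#'
#' @param counts Counts-mode `abundance_table` with at least 4 taxa.
#' @param n_iterations Resampling rounds averaged (default 20).
#' @param exclusion_threshold Pair-exclusion strength (default 0.25).
#' @param max_exclusion_rounds Maximum exclusions per round (default 10).
#' @param seed Integer seed.
#' @return List of class `sparcc_result`: `rho` (symmetric, unit diagonal),
#'   `omega`, `n_iterations`, `exclusion_threshold`.
#' @export
sparcc_correlations <- function(counts, n_iterations = 20L,
                                exclusion_threshold = 0.25,
                                max_exclusion_rounds = 10L, seed = 1L) {
  stopifnot(inherits(counts, "abundance_table"))
  if (counts$mode != "counts") stop("sparcc_correlations: counts-mode table required")
  X <- counts$values
  if (ncol(X) < 4L) stop("sparcc_correlations: at least 4 taxa required")
  Tn <- ncol(X)
  rho_sum <- matrix(0, Tn, Tn)
  omega_sum <- numeric(Tn)
  with_seed(derive_seed(seed, "sparcc"), {
    for (it in seq_len(n_iterations)) {
      g <- matrix(stats::rgamma(length(X), shape = X + 1), nrow(X), Tn)
      frac <- g / rowSums(g)
      res <- sparcc_once(frac, exclusion_threshold, max_exclusion_rounds)
      rho_sum <- rho_sum + res$rho
      omega_sum <- omega_sum + res$omega
    }
  })
  rho <- rho_sum / n_iterations
  if (max(abs(rho)) > 1 + 1e-8) {
    warning("sparcc_correlations: |rho| > 1 clipped")
  }
  rho <- pmin(pmax(rho, -1), 1)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(X), colnames(X))
  structure(list(rho = rho, omega = omega_sum / n_iterations,
                 n_iterations = n_iterations,
                 exclusion_threshold = exclusion_threshold),
            class = "sparcc_result")
}

#' Empirical p-values for SparCC correlations
#'
#' Null datasets are built by independently permuting each taxon's counts
#' across samples (the standard SparCC pseudo-p procedure); SparCC is re-run
#' on each with a reduced iteration count, and two-sided empirical p-values
#' are `(1 + #{|rho_null| >= |rho_obs|}) / (1 + n_null)`.
#'
#' @param counts Counts-mode `abundance_table`.
#' @param observed A `sparcc_result` (or its `rho` matrix).
#' @param n_null Number of null datasets (>= 100; default 1000).
#' @param seed Integer seed.
#' @param n_iterations Resampling rounds per null run (default 5).
#' @param ... Passed to [sparcc_correlations()].
#' @return Matrix of p-values (diagonal 1).
#' @export
sparcc_pvalues <- function(counts, observed, n_null = 1000L, seed = 1L,
                           n_iterations = 5L, ...) {
  if (inherits(observed, "sparcc_result")) observed <- observed$rho
  if (n_null < 100L) stop("sparcc_pvalues: n_null must be >= 100")
  X <- counts$values
  exceed <- matrix(0L, ncol(X), ncol(X))
  for (b in seq_len(n_null)) {
    Xp <- with_seed(derive_seed(seed, paste0("null", b)), {
      apply(X, 2L, sample)
    })
    rownames(Xp) <- rownames(X)
    # clipping warnings are routine on permuted small-sample nulls
    null_rho <- suppressWarnings(sparcc_correlations(
      abundance_table(Xp, mode = "counts"), n_iterations = n_iterations,
      seed = derive_seed(seed, paste0("nullrho", b)), ...))$rho
    exceed <- exceed + (abs(null_rho) >= abs(observed))
  }
  p <- (1 + exceed) / (1 + n_null)
  diag(p) <- 1
  dimnames(p) <- dimnames(observed)
  p
}

#' Build a thresholded correlation network
#'
#' Retains edges with `p < p_threshold` and `|rho| >= edge_threshold`;
#' positive correlations are co-occurrence, negative co-exclusion.
#'
#' @param result `sparcc_result` (or correlation matrix).
#' @param p Matrix of empirical p-values aligned with the correlations.
#' @param edge_threshold Minimum |rho| (default 0.3, the display convention).
#' @param p_threshold Maximum p (default 0.01).
#' @param node_attrs Optional data.frame of node attributes with a
#'   `taxon_id` column (e.g. mean abundance, growth rate, phylum).
#' @return List of class `mc_network`: `nodes`, `edges` (i, j, rho, p, sign).
#' @export
build_network <- function(result, p, edge_threshold = 0.3, p_threshold = 0.01,
                          node_attrs = NULL) {
  rho <- if (inherits(result, "sparcc_result")) result$rho else result
  stopifnot(all(dim(rho) == dim(p)))
  ids <- colnames(rho) %||% as.character(seq_len(ncol(rho)))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  keep <- p[ut] < p_threshold & abs(rho[ut]) >= edge_threshold
  ut <- ut[keep, , drop = FALSE]
  edges <- data.frame(i = ids[ut[, 1L]], j = ids[ut[, 2L]],
                      rho = rho[ut], p = p[ut],
                      sign = ifelse(rho[ut] >= 0, "co_occurrence", "co_exclusion"),
                      stringsAsFactors = FALSE, row.names = NULL)
  nodes <- data.frame(taxon_id = ids, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    nodes <- merge(nodes, node_attrs, by = "taxon_id", all.x = TRUE, sort = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold, p_threshold = p_threshold),
            class = "mc_network")
}

#' @export
print.mc_network <- function(x, ...) {
  cat(sprintf("mc_network: %d nodes, %d edges (|rho| >= %g, p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_threshold, x$p_threshold))
  invisible(x)
}

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character())
  apply(net$edges[, c("i", "j")], 1L, function(e) paste(sort(e), collapse = "||"))
}

#' Compare two correlation networks
#'
#' Edge-set differences on the shared node universe, plus a census of strong
#' edges (|rho| above `strong_threshold`) lost and gained.
#'
#' @param net_a,net_b `mc_network` objects with overlapping node sets
#'   (a = reference, b = comparison; "lost" edges are in a but not b).
#' @param strong_threshold |rho| cutoff for the strong-edge census
#'   (default 0.5).
#' @return List of class `network_diff`: `edges_lost`, `edges_gained`,
#'   `edges_shared` (data.frames), and counts `n_strong_lost`,
#'   `n_strong_gained`.
#' @export
compare_networks <- function(net_a, net_b, strong_threshold = 0.5) {
  stopifnot(inherits(net_a, "mc_network"), inherits(net_b, "mc_network"))
  shared_nodes <- intersect(net_a$nodes$taxon_id, net_b$nodes$taxon_id)
  if (!length(shared_nodes)) stop("compare_networks: disjoint node sets")
  on_shared <- function(net) {
    e <- net$edges
    e[e$i %in% shared_nodes & e$j %in% shared_nodes, , drop = FALSE]
  }
  ea <- on_shared(net_a); eb <- on_shared(net_b)
  ka <- if (nrow(ea)) apply(ea[, c("i", "j")], 1L, function(x) paste(sort(x), collapse = "||")) else character()
  kb <- if (nrow(eb)) apply(eb[, c("i", "j")], 1L, function(x) paste(sort(x), collapse = "||")) else character()
  lost <- ea[!(ka %in% kb), , drop = FALSE]
  gained <- eb[!(kb %in% ka), , drop = FALSE]
  shared <- ea[ka %in% kb, , drop = FALSE]
  structure(list(
    edges_lost = lost, edges_gained = gained, edges_shared = shared,
    n_strong_lost = sum(abs(lost$rho) > strong_threshold),
    n_strong_gained = sum(abs(gained$rho) > strong_threshold),
    strong_threshold = strong_threshold), class = "network_diff")
}

#' @export
print.network_diff <- function(x, ...) {
  cat(sprintf("network_diff: %d lost (%d strong), %d gained (%d strong), %d shared\n",
              nrow(x$edges_lost), x$n_strong_lost,
              nrow(x$edges_gained), x$n_strong_gained, nrow(x$edges_shared)))
  invisible(x)
}
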