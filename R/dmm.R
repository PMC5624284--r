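## Dirichlet-multinomial mixture (DMM) metacommunity typing.
##
## EM with Dirichlet-multinomial component densities: E-step responsibilities
## from the DM log-pmf, M-step mixture weights from responsibility means and
## component Dirichlet parameters via responsibility-weighted Minka fixed-point
## updates. Model choice by a Laplace-approximated negative log posterior over
## theta = log(alpha) with a weak Normal(0, 10^2) prior per coordinate.

# Dirichlet-multinomial log pmf per sample (includes the multinomial
# coefficient so values are comparable across parameterizations).
dm_logpmf <- function(X, alpha, lconst = NULL, n = NULL) {
  if (is.null(n)) n <- rowSums(X)
  if (is.null(lconst)) lconst <- lgamma(n + 1) - rowSums(lgamma(X + 1))
  A <- sum(alpha)
  lconst + lgamma(A) - lgamma(n + A) +
    rowSums(lgamma(sweep(X, 2L, alpha, "+"))) - sum(lgamma(alpha))
}

# One responsibility-weighted Minka fixed-point pass to (local) convergence.
minka_update <- function(X, w, alpha, n, inner_tol = 1e-8, inner_max = 200L,
                         alpha_floor = 1e-6) {
  sw <- sum(w)
  if (sw <= 0) return(alpha)
  # rows with vanishing responsibility contribute nothing to the update
  active <- which(w > 1e-10)
  if (length(active) < length(w)) {
    X <- X[active, , drop = FALSE]
    w <- w[active]
    n <- n[active]
  }
  for (it in seq_len(inner_max)) {
    A <- sum(alpha)
    num <- colSums(w * (digamma(sweep(X, 2L, alpha, "+")) -
                          rep(digamma(alpha), each = nrow(X))))
    den <- sum(w * (digamma(n + A) - digamma(A)))
    if (den <= 0) break
    new_alpha <- pmax(alpha * num / den, alpha_floor)
    delta <- max(abs(new_alpha - alpha) / pmax(alpha, 1e-12))
    alpha <- new_alpha
    if (delta < inner_tol) break
  }
  alpha
}

#' Fit a Dirichlet-multinomial mixture to a count table
#'
#' EM to a local optimum, best of `n_restarts` seeded k-means-initialized
#' restarts by negative log likelihood (`nll`). The fitted optimum also
#' carries `laplace_nlp`, the Laplace-approximated negative log posterior used
#' by [select_k()] to choose the number of metacommunities.
#'
#' @param counts An `abundance_table` in counts mode (integer values, every
#'   sample total positive).
#' @param K Number of mixture components (`1 <= K <= n_samples`).
#' @param n_restarts Number of seeded restarts (default 5).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on the change in `nll` (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class `dmm_model`: `K`, `pi`, `alpha` (K x T matrix),
#'   `responsibilities`, `nll`, `laplace_nlp`, `converged`,
#'   `n_restarts_used`, plus ids.
#' @export
fit_dmm <- function(counts, K, n_restarts = 5L, seed = 1L, tol = 1e-6,
                    max_iter = 1000L) {
  stopifnot(inherits(counts, "abundance_table"))
  if (counts$mode != "counts") stop("fit_dmm: counts-mode table required")
  X <- counts$values
  if (any(abs(X - round(X)) > 1e-9)) stop("fit_dmm: non-integer counts")
  n_i <- rowSums(X)
  if (any(n_i <= 0)) stop("fit_dmm: every sample total must be positive")
  N <- nrow(X)
  if (K < 1 || K > N) stop("fit_dmm: K must lie in [1, n_samples]")
  lconst <- lgamma(n_i + 1) - rowSums(lgamma(X + 1))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- dmm_em_once(X, n_i, lconst, K,
                       seed = derive_seed(seed, paste0("restart", r)),
                       tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$nll < best$nll) best <- fit
    if (K == 1L) break  # deterministic: restarts identical
  }
  best$n_restarts_used <- if (K == 1L) 1L else as.integer(n_restarts)
  lap <- laplace_nlp(X, best$pi, best$alpha, n_i = n_i, lconst = lconst)
  best$laplace_nlp <- lap$nlp
  best$hessian_pd <- lap$pd
  best$sample_ids <- rownames(X)
  best$feature_ids <- colnames(X)
  rownames(best$responsibilities) <- rownames(X)
  colnames(best$alpha) <- colnames(X)
  class(best) <- "dmm_model"
  best
}

dmm_em_once <- function(X, n_i, lconst, K, seed, tol, max_iter) {
  N <- nrow(X); Tn <- ncol(X)
  prop <- X / n_i
  resp <- with_seed(seed, {
    if (K == 1L) {
      matrix(1, N, 1L)
    } else {
      cl <- tryCatch(stats::kmeans(prop, centers = K, nstart = 3L,
                                   iter.max = 50L)$cluster,
                     error = function(e) sample.int(K, N, replace = TRUE))
      if (length(unique(cl)) < K) cl <- sample.int(K, N, replace = TRUE)
      r <- matrix(0, N, K)
      r[cbind(seq_len(N), cl)] <- 1
      r
    }
  })
  # moment-style init, then EM
  alpha <- t(vapply(seq_len(K), function(k) {
    w <- resp[, k]
    pbar <- colSums(w * prop) / sum(w)
    pmax(pbar, 1e-8) * 50
  }, numeric(Tn)))
  pi <- colMeans(resp)
  for (k in seq_len(K)) {
    alpha[k, ] <- minka_update(X, resp[, k], alpha[k, ], n_i)
  }

  nll_prev <- Inf
  converged <- FALSE
  reinit_done <- logical(K)
  for (iter in seq_len(max_iter)) {
    L <- vapply(seq_len(nrow(alpha)), function(k)
      dm_logpmf(X, alpha[k, ], lconst, n_i), numeric(N))
    L <- L + rep(log(pmax(pi, 1e-300)), each = N)
    lse <- row_logsumexp(L)
    nll <- -sum(lse)
    if (nll > nll_prev + 1e-8) {
      log_msg(sprintf("EM nll increased by %.3g at iter %d", nll - nll_prev, iter),
              level = "debug")
    }
    resp <- exp(L - lse)
    if (is.finite(nll_prev) && abs(nll_prev - nll) < tol) {
      converged <- TRUE
      nll_prev <- nll
      break
    }
    nll_prev <- nll

    pi <- colMeans(resp)
    # empty-component rule: one reseed from worst-fit samples, else drop
    empty <- which(pi < 1 / (10 * N))
    if (length(empty)) {
      drop_k <- integer()
      for (k in empty) {
        if (!reinit_done[k]) {
          reinit_done[k] <- TRUE
          worst <- order(apply(L, 1L, max))[seq_len(max(2L, N %/% (2L * ncol(resp))))]
          resp[worst, ] <- 0
          resp[worst, k] <- 1
          log_msg("reinitializing empty component from worst-fit samples",
                  level = "debug")
        } else {
          drop_k <- c(drop_k, k)
        }
      }
      if (length(drop_k)) {
        warning("fit_dmm: dropping ", length(drop_k), " empty component(s)")
        keep <- setdiff(seq_len(ncol(resp)), drop_k)
        resp <- resp[, keep, drop = FALSE]
        resp <- resp / rowSums(resp)
        alpha <- alpha[keep, , drop = FALSE]
        reinit_done <- reinit_done[keep]
        nll_prev <- Inf
      }
      pi <- colMeans(resp)
      pi <- pi / sum(pi)
    }
    for (k in seq_len(nrow(alpha))) {
      # truncated inner pass (generalized EM); a full pass polishes at the end
      alpha[k, ] <- minka_update(X, resp[, k], alpha[k, ], n_i, inner_max = 25L)
    }
  }
  # polish the M-step to the full inner tolerance at the optimum
  for (k in seq_len(nrow(alpha))) {
    alpha[k, ] <- minka_update(X, resp[, k], alpha[k, ], n_i)
  }
  L <- vapply(seq_len(nrow(alpha)), function(k)
    dm_logpmf(X, alpha[k, ], lconst, n_i), numeric(N))
  L <- L + rep(log(pmax(pi, 1e-300)), each = N)
  lse <- row_logsumexp(L)
  list(K = nrow(alpha), pi = pi, alpha = alpha, responsibilities = exp(L - lse),
       nll = -sum(lse), converged = converged, n_iter = iter)
}

# Laplace-approximated negative log posterior at the fitted optimum:
#   nlp = -log p(X | theta) - log p(theta) + 0.5 log|H| - (D/2) log(2 pi)
# with theta = log(alpha), independent Normal(0, 10^2) priors, and H the
# Hessian of the negative log posterior in theta (exact analytic form; the
# mixture weights are held at their plug-in estimates). Falls back to the
# diagonal of H when H is not positive definite.
laplace_nlp <- function(X, weights, alpha, prior_var = 100, n_i = NULL, lconst = NULL) {
  if (is.null(n_i)) n_i <- rowSums(X)
  if (is.null(lconst)) lconst <- lgamma(n_i + 1) - rowSums(lgamma(X + 1))
  K <- nrow(alpha); Tn <- ncol(alpha); N <- nrow(X); D <- K * Tn
  L <- vapply(seq_len(K), function(k) dm_logpmf(X, alpha[k, ], lconst, n_i),
              numeric(N))
  L <- L + rep(log(pmax(weights, 1e-300)), each = N)
  lse <- row_logsumexp(L)
  nll <- -sum(lse)
  resp <- exp(L - lse)

  theta <- log(as.numeric(t(alpha)))  # component-major blocks
  prior_nll <- sum(0.5 * log(2 * base::pi * prior_var) + theta^2 / (2 * prior_var))

  Gth <- vector("list", K)   # N x T gradient of log f_ik wrt theta_k
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    a <- alpha[k, ]
    A <- sum(a)
    dpsiA <- digamma(A) - digamma(n_i + A)           # length N
    Ga <- digamma(sweep(X, 2L, a, "+")) - rep(digamma(a), each = N) + dpsiA
    Gth[[k]] <- sweep(Ga, 2L, a, "*")
    rk <- resp[, k]
    c2 <- trigamma(A) - trigamma(n_i + A)
    term_a <- sum(rk * c2) * outer(a, a)
    tri <- trigamma(sweep(X, 2L, a, "+")) - rep(trigamma(a), each = N)
    term_b <- colSums(rk * (sweep(tri, 2L, a^2, "*") + sweep(Ga, 2L, a, "*")))
    blocks[[k]] <- term_a + diag(term_b, Tn) + crossprod(Gth[[k]] * sqrt(rk))
  }
  H_L <- matrix(0, D, D)
  for (k in seq_len(K)) {
    ik <- (k - 1L) * Tn + seq_len(Tn)
    for (l in seq_len(K)) {
      il <- (l - 1L) * Tn + seq_len(Tn)
      cross <- t(Gth[[k]]) %*% (Gth[[l]] * (resp[, k] * resp[, l]))
      blk <- -cross
      if (k == l) blk <- blk + blocks[[k]]
      H_L[ik, il] <- blk
    }
  }
  H <- -H_L + diag(1 / prior_var, D)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (!is.null(ch)) {
    logdet <- 2 * sum(log(diag(ch)))
    pd <- TRUE
  } else {
    log_msg("Laplace Hessian not positive definite; using its diagonal",
            level = "info")
    logdet <- sum(log(pmax(diag(H), 1e-10)))
    pd <- FALSE
  }
  list(nlp = nll + prior_nll + 0.5 * logdet - (D / 2) * log(2 * base::pi), pd = pd)
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf("dmm_model: K = %d, nll = %.2f, Laplace NLP = %.2f (%s)\n",
              x$K, x$nll, x$laplace_nlp,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  cat("pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of metacommunities by Laplace negative log posterior
#'
#' Fits [fit_dmm()] for each candidate K and returns the K minimising the
#' Laplace-approximated negative log posterior.
#'
#' @param counts Counts-mode `abundance_table`.
#' @param k_min,k_max Candidate K range (default 1..7).
#' @param n_restarts,seed,tol,max_iter Passed to [fit_dmm()].
#' @return An object of class `dmm_selection`: data.frame `curve`
#'   (K, laplace_nlp, nll, converged), `best_K`, and the fitted `models`.
#' @export
select_k <- function(counts, k_min = 1L, k_max = 7L, n_restarts = 5L,
                     seed = 1L, tol = 1e-6, max_iter = 1000L) {
  stopifnot(k_min >= 1, k_min <= k_max)
  if (k_max > nrow(counts$values)) stop("k_max exceeds the number of samples")
  ks <- seq.int(k_min, k_max)
  models <- lapply(ks, function(k) {
    fit_dmm(counts, k, n_restarts = n_restarts,
            seed = derive_seed(seed, paste0("K", k)), tol = tol,
            max_iter = max_iter)
  })
  curve <- data.frame(
    K = ks,
    laplace_nlp = vapply(models, function(m) m$laplace_nlp, numeric(1L)),
    nll = vapply(models, function(m) m$nll, numeric(1L)),
    converged = vapply(models, function(m) isTRUE(m$converged), logical(1L)))
  best <- ks[which.min(curve$laplace_nlp)]
  structure(list(curve = curve, best_K = best, models = stats::setNames(
    models, paste0("K", ks))), class = "dmm_selection")
}

#' @export
print.dmm_selection <- function(x, ...) {
  cat("dmm_selection: best K =", x$best_K, "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Assign samples to metacommunities
#'
#' Hard labels by maximum posterior responsibility under a fitted model;
#' ties break to the lowest component index (with a warning).
#'
#' @param model A `dmm_model`.
#' @param counts Counts-mode `abundance_table` whose features match the model.
#' @return Integer component labels named by sample id.
#' @export
assign_metacommunities <- function(model, counts) {
  stopifnot(inherits(model, "dmm_model"), inherits(counts, "abundance_table"))
  if (!identical(colnames(counts$values), model$feature_ids)) {
    stop("assign_metacommunities: feature ids do not match the model")
  }
  X <- counts$values
  n_i <- rowSums(X)
  lconst <- lgamma(n_i + 1) - rowSums(lgamma(X + 1))
  L <- vapply(seq_len(model$K), function(k)
    dm_logpmf(X, model$alpha[k, ], lconst, n_i), numeric(nrow(X)))
  L <- L + rep(log(pmax(model$pi, 1e-300)), each = nrow(X))
  resp <- exp(L - row_logsumexp(L))
  labels <- integer(nrow(X))
  tie <- FALSE
  for (i in seq_len(nrow(X))) {
    m <- max(resp[i, ])
    w <- which(resp[i, ] >= m - 1e-12)
    if (length(w) > 1L) tie <- TRUE
    labels[i] <- w[1L]
  }
  if (tie) warning("assign_metacommunities: responsibility tie(s) broken to lowest index")
  stats::setNames(labels, rownames(X))
}
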