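# Count data with an optional planted log-abundance correlation between the
# first two taxa.
sparcc_sim <- function(n = 100, t = 20, rho = 0, depth = 2000, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * t), n, t)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  base <- exp(sweep(z * 0.8, 2, rnorm(t, 0, 0.5), "+"))
  frac <- base / rowSums(base)
  x <- t(vapply(seq_len(n), function(i)
    as.numeric(rmultinom(1, depth, frac[i, ])), numeric(t)))
  dimnames(x) <- list(paste0("S", seq_len(n)), paste0("T", seq_len(t)))
  abundance_table(x, mode = "counts")
}

test_that("the basis solve matches an independent least-squares oracle", {
  set.seed(1)
  f <- matrix(rgamma(200 * 4, 5), 200, 4)
  f <- f / rowSums(f)
  lf <- log(f)
  V <- cov(lf)
  t_mat <- outer(diag(V), diag(V), "+") - 2 * V
  res <- metacomm:::sparcc_basis(t_mat)
  # oracle: overdetermined system t_ij = w_i + w_j solved by least squares
  pairs <- t(combn(4, 2))
  A <- matrix(0, nrow(pairs), 4)
  for (r in seq_len(nrow(pairs))) A[r, pairs[r, ]] <- 1
  w_ls <- qr.solve(A, t_mat[pairs])
  expect_lt(max(abs(res$omega - w_ls)), 1e-6)
  rho_oracle <- (outer(w_ls, w_ls, "+") - t_mat) /
    (2 * outer(sqrt(w_ls), sqrt(w_ls)))
  diag(rho_oracle) <- 1
  expect_lt(max(abs(res$rho - rho_oracle)), 1e-6)
})

test_that("independent compositions give correlations inside the null band", {
  at <- sparcc_sim(n = 200, t = 50, rho = 0, seed = 2)
  r <- sparcc_correlations(at, n_iterations = 10, seed = 3)
  off <- abs(r$rho[upper.tri(r$rho)])
  expect_lt(quantile(off, 0.95), 0.25)
})

test_that("a planted correlation of 0.8 is recovered", {
  est <- vapply(1:5, function(s) {
    at <- sparcc_sim(n = 150, t = 32, rho = 0.8, seed = 10 + s)
    sparcc_correlations(at, n_iterations = 10, seed = s)$rho[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.15)
})

test_that("rho is symmetric with unit diagonal and bounded", {
  at <- sparcc_sim(n = 60, t = 10, seed = 4)
  r <- sparcc_correlations(at, n_iterations = 5, seed = 5)
  expect_identical(r$rho, t(r$rho))
  expect_true(all(diag(r$rho) == 1))
  expect_true(all(abs(r$rho) <= 1))
  expect_error(sparcc_correlations(
    abundance_table(at$values[, 1:3], mode = "counts")), "4 taxa")
})

test_that("correlations are invariant to per-sample depth rescaling", {
  at <- sparcc_sim(n = 80, t = 20, rho = 0.6, seed = 6, depth = 1000)
  r1 <- sparcc_correlations(at, n_iterations = 10, seed = 7)
  at10 <- abundance_table(at$values * 10, mode = "counts")
  r2 <- sparcc_correlations(at10, n_iterations = 10, seed = 7)
  d <- abs(r1$rho - r2$rho)[upper.tri(r1$rho)]
  expect_lt(median(d), 0.05)
})

test_that("empirical p-values honour the add-one formula and find edges", {
  at <- sparcc_sim(n = 80, t = 12, rho = 0.9, seed = 8, depth = 3000)
  r <- sparcc_correlations(at, n_iterations = 5, seed = 9)
  p <- sparcc_pvalues(at, r, n_null = 100, seed = 10, n_iterations = 3)
  expect_equal(min(p), 1 / 101)           # attainable minimum
  expect_equal(p[1, 2], 1 / 101)          # the planted edge is extreme
  expect_true(all(diag(p) == 1))
})

test_that("network construction applies both thresholds and the sign rule", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.6
  rho[3, 4] <- rho[4, 3] <- -0.35
  rho[1, 3] <- rho[3, 1] <- 0.9
  dimnames(rho) <- list(paste0("T", 1:4), paste0("T", 1:4))
  p <- matrix(1, 4, 4, dimnames = dimnames(rho))
  p[1, 2] <- p[2, 1] <- 0.005
  p[3, 4] <- p[4, 3] <- 0.002
  # strong rho but non-significant p stays out
  net <- build_network(rho, p)
  expect_equal(nrow(net$edges), 2L)
  expect_identical(sort(net$edges$sign), c("co_exclusion", "co_occurrence"))

  all_p1 <- build_network(rho, matrix(1, 4, 4, dimnames = dimnames(rho)))
  expect_equal(nrow(all_p1$edges), 0L)
})

test_that("network comparison partitions edges and counts strong changes", {
  mk <- function(edges, nodes = paste0("T", 1:6)) {
    structure(list(nodes = data.frame(taxon_id = nodes),
                   edges = edges, edge_threshold = 0.3, p_threshold = 0.01),
              class = "mc_network")
  }
  ea <- data.frame(i = c("T1", "T2", "T3", "T4", "T5"),
                   j = c("T2", "T3", "T4", "T5", "T6"),
                   rho = c(0.6, 0.4, 0.55, 0.35, 0.8),
                   p = 0.001, sign = "co_occurrence")
  na <- mk(ea)
  nb <- mk(ea[0, ])
  d <- compare_networks(na, nb)
  expect_equal(nrow(d$edges_lost), 5L)
  expect_equal(nrow(d$edges_gained), 0L)
  expect_equal(d$n_strong_lost, 3L)

  same <- compare_networks(na, na)
  expect_equal(nrow(same$edges_lost), 0L)
  expect_equal(nrow(same$edges_gained), 0L)
  expect_equal(nrow(same$edges_shared), 5L)

  nc <- mk(ea, nodes = paste0("X", 1:3))
  expect_error(compare_networks(na, nc), "disjoint")
})

test_that("a connected community loses its edges after decorrelation", {
  at <- sparcc_sim(n = 70, t = 10, rho = 0.9, seed = 12, depth = 3000)
  r <- sparcc_correlations(at, n_iterations = 5, seed = 13)
  p <- sparcc_pvalues(at, r, n_null = 150, seed = 14, n_iterations = 3)
  net_ct <- build_network(r, p)
  # decorrelated version of the same community
  set.seed(15)
  Xp <- apply(at$values, 2, sample)
  rownames(Xp) <- rownames(at$values)
  atp <- abundance_table(Xp, mode = "counts")
  rp <- sparcc_correlations(atp, n_iterations = 5, seed = 13)
  pp <- sparcc_pvalues(atp, rp, n_null = 150, seed = 14, n_iterations = 3)
  net_cd <- build_network(rp, pp)
  expect_gt(nrow(net_ct$edges), nrow(net_cd$edges))
  d <- compare_networks(net_ct, net_cd)
  expect_gt(nrow(d$edges_lost), 0L)
})
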