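# Well-separated two-component count data used across several tests.
sep2_data <- function(n = 100, depth = 1000, seed = 21) {
  a1 <- c(rep(5, 10), rep(0.2, 10))
  a2 <- c(rep(0.2, 10), rep(5, 10))
  sim <- simulate_dmm_counts(c(0.5, 0.5), list(a1, a2), n, depth, seed)
  colnames(sim$counts) <- paste0("T", 1:20)
  rownames(sim$counts) <- paste0("S", seq_len(n))
  list(at = abundance_table(sim$counts, mode = "counts"), z = sim$component,
       alpha = rbind(a1, a2))
}

test_that("single-component fit matches a direct numerical maximizer", {
  # genuinely overdispersed data: the DM likelihood has an interior MLE
  sim <- simulate_dmm_counts(1, list(c(2, 5, 10, 3, 1)), 50, 300, seed = 17)
  X <- sim$counts
  dimnames(X) <- list(paste0("S", 1:50), paste0("T", 1:5))
  at <- abundance_table(X, mode = "counts")
  m <- fit_dmm(at, 1, seed = 1, tol = 1e-10)
  n_i <- rowSums(X)
  nll_fun <- function(theta) {
    a <- exp(theta)
    -(sum(lgamma(n_i + 1)) - sum(lgamma(X + 1)) +
        nrow(X) * lgamma(sum(a)) - sum(lgamma(n_i + sum(a))) +
        sum(lgamma(sweep(X, 2, a, "+"))) - nrow(X) * sum(lgamma(a)))
  }
  # box constraints keep the oracle in the numerically faithful region of
  # the lgamma differences; the optimum is interior so they never bind
  opt <- optim(log(colMeans(X / n_i) * 10), nll_fun, method = "L-BFGS-B",
               lower = -12, upper = 7, control = list(maxit = 5000, factr = 10))
  expect_true(all(abs(m$alpha[1, ] / exp(opt$par) - 1) < 1e-4))
  expect_equal(m$nll, opt$value, tolerance = 1e-8)
  expect_true(all(m$responsibilities == 1))
})

test_that("two far-separated components are recovered exactly", {
  d <- sep2_data()
  m <- fit_dmm(d$at, 2, n_restarts = 3, seed = 5)
  lab <- assign_metacommunities(m, d$at)
  agree <- max(mean(lab == d$z), mean(lab == 3 - d$z))
  expect_equal(agree, 1)
  expect_true(m$converged)
})

test_that("fits are deterministic given seed and data", {
  d <- sep2_data(n = 40)
  m1 <- fit_dmm(d$at, 2, n_restarts = 2, seed = 9)
  m2 <- fit_dmm(d$at, 2, n_restarts = 2, seed = 9)
  expect_identical(m1$alpha, m2$alpha)
  expect_identical(m1$nll, m2$nll)
  expect_identical(m1$laplace_nlp, m2$laplace_nlp)
})

test_that("model log-likelihood is monotone in K on separated data", {
  d <- sep2_data(n = 60)
  nlls <- vapply(1:3, function(k)
    fit_dmm(d$at, k, n_restarts = 3, seed = 4)$nll, numeric(1))
  expect_true(all(diff(nlls) < 1e-6))  # nll non-increasing in K
})

test_that("analytic Laplace Hessian agrees with finite differences", {
  sim <- simulate_dmm_counts(c(0.5, 0.5), list(c(5, 1, 0.5), c(0.5, 1, 5)),
                             12, 150, seed = 3)
  X <- sim$counts
  dimnames(X) <- list(paste0("S", 1:12), paste0("T", 1:3))
  at <- abundance_table(X, mode = "counts")
  m <- fit_dmm(at, 2, n_restarts = 2, seed = 2)
  n_i <- rowSums(X)
  lconst <- lgamma(n_i + 1) - rowSums(lgamma(X + 1))
  prior_var <- 100
  # independent numerical route to the same negative log posterior surface
  f <- function(theta) {
    alpha <- matrix(exp(theta), nrow = m$K, byrow = TRUE)
    L <- vapply(seq_len(m$K), function(k) {
      A <- sum(alpha[k, ])
      lconst + lgamma(A) - lgamma(n_i + A) +
        rowSums(lgamma(sweep(X, 2, alpha[k, ], "+"))) - sum(lgamma(alpha[k, ]))
    }, numeric(nrow(X)))
    L <- L + rep(log(m$pi), each = nrow(X))
    mx <- apply(L, 1, max)
    nll <- -sum(mx + log(rowSums(exp(L - mx))))
    nll + sum(0.5 * log(2 * pi * prior_var) + theta^2 / (2 * prior_var))
  }
  theta <- log(as.numeric(t(m$alpha)))
  D <- length(theta)
  h <- 1e-4
  Hnum <- matrix(0, D, D)
  for (i in seq_len(D)) {
    for (j in i:D) {
      ei <- ej <- numeric(D); ei[i] <- h; ej[j] <- h
      Hnum[i, j] <- Hnum[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h^2)
    }
  }
  logdet_num <- determinant(Hnum, logarithm = TRUE)$modulus
  nlp_num <- f(theta) + 0.5 * as.numeric(logdet_num) - (D / 2) * log(2 * pi)
  expect_equal(m$laplace_nlp, nlp_num, tolerance = 1e-3)
})

test_that("Laplace NLP is invariant to sample order", {
  d <- sep2_data(n = 60, seed = 33)
  m1 <- fit_dmm(d$at, 2, n_restarts = 3, seed = 8)
  perm <- rev(seq_len(nrow(d$at$values)))
  atp <- abundance_table(d$at$values[perm, ], mode = "counts")
  m2 <- fit_dmm(atp, 2, n_restarts = 3, seed = 8)
  expect_equal(m1$nll, m2$nll, tolerance = 1e-6)
  expect_equal(m1$laplace_nlp, m2$laplace_nlp, tolerance = 1e-6)
})

test_that("parameter recovery on a 500-sample two-component mixture", {
  d <- sep2_data(n = 500, depth = 2000, seed = 77)
  m <- fit_dmm(d$at, 2, n_restarts = 3, seed = 13)
  perm <- if (cor(m$alpha[1, ], d$alpha[1, ]) > cor(m$alpha[2, ], d$alpha[1, ])) {
    1:2
  } else 2:1
  rel_err <- mean(abs(m$alpha[perm, ] - d$alpha) / d$alpha)
  expect_lt(rel_err, 0.15)
  expect_lt(max(abs(m$pi[perm] - 0.5)), 0.05)
})

test_that("select_k scans the range and respects forced ranges", {
  d <- sep2_data(n = 50, seed = 15)
  sel <- select_k(d$at, 2, 2, n_restarts = 2, seed = 1)
  expect_equal(sel$best_K, 2L)
  expect_true(sel$best_K %in% sel$curve$K)

  # single-component data: K = 1 chosen over K = 2
  at1 <- toy_counts(40, 8, seed = 44, depth = 600)
  sel1 <- select_k(at1, 1, 2, n_restarts = 2, seed = 2)
  expect_equal(sel1$best_K, 1L)
})

test_that("assignment applies the argmax and tie rules", {
  d <- sep2_data(n = 40)
  m <- fit_dmm(d$at, 2, n_restarts = 2, seed = 3)
  lab <- assign_metacommunities(m, d$at)
  stored <- apply(m$responsibilities, 1, which.max)
  expect_identical(unname(lab), unname(stored))

  bad <- abundance_table(d$at$values[, c(2:20, 1)], mode = "counts")
  expect_error(assign_metacommunities(m, bad), "feature ids")
})

test_that("contract violations are rejected", {
  at <- toy_counts(5, 3)
  expect_error(fit_dmm(at, 6), "K must lie")
  atr <- to_relative(at)
  expect_error(fit_dmm(atr, 1), "counts")
  atn <- abundance_table(matrix(c(0.5, 2, 1, 1, 1, 1), 2,
                                dimnames = list(c("a", "b"), c("x", "y", "z"))),
                         mode = "counts")
  expect_error(fit_dmm(atn, 1), "non-integer")
})
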