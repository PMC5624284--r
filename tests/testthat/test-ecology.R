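test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(rep(1 / 8, 8)), log(8))
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(shannon_index(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_index(c(-0.1, 1.1)), "negative")
})

test_that("gene counts apply the one-read threshold", {
  expect_equal(gene_count(c(0, 1, 3, 0)), 2)
  expect_equal(gene_count(rep(0, 5)), 0)
  expect_equal(gene_count(c(0.5, 2)), 1)
})

test_that("distances match brute-force formula evaluation", {
  set.seed(3)
  m <- matrix(runif(3 * 6), 3, 6)
  m <- m / rowSums(m)
  rownames(m) <- paste0("S", 1:3); colnames(m) <- paste0("F", 1:6)
  at <- abundance_table(m, mode = "relative")
  bc <- distance_matrix(at, "bray_curtis")
  js <- distance_matrix(at, "jensen_shannon")
  for (i in 1:2) for (j in (i + 1):3) {
    x <- m[i, ]; y <- m[j, ]
    expect_equal(bc$D[i, j], sum(abs(x - y)) / sum(x + y), tolerance = 1e-12)
    mm <- (x + y) / 2
    kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
    expect_equal(js$D[i, j], sqrt(0.5 * kl(x, mm) + 0.5 * kl(y, mm)),
                 tolerance = 1e-12)
  }
  expect_true(all(diag(bc$D) == 0))
  expect_identical(bc$D, t(bc$D))
})

test_that("extremal distances hit their theoretical bounds", {
  m <- rbind(S1 = c(0.5, 0.5, 0, 0), S2 = c(0, 0, 0.5, 0.5))
  colnames(m) <- paste0("F", 1:4)
  at <- abundance_table(m, mode = "relative")
  expect_equal(distance_matrix(at, "bray_curtis")$D[1, 2], 1)
  expect_equal(distance_matrix(at, "jensen_shannon")$D[1, 2], sqrt(log(2)),
               tolerance = 1e-12)
  # identical rows -> 0 under all metrics
  m2 <- rbind(S1 = c(0.3, 0.7), S2 = c(0.3, 0.7))
  colnames(m2) <- c("a", "b")
  at2 <- abundance_table(m2, mode = "relative")
  expect_equal(distance_matrix(at2, "bray_curtis")$D[1, 2], 0)
  expect_equal(distance_matrix(at2, "jensen_shannon")$D[1, 2], 0)
})

test_that("Jensen-Shannon distance satisfies the triangle inequality", {
  set.seed(11)
  bad <- 0
  for (trial in 1:200) {
    m <- matrix(rgamma(3 * 5, 0.5), 3, 5)
    m <- m / rowSums(m)
    rownames(m) <- paste0("S", 1:3); colnames(m) <- paste0("F", 1:5)
    D <- distance_matrix(abundance_table(m, mode = "relative"),
                         "jensen_shannon")$D
    if (D[1, 2] > D[1, 3] + D[3, 2] + 1e-12) bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("Gower distance handles mixed types and missing pairs", {
  df <- data.frame(age = c(20, 30, 40), sex = c("M", "F", "M"),
                   crp = c(1, NA, 3))
  D <- metacomm:::gower_matrix(df)
  expect_equal(diag(D), rep(0, 3))
  expect_identical(D, t(D))
  # pair (1,2): age term + sex mismatch; crp dropped (NA)
  z <- scale(df$age)[, 1]
  expect_equal(D[1, 2], (abs(z[1] - z[2]) / diff(range(z)) + 1) / 2)
})

test_that("PCoA recovers geometry", {
  # three equidistant samples: two equal positive eigenvalues
  D <- matrix(1, 3, 3) - diag(3)
  p <- pcoa(D, n_axes = 2)
  pos <- p$eigenvalues[p$eigenvalues > 1e-9]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # Euclidean round trip from known 2-D points
  set.seed(5)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  D2 <- as.matrix(dist(pts))
  p2 <- pcoa(D2, n_axes = 2)
  rec <- as.matrix(dist(p2$coordinates))
  expect_lt(max(abs(rec - D2)), 1e-9)

  # duplicate samples have identical coordinates
  D3 <- as.matrix(dist(rbind(pts, pts[1, ])))
  p3 <- pcoa(D3, n_axes = 2)
  expect_equal(p3$coordinates[11, ], p3$coordinates[1, ], tolerance = 1e-9)

  expect_warning(pcoa(D, n_axes = 3), "truncating")
})

test_that("PERMANOVA matches vegan and its own extremal cases", {
  set.seed(9)
  m <- matrix(runif(18 * 10), 18, 10)
  m <- m / rowSums(m)
  rownames(m) <- paste0("S", 1:18); colnames(m) <- paste0("F", 1:10)
  at <- abundance_table(m, mode = "relative")
  D <- distance_matrix(at, "bray_curtis")
  lab <- rep(c("a", "b", "c"), each = 6)
  res <- permanova(D, lab, n_permutations = 99, seed = 1)
  adon <- vegan::adonis2(stats::as.dist(D$D) ~ g,
                         data = data.frame(g = lab), permutations = 99)
  expect_equal(res$pseudo_F, adon$F[1], tolerance = 1e-10)

  # relabeling invariance: permute D and labels consistently
  perm <- sample(18)
  res2 <- permanova(D$D[perm, perm], lab[perm], n_permutations = 99, seed = 1)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-12)

  # two groups of duplicated points far apart: minimal attainable p
  pts <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) + 1e-9 * matrix(rnorm(20), 10, 2)
  Dfar <- as.matrix(dist(pts))
  resf <- permanova(Dfar, rep(c("x", "y"), each = 5), n_permutations = 199, seed = 2)
  expect_equal(resf$p, 1 / 200)

  expect_error(permanova(Dfar, c(rep("x", 9), "y")), "singleton")
})

test_that("bioenv finds the driving covariate and breaks ties lexicographically", {
  set.seed(21)
  n <- 25
  m <- matrix(runif(n * 8), n, 8)
  m <- m / rowSums(m)
  rownames(m) <- paste0("S", 1:n); colnames(m) <- paste0("F", 1:8)
  at <- abundance_table(m, mode = "relative")
  D <- distance_matrix(at, "bray_curtis")
  ax <- pcoa(D, 1)$coordinates[, 1]
  cov <- data.frame(driver = 3 * ax + 5,
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  res <- bioenv(D, cov, max_subset_size = 2)
  expect_true("driver" %in% res$best_subset)
  expect_identical(res$best_subset, "driver")

  # exact duplicate covariates tie; lexicographically smallest reported
  cov2 <- data.frame(b_copy = cov$driver, a_copy = cov$driver)
  res2 <- bioenv(D, cov2, max_subset_size = 1)
  expect_identical(res2$best_subset, "a_copy")

  many <- as.data.frame(matrix(rnorm(n * 21), n))
  expect_error(bioenv(D, many), "max_subset_size")
})

test_that("Fisher association matches hypergeometric enumeration", {
  membership <- rep(c("A", "B"), each = 10)
  disease <- c(rep("CD", 10), rep("CT", 10))
  res <- fisher_association(membership, disease)
  # perfectly associated 2x2 [[10,0],[0,10]]: p = 2 / C(20,10)
  expect_equal(res$p[res$group == "A"], 2 / choose(20, 10), tolerance = 1e-12)

  balanced <- fisher_association(rep(c("A", "B"), 10),
                                 rep(c("CD", "CT"), each = 10))
  expect_equal(balanced$p, c(1, 1))
})

test_that("BH q-values follow the step-up arithmetic", {
  q <- stats::p.adjust(c(0.01, 0.02, 0.9), method = "BH")
  expect_equal(q, c(0.03, 0.03, 0.9))
  # monotone in p-rank and never below p
  set.seed(2)
  p <- runif(50)
  q2 <- stats::p.adjust(p, method = "BH")
  expect_true(all(q2 >= p))
  expect_true(all(diff(q2[order(p)]) > -1e-12))
})

test_that("small-sample Wilcoxon p matches full enumeration", {
  x <- c(1.3, 2.8, 0.5, 3.9)
  y <- c(2.1, 4.4, 0.9, 5.2)
  p_pkg <- metacomm:::wilcox_p(x, y)
  # enumerate all C(8,4) assignments of ranks to group 1
  r <- rank(c(x, y))
  w_obs <- sum(r[1:4]) - 4 * 5 / 2
  ws <- apply(combn(8, 4), 2, function(idx) sum(r[idx]) - 10)
  p_exact <- mean(abs(ws - 8) >= abs(w_obs - 8))  # center = n1*n2/2 = 8
  expect_equal(p_pkg, p_exact, tolerance = 1e-12)
})

test_that("wilcoxon_bh assigns the four-tier scheme", {
  expect_identical(q_tier(c(0.15, 0.0005, 0.07, 0.03, 0.5)),
                   c("*", "****", "**", "***", ""))
  set.seed(4)
  m <- matrix(rnorm(20 * 6), 20, 6)
  m[1:10, 1] <- m[1:10, 1] + 5
  rownames(m) <- paste0("S", 1:20); colnames(m) <- paste0("F", 1:6)
  res <- wilcoxon_bh(m, paste0("S", 1:10), paste0("S", 11:20))
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  expect_identical(res$tier, q_tier(res$q))
  # constant feature gives p = 1
  m[, 2] <- 3
  res2 <- wilcoxon_bh(m, paste0("S", 1:10), paste0("S", 11:20))
  expect_equal(res2$p[2], 1)
})
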