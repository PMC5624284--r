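# Three groups of samples over a small simplex, with optional shift of the
# first feature in group 1.
lefse_toy <- function(n_per = 20, n_feat = 20, shift = 0, seed = 1,
                      base = 5e-3, sd = 2e-4) {
  set.seed(seed)
  n <- 3 * n_per
  # filler features scaled so that F1 keeps its intended absolute abundance
  # after row closure
  m <- matrix(abs(rnorm(n * n_feat, 1, 0.2)), n, n_feat) *
    (1 - base) / (n_feat - 1)
  m[, 1] <- abs(rnorm(n, base, sd))
  m[seq_len(n_per), 1] <- m[seq_len(n_per), 1] + shift
  rownames(m) <- paste0("S", seq_len(n))
  at <- rel_table(m)
  groups <- split(rownames(m), rep(c("g1", "g2", "g3"), each = n_per))
  list(at = at, scheme = comparison_scheme(groups))
}

test_that("constant features fail the screen with p = 1", {
  cm <- matrix(1 / 4, 12, 4, dimnames = list(paste0("S", 1:12), paste0("F", 1:4)))
  cat2 <- abundance_table(cm, mode = "relative")
  sch <- comparison_scheme(split(rownames(cm), rep(c("a", "b"), each = 6)))
  scr2 <- screen_features(cat2, sch)
  expect_true(all(scr2$p == 1))
  expect_false(any(scr2$pass))
})

test_that("complete separation gives the exact rank-sum tail probability", {
  m <- matrix(abs(rnorm(20 * 5, 1, 0.1)), 20, 5)
  m[1:10, 1] <- m[1:10, 1] + 10   # disjoint supports between the groups
  rownames(m) <- paste0("S", 1:20)
  at <- rel_table(m)
  sch <- comparison_scheme(split(rownames(m), rep(c("a", "b"), each = 10)))
  scr <- screen_features(at, sch)
  expect_equal(scr$p[1, 1], 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("null screen pass rate matches the independence approximation", {
  d <- lefse_toy(n_per = 20, n_feat = 200, seed = 8)
  scr <- screen_features(d$at, d$scheme, alpha = 0.05)
  c_n <- length(d$scheme$comparisons)
  expected <- 1 - 0.95^c_n
  se <- sqrt(expected * (1 - expected) / 200)
  expect_lt(abs(mean(scr$pass) - expected), 3 * se + 0.01)
})

test_that("groups below three samples are rejected by name", {
  d <- lefse_toy()
  g <- d$scheme$groups
  g$tiny <- g$g1[1:2]
  expect_error(screen_features(d$at, comparison_scheme(g)), "tiny")
})

test_that("equal-mean features score below the biomarker threshold", {
  below <- vapply(1:10, function(s) {
    d <- lefse_toy(shift = 0, seed = 100 + s)
    es <- lda_effect_size(d$at, d$scheme$groups$g1, d$scheme$groups$g2,
                          features = "F1", seed = s)
    es$lda_score < 2
  }, logical(1))
  expect_gte(sum(below), 9)
})

test_that("strong shifts at moderate abundance exceed the threshold", {
  d <- lefse_toy(shift = 0.05, seed = 3, base = 0.1, sd = 5e-3)
  es <- lda_effect_size(d$at, d$scheme$groups$g1, d$scheme$groups$g2,
                        features = colnames(d$at$values), seed = 4)
  expect_gte(es$lda_score[es$feature_id == "F1"], 2)
  expect_identical(es$enriched_group[es$feature_id == "F1"], "A")
})

test_that("full-sample effect size matches an independent LDA route", {
  skip_if_not_installed("MASS")
  d <- lefse_toy(shift = 0.03, seed = 5, base = 0.05, sd = 3e-3)
  # a strict feature subset: using every feature of a closed composition
  # makes the within-class scatter exactly singular
  feats <- colnames(d$at$values)[1:10]
  es <- lda_effect_size(d$at, d$scheme$groups$g1, d$scheme$groups$g2,
                        features = feats, n_boot = 1, boot_fraction = 1,
                        seed = 9)
  # oracle: MASS::lda on the full sample, same pinned construction
  X <- d$at$values[c(d$scheme$groups$g1, d$scheme$groups$g2), feats] * 1e4
  storage.mode(X) <- "double"
  cl <- factor(rep(c(1, 2), each = 20))
  z <- MASS::lda(X, grouping = cl)
  w <- z$scaling[, 1]
  w <- w / sqrt(sum(w^2))
  ld <- X %*% w
  sep <- abs(mean(ld[cl == 1]) - mean(ld[cl == 2]))
  d_raw <- abs(colMeans(X[cl == 1, ]) - colMeans(X[cl == 2, ]))
  oracle <- log10(1 + 0.5 * (d_raw + abs(w) * sep))
  expect_equal(es$lda_score, unname(oracle), tolerance = 1e-4)
})

test_that("scores are deterministic given the seed", {
  d <- lefse_toy(shift = 0.02)
  a <- lda_effect_size(d$at, d$scheme$groups$g1, d$scheme$groups$g2, seed = 30)
  b <- lda_effect_size(d$at, d$scheme$groups$g1, d$scheme$groups$g2, seed = 30)
  expect_identical(a$lda_score, b$lda_score)
})

test_that("increasing separation never decreases the score", {
  scores <- vapply(c(0, 0.01, 0.02, 0.04, 0.08), function(sh) {
    set.seed(77)  # identical noise across grid points
    m <- matrix(abs(rnorm(40 * 2, 1, 0.05)), 40, 2)
    m[1:20, 1] <- m[1:20, 1] + sh * 20
    rownames(m) <- paste0("S", 1:40)
    at <- rel_table(m)
    lda_effect_size(at, paste0("S", 1:20), paste0("S", 21:40),
                    features = "F1", seed = 1)$lda_score
  }, numeric(1))
  expect_true(all(diff(scores) > -1e-9))
})

test_that("discover_biomarkers recovers spiked taxa and respects thresholds", {
  ch <- cached_cohort(42)
  rel <- to_relative(ch$counts)
  sch <- truth_scheme(ch)
  bm <- discover_biomarkers(rel, sch, seed = 5)
  sig <- ch$truth$signature$taxon_id
  expect_true(all(sig %in% bm$feature_id))
  expect_true(all(bm$lda_score >= 2))
  expect_true(all(bm$passed_screen))

  none <- discover_biomarkers(rel, sch, lda_threshold = Inf, seed = 5)
  expect_equal(nrow(none), 0L)
})

test_that("label permutation leaves few biomarkers", {
  ch <- cached_cohort(42)
  rel <- to_relative(ch$counts)
  ids <- rownames(rel$values)
  counts <- vapply(1:10, function(s) {
    set.seed(400 + s)
    perm <- sample(ids)
    groups <- split(perm, rep(c("p1", "p2", "p3"),
                              length.out = length(perm)))
    sch <- comparison_scheme(groups)
    nrow(discover_biomarkers(rel, sch, seed = s))
  }, numeric(1))
  expect_lte(median(counts), 2)
})
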