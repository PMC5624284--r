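## Synthetic-cohort generator: a seeded generative twin of the study design
## (Dirichlet-multinomial metacommunities with signature taxa, group-shifted
## KO pathways, skewed LPS/SCFA annotations, sloped ori->ter coverage,
## covariates tied to community structure), with ground truth for recovery
## tests.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Simulate counts from a Dirichlet-multinomial mixture
#'
#' Each sample draws a component `z ~ pi`, composition
#' `p ~ Dirichlet(alpha[[z]])`, a depth `d ~ Poisson(depth)` truncated at 1,
#' and counts `x ~ Multinomial(d, p)`.
#'
#' @param pi Mixture weights (simplex over K).
#' @param alpha_list List of K strictly positive Dirichlet parameter vectors
#'   of common length.
#' @param n_samples Number of samples.
#' @param depth Mean sequencing depth (counts per sample).
#' @param seed Integer seed (mandatory).
#' @return List with `counts` (n_samples x T integer matrix) and
#'   `component` (integer labels).
#' @export
simulate_dmm_counts <- function(pi, alpha_list, n_samples, depth, seed) {
  stopifnot(length(pi) == length(alpha_list), n_samples >= 1, depth > 0)
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  if (any(vapply(alpha_list, function(a) any(a <= 0), logical(1L)))) {
    stop("all Dirichlet parameters must be strictly positive")
  }
  tlen <- unique(vapply(alpha_list, length, integer(1L)))
  if (length(tlen) != 1L) stop("alpha vectors must have a common length")
  with_seed(seed, {
    z <- sample.int(length(pi), n_samples, replace = TRUE, prob = pi)
    d <- stats::rpois(n_samples, depth)
    while (any(d == 0)) d[d == 0] <- stats::rpois(sum(d == 0), depth)
    x <- matrix(0L, n_samples, tlen)
    for (i in seq_len(n_samples)) {
      p <- as.numeric(rdirichlet(1L, alpha_list[[z[i]]]))
      x[i, ] <- stats::rmultinom(1L, d[i], p)[, 1L]
    }
    list(counts = x, component = z)
  })
}

#' Simulate a binned replication coverage profile
#'
#' Expected log2 coverage descends linearly from the replication origin to the
#' terminus (half a circular genome away) and ascends back, so that
#' `cov(ori) / cov(ter)` equals `true_ptr`; the profile is scaled to a given
#' mean depth per bin, with optional Poisson counting noise and a seeded
#' rotation of the origin.
#'
#' @param true_ptr Peak-to-trough ratio, `>= 1`.
#' @param n_bins Number of circular bins (`>= 16`; even recommended).
#' @param mean_depth Mean coverage per bin.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @param rotate If TRUE, place the origin at a seeded random bin;
#'   otherwise at bin 1.
#' @return Numeric coverage vector with attribute `ori` (origin bin).
#' @export
simulate_coverage <- function(true_ptr, n_bins = 100L, mean_depth = 200,
                              noise = c("poisson", "none"), seed = 1L,
                              rotate = FALSE) {
  noise <- match.arg(noise)
  if (true_ptr < 1) stop("true_ptr must be >= 1")
  if (n_bins < 16) stop("n_bins must be >= 16")
  with_seed(seed, {
    ori <- if (rotate) sample.int(n_bins, 1L) else 1L
    i <- seq_len(n_bins)
    d <- pmin(abs(i - ori), n_bins - abs(i - ori))
    rel <- 2^(-log2(true_ptr) * d / (n_bins / 2))
    expected <- rel * (mean_depth / mean(rel))
    cov <- if (noise == "poisson") stats::rpois(n_bins, expected) else expected
    structure(as.numeric(cov), ori = ori)
  })
}

#' Default enzyme identifiers per SCFA
#'
#' Terminal biosynthetic enzymes: carbon-monoxide dehydrogenase and the
#' acetyl-CoA synthase complex for acetate; propionyl-CoA transferase and
#' propionyl-CoA/succinyl-CoA transferase for propionate; butyryl-CoA
#' transferase for butyrate.
#'
#' @return Named list mapping SCFA to enzyme id vectors.
#' @export
scfa_enzyme_map <- function() {
  list(
    acetate    = c("co_dehydrogenase", "acetyl_coa_synthase"),
    propionate = c("propionyl_coa_transferase", "propionyl_succinyl_coa_transferase"),
    butyrate   = c("butyryl_coa_transferase")
  )
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the emulated study design: 3 metacommunities over 150 taxa
#' (one control-dominated, one mixed, one case-exclusive), 54 control and 49
#' case samples, 8 signature taxa per component at 8-fold enrichment, KO
#' pathways shifted between disease groups, annotation skew placing
#' hexa-acylated LPS producers in the case-exclusive component and SCFA
#' terminal-enzyme carriers in the control-like components, and sloped
#' coverage profiles with per-(taxon, sample) true PTR.
#'
#' @param n_taxa Number of taxa.
#' @param concentration Total Dirichlet concentration per component; base
#'   abundance profile is proportional to 1/rank.
#' @param allocation data.frame with columns `component`, `disease`, `n`.
#' @param signature_fold Fold-enrichment multiplier applied to each
#'   component's signature-taxon Dirichlet weights (1 = null cohort).
#' @param n_signature Signature taxa per component.
#' @param depth Mean sequencing depth per sample.
#' @param n_kos,n_pathways,pathway_size KO-table dimensions.
#' @param ko_log_effect Log-scale shift applied to member KOs of affected
#'   pathways in CD samples (pathways 1-4 up, 5-8 down; 0 = null).
#' @param covariate_strength Multiplier on covariate-to-community loadings
#'   (0 = null).
#' @param ptr_effect Multiplier on the growth-rate contrast between
#'   components (0 = null).
#' @param coverage_bins,coverage_depth Coverage profile geometry.
#' @param include_coverage Generate per-(taxon, sample) coverage profiles for
#'   the signature taxa (set FALSE to skip the heaviest output).
#' @param seed Mandatory integer seed; all randomness flows from it through
#'   named substreams.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_taxa = 150L,
                          concentration = 600,
                          allocation = data.frame(
                            component = c("A", "A", "B", "B", "C"),
                            disease   = c("CT", "CD", "CT", "CD", "CD"),
                            n         = c(40L, 4L, 14L, 20L, 25L)),
                          signature_fold = 8,
                          n_signature = 8L,
                          depth = 10000,
                          n_kos = 300L,
                          n_pathways = 20L,
                          pathway_size = 10L,
                          ko_log_effect = 0.8,
                          covariate_strength = 1,
                          ptr_effect = 1,
                          coverage_bins = 100L,
                          coverage_depth = 50,
                          include_coverage = TRUE,
                          seed = 42L) {
  if (is.null(seed)) stop("cohort_config: seed is mandatory")
  cfg <- list(n_taxa = as.integer(n_taxa), concentration = concentration,
              allocation = allocation, signature_fold = signature_fold,
              n_signature = as.integer(n_signature), depth = depth,
              n_kos = as.integer(n_kos), n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              ko_log_effect = ko_log_effect,
              covariate_strength = covariate_strength, ptr_effect = ptr_effect,
              coverage_bins = as.integer(coverage_bins),
              coverage_depth = coverage_depth,
              include_coverage = isTRUE(include_coverage),
              seed = as.integer(seed))
  stopifnot(cfg$n_taxa >= 10, cfg$concentration > 0, cfg$signature_fold > 0,
            all(cfg$allocation$n >= 0),
            all(cfg$allocation$disease %in% c("CT", "CD")),
            cfg$n_pathways * cfg$pathway_size <= cfg$n_kos)
  comps <- sort(unique(cfg$allocation$component))
  if (cfg$n_signature * length(comps) * 3 > cfg$n_taxa) {
    stop("cohort_config: too many signature taxa for n_taxa")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# Signature taxon ranks per component: disjoint interleaved mid-abundance
# ranks (8-fold spikes on these stay clear of the dominant head taxa).
signature_ranks <- function(cfg) {
  comps <- sort(unique(cfg$allocation$component))
  k <- length(comps)
  out <- lapply(seq_along(comps), function(j) {
    seq(8L + j, by = k, length.out = cfg$n_signature)
  })
  names(out) <- comps
  out
}

#' Simulate a full synthetic cohort
#'
#' Bundles all generators: DMM counts with per-component signature taxa,
#' sample metadata with covariates tied to community structure, taxon
#' annotations (lipid-A gene presence, SCFA-enzyme carriage), a KO table with
#' group-shifted pathways and its pathway membership map, SCFA terminal-enzyme
#' gene abundances, binned coverage profiles, and the generating truth.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `counts`,
#'   `metadata`, `annotation`, `ko_table`, `pathway_map`, `gene_table`,
#'   `gene_map`, `coverage` (long data.frame or NULL), and `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- if (inherits(config, "cohort_config")) config else do.call(cohort_config, config)
  comps <- sort(unique(cfg$allocation$component))
  K <- length(comps)
  Tn <- cfg$n_taxa
  taxa <- sprintf("MGS%03d", seq_len(Tn))

  base <- (1 / seq_len(Tn))
  base <- base / sum(base) * cfg$concentration
  sig_ranks <- signature_ranks(cfg)
  alpha <- matrix(rep(base, each = K), nrow = K, dimnames = list(comps, taxa))
  for (cmp in comps) alpha[cmp, sig_ranks[[cmp]]] <-
    alpha[cmp, sig_ranks[[cmp]]] * cfg$signature_fold

  # sample labels from the allocation table, order shuffled under a substream
  lab <- do.call(rbind, lapply(seq_len(nrow(cfg$allocation)), function(i) {
    r <- cfg$allocation[i, ]
    if (r$n == 0) return(NULL)
    data.frame(component = r$component, disease = r$disease,
               idx = seq_len(r$n))
  }))
  n <- nrow(lab)
  ord <- with_seed(derive_seed(cfg$seed, "order"), sample.int(n))
  lab <- lab[ord, , drop = FALSE]
  sample_id <- sprintf("%s%03d", lab$disease, stats::ave(
    seq_len(n), lab$disease, FUN = seq_along))
  rownames(lab) <- sample_id

  # counts: component known per sample, composition ~ Dirichlet(alpha_z)
  counts <- with_seed(derive_seed(cfg$seed, "counts"), {
    d <- stats::rpois(n, cfg$depth)
    while (any(d == 0)) d[d == 0] <- stats::rpois(sum(d == 0), cfg$depth)
    x <- matrix(0, n, Tn, dimnames = list(sample_id, taxa))
    for (i in seq_len(n)) {
      p <- as.numeric(rdirichlet(1L, alpha[lab$component[i], ]))
      x[i, ] <- stats::rmultinom(1L, d[i], p)[, 1L]
    }
    x
  })

  # covariates: loadings on component/disease indicators plus noise
  cs <- cfg$covariate_strength
  meta <- with_seed(derive_seed(cfg$seed, "covariates"), {
    isC <- as.numeric(lab$component == comps[K])
    isB <- as.numeric(lab$component == (if (K >= 2) comps[K - 1] else comps[1]))
    isCD <- as.numeric(lab$disease == "CD")
    data.frame(
      sample_id = sample_id,
      disease_status = lab$disease,
      timepoint = "baseline",
      age = round(24 + cs * 5 * isC + stats::rnorm(n, 0, 7), 1),
      bmi = round(21.5 - cs * 2 * isCD + stats::rnorm(n, 0, 3), 1),
      crp = round(pmax(0, 4 + cs * (4 * isC + 1.5 * isB) + stats::rnorm(n, 0, 2)), 2),
      uric_acid = round(300 + cs * 60 * isC + stats::rnorm(n, 0, 50), 1),
      leukocytes = round(pmax(1, 6 + cs * 2 * isC + stats::rnorm(n, 0, 1.5)), 2),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE)
  })
  meta <- as_sample_metadata(meta)

  # annotations: LPS class skewed by component role, SCFA carriage on
  # control-like signature taxa plus a random minority elsewhere
  sigA <- taxa[sig_ranks[[1L]]]
  sigB <- if (K >= 2) taxa[sig_ranks[[2L]]] else character()
  sigC <- taxa[sig_ranks[[K]]]
  ann <- with_seed(derive_seed(cfg$seed, "annotation"), {
    cls <- sample(c("gram_positive", "penta_producer", "hexa_producer", "unclassified"),
                  Tn, replace = TRUE, prob = c(0.45, 0.25, 0.10, 0.20))
    names(cls) <- taxa
    cls[sigA] <- "gram_positive"
    if (K >= 3) cls[sigB] <- sample(c("gram_positive", "penta_producer"),
                                    length(sigB), replace = TRUE, prob = c(0.6, 0.4))
    cls[sigC] <- "hexa_producer"
    genes <- lipid_a_genes()
    pres <- matrix(0L, Tn, length(genes), dimnames = list(taxa, genes))
    for (tx in taxa) {
      pres[tx, ] <- switch(cls[[tx]],
        gram_positive = rep(0L, length(genes)),
        hexa_producer = rep(1L, length(genes)),
        penta_producer = as.integer(genes != "LpxM"),
        unclassified = {
          v <- stats::rbinom(length(genes), 1L, 0.5)
          # avoid accidentally hitting a named pattern
          if (all(v == 1L) || all(v == 0L) || all(v == as.integer(genes != "LpxM"))) {
            v[1L] <- 1L - v[1L]
          }
          v
        })
    }
    scfa <- matrix(0L, Tn, 3L,
                   dimnames = list(taxa, c("acetate_terminal", "propionate_terminal",
                                           "butyrate_terminal")))
    gp <- cls == "gram_positive"
    carrier <- gp & stats::runif(Tn) < 0.3
    scfa[carrier, ] <- t(vapply(which(carrier), function(i)
      stats::rbinom(3L, 1L, 0.5), integer(3L)))
    scfa[sigA, c("acetate_terminal", "butyrate_terminal")] <- 1L
    if (K >= 3) scfa[sigB, c("acetate_terminal", "propionate_terminal")] <- 1L
    scfa[sigC, ] <- 0L
    phyla <- sample(c("Bacteroidetes", "Firmicutes", "Proteobacteria", "Actinobacteria"),
                    Tn, replace = TRUE, prob = c(0.35, 0.4, 0.15, 0.1))
    df <- data.frame(taxon_id = taxa, phylum = phyla, pres, scfa,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df
  })
  annotation <- as_taxon_annotation(ann)

  # KO table: lognormal relative abundances; member KOs of affected pathways
  # shifted in CD samples
  kos <- sprintf("K%05d", seq_len(cfg$n_kos))
  pathways <- sprintf("path%02d", seq_len(cfg$n_pathways))
  pathway_map <- data.frame(
    pathway = rep(pathways, each = cfg$pathway_size),
    ko = kos[seq_len(cfg$n_pathways * cfg$pathway_size)],
    stringsAsFactors = FALSE)
  n_eff <- min(4L, cfg$n_pathways %/% 2L)
  up_paths <- pathways[seq_len(n_eff)]
  down_paths <- pathways[n_eff + seq_len(n_eff)]
  ko_eff <- numeric(cfg$n_kos)
  names(ko_eff) <- kos
  ko_eff[pathway_map$ko[pathway_map$pathway %in% up_paths]] <- cfg$ko_log_effect
  ko_eff[pathway_map$ko[pathway_map$pathway %in% down_paths]] <- -cfg$ko_log_effect
  ko_vals <- with_seed(derive_seed(cfg$seed, "ko"), {
    mu <- stats::rnorm(cfg$n_kos, -6, 1)
    m <- matrix(stats::rnorm(n * cfg$n_kos, 0, 0.6), n, cfg$n_kos)
    m <- exp(sweep(m, 2L, mu, "+") +
               outer(as.numeric(lab$disease == "CD"), ko_eff))
    m / rowSums(m)
  })
  dimnames(ko_vals) <- list(sample_id, kos)
  ko_table <- abundance_table(ko_vals, mode = "relative")

  # SCFA terminal-enzyme gene abundances derived from carrier taxon mass
  rel <- counts / rowSums(counts)
  emap <- scfa_enzyme_map()
  gene_rows <- list()
  for (s in names(emap)) {
    col <- paste0(s, "_terminal")
    carriers <- annotation$taxon_id[annotation[[col]] == 1L]
    for (j in seq_along(carriers)) {
      enz <- emap[[s]][1L + (j %% length(emap[[s]]))]
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = paste0("g_", carriers[j], "_", enz), enzyme_id = enz,
        taxon_id = carriers[j], stringsAsFactors = FALSE)
    }
  }
  gene_map <- unique(do.call(rbind, gene_rows))
  gene_table <- 0.001 * rel[, gene_map$taxon_id, drop = FALSE]
  colnames(gene_table) <- gene_map$gene_id

  # coverage: signature taxa, per-sample true PTR contrast scaled by ptr_effect
  true_ptr <- NULL
  coverage <- NULL
  cov_taxa <- c(sigA, sigB, sigC)
  pe <- cfg$ptr_effect
  true_ptr <- matrix(1.3, length(cov_taxa), n, dimnames = list(cov_taxa, sample_id))
  inC <- lab$component == comps[K]
  true_ptr[sigA, inC] <- max(1, 1.3 - pe * 0.25)
  true_ptr[sigC, inC] <- 1.3 + pe * 0.5
  if (cfg$include_coverage) {
    cov_seed <- derive_seed(cfg$seed, "coverage")
    recs <- vector("list", length(cov_taxa) * n)
    k <- 0L
    for (tx in cov_taxa) {
      for (i in seq_len(n)) {
        k <- k + 1L
        prof <- simulate_coverage(true_ptr[tx, i], n_bins = cfg$coverage_bins,
                                  mean_depth = cfg$coverage_depth,
                                  noise = "poisson",
                                  seed = derive_seed(cov_seed, paste(tx, i)))
        recs[[k]] <- data.frame(taxon_id = tx, sample_id = sample_id[i],
                                bin = seq_len(cfg$coverage_bins),
                                depth = as.numeric(prof),
                                stringsAsFactors = FALSE)
      }
    }
    coverage <- do.call(rbind, recs)
  }

  truth <- list(
    component = stats::setNames(lab$component, sample_id),
    pi = stats::setNames(
      as.numeric(tapply(cfg$allocation$n, cfg$allocation$component, sum)[comps]) / n,
      comps),
    alpha = alpha,
    signature = do.call(rbind, lapply(comps, function(cmp) data.frame(
      component = cmp, taxon_id = taxa[sig_ranks[[cmp]]],
      fold = cfg$signature_fold, stringsAsFactors = FALSE))),
    ko_effects = data.frame(pathway = c(up_paths, down_paths),
                            log_effect = rep(c(cfg$ko_log_effect,
                                               -cfg$ko_log_effect),
                                             c(length(up_paths), length(down_paths))),
                            stringsAsFactors = FALSE),
    true_ptr = true_ptr,
    covariate_strength = cfg$covariate_strength)

  out <- list(counts = abundance_table(counts, mode = "counts"),
              metadata = meta, annotation = annotation,
              ko_table = ko_table, pathway_map = pathway_map,
              gene_table = gene_table, gene_map = gene_map,
              coverage = coverage, truth = truth, config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d taxa, %d components (seed %d)\n",
              nrow(x$counts$values), ncol(x$counts$values),
              length(unique(x$truth$component)), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    ko_table = file.path(outdir, "ko_table.tsv"),
    pathway_map = file.path(outdir, "pathway_map.tsv"),
    gene_table = file.path(outdir, "gene_table.tsv"),
    gene_map = file.path(outdir, "gene_map.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_abundance_table(cohort$counts, paths["counts"])
  write_abundance_table(as.data.frame(cohort$metadata), paths["metadata"])
  write_abundance_table(as.data.frame(cohort$annotation), paths["annotation"])
  write_abundance_table(cohort$ko_table, paths["ko_table"])
  write_abundance_table(cohort$pathway_map, paths["pathway_map"])
  gt <- data.frame(sample_id = rownames(cohort$gene_table),
                   cohort$gene_table, check.names = FALSE)
  write_abundance_table(gt, paths["gene_table"])
  write_abundance_table(cohort$gene_map, paths["gene_map"])
  if (!is.null(cohort$coverage)) {
    paths <- c(paths, coverage = file.path(outdir, "coverage.tsv"))
    write_abundance_table(cohort$coverage, paths["coverage"])
  }
  truth <- cohort$truth
  truth$alpha <- NULL  # large matrix; keep truth JSON compact
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
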