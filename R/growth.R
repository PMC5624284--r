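## Peak-to-trough growth-rate estimation: locate the replication origin and
## terminus on a smoothed circular coverage profile, then estimate the
## ori:ter coverage ratio from the fitted log-linear replication slope.

circular_ma <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  xx <- c(x[(n - half + 1L):n], x, x[1L:half])
  as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2L))[(half + 1L):(half + n)]
}

#' Estimate the peak-to-trough ratio (PTR) from a binned coverage profile
#'
#' The profile is treated as circular. A moving-average smooth
#' (window = `smooth_window_frac` of the bins) locates the replication
#' origin (maximum) and terminus (minimum); the profile is rejected as
#' undetected if mean coverage is below `min_mean_coverage` or the ori-ter
#' circular separation falls outside \[0.3, 0.7\] of the genome length. The
#' PTR itself is the fitted ori:ter ratio of the piecewise log-linear
#' replication profile: log2 coverage regressed on circular distance from
#' the origin, with `ptr = 2^(-slope * n_bins / 2)`, exact on noiseless
#' input and unbiased under counting noise.
#'
#' @param coverage Numeric vector of binned depths (>= 16 bins) or the
#'   output of [simulate_coverage()].
#' @param min_mean_coverage Detection threshold on mean depth per bin
#'   (default 5).
#' @param smooth_window_frac Smoothing window as a fraction of the bins
#'   (default 0.1).
#' @return data.frame (one row): `ptr` (NA when undetected), `detected`,
#'   `ori_bin`, `ter_bin`, `mean_coverage`, `qc_flags`.
#' @export
estimate_ptr <- function(coverage, min_mean_coverage = 5,
                         smooth_window_frac = 0.1) {
  x <- as.numeric(coverage)
  n <- length(x)
  if (n < 16L) stop("estimate_ptr: at least 16 bins required")
  if (any(x < 0)) stop("estimate_ptr: negative coverage")
  mc <- mean(x)
  res <- function(ptr, det, ori, ter, flags) {
    data.frame(ptr = ptr, detected = det, ori_bin = ori, ter_bin = ter,
               mean_coverage = mc, qc_flags = flags, stringsAsFactors = FALSE)
  }
  if (all(x == 0)) return(res(NA_real_, FALSE, NA_integer_, NA_integer_, "all_zero"))
  if (mc < min_mean_coverage) {
    return(res(NA_real_, FALSE, NA_integer_, NA_integer_, "low_coverage"))
  }
  w <- max(1L, round(smooth_window_frac * n))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- circular_ma(x, w)
  if (any(sm <= 0)) return(res(NA_real_, FALSE, NA_integer_, NA_integer_, "zero_bins"))
  lsm <- log2(sm)
  if (max(lsm) - min(lsm) < 1e-12) {
    return(res(1, TRUE, NA_integer_, NA_integer_, "flat"))
  }
  ori <- which.max(lsm)
  ter <- which.min(lsm)
  sep <- ((ter - ori) %% n) / n
  if (sep < 0.3 || sep > 0.7) {
    return(res(NA_real_, FALSE, ori, ter, "separation"))
  }
  pos <- which(x > 0)
  d <- pmin(abs(pos - ori), n - abs(pos - ori))
  fit <- stats::lm.fit(cbind(1, d), log2(x[pos]))
  slope <- fit$coefficients[2L]
  ptr <- 2^(-slope * (n / 2))
  flags <- ""
  if (ptr < 1) {
    ptr <- 1
    flags <- "clamped"
  }
  res(unname(ptr), TRUE, ori, ter, flags)
}

#' Estimate PTRs for a long coverage table
#'
#' @param coverage data.frame with columns `taxon_id`, `sample_id`, `bin`,
#'   `depth` (one profile per taxon-sample pair).
#' @param ... Passed to [estimate_ptr()].
#' @return data.frame with one row per (taxon, sample) profile.
#' @export
estimate_ptr_table <- function(coverage, ...) {
  stopifnot(all(c("taxon_id", "sample_id", "bin", "depth") %in% names(coverage)))
  parts <- split(coverage, list(coverage$taxon_id, coverage$sample_id), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(df) {
    df <- df[order(df$bin), , drop = FALSE]
    est <- estimate_ptr(df$depth, ...)
    cbind(data.frame(taxon_id = df$taxon_id[1L], sample_id = df$sample_id[1L],
                     stringsAsFactors = FALSE), est)
  }))
  rownames(out) <- NULL
  out
}
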