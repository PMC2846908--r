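#' Spearman correlation matrix of replicate arrays
#'
#' Rank-transforms each array (average ranks for ties) and computes the
#' product-moment correlation of the rank vectors — the Spearman correlation
#' of every pair of technical replicates. Constant arrays yield undefined
#' correlations, reported as `NA`.
#'
#' @param norm normalized log2 probe x array matrix.
#' @return symmetric array x array correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(norm) {
  norm <- as.matrix(norm)
  if (ncol(norm) < 2L) stop("need at least 2 arrays")
  suppressWarnings(stats::cor(norm, method = "spearman"))
}

.mean_upper_tri <- function(cm) mean(cm[upper.tri(cm)], na.rm = TRUE)

#' Average replicate correlation with a bootstrap percentile CI
#'
#' The statistic is the mean of the above-diagonal entries of the Spearman
#' correlation matrix of the arrays. Probes are resampled with replacement
#' `B` times; the percentile interval is taken at level
#' `1 - alpha / n_methods` (Bonferroni adjustment across the approaches
#' being compared).
#'
#' @param norm normalized log2 probe x array matrix.
#' @param B bootstrap replicates (default 10000).
#' @param alpha nominal error rate (default 0.05).
#' @param n_methods Bonferroni divisor: number of approaches compared.
#' @param seed optional seed for the resampling.
#' @param stratum label carried into the output.
#' @return one-row data.frame: `stratum`, `mean_corr`, `ci_lower`,
#'   `ci_upper`, `n_probes`, `B`, `n_methods`.
#' @export
mean_corr_ci <- function(norm, B = 10000L, alpha = 0.05, n_methods = 1L,
                         seed = NULL, stratum = "overall") {
  norm <- as.matrix(norm)
  if (B < 100L) warning("B < 100 gives unstable percentile intervals")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(norm)
  est <- .mean_upper_tri(spearman_matrix(norm))
  boot <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    .mean_upper_tri(suppressWarnings(stats::cor(norm[idx, , drop = FALSE],
                                                method = "spearman")))
  }, numeric(1))
  a2 <- alpha / n_methods / 2
  ci <- stats::quantile(boot, c(a2, 1 - a2), na.rm = TRUE, names = FALSE)
  data.frame(stratum = stratum, mean_corr = est,
             ci_lower = min(ci[1], est), ci_upper = max(ci[2], est),
             n_probes = n, B = B, n_methods = n_methods)
}

#' Decile- (or percentile-) stratified replicate correlation
#'
#' Probes are binned into `n_bins` near-equal groups by the across-array
#' median of their normalized intensity; [mean_corr_ci()] is computed within
#' each bin. Low bins are background-dominated, so this resolves how
#' reproducibility varies across the intensity range.
#'
#' @param norm normalized log2 probe x array matrix.
#' @param n_bins number of intensity strata (default 10).
#' @inheritParams mean_corr_ci
#' @return data.frame with one row per bin (`stratum` = `"bin 1"` lowest).
#' @export
stratified_corr <- function(norm, n_bins = 10L, B = 10000L, alpha = 0.05,
                            n_methods = 1L, seed = NULL) {
  norm <- as.matrix(norm)
  n <- nrow(norm)
  stopifnot(n >= n_bins)
  med <- apply(norm, 1, stats::median)
  ord <- order(med)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(d) {
    mean_corr_ci(norm[bin == d, , drop = FALSE], B = B, alpha = alpha,
                 n_methods = n_methods, seed = NULL,
                 stratum = paste("bin", d))
  }))
  rownames(out) <- NULL
  out
}

#' Sliding-window correlation across the intensity range
#'
#' Probes are sorted by their across-array median intensity; within each
#' window of `window` consecutive probes the mean pairwise Spearman
#' correlation of the arrays is computed. Windows advance by `stride`
#' probes and are reported at the intensity percentile of their centre, so
#' that curves from different approaches can be aligned.
#'
#' @param norm normalized log2 probe x array matrix.
#' @param window window size in probes (default 2000).
#' @param stride step between window starts in probes (default 100).
#' @return data.frame: `window`, `start`, `centre_percentile`,
#'   `mean_intensity`, `mean_corr`.
#' @export
sliding_window_corr <- function(norm, window = 2000L, stride = 100L) {
  norm <- as.matrix(norm)
  n <- nrow(norm)
  if (window > n) stop("usage error: window (", window,
                       ") exceeds probe count (", n, ")")
  med <- apply(norm, 1, stats::median)
  ord <- order(med)
  sorted <- norm[ord, , drop = FALSE]
  med_sorted <- med[ord]
  starts <- seq(1L, n - window + 1L, by = stride)
  out <- do.call(rbind, lapply(seq_along(starts), function(i) {
    s <- starts[i]; idx <- s:(s + window - 1L)
    cm <- suppressWarnings(stats::cor(sorted[idx, , drop = FALSE],
                                      method = "spearman"))
    data.frame(window = i, start = s,
               centre_percentile = 100 * (s + (window - 1) / 2) / n,
               mean_intensity = mean(med_sorted[idx]),
               mean_corr = .mean_upper_tri(cm))
  }))
  rownames(out) <- NULL
  out
}
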