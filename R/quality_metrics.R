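#' Negative-control mean and coefficient of variation per array
#'
#' @param norm normalized log2 probe x array matrix.
#' @param negcontrol logical mask marking negative-control probes.
#' @return data.frame with one row per array: `mean` and `cv` (sd/mean) of
#'   the negative-control values.
#' @export
negcontrol_stats <- function(norm, negcontrol) {
  norm <- as.matrix(norm)
  stopifnot(length(negcontrol) == nrow(norm), any(negcontrol))
  v <- norm[negcontrol, , drop = FALSE]
  mu <- colMeans(v)
  if (any(mu == 0))
    stop("negative-control mean is 0 for array ", which(mu == 0)[1],
         "; coefficient of variation undefined")
  data.frame(array = seq_len(ncol(norm)), mean = mu,
             cv = apply(v, 2, stats::sd) / mu, row.names = NULL)
}

#' Per-array signal-to-noise ratio
#'
#' SNR is the per-array median of the normalized log2 intensities minus the
#' mean of the negative-control probes (log2 units): how far typical signal
#' sits above typical background.
#'
#' @param norm normalized log2 probe x array matrix.
#' @param negctrl_mean per-array negative-control means (the `mean` column
#'   of [negcontrol_stats()]).
#' @return numeric vector, one SNR per array.
#' @export
snr <- function(norm, negctrl_mean) {
  norm <- as.matrix(norm)
  stopifnot(length(negctrl_mean) == ncol(norm))
  apply(norm, 2, stats::median) - negctrl_mean
}

#' Per-array dynamic range (proportion of useable data)
#'
#' The fraction of probes strictly above the background bound and strictly
#' below 10% of saturation. The upper filter is evaluated either on the
#' normalized scale against `log2(saturation_frac * ceiling)` or — for
#' approaches that fuse several scans, where the useable upper end is set by
#' the low scan — on a supplied matrix of raw low-scan values against
#' `saturation_frac * ceiling`.
#'
#' @param norm normalized log2 probe x array matrix.
#' @param background per-array background bounds ([background_bound()]).
#' @param upper_raw optional probe x array matrix of raw FLU on which the
#'   saturation filter is evaluated (e.g. the raw low scan for fused data);
#'   if `NULL`, the filter uses `norm` against `log2(saturation_frac * ceiling)`.
#' @param ceiling detector ceiling.
#' @param saturation_frac fraction of the ceiling defining the upper bound
#'   (default 0.1).
#' @return numeric vector of proportions in `[0, 1]`, one per array.
#' @export
dynamic_range <- function(norm, background, upper_raw = NULL,
                          ceiling = 65535, saturation_frac = 0.1) {
  norm <- as.matrix(norm)
  stopifnot(length(background) == ncol(norm))
  above <- sweep(norm, 2, background, ">")
  below <- if (is.null(upper_raw)) {
    norm < log2(saturation_frac * ceiling)
  } else {
    upper_raw <- as.matrix(upper_raw)
    stopifnot(all(dim(upper_raw) == dim(norm)))
    upper_raw < saturation_frac * ceiling
  }
  colMeans(above & below)
}

#' Bonferroni adjustment of p-values
#'
#' @param p raw p-value(s).
#' @param n_comparisons number of comparisons in the family.
#' @return `min(1, p * n_comparisons)`, elementwise.
#' @export
bonferroni_adjust <- function(p, n_comparisons) pmin(1, p * n_comparisons)

#' All pairwise paired t-tests with Bonferroni correction
#'
#' Compares per-array dynamic-range proportions (or any per-array metric)
#' between every pair of approaches with two-sided paired t-tests, adjusting
#' p-values by the Bonferroni rule over all `choose(k, 2)` comparisons.
#' Pairs whose per-array differences have zero variance are reported as not
#' applicable rather than propagating NaN.
#'
#' @param metric_by_approach arrays x approaches matrix (or data.frame) of a
#'   paired per-array metric; columns must be named.
#' @return data.frame with one row per pair: `approach_1`, `approach_2`,
#'   `mean_diff`, `t`, `p`, `p_adj`, `applicable`.
#' @export
paired_bonferroni <- function(metric_by_approach) {
  m <- as.matrix(metric_by_approach)
  k <- ncol(m)
  stopifnot(k >= 2L)
  if (is.null(colnames(m))) colnames(m) <- paste0("approach", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- m[, a] - m[, b]
    if (stats::sd(d) == 0) {
      data.frame(approach_1 = colnames(m)[a], approach_2 = colnames(m)[b],
                 mean_diff = mean(d), t = NA_real_, p = NA_real_,
                 p_adj = NA_real_, applicable = FALSE)
    } else {
      tt <- stats::t.test(m[, a], m[, b], paired = TRUE)
      data.frame(approach_1 = colnames(m)[a], approach_2 = colnames(m)[b],
                 mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 p = tt$p.value, p_adj = bonferroni_adjust(tt$p.value, n_comp),
                 applicable = TRUE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a per-approach quality report
#'
#' @param norm normalized log2 probe x array matrix for one approach.
#' @param negcontrol logical negative-control mask.
#' @param upper_raw optional raw matrix for the saturation filter (see
#'   [dynamic_range()]).
#' @param ceiling detector ceiling.
#' @return list of class `quality_report`: `negctrl` (per-array mean/cv),
#'   `background` (per-array bound), `snr`, `dynamic_range`.
#' @export
quality_report <- function(norm, negcontrol, upper_raw = NULL,
                           ceiling = 65535) {
  nc <- negcontrol_stats(norm, negcontrol)
  bg <- background_bound(norm, negcontrol)
  structure(list(negctrl = nc, background = bg,
                 snr = snr(norm, nc$mean),
                 dynamic_range = dynamic_range(norm, bg, upper_raw = upper_raw,
                                               ceiling = ceiling)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("quality_report over", nrow(x$negctrl), "arrays\n")
  cat(sprintf("  negctrl mean: %.3f  cv: %.3f  snr: %.3f  dynamic range: %.3f\n",
              mean(x$negctrl$mean), mean(x$negctrl$cv), mean(x$snr),
              mean(x$dynamic_range)))
  invisible(x)
}
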