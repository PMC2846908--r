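#' Specify a generative model for multi-PMT scan sets
#'
#' A `truth_model` describes how raw probe fluorescence (FLU) arises when the
#' same array is scanned repeatedly at increasing photomultiplier-tube (PMT)
#' sensitivities. Each scan level `j` has a gain `g_j`; a probe with true
#' abundance `x_i` yields
#'
#' `raw_ij = clip(round(g_j * x_i + b_ij + eps_ij), 0, ceiling)`
#'
#' where `b_ij` is background fluorescence, `eps_ij` is measurement noise with
#' per-scan scale `sigma_j = noise_scale_coeff * g_j * median(x)`, and the
#' clip reflects the 16-bit detector ceiling. Background is itself amplified
#' by the detector: its mean and spread scale as `g_j ^ background_gain_exponent`,
#' with an exponent slightly above 1 so that background grows faster than
#' signal as PMT increases (the empirical behaviour of scanner dark noise).
#'
#' True abundances are drawn once per probe from a log-normal law and shared
#' across all arrays: arrays are technical replicates of one reference RNA.
#' Negative-control probes carry no target and have true abundance 0, so they
#' measure background only.
#'
#' @param n_probes number of probes per array.
#' @param n_arrays number of replicate arrays.
#' @param n_negcontrols number of negative-control probes per array.
#' @param scan_gains strictly increasing positive gains, one per scan level,
#'   lowest scan first. The lowest gain is the reference scale.
#' @param background_mean,background_sd mean and SD (FLU) of the background
#'   fluorescence at unit gain.
#' @param background_gain_exponent exponent `gamma` such that background at
#'   gain `g` has mean `background_mean * g^gamma`. Default 1.2.
#' @param noise_model `"gaussian"` or `"cauchy"` measurement noise.
#' @param noise_scale_coeff dimensionless noise coefficient; the per-scan
#'   noise scale is `noise_scale_coeff * g_j * median(x)` FLU, where
#'   `median(x) = exp(expression_meanlog)`.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   true-abundance law (natural-log scale).
#' @param ceiling detector saturation value (default 65535, 16-bit).
#' @param seed master seed; per-array noise streams are derived from it
#'   deterministically.
#' @return an object of class `truth_model`.
#' @seealso [simulate_scanset()], [default_study_fixture()]
#' @export
truth_model <- function(n_probes = 22575L,
                        n_arrays = 40L,
                        n_negcontrols = 162L,
                        scan_gains = c(1, 5, 25),
                        background_mean = 300,
                        background_sd = 60,
                        background_gain_exponent = 1.2,
                        noise_model = c("gaussian", "cauchy"),
                        noise_scale_coeff = 0.05,
                        expression_meanlog = log(240),
                        expression_sdlog = 2,
                        ceiling = 65535,
                        seed = 1L) {
  noise_model <- match.arg(noise_model)
  n_probes <- as.integer(n_probes)
  n_arrays <- as.integer(n_arrays)
  n_negcontrols <- as.integer(n_negcontrols)
  if (n_probes < 1L || n_arrays < 1L)
    stop("configuration error: n_probes and n_arrays must be positive")
  if (n_negcontrols < 0L || n_negcontrols >= n_probes)
    stop("configuration error: n_negcontrols must be in [0, n_probes)")
  if (length(scan_gains) < 1L || any(scan_gains <= 0))
    stop("configuration error: scan gains must be positive")
  if (length(scan_gains) > 1L && any(diff(scan_gains) <= 0))
    stop("configuration error: scan gains must be strictly increasing (low to high)")
  if (ceiling <= 0) stop("configuration error: ceiling must be positive")
  if (background_sd < 0 || noise_scale_coeff < 0 || expression_sdlog <= 0)
    stop("configuration error: scale parameters must be positive")
  structure(
    list(n_probes = n_probes, n_arrays = n_arrays,
         n_negcontrols = n_negcontrols,
         scan_gains = as.numeric(scan_gains),
         background_mean = background_mean, background_sd = background_sd,
         background_gain_exponent = background_gain_exponent,
         noise_model = noise_model, noise_scale_coeff = noise_scale_coeff,
         expression_meanlog = expression_meanlog,
         expression_sdlog = expression_sdlog,
         ceiling = ceiling, seed = as.integer(seed)),
    class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat("Multi-scan truth model\n")
  cat(sprintf("  %d probes (%d negative controls) x %d arrays x %d scans\n",
              x$n_probes, x$n_negcontrols, x$n_arrays, length(x$scan_gains)))
  cat(sprintf("  gains: %s  noise: %s (coeff %g)  ceiling: %g  seed: %d\n",
              paste(x$scan_gains, collapse = ", "), x$noise_model,
              x$noise_scale_coeff, x$ceiling, x$seed))
  invisible(x)
}

# deterministic sub-seed for array a under master seed s (kept below 2^31)
.array_seed <- function(s, a) {
  as.integer((as.double(s) * 48271 + a * 7919) %% 2147483587)
}

#' Simulate a multi-scan scan set with known ground truth
#'
#' Draws true abundances, background and noise according to a [truth_model()]
#' and returns both the observed (rounded, ceiling-clipped) scan set and the
#' generating truth, so that estimator recovery can be measured exactly.
#'
#' @param model a [truth_model()].
#' @return a list with elements `scanset` (a [scanset()]) and `truth`, where
#'   `truth` has `true_expression` (probe x array matrix; columns identical
#'   because arrays are technical replicates), `gains`, `negcontrol` (logical
#'   mask) and the `model`.
#' @export
simulate_scanset <- function(model) {
  stopifnot(inherits(model, "truth_model"))
  n <- model$n_probes; na <- model$n_arrays
  gains <- model$scan_gains; m <- length(gains)
  set.seed(model$seed)
  x <- stats::rlnorm(n, model$expression_meanlog, model$expression_sdlog)
  neg_idx <- sample.int(n, model$n_negcontrols)
  negmask <- rep(FALSE, n); negmask[neg_idx] <- TRUE
  x[negmask] <- 0

  x_scale <- exp(model$expression_meanlog)      # median of the abundance law
  bg_amp <- gains ^ model$background_gain_exponent
  sigma <- model$noise_scale_coeff * gains * x_scale

  raw <- array(0, dim = c(n, na, m))
  for (a in seq_len(na)) {
    set.seed(.array_seed(model$seed, a))
    for (j in seq_len(m)) {
      b <- if (model$background_mean > 0 || model$background_sd > 0) {
        pmax(stats::rnorm(n, model$background_mean * bg_amp[j],
                          model$background_sd * bg_amp[j]), 0)
      } else 0
      eps <- if (sigma[j] > 0) {
        switch(model$noise_model,
               gaussian = stats::rnorm(n, 0, sigma[j]),
               cauchy   = stats::rcauchy(n, 0, sigma[j]))
      } else 0
      raw[, a, j] <- pmin(pmax(round(gains[j] * x + b + eps), 0), model$ceiling)
    }
  }

  probe_ids <- sprintf("P%05d", seq_len(n))
  ctype <- ifelse(negmask, "negative_control", "experimental")
  ss <- scanset(raw, probe_ids = probe_ids, control_type = ctype,
                scan_labels = paste0("scan", seq_len(m)),
                ceiling = model$ceiling)
  truth <- list(true_expression = matrix(x, n, na),
                gains = gains, negcontrol = negmask, model = model)
  list(scanset = ss, truth = truth)
}

#' Standard simulated study fixture
#'
#' A fixed-seed scan set emulating the structure of a 40-technical-replicate
#' reference-RNA study: 22575 probes per array, 162 negative controls, three
#' ordered PMT scan levels and a 16-bit ceiling. The `mini` variant (2000
#' probes x 8 arrays) keeps the same generative regime but runs the full
#' pipeline in seconds; it is the fixture used throughout the test suite.
#'
#' @param mini if `TRUE`, return the reduced fixture.
#' @param seed master seed (default fixed so the fixture is reproducible).
#' @return as [simulate_scanset()].
#' @export
default_study_fixture <- function(mini = FALSE, seed = 20101L) {
  model <- if (mini) {
    truth_model(n_probes = 2000L, n_arrays = 8L, n_negcontrols = 162L,
                seed = seed)
  } else {
    truth_model(seed = seed)
  }
  simulate_scanset(model)
}
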