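#' @title Multi-scan fusion algorithms
#' @description Three approaches to combining scans of the same array taken
#'   at different PMT sensitivities into a single per-probe intensity:
#'   [lyng_combine()] (multiplicative rescaling of the low scan to impute
#'   saturated high-scan probes), [csml_combine()] (clipping-saturation
#'   maximum likelihood on a robust line fit) and [khondoker_combine()]
#'   (Cauchy functional regression over all scans with ceiling censoring).
#' @name combine
NULL

new_combined_estimate <- function(method, fused, fit, provenance) {
  stopifnot(all(fused >= 0, na.rm = TRUE), all(dim(fused) == dim(provenance)))
  structure(list(method = method, fused = fused, fit = fit,
                 provenance = provenance),
            class = "combined_estimate")
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat(sprintf("combined_estimate [%s]: %d probes x %d arrays\n",
              x$method, nrow(x$fused), ncol(x$fused)))
  tab <- table(x$provenance)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

.as_pa_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
}

# run expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Combine low and high scans by windowed multiplicative scaling
#'
#' Estimates the scanner's multiplicative gain between the low and high scan
#' from probes whose high-scan signal lies in a mid-intensity window (default
#' 20000-30000 FLU, high enough to dominate background, low enough to be
#' unaffected by saturation): the correction factor `k` is the mean of the
#' per-probe high/low ratios in the window. High-scan values above
#' `impute_threshold` (default 50000 FLU) are then replaced by `k * low`;
#' all other probes keep their high-scan value.
#'
#' @param low,high probe x array matrices (or vectors for one array) of raw
#'   FLU from the lowest- and highest-sensitivity scans.
#' @param window numeric length-2: the high-scan FLU window used to estimate
#'   `k`.
#' @param impute_threshold high-scan FLU above which values are imputed from
#'   the low scan.
#' @return a `combined_estimate`; `fit` holds one `LyngFit` per array with
#'   the correction factor `k` and the window population size.
#' @export
lyng_combine <- function(low, high, window = c(20000, 30000),
                         impute_threshold = 50000) {
  low <- .as_pa_matrix(low); high <- .as_pa_matrix(high)
  stopifnot(all(dim(low) == dim(high)), length(window) == 2L,
            window[1] < window[2])
  fused <- high
  prov <- matrix("observed", nrow(high), ncol(high))
  fits <- vector("list", ncol(high))
  for (a in seq_len(ncol(high))) {
    w <- which(high[, a] >= window[1] & high[, a] <= window[2] & low[, a] > 0)
    if (!length(w))
      stop("estimation error: no probes in the high-scan window [",
           window[1], ", ", window[2], "]; widen the window")
    k <- mean(high[w, a] / low[w, a])
    imp <- which(high[, a] > impute_threshold)
    fused[imp, a] <- k * low[imp, a]
    prov[imp, a] <- "imputed"
    fits[[a]] <- list(correction_factor = k, window = window,
                      impute_threshold = impute_threshold,
                      n_window_probes = length(w))
  }
  new_combined_estimate("lyng", fused, fits, prov)
}

# CSML per-probe objective: quadratic fidelity to the low scan plus either a
# quadratic high-scan term (unclipped) or the censored Gaussian tail
# (clipped observation at the ceiling).
csml_objective <- function(t, low, high, a, b, sigma_low, sigma_high,
                           clipped, ceiling) {
  q <- (low - t)^2 / sigma_low^2
  hi <- ifelse(clipped,
               -stats::pnorm(ceiling, mean = a * t + b, sd = sigma_high,
                             lower.tail = FALSE, log.p = TRUE),
               (high - (a * t + b))^2 / sigma_high^2)
  q + hi
}

# vectorised golden-section minimisation of f over per-element brackets
.golden_min <- function(f, lo, hi, iter = 70L) {
  gr <- (sqrt(5) - 1) / 2
  for (i in seq_len(iter)) {
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    left <- f(x1) <= f(x2)
    hi <- ifelse(left, x2, hi)
    lo <- ifelse(left, lo, x1)
  }
  (lo + hi) / 2
}

#' Clipping-saturation maximum-likelihood fusion of two scans
#'
#' Fits a resistant line `high ~ a * low + b` by least trimmed squares
#' (`MASS::lqs`) over probes not at the ceiling, estimates Gaussian noise
#' scales from the robust residual spread (assuming noise scales with gain,
#' `sigma_low = sigma_high / a`), then recovers each probe's latent
#' low-scale intensity `t` by minimising
#' `(low - t)^2/sigma_low^2 + (high - (a t + b))^2/sigma_high^2`;
#' for probes clipped at the ceiling the high-scan term is replaced by the
#' censored tail `-log P(a t + b + eps >= ceiling)`. The fused value is
#' reported on the high-scan scale, `a * t + b`, free of censoring (it may
#' exceed the ceiling for de-censored probes).
#'
#' @param low,high probe x array matrices (or vectors) of raw FLU.
#' @param clip_threshold FLU at or above which a high-scan value is treated
#'   as censored (default: the 16-bit ceiling).
#' @param robust_trim fraction of probes the trimmed-squares line may ignore
#'   (default 0.5, the least-trimmed-squares convention).
#' @param ceiling detector ceiling used in the censored tail.
#' @param lts_seed seed pinned around the randomized trimmed-squares
#'   subsampling, so repeated calls give identical fits.
#' @return a `combined_estimate`; `fit` holds one `CsmlFit` per array
#'   (`scale_a`, `intercept_b`, `sigma_low`, `sigma_high`, `converged`).
#' @export
csml_combine <- function(low, high, clip_threshold = 65535,
                         robust_trim = 0.5, ceiling = 65535,
                         lts_seed = 1L) {
  low <- .as_pa_matrix(low); high <- .as_pa_matrix(high)
  stopifnot(all(dim(low) == dim(high)))
  n <- nrow(low)
  fused <- matrix(NA_real_, n, ncol(low))
  prov <- matrix("estimated", n, ncol(low))
  fits <- vector("list", ncol(low))
  for (ar in seq_len(ncol(low))) {
    l <- low[, ar]; h <- high[, ar]
    unclip <- h < clip_threshold
    if (sum(unclip) < 10L)
      stop("estimation error: fewer than 10 unclipped probes for the line fit")
    q <- max(2L, min(sum(unclip) - 1L, ceiling(sum(unclip) * (1 - robust_trim))))
    # lqs subsamples randomly; pin its stream so the fit is deterministic
    lf <- .with_seed(lts_seed,
                     MASS::lqs(h[unclip] ~ l[unclip], method = "lts",
                               quantile = q))
    b <- unname(coef(lf)[1]); a <- unname(coef(lf)[2])
    if (!is.finite(a) || a <= 0)
      stop("estimation error: non-positive robust slope between scans")
    res <- h[unclip] - (a * l[unclip] + b)
    sigma_high <- max(stats::mad(res) / sqrt(2), 1e-8 * max(stats::median(h), 1))
    sigma_low <- sigma_high / a

    # unclipped probes: the objective is quadratic in t, solve exactly
    t_hat <- numeric(n)
    t_hat[unclip] <- (l[unclip] / sigma_low^2 + a * (h[unclip] - b) / sigma_high^2) /
      (1 / sigma_low^2 + a^2 / sigma_high^2)

    clip_i <- which(!unclip)
    if (length(clip_i)) {
      lc <- l[clip_i]
      edge <- (ceiling - b) / a
      lo_b <- pmin(lc, edge) - 3 * sigma_low
      hi_b <- pmax(lc, edge) + 3 * sigma_low + 6 * sigma_high / a
      f <- function(t) csml_objective(t, lc, h[clip_i], a, b,
                                      sigma_low, sigma_high,
                                      clipped = TRUE, ceiling = ceiling)
      t_hat[clip_i] <- .golden_min(f, lo_b, hi_b)
      prov[clip_i, ar] <- "de-censored"
    }
    bad <- !is.finite(t_hat)
    if (any(bad)) {
      warning(sum(bad), " probes failed the per-probe solve; ",
              "falling back to the rescaled low scan")
      t_hat[bad] <- l[bad]
      prov[bad, ar] <- "fallback"
    }
    fused[, ar] <- pmax(a * t_hat + b, 0)
    fits[[ar]] <- list(scale_a = a, intercept_b = b,
                       sigma_low = sigma_low, sigma_high = sigma_high,
                       clip_threshold = clip_threshold,
                       latent = t_hat, converged = !any(bad))
  }
  new_combined_estimate("csml", fused, fits, prov)
}

# ---- Khondoker-style Cauchy functional regression --------------------------

# log-likelihood contributions per probe for candidate latent values x
# y: n x m matrix, clipped: logical n x m, beta: m, scales s = sigma*beta
.cauchy_ll_rows <- function(x, y, clipped, beta, s) {
  mu <- outer(x, beta)
  ll <- matrix(0, nrow(y), ncol(y))
  u <- !clipped
  ll[u] <- stats::dcauchy(y[u], location = mu[u],
                          scale = rep(s, each = nrow(y))[u], log = TRUE)
  if (any(clipped)) {
    sc <- rep(s, each = nrow(y))[clipped]
    ll[clipped] <- stats::pcauchy(y[clipped], location = mu[clipped],
                                  scale = sc, lower.tail = FALSE, log.p = TRUE)
  }
  rowSums(ll)
}

# profile the latent x per probe given (beta, sigma): coarse candidate scan
# (log-spaced grid plus the exact per-scan ratios, so exact-fit optima are
# reachable) followed by vectorised golden-section refinement. The Cauchy
# mixture can hold one near-equal mode per scan; `thorough` refines around
# every ratio so the reported maximiser resolves each mode, which the cheap
# variant (used inside the alternating loop) does not need
.profile_x <- function(y, clipped, beta, sigma, ceiling, n_grid = 33L,
                       thorough = FALSE) {
  n <- nrow(y); m <- ncol(y)
  s <- pmax(sigma * beta, .Machine$double.xmin)
  ratios <- sweep(y, 2, beta, "/")
  rmax <- apply(ratios, 1, max)
  # bracket on the hull of positive per-scan ratios: modes of the Cauchy
  # mixture live there, and zero observations must not stretch the grid
  rpos <- ratios; rpos[rpos <= 0] <- Inf
  rpos_min <- do.call(pmin, c(as.data.frame(rpos), list(1e-9)))
  lo <- pmax(pmin(rpos_min, rmax) * 0.5, 1e-9)
  hi <- pmax(rmax * 4, lo * (1 + 1e-6))
  grid <- exp(outer(log(lo), rep(1, n_grid)) +
              outer(log(hi / lo), seq(0, 1, length.out = n_grid)))
  cand <- cbind(grid, pmax(ratios, 1e-9))
  best_ll <- rep(-Inf, n); best_x <- pmax(ratios[, 1], 1e-9)
  for (k in seq_len(ncol(cand))) {
    ll <- .cauchy_ll_rows(cand[, k], y, clipped, beta, s)
    better <- is.finite(ll) & ll > best_ll
    best_ll[better] <- ll[better]; best_x[better] <- cand[better, k]
  }
  # local refinement around the best candidate
  span <- (log(hi) - log(lo)) / (n_grid - 1)
  f <- function(lx) -.cauchy_ll_rows(exp(lx), y, clipped, beta, s)
  take_if_better <- function(x_new) {
    ll_new <- .cauchy_ll_rows(x_new, y, clipped, beta, s)
    better <- is.finite(ll_new) & ll_new > best_ll
    best_ll[better] <<- ll_new[better]; best_x[better] <<- x_new[better]
  }
  take_if_better(exp(.golden_min(f, log(best_x) - span, log(best_x) + span,
                                 iter = 34L)))
  if (thorough) {
    # one bracket per ratio, no wider than half the gap to its nearest
    # neighbour, so each golden search sees a single mode
    m <- ncol(y)
    lr_all <- log(pmax(ratios, 1e-9))
    for (j in seq_len(m)) {
      gap <- rep(0.2, n)
      for (k in seq_len(m)[-j]) {
        gap <- pmin(gap, abs(lr_all[, j] - lr_all[, k]) / 2)
      }
      gap <- pmax(gap, 1e-3)
      take_if_better(exp(.golden_min(f, lr_all[, j] - gap, lr_all[, j] + gap,
                                     iter = 34L)))
    }
  }
  best_x
}

.khondoker_ll <- function(x, y, clipped, beta, sigma) {
  sum(.cauchy_ll_rows(x, y, clipped, beta, pmax(sigma * beta,
                                                .Machine$double.xmin)))
}

# 1-d coordinate update: evaluate ll over candidate values (current value
# included, so the step never decreases the likelihood), then refine around
# the best candidate with Brent, keeping the refinement only if it helps
.coord_step <- function(ll_of, cand, current, delta) {
  cand <- unique(c(current, cand))
  vals <- vapply(cand, ll_of, numeric(1))
  best <- cand[which.max(vals)]; best_ll <- max(vals)
  opt <- stats::optimize(function(v) -ll_of(v),
                         interval = c(best - delta, best + delta),
                         tol = 1e-10)
  if (-opt$objective > best_ll) opt$minimum else best
}

# one array's fit: alternate profiling the latent x with coordinate ascent
# over log(sigma) (searched globally each pass, down to the floor, so the
# degenerate sigma -> 0 optimum is reachable when the likelihood favours it)
# and each log(beta_j)
fit_khondoker_array <- function(y, ceiling, sigma_floor, max_iter = 18L,
                                tol = 1e-5) {
  n <- nrow(y); m <- ncol(y)
  clipped <- y >= ceiling
  fully <- rowSums(!clipped) == 0L
  # initial beta from per-scan ratios over jointly unclipped probes
  beta <- numeric(m); beta[1] <- 1
  for (j in seq_len(m)[-1]) {
    ok <- !clipped[, 1] & !clipped[, j] & y[, 1] > 0
    beta[j] <- if (any(ok)) stats::median(y[ok, j] / y[ok, 1]) else beta[j - 1] * 2
  }
  x0 <- apply(sweep(y, 2, beta, "/"), 1, function(r) stats::median(r))
  r1 <- (y[, 1] - x0)[!clipped[, 1]]
  sigma <- max(stats::mad(r1), sigma_floor * 10)

  lsig_grid <- seq(log(sigma_floor), log(max(y) + 1), length.out = 30L)
  ll_old <- -Inf; x <- x0; it <- 0L
  for (it in seq_len(max_iter)) {
    x <- .profile_x(y, clipped, beta, sigma, ceiling)
    ll_sig <- function(ls) .khondoker_ll(x, y, clipped, beta, exp(ls))
    # after the first sweep only search locally, but always keep the floor
    # as a candidate so the degenerate boundary optimum stays reachable
    scand <- if (it == 1L) lsig_grid else
      c(log(sigma_floor), log(sigma) + seq(-0.3, 0.3, length.out = 9L))
    ls <- .coord_step(ll_sig, scand, log(sigma),
                      delta = if (it == 1L) diff(lsig_grid[1:2]) else 0.075)
    sigma <- max(exp(ls), sigma_floor)
    for (j in seq_len(m)[-1]) {
      ll_b <- function(lb) {
        b <- beta; b[j] <- exp(lb)
        .khondoker_ll(x, y, clipped, b, sigma)
      }
      w <- if (it == 1L) 0.6 else 0.12
      cand <- log(beta[j]) + seq(-w, w, length.out = if (it == 1L) 25L else 9L)
      beta[j] <- exp(.coord_step(ll_b, cand, log(beta[j]), delta = w / 10))
    }
    ll <- .khondoker_ll(x, y, clipped, beta, sigma)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  x <- .profile_x(y, clipped, beta, sigma, ceiling, thorough = TRUE)
  fit <- list(beta = beta, sigma = sigma, x = x,
              loglik = .khondoker_ll(x, y, clipped, beta, sigma), n_iter = it)

  # probes censored in every scan carry no interior information
  if (any(fully)) fit$x[fully] <- ceiling / fit$beta[1]
  degenerate <- fit$sigma <= sigma_floor * (1 + 1e-4)
  if (any(diff(fit$beta) < 0))
    warning("fitted gains are not non-decreasing across ordered scans")
  list(betas = fit$beta, sigma = fit$sigma, x_hat = fit$x,
       loglik = fit$loglik, degenerate_scale_flag = degenerate,
       n_iter = fit$n_iter, ceiling = ceiling, clipped = clipped,
       fully_censored = fully)
}

#' Fuse m >= 2 scans by Cauchy functional regression with ceiling censoring
#'
#' Fits, separately for each array, the errors-in-variables model
#' `y_ij = clip(beta_j * x_i + eps_ij, ceiling)` with `eps_ij ~
#' Cauchy(0, sigma * beta_j)` and `beta_1 = 1`: every scan is a scaled
#' observation of the same latent expression `x_i`, noise scales in
#' proportion to the gains, and observations at the detector ceiling enter
#' the likelihood through the Cauchy upper-tail probability. Fitting
#' alternates profiling each `x_i` (1-d, derivative-free) with maximising
#' over `(beta, sigma)`; estimates are returned on the lowest-scan scale.
#'
#' With only two scans the profile likelihood can grow without bound as
#' `sigma -> 0` (each censored high-scan probe whose rescaled low-scan value
#' already exceeds the ceiling is fitted perfectly by a degenerate scale);
#' `sigma` is therefore floored at `sigma_floor_factor * median(y)` and
#' `degenerate_scale_flag` is set when the fit lands on the floor. Three or
#' more scans penalise the degenerate solution and fit stably.
#'
#' @param scanset a [scanset()] (or probe x array x scan array).
#' @param scans indices of the scans to use, low to high (default: all).
#' @param sigma_floor_factor floor for `sigma` as a fraction of the median
#'   intensity (default 1e-6).
#' @param max_iter,tol outer-loop control.
#' @return a `combined_estimate`; `fit` holds one `KhondokerFit` per array
#'   (`betas`, `sigma`, `x_hat`, `loglik`, `degenerate_scale_flag`).
#' @export
khondoker_combine <- function(scanset, scans = NULL,
                              sigma_floor_factor = 1e-6,
                              max_iter = 18L, tol = 1e-5) {
  if (inherits(scanset, "scanset")) {
    arr <- scanset$intensities; ceiling_ <- scanset$ceiling
  } else {
    arr <- scanset; ceiling_ <- 65535
  }
  if (is.null(scans)) scans <- seq_len(dim(arr)[3])
  if (length(scans) < 2L)
    stop("usage error: at least 2 scans are required")
  n <- dim(arr)[1]; na <- dim(arr)[2]
  fused <- matrix(NA_real_, n, na)
  prov <- matrix("estimated", n, na)
  fits <- vector("list", na)
  for (a in seq_len(na)) {
    y <- matrix(arr[, a, scans], n, length(scans))
    sigma_floor <- sigma_floor_factor * max(stats::median(y), 1)
    fit <- fit_khondoker_array(y, ceiling_, sigma_floor,
                               max_iter = max_iter, tol = tol)
    fused[, a] <- pmax(fit$x_hat, 0)
    prov[fit$fully_censored, a] <- "fully-censored"
    fits[[a]] <- fit
  }
  method <- paste0("khondoker", length(scans))
  new_combined_estimate(method, fused, fits, prov)
}

#' Standardized residuals of a Cauchy functional-regression fit
#'
#' For each unclipped observation, `r_ij = (y_ij - min(beta_j * x_hat_i,
#' ceiling)) / (sigma * beta_j)`; observations at the ceiling are excluded
#' and counted. Probes are returned ordered by the rank of their estimated
#' intensity, the layout used to inspect intensity-dependent lack of fit.
#'
#' @param fit one array's `KhondokerFit` (an element of the `fit` list of
#'   [khondoker_combine()]'s result).
#' @param y the probe x scan raw matrix the fit was computed from.
#' @return list with `residuals` (probe x scan, NA where clipped, rows in
#'   rank order of `x_hat`), `rank` (the ordering used), `x_hat` (sorted)
#'   and `n_clipped`.
#' @export
standardized_residuals <- function(fit, y) {
  stopifnot(!is.null(fit$betas), ncol(y) == length(fit$betas))
  mu <- pmin(outer(fit$x_hat, fit$betas), fit$ceiling)
  s <- rep(pmax(fit$sigma * fit$betas, .Machine$double.xmin), each = nrow(y))
  r <- (y - mu) / s
  r[fit$clipped] <- NA_real_
  ord <- order(fit$x_hat)
  list(residuals = r[ord, , drop = FALSE], rank = ord,
       x_hat = fit$x_hat[ord], n_clipped = sum(fit$clipped))
}
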