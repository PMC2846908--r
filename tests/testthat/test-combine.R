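# Lyng ----------------------------------------------------------------------

test_that("lyng correction factor and imputation follow the stated recipe", {
  # hand-computed: only probe 2 is in the 20000-30000 window, ratio 10;
  # probe 3 exceeds 50000 and is imputed as 10 * 6000
  ce <- lyng_combine(c(1000, 2500, 6000), c(10000, 25000, 65535))
  expect_equal(unname(ce$fused[, 1]), c(10000, 25000, 60000))
  expect_equal(ce$fit[[1]]$correction_factor, 10)
  expect_equal(ce$fit[[1]]$n_window_probes, 1L)
  expect_equal(ce$provenance[, 1], c("observed", "observed", "imputed"))
})

test_that("lyng recovers the exact gain on noiseless data", {
  np <- noiseless_pair(gain = 9)
  ce <- lyng_combine(np$low, np$high)
  expect_equal(ce$fit[[1]]$correction_factor, 9, tolerance = 1e-12)
  imputed <- ce$provenance[, 1] == "imputed"
  expect_true(any(imputed))
  expect_equal(ce$fused[imputed, 1], 9 * np$low[imputed], tolerance = 1e-12)
})

test_that("lyng leaves data untouched when nothing exceeds the threshold", {
  low <- seq(100, 4000, length.out = 50)
  high <- 10 * low  # max 40000 < 50000
  ce <- lyng_combine(low, high)
  expect_equal(unname(ce$fused[, 1]), high)
  expect_true(all(ce$provenance == "observed"))
  # an empty estimation window is an error suggesting a wider window
  expect_error(lyng_combine(c(1, 2), c(10, 20)), "widen the window")
})

# CSML ----------------------------------------------------------------------

test_that("csml is exact on noiseless unclipped data and de-censors clipping", {
  np <- noiseless_pair(gain = 10)
  ce <- csml_combine(np$low, np$high)
  f <- ce$fit[[1]]
  expect_equal(f$scale_a, 10, tolerance = 1e-6)
  expect_equal(f$intercept_b, 0, tolerance = 1e-3)
  unclip <- np$high < np$ceiling
  expect_equal(ce$fused[unclip, 1], np$high[unclip], tolerance = 1e-9)
  # the clipped probes are pushed beyond the ceiling to the true line
  i <- which(!unclip & np$low == 7000)
  expect_gt(length(i), 0)
  expect_equal(ce$fused[i, 1], 70000, tolerance = 1e-3 * 70000)
  expect_true(all(ce$fused[!unclip, 1] > np$ceiling))
  expect_true(all(ce$provenance[!unclip, 1] == "de-censored"))
})

test_that("csml per-probe estimates match the brute-force oracle", {
  set.seed(31)
  n <- 400
  low <- exp(runif(n, log(200), log(9000)))
  high <- pmin(10 * low + rnorm(n, 0, 400), 65535)
  ce <- csml_combine(low, high)
  f <- ce$fit[[1]]
  idx <- sample(n, 100)
  oracle <- vapply(idx, function(i) {
    oracle_csml_t(low[i], high[i], f$scale_a, f$intercept_b,
                  f$sigma_low, f$sigma_high, high[i] >= 65535, 65535)
  }, numeric(1))
  expect_lt(max(abs(f$latent[idx] - oracle) / pmax(abs(oracle), 1)), 1e-3)
})

# Khondoker -----------------------------------------------------------------

test_that("khondoker recovers gains exactly on noiseless unclipped scans", {
  set.seed(1)
  x <- runif(400, 100, 6000)
  arr <- array(0, dim = c(400, 1, 3))
  for (j in 1:3) arr[, 1, j] <- c(1, 2, 4)[j] * x  # max 24000, unclipped
  ce <- khondoker_combine(arr)
  f <- ce$fit[[1]]
  expect_equal(f$betas, c(1, 2, 4), tolerance = 1e-6)
  expect_equal(unname(ce$fused[, 1]), x, tolerance = 1e-6)
  # a perfect fit drives the scale to its floor: flagged, by design
  expect_true(f$degenerate_scale_flag)
})

test_that("khondoker per-probe estimates match the brute-force oracle", {
  sim <- small_cauchy()
  ce <- khondoker_combine(sim$scanset)
  f <- ce$fit[[1]]
  y <- scan_matrix(sim$scanset, 1)
  set.seed(57)
  # probes with every scan quantified above zero: zero observations leave
  # flat likelihood ridges on which the maximiser is not unique to 1e-3
  eligible <- which(!f$fully_censored & apply(y > 0, 1, all))
  idx <- sample(eligible, 100)
  oracle <- vapply(idx, function(i) {
    oracle_khondoker_x(y[i, ], f$betas, f$sigma, sim$scanset$ceiling)
  }, numeric(1))
  expect_lt(max(abs(f$x_hat[idx] - oracle) / oracle), 1e-3)
})

test_that("khondoker 3-scan fusion beats every rescaled single scan", {
  sim <- small_cauchy()
  ss <- sim$scanset
  truth <- sim$truth$true_expression[, 1]
  keep <- truth > 0
  ce <- khondoker_combine(ss)
  mre <- function(est) median(abs(est[keep] - truth[keep]) / truth[keep])
  err_fused <- mre(ce$fused[, 1])
  err_scans <- vapply(1:3, function(j) {
    mre(ss$intensities[, 1, j] / sim$truth$gains[j])
  }, numeric(1))
  expect_true(all(err_fused < err_scans))
  # and in log2 RMSE, the censoring-aware fit beats the censored high scan
  expect_lt(log2_rmse(ce$fused[keep, 1], truth[keep]),
            log2_rmse(ss$intensities[keep, 1, 3] / sim$truth$gains[3],
                      truth[keep]))
})

test_that("two-scan fits of three-scan-spread data degenerate to the floor", {
  sim <- small_cauchy()
  ce2 <- khondoker_combine(sim$scanset, scans = c(1, 3))
  expect_true(ce2$fit[[1]]$degenerate_scale_flag)
  ce3 <- khondoker_combine(sim$scanset)
  expect_false(ce3$fit[[1]]$degenerate_scale_flag)
  expect_error(khondoker_combine(sim$scanset, scans = 2L), "at least 2 scans")
})

test_that("fully censored probes carry the censoring bound and provenance", {
  arr <- array(0, dim = c(60, 1, 2))
  set.seed(4)
  x <- c(runif(59, 500, 5000), 1e9)
  for (j in 1:2) arr[, 1, j] <- pmin(c(1, 8)[j] * x + rnorm(60, 0, 20), 65535)
  arr <- pmax(round(arr), 0)
  ce <- khondoker_combine(arr)
  expect_equal(ce$provenance[60, 1], "fully-censored")
  expect_equal(ce$fused[60, 1], 65535 / ce$fit[[1]]$betas[1])
})

# standardized residuals ----------------------------------------------------

test_that("standardized residuals are zero for perfect fits and scale by sigma", {
  # single observation: y = 12, mu = 10, scale 2 -> residual 1
  fit <- list(betas = 1, sigma = 2, x_hat = 10, ceiling = 65535,
              clipped = matrix(FALSE, 1, 1))
  sr <- standardized_residuals(fit, matrix(12, 1, 1))
  expect_equal(unname(sr$residuals[1, 1]), 1)

  # noiseless fit: all residuals 0, clipped entries excluded and counted
  x <- seq(100, 5000, length.out = 50)
  y <- cbind(x, pmin(4 * x, 12000))
  clip <- y >= 12000
  fit2 <- list(betas = c(1, 4), sigma = 1, x_hat = x, ceiling = 12000,
               clipped = clip)
  sr2 <- standardized_residuals(fit2, y)
  expect_equal(sr2$n_clipped, sum(clip))
  expect_equal(sum(is.na(sr2$residuals)), sum(clip))
  expect_true(all(abs(sr2$residuals[!is.na(sr2$residuals)]) < 1e-9))
})

test_that("residual diagnostics separate the stable 3-scan fit from the degenerate 2-scan fit", {
  sim <- small_cauchy()
  ss <- sim$scanset
  ce3 <- khondoker_combine(ss)
  ce2 <- khondoker_combine(ss, scans = c(1, 3))
  sr3 <- standardized_residuals(ce3$fit[[1]], scan_matrix(ss, 1))
  sr2 <- standardized_residuals(ce2$fit[[1]], scan_matrix(ss, 1, scans = c(1, 3)))
  n <- nrow(sr3$residuals)
  mid <- floor(0.45 * n):floor(0.55 * n)
  # a well-specified Cauchy fit has unit-scale standardized residuals
  r3 <- sr3$residuals[mid, ]
  expect_gt(IQR(r3[is.finite(r3)]), 0.5)
  expect_lt(IQR(r3[is.finite(r3)]), 8)
  # the degenerate fit pins its best-fitting scan to the data exactly
  # rows that are fully censored have no finite residual; drop them
  row_min <- function(r) {
    suppressWarnings(apply(abs(r), 1, min, na.rm = TRUE))
  }
  best2 <- row_min(sr2$residuals)
  best3 <- row_min(sr3$residuals)
  expect_lt(median(best2[is.finite(best2)]), 1e-3)
  expect_gt(median(best3[is.finite(best3)]), 1e-3)
})

# cross-cutting properties ---------------------------------------------------

test_that("all three methods are equivariant under a common intensity rescaling", {
  set.seed(21)
  n <- 300
  low <- exp(runif(n, log(500), log(6000)))
  high <- 8 * low + rnorm(n, 0, 100)
  cl <- 0.5  # shrink, so nothing approaches the ceiling after scaling

  k1 <- lyng_combine(low, high, window = c(20000, 30000))
  k2 <- lyng_combine(cl * low, cl * high, window = cl * c(20000, 30000),
                     impute_threshold = cl * 50000)
  expect_equal(k2$fit[[1]]$correction_factor, k1$fit[[1]]$correction_factor,
               tolerance = 1e-10)
  expect_equal(unname(k2$fused), unname(cl * k1$fused), tolerance = 1e-10)

  c1 <- csml_combine(low, high)
  c2 <- csml_combine(cl * low, cl * high)
  expect_equal(c2$fit[[1]]$scale_a, c1$fit[[1]]$scale_a, tolerance = 1e-6)
  expect_equal(unname(c2$fused), unname(cl * c1$fused), tolerance = 1e-3)

  arr <- array(0, dim = c(n, 1, 2))
  arr[, 1, 1] <- low; arr[, 1, 2] <- high
  h1 <- khondoker_combine(arr)
  h2 <- khondoker_combine(cl * arr)
  expect_equal(h2$fit[[1]]$betas, h1$fit[[1]]$betas, tolerance = 1e-3)
  expect_equal(unname(h2$fused), unname(cl * h1$fused), tolerance = 5e-3)
})
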