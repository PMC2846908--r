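# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# model-faithful fixture for the Cauchy functional-regression tests:
# no background, Cauchy noise, ~21% high-scan saturation
cauchy_model <- function(seed, n_probes = 5000L, n_arrays = 4L) {
  truth_model(n_probes = n_probes, n_arrays = n_arrays, n_negcontrols = 0L,
              scan_gains = c(1, 4, 20),
              background_mean = 0, background_sd = 0,
              noise_model = "cauchy", noise_scale_coeff = 0.05,
              expression_meanlog = log(1000), expression_sdlog = 1.5,
              seed = seed)
}

mini_fixture <- function() cached("mini", default_study_fixture(mini = TRUE))

# small Cauchy fixture reused by combine-module tests
small_cauchy <- function() {
  cached("small_cauchy",
         simulate_scanset(cauchy_model(101L, n_probes = 1500L, n_arrays = 1L)))
}

# noiseless two-scan matrices with a clipped tail (one array); includes a
# probe at exactly low = 7000 so de-censoring examples have a known answer
noiseless_pair <- function(gain = 10, n = 400, ceiling = 65535) {
  set.seed(7)
  low <- c(round(seq(200, 9000, length.out = n - 1)), 7000)
  high <- pmin(gain * low, ceiling)
  list(low = low, high = high, gain = gain, ceiling = ceiling)
}

log2_rmse <- function(est, truth) {
  sqrt(mean((log2(pmax(est, 1)) - log2(pmax(truth, 1)))^2))
}

# full pipeline on the mini study fixture, shared by the pipeline and
# acceptance tests (bootstrap kept small; the qualitative checks do not
# depend on it)
mini_report <- function() {
  cached("mini_report", {
    fx <- mini_fixture()
    cfg <- run_config(scanset = fx$scanset, negcontrol = fx$truth$negcontrol,
                      B = 150L, n_bins = 10L, corr_window = 200L,
                      corr_stride = 50L, seed = 42L)
    run_pipeline(cfg)
  })
}
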