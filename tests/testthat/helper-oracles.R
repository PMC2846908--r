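# independent brute-force oracles ------------------------------------------

# grid search + local refinement for the CSML per-probe objective
oracle_csml_t <- function(low, high, a, b, sl, sh, clipped, ceiling) {
  obj <- function(t) {
    hi_term <- if (clipped) {
      -pnorm(ceiling, mean = a * t + b, sd = sh, lower.tail = FALSE,
             log.p = TRUE)
    } else {
      (high - (a * t + b))^2 / sh^2
    }
    (low - t)^2 / sl^2 + hi_term
  }
  hi_end <- max(low, (ceiling - b) / a) + 4 * sl + 8 * sh / a
  grid <- seq(min(low, (ceiling - b) / a) - 4 * sl, hi_end, length.out = 4000)
  vals <- vapply(grid, obj, numeric(1))
  best <- grid[which.min(vals)]
  step <- diff(grid[1:2])
  opt <- optimize(obj, c(best - step, best + step), tol = 1e-9)
  if (opt$objective < min(vals)) opt$minimum else best
}

# grid search + refinement for one probe of the Cauchy censored likelihood;
# every per-scan ratio can host a near-equal mode, so each is polished and
# the best resolved maximiser wins
oracle_khondoker_x <- function(y, beta, sigma, ceiling) {
  clipped <- y >= ceiling
  ll <- function(x) {
    mu <- beta * x; s <- sigma * beta
    sum(ifelse(clipped,
               pcauchy(y, mu, s, lower.tail = FALSE, log.p = TRUE),
               dcauchy(y, mu, s, log = TRUE)))
  }
  r <- y / beta
  grid <- exp(seq(log(max(min(r) * 0.3, 1e-6)), log(max(r) * 6),
                  length.out = 4000))
  lstep <- log(grid[2] / grid[1])
  starts <- c(grid[which.max(vapply(grid, ll, numeric(1)))], r)
  half_gap <- function(s0) {
    others <- abs(log(s0) - log(setdiff(r, s0)))
    max(min(c(0.2, others[others > 0] / 2)), max(lstep, 1e-3))
  }
  cand <- unlist(lapply(starts, function(s0) {
    g <- half_gap(s0)
    opt <- optimize(function(lx) -ll(exp(lx)), log(s0) + c(-g, g),
                    tol = 1e-12)
    exp(opt$minimum)
  }))
  cand <- c(cand, starts)
  cand[which.max(vapply(cand, ll, numeric(1)))]
}

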