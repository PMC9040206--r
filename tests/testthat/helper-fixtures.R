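# shared fixtures built in code

us_rates <- function() {
  load_rates(system.file("extdata", "us_white_rates.csv", package = "riskstrat"))
}

sg_rates <- function() {
  load_rates(system.file("extdata", "sg_synthetic_rates.csv", package = "riskstrat"))
}

bundled_weights <- function() {
  load_weights(system.file("extdata", "prs313_synthetic.tsv", package = "riskstrat"))
}

# constant-rate table spanning [lo, hi) in 5-year steps
const_rates <- function(h, m, lo = 30, hi = 80) {
  lows <- seq(lo, hi - 5, by = 5)
  rates_table(lows, lows + 5, rep(h, length(lows)), rep(m, length(lows)))
}

# independent fine-grid calibration oracle: standard-normal z on a dense
# grid, h0 = lambda / E_surv[exp(beta z)], survivors depleted per interval
grid_calibration_oracle <- function(rates, beta, n_grid = 1e5) {
  z <- seq(-10, 10, length.out = n_grid)
  w <- stats::dnorm(z); w <- w / sum(w)
  rr <- exp(beta * z)
  h0 <- numeric(nrow(rates))
  for (k in seq_len(nrow(rates))) {
    dt <- rates$age_high[k] - rates$age_low[k]
    h0[k] <- rates$incidence[k] / sum(w * rr)
    w <- w * exp(-dt * h0[k] * rr)
    w <- w / sum(w)
  }
  h0
}

# independent fine-step Euler oracle for the competing-hazards 5-year risk
euler_risk_oracle <- function(rates, age, r, window = 5, dt = 1e-4) {
  t <- seq(age, age + window - dt, by = dt)
  idx <- findInterval(t, rates$age_low)
  h <- r * rates$incidence[idx]
  m <- rates$mortality[idx]
  surv <- cumprod(1 - (h + m) * dt)
  surv <- c(1, surv[-length(surv)])
  sum(surv * h * dt)
}

# brute-force signed-rank p-value by enumerating all 2^n sign patterns
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}
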