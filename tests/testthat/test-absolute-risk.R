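test_that("rates tables validate structure and round-trip through CSV", {
  expect_error(rates_table(c(30, 40), c(35, 45), c(1e-4, 2e-4), c(1e-4, 1e-4)),
               "gap or overlap")
  expect_error(rates_table(30, 35, -1e-4, 1e-4), "non-negative")
  rt <- sg_rates()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rates(rt, tmp)
  rt2 <- load_rates(tmp)
  expect_equal(rt2, rt, ignore_attr = FALSE)
  # a gap in the file is caught at load time
  raw <- read.csv(tmp)
  raw <- raw[-3, ]
  write.csv(raw, tmp, row.names = FALSE)
  expect_error(load_rates(tmp), "gap")
})

test_that("zero PRS effect leaves the population incidence untouched", {
  rt <- sg_rates()
  ch <- calibrate_baseline_hazard(rt, beta = 0)
  expect_equal(ch$h0, rt$incidence, tolerance = 1e-12)
})

test_that("first-interval baseline hazard matches the lognormal-mean identity", {
  rt <- rates_table(c(50, 55), c(55, 60), c(0.002, 0.003), c(1e-4, 2e-4))
  ch <- calibrate_baseline_hazard(rt, beta = 0.6)
  # before depletion E[exp(0.6 Z)] = exp(0.18)
  expect_equal(ch$h0[1], 0.002 * exp(-0.18), tolerance = 1e-7)
  # and against an independent fine-grid oracle at every interval
  expect_equal(ch$h0, grid_calibration_oracle(rt, 0.6), tolerance = 1e-8)
})

test_that("survivor mean relative risk strictly decreases across intervals", {
  ch <- calibrate_baseline_hazard(const_rates(0.005, 0.001), beta = 0.8)
  expect_true(all(diff(ch$mean_rr) < 0))
})

test_that("calibration conserves population incidence for a range of beta", {
  rt <- sg_rates()
  for (beta in c(0, 0.3, 0.6, 1.0, 1.2)) {
    ch <- calibrate_baseline_hazard(rt, beta)
    # replay the survivor distribution and re-average the incidence
    gh <- pracma::gaussHermite(64)
    z <- sqrt(2) * gh$x; w <- gh$w / sqrt(pi)
    rr <- exp(beta * z)
    for (k in seq_len(nrow(rt))) {
      recon <- ch$h0[k] * sum(w * rr)
      expect_lt(abs(recon - rt$incidence[k]) / rt$incidence[k], 1e-6)
      w <- w * exp(-(rt$age_high[k] - rt$age_low[k]) * ch$h0[k] * rr)
      w <- w / sum(w)
    }
  }
})

test_that("quadrature calibration agrees with the dense-grid oracle", {
  rt <- sg_rates()
  for (beta in c(0.3, 1.0)) {
    ch <- calibrate_baseline_hazard(rt, beta, quadrature_size = 64)
    oracle <- grid_calibration_oracle(rt, beta)
    expect_lt(max(abs(ch$h0 - oracle) / oracle), 1e-8)
  }
})

test_that("five-year risk matches the constant-hazard closed form", {
  rt <- rates_table(50, 55, 0.002, 0.01)
  r <- five_year_absolute_risk(1, 50, rt$incidence, rt)
  expect_equal(r, 0.002 / 0.012 * (1 - exp(-5 * 0.012)), tolerance = 1e-10)
  # no competing mortality: exponential survival limit
  rt0 <- rates_table(50, 55, 0.002, 0)
  expect_equal(five_year_absolute_risk(1, 50, rt0$incidence, rt0),
               1 - exp(-5 * 0.002), tolerance = 1e-10)
  # no hazard at all
  rtz <- rates_table(50, 55, 0, 0.01)
  expect_equal(five_year_absolute_risk(1, 50, rtz$incidence, rtz), 0)
})

test_that("piecewise projection agrees with a fine-step Euler oracle", {
  set.seed(61)
  rt <- sg_rates()
  for (i in 1:12) {
    h <- runif(1, 1e-4, 0.01); m <- runif(1, 1e-4, 0.02)
    r <- runif(1, 0.2, 3); age <- runif(1, 30, 74.9)
    crt <- const_rates(h, m)
    expect_equal(five_year_absolute_risk(r, age, crt$incidence, crt),
                 euler_risk_oracle(crt, age, r), tolerance = 2e-6)
  }
  # off-boundary age on a non-constant table splits the window correctly
  expect_equal(five_year_absolute_risk(1.4, 47.3, rt$incidence, rt),
               euler_risk_oracle(rt, 47.3, 1.4), tolerance = 2e-6)
})

test_that("risk is monotone in relative risk, incidence and mortality", {
  rt <- sg_rates()
  rr <- seq(0.2, 5, length.out = 30)
  risks <- five_year_absolute_risk(rr, 50, rt$incidence, rt)
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks >= 0 & risks <= 1))
  hi_inc <- rates_table(rt$age_low, rt$age_high, rt$incidence * 2, rt$mortality)
  expect_true(five_year_absolute_risk(1, 50, hi_inc$incidence, hi_inc) >
              five_year_absolute_risk(1, 50, rt$incidence, rt))
  hi_mort <- rates_table(rt$age_low, rt$age_high, rt$incidence, rt$mortality * 5)
  expect_true(five_year_absolute_risk(1, 50, hi_mort$incidence, hi_mort) <
              five_year_absolute_risk(1, 50, rt$incidence, rt))
  expect_error(five_year_absolute_risk(1, 78, rt$incidence, rt), "not covered")
})

test_that("averaging PRS risks over a normal population recovers the population risk", {
  rt <- sg_rates()
  beta <- 0.6
  ch <- calibrate_baseline_hazard(rt, beta)
  set.seed(5)
  z <- rnorm(2e4)
  mean_risk <- mean(prs_absolute_risk(z, 30, ch))
  pop_risk <- five_year_absolute_risk(1, 30, rt$incidence, rt)
  # Monte-Carlo agreement at the youngest age, where no depletion has occurred
  expect_lt(abs(mean_risk - pop_risk) / pop_risk, 0.03)
})

test_that("Gail relative risk reproduces hand-evaluated linear predictors", {
  p <- load_gail_params()
  # all-reference profile: RR exactly 1 in both age segments
  expect_identical(gail_relative_risk("ge14", "lt20", "no", 0, 45, p), 1)
  expect_identical(gail_relative_risk("ge14", "lt20", "no", 0, 60, p), 1)
  # unknowns map to the reference category
  expect_identical(gail_relative_risk("unknown", "unknown", "unknown", 0, 45, p), 1)
  # one relative, all else reference, age 45
  expect_equal(gail_relative_risk("ge14", "lt20", "no", 1, 45, p),
               exp(p$coef_relatives + p$coef_firstbirth_relatives * 0))
  # full profile by hand: menarche <12 (2), first birth >=30 (3), biopsy yes,
  # one relative, age 55
  lp <- 2 * p$coef_menarche + 3 * p$coef_first_birth + p$coef_biopsy +
    p$coef_relatives + p$coef_biopsy_age50 + 3 * p$coef_firstbirth_relatives
  expect_equal(gail_relative_risk("lt12", "ge30", "yes", 1, 55, p), exp(lp))
  # nulliparous codes like the 25-30 category
  expect_equal(gail_relative_risk("ge14", "nulliparous", "no", 0, 45, p),
               gail_relative_risk("ge14", "25to30", "no", 0, 45, p))
  # monotone in a non-negative coefficient
  expect_gte(gail_relative_risk("12to13", "lt20", "no", 0, 45, p),
             gail_relative_risk("ge14", "lt20", "no", 0, 45, p))
  expect_error(gail_relative_risk("ge14", "lt20", "no", 0, 18, p), "domain")
  expect_error(gail_relative_risk("early", "lt20", "no", 0, 45, p),
               "unknown menarche")
})

test_that("Gail absolute risk reduces to population risk when AR = 0", {
  rt <- sg_rates()
  r0 <- gail_absolute_risk("ge14", "lt20", "no", 0, 40, rt, gail_params_null())
  expect_equal(r0, five_year_absolute_risk(1, 40, rt$incidence, rt),
               tolerance = 1e-12)
  # constant-hazard synthetic rates match the closed form
  crt <- const_rates(0.002, 0.01)
  expect_equal(gail_absolute_risk("ge14", "lt20", "no", 0, 55, crt,
                                  gail_params_null()),
               0.002 / 0.012 * (1 - exp(-5 * 0.012)), tolerance = 1e-10)
})

test_that("the average 50-year-old's risk under US white rates is about 1.3%", {
  us <- us_rates()
  r <- threshold_reference_risk(us, age = 50)
  expect_equal(100 * r, 1.3, tolerance = 0.0115)  # within 0.15 percentage points
  expect_equal(gail_absolute_risk("ge14", "lt20", "no", 0, 50, us,
                                  gail_params_null()), r)
})

test_that("a window crossing age 50 switches the AR segment mid-window", {
  us <- us_rates()
  p <- load_gail_params()
  # hand-computed two-segment projection for an all-reference 47-year-old
  sub_h <- c(us$incidence[6] * (1 - p$ar_lt50),   # [47, 50)
             us$incidence[7] * (1 - p$ar_ge50))   # [50, 52)
  sub_m <- c(us$mortality[6], us$mortality[7])
  len <- c(3, 2)
  surv <- 1; manual <- 0
  for (k in 1:2) {
    tot <- sub_h[k] + sub_m[k]
    manual <- manual + surv * sub_h[k] / tot * (1 - exp(-tot * len[k]))
    surv <- surv * exp(-tot * len[k])
  }
  expect_equal(gail_absolute_risk("ge14", "lt20", "no", 0, 47, us, p), manual,
               tolerance = 1e-12)
})
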