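fld500 <- field_context("11.7T", 125.7)
fld800 <- field_context("18.8T", 201.2)
sch <- default_schedule()

test_that("exchange is invisible when dw = 0 or p_B = 0 (exactly flat)", {
  for (par in list(exchange_params(1640, 0.042, 0, c("18.8T" = 15)),
                   exchange_params(1640, 0, 1.0, c("18.8T" = 15)),
                   exchange_params(200, 0, 2.0, c("18.8T" = 7.5)))) {
    expect_identical(bm_r2eff(par, fld800, sch),
                     rep(par$r20_by_field[["18.8T"]], length(sch$nu_cpmg)))
    expect_identical(carver_richards_r2eff(par, fld800, sch),
                     rep(par$r20_by_field[["18.8T"]], length(sch$nu_cpmg)))
  }
})

test_that("numerical propagation matches the independent matrix-exponential oracle", {
  ## frozen regression fixture: main-cluster parameters, 18.8 T, nu = 200
  par <- exchange_params(1640, 0.042, 1.0, c("18.8T" = 15))
  expect_equal(bm_r2eff(par, fld800, sch, nu = 200), 31.4874884957,
               tolerance = 1e-9)
  ## spot checks across regimes
  cases <- expand.grid(k_ex = c(150, 420, 1640, 6000),
                       p_B = c(0.01, 0.146, 0.3),
                       dw = c(0.4, 1.8), nu = c(100, 850, 3000, 6000))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    par <- exchange_params(cs$k_ex, cs$p_B, cs$dw, c("18.8T" = 15))
    expect_equal(bm_r2eff(par, fld800, sch, nu = cs$nu),
                 bm_r2eff_oracle(cs$k_ex, cs$p_B, dw_rad_s(cs$dw, fld800),
                                 15, sch$t_relax, cs$nu),
                 tolerance = 1e-8)
  }
})

test_that("exact closed form tracks propagation; classic form degrades where expected", {
  par <- exchange_params(1600, 0.15, 2.0, c("18.8T" = 15))
  nu <- c(200, 400, 1000, 3000)
  bm <- bm_r2eff(par, fld800, sch, nu)
  expect_equal(carver_richards_r2eff(par, fld800, sch, nu), bm,
               tolerance = 1e-6)
  ## the classic expression neglects the minor-mode amplitude: visibly off
  ## for slow-intermediate exchange with large p_B * dw
  classic <- carver_richards_r2eff(par, fld800, sch, nu, exact = FALSE)
  expect_gt(max(abs(classic - bm)), 0.5)
  ## ... but fine in fast exchange
  par_fast <- exchange_params(8000, 0.05, 0.3, c("18.8T" = 15))
  expect_equal(carver_richards_r2eff(par_fast, fld800, sch, nu,
                                     exact = FALSE),
               bm_r2eff(par_fast, fld800, sch, nu), tolerance = 0.05)
})

test_that("fast-exchange limit has the closed form p_A p_B dw^2 / k_ex", {
  par <- exchange_params(1640, 0.042, 1.0, c("18.8T" = 15))
  expect_equal(rex_fast_limit(par, fld800),
               (1 - 0.042) * 0.042 * (2 * pi * 201.2)^2 / 1640,
               tolerance = 1e-12)
  expect_equal(rex_fast_limit(par, fld800), 39.21, tolerance = 1e-3)
  ## no excited state, no exchange contribution
  par0 <- exchange_params(1640, 0, 1.0, c("18.8T" = 15))
  expect_identical(rex_fast_limit(par0, fld800), 0)
  ## doubling the field doubles dw (rad/s) and quadruples Rex
  fld_x2 <- field_context("x2", 2 * 201.2)
  expect_equal(rex_fast_limit(par, fld_x2), 4 * rex_fast_limit(par, fld800))
})

test_that("low-frequency dispersion approaches the fast-exchange limit when k_ex >> dw", {
  slow_sch <- cpmg_schedule(c(10, 5000), t_relax = 0.1)
  for (k_ex in c(5000, 10000)) for (dw in c(0.2, 0.3))
    for (p_B in c(0.01, 0.05, 0.15)) for (fld in list(fld500, fld800)) {
      if (k_ex / dw_rad_s(dw, fld) <= 10) next
      par <- exchange_params(k_ex, p_B, dw,
                             setNames(15, fld$label))
      rex <- bm_r2eff(par, fld, slow_sch, nu = 10) - 15
      expect_equal(rex, rex_fast_limit(par, fld), tolerance = 0.05)
    }
})

test_that("R2,eff is non-increasing in refocusing frequency in the study regimes", {
  ## monotone quenching holds for intermediate-to-fast exchange; deep slow
  ## exchange (k_ex << dw) shows genuine oscillatory dips and is excluded
  nu <- seq(50, 6000, by = 50)
  for (par in list(exchange_params(1640, 0.042, 1.0, c("18.8T" = 15)),
                   exchange_params(420, 0.146, 0.6, c("18.8T" = 12)),
                   exchange_params(480, 0.029, 1.4, c("18.8T" = 18)),
                   exchange_params(8000, 0.05, 0.5, c("18.8T" = 10)))) {
    r2 <- bm_r2eff(par, fld800, sch, nu)
    expect_true(all(diff(r2) <= 1e-6))
  }
})

test_that("dispersion curves show the study's qualitative features", {
  par <- exchange_params(1640, 0.042, 1.0,
                         c("11.7T" = 12, "18.8T" = 15))
  c500 <- dispersion_curve(par, fld500, sch)
  c800 <- dispersion_curve(par, fld800, sch)
  rex_of <- function(cv) rex_observed(data.frame(nu_cpmg_hz = cv$nu_cpmg,
                                                 r2eff_s = cv$r2eff))
  ## exchange contribution grows with field (dw in rad/s scales with B0)
  expect_gt(rex_of(c800), rex_of(c500))
  ## profiles are flat between 3000 and 6000 s^-1 at k_ex ~ 1640 s^-1
  r3000 <- bm_r2eff(par, fld800, sch, 3000)
  r6000 <- bm_r2eff(par, fld800, sch, 6000)
  expect_lt(abs(r3000 - r6000), 0.2)
  expect_gt(rex_of(c800), 5)
  ## flat parameters give a constant vector
  flat <- dispersion_curve(exchange_params(1640, 0, 0, c("18.8T" = 15)),
                           fld800, sch)
  expect_true(all(flat$r2eff == 15))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(exchange_params(-5, 0.04, 1, c("18.8T" = 15)), "k_ex")
  expect_error(exchange_params(1640, 0.6, 1, c("18.8T" = 15)), "p_B")
  expect_error(exchange_params(1640, 0.04, -1, c("18.8T" = 15)), "dw_ppm")
  expect_error(exchange_params(1640, 0.04, 1, c(15)), "named")
  expect_error(cpmg_schedule(c(100, -5)), "nu_cpmg")
  expect_error(cpmg_schedule(25, t_relax = 0.02), "refocusing")
  par <- exchange_params(1640, 0.042, 1.0, c("18.8T" = 15))
  expect_error(bm_r2eff(par, fld800, sch, nu = -100), "nu")
  expect_error(bm_r2eff(par, fld500, sch), "R2,0")
})
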