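test_that("linear simulator matches independent closed-form superposition", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    p <- random_linear_params()
    n_dose <- sample(1:5, 1)
    sch <- dose_schedule(sort(runif(n_dose, 0, 96)), runif(n_dose, 5, 100))
    prof <- simulate_profile(p, sch, horizon = 120, resolution = 0.5)
    ref <- oracle_linear_conc(p$volume, p$absorption_rate,
                              p$elimination_rate, sch$time, sch$amount,
                              prof$time)
    worst <- max(worst, max(abs(prof$conc - ref)) / max(ref))
  }
  expect_lt(worst, 1e-6)
})

test_that("empty schedules give identically zero profiles in both models", {
  empty <- dose_schedule(numeric(0), numeric(0))
  lin <- simulate_profile(linear_pk(500, 0.8, 0.03), empty, horizon = 48)
  mm <- simulate_profile(mm_pk(500, 0.8, 5, 300), empty, horizon = 48)
  expect_true(all(lin$conc == 0))
  expect_true(all(mm$conc == 0))
  expect_equal(lin$conc[lin$time == 0], 0)
})

test_that("Michaelis-Menten simulator converges to the linear one as km grows", {
  set.seed(7)
  for (i in 1:3) {
    p <- random_linear_params()
    sch <- regimen(runif(1, 10, 60), 24, 10)
    lin <- simulate_profile(p, sch, horizon = 240)
    km <- 1e6 * max(lin$conc)
    mm <- simulate_profile(
      mm_pk(p$volume, p$absorption_rate, vmax = p$elimination_rate * km,
            km = km),
      sch, horizon = 240)
    expect_lt(max(abs(mm$conc - lin$conc)) / max(lin$conc), 1e-3)
  }
})

test_that("concentrations are non-negative and daily means accumulate", {
  fl <- mm_pk(1033, 0.53, 6.5, 448)
  prof <- simulate_profile(fl, regimen(40, 24, 10), horizon = 240)
  expect_true(all(prof$conc >= 0))
  dm <- daily_mean(prof, 1:10)
  expect_true(all(diff(dm) > 0))
  p <- linear_pk(840, 1.0, log(2) / 35)
  dml <- daily_mean(simulate_profile(p, regimen(20, 24, 10), 240), 1:10)
  expect_true(all(diff(dml) > 0))
})

test_that("dose-doubling is homogeneous for linear kinetics but superlinear for saturable", {
  p <- linear_pk(700, 0.6, 0.04)
  s1 <- regimen(20, 24, 8)
  s2 <- regimen(40, 24, 8)
  a <- simulate_profile(p, s1, horizon = 192)
  b <- simulate_profile(p, s2, horizon = 192)
  expect_equal(b$conc, 2 * a$conc, tolerance = 1e-10)
  mm <- mm_pk(1033, 0.53, 6.5, 448)
  ma <- daily_mean(simulate_profile(mm, s1, 192), 8)
  mb <- daily_mean(simulate_profile(mm, s2, 192), 8)
  expect_gt(mb / ma, 2)
})

test_that("daily_mean is a trapezoidal window mean with range checking", {
  tt <- seq(0, 48, by = 0.5)
  const <- structure(data.frame(time = tt, conc = rep(7.5, length(tt))),
                     class = c("conc_profile", "data.frame"))
  expect_equal(daily_mean(const, 1:2), c(7.5, 7.5))
  tri <- structure(data.frame(time = c(0, 6, 12, 18, 24),
                              conc = c(0, 10, 20, 10, 0)),
                   class = c("conc_profile", "data.frame"))
  expect_equal(daily_mean(tri, 1), 10)  # hand-computed trapezoid
  expect_error(daily_mean(tri, 2), "cover")
})

test_that("single-dose metrics recover analytic values for linear kinetics", {
  ke <- log(2) / 30
  p <- linear_pk(800, 1.5, ke)   # ka >> ke
  prof <- simulate_profile(p, dose_schedule(0, 50), horizon = 500,
                           resolution = 0.05)
  m_term <- single_dose_metrics(prof, half_life = "terminal")
  m_peak <- single_dose_metrics(prof, half_life = "peak")
  expect_equal(unname(m_term["t_half"]), 30, tolerance = 1e-4)
  # the peak-anchored estimate carries a small absorption residue upward
  expect_equal(unname(m_peak["t_half"]), 30, tolerance = 0.05)
  expect_gt(unname(m_peak["t_half"]), unname(m_term["t_half"]))
  tmax_true <- log(1.5 / ke) / (1.5 - ke)
  expect_equal(unname(m_term["tmax"]), tmax_true, tolerance = 1e-3)
  cmax_true <- 50 * 1000 / 800 * 1.5 / (1.5 - ke) *
    (exp(-ke * tmax_true) - exp(-1.5 * tmax_true))
  expect_equal(unname(m_term["cmax"]), cmax_true, tolerance = 1e-5)
})

test_that("single-dose metrics handle degenerate profiles", {
  tt <- seq(0, 100, by = 0.5)
  bolus <- structure(data.frame(time = tt, conc = 40 * exp(-0.05 * tt)),
                     class = c("conc_profile", "data.frame"))
  m <- single_dose_metrics(bolus, half_life = "peak")
  expect_equal(unname(m["tmax"]), 0)
  expect_equal(unname(m["t_half"]), log(2) / 0.05, tolerance = 1e-3)
  short <- structure(data.frame(time = tt[tt <= 5],
                                conc = 40 * exp(-0.05 * tt[tt <= 5])),
                     class = c("conc_profile", "data.frame"))
  expect_error(single_dose_metrics(short, half_life = "peak"), "horizon")
})

test_that("steady-state daily mean matches the analytic AUC/interval for linear drugs", {
  p <- linear_pk(900, 0.9, log(2) / 20)
  ss <- steady_state_cave(p, 30, 24)
  css_analytic <- 30 * 1000 / 900 / (log(2) / 20) / 24  # AUC_inf / tau
  expect_equal(ss$css, css_analytic, tolerance = 2e-3)
  expect_true(ss$day_reached < 60)
  expect_true(all(diff(ss$daily_means[1:ss$day_reached]) > 0))
})

test_that("steady-state handles zero dose and reports non-convergence", {
  p <- linear_pk(900, 0.9, log(2) / 20)
  z <- steady_state_cave(p, 0, 24)
  expect_equal(z$css, 0)
  slow <- linear_pk(900, 0.9, log(2) / 60)
  expect_error(steady_state_cave(slow, 30, 24, max_days = 5),
               class = "ssriload_no_convergence")
  expect_error(steady_state_cave(p, 30, 24, tolerance = 0.2), "tolerance")
})
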