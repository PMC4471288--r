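test_that("absorption-rate solve satisfies the peak-time equation and matches bisection", {
  cases <- expand.grid(t_half = c(10, 26, 35, 48), tmax = c(2, 4, 6.5, 9))
  for (i in seq_len(nrow(cases))) {
    ke <- log(2) / cases$t_half[i]
    tmax <- cases$tmax[i]
    ka <- solve_absorption_rate(ke, tmax)
    expect_lt(abs(log(ka / ke) / (ka - ke) - tmax), 1e-8)
    ka_oracle <- bisect(function(k) log(k / ke) / (k - ke) - tmax,
                        ke * (1 + 1e-12), 1000)
    expect_equal(ka, ka_oracle, tolerance = 1e-6)
  }
})

test_that("absorption rate decreases with tmax and fails past the 1/ke limit", {
  ke <- log(2) / 26
  expect_gt(solve_absorption_rate(ke, 1), solve_absorption_rate(ke, 5))
  expect_error(solve_absorption_rate(ke, 1 / ke + 1),
               class = "ssriload_calibration_failure")
})

test_that("linear calibration reproduces the published peak times on forward simulation", {
  for (cfg in list(list(v = 840, th = 35, tm = 4),
                   list(v = 1400, th = 26, tm = 6.5),
                   list(v = 426, th = 16.9, tm = 8))) {
    p <- calibrate_linear(cfg$v, cfg$th, cfg$tm)
    expect_gt(p$absorption_rate, p$elimination_rate)
    chk <- forward_check(p, 50, tmax = cfg$tm, t_half = cfg$th)
    expect_lt(max(abs(chk$rel_residual)), 0.01)
  }
})

test_that("linear calibration round-trips synthetic drugs to 1e-4 on both rates", {
  worst <- 0
  for (seed in 1:50) {
    d <- gen_pk_drug(seed, "linear")
    cal <- calibrate_linear(d$observables$volume, d$observables$t_half,
                            d$observables$tmax)
    worst <- max(worst,
                 abs(cal$absorption_rate - d$params$absorption_rate) /
                   d$params$absorption_rate,
                 abs(cal$elimination_rate - d$params$elimination_rate) /
                   d$params$elimination_rate)
  }
  expect_lt(worst, 1e-4)
})

test_that("Michaelis-Menten calibration with a known km recovers the generating set", {
  worst <- 0
  for (seed in 1:5) {
    d <- gen_pk_drug(seed, "mm")
    cal <- calibrate_mm(d$observables$cmax, d$observables$tmax,
                        d$observables$t_half, d$observables$ref_dose,
                        km = d$params$km, resolution = 0.25)
    err <- abs(unlist(cal)[1:3] - unlist(d$params)[1:3]) /
      unlist(d$params)[1:3]
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.02)
})

test_that("the published fluoxetine constants pass their forward check", {
  printed <- mm_pk(1033, 0.53, 6.5, 448)
  chk <- forward_check(printed, 40, cmax = 35, tmax = 7, t_half = 48)
  expect_lt(max(abs(chk$rel_residual)), 0.05)
  # and calibration seeded only by the observables lands on a valid set
  fit <- calibrate_mm(35, 7, 48, 40, km = 448)
  expect_lt(max(abs(attr(fit, "fit")$rel_residual)), 0.01)
  expect_equal(fit$volume, 1033, tolerance = 0.05)
  expect_equal(fit$absorption_rate, 0.53, tolerance = 0.05)
  expect_equal(fit$vmax, 6.5, tolerance = 0.05)
})

test_that("km is flagged as unidentifiable when no prior is supplied", {
  expect_warning(
    fit <- calibrate_mm(17.6, 6.3, 16, 30),
    "identify km")
  expect_lt(max(abs(attr(fit, "fit")$rel_residual)), 0.01)
})

test_that("forward check exposes a perturbed elimination capacity", {
  d <- gen_pk_drug(12, "mm")
  p <- d$params
  bad <- mm_pk(p$volume, p$absorption_rate, p$vmax * 1.5, p$km)
  chk <- forward_check(bad, d$observables$ref_dose,
                       t_half = d$observables$t_half)
  expect_gt(abs(chk$rel_residual[chk$observable == "t_half"]), 0.2)
  good <- forward_check(p, d$observables$ref_dose,
                        cmax = d$observables$cmax,
                        tmax = d$observables$tmax,
                        t_half = d$observables$t_half,
                        resolution = 0.02)
  expect_lt(max(abs(good$rel_residual)), 1e-3)
})

test_that("pk_model objects expose the standard modelling methods", {
  sert <- pk_model("sertraline", "linear", volume = 1400, t_half = 26,
                   tmax = 6.5, standard_dose = 51)
  expect_named(coef(sert),
               c("volume", "absorption_rate", "elimination_rate"))
  expect_output(print(sert), "sertraline")
  expect_output(print(summary(sert)), "Forward check")
  expect_lt(max(abs(residuals(sert))), 0.01)
  prof <- simulate(sert, schedule = regimen(51, 24, 3), horizon = 72)
  expect_s3_class(prof, "conc_profile")
  at <- predict(sert, times = c(12, 24, 36), schedule = regimen(51, 24, 3))
  expect_equal(at,
               stats::approx(prof$time, prof$conc, c(12, 24, 36))$y,
               tolerance = 1e-8)
})
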