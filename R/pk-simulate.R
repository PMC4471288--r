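#' Simulate a plasma concentration time course
#'
#' `simulate_profile()` integrates the one-compartment model under a
#' multi-dose schedule and returns the concentration on a regular time
#' grid. Linear (first-order elimination) parameters are handled by exact
#' analytic superposition of single-dose terms; Michaelis-Menten
#' parameters by adaptive ODE integration of
#' \deqn{dC/dt = ka \cdot A(t) - V_m C / (K_m + C)}
#' where the absorbable amount \eqn{A(t) = \sum_i (D_i \cdot 10^3 / V)
#' e^{-ka (t - t_i)}} sums the first-order absorption input over all past
#' doses (implemented as a gut compartment with bolus dose events, which is
#' identically that sum). Doses in mg convert to concentration scale as
#' `D * 1000 / V` ng/ml.
#'
#' @param params A [linear_pk()] or [mm_pk()] parameter set.
#' @param schedule A [dose_schedule()]. An empty schedule yields an
#'   identically zero profile.
#' @param horizon Simulation end time, h; must cover all dose events.
#' @param resolution Output grid spacing, h (default 0.1, must be <= 0.5).
#'
#' @return A `conc_profile`: data frame with columns `time` (h) and
#'   `conc` (ng/ml) on a strictly increasing grid starting at 0.
#'
#' @examples
#' fluox <- mm_pk(1033, 0.53, 6.5, 448)
#' prof <- simulate_profile(fluox, regimen(40, 24, 30), horizon = 720)
#' daily_mean(prof, 1)   # ~30.8 ng/ml
#' @export
simulate_profile <- function(params, schedule, horizon,
                             resolution = 0.1) {
  UseMethod("simulate_profile")
}

sim_grid <- function(schedule, horizon, resolution) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (resolution > 0.5 || resolution <= 0) {
    stop("resolution must be in (0, 0.5] h", call. = FALSE)
  }
  if (nrow(schedule) > 0 && max(schedule$time) > horizon) {
    stop("horizon must cover all dose events", call. = FALSE)
  }
  tt <- seq(0, horizon, by = resolution)
  tt <- sort(unique(round(c(tt, schedule$time, horizon), 9)))
  tt
}

new_conc_profile <- function(time, conc) {
  structure(data.frame(time = time, conc = conc),
            class = c("conc_profile", "data.frame"))
}

#' @rdname simulate_profile
#' @export
simulate_profile.linear_pk <- function(params, schedule, horizon,
                                       resolution = 0.1) {
  tt <- sim_grid(schedule, horizon, resolution)
  conc <- numeric(length(tt))
  ka <- params$absorption_rate
  ke <- params$elimination_rate
  scale <- 1000 / params$volume * ka / (ka - ke)
  keep <- schedule$amount > 0
  for (i in which(keep)) {
    tau <- tt - schedule$time[i]
    m <- tau >= 0
    conc[m] <- conc[m] + schedule$amount[i] * scale *
      (exp(-ke * tau[m]) - exp(-ka * tau[m]))
  }
  new_conc_profile(tt, pmax(conc, 0))
}

#' @rdname simulate_profile
#' @export
simulate_profile.mm_pk <- function(params, schedule, horizon,
                                   resolution = 0.1) {
  tt <- sim_grid(schedule, horizon, resolution)
  out <- mm_integrate(params, y0 = c(A = 0, C = 0), times = tt,
                      dose_times = schedule$time[schedule$amount > 0],
                      dose_amounts = schedule$amount[schedule$amount > 0])
  new_conc_profile(tt, pmax(out$conc, 0))
}

# Integrate the (gut, plasma) system over `times`, applying bolus additions
# to the gut compartment at dose_times. Returns conc on the grid and the
# final state, so callers can continue integration incrementally.
mm_integrate <- function(params, y0, times, dose_times, dose_amounts,
                         rtol = 1e-8, atol = 1e-10) {
  ka <- params$absorption_rate
  vm <- params$vmax
  km <- params$km
  rhs <- function(t, y, p) {
    list(c(-ka * y[1], ka * y[1] - vm * y[2] / (km + y[2])))
  }
  if (length(dose_times)) {
    dconc <- tapply(dose_amounts * 1000 / params$volume, dose_times, sum)
    ev <- data.frame(var = "A",
                     time = as.numeric(names(dconc)),
                     value = as.numeric(dconc),
                     method = "add")
    ev <- ev[order(ev$time), ]
    events <- list(data = ev)
  } else {
    events <- NULL
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events)
  list(conc = as.numeric(sol[, "C"]),
       state = c(A = unname(sol[nrow(sol), "A"]),
                 C = unname(sol[nrow(sol), "C"])))
}

#' @rdname simulate_profile
#' @export
simulate_linear <- function(params, schedule, horizon, resolution = 0.1) {
  if (!inherits(params, "linear_pk")) {
    stop("simulate_linear() requires linear_pk parameters", call. = FALSE)
  }
  simulate_profile(params, schedule, horizon, resolution)
}

#' @rdname simulate_profile
#' @export
simulate_mm <- function(params, schedule, horizon, resolution = 0.1) {
  if (!inherits(params, "mm_pk")) {
    stop("simulate_mm() requires mm_pk parameters", call. = FALSE)
  }
  simulate_profile(params, schedule, horizon, resolution)
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf(
    "Concentration profile: %d points, 0-%g h, Cmax %.3g ng/ml\n",
    nrow(x), max(x$time), max(x$conc)))
  invisible(x)
}

#' @param x A `conc_profile`.
#' @param add Overlay on the current plot instead of starting a new one.
#' @param ... Further arguments to [graphics::lines()] / `plot()`.
#' @rdname simulate_profile
#' @export
plot.conc_profile <- function(x, add = FALSE, ...) {
  if (add) {
    graphics::lines(x$time, x$conc, ...)
  } else {
    plot(x$time, x$conc, type = "l", xlab = "Time (h)",
         ylab = "Concentration (ng/ml)", ...)
  }
  invisible(x)
}

trapezoid_mean <- function(time, conc) {
  sum(diff(time) * (conc[-length(conc)] + conc[-1]) / 2) /
    (time[length(time)] - time[1])
}

#' Daily mean concentration
#'
#' Trapezoidal mean of the concentration over the 24-h window of one
#' treatment day. Day `i` is hours `[24*(i-1), 24*i]`, with dose 1 given
#' at t = 0.
#'
#' @param profile A `conc_profile` whose grid covers the requested window.
#' @param day 1-based day index (vectorised).
#' @return Mean concentration(s), ng/ml.
#' @export
daily_mean <- function(profile, day) {
  vapply(day, function(d) {
    lo <- 24 * (d - 1)
    hi <- 24 * d
    i <- profile$time >= lo - 1e-9 & profile$time <= hi + 1e-9
    if (!any(i) || min(profile$time[i]) > lo + 1e-6 ||
        max(profile$time[i]) < hi - 1e-6) {
      stop(sprintf("profile grid does not cover day %d (hours %g-%g)",
                   d, lo, hi), call. = FALSE)
    }
    trapezoid_mean(profile$time[i], profile$conc[i])
  }, numeric(1))
}

#' Single-dose summary metrics
#'
#' Peak concentration (Cmax), its time (Tmax) and the half-life extracted
#' from a single-dose concentration profile. Cmax/Tmax refine the grid
#' maximum by a local parabolic fit. Two half-life definitions are
#' available: `"terminal"` (default) fits a log-linear regression to the
#' late elimination phase and reports `ln(2)/slope` -- the standard
#' terminal elimination half-life, which for saturable elimination
#' converges to `ln(2) * km / vmax`; `"peak"` reports the elapsed time from
#' Tmax until the concentration first falls to Cmax/2 (linear
#' interpolation between grid points). Under saturable kinetics the peak
#' definition exceeds the terminal one because elimination is slower than
#' first-order near the peak.
#'
#' @param profile A `conc_profile` from a single dose at t = 0 whose
#'   horizon reaches well into the elimination phase.
#' @param half_life `"terminal"` or `"peak"`.
#' @return Named numeric vector `c(cmax =, tmax =, t_half =)`.
#' @export
single_dose_metrics <- function(profile,
                                half_life = c("terminal", "peak")) {
  half_life <- match.arg(half_life)
  tt <- profile$time
  cc <- profile$conc
  if (all(cc <= 0)) stop("profile is identically zero", call. = FALSE)
  im <- which.max(cc)
  cmax <- cc[im]
  tmax <- tt[im]
  if (im > 1 && im < length(cc)) {
    # parabola through the three points around the grid maximum
    x <- tt[(im - 1):(im + 1)]
    y <- cc[(im - 1):(im + 1)]
    d21 <- (y[2] - y[1]) / (x[2] - x[1])
    d32 <- (y[3] - y[2]) / (x[3] - x[2])
    curv <- (d32 - d21) / (x[3] - x[1]) * 2
    if (curv < 0) {
      tv <- (x[1] + x[2]) / 2 - d21 / curv
      if (tv > x[1] && tv < x[3]) {
        tmax <- tv
        cmax <- y[2] - curv / 2 * ((x[2] - tv))^2
      }
    }
  }
  t_half <- if (half_life == "peak") {
    peak_half_time(tt, cc, cmax, tmax)
  } else {
    terminal_half_life(tt, cc, cmax, im)
  }
  c(cmax = cmax, tmax = tmax, t_half = t_half)
}

peak_half_time <- function(tt, cc, cmax, tmax) {
  after <- which(tt > tmax & cc <= cmax / 2)
  if (!length(after)) {
    stop("concentration never falls to Cmax/2 within the horizon; ",
         "extend the simulation", call. = FALSE)
  }
  j <- after[1]
  t_cross <- tt[j - 1] + (tt[j] - tt[j - 1]) *
    (cc[j - 1] - cmax / 2) / (cc[j - 1] - cc[j])
  t_cross - tmax
}

# Log-linear fit over the late elimination phase: points past the peak with
# concentration between cmax/8 and cmax * 1e-5, keeping the last half of
# that window so absorption (and, for saturable drugs, concentration-
# dependent clearance) has washed out.
terminal_half_life <- function(tt, cc, cmax, im) {
  cand <- which(seq_along(tt) > im & cc <= cmax / 8 & cc >= cmax * 1e-5)
  if (length(cand) < 10) {
    cand <- which(seq_along(tt) > im & cc <= cmax / 2 & cc > 0)
  }
  if (length(cand) < 4) {
    stop("too little elimination-phase data to estimate a terminal ",
         "half-life; extend the horizon", call. = FALSE)
  }
  cand <- cand[cand >= cand[ceiling(length(cand) / 2)]]
  slope <- stats::coef(stats::lm(log(cc[cand]) ~ tt[cand]))[[2]]
  if (slope >= 0) stop("terminal phase is not decaying", call. = FALSE)
  log(2) / -slope
}

#' Steady-state mean concentration under a fixed regimen
#'
#' Simulates a constant regimen until successive daily mean concentrations
#' change by less than `tolerance` (relative), up to `max_days`. Returns
#' the converged daily mean and the first day meeting the criterion.
#'
#' @param params A `pk_params` set.
#' @param dose Per-interval dose, mg.
#' @param interval Dosing interval, 12 or 24 h.
#' @param tolerance Relative change criterion, in (0, 0.05].
#' @param max_days Simulation cap, days.
#' @param resolution Grid spacing, h.
#' @return List with elements `css` (ng/ml), `day_reached`, and
#'   `daily_means` (the full per-day trajectory).
#' @examples
#' fluox <- mm_pk(1033, 0.53, 6.5, 448)
#' steady_state_cave(fluox, 40, 24)$css   # ~148-149 ng/ml
#' @export
steady_state_cave <- function(params, dose, interval = 24,
                              tolerance = 1e-3, max_days = 60,
                              resolution = 0.1) {
  if (tolerance <= 0 || tolerance > 0.05) {
    stop("tolerance must be in (0, 0.05]", call. = FALSE)
  }
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (dose == 0) {
    return(list(css = 0, day_reached = 1L,
                daily_means = rep(0, max_days)))
  }
  prof <- simulate_profile(params, regimen(dose, interval, max_days),
                           horizon = 24 * max_days,
                           resolution = resolution)
  dm <- daily_mean(prof, seq_len(max_days))
  for (d in 2:max_days) {
    if (abs(dm[d] - dm[d - 1]) < tolerance * dm[d]) {
      return(list(css = dm[d], day_reached = d, daily_means = dm))
    }
  }
  stop(errorCondition(
    sprintf("daily mean not converged within %d days (last value %.4g)",
            max_days, dm[max_days]),
    class = c("ssriload_no_convergence", "error"),
    last_value = dm[max_days]))
}
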