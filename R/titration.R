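#' Fluoxetine loading reference profile
#'
#' Simulates the reference drug's standard regimen (fluoxetine 40 mg once
#' daily by default) and expresses its daily mean concentrations as
#' fractions of the steady-state mean. These fractions are the day-by-day
#' loading targets the titration stage imposes on every other drug.
#'
#' The steady-state mean is taken as the daily mean at `ss_days` (well past
#' convergence; the relative day-to-day change there is ~1e-4), so the
#' fractions are guaranteed to lie in (0, 1] and the final fraction is
#' close to 1.
#'
#' @param model A [pk_model()] or `pk_params` for the reference drug.
#' @param dose Per-interval dose of the reference regimen, mg.
#' @param interval Dosing interval, h.
#' @param days Number of loading days the profile covers (>= 30 typical).
#' @param ss_days Horizon used for the steady-state plateau, days.
#' @param resolution Simulation grid, h.
#' @return A `reference_profile`: list with `daily_means` (ng/ml), `css`
#'   (ng/ml), `fractions`, and the generating configuration.
#' @examples
#' \donttest{
#' ref <- build_reference(ssri_models("fluoxetine")$fluoxetine)
#' ref$fractions[c(1, 30)]   # ~0.208, ~0.998
#' }
#' @export
build_reference <- function(model, dose = 40, interval = 24, days = 30,
                            ss_days = 60, resolution = 0.1) {
  stopifnot(days >= 1, ss_days >= days)
  params <- as_pk_params(model)
  prof <- simulate_profile(params, regimen(dose, interval, ss_days),
                           horizon = 24 * ss_days, resolution = resolution)
  dm <- daily_mean(prof, seq_len(ss_days))
  css <- dm[ss_days]
  structure(list(daily_means = dm[seq_len(days)], css = css,
                 fractions = dm[seq_len(days)] / css,
                 dose = dose, interval = interval, days = days,
                 ss_days = ss_days),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf(
    "Loading reference: %g mg every %g h, css %.1f ng/ml over %d days\n",
    x$dose, x$interval, x$css, x$days))
  cat(sprintf("Fractions of steady state: day 1 %.3f ... day %d %.3f\n",
              x$fractions[1], x$days, x$fractions[x$days]))
  invisible(x)
}

as_pk_params <- function(x) {
  if (inherits(x, "pk_model")) x$params
  else if (inherits(x, "pk_params")) x
  else stop("expected a pk_model or pk_params object", call. = FALSE)
}

#' Per-day concentration targets for a titrated drug
#'
#' Scales the reference loading fractions by the drug's own steady-state
#' mean: `target_i = fraction_i * drug_css`.
#'
#' @param reference A [build_reference()] profile.
#' @param drug_css The drug's steady-state mean concentration, ng/ml.
#' @return Numeric vector of daily mean targets, ng/ml.
#' @export
daily_targets <- function(reference, drug_css) {
  check_positive(drug_css = drug_css)
  reference$fractions * drug_css
}

# Daily mean of day `day` given fixed prior doses plus `dose` given on that
# day. Linear drugs: exact analytic integral of the superposed
# biexponential over the 24-h window. Saturable drugs: 24-h ODE
# integration from a supplied day-start state (or from t = 0 if none).
day_mean_given_dose <- function(params, history_times, history_amounts,
                                day, dose, interval, resolution = 0.1,
                                state = NULL) {
  a <- 24 * (day - 1)
  b <- 24 * day
  dose_times <- if (interval == 12) c(a, a + 12) else a
  if (inherits(params, "linear_pk")) {
    tt <- c(history_times, dose_times)
    aa <- c(history_amounts, rep(dose, length(dose_times)))
    ka <- params$absorption_rate
    ke <- params$elimination_rate
    s <- 1000 / params$volume * ka / (ka - ke)
    tot <- 0
    for (i in seq_along(tt)) {
      if (aa[i] <= 0 || tt[i] >= b) next
      t1 <- max(a, tt[i]) - tt[i]
      t2 <- b - tt[i]
      tot <- tot + aa[i] * s *
        ((exp(-ke * t1) - exp(-ke * t2)) / ke -
         (exp(-ka * t1) - exp(-ka * t2)) / ka)
    }
    list(mean = tot / 24, state = NULL)
  } else {
    if (is.null(state)) {
      state <- c(A = 0, C = 0)
      from <- 0
      ev_t <- c(history_times, dose_times)
      ev_a <- c(history_amounts, rep(dose, length(dose_times)))
    } else {
      from <- a
      ev_t <- dose_times
      ev_a <- rep(dose, length(dose_times))
    }
    tt <- sort(unique(round(c(seq(from, b, by = resolution), ev_t, b), 9)))
    out <- mm_integrate(params, state, tt, ev_t[ev_a > 0], ev_a[ev_a > 0])
    win <- tt >= a - 1e-9
    list(mean = trapezoid_mean(tt[win], out$conc[win]), state = out$state)
  }
}

#' Solve one day's dose to hit a daily mean target
#'
#' Finds the per-interval dose for day `day` such that, conditional on the
#' fixed dosing history of earlier days, the simulated daily mean
#' concentration over that day equals `target`. The daily mean is strictly
#' increasing in the dose, so a bracketed root search (Brent's method via
#' [stats::uniroot()]) converges to a unique solution. With a 12-h
#' interval both doses within the day are constrained equal.
#'
#' @param params A `pk_params` set (or [pk_model()]).
#' @param history A [dose_schedule()] covering days before `day`.
#' @param day 1-based day index to solve.
#' @param target Daily mean concentration target, ng/ml.
#' @param interval Dosing interval, 12 or 24 h.
#' @param bounds Dose search interval, mg. `NULL` auto-brackets by
#'   doubling.
#' @param resolution Simulation grid, h.
#' @return The per-interval dose, mg.
#' @examples
#' \donttest{
#' sert <- calibrate_linear(1400, 26, 6.5)
#' solve_daily_dose(sert, dose_schedule(numeric(0), numeric(0)),
#'                  day = 1, target = 11.6)   # ~23.6 mg
#' }
#' @export
solve_daily_dose <- function(params, history, day, target, interval = 24,
                             bounds = NULL, resolution = 0.1) {
  params <- as_pk_params(params)
  check_positive(target = target)
  if (nrow(history) && max(history$time) >= 24 * (day - 1)) {
    stop("history must only contain doses before the solved day",
         call. = FALSE)
  }
  f <- function(d) {
    day_mean_given_dose(params, history$time, history$amount, day, d,
                        interval, resolution)$mean - target
  }
  base <- f(0)
  if (base >= 0) {
    stop(errorCondition(
      sprintf("day %d: carry-over mean already exceeds the target (%.4g)",
              day, base + target),
      class = c("ssriload_titration_infeasible", "error"), day = day))
  }
  if (is.null(bounds)) {
    hi <- max(1, history$amount, na.rm = TRUE)
    while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
    bounds <- c(0, hi)
  }
  if (f(bounds[2]) < 0) {
    stop(errorCondition(
      sprintf("day %d: target %.4g ng/ml unreachable with dose <= %g mg",
              day, target, bounds[2]),
      class = c("ssriload_titration_infeasible", "error"), day = day))
  }
  stats::uniroot(f, bounds, tol = max(bounds[2] * 1e-9, 1e-10))$root
}

#' Generate a fluoxetine-matched escalating regimen
#'
#' Solves, day by day, the per-interval dose that makes the drug's daily
#' mean concentration track the reference loading fractions scaled to the
#' drug's own steady-state mean. Each day's solve conditions on the doses
#' already fixed for earlier days; with `rounding` set, doses are rounded
#' to the increment (round half up) *before* entering the history, so the
#' schedule remains self-consistent under realistic dose granularity.
#'
#' The drug's steady-state anchor `drug_css` defaults to the plateau daily
#' mean of its standard maintenance regimen (`standard_dose` every
#' `interval` hours), simulated over the reference's `ss_days`.
#'
#' @param model A [pk_model()] (preferred; supplies `standard_dose` and
#'   `interval`) or a `pk_params` set.
#' @param reference A [build_reference()] profile.
#' @param standard_dose,interval Override the model's standard regimen.
#' @param drug_css Steady-state anchor, ng/ml; computed if `NULL`.
#' @param rounding Dose increment, mg (e.g. 0.1); `NULL` for exact doses.
#' @param resolution Simulation grid, h.
#' @return A `titration` object: per-day `doses` (mg per interval),
#'   `targets` and `achieved` daily means (ng/ml, the latter from a full
#'   re-simulation of the final schedule), the final `schedule`, and the
#'   configuration used.
#' @examples
#' \donttest{
#' mods <- ssri_models(c("fluoxetine", "sertraline"))
#' ref <- build_reference(mods$fluoxetine)
#' tit <- generate_titration(mods$sertraline, ref)
#' round(tit$doses[c(1, 30)], 1)   # ~23.6, ~51 mg
#' }
#' @export
generate_titration <- function(model, reference, standard_dose = NULL,
                               interval = NULL, drug_css = NULL,
                               rounding = NULL, resolution = 0.1) {
  stopifnot(inherits(reference, "reference_profile"))
  params <- as_pk_params(model)
  drug <- if (inherits(model, "pk_model")) model$drug else "drug"
  if (is.null(standard_dose) && inherits(model, "pk_model")) {
    standard_dose <- model$standard_dose
  }
  if (is.null(interval) && inherits(model, "pk_model")) {
    interval <- model$interval
  }
  if (is.null(interval)) interval <- 24
  if (is.null(standard_dose)) {
    stop("supply standard_dose (no standard regimen on the model)",
         call. = FALSE)
  }
  if (is.null(drug_css)) {
    anchor <- simulate_profile(
      params, regimen(standard_dose, interval, reference$ss_days),
      horizon = 24 * reference$ss_days, resolution = resolution)
    drug_css <- daily_mean(anchor, reference$ss_days)
  }
  targets <- daily_targets(reference, drug_css)
  days <- reference$days
  bounds <- c(0, 10 * standard_dose)

  doses <- numeric(days)
  hist_t <- numeric(0)
  hist_a <- numeric(0)
  state <- if (inherits(params, "mm_pk")) c(A = 0, C = 0) else NULL
  for (d in seq_len(days)) {
    f <- function(x) {
      day_mean_given_dose(params, hist_t, hist_a, d, x, interval,
                          resolution, state = state)$mean - targets[d]
    }
    if (f(0) >= 0) {
      stop(errorCondition(
        sprintf("%s day %d: carry-over exceeds the target", drug, d),
        class = c("ssriload_titration_infeasible", "error"),
        day = d, drug = drug))
    }
    if (f(bounds[2]) < 0) {
      stop(errorCondition(
        sprintf("%s day %d: target %.4g unreachable below %g mg",
                drug, d, targets[d], bounds[2]),
        class = c("ssriload_titration_infeasible", "error"),
        day = d, drug = drug))
    }
    dose_d <- stats::uniroot(f, bounds, tol = bounds[2] * 1e-9)$root
    if (!is.null(rounding)) {
      dose_d <- floor(dose_d / rounding + 0.5) * rounding
    }
    doses[d] <- dose_d
    new_t <- if (interval == 12) c(24 * (d - 1), 24 * (d - 1) + 12)
             else 24 * (d - 1)
    hist_t <- c(hist_t, new_t)
    hist_a <- c(hist_a, rep(dose_d, length(new_t)))
    if (!is.null(state)) {
      state <- day_mean_given_dose(params, numeric(0), numeric(0), d,
                                   dose_d, interval, resolution,
                                   state = state)$state
    }
  }
  schedule <- dose_schedule(hist_t, hist_a, interval = interval)
  prof <- simulate_profile(params, schedule, horizon = 24 * days,
                           resolution = resolution)
  achieved <- daily_mean(prof, seq_len(days))
  structure(list(drug = drug, doses = doses, targets = targets,
                 achieved = achieved, schedule = schedule,
                 drug_css = drug_css, reference = reference,
                 interval = interval, rounding = rounding,
                 standard_dose = standard_dose),
            class = "titration")
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf(
    "Titrated regimen for %s (every %g h, anchor css %.1f ng/ml)\n",
    x$drug, x$interval, x$drug_css))
  df <- as.data.frame(x)
  show <- df[c(1:3, nrow(df)), ]
  show[] <- lapply(show, function(c) round(c, 2))
  print(show, row.names = FALSE)
  cat(sprintf("max |achieved-target|/target = %.2g\n",
              max(abs(x$achieved - x$targets) / x$targets)))
  invisible(x)
}

#' @export
as.data.frame.titration <- function(x, ...) {
  data.frame(day = seq_along(x$doses), dose = x$doses,
             target = x$targets, achieved = x$achieved)
}

#' @export
plot.titration <- function(x, which = c("concentration", "dose"), ...) {
  which <- match.arg(which)
  d <- seq_along(x$doses)
  if (which == "concentration") {
    plot(d, x$targets, type = "l", lty = 2, xlab = "Day",
         ylab = "Daily mean concentration (ng/ml)", main = x$drug, ...)
    graphics::lines(d, x$achieved, col = 2)
    graphics::legend("bottomright", c("target", "achieved"),
                     lty = c(2, 1), col = c(1, 2), bty = "n")
  } else {
    plot(d, x$doses, type = "s", xlab = "Day",
         ylab = sprintf("Dose (mg / %g h)", x$interval),
         main = x$drug, ...)
  }
  invisible(x)
}
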