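#' Fit a per-drug pharmacokinetic model from published observables
#'
#' `pk_model()` is the package's single model-building entry point. It
#' turns the quantities published for a drug into a calibrated
#' one-compartment model and returns a classed object with the usual
#' modelling methods (`print`, `summary`, `coef`, `predict`, `simulate`,
#' `plot`, `residuals`).
#'
#' For `model = "linear"` supply `volume`, `t_half` and `tmax`
#' (calibration via [calibrate_linear()]). For `model = "mm"` supply
#' `cmax`, `tmax`, `t_half` and `ref_dose`, optionally with a fixed `km`
#' (calibration via [calibrate_mm()]); alternatively pass an already-known
#' parameter set through `params`, in which case the observables (if
#' given) are only used for a forward verification.
#'
#' @param drug Drug name (used in printing and reporting).
#' @param model `"linear"` or `"mm"`; ignored when `params` is supplied.
#' @param volume,t_half,tmax,cmax,ref_dose,km Observables and optional
#'   Michaelis prior; see [calibrate_linear()] and [calibrate_mm()].
#' @param params An existing [linear_pk()]/[mm_pk()] set to use verbatim.
#' @param interval Nominal dosing interval for this drug, 12 or 24 h.
#' @param standard_dose Standard per-interval maintenance dose, mg; used as
#'   the drug's steady-state anchor by the titration stage.
#' @return An object of class `pk_model`.
#' @examples
#' sert <- pk_model("sertraline", "linear", volume = 1400, t_half = 26,
#'                  tmax = 6.5, standard_dose = 51)
#' coef(sert)
#' prof <- simulate(sert, schedule = regimen(50, 24, 7), horizon = 168)
#' @export
pk_model <- function(drug = "drug", model = c("linear", "mm"),
                     volume = NULL, t_half = NULL, tmax = NULL,
                     cmax = NULL, ref_dose = NULL, km = NULL,
                     params = NULL, interval = 24, standard_dose = NULL) {
  if (is.null(params)) {
    model <- match.arg(model)
    params <- if (model == "linear") {
      calibrate_linear(volume = volume, t_half = t_half, tmax = tmax)
    } else {
      calibrate_mm(cmax = cmax, tmax = tmax, t_half = t_half,
                   ref_dose = ref_dose, km = km)
    }
  } else {
    stopifnot(inherits(params, "pk_params"))
    model <- if (inherits(params, "mm_pk")) "mm" else "linear"
  }
  obs <- list(cmax = cmax, tmax = tmax, t_half = t_half,
              ref_dose = ref_dose, volume = volume)
  fit <- attr(params, "fit")
  if (is.null(fit) && (!is.null(tmax) || !is.null(t_half))) {
    fit <- forward_check(params,
                         ref_dose = if (is.null(ref_dose)) 1 else ref_dose,
                         cmax = if (is.null(cmax)) NA else cmax,
                         tmax = if (is.null(tmax)) NA else tmax,
                         t_half = if (is.null(t_half)) NA else t_half)
  }
  attr(params, "fit") <- NULL
  structure(list(drug = drug, model = model, params = params,
                 observables = obs, fit = fit, interval = interval,
                 standard_dose = standard_dose),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("Pharmacokinetic model for %s (%s elimination)\n", x$drug,
              if (x$model == "mm") "Michaelis-Menten" else "first-order"))
  cat("Coefficients:\n")
  print(signif(coef(x), 4))
  if (!is.null(x$standard_dose)) {
    cat(sprintf("Standard regimen: %g mg every %d h\n",
                x$standard_dose, x$interval))
  }
  invisible(x)
}

#' @export
coef.pk_model <- function(object, ...) {
  unlist(object$params)
}

#' @export
summary.pk_model <- function(object, ...) {
  structure(list(model = object, fit = object$fit),
            class = "summary.pk_model")
}

#' @export
print.summary.pk_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$fit)) {
    cat("\nForward check against published observables:\n")
    f <- x$fit
    f$rel_residual <- sprintf("%+.3f%%", 100 * f$rel_residual)
    print(f, row.names = FALSE)
  }
  invisible(x)
}

#' @export
residuals.pk_model <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("no observables were supplied; nothing to check against",
         call. = FALSE)
  }
  stats::setNames(object$fit$rel_residual, object$fit$observable)
}

#' Simulate a concentration time course from a fitted model
#'
#' @param object A `pk_model`.
#' @param nsim Unused (the model is deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param seed Unused.
#' @param schedule A [dose_schedule()]; defaults to the drug's standard
#'   regimen over 30 days.
#' @param horizon,resolution Passed to [simulate_profile()].
#' @param ... Ignored.
#' @return A `conc_profile`.
#' @export
simulate.pk_model <- function(object, nsim = 1, seed = NULL,
                              schedule = NULL, horizon = NULL,
                              resolution = 0.1, ...) {
  if (is.null(schedule)) {
    if (is.null(object$standard_dose)) {
      stop("supply a schedule (the model has no standard regimen)",
           call. = FALSE)
    }
    schedule <- regimen(object$standard_dose, object$interval, 30)
  }
  if (is.null(horizon)) {
    horizon <- if (nrow(schedule)) max(schedule$time) + 24 else 24
  }
  simulate_profile(object$params, schedule, horizon, resolution)
}

#' Predicted concentrations at given times
#'
#' @param object A `pk_model`.
#' @param times Times (h) at which to report the concentration.
#' @param schedule Dose schedule; defaults to the standard regimen.
#' @param resolution Simulation grid, h.
#' @param ... Ignored.
#' @return Numeric vector of concentrations, ng/ml.
#' @export
predict.pk_model <- function(object, times, schedule = NULL,
                             resolution = 0.1, ...) {
  horizon <- max(times) + resolution
  if (!is.null(schedule) && nrow(schedule)) {
    horizon <- max(horizon, max(schedule$time) + resolution)
  }
  prof <- simulate.pk_model(object, schedule = schedule,
                            horizon = horizon, resolution = resolution)
  stats::approx(prof$time, prof$conc, xout = times, rule = 2)$y
}

#' @export
plot.pk_model <- function(x, schedule = NULL, days = 30, ...) {
  if (is.null(schedule) && !is.null(x$standard_dose)) {
    schedule <- regimen(x$standard_dose, x$interval, days)
  }
  prof <- simulate.pk_model(x, schedule = schedule)
  plot(prof, main = x$drug, ...)
  invisible(prof)
}
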