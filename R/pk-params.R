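#' One-compartment kinetic parameter sets
#'
#' `linear_pk()` describes a drug with first-order absorption and
#' first-order elimination; `mm_pk()` describes first-order absorption with
#' saturable (Michaelis-Menten) elimination. Concentrations are plasma
#' concentrations in ng/ml throughout the package; doses are absolute mg.
#'
#' @param volume Apparent volume of distribution, litres.
#' @param absorption_rate First-order absorption rate constant, 1/h.
#' @param elimination_rate First-order elimination rate constant, 1/h.
#' @param vmax Maximum elimination rate, ng ml^-1 h^-1.
#' @param km Michaelis constant, ng/ml. Elimination proceeds at rate
#'   `vmax * C / (km + C)`, approximately first-order with rate `vmax/km`
#'   when `C << km`.
#'
#' @return An object of class `linear_pk` or `mm_pk` (both inherit from
#'   `pk_params`): a named list of the kinetic constants.
#'
#' @examples
#' sert <- linear_pk(volume = 1400, absorption_rate = 0.467,
#'                   elimination_rate = log(2) / 26)
#' fluox <- mm_pk(volume = 1033, absorption_rate = 0.53, vmax = 6.5, km = 448)
#' @export
linear_pk <- function(volume, absorption_rate, elimination_rate) {
  check_positive(volume = volume, absorption_rate = absorption_rate,
                 elimination_rate = elimination_rate)
  if (abs(absorption_rate - elimination_rate) <
      1e-8 * max(absorption_rate, elimination_rate)) {
    stop("absorption_rate and elimination_rate coincide; the single-dose ",
         "solution is degenerate (flip-flop limit). Perturb one rate.",
         call. = FALSE)
  }
  structure(list(volume = volume, absorption_rate = absorption_rate,
                 elimination_rate = elimination_rate),
            class = c("linear_pk", "pk_params"))
}

#' @rdname linear_pk
#' @export
mm_pk <- function(volume, absorption_rate, vmax, km) {
  check_positive(volume = volume, absorption_rate = absorption_rate,
                 vmax = vmax, km = km)
  structure(list(volume = volume, absorption_rate = absorption_rate,
                 vmax = vmax, km = km),
            class = c("mm_pk", "pk_params"))
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.pk_params <- function(x, ...) {
  kind <- if (inherits(x, "mm_pk")) "Michaelis-Menten" else "first-order"
  cat(sprintf("One-compartment PK parameters (%s elimination)\n", kind))
  print(unlist(x))
  invisible(x)
}

#' Dose schedules
#'
#' A dose schedule is an ordered set of dosing events (time in hours since
#' treatment start, amount in mg) plus the nominal dosing interval used for
#' reporting (24 h for once daily, 12 h for twice daily).
#'
#' @param times Event times, h; non-negative and non-decreasing.
#' @param amounts Dose amounts, mg; non-negative, recycled to `length(times)`.
#' @param interval Nominal dosing interval, 12 or 24 h.
#'
#' @return A `dose_schedule`: data frame with columns `time` and `amount`,
#'   with the interval stored as an attribute.
#' @examples
#' regimen(40, interval = 24, days = 30)      # 40 mg once daily, 30 days
#' dose_schedule(c(0, 24, 48), c(10, 20, 30))
#' @export
dose_schedule <- function(times, amounts, interval = 24) {
  stopifnot(is.numeric(times), is.numeric(amounts))
  if (length(times) > 0 && length(amounts) != length(times)) {
    amounts <- rep_len(amounts, length(times))
  }
  if (any(times < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (is.unsorted(times)) stop("dose times must be non-decreasing", call. = FALSE)
  if (any(amounts < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (!interval %in% c(12, 24)) {
    stop("dosing interval must be 12 or 24 h", call. = FALSE)
  }
  structure(data.frame(time = as.numeric(times), amount = as.numeric(amounts)),
            interval = interval,
            class = c("dose_schedule", "data.frame"))
}

#' @rdname dose_schedule
#' @param dose Per-interval dose, mg. For `regimen()` a single amount given
#'   every `interval` hours, or a vector of per-day amounts (with
#'   `interval = 12` the same amount is given twice within each day).
#' @param days Number of treatment days.
#' @export
regimen <- function(dose, interval = 24, days = 30) {
  stopifnot(days >= 1)
  per_day <- rep_len(dose, days)
  if (interval == 24) {
    times <- 24 * (seq_len(days) - 1)
    amounts <- per_day
  } else {
    times <- as.vector(rbind(24 * (seq_len(days) - 1),
                             24 * (seq_len(days) - 1) + 12))
    amounts <- rep(per_day, each = 2)
  }
  dose_schedule(times, amounts, interval = interval)
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule: %d events, interval %g h, total %g mg\n",
              nrow(x), attr(x, "interval"), sum(x$amount)))
  NextMethod()
}

schedule_interval <- function(schedule) {
  iv <- attr(schedule, "interval")
  if (is.null(iv)) 24 else iv
}
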