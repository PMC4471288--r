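#' Build the 30-day dosing recommendation table
#'
#' Runs the full titration pipeline -- reference profile from fluoxetine,
#' steady-state anchors from each drug's standard regimen, day-by-day dose
#' solves -- and assembles the publication-shaped table: one row per day,
#' the fluoxetine daily mean, then a dose / daily-mean column pair per
#' titrated drug (fluvoxamine's dose is per 12-h interval).
#'
#' @param models Named list of [pk_model()]s including `fluoxetine`;
#'   defaults to all bundled drugs.
#' @param reference A [build_reference()] profile; built from the
#'   fluoxetine model if `NULL`.
#' @param days Number of days (rows).
#' @param digits Rounding for the printed table (1 matches the published
#'   precision); `NULL` for full precision.
#' @param rounding Named list of per-drug dose increments passed to
#'   [generate_titration()], e.g. `list(citalopram = 0.1)`.
#' @param file Optional path; the table is written as CSV with a header
#'   row.
#' @return Data frame; the underlying `titration` objects are attached as
#'   attribute `"titrations"`.
#' @examples
#' \donttest{
#' tab <- make_dose_table(days = 3)
#' tab
#' }
#' @export
make_dose_table <- function(models = ssri_models(), reference = NULL,
                            days = 30, digits = 1, rounding = list(),
                            file = NULL) {
  if (!"fluoxetine" %in% names(models)) {
    stop("models must include the reference drug 'fluoxetine'",
         call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- build_reference(models$fluoxetine, days = days)
  }
  stopifnot(reference$days >= days)
  drugs <- setdiff(names(models), "fluoxetine")
  tits <- lapply(drugs, function(d) {
    generate_titration(models[[d]], reference,
                       rounding = rounding[[d]])
  })
  names(tits) <- drugs
  out <- data.frame(day = seq_len(days),
                    fluoxetine_cave = reference$daily_means[seq_len(days)])
  for (d in drugs) {
    out[[paste0(d, "_dose")]] <- tits[[d]]$doses[seq_len(days)]
    out[[paste0(d, "_cave")]] <- tits[[d]]$achieved[seq_len(days)]
  }
  if (!is.null(digits)) {
    out[-1] <- lapply(out[-1], round, digits = digits)
  }
  attr(out, "titrations") <- tits
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
  }
  out
}

#' Constant versus titrated regimen comparison
#'
#' Simulates a drug under its constant standard regimen and under a
#' titrated schedule, and overlays the two concentration time courses --
#' the picture that motivates titration: the constant regimen overshoots
#' the fluoxetine-like loading curve during the first weeks.
#'
#' @param model A [pk_model()] with a standard regimen.
#' @param titration A `titration` object for the same drug.
#' @param days Days to display.
#' @param file Optional PNG path; plotted to the active device if `NULL`.
#' @return Invisibly, a list with the two `conc_profile`s.
#' @export
regimen_comparison <- function(model, titration, days = 30, file = NULL) {
  const <- simulate.pk_model(
    model, schedule = regimen(model$standard_dose, model$interval, days),
    horizon = 24 * days)
  titr <- simulate_profile(model$params, titration$schedule,
                           horizon = 24 * days)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  plot(const, main = model$drug,
       ylim = c(0, max(const$conc, titr$conc)))
  plot(titr, add = TRUE, col = 2)
  graphics::legend("bottomright",
                   c(sprintf("constant %g mg", model$standard_dose),
                     "titrated"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(list(constant = const, titrated = titr))
}

#' Correlation report panels
#'
#' Produces the three scatter-with-fit panels of the correlation stage:
#' ln(t1/2) versus relative risk of SREs in adults, the same in pediatric
#' populations, and 1/T90 versus risk, each annotated with r and p.
#'
#' @param records Drug/SRE records (see [read_sre_records()]).
#' @param file Optional PNG path.
#' @return Invisibly, the list of `sre_correlation` objects.
#' @export
correlation_panels <- function(records, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 420)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op), add = TRUE)
  panels <- list(
    adult = function() correlate_ln_halflife(records, "adult"),
    pediatric = function() correlate_ln_halflife(records, "pediatric"),
    inv_t90 = function() correlate_inverse_t90(records, "adult"))
  out <- lapply(names(panels), function(nm) {
    res <- tryCatch(panels[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "",
           main = nm)
      graphics::text(0, 0, conditionMessage(res), cex = 0.8)
      NULL
    } else {
      plot(res, main = nm)
      res
    }
  })
  invisible(stats::setNames(out, names(panels)))
}

#' Profile and schedule file I/O
#'
#' Small CSV readers/writers for the package's tabular interchange
#' formats: concentration profiles (`time_h`, `conc_ng_ml`) and per-day
#' dose schedules (`drug`, `day`, `dose_mg`).
#'
#' @param profile A `conc_profile`.
#' @param file Path to a CSV file.
#' @name ssriload-io
#' @export
write_profile <- function(profile, file) {
  utils::write.csv(data.frame(time_h = profile$time,
                              conc_ng_ml = profile$conc),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname ssriload-io
#' @export
read_profile <- function(file) {
  df <- utils::read.csv(file)
  new_conc_profile(df$time_h, df$conc_ng_ml)
}

#' @rdname ssriload-io
#' @param schedule A [dose_schedule()] with whole-day dosing.
#' @param drug Drug name written to / selected from the file.
#' @export
write_schedule <- function(schedule, file, drug = "drug") {
  iv <- schedule_interval(schedule)
  day <- floor(schedule$time / 24) + 1
  if (iv == 12) {
    per_day <- tapply(schedule$amount, day, function(a) a[1])
  } else {
    per_day <- tapply(schedule$amount, day, sum)
  }
  utils::write.csv(data.frame(drug = drug,
                              day = as.integer(names(per_day)),
                              dose_mg = as.numeric(per_day)),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname ssriload-io
#' @param interval Dosing interval used to expand per-day doses, h.
#' @export
read_schedule <- function(file, drug = NULL, interval = 24) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!is.null(drug)) df <- df[df$drug == drug, ]
  df <- df[order(df$day), ]
  regimen_from_days(df$day, df$dose_mg, interval)
}

regimen_from_days <- function(day, dose, interval = 24) {
  if (interval == 12) {
    times <- as.vector(rbind(24 * (day - 1), 24 * (day - 1) + 12))
    amounts <- rep(dose, each = 2)
  } else {
    times <- 24 * (day - 1)
    amounts <- dose
  }
  dose_schedule(times, amounts, interval = interval)
}
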