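#' Bundled SSRI modelling assumptions
#'
#' The per-drug observables and constants the package models by default:
#' fluoxetine carries a fully specified Michaelis-Menten parameter set
#' fitted to its single-dose observables (Cmax 35 ng/ml, Tmax 7 h,
#' t1/2 48 h at 40 mg); sertraline, citalopram and venlafaxine (as the
#' combined venlafaxine + O-desmethylvenlafaxine moiety) are first-order
#' drugs specified by (V, t1/2, Tmax); paroxetine and fluvoxamine are
#' saturable drugs specified by single-dose (Cmax, Tmax, t1/2) triples.
#' `standard_dose_mg` is each drug's steady-state anchor regimen -- the
#' maintenance dose whose plateau the titration stage matches.
#'
#' @return Data frame, one row per drug, with a `source` note per row.
#' @export
ssri_assumptions <- function() {
  utils::read.csv(system.file("extdata", "ssri_assumptions.csv",
                              package = "ssriload"),
                  stringsAsFactors = FALSE)
}

#' Published 30-day escalating regimens and daily means
#'
#' The published dosing table this package reproduces: for each of the
#' five titrated drugs, the per-interval dose for days 1-30 and the
#' resulting daily mean concentration, together with the fluoxetine daily
#' mean column that defines the loading target. Fluvoxamine doses are per
#' 12-h interval; all others per 24 h.
#'
#' @return Data frame with columns `day`, `fluoxetine_cave` and
#'   `<drug>_dose` / `<drug>_cave` pairs.
#' @export
reference_regimens <- function() {
  utils::read.csv(system.file("extdata", "reference_regimens.csv",
                              package = "ssriload"),
                  stringsAsFactors = FALSE)
}

.ssriload_cache <- new.env(parent = emptyenv())

#' Fitted models for the six bundled SSRIs
#'
#' Builds (and caches) a [pk_model()] for each bundled drug. Fluoxetine
#' uses its published parameter set verbatim; the linear drugs are
#' calibrated from (V, t1/2, Tmax); paroxetine and fluvoxamine are fitted
#' to their single-dose triples with the Michaelis constant treated as a
#' free bounded parameter (the expected non-identifiability warning is
#' muffled here; call [calibrate_mm()] directly to see it).
#'
#' @param drugs Character vector of drug names; default all six.
#' @return Named list of `pk_model` objects.
#' @examples
#' \donttest{
#' mods <- ssri_models(c("fluoxetine", "sertraline"))
#' coef(mods$sertraline)
#' }
#' @export
ssri_models <- function(drugs = NULL) {
  tab <- ssri_assumptions()
  if (is.null(drugs)) drugs <- tab$drug
  missing <- setdiff(drugs, tab$drug)
  if (length(missing)) {
    stop("unknown drug(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(drugs, function(d) {
    if (!is.null(.ssriload_cache[[d]])) return(.ssriload_cache[[d]])
    r <- tab[tab$drug == d, ]
    m <- if (!is.na(r$ka_per_h)) {
      # fully specified Michaelis-Menten constants (fluoxetine)
      pk_model(d, params = mm_pk(r$volume_l, r$ka_per_h, r$vm_ng_ml_h,
                                 r$km_ng_ml),
               cmax = r$cmax_ng_ml, tmax = r$tmax_h, t_half = r$t_half_h,
               ref_dose = r$ref_dose_mg, interval = r$interval_h,
               standard_dose = r$standard_dose_mg)
    } else if (r$model == "linear") {
      pk_model(d, "linear", volume = r$volume_l, t_half = r$t_half_h,
               tmax = r$tmax_h, interval = r$interval_h,
               standard_dose = r$standard_dose_mg)
    } else {
      withCallingHandlers(
        pk_model(d, "mm", cmax = r$cmax_ng_ml, tmax = r$tmax_h,
                 t_half = r$t_half_h, ref_dose = r$ref_dose_mg,
                 km = if (!is.na(r$km_ng_ml)) r$km_ng_ml,
                 interval = r$interval_h,
                 standard_dose = r$standard_dose_mg),
        warning = function(w) {
          if (grepl("identify km", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
    .ssriload_cache[[d]] <- m
    m
  })
  stats::setNames(out, drugs)
}
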