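# Run code under a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random synthetic drug with its single-dose observables
#'
#' Draws a kinetic parameter set uniformly from physiological ranges that
#' bracket the bundled SSRIs, then measures its single-dose observables by
#' forward simulation (never from closed forms), so that calibration
#' round-trips exercise the same measurement path as real use. For linear
#' drugs the reported half-life is the terminal elimination half-life
#' extracted from the simulated profile; Tmax is drawn subject to
#' `tmax < 0.6 * t_half / ln(2)` so absorption is genuinely faster than
#' elimination and a peak-time solution exists.
#'
#' @param seed Integer seed; identical seeds give identical drugs.
#' @param model `"linear"` or `"mm"`.
#' @param ranges List of `c(low, high)` ranges: `volume` (l), `t_half`
#'   (h), `tmax` (h), `km` (ng/ml).
#' @param ref_dose Dose at which observables are measured, mg.
#' @param resolution Measurement simulation grid, h.
#' @return List with `params` (the generating `pk_params`), `observables`
#'   (list `cmax`, `tmax`, `t_half`, `ref_dose`, `volume`), and `model`.
#' @examples
#' d <- gen_pk_drug(seed = 7, model = "linear")
#' d$observables$t_half
#' @export
gen_pk_drug <- function(seed, model = c("linear", "mm"),
                        ranges = list(volume = c(100, 2000),
                                      t_half = c(5, 60),
                                      tmax = c(2, 10),
                                      km = c(50, 1000)),
                        ref_dose = 40, resolution = 0.02) {
  model <- match.arg(model)
  for (nm in c("volume", "t_half", "tmax",
               if (model == "mm") "km")) {
    rg <- ranges[[nm]]
    if (is.null(rg) || any(rg <= 0) || rg[1] > rg[2]) {
      stop(sprintf("invalid range for '%s'", nm), call. = FALSE)
    }
  }
  with_local_seed(seed, {
    runif1 <- function(rg) if (rg[1] == rg[2]) rg[1] else
      stats::runif(1, rg[1], rg[2])
    volume <- runif1(ranges$volume)
    t_half <- runif1(ranges$t_half)
    tmax_hi <- min(ranges$tmax[2], 0.6 * t_half / log(2))
    tmax <- runif1(c(min(ranges$tmax[1], tmax_hi), tmax_hi))
    ke <- log(2) / t_half
    ka <- solve_absorption_rate(ke, tmax)
    params <- if (model == "linear") {
      linear_pk(volume, ka, ke)
    } else {
      km <- runif1(ranges$km)
      mm_pk(volume, ka, vmax = ke * km, km = km)
    }
    m <- single_dose_metrics(
      single_dose_profile(params, ref_dose, resolution = resolution),
      half_life = "terminal")
    list(params = params,
         observables = list(cmax = unname(m["cmax"]),
                            tmax = unname(m["tmax"]),
                            t_half = unname(m["t_half"]),
                            ref_dose = ref_dose, volume = volume),
         model = model)
  })
}

#' Generate synthetic drug/SRE records with a controlled correlation
#'
#' Draws `(ln t_half, rr)` pairs from a bivariate normal with correlation
#' `true_r`, back-transforming the first coordinate to a positive
#' half-life. Rows whose relative risk falls at or below zero are redrawn
#' (a rare truncation at the default location/scale), keeping all records
#' valid while leaving the target correlation essentially intact.
#'
#' @param n Number of records (>= 3).
#' @param true_r Target correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param population Population label for every record.
#' @param ln_t_half_mean,ln_t_half_sd Location/scale of `ln(t_half)`
#'   (defaults: median half-life 24 h, geometric sd ~1.8).
#' @param rr_mean,rr_sd Location/scale of the relative risk.
#' @return Data frame of records with a `citation` column marking them
#'   synthetic.
#' @examples
#' gen_sre_records(6, true_r = -0.9, seed = 42)
#' @export
gen_sre_records <- function(n, true_r, seed, population = "adult",
                            ln_t_half_mean = log(24), ln_t_half_sd = 0.6,
                            rr_mean = 1.6, rr_sd = 0.35) {
  stopifnot(n >= 3, abs(true_r) <= 1)
  with_local_seed(seed, {
    x <- numeric(n)
    y <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        z1 <- stats::rnorm(1)
        z2 <- stats::rnorm(1)
        xi <- ln_t_half_mean + ln_t_half_sd * z1
        yi <- rr_mean + rr_sd * (true_r * z1 + sqrt(1 - true_r^2) * z2)
        if (yi > 0) break
      }
      x[i] <- xi
      y[i] <- yi
    }
    data.frame(drug = sprintf("drug%02d", seq_len(n)),
               population = population,
               t_half_h = exp(x), rr_sre = y,
               citation = "synthetic", stringsAsFactors = FALSE)
  })
}
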