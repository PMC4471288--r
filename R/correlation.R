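#' Pearson correlation between SSRI kinetics and suicide-related events
#'
#' `correlate_ln_halflife()` relates the natural-log half-life of each
#' drug to the relative risk of suicide-related events (SREs) in a
#' population; `correlate_inverse_t90()` uses the reciprocal of the time
#' to 90% of steady-state accumulation (a direct loading-rate measure)
#' instead. Both report the Pearson coefficient with the two-sided p-value
#' from the exact t transform t = r sqrt((n-2)/(1-r^2)) on `n - 2` degrees
#' of freedom, plus the least-squares line for plotting.
#'
#' @param records Data frame of drug records with columns `drug`,
#'   `population` (`"adult"`/`"pediatric"`), `t_half_h`, `rr_sre` and
#'   optionally `citation` (see [read_sre_records()] and
#'   [gen_sre_records()]).
#' @param population Restrict to one population; `NULL` uses all rows.
#' @return An `sre_correlation` object: list with `n`, `r`, `p_value`,
#'   `slope`, `intercept`, plus the plotted variables.
#' @examples
#' rec <- gen_sre_records(6, true_r = -0.9, seed = 1)
#' correlate_ln_halflife(rec)
#' @export
correlate_ln_halflife <- function(records, population = NULL) {
  sre_correlation(records, transform = "ln_t_half",
                  population = population)
}

#' @rdname correlate_ln_halflife
#' @export
correlate_inverse_t90 <- function(records, population = NULL) {
  sre_correlation(records, transform = "inv_t90",
                  population = population)
}

sre_correlation <- function(records, transform = c("ln_t_half", "inv_t90"),
                            population = NULL) {
  transform <- match.arg(transform)
  records <- validate_sre_records(records)
  if (!is.null(population)) {
    records <- records[records$population == population, ]
  }
  n <- nrow(records)
  if (n < 3) {
    stop(errorCondition(
      sprintf("need at least 3 records, got %d", n),
      class = c("ssriload_insufficient_data", "error")))
  }
  x <- switch(transform,
              ln_t_half = log(records$t_half_h),
              inv_t90 = 1 / time_to_90pct(records$t_half_h))
  y <- records$rr_sre
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("zero variance; correlation undefined",
                        class = c("ssriload_degenerate_data", "error")))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  slope <- ct$estimate * stats::sd(y) / stats::sd(x)
  structure(list(n = n, r = unname(ct$estimate),
                 p_value = unname(ct$p.value),
                 slope = unname(slope),
                 intercept = mean(y) - unname(slope) * mean(x),
                 transform = transform, x = x, y = y,
                 drugs = records$drug,
                 population = population),
            class = "sre_correlation")
}

validate_sre_records <- function(records) {
  need <- c("drug", "population", "t_half_h", "rr_sre")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$t_half_h <= 0)) stop("t_half_h must be > 0", call. = FALSE)
  if (any(records$rr_sre <= 0)) stop("rr_sre must be > 0", call. = FALSE)
  records
}

#' @export
print.sre_correlation <- function(x, ...) {
  lab <- switch(x$transform, ln_t_half = "ln(t1/2)", inv_t90 = "1/T90")
  cat(sprintf("Pearson correlation, %s vs relative risk of SREs%s\n", lab,
              if (is.null(x$population)) "" else
                paste0(" (", x$population, ")")))
  cat(sprintf("n = %d, r = %.3f, two-sided p = %.4g\n", x$n, x$r,
              x$p_value))
  cat(sprintf("fit: RR = %.3f %+.3f * %s\n", x$intercept, x$slope, lab))
  invisible(x)
}

#' @param x An `sre_correlation`.
#' @param ... Further plot arguments.
#' @rdname correlate_ln_halflife
#' @export
plot.sre_correlation <- function(x, ...) {
  lab <- switch(x$transform, ln_t_half = "ln(t1/2) (h)",
                inv_t90 = "1 / T90 (1/h)")
  plot(x$x, x$y, xlab = lab, ylab = "Relative risk of SREs",
       pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  graphics::text(x$x, x$y, x$drugs, pos = 3, cex = 0.7)
  graphics::mtext(sprintf("r = %.2f, p = %.3g", x$r, x$p_value),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Time to 90% of steady-state accumulation
#'
#' Under first-order kinetics a repeatedly dosed drug reaches 90% of its
#' steady-state level after `log2(10)` (about 3.32) half-lives:
#' `T90 = t_half * ln(10) / ln(2)`.
#'
#' @param t_half Half-life, h (vectorised).
#' @return T90 in hours.
#' @examples
#' time_to_90pct(48)   # fluoxetine: ~159.5 h
#' @export
time_to_90pct <- function(t_half) {
  if (any(t_half <= 0)) stop("t_half must be > 0", call. = FALSE)
  t_half * log(10) / log(2)
}

#' Percent change relative to a reference mean
#'
#' `100 * (mean_b - mean_a) / mean_b`: when `a < b` this is the percent by
#' which group a falls short of reference group b (e.g. "x% less time in
#' the open arms than controls").
#'
#' @param mean_a Treated-group mean.
#' @param mean_b Reference (control) mean; must be non-zero.
#' @return Percent difference.
#' @examples
#' percent_change(5.67, 20.03)   # ~71.7, i.e. 72% less
#' @export
percent_change <- function(mean_a, mean_b) {
  if (any(mean_b == 0)) stop("reference mean must be non-zero",
                             call. = FALSE)
  100 * (mean_b - mean_a) / mean_b
}

#' Read a drug/SRE record table
#'
#' @param file CSV with columns `drug`, `population`, `t_half_h`,
#'   `rr_sre`, `citation`. The bundled illustrative table (constructed,
#'   not literature-extracted) is at
#'   `system.file("extdata", "sre_records_synthetic.csv",
#'   package = "ssriload")`.
#' @return Validated data frame of records.
#' @export
read_sre_records <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_sre_records(df)
}
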