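# Independent closed-form superposition of single-dose terms, written as a
# plain double loop so it shares no code with the package simulator.
oracle_linear_conc <- function(volume, ka, ke, dose_times, dose_amounts,
                               times) {
  vapply(times, function(t) {
    tot <- 0
    for (i in seq_along(dose_times)) {
      tau <- t - dose_times[i]
      if (tau < 0) next
      tot <- tot + dose_amounts[i] * 1000 / volume * ka / (ka - ke) *
        (exp(-ke * tau) - exp(-ka * tau))
    }
    tot
  }, numeric(1))
}

# plain bisection, used as the root-finding oracle
bisect <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

trapz_mean <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2) / (x[length(x)] - x[1])
}

random_linear_params <- function() {
  v <- runif(1, 100, 2000)
  ke <- log(2) / runif(1, 5, 60)
  ka <- ke * runif(1, 2.5, 30)
  linear_pk(v, ka, ke)
}
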