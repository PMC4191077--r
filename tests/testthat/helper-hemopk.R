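# Shared fixtures built in code.

# Closed-form one-compartment profile for a zero-order infusion of `dose`
# over `dur` hours into volume V with first-order elimination k.
one_compartment_profile <- function(times, dose, V, k, dur = 1 / 6) {
  rate <- dose / dur
  conc <- ifelse(
    times <= dur,
    rate / (V * k) * (1 - exp(-k * times)),
    rate / (V * k) * (1 - exp(-k * dur)) * exp(-k * (times - dur)))
  conc[times == 0] <- 0
  conc
}

# Random decaying profile with optional missing values, for oracle tests.
random_profile <- function(n = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- sort(stats::runif(n, 0, 48))
  t <- t + seq_along(t) * 1e-6 # enforce strict increase
  c0 <- stats::runif(1, 50, 500)
  k <- stats::runif(1, 0.05, 1)
  conc <- c0 * exp(-k * t) * exp(stats::rnorm(n, 0, 0.2))
  if (stats::runif(1) < 0.3) conc[sample(2:(n - 1), 1)] <- NA
  list(t = t, conc = conc)
}

# Independent cumulative-sum trapezoid oracle (no shared code with the
# implementation): accumulates over non-missing observations.
trapz_oracle <- function(t, c) {
  keep <- which(!is.na(c))
  t <- t[keep]
  c <- c[keep]
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (c[i] + c[i + 1]) / 2
  }
  s
}
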