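# Independent oracles used across the suite.

# Equilibrium reduced fractions of a set of couples that all exchange with
# one another (directly or indirectly): at equilibrium every couple sees the
# same ambient potential E, so red_i = total_i / (1 + exp((E - E_i) * 2F/RT))
# and E is fixed by electron conservation. Solved by 1-D root finding,
# independently of the package's ODE path.
oracle_equilibrium <- function(E_M, totals, initial_fractions,
                               temperature = 298.15) {
  beta <- 2 * 96485 / (8.314 * temperature)
  electrons <- sum(totals * initial_fractions)
  red_at <- function(E) sum(totals / (1 + exp((E - E_M) * beta)))
  if (electrons <= 0) return(rep(0, length(E_M)))
  if (electrons >= sum(totals)) return(rep(1, length(E_M)))
  E <- stats::uniroot(function(E) red_at(E) - electrons,
                      interval = c(-2, 2), tol = 1e-14)$root
  1 / (1 + exp((E - E_M) * beta))
}

# Brute-force maximum OLS slope: every window of m consecutive points, lm().
oracle_max_slope <- function(time, signal, window_length) {
  dt <- stats::median(diff(time))
  m <- max(2L, floor(window_length / dt)) + 1L
  best <- -Inf
  for (i in seq_len(length(time) - m + 1L)) {
    j <- i + m - 1L
    sl <- unname(stats::coef(stats::lm(signal[i:j] ~ time[i:j]))[2L])
    if (sl > best) best <- sl
  }
  best
}

# Small fast parameter override for structural protocol tests that do not
# check the calibrated inhibition numbers.
fast_params <- function(...) {
  utils::modifyList(list(preincubation = 600), list(...))
}

make_two_couple_model <- function(E_A = -0.330, E_B = -0.290, total_A = 10,
                                  total_B = 10, frac_A = 1, frac_B = 0,
                                  k = 0.01, clamped_A = FALSE) {
  network_model(
    couples = list(
      redox_couple("A", E_A, total_A, frac_A, clamped = clamped_A),
      redox_couple("B", E_B, total_B, frac_B)),
    reactions = list(exchange_reaction("A", "B", k)))
}
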