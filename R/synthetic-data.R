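# Seed-deterministic synthetic-data generators: ferredoxin reoxidation
# decays, dark-inactivation activity time courses and noisy assay traces,
# parameterised by genotype defaults taken from the measured kinetics.

#' Noise specification for synthetic traces
#'
#' Additive iid Gaussian noise plus an optional linear baseline drift.
#' Identical seed and parameters give bit-identical output.
#'
#' @param sigma Noise standard deviation, signal units.
#' @param drift Linear baseline drift, signal units per second.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma = 0, drift = 0, seed = NULL) {
  if (!is.numeric(sigma) || sigma < 0) {
    stop("`sigma` must be >= 0", call. = FALSE)
  }
  structure(list(sigma = sigma, drift = drift, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(trace, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0 && noise$drift == 0) return(trace)
  eps <- 0
  if (noise$sigma > 0) {
    if (!is.null(noise$seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(noise$seed)
    }
    eps <- stats::rnorm(length(trace$time), sd = noise$sigma)
  }
  trace$signal <- trace$signal + eps +
    noise$drift * (trace$time - trace$time[1L])
  trace
}

#' Genotype defaults for the synthetic in vivo kinetics
#'
#' Parameter sets behind the generators, per genotype:
#' * `fd_t50` (s): ferredoxin reoxidation half-life after a light pulse —
#'   0.416 (WT), 0.120 (2-CysPrx null), 0.408 / 0.386 (complemented lines
#'   C1 / C2).
#' * `mdh` (`A_end` %, `tau` s): dark-inactivation course of NADPH-MDH,
#'   `A(t) = A_end + (100 - A_end) exp(-t / tau)`. The plateaus (30% WT,
#'   60% null; 30% for C1/C2) are package choices; each `tau` is then
#'   solved so the course passes through the measured 10-s residual
#'   activity (55.8% WT, 90.9% null, 61.0% C1, 73.2% C2).
#' * `prk` (`A_end`, `tau`): gradual decline for WT/C1/C2 (plateau 60%,
#'   tau 120 s over the 0-300 s sampling), flat 100% for the null.
#'
#' @param genotype `"WT"`, `"prx_null"`, `"C1"` or `"C2"`.
#' @return A `genotype_defaults` list with elements `genotype`, `fd_t50`,
#'   `mdh`, `prk`.
#' @export
genotype_defaults <- function(genotype = c("WT", "prx_null", "C1", "C2")) {
  genotype <- match.arg(genotype)
  mdh_tau <- function(A_end, residual_10s) {
    10 / log((100 - A_end) / (residual_10s - A_end))
  }
  def <- switch(genotype,
    WT = list(fd_t50 = 0.416,
              mdh = c(A_end = 30, tau = mdh_tau(30, 55.8)),
              prk = c(A_end = 60, tau = 120)),
    prx_null = list(fd_t50 = 0.120,
                    mdh = c(A_end = 60, tau = mdh_tau(60, 90.9)),
                    prk = c(A_end = 100, tau = Inf)),
    C1 = list(fd_t50 = 0.408,
              mdh = c(A_end = 30, tau = mdh_tau(30, 61.0)),
              prk = c(A_end = 60, tau = 120)),
    C2 = list(fd_t50 = 0.386,
              mdh = c(A_end = 30, tau = mdh_tau(30, 73.2)),
              prk = c(A_end = 60, tau = 120))
  )
  structure(c(list(genotype = genotype), def),
            class = "genotype_defaults")
}

#' Generate a synthetic ferredoxin reoxidation decay
#'
#' Near-infrared ferredoxin signal after darkening: a single exponential
#' `offset + amplitude * exp(-(ln 2 / t50) t)` (amplitude 1, offset 0 —
#' NIR signals are relative) with the genotype's half-life, plus optional
#' noise.
#'
#' @param genotype Genotype name (see [genotype_defaults()]).
#' @param duration Trace duration, seconds (the recording window after the
#'   light pulse).
#' @param dt Sampling interval, seconds.
#' @param noise A [noise_spec()].
#' @param amplitude,offset Decay amplitude and plateau, signal units.
#' @return A [redox_trace()] (units `"rel"`).
#' @export
gen_fd_decay <- function(genotype = "WT", duration = 4.5, dt = 0.001,
                         noise = noise_spec(), amplitude = 1, offset = 0) {
  stopifnot(duration > 0, dt > 0)
  g <- genotype_defaults(genotype)
  time <- seq(0, duration, by = dt)
  k <- log(2) / g$fd_t50
  tr <- redox_trace(time, offset + amplitude * exp(-k * time),
                    units = "rel",
                    meta = list(genotype = g$genotype, kind = "fd_decay",
                                t50 = g$fd_t50))
  apply_noise(tr, noise)
}

#' Generate synthetic dark-inactivation activity time courses
#'
#' Enzyme activity (% of t = 0) sampled at the darkening protocol's time
#' points. Declining genotypes follow
#' `A(t) = A_end + (100 - A_end) exp(-t / tau)` with the genotype defaults;
#' the 2-CysPrx-null PRK course is constant at 100% (within noise).
#' Replicates add independent noise realisations (seeded from
#' `noise$seed`, one offset per replicate).
#'
#' @param genotype Genotype name (see [genotype_defaults()]).
#' @param enzyme `"mdh"` or `"prk"`.
#' @param sample_times Sampling times, seconds, starting at 0.
#' @param noise A [noise_spec()] (sigma in % activity).
#' @param n_replicates Number of replicate traces.
#' @return A single [redox_trace()] (units `"%"`), or a list of traces when
#'   `n_replicates > 1`.
#' @export
gen_inactivation_course <- function(genotype = "WT",
                                    enzyme = c("mdh", "prk"),
                                    sample_times = c(0, 10, 30, 60, 300),
                                    noise = noise_spec(),
                                    n_replicates = 1) {
  enzyme <- match.arg(enzyme)
  if (length(sample_times) < 2L || sample_times[1L] != 0) {
    stop("`sample_times` must start at 0 and contain >= 2 points",
         call. = FALSE)
  }
  g <- genotype_defaults(genotype)
  par <- g[[enzyme]]
  mean_course <- if (is.infinite(par[["tau"]])) {
    rep(100, length(sample_times))
  } else {
    par[["A_end"]] + (100 - par[["A_end"]]) *
      exp(-sample_times / par[["tau"]])
  }
  make_rep <- function(r) {
    ns <- noise
    if (!is.null(noise$seed)) ns$seed <- noise$seed + r - 1L
    apply_noise(
      redox_trace(sample_times, mean_course, units = "%",
                  meta = list(genotype = g$genotype, enzyme = enzyme,
                              replicate = r)),
      ns)
  }
  if (n_replicates == 1) make_rep(1L) else
    lapply(seq_len(n_replicates), make_rep)
}

#' Overlay measurement noise on a simulated assay trace
#'
#' Runs [simulate_protocol()] and adds the noise model to the recorded
#' readout; with `sigma = 0` and `drift = 0` the output is identical to the
#' noise-free simulation.
#'
#' @param config An [assay_config()].
#' @param noise A [noise_spec()].
#' @param t_end,dt_out Passed to [simulate_protocol()].
#' @return A [redox_trace()].
#' @export
gen_assay_trace <- function(config, noise = noise_spec(), t_end = 480,
                            dt_out = 1) {
  res <- simulate_protocol(config, t_end = t_end, dt_out = dt_out)
  apply_noise(res$trace, noise)
}
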