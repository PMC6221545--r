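# Core thermodynamic and mass-action machinery.

test_that("nernst_keq matches closed-form values and identities", {
  # equal potentials: no driving force
  expect_identical(nernst_keq(-0.290, -0.290), 1)
  # frozen values evaluated independently from exp(n F dE / (R T))
  expect_equal(nernst_keq(-0.330, -0.290), 22.5087045, tolerance = 1e-6)
  expect_equal(nernst_keq(-0.290, -0.315), 0.1428173, tolerance = 1e-6)
  expect_equal(1 / nernst_keq(-0.290, -0.315), 7.0019509, tolerance = 1e-6)
  # reciprocity over random potential pairs
  set.seed(11)
  for (i in 1:20) {
    E <- stats::runif(2, -0.45, -0.25)
    expect_equal(nernst_keq(E[1], E[2]) * nernst_keq(E[2], E[1]), 1,
                 tolerance = 1e-12)
  }
  expect_error(nernst_keq(-0.3, -0.3, n = 0), "positive integer")
  expect_error(nernst_keq(-0.3, -0.3, temperature = -1), "positive")
})

test_that("detailed balance holds around reaction cycles by construction", {
  set.seed(42)
  for (i in 1:20) {
    E <- stats::runif(3, -0.45, -0.25)
    prod_cycle <- nernst_keq(E[1], E[2]) * nernst_keq(E[2], E[3]) *
      nernst_keq(E[3], E[1])
    expect_equal(prod_cycle, 1, tolerance = 1e-12)
  }
  # and on a built model: K_eq(A->B) K_eq(B->C) / K_eq(A->C) = 1
  m <- network_model(
    couples = list(redox_couple("A", -0.33, 10, 1),
                   redox_couple("B", -0.30, 5, 0),
                   redox_couple("C", -0.27, 2, 0)),
    reactions = list(exchange_reaction("A", "B", 0.1),
                     exchange_reaction("B", "C", 0.1),
                     exchange_reaction("A", "C", 0.1)))
  K <- vapply(m$reactions, `[[`, 0, "K_eq")
  expect_equal(K[1] * K[2] / K[3], 1, tolerance = 1e-12)
})

test_that("ode_rhs reproduces hand-computed mass-action fluxes", {
  # no reactions: zero derivative
  m0 <- network_model(list(redox_couple("A", -0.3, 10, 1)))
  expect_identical(ode_rhs(m0, c(10)), 0)

  # symmetric exchange, K_eq = 1: v = 0.01 * 10 * 10 = 1 uM/s
  m <- make_two_couple_model(E_A = -0.3, E_B = -0.3)
  d <- ode_rhs(m, c(10, 0))
  expect_equal(d, c(-1, 1), tolerance = 1e-12)

  # clamped donor: exerts mass action but receives no derivative
  mc <- make_two_couple_model(E_A = -0.3, E_B = -0.3, clamped_A = TRUE)
  dc <- ode_rhs(mc, c(10, 0))
  expect_equal(dc, c(0, 1), tolerance = 1e-12)

  expect_error(ode_rhs(m, c(10, 0, 0)), "dimension")
  expect_error(ode_rhs(m, c(-5, 0)), "negative state")
})

test_that("couple totals and substrate+product are conserved along trajectories", {
  model <- network_model(
    couples = list(redox_couple("DTT", -0.33, 100, 1),
                   redox_couple("Trx", -0.29, 5, 0),
                   redox_couple("E", -0.33, 2, 0)),
    reactions = list(exchange_reaction("DTT", "Trx", 1e-4),
                     exchange_reaction("Trx", "E", 0.05)),
    enzymes = list(michaelis_enzyme("cat", "E", kcat = 2, K_m = 100,
                                    substrate = "S", product = "P")),
    metabolites = c(S = 600, P = 0))
  cfg <- assay_config(model, events = list(), readout = "A340_up",
                      readout_species = "P")
  res <- simulate_protocol(cfg, t_end = 300, dt_out = 1)
  s <- res$states
  expect_equal(max(abs(s$met.S + s$met.P - 600)) / 600, 0,
               tolerance = 1e-6)
  # totals: red stays within [0, total]; sums recomputed from final model
  for (nm in c("DTT", "Trx", "E")) {
    tot <- res$model$couples[[nm]]$total
    red <- s[[paste0("red.", nm)]]
    expect_true(all(red >= -1e-6 * tot & red <= tot * (1 + 1e-6)))
  }
  # signal non-decreasing for the NADPH-formation readout
  expect_true(all(diff(res$trace$signal) >= -1e-12))
})

test_that("equilibrate matches independent root-finding on 2- and 3-couple systems", {
  # symmetric case: exact halves
  m <- make_two_couple_model(E_A = -0.3, E_B = -0.3)
  expect_equal(unname(equilibrate(m)), c(0.5, 0.5), tolerance = 1e-8)

  # single couple, no reactions: fractions unchanged
  m1 <- network_model(list(redox_couple("A", -0.3, 10, 0.37)))
  expect_equal(unname(equilibrate(m1)), 0.37, tolerance = 1e-12)

  # randomised 2-couple systems vs the ambient-potential oracle
  set.seed(7)
  for (i in 1:8) {
    E <- sort(stats::runif(2, -0.36, -0.26))
    tot <- stats::runif(2, 2, 100)
    fr <- c(1, 0)
    m2 <- network_model(
      list(redox_couple("A", E[1], tot[1], fr[1]),
           redox_couple("B", E[2], tot[2], fr[2])),
      list(exchange_reaction("A", "B", 0.05)))
    got <- unname(equilibrate(m2))
    want <- oracle_equilibrium(E, tot, fr)
    expect_equal(got, want, tolerance = 1e-6)
    # mass-action quotient equals the Nernst K_eq
    q <- ((1 - got[1]) * got[2] * tot[2] * tot[1]) /
      (got[1] * tot[1] * (1 - got[2]) * tot[2])
    expect_equal(q, nernst_keq(E[1], E[2]), tolerance = 1e-4)
  }

  # randomised 3-couple chains
  for (i in 1:5) {
    E <- stats::runif(3, -0.36, -0.26)
    tot <- stats::runif(3, 2, 50)
    fr <- c(1, 0, 0)
    m3 <- network_model(
      list(redox_couple("A", E[1], tot[1], fr[1]),
           redox_couple("B", E[2], tot[2], fr[2]),
           redox_couple("C", E[3], tot[3], fr[3])),
      list(exchange_reaction("A", "B", 0.05),
           exchange_reaction("B", "C", 0.05)))
    expect_equal(unname(equilibrate(m3)), oracle_equilibrium(E, tot, fr),
                 tolerance = 1e-6)
  }
})

test_that("raising the acceptor midpoint potential raises its equilibrium reduction", {
  fr_B <- vapply(c(-0.33, -0.31, -0.29, -0.27), function(EB) {
    m <- make_two_couple_model(E_B = EB)
    unname(equilibrate(m)["B"])
  }, numeric(1))
  expect_true(all(diff(fr_B) > 0))
})

test_that("constructors validate their inputs", {
  expect_error(redox_couple("A", -0.3, total = -1), "non-negative")
  expect_error(redox_couple("A", -0.3, 10, reduced_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(exchange_reaction("A", "A", 0.1), "different couples")
  expect_error(network_model(list(redox_couple("A", -0.3, 1)),
                             list(exchange_reaction("A", "B", 0.1))),
               "unknown couple")
  expect_error(
    network_model(list(redox_couple("A", -0.3, 1)),
                  enzymes = list(michaelis_enzyme("e", "A", 1, 10,
                                                  "S", "P"))),
    "unknown metabolite")
  expect_error(network_model(list(redox_couple("A", -0.3, 1)),
                             metabolites = c(S = -2)), "negative")
})
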