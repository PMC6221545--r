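# Core data model of the thiol-disulfide redox network: two-electron
# dithiol/disulfide couples, Nernst-constrained exchange reactions,
# Michaelis-Menten enzymes driven by the reduced form of a couple, and the
# shared mass-action ODE right-hand side.

#' Physical constants used by the Nernst relation
#'
#' Faraday constant (C mol^-1) and molar gas constant (J mol^-1 K^-1).
#' Fixed; not user-configurable.
#' @name physical-constants
#' @keywords internal
NULL

FARADAY <- 96485       # C mol^-1
GAS_CONSTANT <- 8.314  # J mol^-1 K^-1

#' Equilibrium constant of a thiol-disulfide exchange from midpoint potentials
#'
#' For the two-electron exchange `donor_red + acceptor_ox <-> donor_ox +
#' acceptor_red` the equilibrium constant is fixed by thermodynamics:
#' `K_eq = exp(n * F * (E_acceptor - E_donor) / (R * T))`. A more positive
#' acceptor midpoint potential gives `K_eq > 1` (forward transfer favoured).
#' Every exchange reaction in a [network_model()] derives its `K_eq` (and the
#' reverse rate constant `k_reverse = k_forward / K_eq`) through this
#' relation, so detailed balance around any reaction cycle holds by
#' construction.
#'
#' @param E_donor,E_acceptor Midpoint redox potentials in volts (signed,
#'   e.g. `-0.315` for the 2-CysPrx disulfide/dithiol couple).
#' @param n Number of electrons transferred (2 for dithiol/disulfide
#'   chemistry).
#' @param temperature Temperature in kelvin.
#' @return Dimensionless equilibrium constant (strictly positive).
#' @examples
#' nernst_keq(-0.330, -0.290)            # FBPase -> Trx-f1, ~22.5
#' nernst_keq(-0.290, -0.315)            # Trx-f1 -> 2-CysPrx, ~0.143
#' 1 / nernst_keq(-0.290, -0.315)        # oxidase direction, ~7
#' @export
nernst_keq <- function(E_donor, E_acceptor, n = 2L, temperature = 298.15) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop("`n` must be a positive integer electron count", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  }
  stopifnot(is.numeric(E_donor), is.numeric(E_acceptor))
  exp(n * FARADAY * (E_acceptor - E_donor) / (GAS_CONSTANT * temperature))
}

#' Define a dithiol/disulfide redox couple
#'
#' A couple is a pool of a redox-active species characterised by its midpoint
#' potential, total concentration and reduced fraction. A *clamped* couple is
#' a chemostat: it exerts mass action on its exchange partners but its
#' reduced fraction is held fixed (used for the in vivo 2-CysPrx pool and for
#' the ferredoxin/FTR pools across the light-dark transition).
#'
#' @param name Identifier, unique within a model.
#' @param E_M Midpoint redox potential, volts.
#' @param total Total pool concentration, uM (reduced + oxidized).
#' @param reduced_fraction Initial reduced fraction in \[0, 1\].
#' @param n_electrons Electrons transferred per exchange (default 2).
#' @param clamped If `TRUE` the reduced fraction is held fixed and the couple
#'   is not a dynamical variable.
#' @return An object of class `redox_couple`.
#' @export
redox_couple <- function(name, E_M, total, reduced_fraction = 0,
                         n_electrons = 2L, clamped = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(E_M) || length(E_M) != 1L || !is.finite(E_M)) {
    stop("`E_M` must be a finite potential in volts", call. = FALSE)
  }
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) ||
      total < 0) {
    stop("`total` must be a non-negative concentration (uM) for couple '",
         name, "'", call. = FALSE)
  }
  if (!is.numeric(reduced_fraction) || length(reduced_fraction) != 1L ||
      is.na(reduced_fraction) || reduced_fraction < 0 ||
      reduced_fraction > 1) {
    stop("`reduced_fraction` must lie in [0, 1] for couple '", name, "'",
         call. = FALSE)
  }
  structure(
    list(name = name, E_M = E_M, total = total,
         reduced_fraction = reduced_fraction,
         n_electrons = as.integer(n_electrons),
         clamped = isTRUE(clamped)),
    class = "redox_couple"
  )
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf(
    "<redox_couple> %s: E_M = %+.0f mV, total = %g uM, reduced = %.3f%s\n",
    x$name, 1000 * x$E_M, x$total, x$reduced_fraction,
    if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Define a reversible thiol-disulfide exchange reaction
#'
#' Second-order exchange `donor_red + acceptor_ox <-> donor_ox +
#' acceptor_red`. Only the forward rate constant is free; the equilibrium
#' constant is derived from the two midpoint potentials when the reaction is
#' attached to a [network_model()], and `k_reverse = k_forward / K_eq`.
#'
#' @param donor,acceptor Names of the donor and acceptor couples (donor is
#'   the electron donor in the forward direction).
#' @param k_forward Second-order rate constant, uM^-1 s^-1.
#' @param enabled Logical; a disabled reaction contributes no flux.
#' @param role Optional tag (e.g. `"trx_prx"`) used by protocol builders to
#'   switch specific reactions on or off (site-directed variants).
#' @return An object of class `exchange_reaction`. `K_eq` and `k_reverse`
#'   are filled in by [network_model()].
#' @export
exchange_reaction <- function(donor, acceptor, k_forward, enabled = TRUE,
                              role = NA_character_) {
  stopifnot(is.character(donor), is.character(acceptor),
            length(donor) == 1L, length(acceptor) == 1L)
  if (identical(donor, acceptor)) {
    stop("donor and acceptor must be different couples", call. = FALSE)
  }
  if (!is.numeric(k_forward) || length(k_forward) != 1L ||
      !is.finite(k_forward) || k_forward < 0) {
    stop("`k_forward` must be a non-negative rate constant (uM^-1 s^-1)",
         call. = FALSE)
  }
  if (isTRUE(enabled) && k_forward == 0) enabled <- FALSE
  structure(
    list(donor = donor, acceptor = acceptor, k_forward = k_forward,
         K_eq = NA_real_, k_reverse = NA_real_, enabled = isTRUE(enabled),
         role = role),
    class = "exchange_reaction"
  )
}

#' Define a Michaelis-Menten enzyme gated by a redox couple
#'
#' Catalytic rate `v = kcat * [couple_red] * S / (K_m + S)`: the reduced form
#' of the associated couple is the catalytically active enzyme (the paradigm
#' of reductively activated chloroplast enzymes such as FBPase and
#' NADPH-MDH). Substrate is converted to product 1:1. An optional cofactor
#' (e.g. NADPH for MDH) is consumed 1:1 with product formation and enters
#' the rate through a second saturable factor `C / (K_m_cofactor + C)`, so
#' turnover stops when the cofactor is exhausted.
#'
#' @param name Identifier.
#' @param couple Name of the redox couple whose reduced form is active.
#' @param kcat Turnover number, s^-1.
#' @param K_m Michaelis constant for the substrate, uM.
#' @param substrate,product Metabolite names (must exist in the model).
#' @param cofactor Optional consumed cofactor metabolite name.
#' @param K_m_cofactor Michaelis constant for the cofactor, uM.
#' @return An object of class `michaelis_enzyme`.
#' @export
michaelis_enzyme <- function(name, couple, kcat, K_m, substrate, product,
                             cofactor = NULL, K_m_cofactor = 20) {
  stopifnot(is.character(name), is.character(couple),
            is.character(substrate), is.character(product))
  if (!is.numeric(kcat) || kcat < 0 || !is.numeric(K_m) || K_m <= 0) {
    stop("`kcat` must be >= 0 and `K_m` > 0 for enzyme '", name, "'",
         call. = FALSE)
  }
  structure(
    list(name = name, couple = couple, kcat = kcat, K_m = K_m,
         substrate = substrate, product = product,
         cofactor = cofactor, K_m_cofactor = K_m_cofactor),
    class = "michaelis_enzyme"
  )
}

#' Assemble a redox network model
#'
#' Validates cross-references, derives every exchange `K_eq` from the Nernst
#' relation at the model temperature, and fixes the state-vector layout:
#' reduced concentrations of all couples (clamped couples keep a slot but
#' receive zero derivative) followed by metabolite concentrations, all in uM.
#'
#' @param couples List of [redox_couple()] objects.
#' @param reactions List of [exchange_reaction()] objects.
#' @param enzymes List of [michaelis_enzyme()] objects.
#' @param metabolites Named numeric vector of metabolite concentrations (uM).
#' @param temperature Kelvin; assays are modelled at 298.15 K (25 C).
#' @return An object of class `network_model`.
#' @export
network_model <- function(couples, reactions = list(), enzymes = list(),
                          metabolites = numeric(0), temperature = 298.15) {
  if (inherits(couples, "redox_couple")) couples <- list(couples)
  if (inherits(reactions, "exchange_reaction")) reactions <- list(reactions)
  if (inherits(enzymes, "michaelis_enzyme")) enzymes <- list(enzymes)
  stopifnot(length(couples) >= 1L)
  if (!all(vapply(couples, inherits, TRUE, "redox_couple"))) {
    stop("`couples` must be a list of redox_couple objects", call. = FALSE)
  }
  cn <- vapply(couples, `[[`, "", "name")
  if (anyDuplicated(cn)) stop("duplicated couple names", call. = FALSE)
  names(couples) <- cn

  metabolites <- unlist(metabolites)
  if (length(metabolites) && (is.null(names(metabolites)) ||
                              any(!nzchar(names(metabolites))))) {
    stop("`metabolites` must be a named vector", call. = FALSE)
  }
  if (any(metabolites < 0)) {
    bad <- names(metabolites)[metabolites < 0][1L]
    stop("negative concentration for metabolite '", bad, "'", call. = FALSE)
  }

  for (rx in reactions) {
    if (!inherits(rx, "exchange_reaction")) {
      stop("`reactions` must be exchange_reaction objects", call. = FALSE)
    }
    for (side in c(rx$donor, rx$acceptor)) {
      if (!side %in% cn) {
        stop("reaction references unknown couple '", side, "'",
             call. = FALSE)
      }
    }
  }
  reactions <- lapply(reactions, function(rx) {
    n <- couples[[rx$acceptor]]$n_electrons
    rx$K_eq <- nernst_keq(couples[[rx$donor]]$E_M,
                          couples[[rx$acceptor]]$E_M,
                          n = n, temperature = temperature)
    rx$k_reverse <- rx$k_forward / rx$K_eq
    rx
  })

  for (en in enzymes) {
    if (!inherits(en, "michaelis_enzyme")) {
      stop("`enzymes` must be michaelis_enzyme objects", call. = FALSE)
    }
    if (!en$couple %in% cn) {
      stop("enzyme '", en$name, "' references unknown couple '", en$couple,
           "'", call. = FALSE)
    }
    for (m in c(en$substrate, en$product, en$cofactor)) {
      if (!m %in% names(metabolites)) {
        stop("enzyme '", en$name, "' references unknown metabolite '", m,
             "'", call. = FALSE)
      }
    }
  }

  structure(
    list(couples = couples, reactions = reactions, enzymes = enzymes,
         metabolites = metabolites, temperature = temperature),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d couple(s), %d reaction(s), %d enzyme(s), %d metabolite(s), T = %.2f K\n",
              length(x$couples), length(x$reactions), length(x$enzymes),
              length(x$metabolites), x$temperature))
  for (cp in x$couples) print(cp)
  for (rx in x$reactions) {
    cat(sprintf("  %s -> %s: k_f = %g, K_eq = %.4g%s\n", rx$donor,
                rx$acceptor, rx$k_forward, rx$K_eq,
                if (rx$enabled) "" else " (disabled)"))
  }
  invisible(x)
}

# --- state vector helpers ---------------------------------------------------

model_state <- function(model) {
  red <- vapply(model$couples, function(cp) cp$reduced_fraction * cp$total,
                numeric(1))
  names(red) <- paste0("red.", names(model$couples))
  met <- model$metabolites
  if (length(met)) names(met) <- paste0("met.", names(model$metabolites))
  c(red, met)
}

state_reduced <- function(model, state) {
  nc <- length(model$couples)
  red <- pmin(pmax(state[seq_len(nc)], 0),
              vapply(model$couples, `[[`, 0, "total"))
  for (i in seq_len(nc)) {
    cp <- model$couples[[i]]
    if (cp$clamped) red[i] <- cp$reduced_fraction * cp$total
  }
  unname(red)
}

#' Mass-action right-hand side of the redox network ODE system
#'
#' Computes the time derivative of the state vector (reduced concentrations
#' of all couples followed by metabolites, uM). Clamped couples contribute to
#' exchange fluxes but receive a zero derivative; within each couple the
#' reduction and oxidation fluxes cancel, so couple totals are conserved
#' exactly between protocol events. Exposed mainly for testing and for use
#' with other integrators; simulations normally go through
#' [simulate_protocol()].
#'
#' @param model A [network_model()].
#' @param state Numeric state vector matching the model layout (see
#'   [network_model()]); entries in uM.
#' @param t Time in seconds (the system is autonomous; accepted for solver
#'   compatibility).
#' @return Derivative vector, uM s^-1.
#' @export
ode_rhs <- function(model, state, t = 0) {
  nc <- length(model$couples)
  nm <- length(model$metabolites)
  if (length(state) != nc + nm) {
    stop("state length ", length(state), " does not match model dimension ",
         nc + nm, call. = FALSE)
  }
  tol <- 1e-6 * max(1, vapply(model$couples, `[[`, 0, "total"),
                    model$metabolites)
  if (any(state < -tol)) {
    stop("negative state entries beyond tolerance", call. = FALSE)
  }
  rhs_core(t, state, model)[[1L]]
}

# internal rhs in deSolve signature; soft-clips transient negatives
rhs_core <- function(t, state, model) {
  nc <- length(model$couples)
  nm <- length(model$metabolites)
  red <- state_reduced(model, state)
  tot <- vapply(model$couples, `[[`, 0, "total")
  ox <- pmax(tot - red, 0)
  idx <- stats::setNames(seq_len(nc), names(model$couples))

  dred <- numeric(nc)
  for (rx in model$reactions) {
    if (!rx$enabled) next
    d <- idx[[rx$donor]]; a <- idx[[rx$acceptor]]
    v <- rx$k_forward * red[d] * ox[a] - rx$k_reverse * ox[d] * red[a]
    dred[d] <- dred[d] - v
    dred[a] <- dred[a] + v
  }
  for (i in seq_len(nc)) if (model$couples[[i]]$clamped) dred[i] <- 0

  dmet <- numeric(nm)
  if (nm) {
    met <- pmax(state[nc + seq_len(nm)], 0)
    midx <- stats::setNames(seq_len(nm), names(model$metabolites))
    for (en in model$enzymes) {
      s <- met[midx[[en$substrate]]]
      v <- en$kcat * red[idx[[en$couple]]] * s / (en$K_m + s)
      if (!is.null(en$cofactor)) {
        co <- met[midx[[en$cofactor]]]
        v <- v * co / (en$K_m_cofactor + co)
      }
      dmet[midx[[en$substrate]]] <- dmet[midx[[en$substrate]]] - v
      dmet[midx[[en$product]]] <- dmet[midx[[en$product]]] + v
      if (!is.null(en$cofactor)) {
        dmet[midx[[en$cofactor]]] <- dmet[midx[[en$cofactor]]] - v
      }
    }
  }
  list(c(dred, dmet))
}

#' Relax a redox network to its equilibrium reduced fractions
#'
#' Integrates the autonomous system over successively doubled horizons until
#' the right-hand side is numerically zero, then returns the reduced fraction
#' of every couple. At equilibrium every enabled exchange satisfies its
#' Nernst-derived mass-action quotient (checked by the test suite against
#' independent 1-D root finding on the shared ambient potential).
#'
#' @param model A [network_model()].
#' @param max_horizon Longest integration horizon tried, seconds.
#' @param tol Convergence tolerance on `max |d state/dt|` relative to the
#'   largest pool.
#' @return Named vector of equilibrium reduced fractions (clamped couples
#'   report their clamp; empty couples report their configured fraction).
#' @export
equilibrate <- function(model, max_horizon = 1e7, tol = 1e-10) {
  state <- model_state(model)
  scale <- max(1, vapply(model$couples, `[[`, 0, "total"))
  horizon <- 10
  repeat {
    deriv <- rhs_core(0, state, model)[[1L]]
    if (max(abs(deriv)) < tol * scale) break
    if (horizon > max_horizon) {
      stop("equilibrate() failed to converge within horizon ", max_horizon,
           " s (max |dx/dt| = ", signif(max(abs(deriv)), 3), " uM/s)",
           call. = FALSE)
    }
    sol <- deSolve::lsoda(y = state, times = c(0, horizon),
                          func = rhs_core, parms = model,
                          rtol = 1e-10, atol = 1e-12)
    state <- sol[nrow(sol), -1L]
    horizon <- horizon * 4
  }
  tot <- vapply(model$couples, `[[`, 0, "total")
  red <- state_reduced(model, state)
  frac <- ifelse(tot > 0, red / tot,
                 vapply(model$couples, `[[`, 0, "reduced_fraction"))
  stats::setNames(pmin(pmax(frac, 0), 1), names(model$couples))
}
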