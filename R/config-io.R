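# YAML model-definition files and optional SBML export. Units are fixed:
# concentrations in uM, potentials in volts, times in seconds.

COUPLE_KEYS <- c("name", "E_M", "total", "reduced_fraction", "n_electrons",
                 "clamped")
REACTION_KEYS <- c("donor", "acceptor", "k_forward", "enabled", "role")
ENZYME_KEYS <- c("name", "couple", "kcat", "K_m", "substrate", "product",
                 "cofactor", "K_m_cofactor")

check_keys <- function(entry, allowed, where) {
  unknown <- setdiff(names(entry), allowed)
  if (length(unknown)) {
    stop("unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Load a redox network model from a YAML configuration file
#'
#' The file has sections `couples`, `reactions`, `enzymes` (optional) and
#' `metabolites` (optional), plus a scalar `temperature` (kelvin). Units
#' are fixed as uM / volts / seconds. Unknown keys are rejected with their
#' location; equilibrium constants may **not** be supplied — they are
#' always derived from the midpoint potentials via the Nernst relation.
#'
#' @param path Path to the YAML file.
#' @return A validated [network_model()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "couples:",
#'   "  - {name: A, E_M: -0.33, total: 10, reduced_fraction: 1}",
#'   "  - {name: B, E_M: -0.29, total: 10, reduced_fraction: 0}",
#'   "reactions:",
#'   "  - {donor: A, acceptor: B, k_forward: 0.01}"), cfg)
#' load_model_config(cfg)
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(raw)) stop("'", path, "' is not a mapping", call. = FALSE)
  check_keys(raw, c("couples", "reactions", "enzymes", "metabolites",
                    "temperature"), "top level")
  if (is.null(raw$couples) || !length(raw$couples)) {
    stop("config must define at least one couple", call. = FALSE)
  }

  couples <- lapply(seq_along(raw$couples), function(i) {
    cp <- raw$couples[[i]]
    check_keys(cp, COUPLE_KEYS, paste0("couples[", i, "]"))
    for (req in c("name", "E_M", "total")) {
      if (is.null(cp[[req]])) {
        stop("couples[", i, "] is missing '", req, "'", call. = FALSE)
      }
    }
    redox_couple(cp$name, cp$E_M, cp$total,
                 reduced_fraction = cp$reduced_fraction %||% 0,
                 n_electrons = cp$n_electrons %||% 2L,
                 clamped = cp$clamped %||% FALSE)
  })

  reactions <- lapply(seq_along(raw$reactions), function(i) {
    rx <- raw$reactions[[i]]
    if (!is.null(rx$K_eq) || !is.null(rx$k_reverse)) {
      stop("reactions[", i, "]: K_eq/k_reverse are derived from the ",
           "midpoint potentials and must not be set", call. = FALSE)
    }
    check_keys(rx, REACTION_KEYS, paste0("reactions[", i, "]"))
    for (req in c("donor", "acceptor", "k_forward")) {
      if (is.null(rx[[req]])) {
        stop("reactions[", i, "] is missing '", req, "'", call. = FALSE)
      }
    }
    exchange_reaction(rx$donor, rx$acceptor, rx$k_forward,
                      enabled = rx$enabled %||% TRUE,
                      role = rx$role %||% NA_character_)
  })

  enzymes <- lapply(seq_along(raw$enzymes), function(i) {
    en <- raw$enzymes[[i]]
    check_keys(en, ENZYME_KEYS, paste0("enzymes[", i, "]"))
    for (req in c("name", "couple", "kcat", "K_m", "substrate",
                  "product")) {
      if (is.null(en[[req]])) {
        stop("enzymes[", i, "] is missing '", req, "'", call. = FALSE)
      }
    }
    michaelis_enzyme(en$name, en$couple, en$kcat, en$K_m, en$substrate,
                     en$product, cofactor = en$cofactor,
                     K_m_cofactor = en$K_m_cofactor %||% 20)
  })

  metabolites <- unlist(raw$metabolites) %||% numeric(0)
  network_model(couples, reactions, enzymes, metabolites = metabolites,
                temperature = raw$temperature %||% 298.15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a network model to SBML Level 3 (mass-action kinetic laws)
#'
#' One-way interoperability export: each couple becomes a reduced and an
#' oxidized species, each exchange reaction a reversible reaction with the
#' mass-action rate `kf * donor_red * acceptor_ox - kr * donor_ox *
#' acceptor_red` as MathML. Requires the xml2 package.
#'
#' @param model A [network_model()].
#' @param path Output file path (`.xml`).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("export_sbml() requires the xml2 package", call. = FALSE)
  }
  stopifnot(inherits(model, "network_model"))
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "redox_network",
                             substanceUnits = "item",
                             timeUnits = "second")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "stroma", size = "1",
                      constant = "true")

  species <- xml2::xml_add_child(mdl, "listOfSpecies")
  add_species <- function(id, conc, constant = FALSE) {
    xml2::xml_add_child(species, "species", id = id,
                        compartment = "stroma",
                        initialConcentration = format(conc),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (constant) "true" else
                          "false",
                        constant = "false")
  }
  for (cp in model$couples) {
    add_species(paste0(sid(cp$name), "_red"),
                cp$reduced_fraction * cp$total, cp$clamped)
    add_species(paste0(sid(cp$name), "_ox"),
                (1 - cp$reduced_fraction) * cp$total, cp$clamped)
  }
  for (m in names(model$metabolites)) {
    add_species(sid(m), model$metabolites[[m]])
  }

  parms <- xml2::xml_add_child(mdl, "listOfParameters")
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  mml <- "http://www.w3.org/1998/Math/MathML"
  ci <- function(parent, name) {
    xml2::xml_set_text(xml2::xml_add_child(parent, "ci"), name)
  }
  times_of <- function(parent, names) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, "times")
    for (nm in names) ci(ap, nm)
    ap
  }
  for (i in seq_along(model$reactions)) {
    rx <- model$reactions[[i]]
    kf_id <- paste0("kf_", i); kr_id <- paste0("kr_", i)
    xml2::xml_add_child(parms, "parameter", id = kf_id,
                        value = format(rx$k_forward), constant = "true")
    xml2::xml_add_child(parms, "parameter", id = kr_id,
                        value = format(rx$k_reverse), constant = "true")
    node <- xml2::xml_add_child(rxs, "reaction",
                                id = paste0("exchange_", i),
                                reversible = "true")
    reac <- xml2::xml_add_child(node, "listOfReactants")
    xml2::xml_add_child(reac, "speciesReference",
                        species = paste0(sid(rx$donor), "_red"),
                        stoichiometry = "1", constant = "true")
    xml2::xml_add_child(reac, "speciesReference",
                        species = paste0(sid(rx$acceptor), "_ox"),
                        stoichiometry = "1", constant = "true")
    prod <- xml2::xml_add_child(node, "listOfProducts")
    xml2::xml_add_child(prod, "speciesReference",
                        species = paste0(sid(rx$donor), "_ox"),
                        stoichiometry = "1", constant = "true")
    xml2::xml_add_child(prod, "speciesReference",
                        species = paste0(sid(rx$acceptor), "_red"),
                        stoichiometry = "1", constant = "true")
    law <- xml2::xml_add_child(node, "kineticLaw")
    math <- xml2::xml_add_child(law, "math", xmlns = mml)
    minus <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(minus, "minus")
    times_of(minus, c(kf_id, paste0(sid(rx$donor), "_red"),
                      paste0(sid(rx$acceptor), "_ox")))
    times_of(minus, c(kr_id, paste0(sid(rx$donor), "_ox"),
                      paste0(sid(rx$acceptor), "_red")))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
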