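SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"
TFX_NS <- "https://thermoflux-r.invalid/ns"

#' Write a network model as SBML Level 3
#'
#' Uses the flux-balance-constraints (fbc v2) package for charges, flux
#' bounds and the biomass objective, and the groups package for
#' subsystem labels.  Compartment physicochemical conditions (pH, ionic
#' strength, membrane potential, temperature) and thermodynamic compound
#' identifiers are stored in a package annotation namespace so that a
#' write/read round trip is lossless.
#'
#' @param model a [network_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0(
      '<sbml xmlns="%s" xmlns:fbc="%s" xmlns:groups="%s" xmlns:tfx="%s" ',
      'level="3" version="1" fbc:required="false" groups:required="false">'),
      SBML_CORE_NS, SBML_FBC_NS, SBML_GROUPS_NS, TFX_NS),
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>")
  for (i in seq_len(nrow(model$compartments))) {
    cp <- model$compartments[i, ]
    out <- c(out, sprintf(paste0(
      '      <compartment id="%s" constant="true" tfx:pH="%s" ',
      'tfx:ionicStrength="%s" tfx:membranePotential="%s" ',
      'tfx:temperature="%s"/>'),
      esc(cp$id), num(cp$pH), num(cp$ionic_strength),
      num(cp$membrane_potential), num(cp$temperature)))
  }
  out <- c(out, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    out <- c(out, sprintf(paste0(
      '      <species id="%s" compartment="%s" hasOnlySubstanceUnits="false" ',
      'boundaryCondition="false" constant="false" fbc:charge="%s" ',
      'tfx:thermoId="%s"/>'),
      esc(mt$id), esc(mt$compartment), num(mt$charge), esc(mt$thermo_id)))
  }
  out <- c(out, "    </listOfSpecies>")

  bounds <- sort(unique(c(model$reactions$lower, model$reactions$upper)))
  bid <- paste0("bnd_", seq_along(bounds))
  names(bid) <- num(bounds)
  out <- c(out, "    <listOfParameters>")
  for (i in seq_along(bounds)) {
    out <- c(out, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      bid[i], num(bounds[i])))
  }
  out <- c(out, "    </listOfParameters>", "    <listOfReactions>")
  st_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction)
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    out <- c(out, sprintf(paste0(
      '      <reaction id="%s" reversible="%s" fast="false" ',
      'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(rx$id), if (rx$lower < 0) "true" else "false",
      bid[num(rx$lower)], bid[num(rx$upper)]))
    st <- st_by_rxn[[rx$id]]
    reac <- st[st$coef < 0, ]
    prod <- st[st$coef > 0, ]
    if (nrow(reac)) {
      out <- c(out, "        <listOfReactants>")
      for (k in seq_len(nrow(reac))) {
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(reac$metabolite[k]), num(-reac$coef[k])))
      }
      out <- c(out, "        </listOfReactants>")
    }
    if (nrow(prod)) {
      out <- c(out, "        <listOfProducts>")
      for (k in seq_len(nrow(prod))) {
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(prod$metabolite[k]), num(prod$coef[k])))
      }
      out <- c(out, "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model$biomass)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "    <groups:listOfGroups>")
  subs <- split(model$reactions$id, model$reactions$subsystem)
  gi <- 0L
  for (sname in names(subs)) {
    gi <- gi + 1L
    out <- c(out, sprintf(
      '      <groups:group groups:id="g%d" groups:kind="partonomy" groups:name="%s">',
      gi, esc(sname)),
      "        <groups:listOfMembers>",
      sprintf('          <groups:member groups:idRef="%s"/>', esc(subs[[sname]])),
      "        </groups:listOfMembers>",
      "      </groups:group>")
  }
  out <- c(out, "    </groups:listOfGroups>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

#' Read a network model from SBML Level 3
#'
#' Understands the fbc (bounds, charges, objective) and groups
#' (subsystems) packages.  Models without subsystem groups load with all
#' subsystems set to `"unassigned"` (with a warning); a missing active
#' flux objective is a configuration error because downstream analyses
#' need a biomass reaction.  Species that represent enzyme-capacity
#' pseudo-metabolites (ids starting with `prot_` or `enz_`) are dropped
#' together with their stoichiometric entries, as are any coupling
#' constraints they carried.
#'
#' @param path an SBML file.
#' @param external id of the external compartment (default `"e"`).
#' @return a [network_model()].
#' @export
read_model_sbml <- function(path, external = "e") {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in '", path, "': ", conditionMessage(e))
  })
  ns <- c(sbml = SBML_CORE_NS, fbc = SBML_FBC_NS, groups = SBML_GROUPS_NS,
          tfx = TFX_NS)
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("malformed SBML in '", path, "': no <model> element")
  }
  attr_or <- function(node, a, default) {
    v <- xml2::xml_attr(node, a)
    ifelse(is.na(v), default, v)
  }
  nnum <- function(x, default = NA_real_) {
    out <- suppressWarnings(as.numeric(x))
    out[is.na(out)] <- default
    out
  }

  cps <- xml2::xml_find_all(mdl, ".//sbml:listOfCompartments/sbml:compartment", ns)
  compartments <- data.frame(
    id = xml2::xml_attr(cps, "id"),
    pH = nnum(attr_or(cps, "pH", "7"), 7),
    ionic_strength = nnum(attr_or(cps, "ionicStrength", "0.15"), 0.15),
    membrane_potential = nnum(attr_or(cps, "membranePotential", "0"), 0),
    temperature = nnum(attr_or(cps, "temperature", "310.15"), 310.15),
    stringsAsFactors = FALSE)

  sps <- xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sps, "id"),
    compartment = xml2::xml_attr(sps, "compartment"),
    charge = nnum(attr_or(sps, "charge", "0"), 0),
    stringsAsFactors = FALSE)
  metabolites$thermo_id <- attr_or(sps, "thermoId", metabolites$id)
  dropped <- grepl("^(prot|enz)_", metabolites$id)
  if (any(dropped)) {
    message("dropping ", sum(dropped),
            " enzyme-constraint pseudo-species: ",
            paste(utils::head(metabolites$id[dropped], 5), collapse = ", "),
            if (sum(dropped) > 5) ", ..." else "")
  }
  drop_ids <- metabolites$id[dropped]
  metabolites <- metabolites[!dropped, , drop = FALSE]

  pars <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- nnum(xml2::xml_attr(pars, "value"))
  names(pval) <- xml2::xml_attr(pars, "id")

  rxs <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction", ns)
  rid <- xml2::xml_attr(rxs, "id")
  get_bound <- function(nodes, a, default) {
    ref <- xml2::xml_attr(nodes, a)
    v <- nnum(ref)                       # numeric literal allowed
    use_par <- is.na(v) & !is.na(ref) & ref %in% names(pval)
    v[use_par] <- pval[ref[use_par]]
    v[is.na(v)] <- default
    v
  }
  reactions <- data.frame(
    id = rid,
    lower = get_bound(rxs, "lowerFluxBound", -1000),
    upper = get_bound(rxs, "upperFluxBound", 1000),
    subsystem = "unassigned", stringsAsFactors = FALSE)

  sto <- list()
  for (i in seq_along(rxs)) {
    reac <- xml2::xml_find_all(rxs[[i]], "./sbml:listOfReactants/sbml:speciesReference", ns)
    prod <- xml2::xml_find_all(rxs[[i]], "./sbml:listOfProducts/sbml:speciesReference", ns)
    sp <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    cf <- c(-nnum(attr_or(reac, "stoichiometry", "1"), 1),
            nnum(attr_or(prod, "stoichiometry", "1"), 1))
    keep <- !sp %in% drop_ids
    if (any(keep)) {
      sto[[length(sto) + 1L]] <- data.frame(
        reaction = rid[i], metabolite = sp[keep], coef = cf[keep],
        stringsAsFactors = FALSE)
    }
  }
  stoichiometry <- do.call(rbind, sto)

  gps <- xml2::xml_find_all(mdl, ".//groups:listOfGroups/groups:group", ns)
  if (length(gps) == 0) {
    warning("SBML file has no subsystem groups; subsystems set to 'unassigned'")
  } else {
    for (g in gps) {
      gname <- xml2::xml_attr(g, "name")
      if (is.na(gname)) gname <- xml2::xml_attr(g, "id")
      members <- xml2::xml_attr(
        xml2::xml_find_all(g, ".//groups:member", ns), "idRef")
      reactions$subsystem[reactions$id %in% members] <- gname
    }
  }

  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing")) {
    stop("configuration error: SBML model declares no biomass objective")
  }
  biomass <- xml2::xml_attr(fo, "reaction")
  if (!biomass %in% reactions$id) {
    stop("configuration error: biomass reaction '", biomass,
         "' not present in the model")
  }
  network_model(metabolites, reactions, stoichiometry, compartments,
                biomass = biomass, external = external)
}

#' Write / read a thermodynamic table as TSV
#'
#' Columns: `compound_id`, `compartment`, `dfG0_prime` (kJ/mol),
#' `dfG0_error` (kJ/mol).
#'
#' @param thermo a [thermo_table()].
#' @param path a TSV file.
#' @return `path` invisibly, or the table.
#' @export
write_thermo_tsv <- function(thermo, path) {
  utils::write.table(as.data.frame(thermo), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thermo_tsv
#' @export
read_thermo_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  thermo_table(df$compound_id, df$dfG0_prime, df$dfG0_error, df$compartment)
}

#' Add exchange reactions for a list of metabolites
#'
#' Adds one reversible boundary half-reaction (`EX_<id>`, default bounds
#' -1000..1000, convention: positive flux = secretion) per listed
#' metabolite.  Metabolites are expected in the external compartment; a
#' missing external species is created (and logged) when the base
#' compound exists internally.  The operation is idempotent: exchanges
#' that already exist are left untouched.
#'
#' @param model a [network_model()].
#' @param metabolite_ids ids of (external) species to exchange.
#' @return the augmented model.
#' @export
add_exchanges <- function(model, metabolite_ids) {
  for (m in metabolite_ids) {
    if (!m %in% model$metabolites$id) {
      base <- sub("_[a-z]$", "", m)
      if (!any(grepl(paste0("^", base, "_"), model$metabolites$id))) {
        stop("unknown metabolite id: ", m)
      }
      message("creating external species ", m)
      model$metabolites <- rbind(model$metabolites, data.frame(
        id = m, compartment = model$external, charge = 0,
        thermo_id = base, stringsAsFactors = FALSE))
    }
    ex_id <- paste0("EX_", sub("_[a-z]$", "", m))
    if (ex_id %in% model$reactions$id) next
    model$reactions <- rbind(model$reactions, data.frame(
      id = ex_id, subsystem = "transport", lower = -1000, upper = 1000,
      stringsAsFactors = FALSE))
    model$stoichiometry <- rbind(model$stoichiometry, data.frame(
      reaction = ex_id, metabolite = m, coef = -1, stringsAsFactors = FALSE))
  }
  network_model(model$metabolites, model$reactions, model$stoichiometry,
                model$compartments, biomass = model$biomass,
                external = model$external)
}

#' Remove blocked reactions
#'
#' A reaction is blocked when both its FVA minimum and maximum are zero
#' within `tol` under the stated bounds (plain FVA, no thermodynamic
#' constraints, no biomass fixing).  All blocked reactions are removed,
#' as are metabolites left without any reaction.  A blocked biomass
#' reaction is retained (with a warning) so the model stays well-formed.
#'
#' @param model a [network_model()].
#' @param condition_bounds optional data.frame (`reaction`, `lower`,
#'   `upper`) of bounds to apply for the test.
#' @param tol absolute flux tolerance.
#' @return list: `model` (pruned), `removed` (character vector of
#'   reaction ids).
#' @export
remove_blocked <- function(model, condition_bounds = NULL, tol = 1e-9) {
  test_model <- model
  if (!is.null(condition_bounds)) {
    test_model <- set_bounds(test_model, condition_bounds$reaction,
                             condition_bounds$lower, condition_bounds$upper)
  }
  tfa <- build_tfa(test_model, thermo = NULL)
  ranges <- solve_fva(tfa, parsimonious = FALSE, fix_biomass = FALSE)
  if (anyNA(ranges$min) || anyNA(ranges$max)) {
    stop("infeasible bounds: the flux variability analysis used for ",
         "blocked-reaction detection did not solve; check the applied ",
         "constraint set (", sum(is.na(ranges$min)), " failed solves)")
  }
  blocked <- ranges$reaction[abs(ranges$min) < tol & abs(ranges$max) < tol]
  if (model$biomass %in% blocked) {
    warning("the biomass reaction is blocked under the stated bounds; ",
            "it is retained so the model stays well-formed")
    blocked <- setdiff(blocked, model$biomass)
  }
  keep <- !model$reactions$id %in% blocked
  reactions <- model$reactions[keep, , drop = FALSE]
  stoich <- model$stoichiometry[model$stoichiometry$reaction %in% reactions$id, ,
                                drop = FALSE]
  mets <- model$metabolites[model$metabolites$id %in% stoich$metabolite, ,
                            drop = FALSE]
  pruned <- network_model(mets, reactions, stoich, model$compartments,
                          biomass = model$biomass, external = model$external)
  list(model = pruned, removed = blocked)
}

#' Write a flux-range set as TSV
#' @param ranges a `flux_ranges` object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ranges_tsv <- function(ranges, path) {
  df <- as.data.frame(ranges)
  df$state <- attr(ranges, "state")
  df$instance <- attr(ranges, "instance")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
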