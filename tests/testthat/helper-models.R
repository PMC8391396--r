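# Small hand-built networks used across tests.

simple_compartments <- function() {
  data.frame(id = c("e", "c"), pH = c(7.4, 7.2), ionic_strength = 0.15,
             membrane_potential = c(0, -0.06), temperature = 310.15,
             stringsAsFactors = FALSE)
}

# linear chain: S_e -(T_S)-> S_c -(CONV)-> 2 P_c -(T_P)-> P_e, uptake capped
chain_model <- function(u = 1, reversible = FALSE) {
  lo <- if (reversible) -1000 else 0
  mets <- data.frame(
    id = c("S_e", "S_c", "P_c", "P_e"),
    compartment = c("e", "c", "c", "e"),
    charge = 0, thermo_id = c("S", "S", "P", "P"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_S", "T_S", "CONV", "T_P", "EX_P"),
    subsystem = c("transport", "transport", "glycolysis", "transport",
                  "transport"),
    lower = c(-u, lo, lo, lo, 0),
    upper = c(0, 1000, 1000, 1000, 1000), stringsAsFactors = FALSE)
  sto <- data.frame(
    reaction = c("EX_S", "T_S", "T_S", "CONV", "CONV", "T_P", "T_P", "EX_P"),
    metabolite = c("S_e", "S_e", "S_c", "S_c", "P_c", "P_c", "P_e", "P_e"),
    coef = c(-1, -1, 1, -1, 2, -1, 1, -1), stringsAsFactors = FALSE)
  network_model(mets, rxns, sto, simple_compartments(), biomass = "EX_P")
}

# two routes of equal yield but different length: S -> P directly (R1) or
# through an intermediate (R2a, R2b)
parallel_model <- function(u = 1) {
  mets <- data.frame(
    id = c("S_e", "S_c", "M_c", "P_c", "P_e"),
    compartment = c("e", "c", "c", "c", "e"), charge = 0,
    thermo_id = c("S", "S", "M", "P", "P"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_S", "T_S", "R1", "R2a", "R2b", "T_P", "EX_P"),
    subsystem = c("transport", "transport", "glycolysis", "glycolysis",
                  "glycolysis", "transport", "transport"),
    lower = c(-u, 0, 0, 0, 0, 0, 0),
    upper = c(0, rep(1000, 6)), stringsAsFactors = FALSE)
  sto <- data.frame(
    reaction = c("EX_S", "T_S", "T_S", "R1", "R1", "R2a", "R2a",
                 "R2b", "R2b", "T_P", "T_P", "EX_P"),
    metabolite = c("S_e", "S_e", "S_c", "S_c", "P_c", "S_c", "M_c",
                   "M_c", "P_c", "P_c", "P_e", "P_e"),
    coef = c(-1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1),
    stringsAsFactors = FALSE)
  network_model(mets, rxns, sto, simple_compartments(), biomass = "EX_P")
}

# branched toy with a dead-end metabolite D_c reachable only via R_dead
branched_model <- function() {
  mets <- data.frame(
    id = c("S_e", "S_c", "A_c", "B_c", "D_c", "P_e"),
    compartment = c("e", "c", "c", "c", "c", "e"), charge = 0,
    thermo_id = c("S", "S", "A", "B", "D", "P"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_S", "T_S", "RA", "RB", "R_dead", "SECR_A", "SECR_B", "EX_P"),
    subsystem = "glycolysis",
    lower = c(-1, 0, 0, 0, 0, 0, 0, 0),
    upper = c(0, rep(1000, 7)), stringsAsFactors = FALSE)
  sto <- data.frame(
    reaction = c("EX_S", "T_S", "T_S", "RA", "RA", "RB", "RB",
                 "R_dead", "R_dead", "SECR_A", "SECR_A", "SECR_B", "SECR_B",
                 "EX_P"),
    metabolite = c("S_e", "S_e", "S_c", "S_c", "A_c", "S_c", "B_c",
                   "S_c", "D_c", "A_c", "P_e", "B_c", "P_e", "P_e"),
    coef = c(-1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1),
    stringsAsFactors = FALSE)
  network_model(mets, rxns, sto, simple_compartments(), biomass = "EX_P")
}

# a flat thermo table covering every compound of a model
flat_thermo <- function(model, value = 0, error = 0) {
  ids <- unique(model$metabolites$thermo_id)
  thermo_table(ids, rep(value, length(ids)), rep(error, length(ids)))
}

# per-reaction brute-force variability oracle: one independent MILP solve
# per bound instead of the batched implementation path
brute_force_ranges <- function(tfa, parsimonious = TRUE, fix_biomass = TRUE) {
  rxns <- tfa$model$reactions$id
  stages <- list()
  ob <- thermoflux:::.net_objective(tfa, tfa$model$biomass)
  if (fix_biomass) {
    stages <- c(stages, list(lp_objective(ob$ind, ob$val, "max", fix = TRUE)))
  }
  if (parsimonious) {
    so <- thermoflux:::.sum_objective(tfa)
    stages <- c(stages, list(lp_objective(so$ind, so$val, "min", fix = TRUE)))
  }
  out <- data.frame(reaction = rxns, min = NA_real_, max = NA_real_)
  for (k in seq_along(rxns)) {
    o <- thermoflux:::.net_objective(tfa, rxns[k])
    lo <- solve_lp1(tfa$problem, stages = stages,
                    queries = list(lp_objective(o$ind, o$val, "min")))
    hi <- solve_lp1(tfa$problem, stages = stages,
                    queries = list(lp_objective(o$ind, o$val, "max")))
    out$min[k] <- lo$queries[[1]]$objective
    out$max[k] <- hi$queries[[1]]$objective
  }
  out
}

toy_roles <- function() {
  list(oxygen_uptake = "EX_o2", atp_synthase = "OXP",
       lactate_secretion = "EX_lac",
       fatty_acid_exchanges = c("EX_fa1", "EX_fa2"))
}

# constrained TFA instance for one bundle condition
bundle_instance <- function(bundle, id) {
  ds <- bundle$conditions[[id]]
  ft <- suppressMessages(fit_condition(ds))
  mdl <- constrain_instance(bundle$model, ft, bundle$truth$exchange_map)
  build_tfa(mdl, bundle$thermo, conc_bounds = ds$conc_bounds)
}
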