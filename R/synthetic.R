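#' @title Seeded toy models and four-condition datasets with known truth
#' @description Generators that emulate the structure of an exometabolome
#'   time-course study on paired drug-resistant / drug-sensitive cell
#'   cultures: a small two-compartment metabolic network with a biomass
#'   reaction, a thermodynamic table consistent with a designed reference
#'   flux distribution, and per-condition cell counts and medium
#'   concentration curves (including one abiotically decaying compound
#'   with a matching cell-free control series).
#' @name synthetic-data
NULL

TOY_SUBSYSTEMS <- c("glycolysis", "TCA", "oxidative phosphorylation",
                    "fatty acid oxidation", "transport", "biomass")

#' Reference (ground-truth) flux distribution of the toy network
#'
#' The toy network's steady state is parameterized by five free rates:
#' glucose uptake `g`, lactate secretion `l`, glutamine-like uptake `u`
#' and the two fatty-acid oxidation fluxes `F1`, `F2`.  All remaining
#' fluxes, including the biomass flux, follow from the mass balances.
#' Filler and loop reactions carry zero reference flux.
#'
#' @param model a toy [network_model()] from [make_toy_model()].
#' @param params list with elements `g`, `l`, `u`, `F1`, `F2`
#'   (mmol/(gDW h) up to a common scale).
#' @param mu optional growth rate (1/h); when given, the whole vector is
#'   rescaled so the biomass flux equals `mu`.
#' @return named flux vector over all reactions, with attribute
#'   `"biomass"` (the biomass flux).
#' @export
toy_reference_flux <- function(model, params, mu = NULL) {
  g <- params$g; l <- params$l; u <- params$u
  F1 <- params$F1; F2 <- params$F2
  b <- (27 * g + 12.5 * (u - l) + 45 * F1 + 57.5 * F2) / 18.75
  p <- 2 * g + u - l - 0.5 * b
  nsh <- 2 * g + u - l
  tca <- p + 4 * F1 + 5 * F2 - 0.5 * b
  oxp <- p + 3 * tca + 6 * F1 + 8 * F2 + nsh
  if (min(b, p, nsh, tca, oxp) < -1e-9) {
    stop("parameter set yields an infeasible (negative) reference flux")
  }
  v <- numeric(nrow(model$reactions))
  names(v) <- model$reactions$id
  v["T_glc"] <- g; v["GLY"] <- g; v["LDH"] <- l; v["T_lac"] <- l
  v["GLNU"] <- u; v["PDH"] <- p; v["TCA"] <- tca; v["NSH"] <- nsh
  v["OXP"] <- oxp; v["T_o2"] <- oxp / 2
  v["FAO1"] <- F1; v["FAO2"] <- F2; v["BIO"] <- b
  v["EX_glc"] <- -g; v["EX_lac"] <- l; v["EX_gln"] <- -u
  v["EX_o2"] <- -oxp / 2; v["EX_fa1"] <- -F1; v["EX_fa2"] <- -F2
  v["EX_bio"] <- b
  if (!is.null(mu)) v <- v * (mu / b)
  attr(v, "biomass") <- if (is.null(mu)) b else mu
  v
}

#' Generate a seeded toy metabolic network and thermodynamic table
#'
#' The network has two internal compartments (cytosol `c`, mitochondrion
#' `m`) plus the external compartment, a biomass reaction consuming three
#' precursors (ATP, pyruvate, acetyl-CoA), exchange reactions for a
#' carbon source, oxygen, a fermentation product, a glutamine-like amino
#' acid and two fatty-acid substrates, an ATP-maintenance drain, and a
#' thermodynamically closed 3-reaction loop (its reaction energies sum to
#' zero exactly, so no feasible solution can circulate flux around it).
#' Formation energies are constructed so that every reaction carrying
#' forward reference flux has attainable \eqn{\Delta_r G' < 0}.
#' `n_internal` above the base 10 adds a chain of glycolytic filler
#' metabolites forming a longer alternative route (zero reference flux).
#'
#' @param seed integer seed; the same seed reproduces the model
#'   bit-identically.
#' @param n_internal number of internal metabolites, between 10 and 60.
#' @return list with elements `model` ([network_model()]), `thermo`
#'   ([thermo_table()]), `ref_flux` (reference flux vector at the default
#'   parameterization) and `ref_params`.
#' @export
make_toy_model <- function(seed = 1L, n_internal = 10L) {
  if (n_internal < 10 || n_internal > 60) {
    stop("n_internal must be between 10 and 60")
  }
  set.seed(as.integer(seed))
  n_fill <- n_internal - 10L

  base_int <- data.frame(
    id = c("glc_c", "atp_c", "pyr_c", "lac_c", "nadh_c",
           "accoa_m", "nadh_m", "o2_m", "x1_c", "x2_c"),
    compartment = c(rep("c", 5), rep("m", 3), "c", "c"),
    stringsAsFactors = FALSE)
  ext <- data.frame(
    id = c("glc_e", "o2_e", "lac_e", "fa1_e", "fa2_e", "gln_e", "bio_e"),
    compartment = "e", stringsAsFactors = FALSE)
  fill <- if (n_fill > 0) {
    data.frame(id = paste0("f", seq_len(n_fill), "_c"), compartment = "c",
               stringsAsFactors = FALSE)
  }
  mets <- rbind(base_int, ext, fill)
  mets$charge <- 0
  mets$thermo_id <- sub("_[cme]$", "", mets$id)

  compartments <- data.frame(
    id = c("e", "c", "m"),
    pH = c(7.4, 7.2, 7.8),
    ionic_strength = c(0.15, 0.15, 0.15),
    membrane_potential = c(0, -0.06, -0.15),
    temperature = 310.15, stringsAsFactors = FALSE)

  rr <- function(id, subsystem, lower, upper) {
    data.frame(id = id, subsystem = subsystem, lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  }
  reactions <- rbind(
    rr(c("EX_glc", "EX_o2", "EX_lac", "EX_fa1", "EX_fa2", "EX_gln"),
       "transport", -1000, 1000),
    rr("EX_bio", "transport", 0, 1000),
    rr(c("T_glc", "T_lac", "T_o2"), "transport", 0, 1000),
    rr("NSH", "transport", -1000, 1000),
    rr("GLY", "glycolysis", 0, 1000),
    rr("LDH", "glycolysis", -1000, 1000),
    rr(c("PDH", "TCA", "GLNU"), "TCA", 0, 1000),
    rr(c("LOOP1", "LOOP2", "LOOP3"), "TCA", -1000, 1000),
    rr("OXP", "oxidative phosphorylation", 0, 1000),
    rr(c("FAO1", "FAO2"), "fatty acid oxidation", 0, 1000),
    rr(c("BIO", "ATPM"), "biomass", 0, 1000))

  sto <- function(reaction, metabolite, coef) {
    data.frame(reaction = reaction, metabolite = metabolite, coef = coef,
               stringsAsFactors = FALSE)
  }
  stoich <- rbind(
    sto("EX_glc", "glc_e", -1), sto("EX_o2", "o2_e", -1),
    sto("EX_lac", "lac_e", -1), sto("EX_fa1", "fa1_e", -1),
    sto("EX_fa2", "fa2_e", -1), sto("EX_gln", "gln_e", -1),
    sto("EX_bio", "bio_e", -1),
    sto("T_glc", c("glc_e", "glc_c"), c(-1, 1)),
    sto("GLY", c("glc_c", "pyr_c", "atp_c", "nadh_c"), c(-1, 2, 2, 2)),
    sto("LDH", c("pyr_c", "nadh_c", "lac_c"), c(-1, -1, 1)),
    sto("T_lac", c("lac_c", "lac_e"), c(-1, 1)),
    sto("T_o2", c("o2_e", "o2_m"), c(-1, 1)),
    sto("PDH", c("pyr_c", "accoa_m", "nadh_m"), c(-1, 1, 1)),
    sto("TCA", c("accoa_m", "nadh_m"), c(-1, 3)),
    sto("GLNU", c("gln_e", "pyr_c", "nadh_c"), c(-1, 1, 1)),
    sto("NSH", c("nadh_c", "nadh_m"), c(-1, 1)),
    sto("OXP", c("nadh_m", "o2_m", "atp_c"), c(-1, -0.5, 2.5)),
    sto("FAO1", c("fa1_e", "accoa_m", "nadh_m"), c(-1, 4, 6)),
    sto("FAO2", c("fa2_e", "accoa_m", "nadh_m"), c(-1, 5, 8)),
    sto("BIO", c("atp_c", "pyr_c", "accoa_m", "bio_e"), c(-10, -0.5, -0.5, 1)),
    sto("ATPM", "atp_c", -1),
    sto("LOOP1", c("pyr_c", "x1_c"), c(-1, 1)),
    sto("LOOP2", c("x1_c", "x2_c"), c(-1, 1)),
    sto("LOOP3", c("x2_c", "pyr_c"), c(-1, 1)))

  if (n_fill > 0) {
    ids <- paste0("f", seq_len(n_fill), "_c")
    chain <- c("glc_c", ids)
    for (i in seq_len(n_fill)) {
      reactions <- rbind(reactions,
        rr(paste0("GLYF", i), "glycolysis", 0, 1000))
      stoich <- rbind(stoich,
        sto(paste0("GLYF", i), c(chain[i], chain[i + 1]), c(-1, 1)))
    }
    reactions <- rbind(reactions,
      rr(paste0("GLYF", n_fill + 1), "glycolysis", 0, 1000))
    stoich <- rbind(stoich,
      sto(paste0("GLYF", n_fill + 1),
          c(ids[n_fill], "pyr_c", "atp_c", "nadh_c"), c(-1, 2, 2, 2)))
  }

  model <- network_model(mets, reactions, stoich, compartments,
                         biomass = "BIO", external = "e")

  # formation energies designed so the reference flux pattern is downhill
  dfg <- c(glc_e = -400, glc_c = -420, atp_c = -98, pyr_c = -202,
           nadh_c = 60, lac_c = -182, lac_e = -192, o2_e = 20, o2_m = 10,
           nadh_m = -200, accoa_m = -32, fa1_e = -1268, fa2_e = -1690,
           gln_e = -112, bio_e = -1397, x1_c = -197, x2_c = -207)
  if (n_fill > 0) {
    fg <- -420 - 55 * seq_len(n_fill) / (n_fill + 1)
    names(fg) <- paste0("f", seq_len(n_fill), "_c")
    dfg <- c(dfg, fg)
  }
  err <- stats::runif(length(dfg), 0.5, 2.5)
  names(err) <- names(dfg)
  err[c("pyr_c", "x1_c", "x2_c")] <- 0  # keeps the loop exactly closed

  thermo <- thermo_table(
    compound_id = sub("_[cme]$", "", names(dfg)),
    dfG0_prime = unname(dfg), dfG0_error = unname(err),
    compartment = mets$compartment[match(names(dfg), mets$id)])

  ref_params <- list(g = 1, l = 1, u = 0.2, F1 = 0.1, F2 = 0.05)
  list(model = model, thermo = thermo,
       ref_flux = toy_reference_flux(model, ref_params),
       ref_params = ref_params)
}

#' A minimal toy for oxygen/substrate trade-off envelopes
#'
#' Seven reactions: a capped fermentable carbon source (ATP without
#' oxygen), an oxygen-costly oxidation route for the same source, an
#' oxygen-efficient fatty-acid oxidation route, an oxidation-cost
#' disposal sink for excess fatty acid, and a fixed ATP demand.  Forcing
#' the fatty-acid influx below its optimum diverts carbon into the
#' costly oxidation route; forcing it above the optimum burns the excess
#' through the disposal sink — so the minimum-oxygen curve over pinned
#' fatty-acid influx has an interior minimum.
#'
#' @param atp_demand fixed ATP maintenance demand.
#' @param glc_cap maximum glucose uptake.
#' @return list with `model`, `thermo` and `roles` (for the sweeps).
#' @export
make_envelope_toy <- function(atp_demand = 2, glc_cap = 1) {
  mets <- data.frame(
    id = c("glc_e", "fa_e", "o2_e", "atp_c"),
    compartment = c("e", "e", "e", "c"),
    charge = 0, stringsAsFactors = FALSE)
  mets$thermo_id <- sub("_[ce]$", "", mets$id)
  compartments <- data.frame(
    id = c("e", "c"), pH = c(7.4, 7.2), ionic_strength = 0.15,
    membrane_potential = c(0, -0.06), temperature = 310.15,
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("EX_glc", "EX_fa", "EX_o2", "FERM", "GOX", "FOX", "FSINK", "ATPM"),
    subsystem = c(rep("transport", 3), "glycolysis",
                  "oxidative phosphorylation", "fatty acid oxidation",
                  "fatty acid oxidation", "biomass"),
    lower = c(-glc_cap, -1000, -1000, 0, 0, 0, 0, atp_demand),
    upper = c(0, 0, 0, 1000, 1000, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
  stoich <- data.frame(
    reaction = c("EX_glc", "EX_fa", "EX_o2",
                 "FERM", "FERM",
                 "GOX", "GOX", "GOX",
                 "FOX", "FOX", "FOX",
                 "FSINK", "FSINK",
                 "ATPM"),
    metabolite = c("glc_e", "fa_e", "o2_e",
                   "glc_e", "atp_c",
                   "glc_e", "o2_e", "atp_c",
                   "fa_e", "o2_e", "atp_c",
                   "fa_e", "o2_e",
                   "atp_c"),
    coef = c(-1, -1, -1,
             -1, 1,
             -1, -2, 2,
             -1, -1, 2,
             -1, -3,
             -1),
    stringsAsFactors = FALSE)
  model <- network_model(mets, reactions, stoich, compartments,
                         biomass = "ATPM", external = "e")
  thermo <- thermo_table(
    compound_id = c("glc", "fa", "o2", "atp"),
    dfG0_prime = c(0, 80, 0, -80), dfG0_error = 0,
    compartment = c("e", "e", "e", "c"))
  roles <- list(oxygen_uptake = "EX_o2", atp_synthase = "FOX",
                lactate_secretion = "FERM", fatty_acid_exchanges = "EX_fa")
  list(model = model, thermo = thermo, roles = roles)
}

.toy_exchange_map <- c(glc = "EX_glc", lac = "EX_lac", gln = "EX_gln",
                       fa1 = "EX_fa1", fa2 = "EX_fa2", o2 = "EX_o2")

.toy_medium_c0 <- c(glc = 2e-3, lac = 1e-4, gln = 5e-4, fa1 = 2.5e-4,
                    fa2 = 2e-4)

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one condition's time-course dataset
#'
#' Cell counts follow \eqn{X(t) = X_0 e^{\mu t}} with multiplicative
#' lognormal noise of the stated CV.  The medium amount of metabolite i
#' follows \eqn{C_i(t) = C_i(0) + q_i (X_0 m_{dw}/\mu)(e^{\mu t} - 1)}
#' (the integrated uptake/secretion of an exponentially growing
#' culture); the designated decaying compound follows the mass balance
#' \eqn{dC/dt = q B(t) - k C}, i.e.
#' \eqn{C(t) = C(0) e^{-kt} + q (X_0 m_{dw}/(\mu + k))(e^{\mu t} -
#' e^{-kt})}, and a matching cell-free control series is produced.
#' Intracellular concentration bounds bracket the reference concentration
#' used in the thermodynamic construction, so every reaction carrying
#' forward reference flux has attainable \eqn{\Delta_r G' < 0}.
#'
#' @param model toy model (for the metabolite universe).
#' @param truth a ground-truth object from [make_bundle()].
#' @param condition_id one of the condition ids in `truth$conditions`.
#' @param times sampling times in hours (must include 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param replicates number of replicate wells.
#' @return a `condition_dataset` list.
#' @export
simulate_condition <- function(model, truth, condition_id,
                               times = c(0, 24, 48, 72), noise_cv = 0.05,
                               replicates = 4) {
  if (!condition_id %in% names(truth$conditions)) {
    stop("unknown condition_id: ", condition_id)
  }
  stopifnot(0 %in% times, noise_cv >= 0)
  cond <- truth$conditions[[condition_id]]
  mu <- cond$mu
  X0 <- truth$X0
  m_dw <- truth$m_dw
  B0 <- X0 * m_dw

  grid <- expand.grid(time_h = times, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  counts <- data.frame(
    condition = condition_id, time_h = grid$time_h, replicate = grid$replicate,
    cells = X0 * exp(mu * grid$time_h) * .lognoise(nrow(grid), noise_cv),
    stringsAsFactors = FALSE)

  k <- truth$abiotic_decay_rate
  med <- list()
  for (met in truth$measured_mets) {
    q <- unname(cond$exchange_rates[.toy_exchange_map[[met]]])
    c0 <- truth$medium_c0[[met]]
    if (identical(met, truth$decay_metabolite)) {
      base <- c0 * exp(-k * grid$time_h) +
        q * (B0 / (mu + k)) * (exp(mu * grid$time_h) - exp(-k * grid$time_h))
    } else {
      base <- c0 + q * (B0 / mu) * (exp(mu * grid$time_h) - 1)
    }
    med[[met]] <- data.frame(
      condition = condition_id, metabolite = met, time_h = grid$time_h,
      replicate = grid$replicate,
      concentration = base * .lognoise(nrow(grid), noise_cv),
      stringsAsFactors = FALSE)
  }
  medium <- do.call(rbind, med)
  rownames(medium) <- NULL

  cellfree <- data.frame(
    condition = condition_id, metabolite = truth$decay_metabolite,
    time_h = grid$time_h, replicate = grid$replicate,
    concentration = truth$medium_c0[[truth$decay_metabolite]] *
      exp(-k * grid$time_h) * .lognoise(nrow(grid), noise_cv),
    stringsAsFactors = FALSE)

  internal <- model$metabolites$id[model$metabolites$compartment != model$external]
  conc_bounds <- data.frame(metabolite = internal, lb = 5e-5, ub = 2e-4,
                            stringsAsFactors = FALSE)

  structure(list(
    id = condition_id, label = cond$label, pair = cond$pair,
    counts = counts, medium = medium, cellfree = cellfree,
    conc_bounds = conc_bounds,
    m_dw = m_dw * (if (noise_cv > 0) .lognoise(1, 0.03) else 1),
    se_m_dw = if (noise_cv > 0) 0.03 * m_dw else 0,
    times = times, replicates = replicates, noise_cv = noise_cv
  ), class = "condition_dataset")
}

#' Generate a complete four-condition synthetic bundle
#'
#' Produces a toy network, its thermodynamic table and four condition
#' datasets: two "resistant" and two "sensitive control" conditions
#' sharing the network but differing in growth rate and metabolic
#' parameterization.  The default reprogramming (applied to both
#' resistant conditions) scales glucose uptake by 0.8 and lactate
#' secretion by 0.5 while tripling both fatty-acid oxidation fluxes,
#' i.e. it is injected into the glycolysis and fatty-acid-oxidation
#' subsystems.  The ground truth records, per condition, the exact
#' reference flux vector and specific exchange rates, plus the set of
#' reactions whose growth-normalized reference flux differs from the
#' paired control by more than the comparison threshold.
#'
#' @param seed integer; fully determines the bundle.
#' @param n_internal internal metabolite count (>= 10).
#' @param times sampling times (h).
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param replicates replicate wells per condition.
#' @param growth_rates named vector of growth rates (1/h) for
#'   `resistant_A`, `sensitive_A`, `resistant_B`, `sensitive_B`.
#' @param solvent_effect apply a shared solvent perturbation to both
#'   members of pair B: a proportional growth slowdown (factor 0.9) that
#'   scales all pair-B fluxes without reprogramming them.
#' @param growth_only make resistant conditions identical to their
#'   controls except for the growth rate (no reprogramming).
#' @param X0 seeded cells per well.
#' @param m_dw dry mass per cell, g.
#' @param abiotic_decay_rate first-order decay rate (1/h) of the
#'   designated medium compound (the glutamine-like substrate).
#' @return a `synthetic_bundle` list: `model`, `thermo`, `conditions`,
#'   `truth`, `pairing`.
#' @export
make_bundle <- function(seed = 1L, n_internal = 10L, times = c(0, 24, 48, 72),
                        noise_cv = 0.05, replicates = 4,
                        growth_rates = c(resistant_A = 0.022,
                                         sensitive_A = 0.033,
                                         resistant_B = 0.026,
                                         sensitive_B = 0.031),
                        solvent_effect = FALSE, growth_only = FALSE,
                        X0 = 2e5, m_dw = 4e-10,
                        abiotic_decay_rate = 0.01) {
  toy <- make_toy_model(seed, n_internal)
  set.seed(as.integer(seed) + 1L)

  theta0 <- toy$ref_params
  reprog <- c(g = 0.8, l = 0.5, F1 = 3, F2 = 3)
  theta_res <- theta0
  if (!growth_only) {
    theta_res$g <- theta0$g * reprog[["g"]]
    theta_res$l <- theta0$l * reprog[["l"]]
    theta_res$F1 <- theta0$F1 * reprog[["F1"]]
    theta_res$F2 <- theta0$F2 * reprog[["F2"]]
  }
  cond_params <- list(
    resistant_A = theta_res, sensitive_A = theta0,
    resistant_B = theta_res, sensitive_B = theta0)
  if (solvent_effect) {
    # the solvent slows growth of both pair-B members proportionally
    # (all fluxes scale with the growth rate; no reprogramming)
    growth_rates[c("resistant_B", "sensitive_B")] <-
      growth_rates[c("resistant_B", "sensitive_B")] * 0.9
  }

  conditions_truth <- list()
  for (id in names(cond_params)) {
    mu <- unname(growth_rates[[id]])
    stopifnot(mu > 0)
    v <- toy_reference_flux(toy$model, cond_params[[id]], mu = mu)
    conditions_truth[[id]] <- list(
      id = id,
      label = if (grepl("^resistant", id)) "resistant" else "sensitive",
      pair = sub(".*_", "", id),
      mu = mu, params = cond_params[[id]],
      ref_flux = v,
      exchange_rates = v[toy$model$exchanges])
  }

  truth <- structure(list(
    seed = as.integer(seed), n_internal = as.integer(n_internal),
    conditions = conditions_truth,
    pairing = list(A = list(resistant = "resistant_A", control = "sensitive_A"),
                   B = list(resistant = "resistant_B", control = "sensitive_B")),
    reprogrammed_subsystems = if (growth_only) character(0) else
      c("glycolysis", "fatty acid oxidation"),
    reprogramming_factors = if (growth_only) NULL else reprog,
    solvent_effect = solvent_effect, growth_only = growth_only,
    decay_metabolite = "gln", abiotic_decay_rate = abiotic_decay_rate,
    measured_mets = names(.toy_medium_c0), medium_c0 = .toy_medium_c0,
    exchange_map = .toy_exchange_map[names(.toy_medium_c0)],
    X0 = X0, m_dw = m_dw
  ), class = "ground_truth")

  conditions <- lapply(names(conditions_truth), function(id) {
    simulate_condition(toy$model, truth, id, times = times,
                       noise_cv = noise_cv, replicates = replicates)
  })
  names(conditions) <- names(conditions_truth)

  structure(list(model = toy$model, thermo = toy$thermo,
                 conditions = conditions, truth = truth,
                 pairing = truth$pairing),
            class = "synthetic_bundle")
}

#' Reactions whose growth-normalized reference flux differs between a
#' resistant condition and its control
#'
#' The ground-truth analogue of the comparison module's dual-bound rule:
#' with noiseless data the flux ranges collapse onto the reference flux
#' vector, so a reaction is truly "different" when the growth-normalized
#' reference fluxes differ relatively by at least `threshold`.
#'
#' @param truth a `ground_truth` object.
#' @param pair `"A"` or `"B"`.
#' @param threshold relative-difference threshold.
#' @param delta denominator floor.
#' @return data.frame: `reaction`, `subsystem` is not included (join with
#'   the model if needed), `rel_diff`, `different`.
#' @export
true_differences <- function(truth, pair = "A", threshold = 0.15,
                             delta = 1e-8) {
  pr <- truth$pairing[[pair]]
  a <- truth$conditions[[pr$resistant]]
  b <- truth$conditions[[pr$control]]
  na <- a$ref_flux / a$mu
  nb <- b$ref_flux / b$mu
  rel <- abs(na - nb) / pmax(abs(na), abs(nb), delta)
  data.frame(reaction = names(na), rel_diff = unname(rel),
             different = unname(rel >= threshold), stringsAsFactors = FALSE)
}

#' Serialize a bundle to plain-text files
#'
#' Writes `model.xml` (SBML L3 with flux-bound and subsystem-group
#' annotations), `thermo.tsv`, `counts.tsv`, `medium.tsv`,
#' `cellfree.tsv`, `conc_bounds.tsv` and `truth.json` into `dir`.
#'
#' @param bundle a [make_bundle()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_sbml(bundle$model, file.path(dir, "model.xml"))
  write_thermo_tsv(bundle$thermo, file.path(dir, "thermo.tsv"))
  tab <- function(what) do.call(rbind, lapply(bundle$conditions, `[[`, what))
  utils::write.table(tab("counts"), file.path(dir, "counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tab("medium"), file.path(dir, "medium.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tab("cellfree"), file.path(dir, "cellfree.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cb <- do.call(rbind, lapply(names(bundle$conditions), function(id) {
    cbind(condition = id, bundle$conditions[[id]]$conc_bounds)
  }))
  utils::write.table(cb, file.path(dir, "conc_bounds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- bundle$truth
  tr$conditions <- lapply(tr$conditions, function(co) {
    co$ref_flux <- as.list(co$ref_flux)
    co$exchange_rates <- as.list(co$exchange_rates)
    co
  })
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
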