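#' @name thermo-constants
#' @title Physical constants used in thermodynamic calculations
#' @description `GAS_CONSTANT` is in kJ/(mol K); `FARADAY` in kJ/(V mol).
#' @keywords internal
GAS_CONSTANT <- 8.31446e-3
FARADAY <- 96.485

#' Construct a thermodynamic table
#'
#' Per-compound standard transformed formation energies with their
#' estimation errors.  Compounds are identified by the id used in the
#' model's `thermo_id` column; a compound may appear once per compartment
#' or once with `compartment = NA` to apply everywhere.
#'
#' @param compound_id character.
#' @param dfG0_prime standard transformed formation energy, kJ/mol.
#' @param dfG0_error estimation error, kJ/mol (>= 0).
#' @param compartment optional compartment id (NA = any).
#' @return data.frame of class `"thermo_table"`.
#' @export
thermo_table <- function(compound_id, dfG0_prime, dfG0_error,
                         compartment = NA_character_) {
  stopifnot(all(dfG0_error >= 0))
  out <- data.frame(compound_id = compound_id,
                    compartment = rep_len(compartment, length(compound_id)),
                    dfG0_prime = dfG0_prime, dfG0_error = dfG0_error,
                    stringsAsFactors = FALSE)
  class(out) <- c("thermo_table", "data.frame")
  out
}

#' Look up formation energies for the metabolites of a model
#'
#' @param model a [network_model()].
#' @param thermo a [thermo_table()].
#' @param id_map optional data.frame (`model_id`, `thermo_id`) overriding
#'   the model's own `thermo_id` column (many-to-one joins allowed).
#' @return data.frame, one row per model metabolite: `dfG0_prime`,
#'   `dfG0_error`, `covered`.
#' @keywords internal
.metabolite_thermo <- function(model, thermo, id_map = NULL) {
  mets <- model$metabolites
  tid <- mets$thermo_id
  if (!is.null(id_map)) {
    i <- match(mets$id, id_map$model_id)
    tid <- ifelse(is.na(i), NA_character_, id_map$thermo_id[i])
  }
  n <- nrow(mets)
  out <- data.frame(id = mets$id, thermo_id = tid,
                    dfG0_prime = rep(NA_real_, n), dfG0_error = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    if (is.na(tid[r])) next
    hit <- thermo$compound_id == tid[r] &
      (is.na(thermo$compartment) | thermo$compartment == mets$compartment[r])
    if (any(hit)) {
      k <- which(hit)[1]
      out$dfG0_prime[r] <- thermo$dfG0_prime[k]
      out$dfG0_error[r] <- thermo$dfG0_error[k]
    }
  }
  out$covered <- !is.na(out$dfG0_prime)
  out
}

#' Standard transformed reaction Gibbs energies
#'
#' Computes, for every reaction, the standard transformed reaction Gibbs
#' energy from the compound formation energies,
#' \deqn{\Delta_r G'^\circ = \sum_j s_j \Delta_f G'^\circ_j,}
#' plus, for reactions spanning compartments, the electrical work of
#' moving charge across the membrane potential
#' (\eqn{F \sum_j s_j z_j \psi_j}, with \eqn{\psi_j} the potential of the
#' compartment of species j relative to the external compartment) and the
#' proton chemical-potential term \eqn{-RT \ln(10) \sum_j s_j \,
#' \mathrm{pH}_j} for explicit proton species.  The error is propagated
#' in quadrature, \eqn{\sqrt{\sum_j s_j^2 \, e_j^2}}.
#'
#' A reaction is `estimable` when it is not an exchange reaction and all
#' of its participants have a formation-energy entry.
#'
#' @param model a [network_model()].
#' @param thermo a [thermo_table()].
#' @param id_map optional id mapping, see [join_thermo()].
#' @param proton_ids compound ids treated as protons (their formation
#'   contribution is fixed by compartment pH, not by the table).
#' @return data.frame: `reaction`, `drG0_prime`, `drG0_error`,
#'   `estimable`.
#' @export
reaction_delta_g0 <- function(model, thermo, id_map = NULL,
                              proton_ids = c("h", "h+")) {
  mt <- .metabolite_thermo(model, thermo, id_map)
  mets <- model$metabolites
  comp <- model$compartments
  RT <- GAS_CONSTANT * comp$temperature[1]
  psi <- comp$membrane_potential[match(mets$compartment, comp$id)]
  pH <- comp$pH[match(mets$compartment, comp$id)]
  is_h <- tolower(mets$thermo_id) %in% proton_ids
  rxns <- model$reactions$id
  st <- model$stoichiometry
  out <- data.frame(reaction = rxns, drG0_prime = NA_real_,
                    drG0_error = NA_real_,
                    estimable = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(rxns)) {
    if (rxns[k] %in% model$exchanges) next
    rows <- which(st$reaction == rxns[k])
    j <- match(st$metabolite[rows], mets$id)
    s <- st$coef[rows]
    if (!all(mt$covered[j] | is_h[j])) next
    chem <- sum(ifelse(is_h[j], -RT * log(10) * pH[j], mt$dfG0_prime[j]) * s)
    elec <- FARADAY * sum(s * mets$charge[j] * psi[j])
    err <- sqrt(sum((s^2 * mt$dfG0_error[j]^2)[!is_h[j]]))
    out$drG0_prime[k] <- chem + elec
    out$drG0_error[k] <- err
    out$estimable[k] <- TRUE
  }
  out
}

#' Join a thermodynamic table onto a model and report coverage
#'
#' Coverage is purely set-theoretic: the fraction of model metabolites
#' with a formation-energy entry and the fraction of non-exchange
#' reactions whose standard reaction energy is estimable (all
#' participants covered).
#'
#' @inheritParams reaction_delta_g0
#' @return list with `coverage_compounds`, `coverage_reactions`,
#'   `unmatched` (metabolite ids without data), `reaction_thermo` (the
#'   [reaction_delta_g0()] table) and `metabolite_thermo`.
#' @export
join_thermo <- function(model, thermo, id_map = NULL) {
  mt <- .metabolite_thermo(model, thermo, id_map)
  rt <- reaction_delta_g0(model, thermo, id_map)
  non_ex <- setdiff(model$reactions$id, model$exchanges)
  list(
    coverage_compounds = mean(mt$covered),
    coverage_reactions = if (length(non_ex))
      mean(rt$estimable[match(non_ex, rt$reaction)]) else NA_real_,
    unmatched = mt$id[!mt$covered],
    reaction_thermo = rt,
    metabolite_thermo = mt
  )
}
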