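#' Construct a stoichiometric network model
#'
#' The container mirrors the usual constraint-based-modeling layout: a
#' metabolite table, a reaction table with flux bounds and subsystem
#' labels, and a stoichiometry triplet table.  Exchange reactions are
#' boundary half-reactions touching exactly one species; by convention a
#' positive exchange flux is secretion and a negative flux is uptake.
#'
#' @param metabolites data.frame with columns `id`, `compartment`,
#'   `charge` (optional, defaults 0) and optionally `thermo_id` (an
#'   external-database identifier used to join thermodynamic data).
#' @param reactions data.frame with columns `id`, `lower`, `upper`,
#'   `subsystem`.
#' @param stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `coef` (products positive, substrates negative).
#' @param compartments data.frame with columns `id`, `pH`,
#'   `ionic_strength` (mol/L), `membrane_potential` (V, relative to the
#'   external compartment) and `temperature` (K).
#' @param biomass id of the biomass reaction.
#' @param external id of the external (boundary) compartment.
#' @return an object of class `"network_model"`.
#' @export
network_model <- function(metabolites, reactions, stoichiometry, compartments,
                          biomass, external = "e") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  if (is.null(metabolites$charge)) metabolites$charge <- 0
  if (is.null(metabolites$thermo_id)) metabolites$thermo_id <- metabolites$id
  stopifnot(!anyDuplicated(metabolites$id), !anyDuplicated(reactions$id))
  bad <- setdiff(stoichiometry$metabolite, metabolites$id)
  if (length(bad)) stop("stoichiometry references unknown metabolites: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(bad)) stop("stoichiometry references unknown reactions: ",
                        paste(bad, collapse = ", "))
  if (any(reactions$lower > reactions$upper)) {
    stop("reaction bounds must satisfy lower <= upper")
  }
  bad <- setdiff(metabolites$compartment, compartments$id)
  if (length(bad)) stop("metabolites reference unknown compartments: ",
                        paste(bad, collapse = ", "))
  if (!biomass %in% reactions$id) stop("biomass reaction '", biomass,
                                       "' not found in the model")
  m <- structure(list(
    metabolites = metabolites, reactions = reactions,
    stoichiometry = stoichiometry, compartments = compartments,
    biomass = biomass, external = external
  ), class = "network_model")
  ex <- find_exchanges(m)
  one_sp <- vapply(ex, function(r) {
    length(unique(stoichiometry$metabolite[stoichiometry$reaction == r])) == 1L
  }, logical(1))
  stopifnot(all(one_sp))
  m$exchanges <- ex
  m
}

#' Identify exchange reactions (boundary half-reactions)
#' @param model a [network_model()].
#' @return character vector of reaction ids touching exactly one species.
#' @export
find_exchanges <- function(model) {
  tab <- table(model$stoichiometry$reaction)
  names(tab)[tab == 1L]
}

#' Dense stoichiometric matrix (species x reactions)
#' @param model a [network_model()].
#' @return numeric matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, rownames(S)), match(st$reaction, colnames(S)))] <- st$coef
  S
}

#' Update flux bounds of one or more reactions
#' @param model a [network_model()].
#' @param ids reaction ids.
#' @param lower,upper new bounds (recycled).
#' @return the updated model.
#' @export
set_bounds <- function(model, ids, lower, upper) {
  i <- match(ids, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction ids: ", paste(ids[is.na(i)], collapse = ", "))
  model$reactions$lower[i] <- rep_len(lower, length(i))
  model$reactions$upper[i] <- rep_len(upper, length(i))
  if (any(model$reactions$lower[i] > model$reactions$upper[i])) {
    stop("reaction bounds must satisfy lower <= upper")
  }
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat("network_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,",
      length(x$exchanges), "exchanges,",
      nrow(x$compartments), "compartments\n")
  cat("biomass reaction:", x$biomass, "\n")
  cat("subsystems:", paste(sort(unique(x$reactions$subsystem)), collapse = ", "), "\n")
  invisible(x)
}

#' Reactions annotated with the compartments they span
#' @keywords internal
.reaction_compartments <- function(model) {
  st <- merge(model$stoichiometry,
              model$metabolites[, c("id", "compartment")],
              by.x = "metabolite", by.y = "id", sort = FALSE)
  split(st$compartment, st$reaction)
}
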