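#' Build a (thermodynamically constrained) flux analysis problem
#'
#' Encodes the network as a mixed-integer linear program.  Every reaction
#' is split into non-negative forward and backward flux variables capped
#' by `M`; net bounds are enforced as rows.  When a thermodynamic table
#' is supplied, every estimable reaction i additionally receives
#'
#' \deqn{\Delta_r G'_i = \Delta_r G'^\circ_i + \gamma_i +
#'   RT \sum_j s_{ij} \ln c_j, \quad \gamma_i \in [-e_i, +e_i],}
#'
#' with per-metabolite log-concentration variables \eqn{\ln c_j}, and the
#' direction-use binaries \eqn{FU_i, BU_i \in \{0,1\}} coupled by
#' \deqn{v^+_i \le M FU_i,\; v^-_i \le M BU_i,\; FU_i + BU_i \le 1,}
#' \deqn{\Delta_r G'_i \le -\epsilon + K_i (1 - FU_i), \quad
#'       -\Delta_r G'_i \le -\epsilon + K_i (1 - BU_i),}
#' so that net forward flux forces a negative reaction Gibbs energy (the
#' second law) and vice versa.  \eqn{K_i} is computed per reaction from
#' the attainable range of \eqn{\Delta_r G'_i} so the big-M couplings are
#' numerically tight.
#'
#' Metabolites without measured concentrations receive the default range
#' (`default_conc`, mol per total protein); measured intervals are
#' clipped into the default range with a warning.
#'
#' @param model a [network_model()].
#' @param thermo a [thermo_table()] or `NULL` for a plain FBA problem.
#' @param conc_bounds optional data.frame (`metabolite`, `lb`, `ub`) of
#'   measured concentration intervals, mol per total protein.
#' @param id_map optional id mapping passed to [reaction_delta_g0()].
#' @param M flux cap, mmol/(gDW h).
#' @param eps strict-inequality surrogate on \eqn{\Delta_r G'}, kJ/mol.
#' @param default_conc default concentration range, mol per total protein.
#' @return an object of class `"tfa_problem"`.
#' @export
build_tfa <- function(model, thermo = NULL, conc_bounds = NULL, id_map = NULL,
                      M = 1000, eps = 1e-6, default_conc = c(1e-12, 0.1)) {
  rx <- model$reactions
  nR <- nrow(rx)
  S <- stoich_matrix(model)
  has_thermo <- !is.null(thermo)

  fcap <- pmin(M, pmax(0, rx$upper))
  bcap <- pmin(M, pmax(0, -rx$lower))

  idx <- list(F = seq_len(nR), B = nR + seq_len(nR))
  ncol_flux <- 2L * nR
  vnames <- c(paste0("F_", rx$id), paste0("B_", rx$id))
  lb <- rep(0, ncol_flux)
  ub <- c(fcap, bcap)
  intg <- rep(0L, ncol_flux)

  rt_tab <- NULL
  lnc_ids <- character(0)
  est <- integer(0)
  RT <- GAS_CONSTANT * model$compartments$temperature[1]
  if (has_thermo) {
    if (length(unique(model$compartments$temperature)) > 1L) {
      warning("multiple compartment temperatures; using the first for RT")
    }
    rt_tab <- reaction_delta_g0(model, thermo, id_map)
    est <- which(rt_tab$estimable)
    mt <- .metabolite_thermo(model, thermo, id_map)
    is_h <- tolower(model$metabolites$thermo_id) %in% c("h", "h+")
    # ln-concentration variables for covered, non-proton metabolites
    lnc_ids <- model$metabolites$id[mt$covered & !is_h]
    ln_lb <- rep(log(default_conc[1]), length(lnc_ids))
    ln_ub <- rep(log(default_conc[2]), length(lnc_ids))
    names(ln_lb) <- names(ln_ub) <- lnc_ids
    if (!is.null(conc_bounds)) {
      for (r in seq_len(nrow(conc_bounds))) {
        m <- conc_bounds$metabolite[r]
        if (!m %in% lnc_ids) next
        clb <- conc_bounds$lb[r]
        cub <- conc_bounds$ub[r]
        if (clb < default_conc[1] || cub > default_conc[2]) {
          warning("concentration bounds for ", m,
                  " outside the default range; clipped")
          clb <- max(clb, default_conc[1])
          cub <- min(cub, default_conc[2])
        }
        ln_lb[m] <- log(clb)
        ln_ub[m] <- log(cub)
      }
    }
    nC <- length(lnc_ids)
    nE <- length(est)
    idx$lnc <- ncol_flux + seq_len(nC)
    names(idx$lnc) <- lnc_ids
    idx$drG <- ncol_flux + nC + seq_len(nE)
    idx$slack <- ncol_flux + nC + nE + seq_len(nE)
    idx$FU <- ncol_flux + nC + 2L * nE + seq_len(nE)
    idx$BU <- ncol_flux + nC + 3L * nE + seq_len(nE)
    names(idx$drG) <- names(idx$slack) <- names(idx$FU) <- names(idx$BU) <-
      rx$id[est]

    # attainable range of drG', used both for variable bounds and K
    g_lo <- g_hi <- numeric(nE)
    for (k in seq_len(nE)) {
      i <- est[k]
      s <- S[, i]
      nz <- which(s != 0 & rownames(S) %in% lnc_ids)
      span_hi <- sum(pmax(s[nz] * ln_lb[rownames(S)[nz]],
                          s[nz] * ln_ub[rownames(S)[nz]]))
      span_lo <- sum(pmin(s[nz] * ln_lb[rownames(S)[nz]],
                          s[nz] * ln_ub[rownames(S)[nz]]))
      g_hi[k] <- rt_tab$drG0_prime[i] + rt_tab$drG0_error[i] + RT * span_hi
      g_lo[k] <- rt_tab$drG0_prime[i] - rt_tab$drG0_error[i] + RT * span_lo
    }
    K <- pmax(abs(g_lo), abs(g_hi)) + 1

    lb <- c(lb, ln_lb, g_lo, -rt_tab$drG0_error[est], rep(0, 2L * nE))
    ub <- c(ub, ln_ub, g_hi, rt_tab$drG0_error[est], rep(1, 2L * nE))
    intg <- c(intg, rep(0L, nC + 2L * nE), rep(1L, 2L * nE))
    vnames <- c(vnames, paste0("lnc_", lnc_ids), paste0("drG_", rx$id[est]),
                paste0("sl_", rx$id[est]), paste0("FU_", rx$id[est]),
                paste0("BU_", rx$id[est]))
  }

  prob <- lp_problem(length(lb), lb = lb, ub = ub, integrality = intg,
                     vnames = vnames)

  # mass balance S (F - B) = 0
  ind <- val <- vector("list", nrow(S))
  for (m in seq_len(nrow(S))) {
    j <- which(S[m, ] != 0)
    ind[[m]] <- c(idx$F[j], idx$B[j])
    val[[m]] <- c(S[m, j], -S[m, j])
  }
  keep <- lengths(ind) > 0
  prob <- lp_add_rows(prob, ind[keep], val[keep], 0, 0,
                      names = paste0("mb_", rownames(S))[keep])

  # net flux bounds lb <= F - B <= ub
  ind <- lapply(seq_len(nR), function(i) c(idx$F[i], idx$B[i]))
  val <- rep(list(c(1, -1)), nR)
  prob <- lp_add_rows(prob, ind, val, rx$lower, rx$upper,
                      names = paste0("net_", rx$id))

  if (has_thermo && length(est)) {
    nE <- length(est)
    # drG - slack - RT * sum_j s_ij lnc_j = drG0
    ind <- val <- vector("list", nE)
    for (k in seq_len(nE)) {
      i <- est[k]
      s <- S[, i]
      nz <- which(s != 0 & rownames(S) %in% lnc_ids)
      ind[[k]] <- c(idx$drG[k], idx$slack[k], idx$lnc[rownames(S)[nz]])
      val[[k]] <- c(1, -1, -RT * s[nz])
    }
    prob <- lp_add_rows(prob, ind, val, rt_tab$drG0_prime[est],
                        rt_tab$drG0_prime[est],
                        names = paste0("dg_", rx$id[est]))
    # flux-direction coupling
    prob <- lp_add_rows(prob,
      lapply(seq_len(nE), function(k) c(idx$F[est[k]], idx$FU[k])),
      lapply(seq_len(nE), function(k) c(1, -max(fcap[est[k]], 1e-12))),
      -Inf, 0, names = paste0("fu_", rx$id[est]))
    prob <- lp_add_rows(prob,
      lapply(seq_len(nE), function(k) c(idx$B[est[k]], idx$BU[k])),
      lapply(seq_len(nE), function(k) c(1, -max(bcap[est[k]], 1e-12))),
      -Inf, 0, names = paste0("bu_", rx$id[est]))
    prob <- lp_add_rows(prob,
      lapply(seq_len(nE), function(k) c(idx$FU[k], idx$BU[k])),
      rep(list(c(1, 1)), nE), -Inf, 1, names = paste0("dir_", rx$id[est]))
    # second-law coupling: drG <= -eps + K (1 - FU); -drG <= -eps + K (1 - BU)
    prob <- lp_add_rows(prob,
      lapply(seq_len(nE), function(k) c(idx$drG[k], idx$FU[k])),
      lapply(seq_len(nE), function(k) c(1, K[k])),
      -Inf, K - eps, names = paste0("slF_", rx$id[est]))
    prob <- lp_add_rows(prob,
      lapply(seq_len(nE), function(k) c(idx$drG[k], idx$BU[k])),
      lapply(seq_len(nE), function(k) c(-1, K[k])),
      -Inf, K - eps, names = paste0("slB_", rx$id[est]))
  }

  structure(list(
    problem = prob, model = model, idx = idx, has_thermo = has_thermo,
    reaction_thermo = rt_tab, RT = RT, M = M, eps = eps,
    estimable = if (has_thermo) model$reactions$id[est] else character(0)
  ), class = "tfa_problem")
}

.net_objective <- function(tfa, rxn, coef = 1) {
  i <- match(rxn, tfa$model$reactions$id)
  if (anyNA(i)) stop("unknown reaction: ", paste(rxn[is.na(i)], collapse = ", "))
  coef <- rep_len(coef, length(i))
  list(ind = c(tfa$idx$F[i], tfa$idx$B[i]), val = c(coef, -coef))
}

.sum_objective <- function(tfa) {
  nR <- nrow(tfa$model$reactions)
  list(ind = c(tfa$idx$F, tfa$idx$B), val = rep(1, 2L * nR))
}

.net_fluxes <- function(tfa, x) {
  nR <- nrow(tfa$model$reactions)
  v <- x[tfa$idx$F] - x[tfa$idx$B]
  names(v) <- tfa$model$reactions$id
  v
}

#' Flux balance analysis on a built problem
#'
#' @param tfa a [build_tfa()] problem.
#' @param objective reaction id to optimize (default: biomass reaction).
#' @param direction `"max"` or `"min"`.
#' @return list: `status`, `objective`, `fluxes` (named net flux vector),
#'   `x` (raw solution).
#' @export
solve_fba <- function(tfa, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(objective)) objective <- tfa$model$biomass
  ob <- .net_objective(tfa, objective)
  res <- solve_lp1(tfa$problem,
                   queries = list(lp_objective(ob$ind, ob$val, direction)))$queries[[1]]
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  }
  x <- unlist(res$x)
  list(status = "optimal", objective = res$objective,
       fluxes = .net_fluxes(tfa, x), x = x)
}

#' Parsimonious FBA: fix the biomass optimum, then minimize total flux
#'
#' @inheritParams solve_fba
#' @param fix_tol absolute slack used when fixing stage optima.
#' @return list: `status`, `biomass`, `min_total_flux`, `fluxes`, `x`.
#' @export
solve_pfba <- function(tfa, fix_tol = 1e-9) {
  ob <- .net_objective(tfa, tfa$model$biomass)
  so <- .sum_objective(tfa)
  res <- solve_lp1(tfa$problem, stages = list(
    lp_objective(ob$ind, ob$val, "max", fix = TRUE, tol = fix_tol),
    lp_objective(so$ind, so$val, "min", fix = FALSE)
  ))
  st <- vapply(res$stages, `[[`, "", "status")
  if (any(st != "optimal")) {
    return(list(status = st[st != "optimal"][1], biomass = NA_real_,
                min_total_flux = NA_real_, fluxes = NULL))
  }
  x <- unlist(res$stages[[2]]$x)
  list(status = "optimal", biomass = res$stages[[1]]$objective,
       min_total_flux = res$stages[[2]]$objective,
       fluxes = .net_fluxes(tfa, x), x = x)
}

#' Flux variability analysis (plain, thermodynamic, or parsimonious)
#'
#' With `parsimonious = TRUE` this is pTFVA: the biomass optimum is fixed,
#' the minimum total flux sum is fixed as an additional constraint, and
#' each reaction's net flux is then minimized and maximized.  With
#' `parsimonious = FALSE` and a thermodynamic problem it is TFVA; on a
#' plain problem it is ordinary FVA.
#'
#' @inheritParams solve_fba
#' @param reactions reaction ids to analyse (default: all).
#' @param parsimonious constrain total flux to the pFBA minimum first.
#' @param fix_biomass fix the biomass optimum before the sweeps.
#' @param fix_tol absolute slack used when fixing stage optima.
#' @param keep_solutions retain every extreme solution vector (used for
#'   second-law auditing).
#' @param instance label stored on the result.
#' @return a `flux_ranges` data.frame (`reaction`, `subsystem`, `min`,
#'   `max`) with attributes `state` (`"raw"`), `biomass`,
#'   `min_total_flux`, `instance` and optionally `solutions`.
#' @export
solve_fva <- function(tfa, reactions = NULL, parsimonious = FALSE,
                      fix_biomass = TRUE, fix_tol = 1e-9,
                      keep_solutions = FALSE, instance = "instance") {
  rxns <- if (is.null(reactions)) tfa$model$reactions$id else reactions
  stages <- list()
  ob <- .net_objective(tfa, tfa$model$biomass)
  if (fix_biomass) {
    stages <- c(stages, list(lp_objective(ob$ind, ob$val, "max",
                                          fix = TRUE, tol = fix_tol)))
  }
  if (parsimonious) {
    so <- .sum_objective(tfa)
    stages <- c(stages, list(lp_objective(so$ind, so$val, "min",
                                          fix = TRUE, tol = fix_tol)))
  }
  queries <- list()
  for (r in rxns) {
    o <- .net_objective(tfa, r)
    queries <- c(queries, list(lp_objective(o$ind, o$val, "min"),
                               lp_objective(o$ind, o$val, "max")))
  }
  res <- solve_lp1(tfa$problem, stages = stages, queries = queries)
  for (s in res$stages) {
    if (s$status != "optimal") {
      stop("stage solve returned status '", s$status,
           "' while preparing the variability analysis")
    }
  }
  n <- length(rxns)
  mins <- maxs <- rep(NA_real_, n)
  sols <- if (keep_solutions) vector("list", 2L * n) else NULL
  for (k in seq_len(n)) {
    lo <- res$queries[[2 * k - 1]]
    hi <- res$queries[[2 * k]]
    if (lo$status == "optimal") mins[k] <- lo$objective
    if (hi$status == "optimal") maxs[k] <- hi$objective
    if (lo$status != "optimal" || hi$status != "optimal") {
      warning("variability solve failed for reaction ", rxns[k],
              " (", lo$status, "/", hi$status, "); range reported as missing")
    }
    if (keep_solutions) {
      sols[[2 * k - 1]] <- if (lo$status == "optimal") unlist(lo$x)
      sols[[2 * k]] <- if (hi$status == "optimal") unlist(hi$x)
    }
  }
  biomass <- if (fix_biomass) res$stages[[1]]$objective else NA_real_
  mtf <- if (parsimonious) res$stages[[length(res$stages)]]$objective else NA_real_
  out <- data.frame(
    reaction = rxns,
    subsystem = tfa$model$reactions$subsystem[match(rxns, tfa$model$reactions$id)],
    min = mins, max = maxs, stringsAsFactors = FALSE)
  flux_ranges(out, state = "raw", biomass = biomass, min_total_flux = mtf,
              instance = instance, solutions = sols)
}

#' @rdname solve_fva
#' @export
solve_ptfva <- function(tfa, reactions = NULL, fix_tol = 1e-9,
                        keep_solutions = FALSE, instance = "instance") {
  solve_fva(tfa, reactions = reactions, parsimonious = TRUE,
            fix_biomass = TRUE, fix_tol = fix_tol,
            keep_solutions = keep_solutions, instance = instance)
}

#' @rdname solve_fva
#' @export
solve_tfva <- function(tfa, reactions = NULL, fix_tol = 1e-9,
                       keep_solutions = FALSE, instance = "instance") {
  solve_fva(tfa, reactions = reactions, parsimonious = FALSE,
            fix_biomass = TRUE, fix_tol = fix_tol,
            keep_solutions = keep_solutions, instance = instance)
}

#' Construct / validate a flux-range set
#' @param df data.frame with columns `reaction`, `subsystem`, `min`, `max`.
#' @param state normalization state.
#' @param biomass biomass flux of the instance (raw state).
#' @param min_total_flux the pFBA flux-sum minimum, if applicable.
#' @param instance instance label.
#' @param solutions optional list of raw extreme solutions.
#' @return the annotated data.frame, class `"flux_ranges"`.
#' @export
flux_ranges <- function(df, state = "raw", biomass = NA_real_,
                        min_total_flux = NA_real_, instance = "instance",
                        solutions = NULL) {
  stopifnot(all(c("reaction", "subsystem", "min", "max") %in% names(df)))
  ok <- is.na(df$min) | is.na(df$max) | df$min <= df$max + 1e-7
  if (!all(ok)) stop("flux ranges must satisfy min <= max")
  structure(df, class = c("flux_ranges", "data.frame"), state = state,
            biomass = biomass, min_total_flux = min_total_flux,
            instance = instance, solutions = solutions)
}

#' Audit a solution vector against the second law
#'
#' Returns every estimable reaction whose net flux exceeds `flux_tol` in
#' one direction while its \eqn{\Delta_r G'} solution value does not have
#' the opposite sign.
#'
#' @param tfa a thermodynamic [build_tfa()] problem.
#' @param x a raw solution vector from one of the solvers.
#' @param flux_tol net-flux tolerance.
#' @return data.frame of violations (zero rows when the solution is
#'   thermodynamically consistent).
#' @export
second_law_violations <- function(tfa, x, flux_tol = 1e-6) {
  stopifnot(tfa$has_thermo)
  v <- .net_fluxes(tfa, x)
  est <- tfa$estimable
  drg <- x[tfa$idx$drG[est]]
  bad <- (v[est] > flux_tol & drg >= 0) | (v[est] < -flux_tol & drg <= 0)
  data.frame(reaction = est[bad], net_flux = unname(v[est][bad]),
             drG = unname(drg[bad]), stringsAsFactors = FALSE)
}
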