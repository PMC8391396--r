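.row_index <- function(prob, name) {
  i <- match(name, prob$rnames)
  if (is.na(i)) stop("no constraint row named ", name)
  i
}

.set_row_bounds <- function(prob, name, lb, ub) {
  i <- .row_index(prob, name)
  prob$rlb[i] <- lb
  prob$rub[i] <- ub
  prob
}

#' Extract key energy-metabolism fluxes from a range set
#'
#' Reports oxygen uptake, ATP synthase flux, fermentation-product
#' (lactate) secretion and total fatty-acid influx (the sum over the
#' configured fatty-acid exchanges), in the normalization state of the
#' supplied ranges.  Uptake quantities are reported positive (influx =
#' minus the exchange flux).
#'
#' @param ranges a `flux_ranges` object.
#' @param roles named list mapping `oxygen_uptake`, `atp_synthase`,
#'   `lactate_secretion` to reaction ids and `fatty_acid_exchanges` to a
#'   character vector of exchange ids.
#' @return data.frame: `role`, `reaction`, `min`, `max` (including one
#'   row per fatty-acid substrate and a `fatty_acid_influx` total).
#' @export
key_fluxes <- function(ranges, roles) {
  need <- c("oxygen_uptake", "atp_synthase", "lactate_secretion",
            "fatty_acid_exchanges")
  miss <- setdiff(need, names(roles))
  if (length(miss)) stop("unmapped roles: ", paste(miss, collapse = ", "))
  get <- function(id) {
    i <- match(id, ranges$reaction)
    if (anyNA(i)) stop("role reaction not in range set: ",
                       paste(id[is.na(i)], collapse = ", "))
    ranges[i, , drop = FALSE]
  }
  o2 <- get(roles$oxygen_uptake)
  atp <- get(roles$atp_synthase)
  lac <- get(roles$lactate_secretion)
  fa <- get(roles$fatty_acid_exchanges)
  rows <- list(
    data.frame(role = "oxygen_uptake", reaction = o2$reaction,
               min = -o2$max, max = -o2$min, stringsAsFactors = FALSE),
    data.frame(role = "atp_synthase", reaction = atp$reaction,
               min = atp$min, max = atp$max, stringsAsFactors = FALSE),
    data.frame(role = "lactate_secretion", reaction = lac$reaction,
               min = lac$min, max = lac$max, stringsAsFactors = FALSE),
    data.frame(role = "fatty_acid_influx", reaction = fa$reaction,
               min = -fa$max, max = -fa$min, stringsAsFactors = FALSE),
    data.frame(role = "fatty_acid_influx_total",
               reaction = paste(fa$reaction, collapse = "+"),
               min = sum(-fa$max), max = sum(-fa$min),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.influx_objective <- function(tfa, rxns) {
  o <- .net_objective(tfa, rxns)
  o$val <- -o$val   # influx = minus net exchange flux
  o
}

#' Minimum fatty-acid influx as a function of pinned oxygen influx
#'
#' For each grid value the oxygen exchange is pinned to that uptake
#' (equality by default; upper-bound mode behind `pin`), total
#' fatty-acid influx is minimized, and the per-substrate breakdown is
#' resolved by lexicographic secondary minimization in the configured
#' substrate order.  The default grid starts at the minimum feasible
#' oxygen influx.  Fluxes are reported raw and divided by the realized
#' biomass flux of each point (growth-normalized).
#'
#' @param tfa a built [build_tfa()] problem with the instance bounds
#'   (biomass bounds active).
#' @param roles role map as in [key_fluxes()].
#' @param o2_grid increasing vector of oxygen-influx values; `NULL` for
#'   an automatic grid from the feasible minimum to 1.5x the
#'   parsimonious operating uptake.
#' @param n_grid automatic grid size.
#' @param pin `"equality"` (pin the exchange) or `"upper"` (cap it).
#' @param parsimonious re-minimize and fix the total flux sum at every
#'   grid point before the sweep objective (the pTFVA convention).
#' @return data.frame of class `"envelope_curve"`: `o2_influx`,
#'   `fa_influx`, one column per substrate, `biomass`, `feasible`, plus
#'   `fa_influx_per_biomass`.
#' @export
sweep_min_fa <- function(tfa, roles, o2_grid = NULL, n_grid = 12,
                         pin = c("equality", "upper"), parsimonious = TRUE) {
  pin <- match.arg(pin)
  o2 <- roles$oxygen_uptake
  fas <- roles$fatty_acid_exchanges
  net_name <- paste0("net_", o2)
  ub0 <- tfa$problem$rub[.row_index(tfa$problem, net_name)]

  if (is.null(o2_grid)) {
    o2_obj <- .influx_objective(tfa, o2)
    res <- solve_lp1(tfa$problem, queries = list(
      lp_objective(o2_obj$ind, o2_obj$val, "min")))$queries[[1]]
    if (res$status != "optimal") stop("instance infeasible: ", res$status)
    u_lo <- res$objective
    pf <- solve_pfba(tfa)
    u_op <- -pf$fluxes[[o2]]
    hi <- max(u_op * 1.5, u_lo * 1.5 + 1e-6)
    o2_grid <- seq(u_lo, hi, length.out = n_grid)
  }
  if (any(diff(o2_grid) <= 0)) stop("o2_grid must be strictly increasing")

  tot <- .influx_objective(tfa, fas)
  so <- .sum_objective(tfa)
  jobs <- lapply(o2_grid, function(u) {
    prob <- if (pin == "equality") {
      .set_row_bounds(tfa$problem, net_name, -u, -u)
    } else {
      .set_row_bounds(tfa$problem, net_name, -u, ub0)
    }
    stages <- list()
    if (parsimonious) {
      stages <- list(lp_objective(so$ind, so$val, "min", fix = TRUE))
    }
    stages <- c(stages, list(lp_objective(tot$ind, tot$val, "min", fix = TRUE)))
    for (s in fas) {
      o <- .influx_objective(tfa, s)
      stages <- c(stages, list(lp_objective(o$ind, o$val, "min", fix = TRUE)))
    }
    list(problem = prob, stages = stages)
  })
  res <- solve_lp(jobs)

  n <- length(o2_grid)
  out <- data.frame(o2_influx = o2_grid, fa_influx = NA_real_,
                    biomass = NA_real_, feasible = FALSE)
  for (s in fas) out[[s]] <- NA_real_
  bio_i <- match(tfa$model$biomass, tfa$model$reactions$id)
  off <- if (parsimonious) 1L else 0L
  for (k in seq_len(n)) {
    st <- res[[k]]$stages
    ok <- all(vapply(st, `[[`, "", "status") == "optimal")
    out$feasible[k] <- ok
    if (!ok) next
    out$fa_influx[k] <- st[[off + 1]]$objective
    for (j in seq_along(fas)) out[[fas[j]]][k] <- st[[off + 1 + j]]$objective
    x <- unlist(st[[length(st)]]$x)
    out$biomass[k] <- x[tfa$idx$F[bio_i]] - x[tfa$idx$B[bio_i]]
  }
  out$fa_influx_per_biomass <- out$fa_influx / out$biomass
  structure(out, class = c("envelope_curve", "data.frame"),
            swept = "oxygen_influx", pin = pin)
}

#' Minimum oxygen influx as a function of pinned total fatty-acid influx
#'
#' Pins the summed fatty-acid influx (equality on the sum across the
#' configured exchanges), minimizes the oxygen influx, and repeats for
#' each requested biomass constraint (one curve per level, biomass
#' pinned to the level).  The grid argmin of every curve is reported in
#' the `"argmin"` attribute.
#'
#' @inheritParams sweep_min_fa
#' @param fa_grid increasing vector of total fatty-acid influx values.
#' @param biomass_levels biomass-flux values (model units); `NULL` keeps
#'   the instance's biomass bounds.
#' @return data.frame of class `"envelope_curve"`: `fa_influx`,
#'   `biomass_level`, `o2_influx`, `feasible`.
#' @export
sweep_min_o2 <- function(tfa, roles, fa_grid, biomass_levels = NULL,
                         pin = c("equality", "upper"), parsimonious = TRUE) {
  pin <- match.arg(pin)
  if (any(diff(fa_grid) <= 0)) stop("fa_grid must be strictly increasing")
  fas <- roles$fatty_acid_exchanges
  o2_obj <- .influx_objective(tfa, roles$oxygen_uptake)
  fa_net <- .net_objective(tfa, fas)

  # appended row: sum of fatty-acid net exchange fluxes
  base <- lp_add_rows(tfa$problem, list(fa_net$ind), list(fa_net$val),
                      -Inf, Inf, names = "fa_total")
  bio_name <- paste0("net_", tfa$model$biomass)
  i_bio <- .row_index(base, bio_name)
  lvls <- if (is.null(biomass_levels)) NA_real_ else biomass_levels

  grid <- expand.grid(fa = fa_grid, lvl = lvls, KEEP.OUT.ATTRS = FALSE)
  jobs <- lapply(seq_len(nrow(grid)), function(k) {
    prob <- base
    f <- grid$fa[k]
    # equality: influx pinned to f; upper: influx capped at f
    prob <- if (pin == "equality") {
      .set_row_bounds(prob, "fa_total", -f, -f)
    } else {
      .set_row_bounds(prob, "fa_total", -f, 0)
    }
    if (!is.na(grid$lvl[k])) {
      prob$rlb[i_bio] <- grid$lvl[k]
      prob$rub[i_bio] <- grid$lvl[k]
    }
    stages <- list()
    if (parsimonious) {
      so <- .sum_objective(tfa)
      stages <- list(lp_objective(so$ind, so$val, "min", fix = TRUE))
    }
    stages <- c(stages, list(lp_objective(o2_obj$ind, o2_obj$val, "min",
                                          fix = FALSE)))
    list(problem = prob, stages = stages)
  })
  res <- solve_lp(jobs)
  out <- data.frame(fa_influx = grid$fa, biomass_level = grid$lvl,
                    o2_influx = NA_real_, feasible = FALSE)
  for (k in seq_len(nrow(grid))) {
    st <- res[[k]]$stages[[length(res[[k]]$stages)]]
    if (st$status == "optimal") {
      out$o2_influx[k] <- st$objective
      out$feasible[k] <- TRUE
    }
  }
  argmin <- do.call(rbind, lapply(
    split(out, factor(out$biomass_level, exclude = NULL)), function(d) {
    d <- d[d$feasible, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[which.min(d$o2_influx), c("biomass_level", "fa_influx", "o2_influx")]
  }))
  structure(out, class = c("envelope_curve", "data.frame"),
            swept = "fatty_acid_influx", pin = pin, argmin = argmin)
}
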