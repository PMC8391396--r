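.check_universe <- function(a, b) {
  sym <- c(setdiff(a$reaction, b$reaction), setdiff(b$reaction, a$reaction))
  if (length(sym)) {
    stop("flux-range sets cover different reactions: ",
         paste(sym, collapse = ", "))
  }
}

#' Normalize a flux-range set by the instance's biomass flux
#'
#' Divides every range endpoint by the instance's biomass flux (the
#' pFBA biomass value stored on the range set), removing growth-magnitude
#' effects; the biomass reaction itself maps to \[1, 1\].
#'
#' @param ranges a `flux_ranges` object in `"raw"` state.
#' @param tol smallest admissible biomass flux.
#' @return the normalized `flux_ranges` (state `"growth_normalized"`).
#' @export
growth_normalize <- function(ranges, tol = 1e-9) {
  if (!identical(attr(ranges, "state"), "raw")) {
    stop("growth_normalize expects ranges in 'raw' state")
  }
  b <- attr(ranges, "biomass")
  if (is.na(b) || b <= tol) {
    stop("biomass flux is zero (or unknown); growth normalization undefined")
  }
  out <- ranges
  out$min <- ranges$min / b
  out$max <- ranges$max / b
  flux_ranges(as.data.frame(out), state = "growth_normalized", biomass = 1,
              min_total_flux = attr(ranges, "min_total_flux") / b,
              instance = attr(ranges, "instance"))
}

#' Flag reactions whose flux ranges differ in both bounds
#'
#' The relative difference per bound is
#' \eqn{|x_a - x_b| / \max(|x_a|, |x_b|, \delta)}; a reaction is flagged
#' when BOTH the lower-bound and the upper-bound relative differences
#' reach the threshold.  The direction records which instance has the
#' higher range midpoint.  Reactions marked incomparable (by
#' [control_ratio()]) in either set are excluded from flagging.
#'
#' @param a,b `flux_ranges` in the same normalization state over the
#'   same reactions.
#' @param threshold relative-difference cutoff (default 0.15).
#' @param delta denominator floor.
#' @return a `comparison_report` data.frame: `reaction`, `subsystem`,
#'   `rel_lb`, `rel_ub`, `flagged`, `direction`, `comparable`.
#' @export
flag_differences <- function(a, b, threshold = 0.15, delta = 1e-8) {
  .check_universe(a, b)
  if (!identical(attr(a, "state"), attr(b, "state"))) {
    stop("flux-range sets are in different normalization states")
  }
  b <- b[match(a$reaction, b$reaction), , drop = FALSE]
  rel <- function(x, y) abs(x - y) / pmax(abs(x), abs(y), delta)
  rel_lb <- rel(a$min, b$min)
  rel_ub <- rel(a$max, b$max)
  comparable <- rep(TRUE, nrow(a))
  if (!is.null(a$comparable)) comparable <- comparable & a$comparable
  if (!is.null(b$comparable)) comparable <- comparable & b$comparable
  flagged <- comparable & rel_lb >= threshold & rel_ub >= threshold
  mid_a <- (a$min + a$max) / 2
  mid_b <- (b$min + b$max) / 2
  direction <- ifelse(abs(mid_a - mid_b) <= delta, "equal",
                      ifelse(mid_a > mid_b, "a", "b"))
  structure(data.frame(
    reaction = a$reaction, subsystem = a$subsystem,
    rel_lb = rel_lb, rel_ub = rel_ub, flagged = flagged,
    direction = direction, comparable = comparable,
    stringsAsFactors = FALSE),
    class = c("comparison_report", "data.frame"),
    threshold = threshold, delta = delta,
    instances = c(attr(a, "instance"), attr(b, "instance")),
    state = attr(a, "state"))
}

#' Feature-scale flux ranges across a set of instances
#'
#' Per reaction, min-max scales all endpoint values (both bounds of
#' every instance jointly) onto \[0, 1\].  Reactions whose endpoints are
#' identical across all instances map to 0.5 everywhere, which keeps the
#' downstream control ratios defined and equal (hence never spuriously
#' flagged).
#'
#' @param sets list of `flux_ranges` (same reactions, same state,
#'   typically `"growth_normalized"`).
#' @param tol degeneracy tolerance on the endpoint spread.
#' @return list of scaled `flux_ranges` (state `"feature_scaled"`).
#' @export
feature_scale <- function(sets, tol = 1e-12) {
  stopifnot(length(sets) >= 2)
  for (s in sets[-1]) .check_universe(sets[[1]], s)
  states <- vapply(sets, attr, "", "state")
  if (length(unique(states)) != 1) {
    stop("all sets must be in the same normalization state")
  }
  ref <- sets[[1]]$reaction
  sets <- lapply(sets, function(s) s[match(ref, s$reaction), , drop = FALSE])
  lo <- do.call(pmin, c(lapply(sets, `[[`, "min"), lapply(sets, `[[`, "max")))
  hi <- do.call(pmax, c(lapply(sets, `[[`, "min"), lapply(sets, `[[`, "max")))
  span <- hi - lo
  degenerate <- span < tol
  lapply(sets, function(s) {
    out <- as.data.frame(s)
    out$min <- ifelse(degenerate, 0.5, (s$min - lo) / span)
    out$max <- ifelse(degenerate, 0.5, (s$max - lo) / span)
    flux_ranges(out, state = "feature_scaled",
                instance = attr(s, "instance"))
  })
}

#' Divide a resistant instance's scaled ranges by its paired control
#'
#' Per bound, the ratio resistant/control with the denominator floored
#' at `delta`; reactions whose control value falls below `delta` in
#' either bound are marked incomparable and excluded from downstream
#' flagging (their count is reported in a message).  Ratio endpoints are
#' re-sorted so that min <= max.
#'
#' @param resistant,sensitive `flux_ranges` in `"feature_scaled"` state.
#' @param delta denominator floor.
#' @return a `flux_ranges` in `"control_ratio"` state with an extra
#'   `comparable` column.
#' @export
control_ratio <- function(resistant, sensitive, delta = 1e-8) {
  .check_universe(resistant, sensitive)
  if (!identical(attr(resistant, "state"), "feature_scaled") ||
      !identical(attr(sensitive, "state"), "feature_scaled")) {
    stop("control_ratio expects feature-scaled range sets")
  }
  sensitive <- sensitive[match(resistant$reaction, sensitive$reaction), ,
                         drop = FALSE]
  comparable <- sensitive$min >= delta & sensitive$max >= delta
  r1 <- resistant$min / pmax(sensitive$min, delta)
  r2 <- resistant$max / pmax(sensitive$max, delta)
  out <- as.data.frame(resistant)
  out$min <- pmin(r1, r2)
  out$max <- pmax(r1, r2)
  out$comparable <- comparable
  if (any(!comparable)) {
    message(sum(!comparable),
            " reactions incomparable (control below the ratio floor)")
  }
  flux_ranges(out, state = "control_ratio",
              instance = paste0(attr(resistant, "instance"), "/",
                                attr(sensitive, "instance")))
}

#' Summarize flagged reactions by subsystem
#'
#' Reports, per subsystem, the proportion of member reactions flagged
#' and the subsystem's share of all flagged reactions after removing the
#' excluded subsystems (shares sum to 1 when any non-excluded reaction
#' is flagged).  Subsystems without any flagged member are omitted.
#'
#' @param report a [flag_differences()] result.
#' @param exclude subsystems excluded from the share computation
#'   (typically `"transport"`).
#' @return data.frame: `subsystem`, `n`, `n_flagged`, `proportion`,
#'   `share`, `n_higher_a`, `n_higher_b`.
#' @export
subsystem_summary <- function(report, exclude = "transport") {
  unknown <- setdiff(exclude, unique(report$subsystem))
  if (length(unknown)) {
    warning("excluded subsystems not present: ", paste(unknown, collapse = ", "))
  }
  agg <- do.call(rbind, lapply(split(report, report$subsystem), function(d) {
    data.frame(subsystem = d$subsystem[1], n = nrow(d),
               n_flagged = sum(d$flagged),
               proportion = mean(d$flagged),
               n_higher_a = sum(d$flagged & d$direction == "a"),
               n_higher_b = sum(d$flagged & d$direction == "b"),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[agg$n_flagged > 0, , drop = FALSE]
  total <- sum(agg$n_flagged[!agg$subsystem %in% exclude])
  agg$share <- ifelse(agg$subsystem %in% exclude, NA_real_,
                      if (total > 0) agg$n_flagged / total else NA_real_)
  agg
}
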