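#' Fit growth and all exchange rates for one condition dataset
#'
#' Runs [fit_growth()] on the cell counts, builds the
#' [biomass_calibration()] from the dataset's dry mass per cell, and
#' fits one specific exchange rate per measured medium metabolite; the
#' abiotic decay correction is applied only to the metabolite that has a
#' cell-free control series.
#'
#' @param dataset a `condition_dataset` (see [simulate_condition()]).
#' @param robust use the soft-L1 loss for the growth fit.
#' @return list: `growth`, `calib`, `exchanges` (named list of
#'   [fit_exchange()] results), `id`.
#' @export
fit_condition <- function(dataset, robust = TRUE) {
  growth <- fit_growth(dataset$counts$time_h, dataset$counts$cells,
                       robust = robust)
  calib <- biomass_calibration(dataset$m_dw, dataset$se_m_dw)
  decay_met <- unique(dataset$cellfree$metabolite)
  mets <- unique(dataset$medium$metabolite)
  exchanges <- lapply(mets, function(m) {
    d <- dataset$medium[dataset$medium$metabolite == m, ]
    ab <- if (length(decay_met) && m %in% decay_met) dataset$cellfree else NULL
    fit_exchange(dataset$times, d, growth, calib, abiotic = ab,
                 metabolite = m)
  })
  names(exchanges) <- mets
  list(id = dataset$id, growth = growth, calib = calib, exchanges = exchanges)
}

#' Apply fitted rates as flux bounds on a model instance
#'
#' Exchange reactions named by `exchange_map` receive the fitted
#' `[lower, upper]` interval (secretion-positive convention); the
#' biomass reaction receives [growth_bounds()].
#'
#' @param model a [network_model()].
#' @param fits a [fit_condition()] result.
#' @param exchange_map named character vector, metabolite -> exchange
#'   reaction id.
#' @return the constrained model.
#' @export
constrain_instance <- function(model, fits, exchange_map) {
  for (m in names(fits$exchanges)) {
    rxn <- exchange_map[[m]]
    if (is.null(rxn) || !rxn %in% model$reactions$id) {
      stop("no exchange reaction mapped for measured metabolite ", m)
    }
    ex <- fits$exchanges[[m]]
    model <- set_bounds(model, rxn, ex$lower, ex$upper)
  }
  gb <- growth_bounds(fits$growth, fits$calib)
  set_bounds(model, model$biomass, gb[1], gb[2])
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparison pipeline on a four-condition bundle
#'
#' Executes, per condition: rate fitting, instance constraint
#' application, thermodynamic problem construction and pTFVA; then the
#' normalization cascade: dual-bound flagging before and after
#' growth-rate normalization for each resistant/control pair, feature
#' scaling across the four instances, division of each resistant
#' instance by its control, and the cross-resistance comparison of the
#' two control-ratio sets, with subsystem summaries.
#'
#' @param bundle a [make_bundle()] result, or any list with elements
#'   `model`, `thermo`, `conditions` (named `condition_dataset`s),
#'   `pairing` and (optionally) `truth$exchange_map`.
#' @param threshold dual-bound relative-difference cutoff.
#' @param exclude subsystems excluded from share summaries.
#' @param exchange_map metabolite -> exchange reaction map; defaults to
#'   the bundle's own map.
#' @param robust robust growth fits.
#' @param keep_solutions retain pTFVA extreme solutions (second-law
#'   audits).
#' @return list of class `"pipeline_result"`; see Details.
#' @details The result contains `fits`, `instances` (per condition:
#'   constrained model, `tfa` problem, raw and growth-normalized
#'   ranges), `reports` (`pre` and `post` per pair, `cross` for the
#'   resistant-vs-resistant comparison), `summaries` (subsystem tables)
#'   and `counts` (flag counts at each cascade stage).
#' @export
run_pipeline <- function(bundle, threshold = 0.15, exclude = "transport",
                         exchange_map = NULL, robust = TRUE,
                         keep_solutions = FALSE) {
  if (is.null(exchange_map)) exchange_map <- bundle$truth$exchange_map
  if (is.null(exchange_map)) stop("config error: no exchange map available")
  pairing <- bundle$pairing
  .validate_pairing(pairing, names(bundle$conditions))

  fits <- list()
  instances <- list()
  for (id in names(bundle$conditions)) {
    ds <- bundle$conditions[[id]]
    ft <- .stage(paste0("fit:", id), fit_condition(ds, robust = robust))
    mdl <- .stage(paste0("constrain:", id),
                  constrain_instance(bundle$model, ft, exchange_map))
    tfa <- .stage(paste0("build:", id),
                  build_tfa(mdl, bundle$thermo, conc_bounds = ds$conc_bounds))
    raw <- .stage(paste0("ptfva:", id),
                  solve_ptfva(tfa, keep_solutions = keep_solutions,
                              instance = id))
    fits[[id]] <- ft
    instances[[id]] <- list(model = mdl, tfa = tfa, ranges_raw = raw,
                            ranges_norm = growth_normalize(raw))
  }

  reports <- list(pre = list(), post = list())
  counts <- list()
  for (p in names(pairing)) {
    res <- pairing[[p]]$resistant
    ctl <- pairing[[p]]$control
    reports$pre[[p]] <- flag_differences(instances[[res]]$ranges_raw,
                                         instances[[ctl]]$ranges_raw,
                                         threshold = threshold)
    reports$post[[p]] <- flag_differences(instances[[res]]$ranges_norm,
                                          instances[[ctl]]$ranges_norm,
                                          threshold = threshold)
    counts[[paste0("pre_", p)]] <- sum(reports$pre[[p]]$flagged)
    counts[[paste0("post_", p)]] <- sum(reports$post[[p]]$flagged)
  }

  scaled <- feature_scale(lapply(instances, `[[`, "ranges_norm"))
  names(scaled) <- names(instances)
  ratios <- list()
  for (p in names(pairing)) {
    ratios[[p]] <- control_ratio(scaled[[pairing[[p]]$resistant]],
                                 scaled[[pairing[[p]]$control]])
  }
  pn <- names(pairing)
  cross <- flag_differences(ratios[[pn[1]]], ratios[[pn[2]]],
                            threshold = threshold)
  counts$cross <- sum(cross$flagged)
  reports$cross <- cross

  summaries <- list(cross = subsystem_summary(cross, exclude = exclude))
  for (p in pn) {
    summaries[[paste0("post_", p)]] <-
      subsystem_summary(reports$post[[p]], exclude = exclude)
  }

  structure(list(fits = fits, instances = instances, scaled = scaled,
                 ratios = ratios, reports = reports, summaries = summaries,
                 counts = counts, threshold = threshold),
            class = "pipeline_result")
}

.validate_pairing <- function(pairing, condition_ids) {
  if (length(pairing) < 1) stop("config error: empty condition pairing")
  for (p in names(pairing)) {
    pr <- pairing[[p]]
    if (is.null(pr$resistant) || is.null(pr$control)) {
      stop("config error: pair '", p,
           "' must name exactly one resistant and one control condition")
    }
    miss <- setdiff(c(pr$resistant, pr$control), condition_ids)
    if (length(miss)) {
      stop("config error: pairing references unknown conditions: ",
           paste(miss, collapse = ", "))
    }
  }
  ctrl <- vapply(pairing, function(p) p$control, "")
  res <- vapply(pairing, function(p) p$resistant, "")
  if (anyDuplicated(res)) {
    stop("config error: a resistant condition appears in more than one pair")
  }
  invisible(TRUE)
}

#' Read and validate a pipeline run configuration (YAML)
#'
#' The configuration lists input paths (`model`, `thermo`, `counts`,
#' `medium`, `cellfree`, `conc_bounds`), the resistant-to-control
#' `pairing`, the comparison `threshold`, the `exchange_map`, excluded
#' subsystems, the default log-concentration range and the seed.
#'
#' @param path YAML file.
#' @return validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$threshold)) cfg$threshold <- 0.15
  if (cfg$threshold <= 0 || cfg$threshold >= 1) {
    stop("config error: threshold must lie in (0, 1)")
  }
  if (is.null(cfg$paths) || is.null(cfg$paths$model)) {
    stop("config error: paths$model is required")
  }
  if (is.null(cfg$pairing)) stop("config error: pairing is required")
  for (p in names(cfg$pairing)) {
    if (is.null(cfg$pairing[[p]]$resistant) || is.null(cfg$pairing[[p]]$control)) {
      stop("config error: pair '", p, "' needs 'resistant' and 'control'")
    }
  }
  if (is.null(cfg$exclude)) cfg$exclude <- "transport"
  structure(cfg, class = "run_config")
}

#' Load bundle-shaped inputs from the files named in a run config
#'
#' @param cfg a [read_run_config()] result.
#' @return a list usable by [run_pipeline()].
#' @export
load_run_inputs <- function(cfg) {
  model <- read_model_sbml(cfg$paths$model)
  thermo <- read_thermo_tsv(cfg$paths$thermo)
  counts <- utils::read.delim(cfg$paths$counts, stringsAsFactors = FALSE)
  medium <- utils::read.delim(cfg$paths$medium, stringsAsFactors = FALSE)
  cellfree <- if (!is.null(cfg$paths$cellfree))
    utils::read.delim(cfg$paths$cellfree, stringsAsFactors = FALSE)
  cb <- if (!is.null(cfg$paths$conc_bounds))
    utils::read.delim(cfg$paths$conc_bounds, stringsAsFactors = FALSE)
  ids <- unique(counts$condition)
  conditions <- lapply(ids, function(id) {
    structure(list(
      id = id, label = NA_character_, pair = NA_character_,
      counts = counts[counts$condition == id, ],
      medium = medium[medium$condition == id, ],
      cellfree = if (!is.null(cellfree)) cellfree[cellfree$condition == id, ]
                 else data.frame(metabolite = character(0)),
      conc_bounds = if (!is.null(cb)) cb[cb$condition == id, ] else NULL,
      m_dw = cfg$m_dw %||% 4e-10,
      se_m_dw = cfg$se_m_dw %||% 0,
      times = sort(unique(counts$time_h[counts$condition == id]))
    ), class = "condition_dataset")
  })
  names(conditions) <- ids
  list(model = model, thermo = thermo, conditions = conditions,
       pairing = cfg$pairing,
       truth = list(exchange_map = unlist(cfg$exchange_map)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
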