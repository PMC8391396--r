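test_that("SBML write/read round trip preserves the model exactly", {
  toy <- make_toy_model(1, 14)
  f <- tempfile(fileext = ".xml")
  write_model_sbml(toy$model, f)
  m2 <- read_model_sbml(f)

  S1 <- stoich_matrix(toy$model)
  S2 <- stoich_matrix(m2)[rownames(S1), colnames(S1)]
  expect_identical(unname(S1), unname(S2))

  i <- match(toy$model$reactions$id, m2$reactions$id)
  expect_equal(m2$reactions$lower[i], toy$model$reactions$lower)
  expect_equal(m2$reactions$upper[i], toy$model$reactions$upper)
  expect_equal(m2$reactions$subsystem[i], toy$model$reactions$subsystem)
  expect_equal(m2$biomass, toy$model$biomass)
  j <- match(toy$model$compartments$id, m2$compartments$id)
  expect_equal(m2$compartments$pH[j], toy$model$compartments$pH)
  expect_equal(m2$compartments$membrane_potential[j],
               toy$model$compartments$membrane_potential)
  k <- match(toy$model$metabolites$id, m2$metabolites$id)
  expect_equal(m2$metabolites$thermo_id[k], toy$model$metabolites$thermo_id)
  unlink(f)
})

test_that("degraded SBML inputs are handled as specified", {
  toy <- make_toy_model(1, 10)
  f <- tempfile(fileext = ".xml")
  write_model_sbml(toy$model, f)
  txt <- readLines(f)

  # drop the subsystem groups -> warning, subsystems default to unassigned
  g0 <- grep("groups:listOfGroups", txt)
  writeLines(txt[-(g0[1]:g0[2])], f)
  expect_warning(m <- read_model_sbml(f), "no subsystem groups")
  expect_true(all(m$reactions$subsystem == "unassigned"))

  # drop the objective -> configuration error
  o0 <- grep("fbc:listOfObjectives", txt)
  writeLines(txt[-(o0[1]:o0[2])], f)
  expect_error(read_model_sbml(f), "no biomass objective")

  # malformed XML -> parse error naming the file
  writeLines(c(txt[1:5], "<unclosed"), f)
  expect_error(read_model_sbml(f), "malformed SBML")
  unlink(f)
})

test_that("enzyme-capacity pseudo-species are dropped on read", {
  toy <- make_toy_model(1, 10)
  f <- tempfile(fileext = ".xml")
  write_model_sbml(toy$model, f)
  txt <- readLines(f)
  sp <- grep("<species id=\"glc_c\"", txt)
  extra <- sub("glc_c", "prot_pool", txt[sp])
  gly <- grep('reaction id="GLY"', txt)
  reac_open <- grep("<listOfReactants>", txt)
  ro <- min(reac_open[reac_open > gly])
  coupling <- '          <speciesReference species="prot_pool" stoichiometry="0.01" constant="true"/>'
  writeLines(append(append(txt, extra, after = sp), coupling, after = ro + 1),
             f)
  expect_message(m <- read_model_sbml(f), "enzyme-constraint pseudo-species")
  expect_false("prot_pool" %in% m$metabolites$id)
  expect_false("prot_pool" %in% m$stoichiometry$metabolite)
  # the remaining GLY stoichiometry is untouched
  S <- stoich_matrix(m)
  expect_identical(S[, "GLY"], stoich_matrix(toy$model)[rownames(S), "GLY"])
  unlink(f)
})

test_that("cobra reads the written SBML and agrees on the FBA optimum", {
  toy <- make_toy_model(1, 12)
  f <- tempfile(fileext = ".xml")
  write_model_sbml(toy$model, f)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "print(len(m.metabolites), len(m.reactions),",
    "      round(m.optimize().objective_value, 6))"), script)
  out <- system2(Sys.which("python"), c(script, f), stdout = TRUE)
  parts <- as.numeric(strsplit(out[length(out)], " +")[[1]])
  expect_equal(parts[1], nrow(toy$model$metabolites))
  expect_equal(parts[2], nrow(toy$model$reactions))
  own <- solve_fba(build_tfa(toy$model))
  expect_equal(parts[3], own$objective, tolerance = 1e-5)
  unlink(c(f, script))
})

test_that("add_exchanges augments, is idempotent, and validates ids", {
  toy <- make_toy_model(1, 10)
  m <- toy$model
  # seven new external species, one exchange each
  seven <- paste0("aux", 1:7, "_e")
  m2 <- m
  m2$metabolites <- rbind(m2$metabolites, data.frame(
    id = seven, compartment = "e", charge = 0,
    thermo_id = sub("_e$", "", seven), stringsAsFactors = FALSE))
  m3 <- add_exchanges(m2, seven)
  expect_equal(nrow(m3$reactions), nrow(m$reactions) + 7)
  expect_identical(add_exchanges(m3, seven), m3)      # idempotent
  expect_identical(add_exchanges(m, character(0)), m) # empty list no-op
  expect_error(add_exchanges(m, "nonexistent_e"), "unknown metabolite")
  # creating the external species from an internal base compound is logged
  m4 <- m
  m4$metabolites <- m4$metabolites[m4$metabolites$id != "lac_e", ]
  m4$reactions <- m4$reactions[!m4$reactions$id %in% c("EX_lac", "T_lac"), ]
  m4$stoichiometry <-
    m4$stoichiometry[!m4$stoichiometry$reaction %in% c("EX_lac", "T_lac"), ]
  m4 <- network_model(m4$metabolites, m4$reactions, m4$stoichiometry,
                      m4$compartments, biomass = "BIO")
  expect_message(m5 <- add_exchanges(m4, "lac_e"), "creating external species")
  expect_true("EX_lac" %in% m5$reactions$id)
})

test_that("blocked reactions are detected and removed per the FVA rule", {
  # chain with the uptake closed: everything upstream is blocked; the
  # (also blocked) biomass reaction is retained with a warning
  ch <- chain_model(u = 1)
  ch <- set_bounds(ch, "EX_S", 0, 0)
  expect_warning(rb <- remove_blocked(ch), "biomass reaction is blocked")
  expect_setequal(rb$removed, c("EX_S", "T_S", "CONV", "T_P"))
  expect_true("EX_P" %in% rb$model$reactions$id)

  # fully open toy model: nothing is blocked
  toy <- make_toy_model(1, 12)
  rb2 <- remove_blocked(toy$model)
  expect_length(rb2$removed, 0)

  # dead-end branch: exactly the dead-end reaction, verified by an
  # exhaustive per-reaction FVA oracle
  br <- branched_model()
  rb3 <- remove_blocked(br)
  tfa <- build_tfa(br)
  oracle <- brute_force_ranges(tfa, parsimonious = FALSE, fix_biomass = FALSE)
  blocked_oracle <- oracle$reaction[abs(oracle$min) < 1e-9 &
                                    abs(oracle$max) < 1e-9]
  expect_setequal(rb3$removed, blocked_oracle)
  expect_setequal(rb3$removed, "R_dead")
  expect_false("D_c" %in% rb3$model$metabolites$id)

  # idempotence: a second pass removes nothing
  expect_length(remove_blocked(rb3$model)$removed, 0)
})

test_that("thermodynamic coverage statistics are set-theoretic", {
  toy <- make_toy_model(1, 10)
  m <- toy$model

  full <- join_thermo(m, toy$thermo)
  expect_equal(full$coverage_compounds, 1)
  expect_equal(full$coverage_reactions, 1)

  empty <- suppressWarnings(
    join_thermo(m, thermo_table(character(0), numeric(0), numeric(0))))
  expect_equal(empty$coverage_compounds, 0)
  expect_equal(empty$coverage_reactions, 0)
  expect_setequal(empty$unmatched, m$metabolites$id)

  # dropping one hub compound reduces estimability by exactly the number
  # of non-exchange reactions touching it (set-count oracle)
  hub <- "nadh"
  partial <- join_thermo(m, toy$thermo[toy$thermo$compound_id != hub, ])
  non_ex <- setdiff(m$reactions$id, m$exchanges)
  hub_mets <- m$metabolites$id[m$metabolites$thermo_id == hub]
  touched <- unique(m$stoichiometry$reaction[
    m$stoichiometry$metabolite %in% hub_mets])
  expected_drop <- length(intersect(touched, non_ex))
  expect_equal(round((full$coverage_reactions - partial$coverage_reactions) *
                       length(non_ex)),
               expected_drop)

  # independent of bounds: tightening bounds leaves coverage unchanged
  m_tight <- set_bounds(m, "EX_glc", -0.1, 0)
  expect_equal(join_thermo(m_tight, toy$thermo)$coverage_reactions,
               full$coverage_reactions)
})

test_that("thermo table TSV round trips", {
  toy <- make_toy_model(2, 10)
  f <- tempfile(fileext = ".tsv")
  write_thermo_tsv(toy$thermo, f)
  t2 <- read_thermo_tsv(f)
  expect_equal(as.data.frame(t2), as.data.frame(toy$thermo),
               tolerance = 1e-12)
  unlink(f)
})
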