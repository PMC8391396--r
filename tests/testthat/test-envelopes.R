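test_that("key-flux extraction maps roles, sums substrates, flips uptake", {
  df <- data.frame(
    reaction = c("EX_o2", "OXP", "EX_lac", "EX_fa1", "EX_fa2"),
    subsystem = c("transport", "oxidative phosphorylation", rep("transport", 3)),
    min = c(-2.0, 4.0, 0.5, -0.1, -0.1),
    max = c(-1.5, 5.0, 0.8, -0.1, 0.0))
  r <- flux_ranges(df, state = "raw", instance = "i")
  kf <- key_fluxes(r, toy_roles())
  expect_equal(kf$min[kf$role == "oxygen_uptake"], 1.5)
  expect_equal(kf$max[kf$role == "oxygen_uptake"], 2.0)
  # singleton substrate carrying [0.1, 0.1] -> influx 0.1
  fa1 <- kf[kf$role == "fatty_acid_influx" & kf$reaction == "EX_fa1", ]
  expect_equal(c(fa1$min, fa1$max), c(0.1, 0.1))
  # additivity: per-substrate totals equal the reported sum
  tot <- kf[kf$role == "fatty_acid_influx_total", ]
  per <- kf[kf$role == "fatty_acid_influx", ]
  expect_equal(tot$min, sum(per$min))
  expect_equal(tot$max, sum(per$max))
  # anaerobic instance: oxygen uptake zero
  df0 <- df; df0$min[1] <- 0; df0$max[1] <- 0
  kf0 <- key_fluxes(flux_ranges(df0, state = "raw"), toy_roles())
  expect_equal(kf0$max[kf0$role == "oxygen_uptake"], 0)

  expect_error(key_fluxes(r, list(oxygen_uptake = "EX_o2")), "unmapped roles")
})

test_that("sweeps agree with the instance's own pTFVA minima at the operating point", {
  b <- make_bundle(1, noise_cv = 0)
  tfa <- bundle_instance(b, "sensitive_A")
  r <- solve_ptfva(tfa)
  o2min <- -r$max[r$reaction == "EX_o2"]
  famin <- -(r$max[r$reaction == "EX_fa1"] + r$max[r$reaction == "EX_fa2"])

  sw_fa <- sweep_min_fa(tfa, toy_roles(), o2_grid = c(o2min, o2min * 1.001))
  expect_true(sw_fa$feasible[1])
  expect_equal(sw_fa$fa_influx[1], famin, tolerance = 1e-6)
  # per-substrate lexicographic breakdown adds up to the total
  expect_equal(sw_fa$EX_fa1[1] + sw_fa$EX_fa2[1], sw_fa$fa_influx[1],
               tolerance = 1e-9)

  sw_o2 <- sweep_min_o2(tfa, toy_roles(), fa_grid = c(famin, famin * 1.001))
  expect_true(sw_o2$feasible[1])
  expect_equal(sw_o2$o2_influx[1], o2min, tolerance = 1e-6)
})

test_that("upper-bound pinning is monotone; equality pinning is not", {
  b <- make_bundle(1, noise_cv = 0)
  ds <- b$conditions$sensitive_A
  ft <- suppressMessages(fit_condition(ds))
  mdl <- constrain_instance(b$model, ft, b$truth$exchange_map)
  # relax biomass so reduced oxygen stays feasible, and open the
  # fatty-acid influx so excess oxygen has something to oxidize
  mu <- ft$growth$mu
  mdl <- set_bounds(mdl, "BIO", 0.2 * mu, mu)
  mdl <- set_bounds(mdl, c("EX_fa1", "EX_fa2"), -1000, 0)
  tfa <- build_tfa(mdl, b$thermo, conc_bounds = ds$conc_bounds)

  r <- solve_ptfva(tfa)
  o2min <- -r$max[r$reaction == "EX_o2"]
  grid <- seq(o2min, o2min * 2.5, length.out = 8)

  up <- sweep_min_fa(tfa, toy_roles(), o2_grid = grid, pin = "upper",
                     parsimonious = FALSE)
  expect_true(all(up$feasible))
  expect_true(all(diff(up$fa_influx) <= 1e-9))

  eq <- sweep_min_fa(tfa, toy_roles(), o2_grid = grid, pin = "equality",
                     parsimonious = FALSE)
  # forcing excess oxygen through the system raises the fatty-acid need
  expect_gt(eq$fa_influx[length(grid)], eq$fa_influx[1] + 1e-6)
})

test_that("forced-influx oxygen curves show an interior minimum", {
  toy <- make_envelope_toy(atp_demand = 2, glc_cap = 1)
  tfa <- build_tfa(toy$model, toy$thermo)
  grid <- seq(0.1, 1.2, by = 0.1)
  sw <- sweep_min_o2(tfa, toy$roles, fa_grid = grid, parsimonious = FALSE)
  expect_true(all(sw$feasible))
  i <- which.min(sw$o2_influx)
  expect_gt(i, 1)
  expect_lt(i, nrow(sw))
  expect_gt(sw$o2_influx[1], sw$o2_influx[i])
  expect_gt(sw$o2_influx[nrow(sw)], sw$o2_influx[i])
  # the argmin attribute reports the same point
  am <- attr(sw, "argmin")
  expect_equal(am$fa_influx[1], grid[i])

  # brute-force two-stage LP oracle at every grid point
  for (k in seq_along(grid)) {
    prob <- tfa$problem
    i_fa <- match("EX_fa", toy$model$reactions$id)
    prob$rlb[match("net_EX_fa", prob$rnames)] <- -grid[k]
    prob$rub[match("net_EX_fa", prob$rnames)] <- -grid[k]
    o <- thermoflux:::.influx_objective(tfa, "EX_o2")
    got <- solve_lp1(prob, queries = list(lp_objective(o$ind, o$val, "min")))
    expect_equal(sw$o2_influx[k], got$queries[[1]]$objective,
                 tolerance = 1e-9)
  }

  # a doubled demand never lowers the oxygen minimum at fixed influx
  sw2 <- sweep_min_o2(tfa, toy$roles, fa_grid = grid,
                      biomass_levels = c(2, 4), parsimonious = FALSE)
  lo <- sw2[sw2$biomass_level == 2, ]
  hi <- sw2[sw2$biomass_level == 4, ]
  both <- lo$feasible & hi$feasible
  expect_true(all(hi$o2_influx[both] >= lo$o2_influx[both] - 1e-9))
})

test_that("envelope extreme points satisfy the thermodynamic constraints", {
  toy <- make_envelope_toy()
  tfa <- build_tfa(toy$model, toy$thermo)
  # pin the fatty-acid exchange at an excess value and audit the solution
  mdl <- set_bounds(toy$model, "EX_fa", -1, -1)
  tfa_pin <- build_tfa(mdl, toy$thermo)
  pf <- solve_pfba(tfa_pin)
  expect_equal(pf$status, "optimal")
  expect_equal(nrow(second_law_violations(tfa_pin, pf$x)), 0)

  expect_error(sweep_min_o2(tfa, toy$roles, fa_grid = c(0.5, 0.4)),
               "strictly increasing")
})
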