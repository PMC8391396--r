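test_that("standard reaction energies: chemical, electrical, proton terms", {
  # zero formation energies, non-transport -> zero energy and error
  ch <- chain_model()
  rt0 <- reaction_delta_g0(ch, flat_thermo(ch))
  conv <- rt0[rt0$reaction == "CONV", ]
  expect_equal(conv$drG0_prime, 0)
  expect_equal(conv$drG0_error, 0)
  expect_true(conv$estimable)
  expect_false(rt0$estimable[rt0$reaction == "EX_S"])  # exchanges excluded

  # uniport of a +1 ion across 0.150 V: electrical work F * dpsi
  mets <- data.frame(id = c("ion_e", "ion_c"), compartment = c("e", "c"),
                     charge = 1, thermo_id = "ion", stringsAsFactors = FALSE)
  comp <- data.frame(id = c("e", "c"), pH = 7, ionic_strength = 0.15,
                     membrane_potential = c(0, 0.150), temperature = 310.15,
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("UNI", "EX_ion"), subsystem = "transport",
                     lower = -1000, upper = 1000, stringsAsFactors = FALSE)
  sto <- data.frame(reaction = c("UNI", "UNI", "EX_ion"),
                    metabolite = c("ion_e", "ion_c", "ion_e"),
                    coef = c(-1, 1, -1), stringsAsFactors = FALSE)
  m <- network_model(mets, rxns, sto, comp, biomass = "EX_ion")
  rt <- reaction_delta_g0(m, thermo_table("ion", 0, 0))
  expect_equal(rt$drG0_prime[rt$reaction == "UNI"], 96.485 * 0.150,
               tolerance = 1e-9)

  # proton translocation contributes RT ln(10) dpH per proton
  mets_h <- data.frame(id = c("h_e", "h_c"), compartment = c("e", "c"),
                       charge = 0, thermo_id = "h", stringsAsFactors = FALSE)
  comp_h <- data.frame(id = c("e", "c"), pH = c(7.4, 7.0),
                       ionic_strength = 0.15, membrane_potential = 0,
                       temperature = 310.15, stringsAsFactors = FALSE)
  rxns_h <- data.frame(id = c("HT", "EX_h"), subsystem = "transport",
                       lower = -1000, upper = 1000, stringsAsFactors = FALSE)
  sto_h <- data.frame(reaction = c("HT", "HT", "EX_h"),
                      metabolite = c("h_e", "h_c", "h_e"),
                      coef = c(-1, 1, -1), stringsAsFactors = FALSE)
  mh <- network_model(mets_h, rxns_h, sto_h, comp_h, biomass = "EX_h")
  rth <- reaction_delta_g0(mh, thermo_table("x", 0, 0))
  RT <- 8.31446e-3 * 310.15
  expect_equal(rth$drG0_prime[rth$reaction == "HT"],
               RT * log(10) * (7.4 - 7.0), tolerance = 1e-9)

  # error propagates in quadrature: A -> B with 2 kJ/mol each -> sqrt(8)
  th <- thermo_table(c("S", "P"), c(0, 0), c(2, 2))
  rte <- reaction_delta_g0(chain_model(), th)
  expect_equal(rte$drG0_error[rte$reaction == "T_S"], sqrt(8),
               tolerance = 1e-12)
})

test_that("non-binding thermodynamics reproduce the plain FBA region", {
  # reversible chain, wide concentration range, zero energies: both
  # directions attainable, so TFVA ranges equal FVA ranges
  ch <- chain_model(u = 1, reversible = TRUE)
  fva <- solve_fva(build_tfa(ch), fix_biomass = FALSE)
  tfva <- solve_fva(build_tfa(ch, flat_thermo(ch, error = 5)),
                    fix_biomass = FALSE)
  expect_equal(tfva$min, fva$min, tolerance = 1e-6)
  expect_equal(tfva$max, fva$max, tolerance = 1e-6)
})

test_that("an uphill reaction with capped concentrations cannot run forward", {
  # CONV gets drG0' = +50 kJ/mol with zero error; concentrations are
  # pinned to a narrow window so RT-term cannot reach -50
  ch <- chain_model(u = 1, reversible = TRUE)
  th <- thermo_table(c("S", "P"), c(0, 25), 0)  # CONV: 2P - S = +50
  cb <- data.frame(metabolite = c("S_c", "P_c"), lb = 9e-5, ub = 1.1e-4)
  tfa <- build_tfa(ch, th, conc_bounds = cb)
  # without thermodynamics the forward direction is open ...
  plain <- solve_fva(build_tfa(ch), reactions = "CONV", fix_biomass = FALSE)
  expect_gt(plain$max[1], 0.9)
  # ... with the capped concentrations, attainable drG' stays positive:
  # forward use is forced off in every solution
  rng <- solve_fva(tfa, reactions = "CONV", fix_biomass = FALSE)
  expect_lt(rng$max[1], 1e-9)
})

test_that("the 3-cycle loop cannot circulate: all 8 direction patterns", {
  toy <- make_toy_model(1, 10)
  tfa <- build_tfa(toy$model, toy$thermo)
  loops <- c("LOOP1", "LOOP2", "LOOP3")
  li <- match(loops, toy$model$reactions$id)
  for (pattern in 0:7) {
    fwd <- as.logical(bitwAnd(pattern, c(1L, 2L, 4L)))
    prob <- tfa$problem
    for (j in seq_along(loops)) {
      fi <- tfa$idx$F[li[j]]; bi <- tfa$idx$B[li[j]]
      if (fwd[j]) {        # force forward flux >= 1e-3, no backward
        prob$lb[fi] <- 1e-3; prob$ub[bi] <- 0
      } else {             # force backward flux >= 1e-3, no forward
        prob$lb[bi] <- 1e-3; prob$ub[fi] <- 0
      }
    }
    r <- solve_lp1(prob, queries = list(lp_objective(1L, 0, "min")))
    expect_equal(r$queries[[1]]$status, "infeasible",
                 info = paste("pattern", pattern))
  }
})

test_that("FBA optima match single-path analytics and vertex enumeration", {
  # chain: maximize product export with uptake capped at u -> yield 2u
  for (u in c(0.5, 1, 2)) {
    f <- solve_fba(build_tfa(chain_model(u = u)))
    expect_equal(f$objective, 2 * u, tolerance = 1e-9)
  }
  # all exchanges closed -> optimum zero
  ch <- chain_model(u = 1)
  ch <- set_bounds(ch, "EX_S", 0, 0)
  expect_equal(solve_fba(build_tfa(ch))$objective, 0, tolerance = 1e-12)

  # branched toy: brute force over LP vertices of the small polytope
  br <- branched_model()
  f <- solve_fba(build_tfa(br))
  # vertex enumeration: uptake splits between RA and RB; both yield 1
  # P per S, R_dead yields none, so the optimum is the full uptake
  expect_equal(f$objective, 1, tolerance = 1e-9)
  expect_equal(unname(f$fluxes["R_dead"]), 0, tolerance = 1e-9)
})

test_that("pFBA prefers the shorter of two equal-yield routes", {
  pm <- parallel_model(u = 1)
  pf <- solve_pfba(build_tfa(pm))
  expect_equal(pf$status, "optimal")
  expect_equal(unname(pf$fluxes["R1"]), 1, tolerance = 1e-9)
  expect_equal(unname(pf$fluxes["R2a"]), 0, tolerance = 1e-9)
  expect_equal(unname(pf$fluxes["R2b"]), 0, tolerance = 1e-9)

  # zero demand -> zero total flux
  closed <- set_bounds(pm, "EX_S", 0, 0)
  expect_equal(solve_pfba(build_tfa(closed))$min_total_flux, 0,
               tolerance = 1e-9)

  # pFBA on the toy carries no loop component
  toy <- make_toy_model(1, 10)
  tf <- build_tfa(toy$model, toy$thermo)
  pf2 <- solve_pfba(tf)
  expect_lt(max(abs(pf2$fluxes[c("LOOP1", "LOOP2", "LOOP3")])), 1e-9)
})

test_that("pTFVA ranges: determined chain, nesting, pFBA containment", {
  ch <- chain_model(u = 1)
  ch <- set_bounds(ch, "EX_S", -1, -1)
  tfa <- build_tfa(ch, flat_thermo(ch, error = 5))
  r <- solve_ptfva(tfa)
  expect_equal(r$min[r$reaction == "T_S"], 1, tolerance = 1e-9)
  expect_equal(r$max[r$reaction == "T_S"], 1, tolerance = 1e-9)
  expect_equal(r$min[r$reaction == "EX_P"], 2, tolerance = 1e-9)

  # pTFVA nested in TFVA, TFVA nested in FVA, reaction-wise
  b <- make_bundle(8, noise_cv = 0.03)
  tfa_i <- bundle_instance(b, "sensitive_A")
  ptv <- solve_ptfva(tfa_i)
  tv <- solve_tfva(tfa_i)
  expect_true(all(ptv$min >= tv$min - 1e-6 & ptv$max <= tv$max + 1e-6))

  # ranges contain the pFBA solution
  pf <- solve_pfba(tfa_i)
  v <- pf$fluxes[ptv$reaction]
  expect_true(all(ptv$min - 1e-6 <= v & v <= ptv$max + 1e-6))
})

test_that("pTFVA is deterministic and partition-invariant", {
  toy <- make_envelope_toy()
  tfa <- build_tfa(toy$model, toy$thermo)
  r1 <- solve_ptfva(tfa)
  r2 <- solve_ptfva(tfa)
  expect_equal(r1$min, r2$min, tolerance = 1e-6)
  expect_equal(r1$max, r2$max, tolerance = 1e-6)

  # partition by reaction: identical results regardless of partitioning
  ids <- r1$reaction
  parts <- split(ids, rep(1:3, length.out = length(ids)))
  got <- do.call(rbind, lapply(parts, function(p) solve_ptfva(tfa, reactions = p)))
  got <- got[match(ids, got$reaction), ]
  expect_equal(got$min, r1$min, tolerance = 1e-9)
  expect_equal(got$max, r1$max, tolerance = 1e-9)
})

test_that("out-of-range concentration bounds are clipped with a warning", {
  ch <- chain_model()
  cb <- data.frame(metabolite = "S_c", lb = 1e-15, ub = 0.5)
  expect_warning(tfa <- build_tfa(ch, flat_thermo(ch), conc_bounds = cb),
                 "clipped")
  i <- tfa$idx$lnc[["S_c"]]
  expect_equal(tfa$problem$lb[i], log(1e-12))
  expect_equal(tfa$problem$ub[i], log(0.1))
})
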