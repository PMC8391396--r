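mk_ranges <- function(df, ...) {
  df$subsystem <- df$subsystem %||% "glycolysis"
  flux_ranges(df, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("growth normalization divides by biomass and is scale invariant", {
  df <- data.frame(reaction = c("R1", "BIO"), subsystem = "glycolysis",
                   min = c(0.5, 0.05), max = c(1.0, 0.05))
  r <- mk_ranges(df, state = "raw", biomass = 0.05)
  n <- growth_normalize(r)
  expect_equal(n$min, c(10, 1))
  expect_equal(n$max, c(20, 1))
  expect_identical(attr(n, "state"), "growth_normalized")

  # uniform rescaling of raw fluxes together with biomass is absorbed
  for (c0 in c(0.1, 3, 42)) {
    r2 <- mk_ranges(transform(df, min = min * c0, max = max * c0),
                    state = "raw", biomass = 0.05 * c0)
    n2 <- growth_normalize(r2)
    expect_equal(n2$min, n$min)
    expect_equal(n2$max, n$max)
  }

  expect_error(growth_normalize(mk_ranges(df, state = "raw", biomass = 0)),
               "normalization undefined")
  expect_error(growth_normalize(n), "'raw' state")
})

test_that("dual-bound flagging requires both bounds to differ", {
  a <- mk_ranges(data.frame(reaction = c("R1", "R2", "R3"),
                            subsystem = "glycolysis",
                            min = c(1.00, 1.00, 1), max = c(2.00, 2.00, 2)),
                 state = "growth_normalized")
  # R1: lower differs 20%, upper 16% -> flagged
  # R2: lower differs 20%, upper 10% -> conjunction fails
  # R3: identical -> zero differences
  b <- mk_ranges(data.frame(reaction = c("R1", "R2", "R3"),
                            subsystem = "glycolysis",
                            min = c(0.80, 0.80, 1), max = c(1.68, 1.80, 2)),
                 state = "growth_normalized")
  rep <- flag_differences(a, b, threshold = 0.15)
  expect_equal(rep$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(rep$rel_lb[3], 0)
  expect_equal(rep$rel_ub[3], 0)
  expect_equal(rep$direction[1], "a")

  # symmetric in the flag, antisymmetric in the direction
  rev <- flag_differences(b, a, threshold = 0.15)
  expect_equal(rev$flagged, rep$flagged)
  expect_equal(rev$direction[1], "b")

  # mismatched reaction universes are rejected with the difference listed
  b2 <- b; b2$reaction[3] <- "OTHER"
  expect_error(flag_differences(a, mk_ranges(as.data.frame(b2),
                                             state = "growth_normalized")),
               "R3")
})

test_that("feature scaling maps onto [0,1] with the degenerate rule", {
  mk <- function(mins, maxs, inst) {
    mk_ranges(data.frame(reaction = c("R1", "R2"), subsystem = "glycolysis",
                         min = mins, max = maxs),
              state = "growth_normalized", instance = inst)
  }
  # R1 endpoints span [2, 6] across instances; R2 is constant
  sets <- list(mk(c(2, 7), c(4, 7), "i1"), mk(c(3, 7), c(6, 7), "i2"))
  sc <- feature_scale(sets)
  expect_equal(sc[[1]]$min[1], 0)    # 2 -> 0
  expect_equal(sc[[2]]$max[1], 1)    # 6 -> 1
  expect_equal(sc[[1]]$max[1], 0.5)  # 4 -> 0.5
  expect_equal(c(sc[[1]]$min[2], sc[[1]]$max[2], sc[[2]]$min[2]),
               rep(0.5, 3))          # degenerate reaction -> all 0.5
  expect_identical(attr(sc[[1]], "state"), "feature_scaled")

  # scaling preserves the within-reaction ordering of all endpoints
  set.seed(12)
  for (rep in 1:20) {
    vals <- matrix(rnorm(8), 2)      # 4 instances x (min,max) for 1 reaction
    vals <- apply(vals, 2, sort)
    sets <- lapply(1:4, function(i) {
      mk_ranges(data.frame(reaction = "R", subsystem = "x",
                           min = vals[1, i], max = vals[2, i]),
                state = "growth_normalized", instance = paste0("i", i))
    })
    sc <- feature_scale(sets)
    raw <- as.vector(vals)
    scl <- unlist(lapply(sc, function(s) c(s$min, s$max)))
    expect_equal(order(raw), order(scl))
    expect_true(all(scl >= 0 & scl <= 1))
  }
})

test_that("control ratios divide paired instances and floor the control", {
  mk <- function(mins, maxs, inst) {
    mk_ranges(data.frame(reaction = c("R1", "R2"), subsystem = "glycolysis",
                         min = mins, max = maxs),
              state = "feature_scaled", instance = inst)
  }
  res <- mk(c(0.8, 0.3), c(0.8, 0.6), "res")
  sen <- mk(c(0.4, 0), c(0.4, 0.5), "sen")
  expect_message(cr <- control_ratio(res, sen), "1 reactions incomparable")
  expect_equal(cr$min[1], 2)
  expect_equal(cr$max[1], 2)
  expect_false(cr$comparable[2])  # control bound below the floor

  # resistant == control everywhere -> all ratios 1, downstream flags empty
  cr2 <- control_ratio(sen_ok <- mk(c(0.5, 0.3), c(0.7, 0.6), "a"),
                       mk(c(0.5, 0.3), c(0.7, 0.6), "b"))
  expect_true(all(cr2$min == 1 & cr2$max == 1))
  rep2 <- flag_differences(cr2, cr2)
  expect_equal(sum(rep2$flagged), 0)

  expect_error(control_ratio(res, mk_ranges(
    data.frame(reaction = c("R1", "R2"), subsystem = "x",
               min = 1, max = 1), state = "growth_normalized")),
    "feature-scaled")
})

test_that("subsystem summaries report proportions and normalized shares", {
  rep <- structure(data.frame(
    reaction = paste0("R", 1:8),
    subsystem = c(rep("glycolysis", 4), rep("TCA", 2), rep("transport", 2)),
    rel_lb = 0.5, rel_ub = 0.5,
    flagged = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    direction = "a", comparable = TRUE, stringsAsFactors = FALSE),
    class = c("comparison_report", "data.frame"))
  s <- subsystem_summary(rep, exclude = "transport")
  gly <- s[s$subsystem == "glycolysis", ]
  expect_equal(gly$proportion, 0.5)       # 2 of 4 members flagged
  expect_equal(gly$share, 2 / 3)          # of 3 non-transport flags
  expect_equal(sum(s$share, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_false("unflagged_subsystem" %in% s$subsystem)

  # all flags inside excluded subsystems: shares empty, proportions kept
  rep2 <- rep
  rep2$flagged <- rep2$subsystem == "transport"
  s2 <- subsystem_summary(rep2, exclude = "transport")
  expect_true(all(is.na(s2$share)))
  expect_equal(s2$proportion[s2$subsystem == "transport"], 1)

  expect_warning(subsystem_summary(rep, exclude = "no_such_subsystem"),
                 "not present")
})
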