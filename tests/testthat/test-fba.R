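# Flux balance analysis, the parsimonious wild-type reference, and the
# production envelope evaluator.

test_that("FBA conserves flux along a chain and handles degenerate input", {
  S <- rbind(c(1, -1, 0), c(0, 1, -1))
  m <- metabolic_model(c("upt", "conv", "exp"), c("A", "B"), S,
                       c(0, 0, 0), c(10, 1000, 1000),
                       biomass_reaction = "exp")
  fba <- solve_fba(m, objective = "exp")
  expect_equal(fba$status, "optimal")
  expect_equal(fba$objective_value, 10)
  expect_equal(unname(fba$v), c(10, 10, 10))

  # knocking out everything leaves only the zero flux
  all_ko <- solve_fba(m, objective = "exp", knockouts = m$reaction_ids)
  expect_true(all_ko$status != "optimal" ||
                abs(all_ko$objective_value) < 1e-9)

  # knocked-out reactions carry exactly zero flux
  ko <- solve_fba(toy7(oracle = FALSE), knockouts = "DRAIN1")
  expect_equal(unname(ko$v["DRAIN1"]), 0)
})

test_that("wild-type reference is parsimonious, deterministic, balanced", {
  m <- toy7(oracle = FALSE)
  w1 <- wild_type_reference(m)
  w2 <- wild_type_reference(m)
  expect_identical(w1$v, w2$v)
  expect_equal(w1$objective_value, 0.5)
  # hand-solved routing: all carbon through the chain, excess through the
  # one-step drain (cheaper than the two-step product route)
  expect_equal(unname(w1$v),
               c(-10, 10, 10, 0, 0, 5, 0.5),
               tolerance = 1e-9)
  expect_lt(max(abs(m$S %*% w1$v)), 1e-6)
})

test_that("parsimony zeroes futile cycles in the reference", {
  # A -> B (fwd) and B -> A (back) form a futile cycle; biomass consumes B
  S <- rbind(c(1, -1, 1, 0), c(0, 1, -1, -1))
  m <- metabolic_model(c("upt", "fwd", "back", "bm"), c("A", "B"), S,
                       c(0, 0, 0, 0), c(5, 1000, 1000, 1000),
                       biomass_reaction = "bm")
  w <- wild_type_reference(m)
  expect_equal(unname(w$v["back"]), 0)
  expect_equal(unname(w$v["bm"]), 5)
})

test_that("production envelope behaves as specified", {
  m <- toy7()
  # wild type grows but nothing is growth-coupled
  wt <- production_at_optimal_growth(m)
  expect_equal(wt$growth, 0.5)
  expect_equal(wt$production_min, 0)
  expect_equal(wt$production_max, 5)
  expect_lte(wt$production_min, wt$production_max)

  # knocking out the drain couples production to growth; value matches the
  # generator's brute-force table
  ko <- production_at_optimal_growth(m, knockout_reactions(m, "DRAIN1"))
  expect_equal(ko$growth, 0.5)
  expect_equal(ko$production_min, 5)
  tab <- attr(m, "oracle_table")
  expect_equal(ko$production_min, tab$production[tab$knockout == "DRAIN1"])

  # a no-op knockout (reaction already bounded to zero) changes nothing
  m0 <- m
  m0$lower_bounds["SYNTH"] <- 0
  m0$upper_bounds["SYNTH"] <- 0
  expect_equal(production_at_optimal_growth(m0),
               production_at_optimal_growth(m0,
                 knockout_reactions(m0, "SYNTH")))

  # infeasible mutant is flagged, not an error
  dead <- production_at_optimal_growth(m, knockout_reactions(m, "EX_carbon"))
  expect_equal(dead$growth, 0)
  expect_true(dead$flagged)
})

test_that("adding knockouts never increases optimal growth", {
  m <- toy8(seed = 4, oracle = FALSE)
  set.seed(11)
  for (i in 1:20) {
    a <- sample(m$reaction_ids, sample.int(2, 1))
    b <- union(a, sample(m$reaction_ids, sample.int(2, 1)))
    ga <- solve_fba(m, knockouts = a)
    gb <- solve_fba(m, knockouts = b)
    va <- if (ga$status == "optimal") ga$objective_value else 0
    vb <- if (gb$status == "optimal") gb$objective_value else 0
    expect_lte(vb, va + 1e-9)
  }
})

test_that("optimal solutions satisfy mass balance within 1e-6", {
  m <- toy8(seed = 2, oracle = FALSE)
  set.seed(5)
  for (i in 1:10) {
    ko <- sample(m$reaction_ids, sample.int(3, 1))
    fba <- solve_fba(m, knockouts = ko)
    if (fba$status == "optimal") {
      expect_lt(max(abs(m$S %*% fba$v)), 1e-6)
      mod <- beeknock:::.bk_apply_knockouts(m, ko)
      expect_true(all(fba$v >= mod$lower_bounds - 1e-9))
      expect_true(all(fba$v <= mod$upper_bounds + 1e-9))
    }
  }
})
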