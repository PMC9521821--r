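# The ROOM mixed-integer program and its viability filter.

test_that("significance bounds follow w +/- (delta|w| + epsilon)", {
  p <- room_parameters(delta = 0.03, epsilon = 0.001)
  sb0 <- significance_bounds(0, p)
  expect_equal(sb0$w_u, 0.001)
  expect_equal(sb0$w_l, -0.001)

  sb10 <- significance_bounds(10, p)
  expect_equal(sb10$w_u, 10.301)
  expect_equal(sb10$w_l, 9.699)

  # symmetric widths, w inside the window
  w <- c(-5, 0, 2, 100)
  sb <- significance_bounds(w, p)
  expect_equal(sb$w_u - w, w - sb$w_l)
  expect_true(all(sb$w_l <= w & w <= sb$w_u))

  # degenerate thresholds collapse the window onto w
  sb00 <- significance_bounds(w, room_parameters(delta = 0, epsilon = 0))
  expect_equal(sb00$w_u, w)
  expect_equal(sb00$w_l, w)
})

test_that("empty knockout set has ROOM objective 0", {
  m <- toy7(oracle = FALSE)
  w <- wild_type_reference(m)
  r <- solve_room(m, NULL, w)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 0)
})

test_that("ROOM solution respects knockout, integrality and mass balance", {
  m <- toy8(seed = 3, oracle = FALSE)
  w <- wild_type_reference(m)
  set.seed(21)
  for (i in 1:8) {
    ko <- sample(m$reaction_ids, sample.int(2, 1))
    r <- solve_room(m, ko, w)
    if (r$status != "optimal") next
    expect_true(all(r$y %in% c(0L, 1L)))
    expect_equal(r$objective, sum(r$y))
    expect_equal(unname(r$v[ko]), rep(0, length(ko)))
    expect_lt(max(abs(m$S %*% r$v)), 1e-6)
    # unchanged reactions sit inside their significance window
    sb <- significance_bounds(w, room_parameters())
    un <- which(r$y == 0L)
    expect_true(all(r$v[un] >= sb$w_l[un] - 1e-6))
    expect_true(all(r$v[un] <= sb$w_u[un] + 1e-6))
  }
})

test_that("MILP objective equals the exhaustive change-pattern oracle", {
  m <- toy7(oracle = FALSE)
  w <- wild_type_reference(m)
  for (ko in list("DRAIN1", "STEP2", c("DRAIN1", "SYNTH"))) {
    r <- solve_room(m, ko, w)
    k <- room_enum_oracle(m, ko, w)
    if (is.na(k)) {
      expect_equal(r$status, "infeasible", info = paste(ko, collapse = ","))
    } else {
      expect_equal(r$objective, k, info = paste(ko, collapse = ","))
    }
  }
})

test_that("LP relaxation never exceeds the integer optimum", {
  m <- toy8(seed = 6, oracle = FALSE)
  w <- wild_type_reference(m)
  set.seed(31)
  for (i in 1:10) {
    ko <- sample(m$reaction_ids, sample.int(3, 1))
    ri <- solve_room(m, ko, w)
    rl <- solve_room(m, ko, w, room_parameters(relaxed = TRUE))
    if (ri$status == "optimal") {
      expect_lte(rl$objective, ri$objective + 1e-6)
    }
  }
})

test_that("viability thresholds match the published filters", {
  mk <- function(growth, production, status = "optimal")
    structure(list(growth = growth, production = production,
                   objective = 1, status = status), class = "room_result")
  # best published knockout list: growth 0.2226, production 8.1943
  expect_true(is_viable(mk(0.2226, 8.1943)))
  expect_false(is_viable(mk(0.05, 5)))
  expect_false(is_viable(mk(0.5, -0.01)))
  expect_false(is_viable(mk(0.5, 5, status = "infeasible")))
  expect_match(attr(is_viable(mk(0.05, 5)), "reason"), "growth")
})

test_that("infeasible mutants are reported in the status, not thrown", {
  m <- toy7(oracle = FALSE)
  w <- wild_type_reference(m)
  # force v = 5 on a dead chain: knock the uptake but require flux
  m2 <- m
  m2$lower_bounds["BIOMASS"] <- 0.4
  r <- solve_room(m2, "EX_carbon", wild_type_reference(m))
  expect_equal(r$status, "infeasible")
  expect_true(is.na(r$objective))
  expect_false(isTRUE(is_viable(r)))
})
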