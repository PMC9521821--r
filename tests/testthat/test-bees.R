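# The Bees Algorithm outer loop: initialization, repair, neighbourhood
# recruitment, determinism and the evaluation budget.

test_that("population initialization is deterministic and repaired", {
  m <- toy8(oracle = FALSE)
  cfg <- ba_config(n = 30, m = 20, e = 2, nep = 4, nsp = 8,
                   dimension = 2000, imax = 1, max_knockout = 3, seed = 5)
  p1 <- init_population(m, cfg)
  p2 <- init_population(m, cfg)
  expect_identical(p1, p2)
  expect_length(p1, 30)
  keys <- vapply(p1, function(c) paste(c$knockout, collapse = "|"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(vapply(p1, function(c) sum(c$presence == 0L),
                         integer(1)) <= 3))

  cfg1 <- ba_config(n = 8, m = 4, e = 2, nep = 2, nsp = 1,
                    dimension = 100, imax = 1, max_knockout = 1, seed = 5)
  p3 <- init_population(m, cfg1)
  expect_true(all(vapply(p3, function(c) sum(c$presence == 0L),
                         integer(1)) <= 1))
})

test_that("initialization errors when the model is too small", {
  S <- matrix(c(-1, 1), 2, 1)
  tiny <- metabolic_model("R1", c("A", "B"), S, 0, 10)
  expect_error(init_population(tiny, ba_config(max_knockout = 2)),
               "fewer reactions")
})

test_that("neighbourhood search returns the best of site and recruits", {
  m <- toy7(oracle = FALSE)
  w <- wild_type_reference(m)
  cfg <- small_config(max_knockout = 1)
  # start from the wild-type genotype; a 1-bit flip reaches the optimum
  site <- beeknock:::.bk_new_candidate(rep(1L, 7), m)
  best <- neighborhood_search(site, m, w, cfg, recruits = 30, seed = 2)
  expect_identical(best$knockout, "DRAIN1")
  expect_equal(best$fitness, 5)

  # from the optimum, no neighbour improves: the site itself comes back
  opt <- beeknock:::.bk_new_candidate(
    as.integer(m$reaction_ids != "DRAIN1"), m)
  kept <- neighborhood_search(opt, m, w, cfg, recruits = 10, seed = 3)
  expect_identical(kept$knockout, "DRAIN1")
})

test_that("identical seeds give identical runs; imax=1 means one iteration", {
  m <- toy7(seed = 2)
  cfg <- small_config(seed = 42, imax = 3)
  r1 <- beeknock(m, cfg)
  r2 <- beeknock(m, cfg)
  r1$evaluations$wall_time <- r2$evaluations$wall_time <- NULL
  expect_identical(r1[names(r1)], r2[names(r2)])

  r3 <- beeknock(m, small_config(seed = 42, imax = 1))
  expect_equal(nrow(r3$trace), 1)
})

test_that("global best trace is non-decreasing (elitism)", {
  m <- toy8(seed = 9)
  res <- beeknock(m, small_config(seed = 4, imax = 8))
  gb <- res$trace$global_best
  gb <- gb[is.finite(gb)]
  expect_true(all(diff(gb) >= 0))
})

test_that("scoring is memoized per distinct knockout set", {
  m <- toy7(seed = 1)
  res <- beeknock(m, small_config(seed = 10, imax = 6))
  # every logged solver call is a distinct knockout set
  expect_false(anyDuplicated(res$evaluations$knockout) > 0)
  expect_equal(nrow(res$evaluations), res$n_room_solves)
})

test_that("ROOM evaluations per iteration respect the recruitment budget", {
  m <- toy8(seed = 7)
  cfg <- small_config(seed = 3, imax = 6)
  res <- beeknock(m, cfg)
  per_iter <- table(factor(res$evaluations$iteration,
                           levels = seq_len(cfg$imax)))
  budget <- cfg$e * cfg$nep + (cfg$m - cfg$e) * cfg$nsp +
    (cfg$n - cfg$m) + cfg$n
  expect_true(all(per_iter <= budget))
})

test_that("a run with no viable candidates is flagged, not an error", {
  # raising the viability threshold above the attainable growth starves
  # the search: growth 0.5 <= threshold is impossible to beat when uptake
  # is cut to make max growth 0.05
  m <- toy7(oracle = FALSE)
  m <- apply_medium(m, c(EX_carbon = 1))  # max growth 0.05 < 0.1
  res <- beeknock(m, small_config(seed = 1, imax = 2))
  expect_false(res$viable_found)
  expect_identical(res$best$knockout, character(0))
  expect_equal(nrow(res$top_sets), 0)
})
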