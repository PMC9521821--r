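# Model container invariants and GPR boolean semantics.

test_that("model constructor enforces its invariants", {
  S <- rbind(c(1, -1, 0), c(0, 1, -1))
  m <- metabolic_model(c("R1", "R2", "R3"), c("A", "B"), S,
                       c(0, 0, 0), c(10, 10, 10))
  expect_s3_class(m, "metabolic_model")
  expect_equal(ncol(m$S), 3)
  expect_equal(nrow(m$S), 2)

  expect_error(
    metabolic_model(c("R1", "R2", "R3"), c("A", "B"), S,
                    c(0, 5, 0), c(10, 2, 10)),
    "lower bound exceeds upper bound.*R2")
  expect_error(
    metabolic_model(c("R1", "R2"), c("A", "B"), S, c(0, 0), c(1, 1)),
    "one column per reaction")
  expect_error(
    metabolic_model(c("R1", "R2", "R3"), c("A", "B"), S,
                    c(0, 0, 0), c(10, 10, 10), biomass_reaction = "nope"),
    "not in the model")
})

test_that("GPR evaluation follows AND/OR semantics", {
  S <- matrix(c(-1, 1), 2, 1)
  mk <- function(rule) metabolic_model("R1", c("A", "B"), S, 0, 10, rule)

  expect_equal(reactions_disabled_by(mk("g1 and g2"), "g1")$reactions, "R1")
  expect_equal(reactions_disabled_by(mk("g1 or g2"), "g1")$reactions,
               character(0))
  expect_equal(
    reactions_disabled_by(mk("(g1 and g2) or g3"), c("g1", "g3"))$reactions,
    "R1")
  # empty GPR is never disabled
  expect_error(reactions_disabled_by(mk(""), "gX"), "unknown gene")
})

test_that("GPR evaluation matches a truth-table oracle", {
  # independent oracle: substitute into a parsed R logical expression
  rules <- c("g1 and g2", "g1 or g2", "(g1 and g2) or g3",
             "g1 and (g2 or (g3 and g4))", "g1 or g2 and g3")
  genes <- paste0("g", 1:4)
  for (rule in rules) {
    ast <- beeknock:::parse_gpr(rule)
    rexpr <- parse(text = gsub(" or ", " | ", gsub(" and ", " & ", rule)))[[1]]
    combos <- expand.grid(rep(list(c(TRUE, FALSE)), 4))
    names(combos) <- genes
    for (i in seq_len(nrow(combos))) {
      present <- combos[i, ]
      knocked <- genes[!unlist(present)]
      expect_identical(
        beeknock:::eval_gpr(ast, knocked),
        eval(rexpr, as.list(present)),
        info = paste(rule, "with", paste(knocked, collapse = ",")))
    }
  }
})

test_that("disabling more genes never re-enables a reaction", {
  m <- toy8(seed = 11, oracle = FALSE)
  set.seed(99)
  for (i in 1:25) {
    g1 <- sample(m$genes, sample.int(3, 1))
    g2 <- union(g1, sample(m$genes, sample.int(3, 1)))
    r1 <- reactions_disabled_by(m, g1)$reactions
    r2 <- reactions_disabled_by(m, g2)$reactions
    expect_true(all(r1 %in% r2))
  }
})

test_that("malformed GPR rules are rejected", {
  S <- matrix(c(-1, 1), 2, 1)
  expect_error(metabolic_model("R1", c("A", "B"), S, 0, 10, "g1 and"),
               "malformed GPR")
  expect_error(metabolic_model("R1", c("A", "B"), S, 0, 10, "(g1 or g2"),
               "malformed GPR")
  expect_error(metabolic_model("R1", c("A", "B"), S, 0, 10, "g1 g2"),
               "malformed GPR")
})

test_that("medium application sets exchange uptake bounds", {
  m <- toy7(oracle = FALSE)
  m2 <- apply_medium(m, c(EX_carbon = 4))
  expect_equal(unname(m2$lower_bounds["EX_carbon"]), -4)
  # exchanges not in the medium have uptake closed, secretion kept
  expect_true(all(m2$lower_bounds[setdiff(exchange_reactions(m2),
                                          "EX_carbon")] >= 0))
  expect_equal(solve_fba(m2)$objective_value, 0.2)
  expect_error(apply_medium(m, c(EX_nope = 1)), "unknown exchange")
})
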