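# three-route model: active R1 (cap 4), inactive direct R2 (cap 4),
# inactive two-step detour R3a/R3b (cap 4); uptake 7
threeRouteModel <- function(uptake = 7) {
  MetabolicModel(
    "threeroute",
    metabolites = data.frame(id = c("A_e", "A_c", "X_c", "B_c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "R1", "R2", "R3a", "R3b", "DM_B"),
      lower_bound = c(-uptake, 0, 0, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 4, 4, 4, 4, 1000),
      gene_reaction_rule = c("", "gT", "gA", "gB", "gC", "gC", "")),
    stoich = list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                  R1 = c(A_c = -1, B_c = 1), R2 = c(A_c = -1, B_c = 1),
                  R3a = c(A_c = -1, X_c = 1), R3b = c(X_c = -1, B_c = 1),
                  DM_B = c(B_c = -1)),
    objective = "DM_B")
}

test_that("reaction activity labels follow GPR evaluation over active genes", {
  m <- gprFixtureModel()
  calls <- data.frame(gene = c("g_t", "g_i1", "g_c1", "g_m"),
                      active = c(TRUE, TRUE, TRUE, FALSE))
  act <- reactionActivityFromCalls(m, calls)
  expect_identical(unname(act[["EX_A_e"]]), "no_gene")
  expect_identical(unname(act[["ISO"]]), "active")    # isozyme g_i1 active
  expect_identical(unname(act[["CPLX"]]), "inactive") # g_c2 missing
  expect_identical(unname(act[["MIX"]]), "active")    # g_i1 and g_c1
  # oracle over all call subsets for every reaction with a rule
  genes <- modelGenes(m)
  for (i in 0:(2^length(genes) - 1)) {
    active <- genes[as.logical(bitwAnd(i, 2^(seq_along(genes) - 1)))]
    act <- reactionActivityFromCalls(m, active)
    for (r in reactionIds(m)) {
      rule <- gprRules(m)[[r]]
      expected <- if (rule$op == "empty") "no_gene"
                  else if (evaluateGPR(rule, active)) "active" else "inactive"
      expect_identical(unname(act[[r]]), expected)
    }
  }
})

test_that("GIMME keeps everything when all reactions are active", {
  m <- makeToyTemplate(1)
  act <- reactionActivityFromCalls(m, modelGenes(m))
  expect_false(any(act == "inactive"))
  out <- gimmeExtract(m, act)
  expect_setequal(reactionIds(out$model), reactionIds(m))
})

test_that("GIMME removes unneeded inactive routes and keeps required ones", {
  # only gA active: R2 and the detour are inactive
  m <- threeRouteModel(uptake = 7)
  act <- reactionActivityFromCalls(m, c("gA", "gT"))
  expect_setequal(names(act)[act == "inactive"], c("R2", "R3a", "R3b"))
  out <- gimmeExtract(m, act, gimmeConfig(fraction = 0.9))
  kept <- reactionIds(out$model)
  # f * opt = 6.3 > 4 = capacity of the active route, so one inactive
  # route must stay; the direct one is cheaper than the two-step detour
  expect_true("R2" %in% kept)
  expect_false(any(c("R3a", "R3b") %in% kept))
  expect_gte(objectiveValue(fba(out$model)), 0.9 * 7 - 1e-6)

  # with ample active capacity every inactive reaction goes
  m2 <- threeRouteModel(uptake = 4)
  out2 <- gimmeExtract(m2, reactionActivityFromCalls(m2, c("gA", "gT")),
                       gimmeConfig(fraction = 0.9))
  expect_setequal(reactionIds(out2$model),
                  c("EX_A_e", "T_A", "R1", "DM_B"))
})

test_that("inactive but objective-essential reactions are retained", {
  m <- chainModel()
  act <- reactionActivityFromCalls(m, character(0))  # R1's gene set empty
  act["R1"] <- "inactive"                            # force the label
  out <- gimmeExtract(m, act)
  expect_true("R1" %in% reactionIds(out$model))
  expect_true("R1" %in% out$report$keptInactive)
})

test_that("GIMME kept set agrees with subset-enumeration oracle", {
  m <- threeRouteModel(uptake = 7)
  act <- reactionActivityFromCalls(m, c("gA", "gT"))
  cfg <- gimmeConfig(fraction = 0.9)
  out <- gimmeExtract(m, act, cfg)
  opt <- objectiveValue(fba(m))
  inactive <- names(act)[act == "inactive"]
  removedInactive <- intersect(out$report$removedReactions, inactive)
  feasibleRemoval <- function(set) {
    sub <- subsetModel(m, setdiff(reactionIds(m), set))
    ok <- tryCatch(objectiveValue(fba(sub)) >= cfg$fraction * opt - 1e-6,
                   error = function(e) FALSE)
    ok
  }
  # the removal GIMME chose is itself feasible
  expect_true(feasibleRemoval(removedInactive))
  # and maximal: adding any kept inactive reaction breaks the contract
  for (r in setdiff(inactive, removedInactive)) {
    expect_false(feasibleRemoval(union(removedInactive, r)), info = r)
  }
  # full enumeration: every strict superset of the removal is infeasible
  for (k in seq_along(inactive)) {
    sets <- utils::combn(inactive, k, simplify = FALSE)
    for (s in sets) {
      if (all(removedInactive %in% s) && length(s) > length(removedInactive)) {
        expect_false(feasibleRemoval(s), info = paste(s, collapse = "+"))
      }
    }
  }
})

test_that("extracted models satisfy the objective and hygiene contracts", {
  sc <- simulateScenario(seed = 2)
  for (ct in names(sc$calls)) {
    constrained <- applyMedia(sc$template, sc$media[[ct]])
    templateOpt <- objectiveValue(fba(constrained))
    built <- buildCellModel(sc$template, sc$calls[[ct]], sc$media[[ct]])
    expect_gte(built$report$objectiveValue, 0.9 * templateOpt - 1e-6)
    # no blocked reactions, no dead ends, no leaks in the output
    expect_length(findBlockedReactions(built$model), 0)
    expect_equal(nrow(removeDeadEnds(built$model)$log), 0)
    expect_length(built$report$leaks, 0)
    # report counts equal direct tallies
    expect_identical(built$report$nReactions, nReactions(built$model))
    expect_identical(built$report$nMetabolites, nMetabolites(built$model))
    expect_identical(built$report$nGenes, length(modelGenes(built$model)))
  }
})

test_that("cell-type media shape the retained routes", {
  sc <- simulateScenario(seed = 1)
  naive <- buildCellModel(sc$template, sc$calls$naive, sc$media$naive)$model
  effector <- buildCellModel(sc$template, sc$calls$effector,
                             sc$media$effector)$model
  # fatty acids are in the naive medium only
  expect_true(all(c("FAt", "FAO") %in% reactionIds(naive)))
  expect_false(any(c("FAt", "FAO") %in% reactionIds(effector)))
})

test_that("task failures are flagged in the build report without aborting", {
  sc <- simulateScenario(seed = 1)
  tasks <- list(metabolicTask("ok", c(glc_e = 5), "pyr_c", "pass"),
                metabolicTask("impossible", c(leu_e = 1), "g6p_c", "pass"))
  expect_warning(
    built <- buildCellModel(sc$template, sc$calls$effector,
                            sc$media$effector, tasks = tasks),
    "expected to pass failed")
  tr <- built$report$taskResults
  expect_true(tr$passed[tr$task == "ok"])
  expect_false(tr$passed[tr$task == "impossible"])
  expect_true(tr$flagged[tr$task == "impossible"])
})
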