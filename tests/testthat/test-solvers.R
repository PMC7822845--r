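test_that("FBA matches closed-form bottleneck values on chains", {
  expect_equal(objectiveValue(fba(chainModel(uptake = 10, capR1 = 10))), 10,
               tolerance = 1e-6)
  expect_equal(objectiveValue(fba(chainModel(uptake = 10, capR1 = 3))), 3,
               tolerance = 1e-6)
  expect_equal(objectiveValue(fba(chainModel(uptake = 2, capR1 = 10))), 2,
               tolerance = 1e-6)
})

test_that("FBA matches the vertex-enumeration oracle on toy networks", {
  models <- list(chainModel(10, 3), twoPathModel(10, 4, 4),
                 twoPathModel(6, 10, 1), gprFixtureModel())
  for (m in models) {
    obj <- as.numeric(reactionIds(m) == objectiveReaction(m))
    expect_equal(objectiveValue(fba(m)), oracleLP(m, obj),
                 tolerance = 1e-6, info = m@id)
  }
})

test_that("FBA reports infeasibility with the solver status", {
  m <- chainModel()
  m <- setBounds(m, "R1", lower = 5, upper = 5)
  m <- setBounds(m, "EX_A_e", lower = -1)   # cannot supply 5
  expect_error(fba(m), "infeasible")
})

test_that("FBA optimum is invariant under reaction order permutation", {
  m <- makeToyTemplate(1)
  base <- objectiveValue(fba(m))
  set.seed(1)
  perm <- sample(nReactions(m))
  rx <- m@reactions[perm, , drop = FALSE]
  rownames(rx) <- NULL
  S <- as.matrix(stoichiometry(m))
  stoich <- lapply(rx$id, function(r) {
    col <- S[, r]
    col[col != 0]
  })
  names(stoich) <- rx$id
  mp <- MetabolicModel("perm", m@metabolites, rx, stoich,
                       objective = objectiveReaction(m))
  expect_equal(objectiveValue(fba(mp)), base, tolerance = 1e-6)
})

test_that("FBA optimum is invariant under reversible-reaction splitting", {
  # A_e <-> A_c reversible transport, then chain to demand
  m <- MetabolicModel(
    "rev",
    metabolites = data.frame(id = c("A_e", "A_c")),
    reactions = data.frame(id = c("EX_A_e", "T_A", "DM_A"),
                           lower_bound = c(-5, -1000, 0),
                           upper_bound = c(1000, 1000, 1000)),
    stoich = list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                  DM_A = c(A_c = -1)),
    objective = "DM_A")
  msplit <- MetabolicModel(
    "revsplit",
    metabolites = data.frame(id = c("A_e", "A_c")),
    reactions = data.frame(id = c("EX_A_e", "T_Af", "T_Ar", "DM_A"),
                           lower_bound = c(-5, 0, 0, 0),
                           upper_bound = c(1000, 1000, 1000, 1000)),
    stoich = list(EX_A_e = c(A_e = -1), T_Af = c(A_e = -1, A_c = 1),
                  T_Ar = c(A_e = 1, A_c = -1), DM_A = c(A_c = -1)),
    objective = "DM_A")
  expect_equal(objectiveValue(fba(m)), objectiveValue(fba(msplit)),
               tolerance = 1e-6)
})

test_that("FVA brackets the FBA flux and matches per-reaction oracles", {
  m <- twoPathModel(10, 8, 8)
  sol <- fluxes(fba(m))
  for (frac in c(0, 0.5, 1)) {
    rng <- fva(m, fraction = frac)
    for (i in seq_len(nrow(rng))) {
      orc <- oracleFVA(m, rng$reaction[i], fraction = frac)
      expect_equal(rng$min[i], unname(orc["min"]), tolerance = 1e-5,
                   info = paste(rng$reaction[i], frac))
      expect_equal(rng$max[i], unname(orc["max"]), tolerance = 1e-5,
                   info = paste(rng$reaction[i], frac))
    }
    if (frac == 1) {
      expect_true(all(rng$min <= sol[rng$reaction] + 1e-6))
      expect_true(all(rng$max >= sol[rng$reaction] - 1e-6))
    }
  }
  # parallel path: range wider at fraction 0 than at 1
  r0 <- fva(m, fraction = 0, reactions = "R1")
  r1 <- fva(m, fraction = 1, reactions = "R1")
  expect_gt(r0$max - r0$min, (r1$max - r1$min) - 1e-9)
})

test_that("blocked reactions are exactly the zero-range reactions", {
  # dangling consumer with no producer for its substrate
  m <- MetabolicModel(
    "blocked",
    metabolites = data.frame(id = c("A_e", "A_c", "B_c", "X_c", "Y_c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "R1", "DM_B", "RX", "RY"),
      lower_bound = c(-10, 0, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000, 10, 10)),
    stoich = list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                  R1 = c(A_c = -1, B_c = 1), DM_B = c(B_c = -1),
                  RX = c(X_c = -1, Y_c = 1), RY = c(Y_c = -1, X_c = 1)),
    objective = "DM_B")
  blocked <- findBlockedReactions(m)
  # RX/RY form an isolated cycle: can carry flux, not blocked; nothing else is
  expect_length(blocked, 0)
  m2 <- setBounds(m, "RY", upper = 0)   # now X has no producer
  expect_setequal(findBlockedReactions(m2), c("RX", "RY"))
  # optimal-path reactions are never blocked
  expect_false(any(c("EX_A_e", "T_A", "R1", "DM_B") %in%
                     findBlockedReactions(m2)))
  # oracle agreement on every reaction
  for (r in reactionIds(m2)) {
    orc <- oracleFVA(m2, r, fraction = 0)
    expect_identical(r %in% findBlockedReactions(m2),
                     max(abs(orc)) < 1e-6, info = r)
  }
})

test_that("quadratic MoMA returns the wild type when unperturbed", {
  m <- twoPathModel(10, 6, 6)
  wt <- fba(m)
  back <- moma(m, wt)
  expect_equal(fluxes(back), fluxes(wt), tolerance = 1e-5)
  expect_lt(sum((fluxes(back) - fluxes(wt))^2), 1e-8)
})

test_that("quadratic MoMA matches a grid-search oracle after knockout", {
  # wild type splits A->B across R1/R2; knocking out R1 leaves a 1-D
  # family parameterized by the R2 flux
  m <- twoPathModel(10, 10, 10)
  wt <- FluxDistribution(
    fluxes = c(EX_A_e = -10, T_A = 10, R1 = 6, R2 = 4, DM_B = 10),
    objectiveValue = 10)
  ko <- setBounds(m, "R1", lower = 0, upper = 0)
  sol <- moma(ko, wt)
  # grid search over R2 in [0, 10]: v = (-r2, r2, 0, r2, r2)
  grid <- seq(0, 10, by = 1e-4)
  dist2 <- (grid - 10)^2 + (grid - 10)^2 + 36 + (grid - 4)^2 + (grid - 10)^2
  best <- grid[which.min(dist2)]
  expect_equal(unname(fluxes(sol)[["R2"]]), best, tolerance = 1e-4)
  expect_equal(unname(fluxes(sol)[["R1"]]), 0, tolerance = 1e-8)

  # capacity-limited variant pins the reroute at the bound
  ko2 <- setBounds(m, "R1", lower = 0, upper = 0)
  ko2 <- setBounds(ko2, "R2", upper = 7)
  sol2 <- moma(ko2, wt)
  expect_equal(unname(fluxes(sol2)[["R2"]]), 7, tolerance = 1e-5)
})

test_that("MoMA growth is zero when the only biomass path is closed", {
  m <- chainModel()
  wt <- fba(m)
  ko <- setBounds(m, "R1", lower = 0, upper = 0)
  sol <- moma(ko, wt)
  expect_equal(objectiveValue(sol), 0, tolerance = 1e-7)
})

test_that("linear MoMA agrees with quadratic on unique-solution cases", {
  m <- chainModel(uptake = 10, capR1 = 3)
  wt <- fba(m)
  ko <- setBounds(m, "R1", upper = 1)
  q <- moma(ko, wt)
  l <- moma(ko, wt, variant = "linear")
  expect_equal(objectiveValue(q), 1, tolerance = 1e-5)
  expect_equal(objectiveValue(l), 1, tolerance = 1e-5)
})

test_that("MoMA distance is zero iff wild type is feasible in the perturbed model", {
  m <- twoPathModel(10, 6, 6)
  wt <- fba(m)
  # perturbation that keeps the wild type feasible
  still <- setBounds(m, "R1", upper = max(abs(fluxes(wt)[["R1"]]), 6))
  s1 <- moma(still, wt)
  expect_lt(sum((fluxes(s1) - fluxes(wt))^2), 1e-8)
  # perturbation that excludes it
  cut <- setBounds(m, "EX_A_e", lower = -4)
  s2 <- moma(cut, wt)
  expect_gt(sum((fluxes(s2) - fluxes(wt))^2), 1e-3)
})
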