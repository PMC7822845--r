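test_that("drug target mapping drops withdrawn drugs and non-model genes", {
  m <- gprFixtureModel()
  ann <- data.frame(
    drug = c("d1", "d2", "d3", "d4"),
    status = c("launched", "withdrawn", "phase2", "launched"),
    stringsAsFactors = FALSE)
  ann$targets <- list(c("g_i1", "g_c1"), "g_i1", "g_absent", c("g_c1", "g_m"))
  mapped <- mapDrugTargets(ann, m)
  expect_setequal(names(mapped), c("g_i1", "g_c1", "g_m"))
  expect_identical(mapped$g_i1, "d1")            # d2 withdrawn
  expect_setequal(mapped$g_c1, c("d1", "d4"))
  # nested-loop oracle
  oracle <- list()
  for (i in seq_len(nrow(ann))) {
    if (tolower(ann$status[i]) == "withdrawn") next
    for (g in ann$targets[[i]]) {
      if (g %in% modelGenes(m)) oracle[[g]] <- union(oracle[[g]], ann$drug[i])
    }
  }
  expect_identical(mapped[sort(names(mapped))], oracle[sort(names(oracle))])
})

test_that("disabled sets match the GPR truth-table oracle for every gene", {
  m <- gprFixtureModel()
  for (g in modelGenes(m)) {
    oracle <- reactionIds(m)[vapply(reactionIds(m), function(r) {
      rule <- gprRules(m)[[r]]
      rule$op != "empty" &&
        evaluateGPR(rule, modelGenes(m)) &&
        !evaluateGPR(rule, setdiff(modelGenes(m), g))
    }, logical(1))]
    expect_setequal(disabledReactions(m, g), oracle)
  }
  # isozyme-backed deletion is silent, complex member disables
  expect_length(disabledReactions(m, "g_i1"), 0)
  expect_identical(disabledReactions(m, "g_c1"), "CPLX")
  expect_length(disabledReactions(m, "g_m"), 0)
})

test_that("knockouts respect isozyme protection and kill single paths", {
  m <- gprFixtureModel()
  wt <- fba(m)
  silent <- geneKnockout(m, "g_i1", wt)
  expect_true(silent$silent)
  expect_equal(silent$growthRatio, 1)
  expect_identical(fluxes(silent$vKO), fluxes(wt))

  lethal <- geneKnockout(m, "g_t", wt)   # sole transport gene
  expect_false(lethal$silent)
  expect_equal(lethal$growthRatio, 0, tolerance = 1e-6)
  # disabled reactions carry zero flux in the knockout state
  expect_true(all(abs(fluxes(lethal$vKO)[lethal$disabled]) < 1e-9))

  # effective-target filter keeps exactly the non-silent knockouts
  kos <- knockoutScreen(m, c("g_i1", "g_t", "g_c1", "g_m"), wt)
  expect_setequal(filterEffectiveTargets(kos), c("g_t", "g_c1"))
})

test_that("isozyme invariance: OR-sibling knockout never changes growth", {
  m <- applyMedia(makeToyTemplate(1), toyMedia("effector"))
  wt <- fba(m)
  for (g in c("g_glut3", "g_hk2", "g_idh3", "g_ldhb", "g_gls2")) {
    ko <- geneKnockout(m, g, wt)
    expect_true(ko$silent, info = g)
    expect_equal(ko$growthRatio, 1, info = g)
  }
})

test_that("flux-change classification applies the magnitude rules", {
  vWT <- c(R1 = 2, R2 = 2, R3 = 2, R4 = 0, R5 = 0, R6 = -2)
  vKO <- c(R1 = 2, R2 = 0, R3 = 2.5, R4 = 1, R5 = 0, R6 = 2)
  fc <- classifyFluxChanges(vWT, vKO)
  cls <- setNames(fc$class, fc$reaction)
  expect_identical(unname(cls[c("R1", "R2", "R3", "R4", "R5")]),
                   c("unchanged", "down", "up", "up", "unchanged"))
  # magnitude comparison: -2 -> +2 is unchanged but sign-flip is logged
  expect_identical(unname(cls[["R6"]]), "unchanged")
  expect_true(fc$sign_flip[fc$reaction == "R6"])
  expect_equal(fc$ratio[fc$reaction == "R2"], 0)
  expect_true(is.na(fc$ratio[fc$reaction == "R4"]))  # undefined at zero WT
})

test_that("classification matches a direct rule oracle on random pairs", {
  set.seed(33)
  relTol <- 0.05; absTol <- 1e-6
  vWT <- setNames(runif(300, -3, 3) * rbinom(300, 1, 0.8), paste0("r", 1:300))
  vKO <- vWT * runif(300, 0, 2) * sample(c(1, -1), 300, TRUE)
  fc <- classifyFluxChanges(vWT, vKO, relTol, absTol)
  for (i in seq_along(vWT)) {
    mw <- abs(vWT[i]); mk <- abs(vKO[i])
    expected <- if (mw <= absTol) {
      if (mk > absTol) "up" else "unchanged"
    } else if (abs(mk - mw) <= absTol ||
               (mk / mw >= 1 - relTol && mk / mw <= 1 + relTol)) {
      "unchanged"
    } else if (mk < mw * (1 - relTol)) "down"
    else if (mk > mw * (1 + relTol)) "up"
    else "unchanged"
    expect_identical(fc$class[i], expected, info = i)
  }
  # symmetric under simultaneous sign flip
  fc2 <- classifyFluxChanges(-vWT, -vKO, relTol, absTol)
  expect_identical(fc$class, fc2$class)
})

test_that("disabled reactions are never classified up", {
  sc <- simulateScenario(seed = 5)
  m <- buildCellModel(sc$template, sc$calls$effector, sc$media$effector)$model
  wt <- fba(m)
  for (g in intersect(c("g_slc1a5", "g_cs", "g_pc", "g_ogdh"), modelGenes(m))) {
    ko <- geneKnockout(m, g, wt)
    if (ko$silent) next
    fc <- classifyFluxChanges(wt, ko$vKO)
    cls <- fc$class[match(ko$disabled, fc$reaction)]
    expect_false(any(cls == "up"), info = g)
  }
})

test_that("essentiality classes follow the growth-ratio cutoffs", {
  m <- applyMedia(makeToyTemplate(1), toyMedia("effector"))
  scr <- essentialityScreen(m, variant = "quadratic")
  cls <- setNames(scr$class, scr$gene)
  # sole transporter of an essential amino acid
  expect_identical(unname(cls[["g_lat1"]]), "essential")
  # silent knockouts are nonessential
  expect_identical(unname(cls[["g_glut3"]]), "nonessential")
  # threshold oracle on the recorded ratios
  for (i in seq_len(nrow(scr))) {
    expected <- if (scr$growth_ratio[i] < 0.01) "essential"
                else if (scr$growth_ratio[i] < 0.5) "reduced" else "nonessential"
    expect_identical(scr$class[i], expected)
  }
})

test_that("precision-recall curves match prefix counting", {
  ratios <- c(a = 0.0, b = 0.1, c = 0.6, d = 0.9, e = 1.0)
  pos <- c("a", "c", "e")
  pr <- essentialityPRCurve(ratios, pos)
  # manual prefix computation
  expect_equal(pr$curve$precision, c(1, 1/2, 2/3, 2/4, 3/5))
  expect_equal(pr$curve$recall, c(1/3, 1/3, 2/3, 2/3, 1))
  manual <- 1/3 * 1 + 0 + (2/3 - 1/3) * (1/2 + 2/3)/2 + 0 +
    (1 - 2/3) * (1/2 + 3/5)/2
  expect_equal(pr$auc, manual)

  # all predictions positive -> area 1
  prAll <- essentialityPRCurve(ratios, names(ratios))
  expect_equal(prAll$auc, 1)
  # no overlap -> precision 0 everywhere
  prNone <- essentialityPRCurve(ratios, "zz")
  expect_true(all(prNone$curve$precision == 0))
  expect_error(essentialityPRCurve(ratios, character(0)), "empty reference")
})
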