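test_that("DEG loading filters at p and fold-change cutoffs with fallback", {
  degs <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(1.4, 1.0, 0.7, -1.2, 0.2, 2.0),
    p_adj = c(0.01, 0.01, 0.01, 0.04, 0.001, 0.2))
  # primary two-fold cutoff: |log2fc| >= 1 and p < 0.05
  out <- loadDEGs(degs, minMetabolicDegs = 1)
  expect_setequal(out$gene, c("g1", "g2", "g4"))   # g6 fails on p
  expect_identical(attr(out, "fc_cutoff"), 2)
  expect_identical(out$direction[out$gene == "g4"], "down")

  # too few metabolic DEGs at two-fold -> 1.5-fold fallback
  out2 <- loadDEGs(degs, minMetabolicDegs = 4)
  expect_true("g3" %in% out2$gene)                 # |1.5fc| = log2(1.5) = 0.585
  expect_identical(attr(out2, "fc_cutoff"), 1.5)

  # metabolic universe restricts the count that triggers fallback
  out3 <- loadDEGs(degs, minMetabolicDegs = 2, metabolicGenes = c("g1"))
  expect_identical(attr(out3, "fc_cutoff"), 1.5)

  expect_error(loadDEGs(data.frame(gene_id = "g", log2fc = 1)), "missing columns")

  # filter oracle
  keep <- abs(degs$log2fc) >= 1 & degs$p_adj < 0.05
  expect_setequal(out$gene, degs$gene_id[keep])
})

test_that("DEG-regulated reaction counts use union semantics per direction", {
  m <- gprFixtureModel()
  # classes: ISO down, CPLX down, MIX up, rest unchanged
  fluxTable <- data.frame(
    reaction = reactionIds(m),
    class = c("unchanged", "unchanged", "down", "down", "up", "unchanged",
              "unchanged"))
  # g_i1 (ISO, MIX) and g_c1 (CPLX, MIX) both upregulated; g_m downregulated
  degs <- data.frame(gene = c("g_i1", "g_c1", "g_m"),
                     direction = c("up", "up", "down"))
  counts <- countDegFluxChanges(fluxTable, degs, m)
  # up group = {ISO, CPLX, MIX}: MIX counted once despite two up-DEGs
  expect_equal(unname(counts["UpDec"]), 2)
  expect_equal(unname(counts["UpInc"]), 1)
  expect_equal(unname(counts["UpUnc"]), 0)
  # down group = reactions of g_m = {MIX}, class up
  expect_equal(unname(counts["DownInc"]), 1)
  expect_equal(unname(counts["DownDec"]), 0)
  # no mapped DEG -> all zero
  none <- countDegFluxChanges(fluxTable,
                              data.frame(gene = "nope", direction = "up"), m)
  expect_true(all(none == 0))
})

test_that("the perturbation effect score reproduces worked values", {
  expect_equal(pes(c(UpDec = 2, UpInc = 0, UpUnc = 0,
                     DownDec = 0, DownInc = 3, DownUnc = 0)), 2)
  expect_equal(pes(c(UpDec = 0, UpInc = 0, UpUnc = 0,
                     DownDec = 0, DownInc = 0, DownUnc = 0)), 0)
  expect_equal(pes(c(UpDec = 3, UpInc = 1, UpUnc = 0,
                     DownDec = 0, DownInc = 0, DownUnc = 2)), 0.5)
  # scale invariance and monotonicity
  base <- c(UpDec = 2, UpInc = 1, UpUnc = 1, DownDec = 1, DownInc = 2,
            DownUnc = 0)
  expect_equal(pes(base), pes(base * 3))
  shifted <- base + c(1, 0, -1, 0, 0, 0)   # UpDec +1 at constant group total
  expect_gte(pes(shifted), pes(base))
})

test_that("PES stays within [-2, 2] and attains the bounds as documented", {
  set.seed(21)
  for (i in 1:200) {
    counts <- setNames(rpois(6, 3),
                       c("UpDec", "UpInc", "UpUnc", "DownDec", "DownInc",
                         "DownUnc"))
    p <- pes(counts)
    expect_gte(p, -2); expect_lte(p, 2)
    expect_equal(p, oraclePes(counts[1], counts[2], counts[3],
                              counts[4], counts[5], counts[6]))
  }
})

test_that("PES ranks put the highest score first and average ties", {
  expect_equal(unname(rankPES(c(a = 2, b = 0, c = -1))), c(1, 2, 3))
  r <- rankPES(c(a = 2, b = 2, c = 0))
  expect_equal(unname(r), c(1.5, 1.5, 3))
  # sort-based oracle
  set.seed(3)
  x <- runif(20)
  expect_equal(unname(rankPES(setNames(x, paste0("g", 1:20)))),
               unname(rank(-x)))
})

test_that("rank z-scores have mean zero and unit variance", {
  z <- zscoreRanks(c(a = 1, b = 2, c = 3))
  expect_equal(unname(z), c(-1, 0, 1))   # sample sd of 1:3 is 1
  zp <- zscoreRanks(c(a = 1, b = 2, c = 3), sdType = "population")
  expect_equal(unname(zp), c(-1, 0, 1) * sqrt(3 / 2))
  set.seed(8)
  for (i in 1:10) {
    ranks <- rankPES(setNames(runif(12), paste0("g", 1:12)))
    z <- zscoreRanks(ranks)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  expect_warning(zAll <- zscoreRanks(c(a = 2, b = 2, c = 2)), "tied")
  expect_true(all(zAll == 0))
})

test_that("aggregation sums per-model z and selects at the cutoff", {
  z <- cbind(m1 = c(g1 = -1.5, g2 = 0.5, g3 = 1.0, g4 = 0),
             m2 = c(g1 = -1.2, g2 = 0.2, g3 = 1.0, g4 = NA))
  expect_message(out <- aggregateAndSelect(z), "excluding 1")
  expect_false("g4" %in% out$gene)
  expect_equal(out$aggregate[out$gene == "g1"], -2.7)
  # threshold oracle on re-standardized aggregates
  agg <- rowSums(z[1:3, ])
  aggZ <- (agg - mean(agg)) / sd(agg)
  for (g in names(agg)) {
    expect_identical(out$selected[out$gene == g],
                     unname(aggZ[g] <= -1), info = g)
  }
  # ranks ascend with the aggregate
  expect_identical(out$gene, names(sort(agg)))
  expect_equal(out$rank, unname(rank(sort(agg))))
  # raw-sum mode thresholds the un-standardized aggregate
  raw <- aggregateAndSelect(z[1:3, ], restandardize = FALSE, cutoff = -1)
  expect_identical(raw$selected, raw$aggregate <= -1)
})

test_that("tie handling flows through ranking to aggregation", {
  pesTables <- list(
    mA = data.frame(gene = c("g1", "g2", "g3", "g4"),
                    pes = c(2, 2, 0, -1)),
    mB = data.frame(gene = c("g1", "g2", "g3", "g4"),
                    pes = c(1.5, 0.5, 0.5, -0.5)))
  out <- rankTargets(pesTables, cutoff = -1)
  # g1 and g2 tie at the top of model A: ranks 1.5 each
  zA <- zscoreRanks(rankPES(setNames(pesTables$mA$pes, pesTables$mA$gene)))
  expect_equal(out$mA[out$gene == "g1"], unname(zA["g1"]))
  expect_equal(out$mA[out$gene == "g2"], unname(zA["g2"]))
  expect_equal(out$mA[match(c("g1", "g2"), out$gene)],
               rep(unname(zA["g1"]), 2))
})

test_that("pathway enrichment matches hypergeometric tail summation", {
  set.seed(17)
  background <- paste0("g", 1:200)
  for (i in 1:50) {
    K <- sample(5:80, 1)
    n <- sample(5:60, 1)
    pw <- sample(background, K)
    gs <- sample(background, n)
    out <- pathwayEnrichment(gs, background, list(p = pw))
    k <- length(intersect(gs, pw))
    expect_equal(out$p, oracleHyperTail(k, K, 200, n), tolerance = 1e-12)
    expect_equal(out$fold_enrichment, (k / n) / (K / 200))
  }
})

test_that("enrichment handles saturated and degenerate pathways", {
  bg <- paste0("g", 1:50)
  out <- pathwayEnrichment(bg, bg, list(all = bg))
  expect_equal(out$fold_enrichment, 1)
  expect_equal(out$p, 1)
  expect_message(
    out2 <- pathwayEnrichment(bg[1:5], bg, list(empty = "zz", all = bg)),
    "skipping")
  expect_identical(out2$pathway, "all")
  expect_error(pathwayEnrichment(c("zz"), bg, list(all = bg)), "subset")
})

test_that("BH adjustment is monotone nondecreasing in raw p order", {
  set.seed(2)
  bg <- paste0("g", 1:300)
  pws <- lapply(1:12, function(i) sample(bg, sample(10:60, 1)))
  names(pws) <- paste0("pw", 1:12)
  out <- pathwayEnrichment(sample(bg, 40), bg, pws)
  ord <- order(out$p)
  expect_true(all(diff(out$fdr[ord]) >= -1e-12))
  expect_equal(out$fdr, p.adjust(out$p, "BH")[seq_len(nrow(out))])
})
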