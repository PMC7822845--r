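test_that("discretization applies the strict majority rule on detected samples", {
  calls <- rbind(a = c(1, 1, 1, 0, 0), b = c(1, 1, 0, 0, NA_real_))
  calls["b", 5] <- 0
  det <- rbind(a = c(1, 1, 1, 1, 1), b = c(1, 1, 1, 1, 0))
  out <- discretizeCalls(calls, det)
  # a: 3 of 5 detected positive -> active (strict > 0.5)
  expect_identical(out$status[out$gene == "a"], "active")
  # b: 2 of 4 detected positive -> inactive (boundary is strict)
  expect_identical(out$status[out$gene == "b"], "inactive")

  # never-detected genes are undetermined, not inactive
  calls2 <- rbind(c = c(0, 0, 0))
  det2 <- rbind(c = c(0, 0, 0))
  expect_identical(discretizeCalls(calls2, det2)$status, "undetermined")

  expect_error(discretizeCalls(matrix(nrow = 0, ncol = 0)), "empty")
  expect_error(discretizeCalls(rbind(a = c(1, 1)), rbind(a = c(1, 0))),
               "not detected")
})

test_that("discretization matches a per-gene counting oracle on random matrices", {
  set.seed(11)
  calls <- matrix(rbinom(160, 1, 0.5), 20, 8,
                  dimnames = list(paste0("g", 1:20), NULL))
  det <- matrix(rbinom(160, 1, 0.8), 20, 8,
                dimnames = list(paste0("g", 1:20), NULL))
  calls <- calls * det
  out <- discretizeCalls(calls, det)
  for (i in 1:20) {
    nd <- sum(det[i, ])
    ne <- sum(calls[i, ] == 1 & det[i, ] == 1)
    expected <- if (nd == 0) "undetermined"
                else if (ne / nd > 0.5) "active" else "inactive"
    expect_identical(out$status[i], expected, info = rownames(calls)[i])
    if (nd > 0) expect_equal(out$support[i], ne / nd)
  }
})

test_that("integration tiers follow the consensus rules", {
  trans <- data.frame(gene = c("both", "tr_hi", "tr_lo", "none", "tr_only"),
                      support = c(0.8, 0.92, 0.7, 0.2, 0.95),
                      status = c("active", "active", "active", "inactive",
                                 "active"))
  prot <- data.frame(gene = c("both", "tr_hi", "tr_lo", "none", "pr_hi",
                              "pr_lo"),
                     support = c(0.9, 0.3, 0.2, 0.1, 0.8, 0.9),
                     quantile = c(0.5, 0.4, 0.3, 0.2, 0.80, 0.60),
                     status = c("active", "inactive", "inactive", "inactive",
                                "active", "active"))
  out <- integrateOmics(trans, prot)
  tier <- function(g) out$tier[out$gene == g]
  expect_identical(tier("both"), "high")
  # transcriptomics-only at support 0.92 >= 0.90 -> included
  expect_identical(tier("tr_hi"), "moderate_transcriptomic")
  expect_identical(tier("tr_lo"), "none")
  expect_identical(tier("tr_only"), "moderate_transcriptomic")
  # proteomics-only: quantile 0.80 >= 0.75 in, 0.60 out
  expect_identical(tier("pr_hi"), "moderate_proteomic")
  expect_identical(tier("pr_lo"), "none")
  expect_identical(tier("none"), "none")
  expect_identical(out$active, out$tier != "none")
})

test_that("integration matches a rule-by-rule oracle on random fixtures", {
  set.seed(5)
  genes <- paste0("g", 1:60)
  trans <- data.frame(gene = genes, support = runif(60),
                      status = sample(c("active", "inactive"), 60, TRUE))
  prot <- data.frame(gene = genes, support = runif(60),
                     quantile = runif(60),
                     status = sample(c("active", "inactive"), 60, TRUE))
  out <- integrateOmics(trans, prot)
  for (i in seq_along(genes)) {
    tA <- trans$status[i] == "active"
    pA <- prot$status[i] == "active"
    expected <- if (tA && pA) "high"
      else if (tA && !pA && trans$support[i] >= 0.9) "moderate_transcriptomic"
      else if (!tA && pA && prot$quantile[i] >= 0.75) "moderate_proteomic"
      else "none"
    expect_identical(out$tier[out$gene == genes[i]], expected, info = genes[i])
  }
  # size sandwich: overlap <= integrated <= union of single-omics actives
  overlap <- sum(trans$status == "active" & prot$status == "active")
  union <- sum(trans$status == "active" | prot$status == "active")
  expect_gte(sum(out$active), overlap)
  expect_lte(sum(out$active), union)
})

test_that("integration is monotone in transcriptomic support", {
  trans <- data.frame(gene = "g", support = 0.85, status = "active")
  prot <- data.frame(gene = "g", support = 0.2, quantile = 0.4,
                     status = "inactive")
  low <- integrateOmics(trans, prot)
  trans$support <- 0.95
  high <- integrateOmics(trans, prot)
  expect_false(low$active)
  expect_true(high$active)  # raising support never flips active -> inactive
})

test_that("proteomics quantiles are computed per sample then averaged", {
  ab <- rbind(hi = c(100, 200), mid = c(10, 20), lo = c(1, 2),
              gone = c(NA, NA))
  out <- proteomicsActivity(ab)
  expect_identical(out$status[out$gene == "gone"], "undetermined")
  q <- setNames(out$quantile, out$gene)
  expect_gt(q[["hi"]], q[["mid"]])
  expect_gt(q[["mid"]], q[["lo"]])
  expect_equal(unname(q[["hi"]]), 1)  # top rank of 3 detected in both samples
})

test_that("multi-dataset combination uses a per-dataset majority", {
  d1 <- data.frame(gene = c("a", "b"), support = c(1, 0),
                   status = c("active", "inactive"))
  d2 <- data.frame(gene = c("a", "b"), support = c(1, 1),
                   status = c("active", "active"))
  d3 <- data.frame(gene = c("a", "b", "c"), support = c(0, 1, NA),
                   status = c("inactive", "active", "undetermined"))
  out <- combineActivityCalls(list(d1, d2, d3))
  # a: 2/3 active -> active ; b: 2/3 -> active ; c: undetermined everywhere
  expect_identical(out$status[out$gene == "a"], "active")
  expect_identical(out$status[out$gene == "b"], "active")
  expect_identical(out$status[out$gene == "c"], "undetermined")
})

test_that("presence matrices and abundance tables round-trip via TSV", {
  sc <- simulateScenario(seed = 3)
  dir <- withr::local_tempdir()
  writeScenario(sc, dir)
  pm <- readPresenceMatrix(file.path(dir, "naive_calls.tsv"),
                          file.path(dir, "naive_detected.tsv"))
  expect_equal(pm$calls, sc$omics$naive$transcriptomics$calls)
  expect_equal(pm$detected, sc$omics$naive$transcriptomics$detected)
  ab <- readAbundanceTable(file.path(dir, "naive_abundance.tsv"))
  expect_equal(ab, sc$omics$naive$proteomics, tolerance = 1e-10)
})
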