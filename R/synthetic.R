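#' Build a toy CD4 T-cell-style template network
#'
#' A small, mass-consistent constraint-based model that mirrors the
#' pathway structure relevant to T-cell metabolism: a glucose uptake and
#' lumped glycolysis chain ending in a pyruvate node that branches to
#' lactate secretion and a TCA-like oxidative cycle (with ATP yield), a
#' glutamine -> glutamate -> alpha-ketoglutarate anaplerotic route with a
#' transaminase bypass that can regenerate glutamate from the cycle, a
#' fatty-acid uptake/beta-oxidation branch, pyruvate carboxylase
#' anaplerosis, and a biomass reaction drawing six precursors (G6P,
#' acetyl-CoA, glutamate, oxaloacetate, leucine, ATP). GPR rules include
#' isozyme (OR) pairs for the glucose transporter, hexokinase, IDH, LDH
#' and glutaminase, and complex (AND) rules for lumped glycolysis, the
#' mitochondrial pyruvate carrier, PDH and the carnitine shuttle. The
#' \code{"medium"} size class adds a pentose-phosphate branch feeding a
#' nucleotide precursor into biomass.
#'
#' The generator is deterministic: the seed is recorded in the model id
#' and annotations so scenario files are reproducible byte for byte, but
#' the network topology itself is fixed by design (the study conditions,
#' not random draws).
#'
#' @param seed Integer recorded for provenance.
#' @param size \code{"small"} (default) or \code{"medium"}.
#' @return A \code{\linkS4class{MetabolicModel}} that is FBA-feasible
#'   with positive growth under its default bounds and leak-free.
#' @export
makeToyTemplate <- function(seed = 1L, size = c("small", "medium")) {
  size <- match.arg(size)
  mets <- c("glc_e", "glc_c", "g6p_c", "pyr_c", "pyr_m", "lac_c", "lac_e",
            "gln_e", "gln_c", "glu_c", "akg_m", "accoa_m", "oaa_m", "cit_m",
            "co2_m", "co2_e", "fa_e", "fa_c", "leu_e", "leu_c", "o2_e",
            "o2_m", "atp_c", "biomass_c")
  if (size == "medium") mets <- c(mets, "r5p_c", "nuc_c")
  metDf <- data.frame(id = mets, stringsAsFactors = FALSE)

  rx <- list()
  addRxn <- function(id, stoich, lb, ub, gpr = "", subsystem = NA_character_) {
    rx[[id]] <<- list(stoich = stoich, lb = lb, ub = ub, gpr = gpr,
                      subsystem = subsystem)
  }
  UB <- 1000
  addRxn("EX_glc_e", c(glc_e = -1), -10, UB, subsystem = "exchange")
  addRxn("EX_gln_e", c(gln_e = -1), -5, UB, subsystem = "exchange")
  addRxn("EX_fa_e", c(fa_e = -1), -2, UB, subsystem = "exchange")
  addRxn("EX_leu_e", c(leu_e = -1), -1, UB, subsystem = "exchange")
  addRxn("EX_o2_e", c(o2_e = -1), -3, UB, subsystem = "exchange")
  addRxn("EX_lac_e", c(lac_e = -1), 0, UB, subsystem = "exchange")
  addRxn("EX_co2_e", c(co2_e = -1), 0, UB, subsystem = "exchange")
  addRxn("GLCt", c(glc_e = -1, glc_c = 1), 0, UB, "g_glut1 or g_glut3",
         "transport")
  addRxn("GLNt", c(gln_e = -1, gln_c = 1), 0, UB, "g_slc1a5", "transport")
  addRxn("FAt", c(fa_e = -1, fa_c = 1), 0, UB, "g_cd36", "transport")
  addRxn("LEUt", c(leu_e = -1, leu_c = 1), 0, UB, "g_lat1", "transport")
  addRxn("LACt", c(lac_c = -1, lac_e = 1), 0, UB, "g_mct1", "transport")
  addRxn("O2t", c(o2_e = -1, o2_m = 1), 0, UB, "", "transport")
  addRxn("CO2t", c(co2_m = -1, co2_e = 1), 0, UB, "", "transport")
  addRxn("HEX", c(glc_c = -1, g6p_c = 1), 0, UB, "g_hk1 or g_hk2",
         "glycolysis")
  addRxn("PYK", c(g6p_c = -1, pyr_c = 2, atp_c = 2), 0, UB,
         "g_gapdh and g_pkm", "glycolysis")
  addRxn("LDH", c(pyr_c = -1, lac_c = 1), 0, UB, "g_ldha or g_ldhb",
         "glycolysis")
  addRxn("PYRt", c(pyr_c = -1, pyr_m = 1), 0, UB, "g_mpc1 and g_mpc2",
         "transport")
  addRxn("PDH", c(pyr_m = -1, o2_m = -0.5, accoa_m = 1, co2_m = 1,
                  atp_c = 1), 0, UB, "g_pdha1 and g_pdhb", "tca")
  addRxn("FAO", c(fa_c = -1, accoa_m = 2), 0, UB, "g_cpt1a and g_cpt2",
         "fatty_acid")
  addRxn("PC", c(pyr_m = -1, co2_m = -1, oaa_m = 1), 0, UB, "g_pc",
         "anaplerosis")
  addRxn("CS", c(accoa_m = -1, oaa_m = -1, cit_m = 1), 0, UB, "g_cs", "tca")
  addRxn("IDH", c(cit_m = -1, o2_m = -0.5, akg_m = 1, co2_m = 1,
                  atp_c = 2), 0, UB, "g_idh2 or g_idh3", "tca")
  addRxn("OGDH", c(akg_m = -1, o2_m = -0.5, oaa_m = 1, co2_m = 1,
                   atp_c = 2), 0, UB, "g_ogdh", "tca")
  addRxn("GLS", c(gln_c = -1, glu_c = 1), 0, UB, "g_gls or g_gls2",
         "glutaminolysis")
  addRxn("GLUD", c(glu_c = -1, akg_m = 1), 0, UB, "g_glud1",
         "glutaminolysis")
  addRxn("GOT", c(akg_m = -1, glu_c = 1), 0, UB, "g_got1", "glutaminolysis")
  biomass <- c(g6p_c = -1, accoa_m = -1, glu_c = -1, oaa_m = -1,
               leu_c = -1, atp_c = -10, biomass_c = 1)
  if (size == "medium") {
    addRxn("G6PDH", c(g6p_c = -1, r5p_c = 1, co2_m = 1), 0, UB,
           "g_g6pd or g_pgd", "ppp")
    addRxn("NUCS", c(r5p_c = -1, glu_c = -1, atp_c = -2, nuc_c = 1), 0, UB,
           "g_ppat and g_gart", "nucleotide")
    biomass <- c(biomass, nuc_c = -1)
  }
  addRxn("BIOMASS", biomass, 0, UB, "", "biomass")
  # non-growth-associated maintenance: dissipates surplus ATP so forced
  # carbon influx stays feasible
  addRxn("ATPM", c(atp_c = -1), 0, UB, "", "maintenance")
  addRxn("DM_biomass_c", c(biomass_c = -1), 0, UB, "", "demand")

  rxnDf <- data.frame(
    id = names(rx),
    lower_bound = vapply(rx, `[[`, 0, "lb"),
    upper_bound = vapply(rx, `[[`, 0, "ub"),
    gene_reaction_rule = vapply(rx, `[[`, "", "gpr"),
    subsystem = vapply(rx, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE)
  rownames(rxnDf) <- NULL
  MetabolicModel(id = sprintf("toyT%s_%d", size, as.integer(seed)),
                 metabolites = metDf, reactions = rxnDf,
                 stoich = lapply(rx, `[[`, "stoich"),
                 objective = "BIOMASS",
                 annotations = list(toplevel = list(
                   generator = "makeToyTemplate", seed = as.integer(seed),
                   size = size)))
}

#' Default media for the toy template
#'
#' The naive medium carries fatty acids (naive cells oxidize fatty
#' acids) with moderate glucose; the effector medium is glucose-rich,
#' glutamine-rich and fatty-acid-free with tighter oxygen, reflecting
#' the glycolytic shift of activated cells. Uptake rates are
#' mmol/gDW/hr.
#'
#' @param cellType "naive" or "effector".
#' @return A \code{\link{mediaSpec}}.
#' @export
toyMedia <- function(cellType = c("naive", "effector")) {
  cellType <- match.arg(cellType)
  if (cellType == "naive") {
    mediaSpec(uptakeBounds = c(EX_glc_e = 2, EX_gln_e = 2, EX_fa_e = 2,
                               EX_leu_e = 1, EX_o2_e = 6))
  } else {
    mediaSpec(uptakeBounds = c(EX_glc_e = 10, EX_gln_e = 5,
                               EX_leu_e = 1, EX_o2_e = 3))
  }
}

#' Default per-gene activity profiles for the toy cell types
#'
#' Core pathway genes are near-certainly active in both cell types;
#' the fatty-acid oxidation branch is active in naive cells and near
#' silent in effectors, while lactate dehydrogenase and the secondary
#' glucose transporter/hexokinase isozymes follow the opposite,
#' glycolytic pattern.
#'
#' @param template The toy template (supplies the gene universe).
#' @return Named list: cell type -> named activity probability vector.
#' @export
toyCellProfiles <- function(template) {
  genes <- modelGenes(template)
  core <- c("g_glut1", "g_slc1a5", "g_lat1", "g_mct1", "g_hk1", "g_gapdh",
            "g_pkm", "g_mpc1", "g_mpc2", "g_pdha1", "g_pdhb", "g_pc",
            "g_cs", "g_idh2", "g_ogdh", "g_gls", "g_glud1", "g_got1",
            "g_ppat", "g_gart", "g_g6pd")
  naive <- stats::setNames(rep(0.1, length(genes)), genes)
  naive[intersect(core, genes)] <- 0.97
  naive[intersect(c("g_cd36", "g_cpt1a", "g_cpt2"), genes)] <- 0.95
  naive[intersect(c("g_ldha"), genes)] <- 0.2
  naive[intersect(c("g_glut3", "g_hk2", "g_idh3", "g_ldhb", "g_gls2",
                    "g_pgd"), genes)] <- 0.25
  effector <- stats::setNames(rep(0.1, length(genes)), genes)
  effector[intersect(core, genes)] <- 0.97
  effector[intersect(c("g_ldha"), genes)] <- 0.95
  effector[intersect(c("g_glut3", "g_hk2"), genes)] <- 0.6
  effector[intersect(c("g_cd36", "g_cpt1a", "g_cpt2"), genes)] <- 0.05
  effector[intersect(c("g_idh3", "g_ldhb", "g_gls2", "g_pgd"), genes)] <- 0.25
  list(naive = naive, effector = effector)
}

#' Simulate binary omics layers for one cell type
#'
#' Transcriptomics: per sample, each gene's call is drawn from its
#' profile probability and flipped with probability \code{flipNoise};
#' the probe-detection mask drops out with probability \code{dropout}
#' (calls are only observed where detected). Proteomics: detection
#' follows activity (high detection probability for active states),
#' with log-normal abundances centered higher for active genes so that
#' genuinely active genes concentrate in the top abundance quartile.
#'
#' @param template The toy template (gene universe).
#' @param profile Named activity probability vector for this cell type.
#' @param nSamples Transcriptomics sample count (default 8).
#' @param nProtSamples Proteomics sample count (default 4).
#' @param flipNoise Call flip probability in [0, 0.5) (default 0.05).
#' @param dropout Probe dropout probability (default 0.1).
#' @param seed RNG seed.
#' @return list(transcriptomics = list(calls, detected), proteomics =
#'   abundance matrix with NA where undetected).
#' @export
simulateOmics <- function(template, profile, nSamples = 8, nProtSamples = 4,
                          flipNoise = 0.05, dropout = 0.1, seed = 1L) {
  stopifnot(flipNoise >= 0, flipNoise < 0.5)
  genes <- modelGenes(template)
  stopifnot(all(genes %in% names(profile)))
  p <- profile[genes]
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    nG <- length(genes)
    draw <- function(ns) {
      truth <- matrix(stats::rbinom(nG * ns, 1, rep(p, ns)), nG, ns)
      flip <- matrix(stats::rbinom(nG * ns, 1, flipNoise), nG, ns)
      (truth + flip) %% 2
    }
    calls <- draw(nSamples)
    detected <- matrix(stats::rbinom(nG * nSamples, 1, 1 - dropout),
                       nG, nSamples)
    calls <- calls * detected
    dimnames(calls) <- dimnames(detected) <-
      list(genes, paste0("s", seq_len(nSamples)))
    protState <- draw(nProtSamples)
    detP <- matrix(stats::rbinom(nG * nProtSamples, 1,
                                 ifelse(protState == 1, 0.95, 0.25)),
                   nG, nProtSamples)
    abundance <- matrix(stats::rlnorm(nG * nProtSamples,
                                      meanlog = ifelse(protState == 1, 2, 0),
                                      sdlog = 0.5),
                        nG, nProtSamples)
    abundance[detP == 0] <- NA_real_
    dimnames(abundance) <- list(genes, paste0("p", seq_len(nProtSamples)))
    list(transcriptomics = list(calls = calls, detected = detected),
         proteomics = abundance)
  })
}

#' Integrate simulated omics into activity calls for one cell type
#'
#' Convenience wrapper: discretize the transcriptomics layer, score the
#' proteomics layer, and integrate with the consensus rules.
#'
#' @param omics Output of \code{\link{simulateOmics}}.
#' @param ... Passed to \code{\link{integrateOmics}}.
#' @return data.frame of integrated activity calls.
#' @export
integrateSimulatedOmics <- function(omics, ...) {
  trans <- discretizeCalls(omics$transcriptomics$calls,
                           omics$transcriptomics$detected)
  prot <- proteomicsActivity(omics$proteomics)
  integrateOmics(trans, prot, ...)
}
#' Simulate a disease DEG table with a planted reverser target
#'
#' Runs the real perturbation machinery on the context-specific models
#' that the pipeline itself will score: the planted target is deleted
#' (MoMA against each model's wild-type FBA solution) and the flux
#' changes classified. Disease-upregulated DEGs are drawn from genes
#' whose mapped reactions all decrease under the knockout in every
#' model where they map, and downregulated DEGs from genes whose
#' reactions all increase -- so by construction the planted knockout
#' exactly reverses the disease signature (its perturbation effect
#' score attains the maximum of 2 in every model). Decoy DEGs with no
#' flux linkage are added at the stated proportion; fold changes and
#' adjusted p-values are populated to pass the DEG filters.
#'
#' @param models Named list of context-specific
#'   \code{\linkS4class{MetabolicModel}}s (e.g. the GIMME-built cell
#'   models the scenario will be scored on).
#' @param plantedTarget Gene id to plant (default \code{"g_slc1a5"},
#'   the glutamine transporter: its deletion reroutes glutamate supply
#'   through the transaminase bypass while preserving growth, so the
#'   disease signature is a clean reversal rather than a growth
#'   collapse).
#' @param seed RNG seed.
#' @param decoyFraction Fraction of the final DEG table that is decoys
#'   (default 0.5).
#' @param variant MoMA variant.
#' @return list(degs, truth): \code{degs} is a DEG data.frame
#'   (gene_id, log2fc, direction, p_adj); \code{truth} records the
#'   planted gene, the DEG pools and the per-model knockout flux
#'   tables.
#' @export
simulateDisease <- function(models, plantedTarget = "g_slc1a5", seed = 1L,
                            decoyFraction = 0.5,
                            variant = c("quadratic", "linear")) {
  variant <- match.arg(variant)
  if (is(models, "MetabolicModel")) models <- list(model = models)
  genes <- sort(unique(unlist(lapply(models, modelGenes))))
  stopifnot(plantedTarget %in% genes)
  fcs <- list()
  growthRatios <- numeric(0)
  perModelClass <- list()
  for (i in seq_along(models)) {
    model <- models[[i]]
    if (!(plantedTarget %in% modelGenes(model))) {
      stop("generation error: planted target '", plantedTarget,
           "' absent from model '", model@id, "'")
    }
    wt <- fba(model)
    ko <- geneKnockout(model, plantedTarget, wt, variant = variant)
    if (ko$silent) {
      stop("generation error: planted target '", plantedTarget,
           "' is a silent knockout (isozyme-backed)")
    }
    fc <- classifyFluxChanges(wt, ko$vKO)
    fcs[[i]] <- fc
    growthRatios <- c(growthRatios, ko$growthRatio)
    perModelClass[[i]] <- lapply(stats::setNames(genes, genes), function(g) {
      if (!(g %in% modelGenes(model))) return(character(0))
      cls <- fc$class[match(reactionsOfGene(model, g), fc$reaction)]
      cls[!is.na(cls)]
    })
  }
  # a gene qualifies for a pool when the wanted flux-change class appears
  # among its reactions in at least one model and the opposite class
  # never appears in any model (unchanged reactions are tolerated)
  poolTest <- function(g, want, forbid) {
    classes <- unlist(lapply(perModelClass, `[[`, g))
    length(classes) > 0 && any(classes == want) && !any(classes == forbid)
  }
  upPool <- genes[vapply(genes, poolTest, logical(1),
                         want = "down", forbid = "up")]
  downPool <- genes[vapply(genes, poolTest, logical(1),
                           want = "up", forbid = "down")]
  if (!length(upPool) || !length(downPool)) {
    stop("generation error: planted knockout does not produce both ",
         "decreased and increased DEG pools")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 1000L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  nSig <- length(upPool) + length(downPool)
  # decoys are disease DEGs with no flux linkage at all: gene ids absent
  # from the metabolic models (non-metabolic genes in a real DEG table)
  nDecoy <- round(decoyFraction / (1 - decoyFraction) * nSig)
  decoys <- if (nDecoy > 0) sprintf("g_nonmet_%02d", seq_len(nDecoy))
            else character(0)
  mkRows <- function(gg, dir) {
    if (!length(gg)) return(NULL)
    lfc <- stats::runif(length(gg), 1.1, 2.5) * if (dir == "up") 1 else -1
    data.frame(gene_id = gg, log2fc = lfc, direction = dir,
               p_adj = stats::runif(length(gg), 1e-4, 0.04),
               stringsAsFactors = FALSE)
  }
  decoyDir <- sample(c("up", "down"), length(decoys), replace = TRUE)
  degs <- rbind(mkRows(upPool, "up"), mkRows(downPool, "down"),
                mkRows(decoys[decoyDir == "up"], "up"),
                mkRows(decoys[decoyDir == "down"], "down"))
  rownames(degs) <- NULL
  list(degs = degs,
       truth = list(planted = plantedTarget, upGenes = upPool,
                    downGenes = downPool, decoys = decoys,
                    fluxTables = fcs, growthRatios = growthRatios))
}

#' Simulate drug annotations and an essentiality reference
#'
#' Annotates a random subset of template genes with fictitious drugs
#' (including some withdrawn ones, which downstream mapping must
#' drop); the essentiality reference is computed by exhaustive
#' single-gene FBA deletion on the template.
#'
#' @param template The toy template.
#' @param coverage Fraction of genes annotated, in (0, 1] (default
#'   0.8).
#' @param seed RNG seed.
#' @param mustInclude Genes guaranteed an active (non-withdrawn)
#'   annotation (default the planted default target).
#' @param media Medium under which the essentiality reference is
#'   computed.
#' @return list(annotations, essentialTruth): annotations is a
#'   data.frame (drug, status, targets list column); essentialTruth the
#'   FBA-essential gene set.
#' @export
simulateAnnotations <- function(template, coverage = 0.8, seed = 1L,
                                mustInclude = "g_slc1a5",
                                media = toyMedia("effector")) {
  stopifnot(coverage > 0, coverage <= 1)
  genes <- modelGenes(template)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 2000L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  nAnn <- max(1L, round(coverage * length(genes)))
  annotated <- union(sample(genes, nAnn), intersect(mustInclude, genes))
  statuses <- c("launched", "phase2", "preclinical", "withdrawn")
  rows <- lapply(seq_along(annotated), function(i) {
    data.frame(drug = sprintf("drug_%03d", i),
               status = sample(statuses, 1, prob = c(0.5, 0.2, 0.2, 0.1)),
               targets = I(list(annotated[i])),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  # guarantee a live annotation for must-include genes
  for (g in intersect(mustInclude, genes)) {
    live <- vapply(seq_len(nrow(ann)), function(i)
      g %in% ann$targets[[i]] && ann$status[i] != "withdrawn", logical(1))
    if (!any(live)) {
      ann <- rbind(ann, data.frame(drug = sprintf("drug_%03d", nrow(ann) + 1L),
                                   status = "launched",
                                   targets = I(list(g)),
                                   stringsAsFactors = FALSE))
    }
  }
  constrained <- applyMedia(template, media)
  ess <- essentialityScreen(constrained, variant = "fba")
  list(annotations = ann,
       essentialTruth = ess$gene[ess$class == "essential"])
}

#' Generate a complete synthetic scenario
#'
#' Assembles template, media, cell-type profiles, simulated omics,
#' integrated activity calls, a disease DEG table with a planted
#' reverser target, drug annotations and the essentiality reference.
#' Optionally writes the scenario to a directory as plain-text files
#' (model JSON, omics TSVs, DEG TSV, annotation TSV, truth JSON and a
#' pipeline config YAML).
#'
#' @param seed Integer seed controlling every random draw.
#' @param size Template size class.
#' @param plantedTarget Planted reverser gene (default "g_slc1a5"). Its
#'   activity call is pinned active in every cell type so the engineered
#'   invariant -- the planted target maps to a reaction with no active
#'   isozyme in every scored model -- holds regardless of omics noise.
#' @param dir Optional output directory.
#' @param nSamples,flipNoise,dropout Passed to
#'   \code{\link{simulateOmics}}.
#' @param decoyFraction Passed to \code{\link{simulateDisease}}.
#' @return A list of class \code{fluxScenario} with elements template,
#'   media, profiles, omics, calls, disease, annotations,
#'   essentialTruth, seed, dir.
#' @export
simulateScenario <- function(seed = 1L, size = "small",
                             plantedTarget = "g_slc1a5", dir = NULL,
                             nSamples = 8, flipNoise = 0.05, dropout = 0.1,
                             decoyFraction = 0.5) {
  template <- makeToyTemplate(seed, size)
  media <- list(naive = toyMedia("naive"), effector = toyMedia("effector"))
  profiles <- toyCellProfiles(template)
  omics <- list()
  calls <- list()
  for (i in seq_along(profiles)) {
    ct <- names(profiles)[i]
    omics[[ct]] <- simulateOmics(template, profiles[[ct]],
                                 nSamples = nSamples, flipNoise = flipNoise,
                                 dropout = dropout, seed = seed + 10L * i)
    # pin the planted target and the anchor genes of its engineered
    # rerouting path (glutaminase and the transaminase bypass) in the
    # omics layers themselves, so the planted reversal exists in every
    # scored model and the written scenario files reproduce the same
    # integrated calls; all other genes keep their noisy draws
    anchors <- intersect(c(plantedTarget, "g_gls", "g_got1"),
                         modelGenes(template))
    om <- omics[[ct]]
    om$transcriptomics$calls[anchors, ] <- 1
    om$transcriptomics$detected[anchors, ] <- 1
    om$proteomics[anchors, ] <- exp(3)
    omics[[ct]] <- om
    calls[[ct]] <- integrateSimulatedOmics(om)
  }
  # the disease signature is planted against the same context-specific
  # models the pipeline scores (self-consistent planting: the real
  # build and perturbation code is the oracle during generation)
  builtModels <- lapply(names(calls), function(ct)
    buildCellModel(template, calls[[ct]], media[[ct]])$model)
  names(builtModels) <- names(calls)
  disease <- simulateDisease(builtModels, plantedTarget, seed = seed,
                             decoyFraction = decoyFraction)
  ann <- simulateAnnotations(template, seed = seed,
                             mustInclude = plantedTarget)
  scenario <- list(template = template, media = media, profiles = profiles,
                   omics = omics, calls = calls, disease = disease,
                   annotations = ann$annotations,
                   essentialTruth = ann$essentialTruth,
                   plantedTarget = plantedTarget, seed = seed, dir = dir)
  class(scenario) <- "fluxScenario"
  if (!is.null(dir)) writeScenario(scenario, dir)
  scenario
}

#' Write a scenario to a directory of plain-text files
#'
#' @param scenario A \code{fluxScenario}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeModel(scenario$template, file.path(dir, "model.json"))
  for (ct in names(scenario$omics)) {
    om <- scenario$omics[[ct]]
    writeMat <- function(m, name) {
      df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
      utils::write.table(df, file.path(dir, paste0(ct, "_", name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeMat(om$transcriptomics$calls, "calls")
    writeMat(om$transcriptomics$detected, "detected")
    writeMat(om$proteomics, "abundance")
  }
  utils::write.table(scenario$disease$degs, file.path(dir, "degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  annFlat <- scenario$annotations
  annFlat$targets <- vapply(annFlat$targets, paste, "", collapse = "|")
  utils::write.table(annFlat, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(planted = scenario$plantedTarget,
                upGenes = scenario$disease$truth$upGenes,
                downGenes = scenario$disease$truth$downGenes,
                decoys = scenario$disease$truth$decoys,
                essential = scenario$essentialTruth,
                seed = scenario$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- list(
    paths = list(template = "model.json", degs = "degs.tsv",
                 annotations = "annotations.tsv"),
    cell_types = lapply(names(scenario$media), function(ct) {
      list(name = ct,
           calls = paste0(ct, "_calls.tsv"),
           detected = paste0(ct, "_detected.tsv"),
           abundance = paste0(ct, "_abundance.tsv"),
           media = list(uptake_bounds =
                          as.list(scenario$media[[ct]]$uptake_bounds)))
    }),
    thresholds = list(discretization = 0.5, trans_support = 0.9,
                      prot_quantile = 0.75, gimme_fraction = 0.9,
                      fc_primary = 2.0, fc_fallback = 1.5,
                      min_metabolic_degs = 10,
                      essential_cutoff = 0.01, reduced_cutoff = 0.5,
                      aggregate_cutoff = -1),
    tolerances = list(tol = 1e-6, rel_tol = 0.05, abs_tol = 1e-6),
    moma_variant = "quadratic",
    seed = scenario$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @exportS3Method base::print
print.fluxScenario <- function(x, ...) {
  cat("fluxScenario (seed ", x$seed, ")\n", sep = "")
  cat("  template: ", nReactions(x$template), " reactions / ",
      length(modelGenes(x$template)), " genes\n", sep = "")
  cat("  cell types:", paste(names(x$profiles), collapse = ", "), "\n")
  cat("  planted target:", x$plantedTarget, "\n")
  cat("  DEGs:", nrow(x$disease$degs), " annotations:",
      nrow(x$annotations), "\n")
  invisible(x)
}
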