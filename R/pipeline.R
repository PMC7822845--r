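#' Knockout screen over a set of genes
#'
#' Runs \code{\link{geneKnockout}} for every gene against one cached
#' wild-type FBA solution.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param genes Genes to screen (default: all model genes).
#' @param referenceFlux Cached wild-type solution (computed when NULL).
#' @param variant MoMA variant.
#' @return Named list of \code{knockoutResult} objects.
#' @export
knockoutScreen <- function(model, genes = NULL, referenceFlux = NULL,
                           variant = c("quadratic", "linear")) {
  variant <- match.arg(variant)
  if (is.null(genes)) genes <- model@genes
  if (is.null(referenceFlux)) referenceFlux <- fba(model)
  kos <- lapply(genes, function(g)
    geneKnockout(model, g, referenceFlux, variant = variant))
  stats::setNames(kos, genes)
}

#' Score knockouts against a disease DEG table
#'
#' For each non-silent knockout, classifies all flux changes against
#' the wild-type distribution, counts DEG-regulated reactions per class
#' and computes the perturbation effect score.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param knockouts Output of \code{\link{knockoutScreen}}.
#' @param degs Filtered DEG table from \code{\link{loadDEGs}}.
#' @param referenceFlux The cached wild-type solution the knockouts
#'   were computed against.
#' @param relTol,absTol Flux-change classification tolerances.
#' @return data.frame: gene, the six counts, pes (one row per
#'   effective, non-silent knockout).
#' @export
scoreTargets <- function(model, knockouts, degs, referenceFlux,
                         relTol = 0.05, absTol = 1e-6) {
  eff <- filterEffectiveTargets(knockouts)
  rows <- lapply(eff, function(g) {
    ko <- knockouts[[g]]
    fc <- classifyFluxChanges(referenceFlux, ko$vKO, relTol = relTol,
                              absTol = absTol)
    counts <- countDegFluxChanges(fc, degs, model)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE),
          as.data.frame(t(counts)),
          data.frame(pes = pes(counts)))
  })
  if (!length(rows)) {
    return(data.frame(gene = character(0), UpDec = numeric(0),
                      UpInc = numeric(0), UpUnc = numeric(0),
                      DownDec = numeric(0), DownInc = numeric(0),
                      DownUnc = numeric(0), pes = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank and select targets across cell-type models
#'
#' Takes per-model PES tables for one disease, ranks PES within each
#' model (rank 1 = highest PES), z-standardizes the ranks, sums them
#' over models for genes scored in every model, and selects targets at
#' the aggregate cutoff.
#'
#' @param pesTables Named list (model id -> data.frame from
#'   \code{\link{scoreTargets}}).
#' @param cutoff Aggregate selection cutoff (default -1).
#' @param restandardize Apply the cutoff to the re-standardized
#'   aggregate (default TRUE).
#' @param sdType Standard deviation convention for the z-scores.
#' @return data.frame from \code{\link{aggregateAndSelect}} with one z
#'   column per model.
#' @export
rankTargets <- function(pesTables, cutoff = -1, restandardize = TRUE,
                        sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  zList <- lapply(pesTables, function(tab) {
    ranks <- rankPES(stats::setNames(tab$pes, tab$gene))
    zscoreRanks(ranks, sdType = sdType)
  })
  genes <- sort(unique(unlist(lapply(zList, names))))
  zMat <- sapply(zList, function(z) z[match(genes, names(z))])
  if (is.null(dim(zMat))) zMat <- matrix(zMat, nrow = length(genes))
  rownames(zMat) <- genes
  colnames(zMat) <- names(pesTables)
  aggregateAndSelect(zMat, cutoff = cutoff, restandardize = restandardize,
                     sdType = sdType)
}

#' Run the full pipeline on an in-memory synthetic scenario
#'
#' Stages: integrate omics (already integrated in the scenario), build
#' one context-specific model per cell type (media + GIMME + hygiene),
#' screen drug-target knockouts per model, classify flux changes and
#' score each target against the disease DEGs, then rank and select
#' across models.
#'
#' @param scenario A \code{fluxScenario} from
#'   \code{\link{simulateScenario}}.
#' @param gimmeFraction Objective fraction for GIMME.
#' @param variant MoMA variant.
#' @param relTol,absTol Flux-change tolerances.
#' @param cutoff Aggregate z selection cutoff.
#' @param minGroupFraction Passed through to DEG loading as
#'   \code{minMetabolicDegs}.
#' @return list: models, buildReports, knockouts, pesTables, ranking,
#'   degs.
#' @export
runScenario <- function(scenario, gimmeFraction = 0.9,
                        variant = c("quadratic", "linear"),
                        relTol = 0.05, absTol = 1e-6, cutoff = -1,
                        minGroupFraction = 10) {
  variant <- match.arg(variant)
  stopifnot(inherits(scenario, "fluxScenario"))
  degs <- loadDEGs(scenario$disease$degs,
                   metabolicGenes = modelGenes(scenario$template),
                   minMetabolicDegs = minGroupFraction)
  models <- list(); reports <- list(); knockouts <- list(); pesTables <- list()
  for (ct in names(scenario$calls)) {
    built <- buildCellModel(scenario$template, scenario$calls[[ct]],
                            scenario$media[[ct]],
                            config = gimmeConfig(fraction = gimmeFraction))
    models[[ct]] <- built$model
    reports[[ct]] <- built$report
    wt <- fba(built$model)
    targets <- names(mapDrugTargets(scenario$annotations, built$model))
    kos <- knockoutScreen(built$model, targets, wt, variant = variant)
    knockouts[[ct]] <- kos
    pesTables[[ct]] <- scoreTargets(built$model, kos, degs, wt,
                                    relTol = relTol, absTol = absTol)
  }
  ranking <- rankTargets(pesTables, cutoff = cutoff)
  list(models = models, buildReports = reports, knockouts = knockouts,
       pesTables = pesTables, ranking = ranking, degs = degs)
}

.configSchema <- list(
  toplevel = c("paths", "cell_types", "thresholds", "tolerances",
               "moma_variant", "seed"),
  paths = c("template", "degs", "annotations", "pathways", "tasks"),
  cell_types = c("name", "calls", "detected", "abundance", "media"),
  thresholds = c("discretization", "trans_support", "prot_quantile",
                 "gimme_fraction", "fc_primary", "fc_fallback",
                 "min_metabolic_degs", "essential_cutoff", "reduced_cutoff",
                 "aggregate_cutoff"),
  tolerances = c("tol", "rel_tol", "abs_tol"))

#' Read and validate a pipeline configuration file
#'
#' YAML with sections \code{paths} (template / degs / annotations and
#' optional pathways, tasks), \code{cell_types} (name, omics file
#' paths, media), \code{thresholds}, \code{tolerances},
#' \code{moma_variant} and \code{seed}. Unknown keys anywhere are
#' rejected before any computation.
#'
#' @param path YAML config path.
#' @return Validated config list of class \code{pipelineConfig} with
#'   defaults filled in; relative paths are resolved against the config
#'   file's directory.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  rejectUnknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("config validation error: unknown key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  rejectUnknown(cfg, .configSchema$toplevel, "top level")
  if (is.null(cfg$paths) || is.null(cfg$paths$template)) {
    stop("config validation error: paths$template is required")
  }
  rejectUnknown(cfg$paths, .configSchema$paths, "paths")
  for (ct in cfg$cell_types) {
    rejectUnknown(ct, .configSchema$cell_types, "cell_types entry")
  }
  if (!is.null(cfg$thresholds)) {
    rejectUnknown(cfg$thresholds, .configSchema$thresholds, "thresholds")
  }
  if (!is.null(cfg$tolerances)) {
    rejectUnknown(cfg$tolerances, .configSchema$tolerances, "tolerances")
  }
  defaults <- list(
    thresholds = list(discretization = 0.5, trans_support = 0.9,
                      prot_quantile = 0.75, gimme_fraction = 0.9,
                      fc_primary = 2.0, fc_fallback = 1.5,
                      min_metabolic_degs = 10, essential_cutoff = 0.01,
                      reduced_cutoff = 0.5, aggregate_cutoff = -1),
    tolerances = list(tol = 1e-6, rel_tol = 0.05, abs_tol = 1e-6),
    moma_variant = "quadratic", seed = 1L)
  cfg$thresholds <- utils::modifyList(defaults$thresholds,
                                      cfg$thresholds %||% list())
  cfg$tolerances <- utils::modifyList(defaults$tolerances,
                                      cfg$tolerances %||% list())
  cfg$moma_variant <- cfg$moma_variant %||% defaults$moma_variant
  cfg$seed <- cfg$seed %||% defaults$seed
  th <- cfg$thresholds
  if (th$discretization <= 0 || th$discretization > 1 ||
      th$gimme_fraction <= 0 || th$gimme_fraction > 1 ||
      th$prot_quantile < 0 || th$prot_quantile > 1 ||
      th$trans_support < 0 || th$trans_support > 1) {
    stop("config validation error: threshold out of documented range")
  }
  if (!cfg$moma_variant %in% c("quadratic", "linear")) {
    stop("config validation error: moma_variant must be quadratic or linear")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(base, p)
  }
  cfg$paths <- lapply(cfg$paths, resolve)
  cfg$cell_types <- lapply(cfg$cell_types, function(ct) {
    for (k in c("calls", "detected", "abundance")) ct[[k]] <- resolve(ct[[k]])
    ct
  })
  cfg$configFile <- path
  class(cfg) <- "pipelineConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the file-driven analysis pipeline
#'
#' Executes integrate -> build (per cell type) -> knockout screen ->
#' classify + score -> rank + select from a validated configuration,
#' writing each stage's typed output and a provenance-stamped log under
#' \code{outDir}. Re-running with an identical config reproduces
#' byte-identical TSV outputs.
#'
#' @param config A \code{pipelineConfig} from
#'   \code{\link{readPipelineConfig}} (or a path to one).
#' @param outDir Output directory for stage artifacts.
#' @return Invisibly, a list with models, pesTables and the final
#'   ranking.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  provenance <- c(
    paste0("# config: ", config$configFile),
    paste0("# config_md5: ", unname(tools::md5sum(config$configFile))),
    paste0("# seed: ", config$seed),
    paste0("# stage_version: ", as.character(utils::packageVersion("FluxPerturb"))))
  logLines <- c(provenance)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    logLines <<- c(logLines, msg)
  }
  writeStage <- function(df, name) {
    p <- file.path(outDir, name)
    con <- file(p, "w")
    writeLines(provenance, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    p
  }
  th <- config$thresholds
  tl <- config$tolerances
  stage <- "read inputs"
  result <- tryCatch({
    template <- readModel(config$paths$template)
    say("loaded template '", template@id, "' (", nReactions(template),
        " reactions)")
    degsRaw <- config$paths$degs
    annPath <- config$paths$annotations
    ann <- if (!is.null(annPath)) readDrugAnnotations(annPath) else NULL
    degs <- if (!is.null(degsRaw)) {
      loadDEGs(degsRaw, primaryFcCutoff = th$fc_primary,
               fallbackFcCutoff = th$fc_fallback,
               minMetabolicDegs = th$min_metabolic_degs,
               metabolicGenes = modelGenes(template))
    } else NULL
    stage <- "integrate"
    callsByType <- list(); mediaByType <- list()
    for (ct in config$cell_types) {
      pm <- readPresenceMatrix(ct$calls, ct$detected)
      trans <- discretizeCalls(pm$calls, pm$detected,
                               threshold = th$discretization)
      prot <- proteomicsActivity(readAbundanceTable(ct$abundance),
                                 threshold = th$discretization)
      integ <- integrateOmics(trans, prot,
                              transSupportMin = th$trans_support,
                              protQuantileMin = th$prot_quantile)
      callsByType[[ct$name]] <- integ
      mediaByType[[ct$name]] <- mediaSpec(
        uptakeBounds = unlist(ct$media$uptake_bounds),
        freeMetabolites = ct$media$free_metabolites)
      writeStage(integ, paste0("calls_", ct$name, ".tsv"))
      say("integrated omics for ", ct$name, ": ", sum(integ$active),
          " active genes")
    }
    stage <- "build"
    tasks <- if (!is.null(config$paths$tasks))
      readTaskTable(config$paths$tasks) else NULL
    models <- list(); pesTables <- list()
    for (ctName in names(callsByType)) {
      built <- buildCellModel(template, callsByType[[ctName]],
                              mediaByType[[ctName]], tasks = tasks,
                              config = gimmeConfig(
                                fraction = th$gimme_fraction,
                                tol = tl$tol))
      models[[ctName]] <- built$model
      writeModel(built$model, file.path(outDir,
                                        paste0("model_", ctName, ".json")))
      say("built ", ctName, " model: ", nReactions(built$model),
          " reactions, objective ",
          format(built$report$objectiveValue, digits = 6))
      if (length(built$report$leaks)) {
        say("warning: leaks in ", ctName, " model: ",
            paste(built$report$leaks, collapse = ", "))
      }
      stage <- "knockout screen"
      wt <- fba(built$model)
      targets <- if (is.null(ann)) built$model@genes
                 else names(mapDrugTargets(ann, built$model))
      kos <- knockoutScreen(built$model, targets, wt,
                            variant = config$moma_variant)
      silent <- vapply(kos, `[[`, logical(1), "silent")
      if (any(silent)) {
        say("silent knockouts in ", ctName, ": ",
            paste(names(kos)[silent], collapse = ", "))
      }
      koDf <- data.frame(
        gene = names(kos),
        n_disabled = vapply(kos, function(k) length(k$disabled), 0L),
        growth_ratio = vapply(kos, `[[`, 0, "growthRatio"),
        silent = silent, stringsAsFactors = FALSE)
      writeStage(koDf, paste0("knockouts_", ctName, ".tsv"))
      stage <- "classify and score"
      if (!is.null(degs)) {
        pesTables[[ctName]] <- scoreTargets(built$model, kos, degs, wt,
                                            relTol = tl$rel_tol,
                                            absTol = tl$abs_tol)
        writeStage(pesTables[[ctName]], paste0("pes_", ctName, ".tsv"))
      }
    }
    stage <- "rank and select"
    ranking <- NULL
    if (length(pesTables)) {
      ranking <- rankTargets(pesTables, cutoff = th$aggregate_cutoff)
      writeStage(ranking, "ranking.tsv")
      say("selected ", sum(ranking$selected), " of ", nrow(ranking),
          " targets at aggregate z <= ", th$aggregate_cutoff)
    }
    list(models = models, pesTables = pesTables, ranking = ranking)
  }, error = function(e) {
    writeLines(c(logLines, paste0("FAILED at stage '", stage, "': ",
                                  conditionMessage(e))), logFile)
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         " (artifacts in ", outDir, ")", call. = FALSE)
  })
  writeLines(logLines, logFile)
  invisible(result)
}
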