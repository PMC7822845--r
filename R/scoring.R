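#' Load and filter a disease DEG table
#'
#' Retains genes with adjusted p below 0.05 and absolute fold change at
#' or above the primary cutoff (two-fold). When fewer than
#' \code{minMetabolicDegs} of the retained genes are metabolic (present
#' in \code{metabolicGenes}), the fallback 1.5-fold cutoff is applied
#' instead; the chosen cutoff is recorded in the \code{fc_cutoff}
#' attribute.
#'
#' @param degs data.frame or TSV path with columns \code{gene_id},
#'   \code{log2fc}, \code{p_adj} (optional \code{direction}; derived
#'   from the log2 fold-change sign when absent).
#' @param primaryFcCutoff,fallbackFcCutoff Fold-change cutoffs on the
#'   linear scale (defaults 2 and 1.5).
#' @param minMetabolicDegs Minimum metabolic DEG count under the primary
#'   cutoff before falling back (default 10).
#' @param metabolicGenes Gene universe used to count metabolic DEGs
#'   (default: all genes in the table).
#' @param pAdjCutoff Adjusted-p cutoff (default 0.05).
#' @return Filtered data.frame with columns gene, direction, log2fc,
#'   p_adj and attribute \code{fc_cutoff}.
#' @export
loadDEGs <- function(degs, primaryFcCutoff = 2, fallbackFcCutoff = 1.5,
                     minMetabolicDegs = 10, metabolicGenes = NULL,
                     pAdjCutoff = 0.05) {
  if (is.character(degs)) degs <- utils::read.delim(degs, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p_adj")
  miss <- setdiff(need, names(degs))
  if (length(miss)) stop("input error: DEG table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(degs$direction)) {
    degs$direction <- ifelse(degs$log2fc >= 0, "up", "down")
  }
  filterAt <- function(fc) {
    keep <- degs$p_adj < pAdjCutoff & abs(degs$log2fc) >= log2(fc)
    out <- degs[keep, , drop = FALSE]
    data.frame(gene = out$gene_id, direction = out$direction,
               log2fc = out$log2fc, p_adj = out$p_adj,
               stringsAsFactors = FALSE)
  }
  primary <- filterAt(primaryFcCutoff)
  nMet <- if (is.null(metabolicGenes)) nrow(primary)
          else sum(primary$gene %in% metabolicGenes)
  if (nMet < minMetabolicDegs) {
    out <- filterAt(fallbackFcCutoff)
    attr(out, "fc_cutoff") <- fallbackFcCutoff
  } else {
    out <- primary
    attr(out, "fc_cutoff") <- primaryFcCutoff
  }
  rownames(out) <- NULL
  out
}

#' Count DEG-regulated reactions by flux-change class
#'
#' The up group is the set of distinct reactions whose GPR contains at
#' least one disease-upregulated DEG, partitioned by flux-change class
#' into UpDec / UpInc / UpUnc; the down group likewise for downregulated
#' DEGs. A reaction regulated by several same-direction DEGs counts
#' once (union semantics); one regulated by both an up- and a down-DEG
#' contributes to both groups.
#'
#' @param fluxTable data.frame from \code{\link{classifyFluxChanges}}.
#' @param degs data.frame from \code{\link{loadDEGs}} (columns gene,
#'   direction).
#' @param model A \code{\linkS4class{MetabolicModel}} supplying the
#'   gene-reaction incidence.
#' @return Named numeric vector with elements UpDec, UpInc, UpUnc,
#'   DownDec, DownInc, DownUnc.
#' @export
countDegFluxChanges <- function(fluxTable, degs, model) {
  groupRxns <- function(direction) {
    gg <- intersect(degs$gene[degs$direction == direction], model@genes)
    unique(unlist(lapply(gg, function(g) reactionsOfGene(model, g))))
  }
  classOf <- function(rxns) {
    cls <- fluxTable$class[match(rxns, fluxTable$reaction)]
    cls[!is.na(cls)]
  }
  up <- classOf(groupRxns("up"))
  dn <- classOf(groupRxns("down"))
  c(UpDec = sum(up == "down"), UpInc = sum(up == "up"),
    UpUnc = sum(up == "unchanged"),
    DownDec = sum(dn == "down"), DownInc = sum(dn == "up"),
    DownUnc = sum(dn == "unchanged"))
}

#' Perturbation effect score (PES)
#'
#' PES = (UpDec - UpInc) / (UpDec + UpInc + UpUnc)
#'     + (DownInc - DownDec) / (DownInc + DownDec + DownUnc).
#'
#' A positive score means the knockout reverses the disease signature:
#' it decreases flux through reactions controlled by disease-upregulated
#' genes and/or increases flux through reactions controlled by
#' downregulated ones. A term with zero denominator (no reaction mapped
#' in that group) contributes 0, keeping the score defined and bounded
#' in [-2, 2].
#'
#' @param counts Named numeric vector with UpDec, UpInc, UpUnc, DownDec,
#'   DownInc, DownUnc (as from \code{\link{countDegFluxChanges}}).
#' @return Numeric score in [-2, 2].
#' @export
pes <- function(counts) {
  need <- c("UpDec", "UpInc", "UpUnc", "DownDec", "DownInc", "DownUnc")
  stopifnot(all(need %in% names(counts)), all(counts >= 0))
  counts <- counts[need]
  upTot <- counts[["UpDec"]] + counts[["UpInc"]] + counts[["UpUnc"]]
  dnTot <- counts[["DownDec"]] + counts[["DownInc"]] + counts[["DownUnc"]]
  upTerm <- if (upTot > 0) (counts[["UpDec"]] - counts[["UpInc"]]) / upTot else 0
  dnTerm <- if (dnTot > 0) (counts[["DownInc"]] - counts[["DownDec"]]) / dnTot else 0
  upTerm + dnTerm
}

#' Rank PES values within one model/disease combination
#'
#' The gene with the highest PES gets rank 1, the minimum PES the
#' lowest rank; ties receive the average of their positions.
#'
#' @param scores Named numeric vector, gene -> PES.
#' @return Named numeric vector of ranks.
#' @export
rankPES <- function(scores) {
  stopifnot(length(scores) > 0)
  rank(-scores, ties.method = "average")
}

#' Z-standardize PES ranks within a model
#'
#' z = (x - mean) / sd over the ranks of one model/disease; the sample
#' (n-1) standard deviation is the default. When all ranks tie the
#' z-scores are set to 0 with a warning.
#'
#' @param ranks Named numeric rank vector from \code{\link{rankPES}}.
#' @param sdType \code{"sample"} (n-1, default) or \code{"population"}.
#' @return Named numeric vector of z-scores (mean 0, sd 1).
#' @export
zscoreRanks <- function(ranks, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  mu <- mean(ranks)
  n <- length(ranks)
  sigma <- if (sdType == "sample") stats::sd(ranks)
           else sqrt(sum((ranks - mu)^2) / n)
  if (is.na(sigma) || sigma < .Machine$double.eps) {
    warning("all ranks tied: z-scores set to 0")
    return(stats::setNames(rep(0, n), names(ranks)))
  }
  (ranks - mu) / sigma
}

#' Aggregate per-model z-scores and select targets
#'
#' For each gene the z-scores are summed over cell-type models (genes
#' missing a z in any model are excluded and logged); genes are ranked
#' from minimum to maximum aggregate. Selection applies the cutoff on
#' the re-standardized aggregate (one standard deviation below the mean
#' aggregated score at the default -1); set
#' \code{restandardize = FALSE} to threshold the raw sum instead.
#'
#' @param zMatrix Numeric matrix, genes x models, of per-model z-scores
#'   (NA where a gene was not scored in a model).
#' @param cutoff Selection cutoff (default -1).
#' @param restandardize Apply the cutoff to the re-standardized
#'   aggregate (default TRUE).
#' @param sdType Passed to the re-standardization.
#' @return data.frame: gene, per-model z columns, aggregate, aggregate_z,
#'   rank, selected; attribute \code{excluded} lists genes dropped for
#'   missing models.
#' @export
aggregateAndSelect <- function(zMatrix, cutoff = -1, restandardize = TRUE,
                               sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  zMatrix <- as.matrix(zMatrix)
  complete <- rowSums(is.na(zMatrix)) == 0
  excluded <- rownames(zMatrix)[!complete]
  if (length(excluded)) {
    message("aggregateAndSelect: excluding ", length(excluded),
            " gene(s) missing a z-score in some model")
  }
  zc <- zMatrix[complete, , drop = FALSE]
  aggregate <- rowSums(zc)
  mu <- mean(aggregate)
  sigma <- if (sdType == "sample") stats::sd(aggregate)
           else sqrt(mean((aggregate - mu)^2))
  aggZ <- if (is.na(sigma) || sigma < .Machine$double.eps) {
    rep(0, length(aggregate))
  } else {
    (aggregate - mu) / sigma
  }
  crit <- if (restandardize) aggZ else aggregate
  out <- data.frame(gene = rownames(zc), zc, aggregate = aggregate,
                    aggregate_z = aggZ,
                    rank = rank(aggregate, ties.method = "average"),
                    selected = crit <= cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$aggregate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Pathway enrichment by one-sided Fisher exact test
#'
#' For each pathway with gene set P, the overlap k of the query set
#' (size n) with P (K = |P ∩ background|, N = |background|) is tested
#' against the hypergeometric upper tail; p-values are adjusted across
#' pathways by Benjamini-Hochberg, and fold enrichment is
#' (k/n) / (K/N). Significance requires p < 0.05 and FDR < 0.05.
#'
#' @param geneSet Character vector of query genes (subset of
#'   background).
#' @param background Character vector, the gene universe.
#' @param pathwayMap Named list: pathway id -> character vector of
#'   member genes.
#' @return data.frame: pathway, k, n, K, N, fold_enrichment, p, fdr,
#'   significant. Pathways with empty background intersection are
#'   skipped (message).
#' @export
pathwayEnrichment <- function(geneSet, background, pathwayMap) {
  geneSet <- unique(geneSet)
  background <- unique(background)
  if (!all(geneSet %in% background)) {
    stop("input error: gene set must be a subset of the background")
  }
  N <- length(background)
  n <- length(geneSet)
  rows <- lapply(names(pathwayMap), function(pw) {
    P <- intersect(pathwayMap[[pw]], background)
    K <- length(P)
    if (K == 0) {
      message("pathwayEnrichment: skipping '", pw,
              "' (no background overlap)")
      return(NULL)
    }
    k <- length(intersect(geneSet, P))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0) (k / n) / (K / N) else NA_real_
    data.frame(pathway = pw, k = k, n = n, K = K, N = N,
               fold_enrichment = fold, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(pathway = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < 0.05 & out$fdr < 0.05
  out[order(out$p), , drop = FALSE]
}

#' Read a pathway map from TSV
#'
#' Columns \code{pathway_id} and \code{genes} (pipe-separated gene
#' ids).
#'
#' @param path TSV path.
#' @return Named list pathway -> gene vector.
#' @export
readPathwayMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(strsplit(df$genes, "|", fixed = TRUE), df$pathway_id)
}
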