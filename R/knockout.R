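#' Read drug annotations, excluding withdrawn drugs
#'
#' TSV columns: \code{drug}, \code{status} (launched / phase* /
#' preclinical / withdrawn), \code{targets} (pipe-separated gene ids).
#' Withdrawn drugs and their annotations are removed at load time.
#'
#' @param path TSV path.
#' @return data.frame with columns drug, status, targets (list column of
#'   gene id vectors).
#' @export
readDrugAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "status", "targets")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[tolower(df$status) != "withdrawn", , drop = FALSE]
  df$targets <- strsplit(df$targets, "|", fixed = TRUE)
  rownames(df) <- NULL
  df
}

#' Map drug targets onto model genes
#'
#' @param annotations data.frame as returned by
#'   \code{\link{readDrugAnnotations}} (withdrawn drugs already
#'   removed; any rows still marked withdrawn are dropped here too).
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @return Named list: model gene id -> character vector of drugs
#'   targeting it. Genes absent from the model never appear.
#' @export
mapDrugTargets <- function(annotations, model) {
  annotations <- annotations[tolower(annotations$status) != "withdrawn", ,
                             drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    for (g in intersect(annotations$targets[[i]], model@genes)) {
      out[[g]] <- c(out[[g]], annotations$drug[i])
    }
  }
  lapply(out, unique)
}

#' Reactions disabled by deleting a gene
#'
#' A reaction is disabled when its (non-empty) GPR evaluates true with
#' the full gene set but false once the gene is removed -- so a gene
#' backed by an active isozyme disables nothing.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param gene Gene id in the model.
#' @return Character vector of disabled reaction ids (possibly empty).
#' @export
disabledReactions <- function(model, gene) {
  if (!(gene %in% model@genes)) stop("gene '", gene, "' not in model")
  remaining <- setdiff(model@genes, gene)
  cand <- reactionsOfGene(model, gene)
  cand[vapply(cand, function(r) {
    rule <- model@gpr[[r]]
    evaluateGPR(rule, model@genes) && !evaluateGPR(rule, remaining)
  }, logical(1))]
}

#' Single-gene knockout with MoMA flux prediction
#'
#' Reactions whose GPR goes false without the gene are closed to
#' [0, 0]; the perturbed flux state is then predicted by MoMA against
#' the cached wild-type distribution. A knockout that disables no
#' reaction (isozyme-backed) is flagged silent and returns the wild-type
#' fluxes unchanged.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param gene Gene id to delete.
#' @param referenceFlux Wild-type \code{\linkS4class{FluxDistribution}},
#'   typically one cached \code{\link{fba}} call per model; computed on
#'   the fly when NULL.
#' @param variant MoMA variant, \code{"quadratic"} or \code{"linear"}.
#' @return list of class \code{knockoutResult}: gene, disabled
#'   (reaction ids), silent flag, vKO
#'   (\code{\linkS4class{FluxDistribution}}), growth, growthRatio.
#' @export
geneKnockout <- function(model, gene, referenceFlux = NULL,
                         variant = c("quadratic", "linear")) {
  variant <- match.arg(variant)
  if (is.null(referenceFlux)) referenceFlux <- fba(model)
  disabled <- disabledReactions(model, gene)
  wtGrowth <- fluxes(referenceFlux)[[model@objective]]
  if (!length(disabled)) {
    res <- list(gene = gene, disabled = character(0), silent = TRUE,
                vKO = referenceFlux, growth = wtGrowth,
                growthRatio = 1)
    class(res) <- "knockoutResult"
    return(res)
  }
  perturbed <- setBounds(model, disabled, lower = 0, upper = 0)
  vKO <- moma(perturbed, referenceFlux, variant = variant)
  growth <- objectiveValue(vKO)
  ratio <- if (abs(wtGrowth) > 1e-12) max(growth, 0) / wtGrowth else NA_real_
  res <- list(gene = gene, disabled = disabled, silent = FALSE, vKO = vKO,
              growth = growth, growthRatio = ratio)
  class(res) <- "knockoutResult"
  res
}

#' @exportS3Method base::print
print.knockoutResult <- function(x, ...) {
  cat("knockout of", x$gene,
      if (x$silent) "(silent: no reaction disabled)" else "", "\n")
  if (!x$silent) {
    cat("  disabled:", paste(x$disabled, collapse = ", "), "\n")
    cat("  growth ratio:", format(x$growthRatio, digits = 4), "\n")
  }
  invisible(x)
}

#' Effective drug targets: genes whose deletion blocks a reaction
#'
#' @param knockouts List of \code{knockoutResult} objects.
#' @return Character vector of genes with at least one disabled
#'   reaction.
#' @export
filterEffectiveTargets <- function(knockouts) {
  eff <- vapply(knockouts, function(k) length(k$disabled) >= 1L, logical(1))
  vapply(knockouts[eff], `[[`, "", "gene")
}

#' Classify per-reaction flux changes after a perturbation
#'
#' Comparison is on flux magnitudes (|v|), since for reversible
#' reactions the sign encodes direction rather than activity; sign
#' reversals are logged in the \code{sign_flip} column. A reaction is
#' unchanged when the magnitudes differ by at most \code{absTol} or
#' their ratio lies within \code{1 +/- relTol}; it is down/up when the
#' perturbed magnitude falls below/above that band. When the wild-type
#' magnitude is itself within \code{absTol} of zero the ratio is
#' undefined (NA) and the reaction is up if the perturbed flux exceeds
#' \code{absTol}, else unchanged. Signed comparison is available behind
#' \code{signed = TRUE}.
#'
#' @param vWT,vKO Named numeric flux vectors (or
#'   \code{FluxDistribution}s) over the same reaction universe.
#' @param relTol Relative tolerance band (default 0.05).
#' @param absTol Absolute zero tolerance (default 1e-6).
#' @param signed Compare signed fluxes instead of magnitudes.
#' @return data.frame: reaction, v_wt, v_ko, ratio, class (down / up /
#'   unchanged), sign_flip.
#' @export
classifyFluxChanges <- function(vWT, vKO, relTol = 0.05, absTol = 1e-6,
                                signed = FALSE) {
  if (is(vWT, "FluxDistribution")) vWT <- fluxes(vWT)
  if (is(vKO, "FluxDistribution")) vKO <- fluxes(vKO)
  stopifnot(setequal(names(vWT), names(vKO)))
  vKO <- vKO[names(vWT)]
  mWT <- if (signed) vWT else abs(vWT)
  mKO <- if (signed) vKO else abs(vKO)
  ratio <- ifelse(abs(mWT) > absTol, mKO / mWT, NA_real_)
  cls <- character(length(vWT))
  zeroWT <- abs(mWT) <= absTol
  cls[zeroWT] <- ifelse(abs(mKO[zeroWT]) > absTol, "up", "unchanged")
  nz <- !zeroWT
  unchanged <- nz & (abs(mKO - mWT) <= absTol |
                       (!is.na(ratio) & ratio >= 1 - relTol & ratio <= 1 + relTol))
  cls[unchanged] <- "unchanged"
  cls[nz & !unchanged & mKO < mWT * (1 - relTol)] <- "down"
  cls[nz & !unchanged & mKO > mWT * (1 + relTol)] <- "up"
  # band edges not caught by the strict comparisons are unchanged
  cls[cls == ""] <- "unchanged"
  data.frame(reaction = names(vWT), v_wt = unname(vWT), v_ko = unname(vKO),
             ratio = unname(ratio), class = cls,
             sign_flip = sign(vWT) * sign(vKO) < 0 &
               abs(vWT) > absTol & abs(vKO) > absTol,
             stringsAsFactors = FALSE)
}

#' Gene essentiality screen
#'
#' Knocks out each gene and classifies the effect on growth:
#' essential when the growth ratio falls below \code{essentialCutoff},
#' reduced below \code{reducedCutoff}, otherwise nonessential.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param genes Genes to screen (default all model genes).
#' @param referenceFlux Cached wild-type FBA solution (computed when
#'   NULL).
#' @param essentialCutoff,reducedCutoff Growth-ratio cutoffs (defaults
#'   0.01 and 0.5).
#' @param variant MoMA variant; \code{"fba"} instead reoptimizes growth
#'   in the deletion strain (classic FBA single-gene deletion).
#' @return data.frame: gene, growth_ratio, n_disabled, class.
#' @export
essentialityScreen <- function(model, genes = NULL, referenceFlux = NULL,
                               essentialCutoff = 0.01, reducedCutoff = 0.5,
                               variant = c("quadratic", "linear", "fba")) {
  variant <- match.arg(variant)
  if (is.null(genes)) genes <- model@genes
  stopifnot(all(genes %in% model@genes))
  if (is.null(referenceFlux)) referenceFlux <- fba(model)
  wtGrowth <- fluxes(referenceFlux)[[model@objective]]
  rows <- lapply(genes, function(g) {
    if (variant == "fba") {
      disabled <- disabledReactions(model, g)
      ratio <- if (!length(disabled)) 1 else {
        km <- setBounds(model, disabled, lower = 0, upper = 0)
        gr <- tryCatch(objectiveValue(fba(km)), error = function(e) 0)
        if (abs(wtGrowth) > 1e-12) max(gr, 0) / wtGrowth else NA_real_
      }
      nDis <- length(disabled)
    } else {
      ko <- geneKnockout(model, g, referenceFlux, variant = variant)
      ratio <- ko$growthRatio
      nDis <- length(ko$disabled)
    }
    data.frame(gene = g, growth_ratio = ratio, n_disabled = nDis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- ifelse(out$growth_ratio < essentialCutoff, "essential",
                      ifelse(out$growth_ratio < reducedCutoff, "reduced",
                             "nonessential"))
  out
}

#' Precision-recall curve for essentiality predictions
#'
#' Genes are ranked by ascending predicted growth ratio (most essential
#' first, ties broken alphabetically for determinism); precision and
#' recall are computed at every prefix of the ranking and the area under
#' the curve by trapezoidal integration over recall.
#'
#' @param growthRatios Named numeric vector, gene -> predicted growth
#'   ratio.
#' @param referencePositive Character vector of reference essential
#'   genes (nonempty).
#' @return list(curve, auc): curve is a data.frame with rank, gene,
#'   precision, recall.
#' @export
essentialityPRCurve <- function(growthRatios, referencePositive) {
  if (!length(referencePositive)) {
    stop("input error: empty reference essential gene set")
  }
  ord <- order(growthRatios, names(growthRatios))
  genes <- names(growthRatios)[ord]
  isPos <- genes %in% referencePositive
  tp <- cumsum(isPos)
  k <- seq_along(genes)
  nPos <- sum(names(growthRatios) %in% referencePositive)
  precision <- tp / k
  recall <- if (nPos > 0) tp / nPos else rep(0, length(k))
  curve <- data.frame(rank = k, gene = genes, precision = precision,
                      recall = recall, stringsAsFactors = FALSE)
  auc <- 0
  if (length(k) > 1) {
    dr <- diff(recall)
    auc <- sum(dr * (precision[-1] + precision[-length(precision)]) / 2)
  }
  if (length(k) >= 1 && recall[1] > 0) {
    # first step from recall 0 at the same precision
    auc <- auc + recall[1] * precision[1]
  }
  list(curve = curve, auc = auc)
}
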