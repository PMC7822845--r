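#' Discretize presence calls into per-gene activity
#'
#' A gene is called active when it is expressed in more than
#' \code{threshold} (strictly) of the samples in which its probe was
#' detected; genes never detected are reported as undetermined rather
#' than inactive.
#'
#' @param calls genes x samples binary (0/1) matrix of expression calls,
#'   rownames = gene ids.
#' @param detected genes x samples binary detection mask (1 = probe
#'   present); defaults to all-detected. Expression calls are only
#'   counted where detected.
#' @param threshold Fraction in (0, 1]; the comparison is strict
#'   (\code{support > threshold}).
#' @return data.frame with columns gene, n_detected, n_expressed,
#'   support, status (active/inactive/undetermined).
#' @export
discretizeCalls <- function(calls, detected = NULL, threshold = 0.5) {
  if (is.null(dim(calls)) || nrow(calls) == 0 || ncol(calls) == 0) {
    stop("input error: empty presence matrix")
  }
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(detected)) {
    detected <- matrix(1, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  }
  stopifnot(identical(dim(calls), dim(detected)))
  if (any(calls == 1 & detected == 0)) {
    stop("invalid presence matrix: expression call where probe not detected")
  }
  nDet <- rowSums(detected == 1)
  nExp <- rowSums(calls == 1 & detected == 1)
  support <- ifelse(nDet > 0, nExp / nDet, NA_real_)
  status <- ifelse(nDet == 0, "undetermined",
                   ifelse(support > threshold, "active", "inactive"))
  data.frame(gene = rownames(calls), n_detected = nDet, n_expressed = nExp,
             support = support, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine per-dataset activity calls for one cell type
#'
#' Each dataset is discretized separately; a gene is then active when it
#' is active in more than \code{threshold} of the datasets in which it
#' was determined. Per-dataset majority prevents large datasets from
#' dominating small ones.
#'
#' @param callList List of data.frames from \code{\link{discretizeCalls}}.
#' @param threshold Strict majority fraction across datasets.
#' @return data.frame with gene, n_datasets, n_active, support, status.
#' @export
combineActivityCalls <- function(callList, threshold = 0.5) {
  stopifnot(length(callList) >= 1)
  if (length(callList) == 1L) {
    df <- callList[[1]]
    return(data.frame(gene = df$gene, n_datasets = ifelse(df$status == "undetermined", 0L, 1L),
                      n_active = as.integer(df$status == "active"),
                      support = as.numeric(df$status == "active"),
                      status = df$status, stringsAsFactors = FALSE))
  }
  genes <- sort(unique(unlist(lapply(callList, `[[`, "gene"))))
  det <- sapply(callList, function(df) {
    s <- df$status[match(genes, df$gene)]
    !is.na(s) & s != "undetermined"
  })
  act <- sapply(callList, function(df) {
    s <- df$status[match(genes, df$gene)]
    !is.na(s) & s == "active"
  })
  nDatasets <- rowSums(det)
  nActive <- rowSums(act)
  support <- ifelse(nDatasets > 0, nActive / nDatasets, NA_real_)
  status <- ifelse(nDatasets == 0, "undetermined",
                   ifelse(support > threshold, "active", "inactive"))
  data.frame(gene = genes, n_datasets = nDatasets, n_active = nActive,
             support = support, status = status, stringsAsFactors = FALSE)
}

#' Proteomics activity and abundance quantiles
#'
#' Presence is detection of the protein in a sample; a protein is active
#' when present in more than \code{threshold} of samples. The abundance
#' rank statistic is the within-sample quantile (among detected
#' proteins), averaged over the samples where the protein was detected,
#' so differing abundance scales across runs do not mix.
#'
#' @param abundance genes x samples numeric matrix; NA or 0 = not
#'   detected.
#' @param threshold Strict majority fraction of samples.
#' @return data.frame with gene, support, quantile, status.
#' @export
proteomicsActivity <- function(abundance, threshold = 0.5) {
  if (is.null(dim(abundance)) || nrow(abundance) == 0) {
    stop("input error: empty abundance table")
  }
  detected <- !is.na(abundance) & abundance > 0
  qmat <- apply(abundance, 2, function(col) {
    det <- !is.na(col) & col > 0
    q <- rep(NA_real_, length(col))
    if (sum(det) > 0) {
      r <- rank(col[det], ties.method = "average")
      q[det] <- r / sum(det)
    }
    q
  })
  nDet <- rowSums(detected)
  support <- ifelse(ncol(abundance) > 0, nDet / ncol(abundance), NA_real_)
  quant <- ifelse(nDet > 0, rowMeans(qmat, na.rm = TRUE), NA_real_)
  status <- ifelse(nDet == 0, "undetermined",
                   ifelse(support > threshold, "active", "inactive"))
  data.frame(gene = rownames(abundance), support = support,
             quantile = quant, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Integrate transcriptomics and proteomics activity calls
#'
#' Consensus tiers: genes active in both layers are high confidence;
#' genes active only in transcriptomics are kept (moderate confidence)
#' when expressed in at least 90\% of samples; genes active only in
#' proteomics are kept when their abundance quantile is in the top
#' quartile (>= 0.75). All other genes are inactive. Both moderate
#' cutoffs are inclusive; the activity majority itself is strict.
#'
#' @param trans data.frame from \code{\link{discretizeCalls}} or
#'   \code{\link{combineActivityCalls}} (columns gene, support, status).
#' @param prot data.frame from \code{\link{proteomicsActivity}}
#'   (columns gene, support, quantile, status).
#' @param transSupportMin Inclusive support cutoff for
#'   transcriptomics-only genes (default 0.90).
#' @param protQuantileMin Inclusive abundance-quantile cutoff for
#'   proteomics-only genes (default 0.75).
#' @return data.frame with gene, active, tier
#'   (high/moderate_transcriptomic/moderate_proteomic/none), support.
#' @export
integrateOmics <- function(trans, prot, transSupportMin = 0.90,
                           protQuantileMin = 0.75) {
  genes <- sort(union(trans$gene, prot$gene))
  ti <- match(genes, trans$gene)
  pi <- match(genes, prot$gene)
  tAct <- !is.na(ti) & trans$status[ti] %in% "active"
  pAct <- !is.na(pi) & prot$status[pi] %in% "active"
  tSup <- ifelse(is.na(ti), NA_real_, trans$support[ti])
  pQ <- ifelse(is.na(pi), NA_real_, prot$quantile[pi])
  tier <- rep("none", length(genes))
  tier[tAct & pAct] <- "high"
  tier[tAct & !pAct & !is.na(tSup) & tSup >= transSupportMin] <-
    "moderate_transcriptomic"
  tier[!tAct & pAct & !is.na(pQ) & pQ >= protQuantileMin] <-
    "moderate_proteomic"
  support <- pmax(ifelse(is.na(tSup), -Inf, tSup),
                  ifelse(is.na(pi), -Inf, prot$support[pi]))
  support[!is.finite(support)] <- NA_real_
  data.frame(gene = genes, active = tier != "none", tier = tier,
             support = support, stringsAsFactors = FALSE)
}

#' Read a presence matrix (and detection mask) from TSV
#'
#' First column \code{gene_id}, remaining columns one 0/1 call per
#' sample; the optional mask file is parallel with 1 where the probe was
#' present.
#'
#' @param path TSV of expression calls.
#' @param detectedPath Optional TSV of the detection mask.
#' @return list(calls, detected) of binary matrices.
#' @export
readPresenceMatrix <- function(path, detectedPath = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  detected <- NULL
  if (!is.null(detectedPath)) {
    dd <- utils::read.delim(detectedPath, stringsAsFactors = FALSE,
                            check.names = FALSE)
    detected <- as.matrix(dd[, -1, drop = FALSE])
    rownames(detected) <- dd[[1]]
    detected <- detected[rownames(calls), , drop = FALSE]
  }
  list(calls = calls, detected = detected)
}

#' Read a proteomics abundance table from TSV
#'
#' @param path TSV with first column gene_id and one abundance column
#'   per sample (NA or 0 = not detected).
#' @return Numeric matrix, genes x samples.
#' @export
readAbundanceTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write integrated activity calls to TSV
#'
#' @param calls data.frame from \code{\link{integrateOmics}}.
#' @param path Output path.
#' @export
writeActivityCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
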