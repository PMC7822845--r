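#' @include AllClasses.R
NULL

#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @export
setGeneric("objectiveReaction", function(object) standardGeneric("objectiveReaction"))
#' @export
setGeneric("objectiveReaction<-", function(object, value) standardGeneric("objectiveReaction<-"))
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @export
setGeneric("isExchange", function(object) standardGeneric("isExchange"))
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' Accessors for MetabolicModel and FluxDistribution
#'
#' \code{reactionIds}, \code{metaboliteIds}, \code{modelGenes},
#' \code{objectiveReaction}, \code{stoichiometry}, \code{lowerBounds},
#' \code{upperBounds}, \code{gprRules} and \code{isExchange} expose the
#' typed contents of a \code{\linkS4class{MetabolicModel}} without slot
#' access; \code{fluxes} and \code{objectiveValue} read a
#' \code{\linkS4class{FluxDistribution}}. \code{setBounds} returns a
#' modified copy of the model; an exchange reaction is one touching
#' exactly one metabolite.
#'
#' @param object A \code{MetabolicModel} or \code{FluxDistribution}.
#' @param value Replacement value for replacement functions.
#' @name model-accessors
#' @aliases reactionIds metaboliteIds modelGenes objectiveReaction
#'   stoichiometry lowerBounds upperBounds gprRules isExchange fluxes
#'   objectiveValue
NULL

#' @rdname model-accessors
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)
#' @rdname model-accessors
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)
#' @rdname model-accessors
setMethod("modelGenes", "MetabolicModel", function(object) object@genes)
#' @rdname model-accessors
setMethod("objectiveReaction", "MetabolicModel", function(object) object@objective)
#' @rdname model-accessors
setMethod("objectiveReaction<-", "MetabolicModel", function(object, value) {
  object@objective <- value
  validObject(object)
  object
})
#' @rdname model-accessors
setMethod("stoichiometry", "MetabolicModel", function(object) object@stoichiometry)
#' @rdname model-accessors
setMethod("lowerBounds", "MetabolicModel", function(object)
  stats::setNames(object@reactions$lower_bound, object@reactions$id))
#' @rdname model-accessors
setMethod("upperBounds", "MetabolicModel", function(object)
  stats::setNames(object@reactions$upper_bound, object@reactions$id))
#' @rdname model-accessors
setMethod("gprRules", "MetabolicModel", function(object) object@gpr)
#' @rdname model-accessors
setMethod("isExchange", "MetabolicModel", function(object) {
  # an exchange touches exactly one metabolite, and that metabolite sits
  # in the extracellular compartment; single-metabolite reactions on
  # internal compartments are demands/sinks, not exchanges, and are left
  # alone by media handling and the leak test
  S <- object@stoichiometry != 0
  nmet <- as.vector(Matrix::colSums(S))
  single <- nmet == 1L
  comp <- as.character(object@metabolites$compartment)
  out <- stats::setNames(single, object@reactions$id)
  if (!all(is.na(comp))) {
    whichMet <- rep(NA_integer_, ncol(S))
    idx <- Matrix::which(S[, single, drop = FALSE], arr.ind = TRUE)
    whichMet[which(single)[idx[, 2]]] <- idx[, 1]
    out[single] <- comp[whichMet[single]] %in% "e" |
      is.na(comp[whichMet[single]])
  }
  out
})
#' @rdname model-accessors
setMethod("fluxes", "FluxDistribution", function(object) object@fluxes)
#' @rdname model-accessors
setMethod("objectiveValue", "FluxDistribution", function(object) object@objectiveValue)

#' Reaction and metabolite counts
#'
#' @param object A \code{MetabolicModel}.
#' @return Integer count.
#' @export
nReactions <- function(object) nrow(object@reactions)

#' @rdname nReactions
#' @export
nMetabolites <- function(object) nrow(object@metabolites)

#' Set flux bounds on one or more reactions
#'
#' @param model A \code{MetabolicModel}.
#' @param reactions Character vector of reaction ids.
#' @param lower,upper Numeric replacement bounds, recycled along
#'   \code{reactions}; \code{NULL} leaves the bound untouched.
#' @return The modified model.
#' @export
setBounds <- function(model, reactions, lower = NULL, upper = NULL) {
  idx <- match(reactions, model@reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ",
         paste(reactions[is.na(idx)], collapse = ", "))
  }
  if (!is.null(lower)) model@reactions$lower_bound[idx] <- rep_len(lower, length(idx))
  if (!is.null(upper)) model@reactions$upper_bound[idx] <- rep_len(upper, length(idx))
  validObject(model)
  model
}

#' Reactions associated with a gene through its GPR rules
#'
#' @param model A \code{MetabolicModel}.
#' @param gene Gene identifier; must be in \code{modelGenes(model)}.
#' @return Character vector of reaction ids whose GPR leaf set contains
#'   the gene (possibly empty).
#' @export
reactionsOfGene <- function(model, gene) {
  if (!(gene %in% model@genes)) {
    stop("gene '", gene, "' not in model gene list")
  }
  hit <- vapply(model@gpr, function(r) gene %in% gprGenes(r), logical(1))
  names(hit)[hit]
}

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@id, "'\n", sep = "")
  cat("  metabolites: ", nrow(object@metabolites),
      "  reactions: ", nrow(object@reactions),
      "  genes: ", length(object@genes), "\n", sep = "")
  cat("  objective:   ", object@objective, "\n", sep = "")
  ex <- sum(isExchange(object))
  cat("  exchanges:   ", ex, "\n", sep = "")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", length(object@fluxes), " reactions, status ",
      object@status, ")\n", sep = "")
  cat("  objective value: ", format(object@objectiveValue, digits = 6), "\n",
      sep = "")
})
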