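#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
#' @importClassesFrom Matrix Matrix
NULL

#' MetabolicModel: a genome-scale constraint-based metabolic model
#'
#' Central container for a stoichiometric network: metabolite and
#' reaction tables, the sparse stoichiometric matrix S (metabolites by
#' reactions), parsed gene-protein-reaction (GPR) rules, the gene set,
#' and the designated objective (biomass) reaction. Flux bounds are in
#' mmol/gDW/hr; reversibility is encoded purely by a negative lower
#' bound. Exchange reactions are written \code{met_e <-> nothing} with a
#' single stoichiometric entry of -1, so uptake is negative flux.
#'
#' @slot id Model identifier.
#' @slot metabolites data.frame with columns id, name, compartment,
#'   formula, charge.
#' @slot reactions data.frame with columns id, name, subsystem,
#'   lower_bound, upper_bound, gene_reaction_rule.
#' @slot stoichiometry sparse \code{Matrix} (dgCMatrix), rows named by
#'   metabolite id, columns by reaction id.
#' @slot gpr list of parsed \code{gprRule} objects, named by reaction id.
#' @slot genes character vector of gene identifiers (opaque strings,
#'   assumed harmonized across inputs).
#' @slot objective reaction id of the biomass objective.
#' @slot annotations list of opaque extras preserved from file input.
#'
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    id = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    gpr = "list",
    genes = "character",
    objective = "character",
    annotations = "list"
  ))

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn)) {
    msg <- c(msg, "stoichiometric matrix dimensions inconsistent with tables")
  } else {
    if (!identical(rownames(S), as.character(met$id)))
      msg <- c(msg, "stoichiometry rownames do not match metabolite ids")
    if (!identical(colnames(S), as.character(rxn$id)))
      msg <- c(msg, "stoichiometry colnames do not match reaction ids")
  }
  if (length(object@objective) != 1L || !(object@objective %in% rxn$id))
    msg <- c(msg, "objective reaction missing from the model")
  if (any(rxn$lower_bound > rxn$upper_bound))
    msg <- c(msg, "lower_bound > upper_bound for some reaction")
  if (!identical(names(object@gpr), as.character(rxn$id)))
    msg <- c(msg, "gpr list names do not match reaction ids")
  leafGenes <- unique(unlist(lapply(object@gpr, gprGenes)))
  extra <- setdiff(leafGenes, object@genes)
  if (length(extra))
    msg <- c(msg, paste0("GPR genes not in model gene list: ",
                         paste(utils::head(extra, 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicModel
#'
#' @param id Model identifier.
#' @param metabolites data.frame with at least column \code{id}; columns
#'   name, compartment, formula, charge are filled with defaults when
#'   absent. The compartment defaults to the suffix after the last
#'   underscore of the metabolite id.
#' @param reactions data.frame with at least columns \code{id},
#'   \code{lower_bound}, \code{upper_bound}; optional name, subsystem,
#'   gene_reaction_rule.
#' @param stoich named list (by reaction id) of named numeric vectors
#'   (metabolite id -> signed coefficient).
#' @param objective reaction id of the biomass objective.
#' @param genes optional gene universe; defaults to the union of GPR
#'   leaves.
#' @param annotations opaque list carried through file round trips.
#' @return A validated \code{MetabolicModel}.
#' @export
MetabolicModel <- function(id, metabolites, reactions, stoich, objective,
                           genes = NULL, annotations = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- sub("^.*_", "", metabolites$id)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  if (is.null(reactions$gene_reaction_rule)) reactions$gene_reaction_rule <- ""
  reactions$gene_reaction_rule[is.na(reactions$gene_reaction_rule)] <- ""
  stopifnot(all(reactions$id %in% names(stoich)))
  metIdx <- stats::setNames(seq_len(nrow(metabolites)), metabolites$id)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_len(nrow(reactions))) {
    sv <- stoich[[reactions$id[k]]]
    if (length(sv)) {
      unknown <- setdiff(names(sv), metabolites$id)
      if (length(unknown)) {
        stop("reaction ", reactions$id[k], " references unknown metabolites: ",
             paste(unknown, collapse = ", "))
      }
      i <- c(i, metIdx[names(sv)])
      j <- c(j, rep.int(k, length(sv)))
      x <- c(x, as.numeric(sv))
    }
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  gpr <- lapply(reactions$gene_reaction_rule, parseGPR)
  names(gpr) <- reactions$id
  if (is.null(genes)) genes <- unique(unlist(lapply(gpr, gprGenes)))
  genes <- sort(unique(as.character(genes)))
  new("MetabolicModel", id = id, metabolites = metabolites,
      reactions = reactions, stoichiometry = S, gpr = gpr,
      genes = genes, objective = objective, annotations = annotations)
}

#' FluxDistribution: a steady-state flux vector
#'
#' Result of an FBA or MoMA solve: one flux per reaction satisfying
#' S v = 0 within solver tolerance and all bounds, plus the flux through
#' the objective reaction.
#'
#' @slot fluxes named numeric vector, reaction id -> flux (mmol/gDW/hr).
#' @slot objectiveValue flux through the objective reaction.
#' @slot status solver status string ("optimal" for a clean solve).
#'
#' @exportClass FluxDistribution
setClass("FluxDistribution",
  representation(fluxes = "numeric", objectiveValue = "numeric",
                 status = "character"))

setValidity("FluxDistribution", function(object) {
  if (is.null(names(object@fluxes))) "fluxes must be named by reaction id"
  else TRUE
})

FluxDistribution <- function(fluxes, objectiveValue, status = "optimal") {
  new("FluxDistribution", fluxes = fluxes,
      objectiveValue = as.numeric(objectiveValue), status = status)
}
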