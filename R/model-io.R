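.BIGBOUND <- 1000

#' Read a metabolic model from the community JSON dialect
#'
#' Expects top-level keys \code{id}, \code{metabolites}, \code{reactions}
#' (and optionally \code{genes}); reaction objects carry \code{id},
#' \code{metabolites} (metabolite id -> signed coefficient),
#' \code{lower_bound}, \code{upper_bound}, \code{gene_reaction_rule},
#' \code{subsystem}. The objective reaction is the one with nonzero
#' \code{objective_coefficient}. Unknown annotation fields are preserved
#' opaquely and re-emitted by \code{\link{writeModel}}.
#'
#' @param path Path to a JSON model file.
#' @param format Only \code{"json"} is supported.
#' @return A \code{\linkS4class{MetabolicModel}}.
#' @export
readModel <- function(path, format = c("json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  required <- c("id", "metabolites", "reactions")
  missingKeys <- setdiff(required, names(doc))
  if (length(missingKeys)) {
    stop("model format error: missing required keys: ",
         paste(missingKeys, collapse = ", "))
  }
  metKnown <- c("id", "name", "compartment", "formula", "charge")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("model format error: metabolite without id")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment))
                 sub("^.*_", "", m$id) else m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
               stringsAsFactors = FALSE)
  }))
  metExtra <- lapply(doc$metabolites, function(m) m[setdiff(names(m), metKnown)])
  names(metExtra) <- mets$id

  rxnKnown <- c("id", "name", "metabolites", "lower_bound", "upper_bound",
                "gene_reaction_rule", "subsystem", "objective_coefficient")
  rxnMissing <- unlist(lapply(doc$reactions, function(r) {
    need <- c("id", "metabolites", "lower_bound", "upper_bound")
    if (is.null(r$id)) return("reaction id")
    miss <- need[vapply(need, function(k) is.null(r[[k]]), logical(1))]
    if (length(miss)) paste0(r$id, ": ", paste(miss, collapse = "/")) else NULL
  }))
  if (length(rxnMissing)) {
    stop("model format error: missing required keys: ",
         paste(rxnMissing, collapse = "; "))
  }
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id,
               name = if (is.null(r$name)) r$id else r$name,
               subsystem = if (is.null(r$subsystem)) NA_character_ else r$subsystem,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               gene_reaction_rule = if (is.null(r$gene_reaction_rule)) ""
                 else r$gene_reaction_rule,
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r)
    vapply(r$metabolites, as.numeric, numeric(1)))
  names(stoich) <- rxns$id
  rxnExtra <- lapply(doc$reactions, function(r) r[setdiff(names(r), rxnKnown)])
  names(rxnExtra) <- rxns$id

  objCoef <- vapply(doc$reactions, function(r)
    if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient),
    numeric(1))
  if (!any(objCoef != 0)) {
    stop("model format error: missing required keys: objective ",
         "(no reaction has a nonzero objective_coefficient)")
  }
  objective <- rxns$id[which(objCoef != 0)[1]]

  genes <- NULL
  if (!is.null(doc$genes)) {
    genes <- vapply(doc$genes, function(g)
      if (is.list(g)) as.character(g$id) else as.character(g), character(1))
  }
  topExtra <- doc[setdiff(names(doc), c("id", "metabolites", "reactions", "genes"))]
  MetabolicModel(id = doc$id, metabolites = mets, reactions = rxns,
                 stoich = stoich, objective = objective, genes = genes,
                 annotations = list(toplevel = topExtra,
                                    metabolites = metExtra,
                                    reactions = rxnExtra))
}

#' Write a metabolic model to the community JSON dialect
#'
#' \code{readModel(writeModel(m, path))} is the identity on all typed
#' fields; opaque annotations captured at read time are re-emitted.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param path Output path.
#' @param format Only \code{"json"} is supported.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path, format = c("json")) {
  format <- match.arg(format)
  ann <- model@annotations
  S <- model@stoichiometry
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    c(out, ann$metabolites[[m$id]])
  })
  rxns <- lapply(seq_len(nrow(model@reactions)), function(j) {
    r <- model@reactions[j, ]
    sv <- S[, j]
    sv <- sv[sv != 0]
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(sv),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gene_reaction_rule)
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    if (r$id == model@objective) out$objective_coefficient <- 1
    c(out, ann$reactions[[r$id]])
  })
  doc <- c(list(id = model@id, metabolites = mets, reactions = rxns,
                genes = lapply(model@genes, function(g) list(id = g))),
           ann$toplevel)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Media specification
#'
#' A growth medium: maximum uptake rates for nutrient exchange reactions
#' plus a set of basal metabolites whose uptake is left unconstrained
#' (water, oxygen, protons and similar freely available species).
#'
#' @param uptakeBounds Named numeric vector, exchange reaction id ->
#'   maximum uptake rate (mmol/gDW/hr, nonnegative).
#' @param freeMetabolites Character vector of basal metabolite ids.
#' @return An object of class \code{mediaSpec}.
#' @export
mediaSpec <- function(uptakeBounds = numeric(0), freeMetabolites = character(0)) {
  uptakeBounds <- unlist(uptakeBounds)
  if (length(uptakeBounds) && (is.null(names(uptakeBounds)) || any(uptakeBounds < 0))) {
    stop("uptakeBounds must be a named nonnegative vector")
  }
  structure(list(uptake_bounds = uptakeBounds,
                 free_metabolites = as.character(freeMetabolites)),
            class = "mediaSpec")
}

#' Apply a growth medium to a model
#'
#' Sets the lower bound of every listed nutrient exchange to minus its
#' uptake rate, closes uptake (lower bound 0) on all other non-basal
#' exchanges, opens basal-metabolite exchanges fully for uptake, and
#' leaves all secretion (upper) bounds and all internal reactions
#' untouched.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param media A \code{\link{mediaSpec}}.
#' @return The constrained model.
#' @export
applyMedia <- function(model, media) {
  stopifnot(inherits(media, "mediaSpec"))
  ex <- isExchange(model)
  listed <- names(media$uptake_bounds)
  unknown <- setdiff(listed, model@reactions$id)
  if (length(unknown)) {
    stop("media specification error: unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  nonEx <- listed[!ex[listed]]
  if (length(nonEx)) {
    stop("media specification error: not exchange reactions: ",
         paste(nonEx, collapse = ", "))
  }
  # metabolite of each exchange reaction
  exIds <- names(ex)[ex]
  exMet <- vapply(exIds, function(r) {
    col <- model@stoichiometry[, r]
    names(col)[col != 0][1]
  }, character(1))
  basalEx <- exIds[exMet %in% media$free_metabolites]
  for (r in exIds) {
    if (r %in% listed) {
      model@reactions$lower_bound[model@reactions$id == r] <-
        -media$uptake_bounds[[r]]
    } else if (r %in% basalEx) {
      model@reactions$lower_bound[model@reactions$id == r] <- -.BIGBOUND
    } else {
      i <- model@reactions$id == r
      model@reactions$lower_bound[i] <- max(model@reactions$lower_bound[i], 0)
    }
  }
  validObject(model)
  model
}

#' Read a media specification from a structured config file
#'
#' Reads the \code{media} section of a YAML config: \code{uptake_bounds}
#' maps exchange reaction ids to uptake rates; \code{free_metabolites}
#' lists basal metabolite ids.
#'
#' @param path YAML file path.
#' @param section Name of the media section (default \code{"media"});
#'   pass \code{NULL} if the file itself is the media mapping.
#' @return A \code{\link{mediaSpec}}.
#' @export
readMediaSpec <- function(path, section = "media") {
  doc <- yaml::read_yaml(path)
  if (!is.null(section)) {
    if (is.null(doc[[section]])) stop("no '", section, "' section in ", path)
    doc <- doc[[section]]
  }
  mediaSpec(uptakeBounds = unlist(doc$uptake_bounds),
            freeMetabolites = doc$free_metabolites)
}

#' Keep a subset of reactions, dropping newly unused metabolites
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param keep Character vector of reaction ids to retain.
#' @param dropOrphans Drop metabolites that no longer occur in any kept
#'   reaction (default TRUE).
#' @return The reduced model; the gene list shrinks to genes appearing
#'   in kept GPRs.
#' @export
subsetModel <- function(model, keep, dropOrphans = TRUE) {
  if (!(model@objective %in% keep)) {
    stop("model hygiene error: objective reaction '", model@objective,
         "' not in kept reaction set")
  }
  jkeep <- model@reactions$id %in% keep
  S <- model@stoichiometry[, jkeep, drop = FALSE]
  rxns <- model@reactions[jkeep, , drop = FALSE]
  rownames(rxns) <- NULL
  mets <- model@metabolites
  if (dropOrphans) {
    used <- as.vector(Matrix::rowSums(S != 0)) > 0
    S <- S[used, , drop = FALSE]
    mets <- mets[used, , drop = FALSE]
    rownames(mets) <- NULL
  }
  gpr <- model@gpr[rxns$id]
  genes <- sort(unique(unlist(lapply(gpr, gprGenes))))
  ann <- model@annotations
  ann$reactions <- ann$reactions[names(ann$reactions) %in% rxns$id]
  ann$metabolites <- ann$metabolites[names(ann$metabolites) %in% mets$id]
  new("MetabolicModel", id = model@id, metabolites = mets, reactions = rxns,
      stoichiometry = S, gpr = gpr, genes = genes,
      objective = model@objective, annotations = ann)
}
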