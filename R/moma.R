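#' Minimization of Metabolic Adjustment (MoMA)
#'
#' Predicts the flux state of a perturbed model as the feasible flux
#' vector closest to a wild-type reference distribution: the quadratic
#' variant minimizes the squared Euclidean distance, the linear variant
#' the sum of absolute deviations (kept linear by nonnegative
#' forward/reverse deviation variables). Reactions absent from the
#' reference are treated as zero wild-type flux.
#'
#' @param model The perturbed \code{\linkS4class{MetabolicModel}} (e.g.
#'   with knocked-out reactions closed to [0, 0]).
#' @param referenceFlux A \code{\linkS4class{FluxDistribution}} (or
#'   named numeric vector) from the unperturbed model, typically one
#'   cached FBA solution.
#' @param variant \code{"quadratic"} (default) or \code{"linear"}.
#' @return A \code{\linkS4class{FluxDistribution}} whose
#'   \code{objectiveValue} is the flux through the model's objective
#'   reaction (the knockout growth).
#' @export
moma <- function(model, referenceFlux, variant = c("quadratic", "linear")) {
  variant <- match.arg(variant)
  ref <- if (is(referenceFlux, "FluxDistribution")) fluxes(referenceFlux)
         else referenceFlux
  rid <- model@reactions$id
  w <- numeric(length(rid))
  hit <- match(rid, names(ref))
  w[!is.na(hit)] <- ref[hit[!is.na(hit)]]
  lb <- pmax(model@reactions$lower_bound, -.BIGCAP)
  ub <- pmin(model@reactions$upper_bound, .BIGCAP)
  S <- model@stoichiometry
  if (variant == "quadratic") {
    res <- .qpMoma(S = S, w = w, lb = lb, ub = ub)
    if (res$status != "optimal") {
      stop("MoMA infeasible for model '", model@id, "': solver status '",
           res$status, "'")
    }
    v <- res$v
  } else {
    # variables: [v, dPlus, dMinus], minimize sum(dPlus + dMinus)
    # with v - dPlus + dMinus = w
    n <- length(rid)
    Aeq <- rbind(cbind(as.matrix(S), matrix(0, nrow(S), 2 * n)),
                 cbind(diag(n), -diag(n), diag(n)))
    beq <- c(numeric(nrow(S)), w)
    obj <- c(numeric(n), rep(1, 2 * n))
    res <- .lp(obj, Aeq, beq,
               lb = c(lb, numeric(2 * n)),
               ub = c(ub, rep(.BIGCAP, 2 * n)),
               maximize = FALSE)
    if (res$status != "optimal") {
      stop("MoMA (linear) infeasible for model '", model@id,
           "': solver status '", res$status, "'")
    }
    v <- res$x[seq_len(n)]
  }
  FluxDistribution(fluxes = stats::setNames(v, rid),
                   objectiveValue = v[match(model@objective, rid)],
                   status = "optimal")
}
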