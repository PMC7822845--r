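#' Flux Balance Analysis
#'
#' Maximizes flux through the objective (biomass) reaction subject to
#' steady-state mass balance (S v = 0) and the model's flux bounds. The
#' optimum is unique but the returned flux vector is one optimal vertex;
#' downstream knockout analyses therefore reference a single cached FBA
#' solution per model.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param objective Optional reaction id to optimize instead of the
#'   model's objective.
#' @param maximize Maximize (default) or minimize the objective flux.
#' @return A \code{\linkS4class{FluxDistribution}}.
#' @export
fba <- function(model, objective = NULL, maximize = TRUE) {
  objective <- if (is.null(objective)) model@objective else objective
  rid <- model@reactions$id
  j <- match(objective, rid)
  if (is.na(j)) stop("objective reaction '", objective, "' not in model")
  obj <- numeric(length(rid)); obj[j] <- 1
  res <- .lp(obj, Aeq = model@stoichiometry, beq = numeric(nrow(model@stoichiometry)),
             lb = model@reactions$lower_bound, ub = model@reactions$upper_bound,
             maximize = maximize)
  if (res$status != "optimal") {
    stop("FBA infeasible for model '", model@id, "': solver status '",
         res$status, "'")
  }
  FluxDistribution(fluxes = stats::setNames(res$x, rid),
                   objectiveValue = res$x[j], status = res$status)
}

#' Flux Variability Analysis
#'
#' For every reaction, the minimum and maximum attainable steady-state
#' flux while the objective flux is held at at least
#' \code{fraction} times the FBA optimum.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param fraction Required fraction of the FBA optimum in [0, 1];
#'   fraction 0 imposes no objective constraint (pure feasibility).
#' @param reactions Reaction ids to analyze (default all).
#' @return data.frame with columns \code{reaction}, \code{min},
#'   \code{max}.
#' @export
fva <- function(model, fraction = 1, reactions = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  rid <- model@reactions$id
  if (is.null(reactions)) reactions <- rid
  stopifnot(all(reactions %in% rid))
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  S <- model@stoichiometry
  b0 <- numeric(nrow(S))
  Ale <- NULL; ble <- NULL
  if (fraction > 0) {
    opt <- objectiveValue(fba(model))
    row <- numeric(length(rid))
    row[match(model@objective, rid)] <- -1
    Ale <- matrix(row, nrow = 1)
    # tiny slack so the constraint is attainable despite solver round-off
    ble <- -(fraction * opt - 1e-7 * max(1, abs(opt)))
  }
  out <- lapply(reactions, function(r) {
    obj <- numeric(length(rid)); obj[match(r, rid)] <- 1
    lo <- .lp(obj, S, b0, lb, ub, Ale, ble, maximize = FALSE)
    hi <- .lp(obj, S, b0, lb, ub, Ale, ble, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible for reaction '", r, "': solver status '",
           lo$status, "'/'", hi$status, "'")
    }
    data.frame(reaction = r, min = lo$value, max = hi$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Find blocked reactions
#'
#' A reaction is blocked when it cannot carry flux under any feasible
#' steady state, i.e. its FVA range at objective fraction 0 lies within
#' the zero tolerance.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param tol Zero-flux tolerance (default 1e-6).
#' @return Character vector of blocked reaction ids.
#' @export
findBlockedReactions <- function(model, tol = 1e-6) {
  rid <- model@reactions$id
  n <- length(rid)
  sys <- .lpSystem(model@stoichiometry, numeric(nrow(model@stoichiometry)),
                   pmax(model@reactions$lower_bound, -.BIGCAP),
                   pmin(model@reactions$upper_bound, .BIGCAP))
  if (is.null(sys)) stop("blocked-reaction scan: model infeasible")
  # start from one feasible point: any reaction already carrying flux
  # there is certainly not blocked
  base <- .lpFeasiblePoint(sys)
  if (!base$ok) stop("blocked-reaction scan: model infeasible")
  blocked <- character(0)
  for (j in seq_len(n)) {
    if (abs(base$x[j]) > tol) next
    e <- numeric(n); e[j] <- 1
    if (.lpCanReach(sys, e, tol)) next
    if (.lpCanReach(sys, -e, tol)) next
    blocked <- c(blocked, rid[j])
  }
  blocked
}
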