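#' GIMME configuration
#'
#' @param fraction Required fraction of the template's optimal objective
#'   that the extracted model must retain, in (0, 1]. Default 0.9.
#' @param penalty Positive penalty per unit of flux through
#'   expression-inactive reactions. Under binary activity data the
#'   GIMME expression penalty collapses to a constant, so 1 is the
#'   natural default.
#' @param tol Zero-flux tolerance.
#' @return An object of class \code{gimmeConfig}.
#' @export
gimmeConfig <- function(fraction = 0.9, penalty = 1, tol = 1e-6) {
  stopifnot(fraction > 0, fraction <= 1, penalty > 0, tol > 0)
  structure(list(fraction = fraction, penalty = penalty, tol = tol),
            class = "gimmeConfig")
}

#' Label reactions by expression activity through their GPR rules
#'
#' A reaction is active when its GPR evaluates true over the active gene
#' set -- so a reaction catalyzed by several isozymes stays active when
#' any one of them is expressed, and the complete gene rule is retained
#' on kept reactions regardless of individual member activity. Reactions
#' without a GPR are labelled \code{no_gene}.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param calls data.frame with columns gene and active (e.g. from
#'   \code{\link{integrateOmics}}), or a character vector of active
#'   genes.
#' @return Named character vector over reactions:
#'   active/inactive/no_gene.
#' @export
reactionActivityFromCalls <- function(model, calls) {
  activeGenes <- if (is.character(calls)) calls
                 else as.character(calls$gene[calls$active])
  vapply(model@gpr, function(r) {
    if (r$op == "empty") "no_gene"
    else if (evaluateGPR(r, activeGenes)) "active"
    else "inactive"
  }, character(1))
}

#' GIMME extraction of a context-specific model
#'
#' Solves the linear program: minimize total penalized flux through
#' expression-inactive reactions subject to steady state, bounds and the
#' objective held at at least \code{fraction} of the template optimum.
#' All active and gene-free reactions are kept; inactive reactions are
#' kept only when they carry flux in the minimizing solution (data-
#' unsupported reactions required for the objective). The pruned model
#' is then cleaned of dead-end metabolites and blocked reactions.
#'
#' @param model Template \code{\linkS4class{MetabolicModel}} with its
#'   medium already applied; must be FBA-feasible.
#' @param activity Named activity vector from
#'   \code{\link{reactionActivityFromCalls}}.
#' @param config A \code{\link{gimmeConfig}}.
#' @return list(model, report): the extracted model and a report with
#'   the GIMME flux, kept/removed reactions and the retained objective
#'   value (always >= fraction x template optimum).
#' @export
gimmeExtract <- function(model, activity, config = gimmeConfig()) {
  stopifnot(inherits(config, "gimmeConfig"))
  rid <- model@reactions$id
  stopifnot(all(rid %in% names(activity)))
  activity <- activity[rid]
  wt <- tryCatch(fba(model), error = function(e) {
    stop("GIMME build error: template model infeasible (", conditionMessage(e), ")")
  })
  opt <- objectiveValue(wt)
  n <- length(rid)
  lb <- pmax(model@reactions$lower_bound, -.BIGCAP)
  ub <- pmin(model@reactions$upper_bound, .BIGCAP)
  S <- as.matrix(model@stoichiometry)
  # forward/reverse split: v = p - q with p, q >= 0 keeps |v| linear
  Aeq <- cbind(S, -S)
  beq <- numeric(nrow(S))
  pUb <- pmax(ub, 0); qUb <- pmax(-lb, 0)
  # enforce v within [lb, ub] where lb > 0 or ub < 0 (forced direction)
  extra <- NULL; extraB <- NULL
  forced <- which(lb > 0 | ub < 0)
  for (j in forced) {
    row <- numeric(2 * n); row[j] <- -1; row[n + j] <- 1
    extra <- rbind(extra, row)            # -(p - q) <= -lb  =>  v >= lb
    extraB <- c(extraB, -lb[j])
    row2 <- numeric(2 * n); row2[j] <- 1; row2[n + j] <- -1
    extra <- rbind(extra, row2)           # v <= ub
    extraB <- c(extraB, ub[j])
  }
  objRow <- numeric(2 * n)
  jObj <- match(model@objective, rid)
  objRow[jObj] <- -1; objRow[n + jObj] <- 1   # -v_obj <= -fraction*opt
  Ale <- rbind(objRow, extra)
  ble <- c(-(config$fraction * opt - 1e-7 * max(1, abs(opt))), extraB)
  cost <- numeric(2 * n)
  inact <- activity == "inactive"
  cost[c(which(inact), n + which(inact))] <- config$penalty
  res <- .lp(cost, Aeq, beq, lb = numeric(2 * n), ub = c(pUb, qUb),
             Ale = Ale, ble = ble, maximize = FALSE)
  if (res$status != "optimal") {
    stop("GIMME build error: penalized flux program not solvable (status '",
         res$status, "')")
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- rid
  keep <- !inact | abs(v) > config$tol
  keep[jObj] <- TRUE
  pruned <- subsetModel(model, rid[keep])
  de <- removeDeadEnds(pruned)
  cleaned <- de$model
  blocked <- findBlockedReactions(cleaned, tol = config$tol)
  blocked <- setdiff(blocked, model@objective)
  if (length(blocked)) {
    cleaned <- removeDeadEnds(subsetModel(cleaned, setdiff(reactionIds(cleaned), blocked)))$model
  }
  outOpt <- objectiveValue(fba(cleaned))
  if (outOpt < config$fraction * opt - 1e-5 * max(1, abs(opt))) {
    stop("GIMME internal consistency error: extracted model attains ",
         outOpt, " < ", config$fraction, " x ", opt)
  }
  removed <- setdiff(rid, reactionIds(cleaned))
  list(model = cleaned,
       report = list(
         templateObjective = opt,
         extractedObjective = outOpt,
         fraction = config$fraction,
         gimmeFlux = v,
         activity = activity,
         keptInactive = intersect(rid[inact & keep], reactionIds(cleaned)),
         removedReactions = removed,
         deadEndLog = de$log,
         blockedRemoved = blocked))
}

#' Build a cell-type-specific model from a template and activity calls
#'
#' Pipeline: apply the cell type's medium, run GIMME extraction, leak
#' test the result, and check the metabolic task suite. Task failures
#' for tasks expected to pass are flagged in the report but non-fatal.
#'
#' @param template Template \code{\linkS4class{MetabolicModel}}.
#' @param calls Integrated activity calls (data.frame with gene,
#'   active).
#' @param media A \code{\link{mediaSpec}} for this cell type.
#' @param tasks Optional list of \code{\link{metabolicTask}} objects.
#' @param config A \code{\link{gimmeConfig}}.
#' @return list(model, report); the report carries metabolite, reaction
#'   and gene counts, the leak list, task results and the GIMME report.
#' @export
buildCellModel <- function(template, calls, media, tasks = NULL,
                           config = gimmeConfig()) {
  constrained <- applyMedia(template, media)
  activity <- reactionActivityFromCalls(constrained, calls)
  ext <- gimmeExtract(constrained, activity, config)
  model <- ext$model
  leaks <- leakTest(model, tol = config$tol)
  taskResults <- NULL
  if (!is.null(tasks) && length(tasks)) {
    taskResults <- data.frame(
      task = vapply(tasks, `[[`, "", "id"),
      expected = vapply(tasks, `[[`, "", "expected"),
      passed = vapply(tasks, function(t)
        checkMetabolicTask(model, t, tol = config$tol), logical(1)),
      stringsAsFactors = FALSE)
    taskResults$flagged <- taskResults$expected == "pass" & !taskResults$passed
    if (any(taskResults$flagged)) {
      warning("build report: ", sum(taskResults$flagged),
              " task(s) expected to pass failed")
    }
  }
  report <- list(
    nMetabolites = nMetabolites(model),
    nReactions = nReactions(model),
    nGenes = length(modelGenes(model)),
    objectiveValue = ext$report$extractedObjective,
    leaks = leaks,
    taskResults = taskResults,
    taskPassRate = if (is.null(taskResults)) NA_real_
                   else mean(taskResults$passed == (taskResults$expected == "pass")),
    gimme = ext$report)
  list(model = model, report = report)
}
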