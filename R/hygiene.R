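#' Remove dead-end metabolites and their reactions
#'
#' Iteratively deletes metabolites that can only be produced or only
#' consumed (given current bounds, so a reversible reaction counts on
#' both sides and an open exchange supplies or drains its metabolite)
#' together with their incident reactions, until a fixpoint. The result
#' is independent of metabolite scan order.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param tol Bound tolerance below which a direction is considered
#'   closed.
#' @return list(model, log) where \code{log} is a data.frame with one
#'   row per removed metabolite (trigger) and the reactions it took
#'   with it.
#' @export
removeDeadEnds <- function(model, tol = 1e-9) {
  logRows <- list()
  repeat {
    S <- model@stoichiometry
    lb <- model@reactions$lower_bound
    ub <- model@reactions$upper_bound
    Sm <- as(S, "TsparseMatrix")
    canFwd <- ub > tol    # reaction can run forward
    canRev <- lb < -tol   # reaction can run in reverse
    nm <- nrow(S)
    producible <- logical(nm); consumable <- logical(nm); present <- logical(nm)
    ii <- Sm@i + 1L; jj <- Sm@j + 1L; xx <- Sm@x
    present[unique(ii)] <- TRUE
    pos <- xx > 0; neg <- xx < 0
    producible[unique(c(ii[pos & canFwd[jj]], ii[neg & canRev[jj]]))] <- TRUE
    consumable[unique(c(ii[neg & canFwd[jj]], ii[pos & canRev[jj]]))] <- TRUE
    dead <- which(present & !(producible & consumable))
    orphan <- which(!present)
    if (!length(dead) && !length(orphan)) break
    dropRxn <- character(0)
    for (i in dead) {
      incident <- colnames(S)[as.vector(S[i, ] != 0)]
      if (model@objective %in% incident) {
        stop("model hygiene error: removing dead-end metabolite '",
             rownames(S)[i], "' would delete the objective reaction")
      }
      logRows[[length(logRows) + 1L]] <- data.frame(
        metabolite = rownames(S)[i],
        reactions = paste(incident, collapse = ";"),
        stringsAsFactors = FALSE)
      dropRxn <- union(dropRxn, incident)
    }
    keep <- setdiff(model@reactions$id, dropRxn)
    model <- subsetModel(model, keep, dropOrphans = TRUE)
  }
  logDf <- if (length(logRows)) do.call(rbind, logRows)
           else data.frame(metabolite = character(0), reactions = character(0),
                           stringsAsFactors = FALSE)
  list(model = model, log = logDf)
}

#' Leak test: can the model create metabolites from nothing?
#'
#' With every exchange reaction closed to [0, 0], each metabolite in
#' turn is given a temporary drain whose flux is maximized; a
#' mass-balanced model can drain nothing, so any metabolite with drain
#' flux above tolerance indicates a stoichiometric leak (mass imbalance
#' or an erroneous irreversibility).
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param tol Zero-flux tolerance.
#' @return Character vector of leaking metabolite ids (empty when
#'   clean).
#' @export
leakTest <- function(model, tol = 1e-6) {
  ex <- isExchange(model)
  closed <- setBounds(model, names(ex)[ex], lower = 0, upper = 0)
  S <- as.matrix(closed@stoichiometry)
  lb <- closed@reactions$lower_bound
  ub <- closed@reactions$upper_bound
  n <- ncol(S)
  leaks <- character(0)
  for (i in seq_len(nrow(S))) {
    Saug <- cbind(S, 0)
    Saug[i, n + 1] <- -1
    obj <- c(numeric(n), 1)
    res <- .lp(obj, Saug, numeric(nrow(S)),
               lb = c(lb, 0), ub = c(ub, .BIGBOUND), maximize = TRUE)
    if (res$status == "optimal" && res$value > tol) {
      leaks <- c(leaks, rownames(S)[i])
    }
  }
  leaks
}

#' Metabolic task specification
#'
#' @param id Task identifier.
#' @param inputs Named numeric vector, metabolite id -> maximum uptake
#'   rate.
#' @param outputs Character vector of metabolite ids that must all be
#'   producible.
#' @param expected \code{"pass"} or \code{"fail"}.
#' @return An object of class \code{metabolicTask}.
#' @export
metabolicTask <- function(id, inputs, outputs, expected = "pass") {
  stopifnot(is.numeric(inputs), !is.null(names(inputs)) || length(inputs) == 0,
            expected %in% c("pass", "fail"))
  structure(list(id = id, inputs = inputs, outputs = as.character(outputs),
                 expected = expected), class = "metabolicTask")
}

#' Check a metabolic task
#'
#' All exchange reactions are closed; temporary uptakes are opened for
#' the task inputs at their stated rates and temporary sinks added for
#' the outputs. The task passes iff every output sink can carry flux
#' above tolerance.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param task A \code{\link{metabolicTask}}.
#' @param tol Zero-flux tolerance.
#' @return Logical: TRUE for pass.
#' @export
checkMetabolicTask <- function(model, task, tol = 1e-6) {
  stopifnot(inherits(task, "metabolicTask"))
  mets <- model@metabolites$id
  unknown <- setdiff(c(names(task$inputs), task$outputs), mets)
  if (length(unknown)) {
    stop("task specification error: unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  }
  ex <- isExchange(model)
  closed <- setBounds(model, names(ex)[ex], lower = 0, upper = 0)
  S <- as.matrix(closed@stoichiometry)
  n <- ncol(S)
  lb <- closed@reactions$lower_bound
  ub <- closed@reactions$upper_bound
  nin <- length(task$inputs)
  nout <- length(task$outputs)
  aug <- matrix(0, nrow(S), nin + nout,
                dimnames = list(rownames(S), NULL))
  for (k in seq_len(nin)) aug[names(task$inputs)[k], k] <- 1     # supply
  for (k in seq_len(nout)) aug[task$outputs[k], nin + k] <- -1   # sink
  Saug <- cbind(S, aug)
  lbA <- c(lb, numeric(nin + nout))
  ubA <- c(ub, as.numeric(task$inputs), rep(.BIGBOUND, nout))
  for (k in seq_len(nout)) {
    obj <- numeric(ncol(Saug)); obj[n + nin + k] <- 1
    res <- .lp(obj, Saug, numeric(nrow(Saug)), lbA, ubA, maximize = TRUE)
    if (res$status != "optimal" || res$value <= tol) return(FALSE)
  }
  TRUE
}

#' Read a task catalogue from TSV
#'
#' Columns: \code{task_id}, \code{inputs} (semicolon-separated
#' \code{met:rate} pairs), \code{outputs} (semicolon-separated
#' metabolite ids), \code{expected} (pass/fail).
#'
#' @param path TSV file path.
#' @return List of \code{\link{metabolicTask}} objects.
#' @export
readTaskTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("task_id", "inputs", "outputs", "expected")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("task table missing columns: ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    pairs <- strsplit(df$inputs[i], ";", fixed = TRUE)[[1]]
    pairs <- pairs[nzchar(pairs)]
    parts <- strsplit(pairs, ":", fixed = TRUE)
    inputs <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                              vapply(parts, `[`, "", 1))
    outputs <- strsplit(df$outputs[i], ";", fixed = TRUE)[[1]]
    metabolicTask(df$task_id[i], inputs, outputs[nzchar(outputs)],
                  df$expected[i])
  })
}
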