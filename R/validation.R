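#' Nutrient uptake sweep with windowed averaging
#'
#' Varies the maximum uptake rate of one nutrient exchange over a grid;
#' at each grid point the growth rate is computed at \code{window}
#' uptake values spaced \code{step} apart and centered on the point,
#' and the mean and standard deviation over the window are reported
#' (so the reported growth at 3.0 with window 5 and step 0.1 averages
#' the growths at 2.8, 2.9, 3.0, 3.1, 3.2). An infeasible point is
#' recorded as growth 0 and flagged. Window 1 reduces to pointwise FBA.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param exchangeId Exchange reaction id to sweep.
#' @param grid Strictly increasing nonnegative uptake values.
#' @param window Odd number of uptake values averaged per grid point
#'   (default 5).
#' @param step Spacing of the window values (default 0.1).
#' @return data.frame: uptake, growth (windowed mean), sd, n,
#'   infeasible.
#' @export
nutrientSweep <- function(model, exchangeId, grid, window = 5, step = 0.1) {
  ex <- isExchange(model)
  if (!exchangeId %in% names(ex) || !ex[[exchangeId]]) {
    stop("'", exchangeId, "' is not an exchange reaction of the model")
  }
  stopifnot(window >= 1, window %% 2 == 1, all(diff(grid) > 0))
  growthAt <- function(u) {
    u <- max(u, 0)
    m <- setBounds(model, exchangeId, lower = -u)
    tryCatch(objectiveValue(fba(m)), error = function(e) NA_real_)
  }
  half <- (window - 1) / 2
  rows <- lapply(grid, function(g) {
    us <- g + step * seq(-half, half)
    vals <- vapply(us, growthAt, numeric(1))
    flag <- anyNA(vals)
    vals[is.na(vals)] <- 0
    data.frame(uptake = g, growth = mean(vals), sd = stats::sd(vals),
               n = window, infeasible = flag)
  })
  out <- do.call(rbind, rows)
  if (window == 1) out$sd <- 0
  out
}

#' Conditional nutrient dependency surface
#'
#' Full-factorial FBA growth over the uptake grids of two nutrients,
#' with a summary of whether nutrient B affects growth only when
#' nutrient A is limiting (the classic glutamine-under-glucose-
#' limitation behavior).
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param exchangeA,exchangeB Exchange reaction ids.
#' @param gridA,gridB Nonnegative uptake grids.
#' @param tol Growth-difference tolerance for "affects growth".
#' @return list(surface, summary): surface is a data.frame (uptakeA,
#'   uptakeB, growth); summary gives, per uptakeA, whether B changes
#'   growth (bEffect) and the largest uptakeA at which it does
#'   (aThreshold, NA when none).
#' @export
conditionalDependency <- function(model, exchangeA, exchangeB, gridA, gridB,
                                  tol = 1e-6) {
  ex <- isExchange(model)
  stopifnot(ex[[exchangeA]], ex[[exchangeB]])
  surface <- expand.grid(uptakeA = gridA, uptakeB = gridB)
  surface$growth <- apply(surface, 1, function(r) {
    m <- setBounds(model, exchangeA, lower = -r[["uptakeA"]])
    m <- setBounds(m, exchangeB, lower = -r[["uptakeB"]])
    tryCatch(objectiveValue(fba(m)), error = function(e) 0)
  })
  eff <- vapply(gridA, function(a) {
    g <- surface$growth[surface$uptakeA == a]
    max(g) - min(g) > tol
  }, logical(1))
  summary <- data.frame(uptakeA = gridA, bEffect = eff)
  aThreshold <- if (any(eff)) max(gridA[eff]) else NA_real_
  list(surface = surface, summary = summary, aThreshold = aThreshold)
}

#' Response of one reaction to forced flux through another
#'
#' Sets the lower bound of the forced reaction to each level, solves
#' FBA and records the flux through the observed reaction; the monotone
#' trend of the response is summarized. Infeasible forcing levels are
#' flagged.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param forcedId Reaction whose flux is forced (lower bound raised).
#' @param levels Increasing forcing levels.
#' @param observedId Reaction whose flux is recorded.
#' @return list(curve, trend): curve is a data.frame (forced, observed,
#'   feasible); trend is "decreasing", "increasing", "flat" or "mixed"
#'   over feasible points.
#' @export
forcedFluxResponse <- function(model, forcedId, levels, observedId) {
  stopifnot(forcedId %in% model@reactions$id,
            observedId %in% model@reactions$id)
  rows <- lapply(levels, function(lv) {
    m <- setBounds(model, forcedId, lower = lv)
    sol <- tryCatch(fba(m), error = function(e) NULL)
    data.frame(forced = lv,
               observed = if (is.null(sol)) NA_real_
                          else fluxes(sol)[[observedId]],
               feasible = !is.null(sol))
  })
  curve <- do.call(rbind, rows)
  obs <- curve$observed[curve$feasible]
  trend <- if (length(obs) < 2) "flat" else {
    d <- diff(obs)
    if (all(d <= 1e-9) && any(d < -1e-9)) "decreasing"
    else if (all(d >= -1e-9) && any(d > 1e-9)) "increasing"
    else if (all(abs(d) <= 1e-9)) "flat"
    else "mixed"
  }
  list(curve = curve, trend = trend)
}

#' Run a qualitative behavior suite against a model
#'
#' Each specification perturbs the model (nutrient removal, gene
#' knockout, or forced reaction flux), reads an observable (growth or a
#' named reaction flux) and compares the qualitative outcome against
#' the expectation (zero / decreased / increased / unchanged /
#' nonzero). Verdicts are agree / partial / disagree; partial marks an
#' outcome in the expected direction but of different severity (e.g.
#' zero growth where a decrease was expected). Unresolvable specs are
#' reported as errors and the suite continues.
#'
#' @param model A \code{\linkS4class{MetabolicModel}}.
#' @param specs data.frame with columns description, perturbation_type
#'   (remove_nutrient / gene_knockout / force_flux), perturbation_arg
#'   (exchange id, gene id, or "reaction:level"), observable ("growth"
#'   or a reaction id), expected.
#' @param relTol Relative tolerance for decreased/increased/unchanged.
#' @param absTol Absolute zero tolerance.
#' @return data.frame: the specs plus baseline, observed and verdict
#'   columns.
#' @export
runBehaviorSuite <- function(model, specs, relTol = 0.05, absTol = 1e-6) {
  base <- fba(model)
  readObs <- function(sol, observable) {
    if (observable == "growth") objectiveValue(sol)
    else fluxes(sol)[[observable]]
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    baseVal <- NA_real_; obsVal <- NA_real_
    verdict <- tryCatch({
      pert <- switch(sp$perturbation_type,
        remove_nutrient = setBounds(model, sp$perturbation_arg, lower = 0),
        gene_knockout = {
          dis <- disabledReactions(model, sp$perturbation_arg)
          if (length(dis)) setBounds(model, dis, lower = 0, upper = 0)
          else model
        },
        force_flux = {
          parts <- strsplit(sp$perturbation_arg, ":", fixed = TRUE)[[1]]
          setBounds(model, parts[1], lower = as.numeric(parts[2]))
        },
        stop("unknown perturbation type '", sp$perturbation_type, "'"))
      if (!(sp$observable %in% c("growth", model@reactions$id))) {
        stop("unresolvable observable '", sp$observable, "'")
      }
      sol <- tryCatch(fba(pert), error = function(e) NULL)
      baseVal <- readObs(base, sp$observable)
      obsVal <- if (is.null(sol)) 0 else readObs(sol, sp$observable)
      b <- abs(baseVal)
      o <- abs(obsVal)
      outcome <- if (o <= absTol) "zero"
        else if (b > absTol && o < b * (1 - relTol)) "decreased"
        else if (o > max(b * (1 + relTol), absTol)) "increased"
        else "unchanged"
      expected <- sp$expected
      if (outcome == expected) "agree"
      else if (expected == "nonzero" && outcome != "zero") "agree"
      else if (expected == "decreased" && outcome == "zero") "partial"
      else if (expected == "zero" && outcome == "decreased") "partial"
      else "disagree"
    }, error = function(e) paste0("error: ", conditionMessage(e)))
    cbind(sp, data.frame(baseline = baseVal, observed = obsVal,
                         verdict = verdict, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a behavior specification table from TSV
#'
#' @param path TSV with columns description, perturbation_type,
#'   perturbation_arg, observable, expected.
#' @return data.frame of specs.
#' @export
readBehaviorSpecs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("description", "perturbation_type", "perturbation_arg",
            "observable", "expected")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("behavior spec table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
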