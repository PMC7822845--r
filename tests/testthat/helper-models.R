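# Fixture builders and independent oracles used across the suite.

# --- fixtures -------------------------------------------------------------

# linear chain: EX_A -> transport -> R1 (capacity capR1) -> demand
chainModel <- function(uptake = 10, capR1 = 10) {
  MetabolicModel(
    id = "chain",
    metabolites = data.frame(id = c("A_e", "A_c", "B_c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "R1", "DM_B"),
      lower_bound = c(-uptake, 0, 0, 0),
      upper_bound = c(1000, 1000, capR1, 1000)),
    stoich = list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                  R1 = c(A_c = -1, B_c = 1), DM_B = c(B_c = -1)),
    objective = "DM_B")
}

# two parallel routes A -> B (R1 and R2), then demand
twoPathModel <- function(uptake = 10, cap1 = 10, cap2 = 10,
                         gpr1 = "", gpr2 = "") {
  MetabolicModel(
    id = "twopath",
    metabolites = data.frame(id = c("A_e", "A_c", "B_c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "R1", "R2", "DM_B"),
      lower_bound = c(-uptake, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, cap1, cap2, 1000),
      gene_reaction_rule = c("", "", gpr1, gpr2, "")),
    stoich = list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                  R1 = c(A_c = -1, B_c = 1), R2 = c(A_c = -1, B_c = 1),
                  DM_B = c(B_c = -1)),
    objective = "DM_B")
}

# small gene-rich branch model used for knockout logic tests
gprFixtureModel <- function() {
  MetabolicModel(
    id = "gprfix",
    metabolites = data.frame(id = c("A_e", "A_c", "B_c", "C_c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "ISO", "CPLX", "MIX", "DM_B", "DM_C"),
      lower_bound = c(-10, 0, 0, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 10, 10, 10, 1000, 1000),
      gene_reaction_rule = c("", "g_t", "g_i1 or g_i2", "g_c1 and g_c2",
                             "(g_i1 and g_c1) or g_m", "", "")),
    stoich = list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                  ISO = c(A_c = -1, B_c = 1), CPLX = c(A_c = -1, B_c = 1),
                  MIX = c(A_c = -1, C_c = 1), DM_B = c(B_c = -1),
                  DM_C = c(C_c = -1)),
    objective = "DM_B")
}

# --- GPR oracle -----------------------------------------------------------

# brute-force truth-table evaluation of the *text* of a GPR by direct
# substitution into an R logical expression
gprTextOracle <- function(text, genes, active) {
  expr <- text
  expr <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, g %in% active, envir = env)
  eval(parse(text = expr), envir = env)
}

# random well-formed GPR expression over the given genes
randomGprText <- function(genes, depth = 2) {
  if (depth == 0 || length(genes) == 1 || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  left <- randomGprText(genes, depth - 1)
  right <- randomGprText(genes, depth - 1)
  sprintf("(%s %s %s)", left, op, right)
}

# --- LP vertex-enumeration oracle ----------------------------------------

# all vertices of {S v = b, lb <= v <= ub} by enumerating active bound
# sets; optionally one extra equality row (for objective-fraction faces)
enumerateVertices <- function(S, b, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  dof <- n - r
  verts <- list()
  addVertex <- function(v) {
    if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7)) {
      verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
    }
  }
  if (dof == 0) {
    v <- qr.coef(qr(S), b); v[is.na(v)] <- 0
    if (max(abs(S %*% v - b)) < tol) addVertex(as.vector(v))
  } else {
    combos <- utils::combn(n, dof)
    for (ci in seq_len(ncol(combos))) {
      J <- combos[, ci]
      sides <- expand.grid(rep(list(c(1, 2)), dof))
      for (si in seq_len(nrow(sides))) {
        fixedVals <- ifelse(unlist(sides[si, ]) == 1, lb[J], ub[J])
        if (any(!is.finite(fixedVals))) next
        rest <- setdiff(seq_len(n), J)
        rhs <- b - S[, J, drop = FALSE] %*% fixedVals
        sol <- qr.coef(qr(S[, rest, drop = FALSE]), rhs)
        if (anyNA(sol)) next
        v <- numeric(n)
        v[J] <- fixedVals
        v[rest] <- sol
        if (max(abs(S %*% v - b)) < tol) addVertex(v)
      }
    }
  }
  verts
}

# LP oracle: optimum of c'v over {S v = 0, bounds} by vertex enumeration
oracleLP <- function(model, obj, maximize = TRUE, extraRow = NULL,
                     extraRhs = 0) {
  S <- as.matrix(stoichiometry(model))
  b <- numeric(nrow(S))
  if (!is.null(extraRow)) {
    S <- rbind(S, extraRow)
    b <- c(b, extraRhs)
  }
  lb <- unname(lowerBounds(model))
  ub <- unname(upperBounds(model))
  verts <- enumerateVertices(S, b, lb, ub)
  if (!length(verts)) return(NA_real_)
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  if (maximize) max(vals) else min(vals)
}

# FVA oracle: per-reaction min/max over the polytope with the objective
# held at >= frac * opt (the optimum of a linear functional over a
# polytope is attained at a vertex of the polytope including the cut, so
# vertices of the cut face are enumerated too)
oracleFVA <- function(model, reaction, fraction = 0) {
  rid <- reactionIds(model)
  obj <- as.numeric(rid == objectiveReaction(model))
  e <- as.numeric(rid == reaction)
  S <- as.matrix(stoichiometry(model))
  lb <- unname(lowerBounds(model))
  ub <- unname(upperBounds(model))
  verts <- enumerateVertices(S, numeric(nrow(S)), lb, ub)
  keepVals <- function(vs) vapply(vs, function(v) sum(e * v), numeric(1))
  if (fraction > 0) {
    opt <- max(vapply(verts, function(v) sum(obj * v), numeric(1)))
    level <- fraction * opt
    ok <- verts[vapply(verts, function(v) sum(obj * v) >= level - 1e-7,
                       logical(1))]
    faceVerts <- enumerateVertices(rbind(S, obj),
                                   c(numeric(nrow(S)), level), lb, ub)
    vals <- keepVals(c(ok, faceVerts))
  } else {
    vals <- keepVals(verts)
  }
  c(min = min(vals), max = max(vals))
}

# --- misc oracles ---------------------------------------------------------

# hypergeometric upper-tail by direct summation
oracleHyperTail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(stats::dhyper(kk, K, N - K, n))
}

# PES by direct arithmetic, independent of the package implementation
oraclePes <- function(ud, ui, uu, dd, di, du) {
  up <- ud + ui + uu
  dn <- dd + di + du
  as.numeric((if (up > 0) (ud - ui) / up else 0) +
             (if (dn > 0) (di - dd) / dn else 0))
}
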