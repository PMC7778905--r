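## Flux-carrying status classification (A/a/b/B) via a flux variability
## variant, plus exact rational-arithmetic oracles.
##
## Status semantics over the steady-state polytope {v : S v = 0,
## lb <= v <= ub}:
##   A  carries non-zero flux under the original bounds;
##   a  carries flux once all boundary (exchange) reactions are made
##      bidirectional;
##   b  carries flux once every reaction is made bidirectional;
##   B  can never carry flux (network topology: e.g. a dead-end
##      metabolite).
## "Carries flux" means max v_r > tol or min v_r < -tol for the two LPs
## minimizing/maximizing v_r.  The three regimes relax bounds
## monotonically, so a status can only improve along the relaxation.

.REGIMES <- c("ORIGINAL", "BOUNDARY_RELAXED", "ALL_RELAXED")

#' Construct a flux problem from a model
#'
#' Boundary (exchange) reactions are those with an empty equation side or
#' involving a boundary-flagged species.  Boundary-flagged species are
#' not mass-balanced (their rows are dropped).  Bounds that exclude zero
#' (e.g. a forced maintenance flux) are clamped to include zero with a
#' warning, since the status definition presumes zero flux is feasible.
#'
#' @param model a [GsmnModel-class] object.
#' @param tol flux tolerance.
#' @param bigM bound magnitude for relaxed regimes.
#' @return a [FluxProblem-class] object.
#' @export
fluxProblem <- function(model, tol = 1e-6, bigM = 1000) {
  stopifnot(is(model, "GsmnModel"))
  sp <- model@species
  internal <- sp$id[!sp$boundary]
  rx <- model@reactions
  n <- nrow(rx)
  S <- matrix(0, length(internal), n,
              dimnames = list(internal, rx$id))
  boundary <- logical(n)
  for (i in seq_len(n)) {
    eq <- model@equations[[i]]
    touchesBoundary <- any(c(eq$left$met, eq$right$met) %in% sp$id[sp$boundary])
    for (k in seq_len(nrow(eq$left))) {
      m <- eq$left$met[k]
      if (m %in% internal)
        S[m, i] <- S[m, i] - eq$left$num[k] / eq$left$den[k]
    }
    for (k in seq_len(nrow(eq$right))) {
      m <- eq$right$met[k]
      if (m %in% internal)
        S[m, i] <- S[m, i] + eq$right$num[k] / eq$right$den[k]
    }
    boundary[i] <- touchesBoundary ||
      nrow(eq$left) == 0L || nrow(eq$right) == 0L
  }
  lb <- rx$lb; ub <- rx$ub
  clamp <- lb > 0 | ub < 0
  if (any(clamp)) {
    .log("WARNING", "bounds exclude zero for ",
         paste(rx$id[clamp], collapse = ", "),
         "; clamping to include zero for status computation")
    warning("bounds exclude zero for ", paste(rx$id[clamp], collapse = ", "),
            "; clamped to include zero for status computation", call. = FALSE)
    lb <- pmin(lb, 0); ub <- pmax(ub, 0)
  }
  new("FluxProblem", S = S, lb = lb, ub = ub, boundary = boundary,
      rxnIds = rx$id, metIds = internal, tol = tol, bigM = bigM)
}

#' Construct a flux problem from raw matrices
#'
#' @param S stoichiometric matrix.
#' @param lb,ub bound vectors.
#' @param boundary logical vector of boundary reactions (default: columns
#'   touching no metabolite twice, i.e. single-entry columns, are *not*
#'   auto-detected; all `FALSE`).
#' @param tol,bigM as in [fluxProblem()].
#' @return a [FluxProblem-class] object.
#' @export
fluxProblemFromMatrices <- function(S, lb, ub, boundary = rep(FALSE, ncol(S)),
                                    tol = 1e-6, bigM = 1000) {
  rxn <- colnames(S)
  if (is.null(rxn)) rxn <- sprintf("R%d", seq_len(ncol(S)))
  met <- rownames(S)
  if (is.null(met)) met <- sprintf("M%d", seq_len(nrow(S)))
  new("FluxProblem", S = unname(as.matrix(S)), lb = pmin(lb, 0),
      ub = pmax(ub, 0), boundary = boundary, rxnIds = rxn, metIds = met,
      tol = tol, bigM = bigM)
}

.regimeBounds <- function(problem, regime) {
  regime <- match.arg(regime, .REGIMES)
  lb <- problem@lb; ub <- problem@ub; M <- problem@bigM
  if (regime == "BOUNDARY_RELAXED") {
    lb[problem@boundary] <- -M; ub[problem@boundary] <- M
  } else if (regime == "ALL_RELAXED") {
    lb[] <- -M; ub[] <- M
  }
  list(lb = lb, ub = ub)
}

#' Flux range of one reaction under a relaxation regime
#'
#' Two LPs (minimize and maximize \eqn{v_r}) under \eqn{S v = 0} and the
#' regime-adjusted bounds.
#'
#' @param problem a [FluxProblem-class].
#' @param r reaction index or id.
#' @param regime `"ORIGINAL"`, `"BOUNDARY_RELAXED"` or `"ALL_RELAXED"`.
#' @return numeric `c(min, max)`.
#' @export
fluxRange <- function(problem, r, regime = "ORIGINAL") {
  stopifnot(is(problem, "FluxProblem"))
  if (is.character(r)) r <- match(r, problem@rxnIds)
  stopifnot(!is.na(r), r >= 1, r <= ncol(problem@S))
  bd <- .regimeBounds(problem, regime)
  obj <- numeric(ncol(problem@S)); obj[r] <- 1
  mx <- solveFluxLP(obj, problem@S, bd$lb, bd$ub, maximize = TRUE)$value
  mn <- solveFluxLP(obj, problem@S, bd$lb, bd$ub, maximize = FALSE)$value
  c(min = mn, max = mx)
}

.carries <- function(problem, r, regime) {
  bd <- .regimeBounds(problem, regime)
  obj <- numeric(ncol(problem@S)); obj[r] <- 1
  mx <- solveFluxLP(obj, problem@S, bd$lb, bd$ub, maximize = TRUE)$value
  if (mx > problem@tol) return(TRUE)
  mn <- solveFluxLP(obj, problem@S, bd$lb, bd$ub, maximize = FALSE)$value
  mn < -problem@tol
}

#' Classify the flux status of one reaction
#'
#' Regimes are evaluated lazily in order (original bounds, boundary
#' reactions relaxed, all relaxed); the first regime in which the
#' reaction can carry flux determines the status (`A`, `a`, `b`), and a
#' reaction blocked in all three is `B`.
#'
#' @param problem a [FluxProblem-class].
#' @param r reaction index or id.
#' @return character scalar, one of `"A"`, `"a"`, `"b"`, `"B"`.
#' @export
classifyStatus <- function(problem, r) {
  stopifnot(is(problem, "FluxProblem"))
  if (is.character(r)) r <- match(r, problem@rxnIds)
  stopifnot(!is.na(r), r >= 1, r <= ncol(problem@S))
  if (.carries(problem, r, "ORIGINAL")) return("A")
  if (.carries(problem, r, "BOUNDARY_RELAXED")) return("a")
  if (.carries(problem, r, "ALL_RELAXED")) return("b")
  "B"
}

#' Status profile of a whole model
#'
#' @param problem a [FluxProblem-class].
#' @return a [StatusProfile-class] object.
#' @export
statusProfile <- function(problem) {
  stopifnot(is(problem, "FluxProblem"))
  n <- ncol(problem@S)
  status <- vapply(seq_len(n), function(r) classifyStatus(problem, r),
                   character(1))
  counts <- vapply(c("A", "a", "b", "B"), function(s) sum(status == s),
                   integer(1))
  new("StatusProfile",
      status = data.frame(reaction = problem@rxnIds, status = status,
                          stringsAsFactors = FALSE),
      counts = counts)
}

#' Compare status profiles before and after mapping
#'
#' @param before,after [StatusProfile-class] objects.
#' @param reactionMap named character vector: reaction id in `before` to
#'   reaction id in `after` (the one-to-one mapped reactions).
#' @return list with `pairs` (per-reaction before/after statuses),
#'   `changed` (the subset that changed) and `conserved` (`TRUE` iff no
#'   change).
#' @export
conservationCheck <- function(before, after, reactionMap) {
  stopifnot(is(before, "StatusProfile"), is(after, "StatusProfile"))
  ib <- match(names(reactionMap), before@status$reaction)
  ia <- match(unname(reactionMap), after@status$reaction)
  if (anyNA(ib))
    stop("reaction(s) not in 'before' profile: ",
         paste(names(reactionMap)[is.na(ib)], collapse = ", "))
  if (anyNA(ia))
    stop("reaction(s) not in 'after' profile: ",
         paste(reactionMap[is.na(ia)], collapse = ", "))
  pairs <- data.frame(reaction = names(reactionMap),
                      mapped = unname(reactionMap),
                      before = before@status$status[ib],
                      after = after@status$status[ia],
                      stringsAsFactors = FALSE)
  changed <- pairs[pairs$before != pairs$after, , drop = FALSE]
  list(pairs = pairs, changed = changed, conserved = nrow(changed) == 0L)
}

## ---- exact oracles ---------------------------------------------------------

#' Exact nullspace flux test
#'
#' `TRUE` iff some steady-state vector has non-zero flux through reaction
#' `r`, decided exactly in rational arithmetic: appending the unit row
#' \eqn{e_r} to `S` raises the rank iff \eqn{e_r} is not orthogonal to
#' the nullspace of `S`.  This equals "can carry flux under ALL_RELAXED"
#' for any positive bound magnitude.
#'
#' @param S stoichiometric matrix (rational entries).
#' @param r reaction (column) index.
#' @return logical scalar.
#' @export
nullspaceFluxTest <- function(S, r) {
  S <- as.matrix(S)
  stopifnot(r >= 1, r <= ncol(S))
  er <- numeric(ncol(S)); er[r] <- 1
  .intRank(rbind(S, er)) > .intRank(S)
}

#' Exact flux range by vertex enumeration
#'
#' Enumerates the vertices of the bounded polytope
#' \eqn{\{v : S v = 0, lb \le v \le ub\}} in exact rational arithmetic
#' (every vertex fixes `ncol(S) - rank(S)` coordinates at a bound) and
#' reads off min/max of \eqn{v_r}.  Exponential in the number of
#' reactions; intended as an oracle for networks with at most ~8
#' reactions.
#'
#' @param S stoichiometric matrix with integer entries.
#' @param lb,ub integer bound vectors.
#' @param r reaction (column) index.
#' @return numeric `c(min, max)` (exact rational values as doubles).
#' @export
exactFluxRange <- function(S, lb, ub, r) {
  S <- .toIntegerMatrix(as.matrix(S))
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, r >= 1, r <= n)
  k <- .intRank(S)
  nfix <- n - k
  best <- c(min = 0, max = 0)        # v = 0 is always feasible here
  consider <- function(v) {
    if (v[r] < best["min"]) best["min"] <<- v[r]
    if (v[r] > best["max"]) best["max"] <<- v[r]
  }
  if (nfix == 0L) {
    ## unique solution v = 0
    return(best)
  }
  fixSets <- utils::combn(n, nfix, simplify = FALSE)
  for (F in fixSets) {
    free <- setdiff(seq_len(n), F)
    Sf <- S[, free, drop = FALSE]
    if (.intRank(Sf) < length(free)) next
    ## pick independent rows of Sf
    rows <- integer(0)
    for (i in seq_len(nrow(Sf))) {
      if (.intRank(Sf[c(rows, i), , drop = FALSE]) > length(rows))
        rows <- c(rows, i)
      if (length(rows) == length(free)) break
    }
    Ssq <- Sf[rows, , drop = FALSE]
    bndChoices <- expand.grid(rep(list(c(1L, 2L)), nfix))
    for (ch in seq_len(nrow(bndChoices))) {
      fixVal <- ifelse(unlist(bndChoices[ch, ]) == 1L, lb[F], ub[F])
      rhs <- -S[rows, F, drop = FALSE] %*% fixVal
      sol <- .ratSolve(Ssq, as.vector(rhs))
      if (is.null(sol)) next
      v <- numeric(n)
      v[F] <- fixVal
      v[free] <- sol$num / sol$den
      ## verify all constraints (including dependent rows) exactly
      if (any(abs(S %*% v) > 1e-9)) next
      if (any(v < lb - 1e-9) || any(v > ub + 1e-9)) next
      consider(v)
    }
  }
  best
}

#' Exact status classification via vertex enumeration
#'
#' Oracle counterpart of [classifyStatus()]: uses [exactFluxRange()] per
#' regime (exact rational arithmetic, no LP, no tolerance).
#'
#' @param problem a [FluxProblem-class] with integer stoichiometry and
#'   bounds.
#' @param r reaction index.
#' @return character scalar status.
#' @export
exactClassifyStatus <- function(problem, r) {
  stopifnot(is(problem, "FluxProblem"))
  for (regime in .REGIMES) {
    bd <- .regimeBounds(problem, regime)
    if (regime == "ALL_RELAXED") {
      ## symmetric full box: rank test is exact and much faster
      if (nullspaceFluxTest(problem@S, r))
        return(switch(regime, ORIGINAL = "A", BOUNDARY_RELAXED = "a", "b"))
      return("B")
    }
    rg <- exactFluxRange(problem@S, bd$lb, bd$ub, r)
    if (rg["max"] > 0 || rg["min"] < 0)
      return(switch(regime, ORIGINAL = "A", BOUNDARY_RELAXED = "a", "b"))
  }
  "B"
}
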