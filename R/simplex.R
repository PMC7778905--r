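## A small dense bounded-variable primal simplex.
##
## Solves   max c'x   subject to  A x = 0,  0 <= x <= cap
## starting from x = 0 with an artificial identity basis fixed at zero.
## Bland's rule is used for both the entering and the leaving choice, so
## the method terminates despite the heavy degeneracy of steady-state
## flux polytopes.  Problems here are tiny (tens of columns), so a dense
## implementation with per-iteration solves is robust and fast enough.

.simplexCore <- function(cvec, A, cap, tol = 1e-9, maxit = 50000L) {
  m <- nrow(A); n <- ncol(A)
  A <- cbind(A, diag(1, m))          # artificials, capped at zero
  cvec <- c(cvec, rep(0, m))
  cap <- c(cap, rep(0, m))
  N <- n + m
  basis <- (n + 1L):N
  atUpper <- rep(FALSE, N)
  xval <- rep(0, N)
  for (it in seq_len(maxit)) {
    B <- A[, basis, drop = FALSE]
    y <- solve(t(B), cvec[basis])
    inBasis <- rep(FALSE, N); inBasis[basis] <- TRUE
    d <- cvec - as.vector(y %*% A)
    elig <- which(!inBasis & ((!atUpper & d > tol) | (atUpper & d < -tol)))
    if (length(elig) == 0L)
      return(list(status = "optimal", value = sum(cvec * xval),
                  x = xval[seq_len(n)]))
    q <- min(elig)                   # Bland: entering variable
    delta <- if (atUpper[q]) -1 else 1
    w <- solve(B, A[, q])
    chg <- delta * w                 # basic values move by -t * chg
    xB <- xval[basis]
    ## step limits: entering bound span, basic lower bounds, basic caps
    lim <- rep(Inf, m)
    dec <- chg > tol                 # basic decreases toward 0
    inc <- chg < -tol                # basic increases toward its cap
    lim[dec] <- xB[dec] / chg[dec]
    lim[inc] <- (cap[basis[inc]] - xB[inc]) / (-chg[inc])
    tmax <- min(cap[q], lim)
    tmax <- max(tmax, 0)
    blocking <- which(lim <= tmax + tol)
    xval[basis] <- pmax(xB - tmax * chg, 0)
    xval[q] <- if (atUpper[q]) cap[q] - tmax else tmax
    if (length(blocking) == 0L || cap[q] < min(lim[blocking]) - tol) {
      ## entering variable runs to its other bound; basis unchanged
      atUpper[q] <- !atUpper[q]
      xval[q] <- if (atUpper[q]) cap[q] else 0
    } else {
      leave <- blocking[which.min(basis[blocking])]   # Bland: leaving
      lv <- basis[leave]
      hitUpper <- chg[leave] < 0
      xval[lv] <- if (hitUpper) cap[lv] else 0
      atUpper[lv] <- hitUpper
      basis[leave] <- q
    }
  }
  stop("simplex iteration limit reached (", maxit, ")")
}

#' Solve a small flux LP
#'
#' Maximizes (or minimizes) a linear objective over the steady-state flux
#' polytope \eqn{\{v : A v = 0, lb \le v \le ub\}}.  Bounds must be finite
#' and contain zero (flux problems guarantee this after bound clamping).
#'
#' @param obj numeric objective vector.
#' @param A numeric constraint matrix (metabolites x reactions).
#' @param lb,ub numeric bound vectors.
#' @param maximize logical; minimize when `FALSE`.
#' @return list with `value` (optimal objective) and `x` (an optimal flux
#'   vector).
#' @examples
#' A <- matrix(c(1, -1), 1)           # v1 = v2
#' solveFluxLP(c(1, 0), A, c(0, 0), c(10, 10))$value
#' @export
solveFluxLP <- function(obj, A, lb, ub, maximize = TRUE) {
  stopifnot(length(obj) == ncol(A), length(lb) == ncol(A),
            length(ub) == ncol(A), all(is.finite(lb)), all(is.finite(ub)))
  if (any(lb > 1e-12) || any(ub < -1e-12))
    stop("bounds must contain zero; clamp them first")
  cc <- if (maximize) obj else -obj
  n <- length(obj)
  if (nrow(A) == 0L) {            # no mass-balance rows: box optimum
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, 0))
    val <- sum(cc * x)
    return(list(value = if (maximize) val else -val, x = x))
  }
  ## split each variable with lb < 0 into forward and backward parts
  hasBack <- lb < 0
  Ae <- cbind(A, -A[, hasBack, drop = FALSE])
  cs <- c(cc, -cc[hasBack])
  cap <- c(pmax(ub, 0), -lb[hasBack])
  res <- .simplexCore(cs, Ae, cap)
  x <- res$x[seq_len(n)]
  x[hasBack] <- x[hasBack] - res$x[(n + 1L):length(res$x)][seq_len(sum(hasBack))]
  val <- sum(cc * x)
  list(value = if (maximize) val else -val, x = x)
}
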