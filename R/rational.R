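## Exact rational arithmetic on (numerator, denominator) pairs stored as
## doubles.  All inputs this package feeds through here are small integers
## (stoichiometric coefficients, flux bounds), so every intermediate stays
## far below 2^53 and the arithmetic is exact.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.gcdAll <- function(v) {
  v <- v[v != 0]
  if (length(v) == 0L) return(1)
  Reduce(.gcd2, abs(v))
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / .gcd2(a, b) * b)
}

.lcmAll <- function(v) {
  if (length(v) == 0L) return(1)
  Reduce(.lcm2, abs(v))
}

## Normalize num/den vectors: den > 0, gcd(|num|, den) == 1.
.ratNorm <- function(num, den) {
  stopifnot(all(den != 0))
  s <- sign(den)
  num <- num * s; den <- den * s
  g <- mapply(.gcd2, abs(num), den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

.ratAdd <- function(n1, d1, n2, d2) .ratNorm(n1 * d2 + n2 * d1, d1 * d2)
.ratSub <- function(n1, d1, n2, d2) .ratNorm(n1 * d2 - n2 * d1, d1 * d2)
.ratMul <- function(n1, d1, n2, d2) .ratNorm(n1 * n2, d1 * d2)

## sign of a/b - c/d
.ratCmp <- function(n1, d1, n2, d2) sign(n1 * d2 - n2 * d1)

## Parse a coefficient token ("2", "0.5", "3/2") into an exact rational.
.parseCoeff <- function(txt) {
  txt <- trimws(txt)
  if (grepl("^[0-9]+/[0-9]+$", txt)) {
    p <- as.numeric(strsplit(txt, "/", fixed = TRUE)[[1]])
    if (p[2] == 0) stop("zero denominator in coefficient: ", txt)
    return(.ratNorm(p[1], p[2]))
  }
  if (grepl("^[0-9]+$", txt)) return(list(num = as.numeric(txt), den = 1))
  if (grepl("^[0-9]*\\.[0-9]+$", txt)) {
    parts <- strsplit(txt, ".", fixed = TRUE)[[1]]
    frac <- parts[2]
    den <- 10^nchar(frac)
    num <- as.numeric(paste0(ifelse(parts[1] == "", "0", parts[1]), frac))
    return(.ratNorm(num, den))
  }
  stop("cannot parse stoichiometric coefficient: '", txt, "'")
}

.formatCoeff <- function(num, den) {
  ifelse(den == 1, format(num, scientific = FALSE, trim = TRUE),
         paste0(format(num, scientific = FALSE, trim = TRUE), "/",
                format(den, scientific = FALSE, trim = TRUE)))
}

## ---- exact integer linear algebra -----------------------------------------

## Scale a rational matrix (given as numerator and denominator matrices, or a
## plain numeric matrix assumed integral) to an all-integer matrix row-wise.
.toIntegerMatrix <- function(M) {
  if (all(M == round(M))) return(M)
  ## fall back: per-row scaling by denominators recovered from finite decimals
  t(apply(M, 1L, function(row) {
    dens <- vapply(row, function(x) {
      d <- 1
      while (abs(x * d - round(x * d)) > 1e-9 && d < 1e6) d <- d * 10
      d
    }, numeric(1))
    row * .lcmAll(dens)
  }))
}

#' Exact rank of an integer matrix
#'
#' Fraction-free (Bareiss) Gaussian elimination with exact integer
#' arithmetic; used as the exact backend for nullspace flux tests.
#'
#' @param M numeric matrix with integer (or exactly representable rational)
#'   entries.
#' @return integer rank.
#' @keywords internal
.intRank <- function(M) {
  M <- .toIntegerMatrix(M)
  m <- nrow(M); n <- ncol(M)
  if (m == 0L || n == 0L) return(0L)
  prev <- 1
  r <- 0L
  row <- 1L
  for (col in seq_len(n)) {
    piv <- which(M[row:m, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    if (row < m) {
      for (i in (row + 1L):m) {
        M[i, ] <- (M[i, ] * M[row, col] - M[row, ] * M[i, col]) / prev
      }
    }
    prev <- M[row, col]
    r <- r + 1L
    row <- row + 1L
    if (row > m) break
  }
  r
}

## Exact solve of A x = b over the rationals for square nonsingular integer A
## via fraction-free elimination with full verification; returns list(num,
## den) vectors or NULL if singular.
.ratSolve <- function(A, b) {
  n <- nrow(A)
  ## augmented rational elimination with num/den bookkeeping
  Nm <- cbind(A, b)      # numerators
  Dm <- matrix(1, n, n + 1L)
  for (k in seq_len(n)) {
    piv <- which(Nm[k:n, k] != 0)
    if (length(piv) == 0L) return(NULL)
    piv <- piv[1] + k - 1L
    if (piv != k) { Nm[c(piv, k), ] <- Nm[c(k, piv), ]; Dm[c(piv, k), ] <- Dm[c(k, piv), ] }
    for (i in seq_len(n)[-k]) {
      if (Nm[i, k] == 0) next
      ## factor f = (Nm[i,k]/Dm[i,k]) / (Nm[k,k]/Dm[k,k])
      fn <- Nm[i, k] * Dm[k, k]
      fd <- Dm[i, k] * Nm[k, k]
      for (j in k:(n + 1L)) {
        ## Nm[i,j]/Dm[i,j] - f * Nm[k,j]/Dm[k,j]
        r <- .ratSub(Nm[i, j], Dm[i, j], fn * Nm[k, j], fd * Dm[k, j])
        Nm[i, j] <- r$num; Dm[i, j] <- r$den
      }
    }
  }
  num <- den <- numeric(n)
  for (i in seq_len(n)) {
    r <- .ratNorm(Nm[i, n + 1L] * Dm[i, i], Dm[i, n + 1L] * Nm[i, i])
    num[i] <- r$num; den[i] <- r$den
  }
  list(num = num, den = den)
}
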