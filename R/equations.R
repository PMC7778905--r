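## Reaction equation grammar and term algebra.
##
## Text form: "2 A + B = C", with "=" (bidirectional), "-->" (left to
## right) or "<--" (right to left) as the arrow; each term is
## [coefficient] metabolite[@compartment], coefficients are positive
## rationals ("2", "0.5", "3/2") and default to 1.  In memory an equation
## is a pair of term tables with exact rational coefficients; side
## membership is carried by the table, never by sign.

.emptyTerms <- function() {
  data.frame(met = character(0), num = numeric(0), den = numeric(0),
             comp = character(0), stringsAsFactors = FALSE)
}

.parseSide <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(.emptyTerms())
  toks <- strsplit(txt, " + ", fixed = TRUE)[[1]]
  rows <- lapply(toks, function(tk) {
    tk <- trimws(tk)
    m <- regmatches(tk, regexec("^(?:([0-9][0-9./]*)\\s+)?(\\S+?)(?:@(\\S+))?$", tk,
                                perl = TRUE))[[1]]
    if (length(m) == 0L || !nzchar(m[3]))
      stop("cannot parse equation term: '", tk, "'")
    co <- if (nzchar(m[2])) .parseCoeff(m[2]) else list(num = 1, den = 1)
    if (co$num <= 0) stop("non-positive coefficient in term: '", tk, "'")
    data.frame(met = m[3], num = co$num, den = co$den,
               comp = if (nzchar(m[4])) m[4] else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parse a reaction equation
#'
#' @param text equation text, e.g. `"2 A + B = C"`,
#'   `"glc@c + atp@c --> g6p@c + adp@c"`.
#' @return an object of class `Equation`: list with term tables `left`,
#'   `right` (columns `met`, `num`, `den`, `comp`) and `direction`
#'   (`"LR"`, `"RL"` or `"BIDIRECTIONAL"`).
#' @examples
#' eq <- parseEquation("2 A + B = C")
#' eq$left$num
#' @export
parseEquation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  arrow <- NULL; direction <- NULL
  for (cand in list(c(" --> ", "LR"), c(" <-- ", "RL"), c(" = ", "BIDIRECTIONAL"))) {
    if (grepl(cand[1], text, fixed = TRUE)) { arrow <- cand[1]; direction <- cand[2]; break }
  }
  ## tolerate arrows flush against an empty side, e.g. " = B" written "= B"
  if (is.null(arrow)) {
    for (cand in list(c("-->", "LR"), c("<--", "RL"), c("=", "BIDIRECTIONAL"))) {
      if (grepl(cand[1], text, fixed = TRUE)) { arrow <- cand[1]; direction <- cand[2]; break }
    }
  }
  if (is.null(arrow)) stop("no reaction arrow ('=', '-->', '<--') in: '", text, "'")
  pos <- regexpr(arrow, text, fixed = TRUE)
  eq <- list(left = .parseSide(substring(text, 1L, pos - 1L)),
             right = .parseSide(substring(text, pos + attr(pos, "match.length"))),
             direction = direction)
  class(eq) <- "Equation"
  eq
}

.newEquation <- function(left, right, direction = "BIDIRECTIONAL") {
  eq <- list(left = if (is.null(left)) .emptyTerms() else left,
             right = if (is.null(right)) .emptyTerms() else right,
             direction = direction)
  class(eq) <- "Equation"
  eq
}

.formatSide <- function(terms) {
  if (nrow(terms) == 0L) return("")
  paste(ifelse(terms$num == 1 & terms$den == 1,
               paste0(terms$met, ifelse(nzchar(terms$comp),
                                        paste0("@", terms$comp), "")),
               paste0(.formatCoeff(terms$num, terms$den), " ", terms$met,
                      ifelse(nzchar(terms$comp), paste0("@", terms$comp), ""))),
        collapse = " + ")
}

#' Format an equation back to text
#'
#' @param eq an `Equation`.
#' @return character scalar in the shared equation grammar.
#' @export
formatEquation <- function(eq) {
  stopifnot(inherits(eq, "Equation"))
  arrow <- switch(eq$direction, LR = "-->", RL = "<--", BIDIRECTIONAL = "=")
  paste(.formatSide(eq$left), arrow, .formatSide(eq$right))
}

## Combine duplicate (met, comp) terms within one side, summing rational
## coefficients; drop zero terms.  Deterministic order: (met, comp).
.combineSide <- function(terms) {
  if (nrow(terms) == 0L) return(terms)
  key <- paste0(terms$met, "\r", terms$comp)
  out <- lapply(split(seq_len(nrow(terms)), key), function(idx) {
    num <- 0; den <- 1
    for (i in idx) {
      r <- .ratAdd(num, den, terms$num[i], terms$den[i])
      num <- r$num; den <- r$den
    }
    data.frame(met = terms$met[idx[1]], num = num, den = den,
               comp = terms$comp[idx[1]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$num != 0, , drop = FALSE]
  out <- out[order(out$met, out$comp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Cancel the common part of any (met, comp) present on both sides:
## min(coeff) is removed from each side.
.cancelSides <- function(left, right) {
  if (nrow(left) && nrow(right)) {
    lk <- paste0(left$met, "\r", left$comp)
    rk <- paste0(right$met, "\r", right$comp)
    common <- intersect(lk, rk)
    for (k in common) {
      i <- match(k, lk); j <- match(k, rk)
      cmp <- .ratCmp(left$num[i], left$den[i], right$num[j], right$den[j])
      if (cmp <= 0) {          # left coefficient is the minimum
        r <- .ratSub(right$num[j], right$den[j], left$num[i], left$den[i])
        right$num[j] <- r$num; right$den[j] <- r$den
        left$num[i] <- 0
      } else {
        r <- .ratSub(left$num[i], left$den[i], right$num[j], right$den[j])
        left$num[i] <- r$num; left$den[i] <- r$den
        right$num[j] <- 0
      }
    }
    left <- left[left$num != 0, , drop = FALSE]
    right <- right[right$num != 0, , drop = FALSE]
    rownames(left) <- rownames(right) <- NULL
  }
  list(left = left, right = right)
}

#' Is an equation empty?
#'
#' An equation is empty when both sides cancel entirely after metabolite
#' merging; empty reactions disappear from mapped models.
#'
#' @param eq an `Equation`.
#' @return logical scalar.
#' @export
isEmptyEquation <- function(eq) nrow(eq$left) == 0L && nrow(eq$right) == 0L

#' Normalize a name for symbol matching
#'
#' Case-folds and collapses all runs of non-alphanumeric characters
#' (whitespace, hyphens, punctuation) to single spaces.  Exact match after
#' this normalization is the only name evidence ever used; no fuzzy or
#' synonym matching.
#'
#' @param x character vector.
#' @return character vector of normalized names.
#' @examples
#' normalizeName(c("L-Alanine", "l alanine"))
#' @export
normalizeName <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}
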