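## Rewriting reactions in the unified namespace: substitution, like-term
## combination, cross-side cancellation, proton balancing, transported
## proton labelling, canonical keys and reaction deduplication.

#' Rewrite an equation under a metabolite mapping
#'
#' Substitutes namespace ids, combines like terms within a side (summing
#' coefficients), cancels the common `min(coeff)` of any (metabolite,
#' compartment) present on both sides and drops zero terms.  The result
#' may be empty: acid/base or tautomer merges can cancel a reaction
#' entirely, and such reactions disappear from mapped models.
#'
#' @param eq an `Equation`.
#' @param mapping named character vector (term metabolite id to namespace
#'   id).  Ids absent from the mapping raise an error unless
#'   `partial = TRUE`, in which case they are kept verbatim.
#' @param partial keep unmapped ids instead of erroring.
#' @return the rewritten `Equation`.
#' @export
rewriteEquation <- function(eq, mapping, partial = FALSE) {
  stopifnot(inherits(eq, "Equation"))
  subst <- function(terms) {
    if (nrow(terms) == 0L) return(terms)
    hit <- terms$met %in% names(mapping)
    if (!partial && !all(hit))
      stop("unmapped metabolite(s): ",
           paste(unique(terms$met[!hit]), collapse = ", "))
    terms$met[hit] <- unname(mapping[terms$met[hit]])
    terms
  }
  left <- .combineSide(subst(eq$left))
  right <- .combineSide(subst(eq$right))
  cs <- .cancelSides(left, right)
  .newEquation(cs$left, cs$right, eq$direction)
}

## ---- chemical formulas -----------------------------------------------------

#' Parse a Hill formula into element counts
#'
#' Supports multi-component formulas (`.`-separated, with optional
#' leading component multipliers).
#'
#' @param formula character scalar, e.g. `"C6H12O6"`, `"2C2H4O2.Ca"`.
#' @return named numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  counts <- numeric(0)
  for (comp in strsplit(formula, ".", fixed = TRUE)[[1]]) {
    mult <- 1
    mm <- regmatches(comp, regexec("^([0-9]+)(.*)$", comp))[[1]]
    if (length(mm) && nzchar(mm[2])) { mult <- as.numeric(mm[2]); comp <- mm[3] }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", comp)[[1]]
    toks <- regmatches(comp, gregexpr("([A-Z][a-z]?)([0-9]*)", comp))[[1]]
    if (paste(toks, collapse = "") != comp)
      stop("unparseable formula: '", formula, "'")
    for (tk in toks) {
      el <- sub("[0-9]*$", "", tk)
      n <- sub("^[A-Za-z]+", "", tk)
      n <- if (nzchar(n)) as.numeric(n) else 1
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + mult * n
    }
  }
  counts
}

#' Check the elemental and charge balance of an equation
#'
#' Computes coefficient-weighted element and charge deltas (right minus
#' left).  Verdicts: `BALANCED` (all deltas zero), `PROTON_ONLY` (the
#' only imbalance is n hydrogens together with a charge delta of n, i.e.
#' fixable by adding protons), `UNBALANCED`, or `UNKNOWN` when any
#' participant lacks a formula or charge.
#'
#' @param eq an `Equation`.
#' @param props data.frame with columns `met`, `formula`, `charge` (or a
#'   named list of `list(formula=, charge=)`).
#' @return an object of class `BalanceReport`: list with `element_delta`
#'   (named numeric, right minus left), `charge_delta`, `verdict`.
#' @export
balanceCheck <- function(eq, props) {
  stopifnot(inherits(eq, "Equation"))
  if (is.data.frame(props)) {
    look <- function(met) {
      i <- match(met, props$met)
      if (is.na(i)) return(NULL)
      list(formula = props$formula[i], charge = props$charge[i])
    }
  } else look <- function(met) props[[met]]
  delta <- numeric(0); chargeDelta <- 0; unknown <- FALSE
  addSide <- function(terms, sgn) {
    for (i in seq_len(nrow(terms))) {
      p <- look(terms$met[i])
      coeff <- terms$num[i] / terms$den[i]
      if (is.null(p) || is.na(p$formula) || !nzchar(p$formula) || is.na(p$charge)) {
        unknown <<- TRUE
        next
      }
      cnt <- parseFormula(p$formula)
      for (el in names(cnt))
        delta[el] <<- (if (el %in% names(delta)) delta[[el]] else 0) +
          sgn * coeff * cnt[[el]]
      chargeDelta <<- chargeDelta + sgn * coeff * p$charge
    }
  }
  addSide(eq$left, -1)
  addSide(eq$right, +1)
  delta <- delta[abs(delta) > 1e-12]
  verdict <- if (unknown) "UNKNOWN"
    else if (length(delta) == 0L && abs(chargeDelta) < 1e-12) "BALANCED"
    else if (length(delta) == 1L && names(delta) == "H" &&
             abs(chargeDelta - delta[["H"]]) < 1e-12) "PROTON_ONLY"
    else "UNBALANCED"
  out <- list(element_delta = delta, charge_delta = chargeDelta,
              verdict = verdict)
  class(out) <- "BalanceReport"
  out
}

#' Balance a proton-only imbalance by adding MNXM1
#'
#' Adds `|n|` balancing protons (`MNXM1`) to the deficient side, in the
#' compartment used by the majority of terms.  Only `PROTON_ONLY` reports
#' are accepted: a non-proton imbalance is never silently "fixed".
#'
#' @param eq an `Equation`.
#' @param report the [balanceCheck()] report for `eq`.
#' @param proton namespace id of the balancing proton.
#' @return the balanced `Equation`.
#' @export
protonBalance <- function(eq, report, proton = "MNXM1") {
  stopifnot(inherits(eq, "Equation"), inherits(report, "BalanceReport"))
  if (report$verdict != "PROTON_ONLY")
    stop("protonBalance requires a PROTON_ONLY report, got ", report$verdict)
  n <- report$element_delta[["H"]]
  comps <- c(eq$left$comp, eq$right$comp)
  comp <- if (length(comps)) {
    tb <- sort(table(comps), decreasing = TRUE)
    names(tb)[tb == max(tb)][1]
  } else ""
  term <- data.frame(met = proton, num = abs(n), den = 1, comp = comp,
                     stringsAsFactors = FALSE)
  if (n > 0) {                      # right has excess H: left is deficient
    left <- .combineSide(rbind(eq$left, term)); right <- eq$right
  } else {
    left <- eq$left; right <- .combineSide(rbind(eq$right, term))
  }
  .newEquation(left, right, eq$direction)
}

#' Distinguish transported from balancing protons
#'
#' Protons crossing compartments account for the proton motive force and
#' get their own identifier: for each pair of distinct compartments with
#' protons on opposite sides, `k = min(left coefficient, right
#' coefficient)` protons are relabelled `MNXM01` on both sides; the
#' remainder stay `MNXM1`.
#'
#' @param eq an `Equation` with compartment labels.
#' @param proton,transported the two proton identifiers.
#' @return the relabelled `Equation`.
#' @export
classifyTransportedProtons <- function(eq, proton = "MNXM1",
                                       transported = "MNXM01") {
  stopifnot(inherits(eq, "Equation"))
  left <- eq$left; right <- eq$right
  li <- which(left$met == proton); ri <- which(right$met == proton)
  for (i in li) {
    for (j in ri) {
      if (left$comp[i] == right$comp[j]) next
      if (left$num[i] == 0 || right$num[j] == 0) next
      k <- if (.ratCmp(left$num[i], left$den[i], right$num[j], right$den[j]) <= 0)
        list(num = left$num[i], den = left$den[i])
      else list(num = right$num[j], den = right$den[j])
      ## remove k from each proton term, add k as transported
      rl <- .ratSub(left$num[i], left$den[i], k$num, k$den)
      rr <- .ratSub(right$num[j], right$den[j], k$num, k$den)
      left <- rbind(left, data.frame(met = transported, num = k$num, den = k$den,
                                     comp = left$comp[i], stringsAsFactors = FALSE))
      right <- rbind(right, data.frame(met = transported, num = k$num, den = k$den,
                                       comp = right$comp[j], stringsAsFactors = FALSE))
      left$num[i] <- rl$num; left$den[i] <- rl$den
      right$num[j] <- rr$num; right$den[j] <- rr$den
    }
  }
  .newEquation(.combineSide(left[left$num != 0, , drop = FALSE]),
               .combineSide(right[right$num != 0, , drop = FALSE]),
               eq$direction)
}

## ---- canonical keys --------------------------------------------------------

## Scale all coefficients to the smallest coprime integers: multiply by
## the LCM of denominators, divide by the GCD of numerators.
.scaleCoeffs <- function(left, right) {
  dens <- c(left$den, right$den)
  nums <- c(left$num, right$num)
  if (length(nums) == 0L) return(list(left = left, right = right))
  L <- .lcmAll(dens)
  ints <- nums * (L / dens)
  g <- .gcdAll(ints)
  scale <- function(t) {
    if (nrow(t) == 0L) return(t)
    t$num <- t$num * (L / t$den) / g
    t$den <- rep(1, nrow(t))
    t
  }
  list(left = scale(left), right = scale(right))
}

#' Canonical key of an equation
#'
#' Terms are sorted by (metabolite, compartment) within sides,
#' coefficients scaled to the smallest coprime integers, and the
#' orientation chosen so the lexicographically smaller side string comes
#' first; the direction is not part of the key.  Two equations get equal
#' keys iff they are the same reaction up to direction and scaling.  The
#' empty equation has the reserved key `"EMPTY"`.
#'
#' @param eq an `Equation` rewritten in namespace ids.
#' @return list with `key` (single text line) and `flipped` (logical:
#'   whether the canonical orientation swaps the sides).
#' @export
canonicalKey <- function(eq) {
  stopifnot(inherits(eq, "Equation"))
  if (isEmptyEquation(eq)) return(list(key = "EMPTY", flipped = FALSE))
  left <- .combineSide(eq$left); right <- .combineSide(eq$right)
  sc <- .scaleCoeffs(left, right)
  ls <- .formatSide(sc$left); rs <- .formatSide(sc$right)
  flipped <- rs < ls
  key <- if (flipped) paste(rs, "=", ls) else paste(ls, "=", rs)
  list(key = key, flipped = flipped)
}

## effective direction of a member once its equation is expressed in the
## canonical orientation
.foldDirection <- function(direction, flipped) {
  if (!flipped || direction == "BIDIRECTIONAL") return(direction)
  if (direction == "LR") "RL" else "LR"
}

## ---- reaction namespace ----------------------------------------------------

#' Rhea-style source prefixes preferred as reaction references
#' @return character vector.
#' @export
rheaReactionPrefixes <- function() c("rheaR", "rhea")

#' Build the unified reaction namespace
#'
#' Rewrites every source reaction with the metabolite mapping, applies the
#' proton passes (balance protons added for `PROTON_ONLY` imbalances,
#' transported protons relabelled), computes canonical keys and groups
#' reactions by key.  One unified reaction is emitted per group;
#' references prefer a Rhea member, then the priority order; identifiers
#' `MNXR1`, `MNXR2`, ... are assigned deterministically in sorted
#' reference order.  The empty-key group is emitted with `empty = TRUE`
#' (such reactions are excluded from mapped models); members that
#' disagree on direction yield `BIDIRECTIONAL`.
#'
#' @param reactions source reaction table (`prefix`, `local_id`,
#'   `equation`, `direction`, `xrefs`).
#' @param mapping named character: `"prefix:id"` to namespace metabolite
#'   id (total on all referenced metabolites).
#' @param chemProps data.frame with `met`, `formula`, `charge` for the
#'   namespace metabolites (used for balance checks); may be `NULL`.
#' @param priority source priority order for reference selection.
#' @return list with `reac` (unified reaction table: `mnx_id`,
#'   `equation`, `direction`, `reference`, `empty`, `balance`, `members`)
#'   and `reacXref` (`source`, `mnx_id`).
#' @export
buildReactionNamespace <- function(reactions, mapping, chemProps = NULL,
                                   priority = defaultPriority()) {
  if (is.null(chemProps)) {
    chemProps <- data.frame(met = character(0), formula = character(0),
                            charge = numeric(0), stringsAsFactors = FALSE)
  }
  if (!"MNXM1" %in% chemProps$met)
    chemProps <- rbind(chemProps,
                       data.frame(met = c("MNXM1", "MNXM01"), formula = "H",
                                  charge = 1, stringsAsFactors = FALSE))
  n <- nrow(reactions)
  keys <- character(n); dirs <- character(n); eqs <- vector("list", n)
  verdicts <- character(n)
  for (r in seq_len(n)) {
    eq <- parseEquation(reactions$equation[r])
    if (eq$direction == "BIDIRECTIONAL" && nzchar(reactions$direction[r]))
      eq$direction <- reactions$direction[r]
    ## source-local ids -> namespace ids
    pref <- reactions$prefix[r]
    local <- unique(c(eq$left$met, eq$right$met))
    mp <- mapping[paste0(pref, ":", local)]
    if (anyNA(mp))
      stop("unmapped metabolite(s) in ", pref, ":", reactions$local_id[r], ": ",
           paste(local[is.na(mp)], collapse = ", "))
    names(mp) <- local
    eq <- rewriteEquation(eq, mp)
    bal <- balanceCheck(eq, chemProps)
    if (bal$verdict == "PROTON_ONLY") {
      eq <- protonBalance(eq, bal)
      bal <- balanceCheck(eq, chemProps)
    }
    eq <- classifyTransportedProtons(eq)
    ck <- canonicalKey(eq)
    keys[r] <- ck$key
    dirs[r] <- .foldDirection(eq$direction, ck$flipped)
    eqs[[r]] <- eq
    verdicts[r] <- bal$verdict
  }
  sref <- paste0(reactions$prefix, ":", reactions$local_id)
  groups <- split(seq_len(n), keys)
  ## reference selection per group
  refOf <- vapply(groups, function(idx) {
    pfx <- reactions$prefix[idx]
    isRhea <- pfx %in% rheaReactionPrefixes()
    pr <- match(pfx, priority); pr[is.na(pr)] <- length(priority) + 1L
    ord <- order(!isRhea, pr, pfx, reactions$local_id[idx])
    sref[idx[ord[1]]]
  }, character(1))
  refPrefix <- sub(":.*$", "", refOf)
  refLocal <- sub("^[^:]*:", "", refOf)
  ord <- order(refPrefix, refLocal)
  rows <- list(); xr <- list()
  for (k in seq_along(ord)) {
    g <- ord[k]
    idx <- groups[[g]]
    mnx <- paste0("MNXR", k)
    memberDirs <- unique(dirs[idx])
    dir <- if (length(memberDirs) == 1L) memberDirs else "BIDIRECTIONAL"
    ## canonical equation: re-orient the first member's rewritten form
    ex <- eqs[[idx[1]]]
    ck <- canonicalKey(ex)
    if (ck$flipped) ex <- .newEquation(ex$right, ex$left, dir)
    sc <- .scaleCoeffs(.combineSide(ex$left), .combineSide(ex$right))
    ex <- .newEquation(sc$left, sc$right, dir)
    rows[[k]] <- data.frame(
      mnx_id = mnx, equation = formatEquation(ex), direction = dir,
      reference = refOf[g], empty = names(groups)[g] == "EMPTY",
      balance = verdicts[idx[1]],
      members = paste(sort(sref[idx]), collapse = ";"),
      stringsAsFactors = FALSE)
    xr[[k]] <- data.frame(source = sref[idx], mnx_id = mnx,
                          stringsAsFactors = FALSE)
  }
  reac <- do.call(rbind, rows)
  reacXref <- do.call(rbind, xr)
  if (is.null(reac)) {
    reac <- data.frame(mnx_id = character(0), equation = character(0),
                       direction = character(0), reference = character(0),
                       empty = logical(0), balance = character(0),
                       members = character(0), stringsAsFactors = FALSE)
    reacXref <- data.frame(source = character(0), mnx_id = character(0),
                           stringsAsFactors = FALSE)
  } else {
    reac <- reac[order(reac$mnx_id), , drop = FALSE]
    reacXref <- reacXref[order(reacXref$source), , drop = FALSE]
    rownames(reac) <- rownames(reacXref) <- NULL
  }
  list(reac = reac, reacXref = reacXref)
}
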