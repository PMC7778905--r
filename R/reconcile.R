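## Building the unified metabolite namespace.
##
## Three lines of evidence are applied successively, each run to a fixed
## point before the next starts:
##   1. identical normalized structures (protonation/charge/isotope
##      layers elided, stereo respected);
##   2. similar structures in reaction context (a fully specified
##      stereoisomer against an unspecified one, aligned as the single
##      unmatched pair of two cross-referenced reactions);
##   3. structure and symbol in reaction context (at least one member has
##      no structure, and the two share a normalized name).
## Imported metabolite-to-metabolite cross-references are never consulted;
## only reaction cross-references provide context.

## ---- union-find ------------------------------------------------------------

.pfFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

.pfRoots <- function(parent) {
  vapply(seq_along(parent), function(i) .pfFind(parent, i), integer(1))
}

## Union: the smaller root index becomes the representative, so results
## are independent of merge order.
.pfUnion <- function(parent, i, j) {
  ri <- .pfFind(parent, i); rj <- .pfFind(parent, j)
  if (ri == rj) return(list(parent = parent, merged = FALSE))
  if (ri < rj) parent[rj] <- ri else parent[ri] <- rj
  list(parent = parent, merged = TRUE)
}

## ---- metabolite table helpers ---------------------------------------------

.metRef <- function(metabolites) {
  if (nrow(metabolites) == 0L) return(character(0))
  paste0(metabolites$prefix, ":", metabolites$local_id)
}

.metKeys <- function(metabolites, policy) {
  keys <- vector("list", nrow(metabolites))
  has <- !is.na(metabolites$inchi) & nzchar(metabolites$inchi)
  for (i in which(has)) {
    keys[[i]] <- structureKey(parseInchi(metabolites$inchi[i]), policy)
  }
  keys
}

.metNames <- function(metabolites) {
  lapply(seq_len(nrow(metabolites)), function(i) {
    nm <- metabolites$name[i]
    extra <- if ("names" %in% names(metabolites) && !is.na(metabolites$names[i]))
      strsplit(metabolites$names[i], ";", fixed = TRUE)[[1]] else character(0)
    unique(normalizeName(c(nm, extra)))
  })
}

## side occurrence index: for each metabolite index, the reactions and
## sides it occurs in -- used for same-reaction-sides checks
.sideIndex <- function(metabolites, reactions) {
  ref2idx <- seq_len(nrow(metabolites))
  names(ref2idx) <- .metRef(metabolites)
  occ <- list()
  if (is.null(reactions) || nrow(reactions) == 0L) return(occ)
  for (r in seq_len(nrow(reactions))) {
    eq <- parseEquation(reactions$equation[r])
    rref <- paste0(reactions$prefix[r], ":", reactions$local_id[r])
    for (side in c("left", "right")) {
      for (met in eq[[side]]$met) {
        key <- paste0(reactions$prefix[r], ":", met)
        occ[[key]] <- rbind(occ[[key]],
                            data.frame(reaction = rref, side = side,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  occ
}

## would merging classes of i and j place two members of one class on
## opposite sides of some reaction?
.unionConflicts <- function(parent, ids, sideIdx, i, j) {
  members <- c(which(.pfRoots(parent) == .pfFind(parent, i)),
               which(.pfRoots(parent) == .pfFind(parent, j)))
  occ <- do.call(rbind, lapply(ids[members], function(ref) {
    o <- sideIdx[[ref]]
    if (is.null(o)) return(NULL)
    cbind(o, ref = ref)
  }))
  if (is.null(occ) || nrow(occ) < 2L) return(character(0))
  bad <- character(0)
  for (rx in unique(occ$reaction)) {
    sides <- unique(occ$side[occ$reaction == rx])
    if (length(sides) == 2L) bad <- c(bad, rx)
  }
  bad
}

## ---- evidence pass 1: identical structures --------------------------------

#' Merge metabolites with identical normalized structures
#'
#' Evidence pass 1: two metabolites share a merge set iff both carry an
#' InChI and their structure keys under `policy` are equal.  Metabolites
#' without a structure stay singletons here; names alone never merge in
#' this pass.
#'
#' @param metabolites data.frame with columns `prefix`, `local_id`,
#'   `name`, optional `names` (`;`-joined synonyms), `formula`, `charge`,
#'   `inchi`.
#' @param policy structure-key policy; the default (stereo-respecting)
#'   policy is required for the standard pipeline.
#' @param strict when `TRUE`, unions that would put two members of one
#'   set on opposite sides of a reaction are rejected (recorded as
#'   `REJECTED` conflicts) instead of merely flagged.
#' @param reactions source reaction table (needed only for `strict`).
#' @return a [MergePartition-class].
#' @export
mergeIdenticalStructures <- function(metabolites, policy = defaultKeyPolicy(),
                                     strict = FALSE, reactions = NULL) {
  ids <- .metRef(metabolites)
  if (anyDuplicated(ids))
    stop("duplicate (prefix, local_id): ", ids[anyDuplicated(ids)])
  pt <- newPartition(ids)
  keys <- .metKeys(metabolites, policy)
  has <- which(!vapply(keys, is.null, logical(1)))
  kstr <- vapply(keys[has], .keyString, character(1))
  parent <- pt@parent
  ev <- list()
  cf <- list()
  sideIdx <- if (strict) .sideIndex(metabolites, reactions) else NULL
  for (grp in split(has, kstr)) {
    if (length(grp) < 2L) next
    grp <- grp[order(ids[grp])]
    for (k in 2L:length(grp)) {
      i <- grp[1L]; j <- grp[k]
      if (strict) {
        bad <- .unionConflicts(parent, ids, sideIdx, i, j)
        if (length(bad)) {
          cf[[length(cf) + 1L]] <- data.frame(
            kind = "SAME_REACTION_SIDES",
            members = paste(sort(c(ids[i], ids[j])), collapse = ";"),
            reaction = bad[1], resolution = "REJECTED",
            stringsAsFactors = FALSE)
          next
        }
      }
      u <- .pfUnion(parent, i, j)
      parent <- u$parent
      if (u$merged)
        ev[[length(ev) + 1L]] <- data.frame(
          kind = "IDENTICAL_STRUCTURE", a = ids[i], b = ids[j],
          context1 = NA_character_, context2 = NA_character_,
          stringsAsFactors = FALSE)
    }
  }
  initialize(pt, parent = parent,
             evidence = if (length(ev)) do.call(rbind, ev) else .emptyEvidence(),
             conflicts = if (length(cf)) do.call(rbind, cf) else .emptyConflicts())
}

## ---- reaction context alignment -------------------------------------------

.termClassKey <- function(terms, prefix, parent, idIndex) {
  if (nrow(terms) == 0L) return(character(0))
  refs <- paste0(prefix, ":", terms$met)
  idx <- idIndex[refs]
  if (anyNA(idx)) stop("unresolvable metabolite reference: ",
                       paste(refs[is.na(idx)], collapse = ", "))
  roots <- vapply(idx, function(i) .pfFind(parent, i), integer(1))
  paste0(roots, "\r", terms$num, "/", terms$den, "\r", terms$comp)
}

## Align one side pair; returns NULL on failure, list(pairs=...) on
## success where pairs is a (possibly empty) data.frame of candidate refs.
.alignSides <- function(t1, t2, p1, p2, parent, idIndex, side) {
  k1 <- .termClassKey(t1, p1, parent, idIndex)
  k2 <- .termClassKey(t2, p2, parent, idIndex)
  ## multiset difference via table counts
  tab1 <- table(k1); tab2 <- table(k2)
  all <- union(names(tab1), names(tab2))
  c1 <- ifelse(all %in% names(tab1), as.integer(tab1[all]), 0L)
  c2 <- ifelse(all %in% names(tab2), as.integer(tab2[all]), 0L)
  extra1 <- sum(pmax(c1 - c2, 0L)); extra2 <- sum(pmax(c2 - c1, 0L))
  noPairs <- data.frame(a = character(0), b = character(0), side = character(0),
                        stringsAsFactors = FALSE)
  if (extra1 == 0L && extra2 == 0L) return(list(pairs = noPairs))
  if (extra1 != 1L || extra2 != 1L) return(NULL)
  key1 <- all[c1 - c2 == 1L]; key2 <- all[c2 - c1 == 1L]
  i1 <- which(k1 == key1)[1]; i2 <- which(k2 == key2)[1]
  ## equal stoichiometric coefficients and compartments are required
  if (.ratCmp(t1$num[i1], t1$den[i1], t2$num[i2], t2$den[i2]) != 0L)
    return(NULL)
  if (!identical(t1$comp[i1], t2$comp[i2])) return(NULL)
  list(pairs = data.frame(a = paste0(p1, ":", t1$met[i1]),
                          b = paste0(p2, ":", t2$met[i2]),
                          side = side, stringsAsFactors = FALSE))
}

#' Candidate metabolite pairs from two cross-referenced reactions
#'
#' Rewrites both equations with the current partition's class ids.  If
#' they become identical except for exactly one unmatched term on the
#' left and/or exactly one on the right (equal coefficients and
#' compartments), those term pairs are emitted as merge candidates;
#' otherwise nothing is emitted.  When either reaction is bidirectional
#' both relative orientations are tried and a unique consistent
#' orientation is required.
#'
#' @param r1,r2 one-row slices of a source reaction table (columns
#'   `prefix`, `local_id`, `equation`, `direction`).
#' @param partition the current [MergePartition-class].
#' @return data.frame with columns `a`, `b`, `side` (possibly 0 rows).
#' @export
contextCandidatePairs <- function(r1, r2, partition) {
  idIndex <- seq_along(partition@ids); names(idIndex) <- partition@ids
  parent <- partition@parent
  e1 <- parseEquation(r1$equation)
  e2 <- parseEquation(r2$equation)
  orientations <- if (e1$direction == "BIDIRECTIONAL" ||
                      e2$direction == "BIDIRECTIONAL") c("fwd", "rev")
    else if (e1$direction == e2$direction) "fwd" else "rev"
  found <- list()
  for (o in orientations) {
    L2 <- if (o == "fwd") e2$left else e2$right
    R2 <- if (o == "fwd") e2$right else e2$left
    al <- .alignSides(e1$left, L2, r1$prefix, r2$prefix, parent, idIndex, "left")
    if (is.null(al)) next
    ar <- .alignSides(e1$right, R2, r1$prefix, r2$prefix, parent, idIndex, "right")
    if (is.null(ar)) next
    found[[o]] <- rbind(al$pairs, ar$pairs)
  }
  none <- data.frame(a = character(0), b = character(0), side = character(0),
                     stringsAsFactors = FALSE)
  ## a unique consistent orientation is required; with two successes,
  ## accept only if both propose the same pairs (else ambiguous)
  if (length(found) == 0L) return(none)
  if (length(found) == 2L) {
    s1 <- found[[1]][order(found[[1]]$a, found[[1]]$b), , drop = FALSE]
    s2 <- found[[2]][order(found[[2]]$a, found[[2]]$b), , drop = FALSE]
    rownames(s1) <- rownames(s2) <- NULL
    if (identical(s1, s2)) return(found[[1]])
    return(none)
  }
  found[[1]]
}

## ---- evidence passes 2 and 3 ----------------------------------------------

.xrefPairs <- function(reactions) {
  if (is.null(reactions) || nrow(reactions) == 0L) return(NULL)
  rref <- paste0(reactions$prefix, ":", reactions$local_id)
  idx <- seq_len(nrow(reactions)); names(idx) <- rref
  pairs <- list()
  for (r in seq_len(nrow(reactions))) {
    xr <- reactions$xrefs[r]
    if (is.na(xr) || !nzchar(xr)) next
    for (tgt in strsplit(xr, ";", fixed = TRUE)[[1]]) {
      j <- idx[tgt]
      if (is.na(j)) next
      if (sub(":.*", "", tgt) == reactions$prefix[r])
        next      # xrefs never point into the same prefix
      pairs[[length(pairs) + 1L]] <- sort(c(r, unname(j)))
    }
  }
  if (!length(pairs)) return(NULL)
  unique(do.call(rbind, pairs))
}

.rejectedPairs <- function(conflicts) {
  if (nrow(conflicts) == 0L) return(character(0))
  conflicts$members[conflicts$resolution == "REJECTED"]
}

#' Apply reaction-context merges (evidence passes 2 and 3)
#'
#' Pass 2 merges a candidate pair iff [similarStructures()] returns
#' `STEREO_RELAXED` (identical structures were already merged in pass 1);
#' pass 3 merges a pair iff at least one member lacks a structure and the
#' two share a normalized name.  Each pass runs to a fixed point (new
#' merges can create new candidates); pass 2 completes before pass 3
#' starts.  Pairs flagged as `REJECTED` conflicts are skipped and logged.
#'
#' @param partition [MergePartition-class] from pass 1.
#' @param metabolites source metabolite table.
#' @param reactions source reaction table with `xrefs` column
#'   (`;`-joined `"prefix:id"` refs into other sources).
#' @param policy structure-key policy (default policy required).
#' @param strict reject unions creating same-reaction-sides conflicts.
#' @return the grown [MergePartition-class].
#' @export
applyContextMerges <- function(partition, metabolites, reactions,
                               policy = defaultKeyPolicy(), strict = FALSE) {
  ids <- .metRef(metabolites)
  stopifnot(identical(ids, partition@ids))
  keys <- .metKeys(metabolites, policy)
  nameSets <- .metNames(metabolites)
  idIndex <- seq_along(ids); names(idIndex) <- ids
  xp <- .xrefPairs(reactions)
  if (is.null(xp)) return(partition)
  sideIdx <- if (strict) .sideIndex(metabolites, reactions) else NULL
  parent <- partition@parent
  ev <- list(); cf <- list()
  rejected <- .rejectedPairs(partition@conflicts)
  seenConf <- character(0)

  tryUnion <- function(ia, ib, kind, ctx1, ctx2) {
    pairKey <- paste(sort(c(ids[ia], ids[ib])), collapse = ";")
    if (pairKey %in% rejected) {
      .log("INFO", "skipping merge of rejected pair ", pairKey)
      return(FALSE)
    }
    if (strict) {
      bad <- .unionConflicts(parent, ids, sideIdx, ia, ib)
      if (length(bad)) {
        cf[[length(cf) + 1L]] <<- data.frame(
          kind = "SAME_REACTION_SIDES", members = pairKey,
          reaction = bad[1], resolution = "REJECTED", stringsAsFactors = FALSE)
        rejected <<- c(rejected, pairKey)
        return(FALSE)
      }
    }
    u <- .pfUnion(parent, ia, ib)
    if (!u$merged) return(FALSE)
    parent <<- u$parent
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, a = ids[ia], b = ids[ib],
      context1 = ctx1, context2 = ctx2, stringsAsFactors = FALSE)
    TRUE
  }

  runPass <- function(pass) {
    repeat {
      changed <- FALSE
      for (p in seq_len(nrow(xp))) {
        r1 <- reactions[xp[p, 1], , drop = FALSE]
        r2 <- reactions[xp[p, 2], , drop = FALSE]
        pt <- initialize(partition, parent = parent)
        cands <- tryCatch(contextCandidatePairs(r1, r2, pt),
                          error = function(e) NULL)
        if (is.null(cands) || nrow(cands) == 0L) next
        ctx1 <- paste0(r1$prefix, ":", r1$local_id)
        ctx2 <- paste0(r2$prefix, ":", r2$local_id)
        for (k in seq_len(nrow(cands))) {
          ia <- idIndex[[cands$a[k]]]; ib <- idIndex[[cands$b[k]]]
          ka <- keys[[ia]]; kb <- keys[[ib]]
          if (pass == 2L) {
            if (is.null(ka) || is.null(kb)) next
            verdict <- similarStructures(ka, kb)
            if (verdict == "STEREO_RELAXED") {
              changed <- tryUnion(ia, ib, "CONTEXT_STRUCTURE", ctx1, ctx2) || changed
            } else if (verdict == "DIFFERENT" &&
                       identical(ka$skeleton, kb$skeleton) &&
                       nzchar(ka$stereo) && nzchar(kb$stereo)) {
              pk <- paste(sort(c(ids[ia], ids[ib])), collapse = ";")
              if (!pk %in% seenConf) {
                seenConf <<- c(seenConf, pk)
                cf[[length(cf) + 1L]] <<- data.frame(
                  kind = "STEREO_AMBIGUITY", members = pk,
                  reaction = ctx1, resolution = "PENDING",
                  stringsAsFactors = FALSE)
              }
            }
          } else {
            if (!is.null(ka) && !is.null(kb)) next  # structure wins over names
            if (length(intersect(nameSets[[ia]], nameSets[[ib]])) > 0L)
              changed <- tryUnion(ia, ib, "CONTEXT_NAME", ctx1, ctx2) || changed
          }
        }
      }
      if (!changed) break
    }
  }
  runPass(2L)
  runPass(3L)
  initialize(partition, parent = parent,
             evidence = rbind(partition@evidence,
                              if (length(ev)) do.call(rbind, ev)),
             conflicts = rbind(partition@conflicts,
                               if (length(cf)) do.call(rbind, cf)))
}

## ---- conflict detection ----------------------------------------------------

#' Detect same-reaction-sides conflicts
#'
#' Emits a `SAME_REACTION_SIDES` conflict for every reaction in which two
#' members of one merge set occur on opposite sides.  Tautomer and
#' acid/base pairs can be validly merged (possibly yielding an empty
#' reaction), so conflicts default to `PENDING` review; refs listed in
#' `accepted` mark their classes `ACCEPTED`, which silences the flag but
#' keeps the log entry.
#'
#' @param partition a [MergePartition-class].
#' @param reactions source reaction table.
#' @param accepted character vector of metabolite refs whose classes are
#'   whitelisted (acid/base, tautomer pairs).
#' @return data.frame of conflicts.
#' @export
detectConflicts <- function(partition, reactions, accepted = character(0)) {
  ids <- partition@ids
  idIndex <- seq_along(ids); names(idIndex) <- ids
  parent <- partition@parent
  roots <- .pfRoots(parent)
  acceptedRoots <- unique(roots[idIndex[accepted[accepted %in% ids]]])
  out <- list()
  for (r in seq_len(nrow(reactions))) {
    eq <- parseEquation(reactions$equation[r])
    lrefs <- paste0(reactions$prefix[r], ":", eq$left$met)
    rrefs <- paste0(reactions$prefix[r], ":", eq$right$met)
    li <- idIndex[lrefs]; ri <- idIndex[rrefs]
    if (anyNA(li) || anyNA(ri)) next
    lroots <- roots[li]; rroots <- roots[ri]
    for (cl in intersect(lroots, rroots)) {
      members <- sort(unique(c(lrefs[lroots == cl], rrefs[rroots == cl])))
      out[[length(out) + 1L]] <- data.frame(
        kind = "SAME_REACTION_SIDES",
        members = paste(members, collapse = ";"),
        reaction = paste0(reactions$prefix[r], ":", reactions$local_id[r]),
        resolution = if (cl %in% acceptedRoots) "ACCEPTED" else "PENDING",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyConflicts())
  do.call(rbind, out)
}

## ---- reference selection and identifier assignment ------------------------

#' Default source priority order for reference selection
#'
#' @return character vector of source prefixes, most preferred first.
#' @export
defaultPriority <- function() {
  c("chebi", "metacycM", "keggC", "biggM", "seedM", "hmdb", "sabiorkM",
    "lipidmaps", "slm", "reactome", "envipath")
}

#' Select the reference member of a merge set
#'
#' Picks, in order: (1) a ChEBI member whose id appears in Rhea reactions;
#' (2) the member whose prefix is earliest in `priority` and that has a
#' structure; (3) the earliest-priority member regardless of structure.
#' Ties at every stage break by lexicographically smallest
#' `(prefix, local_id)`.
#'
#' @param members data.frame slice of the source metabolite table (the
#'   merge set's members).
#' @param rheaChebiIds character vector of ChEBI local ids that occur in
#'   Rhea reactions.
#' @param priority ordered character vector of prefixes.
#' @return single `"prefix:id"` reference.
#' @export
selectReference <- function(members, rheaChebiIds = character(0),
                            priority = defaultPriority()) {
  if (nrow(members) == 0L) stop("empty member set")
  ord <- order(members$prefix, members$local_id)
  members <- members[ord, , drop = FALSE]
  inRhea <- members$prefix == "chebi" & members$local_id %in% rheaChebiIds
  if (any(inRhea)) {
    m <- members[inRhea, ][1, ]
    return(paste0(m$prefix, ":", m$local_id))
  }
  pr <- match(members$prefix, priority)
  pr[is.na(pr)] <- length(priority) + 1L
  hasStruct <- !is.na(members$inchi) & nzchar(members$inchi)
  for (pool in list(which(hasStruct), seq_len(nrow(members)))) {
    if (length(pool)) {
      best <- pool[order(pr[pool], members$prefix[pool], members$local_id[pool])][1]
      return(paste0(members$prefix[best], ":", members$local_id[best]))
    }
  }
}

#' Assign deterministic namespace identifiers
#'
#' Merge sets are sorted by their reference `(prefix, local_id)` and
#' numbered `MNXM2`, `MNXM3`, ... without zero padding.  `MNXM1` (the
#' equation-balancing proton) and `MNXM01` (the transported proton) are
#' pre-allocated and never reassigned.  Rerunning on identical input
#' yields byte-identical output.
#'
#' @param partition a finalized [MergePartition-class].
#' @param metabolites source metabolite table.
#' @param rheaChebiIds,priority passed to [selectReference()].
#' @return data.frame of namespace entries: `mnx_id`, `name`,
#'   `reference`, `formula`, `charge`, `inchi`, `members` (`;`-joined).
#' @export
assignIds <- function(partition, metabolites,
                      rheaChebiIds = character(0),
                      priority = defaultPriority()) {
  ids <- .metRef(metabolites)
  stopifnot(identical(ids, partition@ids))
  roots <- .pfRoots(partition@parent)
  reserved <- data.frame(
    mnx_id = c("MNXM01", "MNXM1"),
    name = c("H(+), transported", "H(+)"),
    reference = c("mnx:MNXM01", "mnx:MNXM1"),
    formula = "H", charge = 1,
    inchi = "InChI=1S/p+1",
    members = "", stringsAsFactors = FALSE)
  if (length(roots) == 0L) return(reserved)
  classes <- split(seq_along(roots), roots)
  refs <- vapply(classes, function(idx) {
    selectReference(metabolites[idx, , drop = FALSE], rheaChebiIds, priority)
  }, character(1))
  refPrefix <- sub(":.*$", "", refs)
  refLocal <- sub("^[^:]*:", "", refs)
  ord <- order(refPrefix, refLocal)
  rows <- lapply(seq_along(ord), function(k) {
    idx <- classes[[ord[k]]]
    ref <- refs[ord[k]]
    mnx <- paste0("MNXM", k + 1L)
    if (mnx %in% reserved$mnx_id) stop("collision with reserved id ", mnx)
    refRow <- metabolites[idx[ids[idx] == ref], , drop = FALSE]
    data.frame(mnx_id = mnx,
               name = refRow$name[1],
               reference = ref,
               formula = if (is.na(refRow$formula[1])) NA_character_ else refRow$formula[1],
               charge = refRow$charge[1],
               inchi = if (is.na(refRow$inchi[1])) NA_character_ else refRow$inchi[1],
               members = paste(sort(ids[idx]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- rbind(reserved, do.call(rbind, rows))
  out[order(out$mnx_id), , drop = FALSE]
}

## ---- full pipeline ---------------------------------------------------------

#' Run the full three-pass metabolite reconciliation
#'
#' @param sources list with `metabolites` and `reactions` tables covering
#'   all source namespaces (see [readSourceDir()]).
#' @param rheaChebiIds,priority reference-selection inputs.
#' @param strict reject same-reaction-sides unions instead of flagging.
#' @return list with `partition` ([MergePartition-class]), `entries`
#'   (namespace entry table from [assignIds()]), `conflicts`
#'   (post-hoc [detectConflicts()] table) and `mapping` (named character:
#'   source ref to namespace id).
#' @export
reconcileSources <- function(sources, rheaChebiIds = character(0),
                             priority = defaultPriority(), strict = FALSE) {
  mets <- sources$metabolites
  rxns <- sources$reactions
  pt <- mergeIdenticalStructures(mets, strict = strict, reactions = rxns)
  .log("INFO", "pass 1: ", sum(evidenceLog(pt)$kind == "IDENTICAL_STRUCTURE"),
       " identical-structure merges")
  pt <- applyContextMerges(pt, mets, rxns, strict = strict)
  .log("INFO", "passes 2+3 complete: ", nrow(evidenceLog(pt)), " merges total")
  entries <- assignIds(pt, mets, rheaChebiIds, priority)
  conflicts <- detectConflicts(pt, rxns)
  mapping <- character(0)
  memb <- entries$members
  for (i in seq_len(nrow(entries))) {
    if (!nzchar(memb[i])) next
    for (ref in strsplit(memb[i], ";", fixed = TRUE)[[1]])
      mapping[ref] <- entries$mnx_id[i]
  }
  list(partition = pt, entries = entries, conflicts = conflicts,
       mapping = mapping)
}

#' All merged pairs implied by a partition
#'
#' @param partition a [MergePartition-class].
#' @return data.frame with columns `a`, `b` (every unordered pair within
#'   a merge set, `a < b`).
#' @export
mergedPairs <- function(partition) {
  roots <- .pfRoots(partition@parent)
  out <- list()
  for (cls in split(partition@ids, roots)) {
    if (length(cls) < 2L) next
    cls <- sort(cls)
    cmb <- utils::combn(cls, 2L)
    out[[length(out) + 1L]] <- data.frame(a = cmb[1, ], b = cmb[2, ],
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
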