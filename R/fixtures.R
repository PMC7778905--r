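## Synthetic source databases and models with known ground truth.
##
## Source fixtures emulate the statistical structure of overlapping
## biochemical namespaces: one true compound appears in several sources
## under different local ids and name spellings, with its structure
## sometimes protonated differently, sometimes stereo-erased and
## sometimes dropped entirely; shared reactions are written per source
## and cross-referenced.  Synthetic InChIs come from a restricted valid
## grammar (chain skeletons over C/N/O with optional stereo and
## protonation layers), which keeps the structure layer machinery fully
## exercised without a cheminformatics dependency.
##
## Model fixtures assemble disjoint motifs with provable flux status:
## open reversible chains (A), chains gated by export-only exchanges (a),
## irreversible cycles with one reversed edge (b) and dead-end producers
## (B).  Note that single-reaction 'a' or 'b' blocks are impossible: a
## reaction blocked in one regime but feasible in the next must traverse
## another reaction of the same status against its bound, so those
## statuses always come in groups of two or more (the generator rejects
## such configurations as infeasible).

#' Fixture generator configuration
#'
#' @param n_true_compounds number of distinct true compounds.
#' @param n_sources number of source namespaces (first covers everything,
#'   later ones deterministic 3/4 slices).
#' @param structure_dropout probability a source copy loses its InChI
#'   (keeping name and formula).
#' @param protonation_perturb probability a structure-bearing copy gets a
#'   protonation variant (`/p-1`, charge shifted).
#' @param stereo_erase probability a stereo-bearing copy loses its stereo
#'   layers.
#' @param n_shared_reactions number of reactions shared across sources.
#' @param xref_density probability of a cross-reference edge between two
#'   source copies of one reaction (a minimum of two edges per reaction
#'   is enforced whenever possible).
#' @param n_acid_base number of planted same-reaction-sides conflicts
#'   (an acid and its conjugate base on the two sides of one reaction).
#' @param model_blocks named integer vector: how many reactions of each
#'   status (`A`, `a`, `b`, `B`) the model fixture must contain.
#' @param seed integer seed; fully determines all outputs.
#' @return a `FixtureConfig` list.
#' @export
fixtureConfig <- function(n_true_compounds = 40, n_sources = 3,
                          structure_dropout = 0.3, protonation_perturb = 0.5,
                          stereo_erase = 0.15, n_shared_reactions = 25,
                          xref_density = 0.9, n_acid_base = 0,
                          model_blocks = c(A = 5, a = 2, b = 2, B = 3),
                          seed = 42) {
  stopifnot(n_true_compounds >= 1, n_sources >= 2,
            structure_dropout >= 0, structure_dropout <= 1,
            protonation_perturb >= 0, protonation_perturb <= 1,
            stereo_erase >= 0, stereo_erase <= 1,
            xref_density >= 0, xref_density <= 1)
  out <- list(n_true_compounds = n_true_compounds, n_sources = n_sources,
              structure_dropout = structure_dropout,
              protonation_perturb = protonation_perturb,
              stereo_erase = stereo_erase,
              n_shared_reactions = n_shared_reactions,
              xref_density = xref_density, n_acid_base = n_acid_base,
              model_blocks = model_blocks, seed = seed)
  class(out) <- "FixtureConfig"
  out
}

#' Named fixture presets
#'
#' `default` is the standard reconciliation benchmark; `figure1` is the
#' five-metabolites-in-four-reactions teaching example that reconciles to
#' two namespace metabolites in a single reaction through all three
#' evidence kinds; `status-mix` is a model with planted status counts.
#'
#' @param preset one of `"default"`, `"figure1"`, `"status-mix"`.
#' @param seed integer seed.
#' @return a `FixtureConfig`.
#' @export
fixturePreset <- function(preset = c("default", "figure1", "status-mix"),
                          seed = 42) {
  preset <- match.arg(preset)
  switch(preset,
    "default" = fixtureConfig(seed = seed),
    "figure1" = {
      cfg <- fixtureConfig(n_true_compounds = 2, n_sources = 2,
                           structure_dropout = 0, protonation_perturb = 0,
                           stereo_erase = 0, n_shared_reactions = 0,
                           xref_density = 1, seed = seed)
      cfg$figure1 <- TRUE
      cfg
    },
    "status-mix" = fixtureConfig(model_blocks = c(A = 6, a = 4, b = 3, B = 4),
                                 seed = seed))
}

## ---- synthetic chemistry ---------------------------------------------------

## distinct (C, N, O) composition per compound index
.compoundComposition <- function(i) {
  combos <- expand.grid(C = 3:12, N = 0:3, O = 0:4)
  combos <- combos[order(combos$C, combos$N, combos$O), ]
  combos[((i - 1L) %% nrow(combos)) + 1L, ]
}

.compoundFormula <- function(i) {
  cc <- .compoundComposition(i)
  paste0("C", cc$C, "H", 2 * cc$C + 2,
         if (cc$N > 0) paste0("N", cc$N) else "",
         if (cc$O > 0) paste0("O", cc$O) else "")
}

.compoundInchi <- function(i, stereo = FALSE, protonated = FALSE) {
  cc <- .compoundComposition(i)
  heavy <- cc$C + cc$N + cc$O
  conn <- paste(seq_len(heavy), collapse = "-")
  body <- paste0("InChI=1S/", .compoundFormula(i), "/c", conn,
                 "/h", paste0("1-", cc$C, "H2"))
  if (stereo) body <- paste0(body, "/t2-/m0/s1")
  if (protonated) body <- paste0(body, "/p-1")
  body
}

.SYLLABLES <- c("arin", "bosol", "cytate", "dulose", "erinol", "famine",
                "gluate", "hepin", "inate", "julose", "ketol", "lanine")

.compoundName <- function(i) {
  paste0("cmpd-", sprintf("%03d", i), "-",
         .SYLLABLES[((i - 1L) %% length(.SYLLABLES)) + 1L])
}

## per-source spelling variant that normalizes back to the same name
.nameVariant <- function(base, s) {
  switch((s %% 3L) + 1L,
         base,
         toupper(base),
         gsub("-", " ", base, fixed = TRUE))
}

.compoundHasStereo <- function(i) i %% 3L == 0L

## ---- source generator ------------------------------------------------------

.figure1Sources <- function() {
  ## five source metabolites (X: a,b,c; Y: d,e) in four cross-referenced
  ## reactions that reconcile to two namespace metabolites in a single
  ## reaction via all three evidence kinds:
  ##   pass 1 merges a,b (identical structures, stereo included)
  ##   pass 2 merges c into {a,b} (stereo-erased structure, in context)
  ##   pass 3 merges e into {d}  (no structure, shared name, in context)
  xFull <- .compoundInchi(1, stereo = TRUE)
  xBald <- .compoundInchi(1, stereo = FALSE)
  yFull <- .compoundInchi(2, stereo = FALSE)
  mets <- data.frame(
    prefix = c("alpha", "alpha", "beta", "beta", "beta"),
    local_id = c("a", "d", "b", "c", "e"),
    name = c("xylunate", "yronate", "Xylunate", "xylunate (no stereo)", "YRONATE"),
    names = NA_character_,
    formula = c(.compoundFormula(1), .compoundFormula(2),
                .compoundFormula(1), .compoundFormula(1), .compoundFormula(2)),
    charge = 0,
    inchi = c(xFull, yFull, xFull, xBald, NA),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    prefix = c("alpha", "beta", "beta", "alpha"),
    local_id = c("r1", "r2", "r3", "r4"),
    equation = c("a --> d", "b --> e", "c --> e", "a <-- d"),
    direction = c("LR", "LR", "LR", "RL"),
    xrefs = c("beta:r2", "alpha:r1", "alpha:r1", "beta:r2"),
    stringsAsFactors = FALSE)
  truth <- list(
    partition = list(c("alpha:a", "beta:b", "beta:c"),
                     c("alpha:d", "beta:e")),
    conflicts = character(0),
    n_nonempty_reactions = 1L)
  list(metabolites = mets, reactions = rxns, truth = truth)
}

#' Generate synthetic source databases with known ground truth
#'
#' @param config a `FixtureConfig` (see [fixtureConfig()] /
#'   [fixturePreset()]).
#' @param dir optional output directory; when given, TSVs are written via
#'   [writeSourceDir()].
#' @param adversarial_met_xrefs plant deliberately wrong
#'   metabolite-to-metabolite cross-references in the TSVs (the
#'   reconciliation must ignore them).
#' @return list with `sources` (`metabolites` + `reactions` tables) and
#'   `truth` (true partition as list of ref vectors, planted conflict
#'   refs).
#' @export
generateSources <- function(config, dir = NULL, adversarial_met_xrefs = FALSE) {
  stopifnot(inherits(config, "FixtureConfig"))
  if (isTRUE(config$figure1)) {
    fx <- .figure1Sources()
    if (!is.null(dir)) writeSourceDir(fx, dir)
    return(list(sources = fx[c("metabolites", "reactions")], truth = fx$truth))
  }
  set.seed(config$seed)
  nC <- config$n_true_compounds
  nS <- config$n_sources
  ## deterministic coverage: source 1 covers all; later sources 3/4 slices
  covered <- lapply(seq_len(nS), function(s) {
    if (s == 1L) seq_len(nC)
    else which(seq_len(nC) %% 4L != ((s - 1L) %% 4L))
  })
  mets <- list(); truthSets <- rep(list(character(0)), nC)
  hasInchi <- matrix(FALSE, nC, nS)
  for (s in seq_len(nS)) {
    prefix <- paste0("src", s)
    for (i in covered[[s]]) {
      drop <- stats::runif(1) < config$structure_dropout
      prot <- stats::runif(1) < config$protonation_perturb
      erase <- .compoundHasStereo(i) && stats::runif(1) < config$stereo_erase
      inchi <- if (drop) NA_character_ else
        .compoundInchi(i, stereo = .compoundHasStereo(i) && !erase,
                       protonated = prot)
      ref <- paste0(prefix, ":", sprintf("M%04d", i))
      mets[[length(mets) + 1L]] <- data.frame(
        prefix = prefix, local_id = sprintf("M%04d", i),
        name = .nameVariant(.compoundName(i), s),
        names = NA_character_,
        formula = .compoundFormula(i),
        charge = if (!drop && prot) -1 else 0,
        inchi = inchi, stringsAsFactors = FALSE)
      truthSets[[i]] <- c(truthSets[[i]], ref)
      hasInchi[i, s] <- !drop
    }
  }
  mets <- do.call(rbind, mets)

  ## shared reactions: 2 left + 2 right compounds.  Members of one
  ## reaction are drawn from coverage-compatible compounds so the
  ## reaction is genuinely shared: each compound's copies need at least
  ## two cross-referenced reaction contexts to be reconcilable when its
  ## structure is dropped or stereo-erased.  Compounds are grouped by the
  ## set of sources covering them; a reaction mixes a group only with
  ## fully-covered compounds, and the covering design places every
  ## compound in two reactions.
  nR <- config$n_shared_reactions
  covClass <- vapply(seq_len(nC), function(i)
    paste(which(vapply(covered, function(cv) i %in% cv, logical(1))),
          collapse = ","), character(1))
  fullClass <- paste(seq_len(nS), collapse = ",")
  rxnMembers <- list()
  if (nR > 0) {
    for (cls in unique(covClass)) {
      pool <- which(covClass == cls)
      pool <- c(sample(pool), sample(pool))      # each compound twice
      filler <- which(covClass == fullClass)
      while (length(pool) > 0L) {
        memb <- pool[seq_len(min(4L, length(pool)))]
        pool <- pool[-seq_len(length(memb))]
        while (length(unique(memb)) < 4L)
          memb <- unique(c(memb, sample(filler, 1L)))
        rxnMembers[[length(rxnMembers) + 1L]] <- unique(memb)[1:4]
      }
    }
    if (length(rxnMembers) > nR)
      stop("config infeasible: ", nR, " shared reactions cannot give every ",
           "compound two reaction contexts (need ", length(rxnMembers), ")")
    full <- which(covClass == fullClass)
    while (length(rxnMembers) < nR)
      rxnMembers[[length(rxnMembers) + 1L]] <- sample(full, 4L)
  }
  rxns <- list()
  truthConflicts <- character(0)
  for (j in seq_along(rxnMembers)) {
    memb <- rxnMembers[[j]]
    co <- rep(1L, 4L)
    if (stats::runif(1) < 0.3) co[sample(4L, 1L)] <- 2L
    carriers <- which(vapply(covered, function(cv) all(memb %in% cv), logical(1)))
    if (length(carriers) == 0L) next
    dirFlip <- stats::runif(length(carriers)) < 0.2
    for (k in seq_along(carriers)) {
      s <- carriers[k]
      ids <- sprintf("M%04d", memb)
      lhs <- paste(ifelse(co[1:2] > 1L, paste(co[1:2], ids[1:2]), ids[1:2]),
                   collapse = " + ")
      rhs <- paste(ifelse(co[3:4] > 1L, paste(co[3:4], ids[3:4]), ids[3:4]),
                   collapse = " + ")
      eqn <- if (dirFlip[k]) paste(rhs, "<--", lhs) else paste(lhs, "-->", rhs)
      rxns[[length(rxns) + 1L]] <- data.frame(
        prefix = paste0("src", s), local_id = sprintf("R%03d", j),
        equation = eqn, direction = if (dirFlip[k]) "RL" else "LR",
        xrefs = "", stringsAsFactors = FALSE)
    }
    ## cross-reference edges between the carriers, min 2 when possible
    if (length(carriers) >= 2L) {
      pairsAll <- utils::combn(carriers, 2L, simplify = FALSE)
      keep <- stats::runif(length(pairsAll)) < config$xref_density
      need <- min(2L, length(pairsAll))
      if (sum(keep) < need) {
        force <- sample(which(!keep))[seq_len(need - sum(keep))]
        keep[force] <- TRUE
      }
      for (p in pairsAll[keep]) {
        i1 <- length(rxns) - length(carriers) + match(p[1], carriers)
        i2 <- length(rxns) - length(carriers) + match(p[2], carriers)
        addX <- function(i, tgt) {
          cur <- rxns[[i]]$xrefs
          rxns[[i]]$xrefs <<- if (nzchar(cur)) paste0(cur, ";", tgt) else tgt
        }
        addX(i2, paste0(rxns[[i1]]$prefix, ":", rxns[[i1]]$local_id))
        addX(i1, paste0(rxns[[i2]]$prefix, ":", rxns[[i2]]$local_id))
      }
    }
  }

  ## planted acid/base conflicts: one source holds both protonation forms
  ## of a compound, linked by a reaction -- pass 1 merges them and the
  ## reaction flags SAME_REACTION_SIDES (and empties under mapping)
  if (config$n_acid_base > 0) {
    picks <- seq_len(config$n_acid_base)
    for (k in picks) {
      i <- covered[[1]][k]
      idA <- sprintf("M%04da", i); idB <- sprintf("M%04db", i)
      mets <- rbind(mets, data.frame(
        prefix = "src1", local_id = c(idA, idB),
        name = paste0(.compoundName(i), c(" (acid)", " (base)")),
        names = NA_character_, formula = .compoundFormula(i),
        charge = c(0, -1),
        inchi = c(.compoundInchi(i, stereo = .compoundHasStereo(i)),
                  .compoundInchi(i, stereo = .compoundHasStereo(i),
                                 protonated = TRUE)),
        stringsAsFactors = FALSE))
      rxns[[length(rxns) + 1L]] <- data.frame(
        prefix = "src1", local_id = sprintf("RAB%02d", k),
        equation = paste(idA, "=", idB), direction = "BIDIRECTIONAL",
        xrefs = "", stringsAsFactors = FALSE)
      truthSets[[i]] <- c(truthSets[[i]], paste0("src1:", idA),
                          paste0("src1:", idB))
      truthConflicts <- c(truthConflicts, paste0("src1:", sprintf("RAB%02d", k)))
    }
  }

  reactions <- if (length(rxns)) do.call(rbind, rxns)
    else data.frame(prefix = character(0), local_id = character(0),
                    equation = character(0), direction = character(0),
                    xrefs = character(0), stringsAsFactors = FALSE)
  sources <- list(metabolites = mets, reactions = reactions)
  truth <- list(partition = truthSets, conflicts = truthConflicts)
  if (!is.null(dir)) {
    metXrefs <- NULL
    if (adversarial_met_xrefs) {
      ## wrong on purpose: point every copy of compound i at compound i+1
      ref <- paste0(mets$prefix, ":", mets$local_id)
      idx <- as.integer(sub("[ab]?$", "", sub("^M", "", mets$local_id)))
      wrong <- sprintf("src1:M%04d", (idx %% config$n_true_compounds) + 1L)
      metXrefs <- data.frame(ref = ref, xrefs = wrong, stringsAsFactors = FALSE)
    }
    writeSourceDir(sources, dir, metXrefs = metXrefs)
  }
  list(sources = sources, truth = truth)
}

## ---- model generator -------------------------------------------------------

.motifBuilder <- function() {
  species <- list(); reactions <- list()
  addSpecies <- function(id, boundary = FALSE) {
    species[[length(species) + 1L]] <<- data.frame(
      id = id, name = id, compartment = "c", boundary = boundary,
      formula = NA_character_, charge = NA_real_, annotations = "",
      stringsAsFactors = FALSE)
    id
  }
  addReaction <- function(id, lhs, rhs, lb, ub) {
    terms <- function(x) if (length(x) == 0L) .emptyTerms() else
      data.frame(met = x, num = 1, den = 1, comp = "c", stringsAsFactors = FALSE)
    reactions[[length(reactions) + 1L]] <<- list(
      id = id, eq = .newEquation(terms(lhs), terms(rhs),
                                 if (lb < 0) "BIDIRECTIONAL" else "LR"),
      lb = lb, ub = ub)
    id
  }
  list(addSpecies = addSpecies, addReaction = addReaction,
       collect = function() list(species = do.call(rbind, species),
                                 reactions = reactions))
}

#' Generate a model fixture with planted flux statuses
#'
#' Builds status motifs per `config$model_blocks` (see the file header
#' for the motif catalogue), wires A- and a-motifs to a hub metabolite
#' with its own exchange (the hub exchange counts as one of the A
#' reactions), keeps b/B motifs as separate components and emits the
#' model plus its ground-truth statuses.  Configurations with a single
#' `a` or `b` reaction are provably infeasible and rejected.
#'
#' @param config a `FixtureConfig`.
#' @param path optional SBML output path.
#' @return list with `model` ([GsmnModel-class]) and `statuses` (named
#'   character vector, reaction id to planted status).
#' @export
generateModel <- function(config, path = NULL) {
  stopifnot(inherits(config, "FixtureConfig"))
  blocks <- config$model_blocks
  for (s in c("A", "a", "b", "B")) if (is.na(blocks[s])) blocks[s] <- 0L
  M <- 1000
  if (blocks["a"] == 1L || blocks["b"] == 1L)
    stop("config infeasible: a single reaction can never have status 'a' or ",
         "'b' (its relaxation witness must traverse a second reaction of ",
         "the same status)")
  if (blocks["a"] > 0L && blocks["A"] < 2L)
    stop("config infeasible: 'a' motifs drain into the hub, which needs at ",
         "least two 'A' reactions (its exchange plus an original-bounds ",
         "flux route) to stay status A")
  b <- .motifBuilder()
  statuses <- character(0)
  tag <- function(ids, st) statuses[ids] <<- st

  nA <- blocks[["A"]]; na <- blocks[["a"]]; nb <- blocks[["b"]]; nB <- blocks[["B"]]
  if (nA == 1L && na == 0L) {
    ## a single exchange over a boundary-flagged species is trivially A
    bm <- b$addSpecies("Xfree", boundary = TRUE)
    tag(b$addReaction("EX_single", bm, character(0), -M, M), "A")
  } else if (nA >= 1L) {
    hub <- b$addSpecies("HUB")
    tag(b$addReaction("EX_hub", hub, character(0), -M, M), "A")
    if (nA == 2L) {
      tag(b$addReaction("EX_hub2", hub, character(0), -M, M), "A")
    } else if (nA > 2L) {
      prev <- hub
      for (k in seq_len(nA - 2L)) {
        nx <- b$addSpecies(paste0("Achain", k))
        tag(b$addReaction(paste0("RA", k), prev, nx, -M, M), "A")
        prev <- nx
      }
      tag(b$addReaction("EX_A", prev, character(0), -M, M), "A")
    }
    if (na >= 2L) {
      ## export-only exchange, irreversible chain into the hub: blocked
      ## until boundary reactions may import
      prev <- b$addSpecies("aIn")
      tag(b$addReaction("EX_a", prev, character(0), 0, M), "a")
      if (na > 2L) for (k in seq_len(na - 2L)) {
        nx <- b$addSpecies(paste0("achain", k))
        tag(b$addReaction(paste0("Ra", k), prev, nx, 0, M), "a")
        prev <- nx
      }
      tag(b$addReaction("Ra_hub", prev, hub, 0, M), "a")
    }
  }
  if (nb >= 2L) {
    ## irreversible cycle with one reversed edge: blocked in every regime
    ## until all bounds are relaxed, then the cycle vector carries flux
    ids <- vapply(seq_len(nb), function(k) b$addSpecies(paste0("bcyc", k)),
                  character(1))
    for (k in seq_len(nb - 1L))
      tag(b$addReaction(paste0("Rb", k), ids[k], ids[(k %% nb) + 1L], 0, M), "b")
    tag(b$addReaction(paste0("Rb", nb), ids[1], ids[nb], 0, M), "b")
  }
  if (nB >= 1L) for (k in seq_len(nB)) {
    src <- b$addSpecies(paste0("Bsrc", k))
    snk <- b$addSpecies(paste0("Bdead", k))
    tag(b$addReaction(paste0("RB", k), src, snk, 0, M), "B")
  }
  parts <- b$collect()
  if (is.null(parts$species)) stop("config infeasible: no blocks requested")
  rx <- do.call(rbind, lapply(parts$reactions, function(r)
    data.frame(id = r$id, name = r$id, lb = r$lb, ub = r$ub,
               reversible = r$lb < 0, stringsAsFactors = FALSE)))
  model <- new("GsmnModel", modelId = paste0("fixture_seed", config$seed),
               compartments = "c", species = parts$species,
               reactions = rx,
               equations = lapply(parts$reactions, `[[`, "eq"),
               objective = character(0))
  if (!is.null(path)) writeSbmlModel(model, path)
  list(model = model, statuses = statuses[rx$id])
}
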