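#' @import methods
NULL

#' MergePartition: a union-find partition of source metabolites
#'
#' Tracks which source metabolites (referenced as `"prefix:id"`) have been
#' merged into one namespace entry, the evidence for every non-singleton
#' union and any conflicts raised along the way.  Merging is monotone:
#' sets only grow during a reconciliation run.
#'
#' @slot ids character, one `"prefix:id"` per source metabolite.
#' @slot parent integer, union-find parent pointers (`parent[i] == i` at a
#'   root).
#' @slot evidence data.frame with columns `kind`
#'   (`IDENTICAL_STRUCTURE`, `CONTEXT_STRUCTURE`, `CONTEXT_NAME`), `a`,
#'   `b` (metabolite refs) and `context1`, `context2` (reaction refs, `NA`
#'   for structure-identity evidence).
#' @slot conflicts data.frame with columns `kind` (`SAME_REACTION_SIDES`,
#'   `STEREO_AMBIGUITY`, `NAME_CLASH`), `members` (`;`-joined refs),
#'   `reaction`, `resolution` (`PENDING`, `ACCEPTED`, `REJECTED`).
#' @export
setClass("MergePartition",
  representation(ids = "character", parent = "integer",
                 evidence = "data.frame", conflicts = "data.frame"),
  validity = function(object) {
    n <- length(object@ids)
    if (length(object@parent) != n)
      return("parent vector length must match ids")
    if (n && (any(object@parent < 1L) || any(object@parent > n)))
      return("parent pointers out of range")
    if (anyDuplicated(object@ids))
      return("duplicate (prefix, local_id) metabolite refs")
    need <- c("kind", "a", "b", "context1", "context2")
    if (!all(need %in% names(object@evidence)))
      return("evidence log misses required columns")
    ctx <- object@evidence
    if (nrow(ctx)) {
      bad <- ctx$kind == "IDENTICAL_STRUCTURE" & !is.na(ctx$context1)
      if (any(bad)) return("IDENTICAL_STRUCTURE evidence never carries a context")
      bad <- ctx$kind != "IDENTICAL_STRUCTURE" & is.na(ctx$context1)
      if (any(bad)) return("context evidence must carry a reaction context")
    }
    TRUE
  })

.emptyEvidence <- function() {
  data.frame(kind = character(0), a = character(0), b = character(0),
             context1 = character(0), context2 = character(0),
             stringsAsFactors = FALSE)
}

.emptyConflicts <- function() {
  data.frame(kind = character(0), members = character(0),
             reaction = character(0), resolution = character(0),
             stringsAsFactors = FALSE)
}

#' Create an all-singleton partition
#'
#' @param ids character vector of `"prefix:id"` metabolite refs.
#' @return a [MergePartition-class] object.
#' @export
newPartition <- function(ids) {
  new("MergePartition", ids = ids, parent = seq_along(ids),
      evidence = .emptyEvidence(), conflicts = .emptyConflicts())
}

#' MnxNamespace: the unified metabolite and reaction namespace
#'
#' @slot chem data.frame of namespace metabolites: `mnx_id`, `name`,
#'   `reference` (`"prefix:id"` of the selected reference member),
#'   `formula`, `charge`, `inchi`.
#' @slot chemXref data.frame: `source` (`"prefix:id"`), `mnx_id`.
#' @slot reac data.frame of namespace reactions: `mnx_id`, `equation`
#'   (canonical text), `direction`, `reference`, `empty`, `balance`.
#' @slot reacXref data.frame: `source`, `mnx_id`.
#' @export
setClass("MnxNamespace",
  representation(chem = "data.frame", chemXref = "data.frame",
                 reac = "data.frame", reacXref = "data.frame"),
  validity = function(object) {
    if (anyDuplicated(object@chem$mnx_id)) return("duplicate chem mnx_id")
    if (anyDuplicated(object@reac$mnx_id)) return("duplicate reac mnx_id")
    if (nrow(object@chemXref) &&
        !all(object@chemXref$mnx_id %in% object@chem$mnx_id))
      return("dangling chem xref")
    if (nrow(object@reacXref) &&
        !all(object@reacXref$mnx_id %in% object@reac$mnx_id))
      return("dangling reac xref")
    TRUE
  })

#' GsmnModel: a genome-scale metabolic network
#'
#' A stoichiometric model with flux bounds, as read from SBML level 2 or
#' level 3 (+FBC) or produced by mapping onto the unified namespace.
#'
#' @slot modelId character scalar.
#' @slot compartments character vector of compartment ids.
#' @slot species data.frame: `id`, `name`, `compartment`, `boundary`
#'   (logical), `formula`, `charge`, `annotations` (`;`-joined
#'   `"prefix:id"`).
#' @slot reactions data.frame: `id`, `name`, `lb`, `ub`, `reversible`.
#' @slot equations list of [parseEquation()] `Equation` objects over
#'   species ids (term `comp` holds the species' compartment).
#' @slot objective character, id of the objective reaction (or empty).
#' @export
setClass("GsmnModel",
  representation(modelId = "character", compartments = "character",
                 species = "data.frame", reactions = "data.frame",
                 equations = "list", objective = "character"),
  validity = function(object) {
    if (length(object@equations) != nrow(object@reactions))
      return("one equation per reaction required")
    mets <- unique(unlist(lapply(object@equations,
                                 function(e) c(e$left$met, e$right$met))))
    if (length(mets) && !all(mets %in% object@species$id))
      return("equation references unknown species")
    if (nrow(object@reactions) &&
        any(!is.finite(object@reactions$lb) | !is.finite(object@reactions$ub)))
      return("bounds must be finite after big-M substitution")
    TRUE
  })

#' FluxProblem: steady-state flux feasibility problem
#'
#' @slot S numeric stoichiometric matrix (metabolites x reactions).
#' @slot lb,ub numeric bound vectors (finite, containing zero).
#' @slot boundary logical, which reactions are boundary (exchange)
#'   reactions.
#' @slot rxnIds,metIds character identifiers.
#' @slot tol numeric flux tolerance.
#' @slot bigM numeric bound magnitude used for relaxed regimes.
#' @export
setClass("FluxProblem",
  representation(S = "matrix", lb = "numeric", ub = "numeric",
                 boundary = "logical", rxnIds = "character",
                 metIds = "character", tol = "numeric", bigM = "numeric"),
  validity = function(object) {
    n <- ncol(object@S)
    if (length(object@lb) != n || length(object@ub) != n ||
        length(object@boundary) != n || length(object@rxnIds) != n)
      return("per-reaction vectors must match ncol(S)")
    if (length(object@metIds) != nrow(object@S))
      return("metIds must match nrow(S)")
    if (n && (any(object@lb > 0) || any(object@ub < 0)))
      return("bounds must contain zero (clamp before constructing)")
    TRUE
  })

#' StatusProfile: per-reaction A/a/b/B flux status
#'
#' Statuses: `A` carries flux under the original bounds, `a` only after
#' all boundary reactions are made bidirectional, `b` only after all
#' reactions are made bidirectional, `B` never (topologically blocked).
#'
#' @slot status data.frame: `reaction`, `status`.
#' @slot counts named integer vector over `c("A","a","b","B")`.
#' @export
setClass("StatusProfile",
  representation(status = "data.frame", counts = "integer"),
  validity = function(object) {
    if (!all(object@status$status %in% c("A", "a", "b", "B")))
      return("invalid status value")
    if (sum(object@counts) != nrow(object@status))
      return("counts must sum to number of classified reactions")
    TRUE
  })

#' MappingReport: diagnostics from mapping a model onto the namespace
#'
#' @slot species data.frame: `species`, `outcome`
#'   (`MAPPED_BY_ANNOTATION`, `MAPPED_BY_ID`, `MAPPED_BY_NAME`,
#'   `UNMAPPED`), `target` (namespace id or `NA`).
#' @slot reactions data.frame: `reaction`, `outcome` (`ONE_TO_ONE`,
#'   `MERGED`, `EMPTIED`, `UNMAPPED_PARTICIPANT`), `target` (canonical
#'   key / group id or `NA`).
#' @slot messages data.frame: `severity`, `entity`, `text`.
#' @export
setClass("MappingReport",
  representation(species = "data.frame", reactions = "data.frame",
                 messages = "data.frame"))

setMethod("show", "MergePartition", function(object) {
  roots <- vapply(seq_along(object@parent), function(i) .pfFind(object@parent, i),
                  integer(1))
  sizes <- table(roots)
  cat("MergePartition:", length(object@ids), "metabolites in",
      length(sizes), "classes (", sum(sizes > 1), "non-singleton );",
      nrow(object@evidence), "evidence records,",
      nrow(object@conflicts), "conflicts\n")
})

setMethod("show", "MnxNamespace", function(object) {
  cat("MnxNamespace:", nrow(object@chem), "metabolites (",
      nrow(object@chemXref), "xrefs ),", nrow(object@reac), "reactions (",
      nrow(object@reacXref), "xrefs )\n")
})

setMethod("show", "GsmnModel", function(object) {
  cat("GsmnModel", object@modelId, ":", nrow(object@species), "species,",
      nrow(object@reactions), "reactions,",
      length(object@compartments), "compartments\n")
})

setMethod("show", "FluxProblem", function(object) {
  cat("FluxProblem:", nrow(object@S), "metabolites x", ncol(object@S),
      "reactions;", sum(object@boundary), "boundary; tol =", object@tol,
      "; bigM =", object@bigM, "\n")
})

setMethod("show", "StatusProfile", function(object) {
  cat("StatusProfile:",
      paste(names(object@counts), object@counts, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "MappingReport", function(object) {
  cat("MappingReport:", nrow(object@species), "species,",
      nrow(object@reactions), "reactions,", nrow(object@messages),
      "messages\n")
})

## ---- accessors -------------------------------------------------------------

#' @describeIn MergePartition-class evidence log accessor
#' @param object,x a `MergePartition`.
#' @export
evidenceLog <- function(object) object@evidence

#' @describeIn MergePartition-class conflict log accessor
#' @export
conflictLog <- function(object) object@conflicts

#' Namespace table accessors
#'
#' @param object an [MnxNamespace-class] object.
#' @return the requested data.frame.
#' @export
chemTable <- function(object) object@chem

#' @rdname chemTable
#' @export
chemXrefTable <- function(object) object@chemXref

#' @rdname chemTable
#' @export
reacTable <- function(object) object@reac

#' @rdname chemTable
#' @export
reacXrefTable <- function(object) object@reacXref

#' Model table accessors
#'
#' @param object a [GsmnModel-class] object.
#' @return the requested component.
#' @export
speciesTable <- function(object) object@species

#' @rdname speciesTable
#' @export
reactionTable <- function(object) object@reactions

#' @rdname speciesTable
#' @export
modelEquations <- function(object) object@equations

#' Status profile accessors
#'
#' @param object a [StatusProfile-class] object.
#' @return status table or counts vector.
#' @export
statusTable <- function(object) object@status

#' @rdname statusTable
#' @export
statusCounts <- function(object) object@counts

#' Mapping report accessors
#'
#' @param object a [MappingReport-class] object.
#' @return the requested data.frame.
#' @export
speciesOutcomes <- function(object) object@species

#' @rdname speciesOutcomes
#' @export
reactionOutcomes <- function(object) object@reactions

#' @rdname speciesOutcomes
#' @export
mappingMessages <- function(object) object@messages
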