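## Mapping a GSMN onto the unified namespace, with per-entity diagnostics.
##
## Species are mapped by precedence: identifiers.org annotation, then
## exact cross-reference of the declared id, then exact normalized name;
## the first match wins and disagreement between annotation and name is
## logged at WARNING.  Unmapped species keep their model-local ids.
## Reactions are rewritten inside the model's own compartments; equations
## that cancel away are dropped (EMPTIED), and reactions whose canonical
## keys collide after mapping are reported MERGED.

.speciesIdCandidates <- function(id, compartments) {
  cands <- id
  stripped <- sub("^M_", "", id)
  cands <- c(cands, stripped)
  for (comp in compartments) {
    sfx <- paste0("_", comp, "$")
    cands <- c(cands, sub(sfx, "", id), sub(sfx, "", stripped))
  }
  ## generic single-letter compartment tag
  cands <- c(cands, sub("_[a-z][a-z0-9]?$", "", stripped))
  unique(cands)
}

#' Map a model onto the unified namespace
#'
#' @param model a [GsmnModel-class] object.
#' @param namespace an [MnxNamespace-class] object.
#' @return list with `model` (the mapped [GsmnModel-class]) and `report`
#'   (a [MappingReport-class]).
#' @export
mapModel <- function(model, namespace) {
  stopifnot(is(model, "GsmnModel"), is(namespace, "MnxNamespace"))
  chem <- namespace@chem
  xref <- namespace@chemXref
  xrefMap <- stats::setNames(xref$mnx_id, xref$source)
  ## bare-local-id lookup, kept only where unambiguous across prefixes
  localIds <- sub("^[^:]*:", "", xref$source)
  uniq <- tapply(xref$mnx_id, localIds, function(v) {
    u <- unique(v); if (length(u) == 1L) u else NA_character_
  })
  localMap <- uniq[!is.na(uniq)]
  nameMap <- tapply(chem$mnx_id, normalizeName(chem$name), function(v) {
    u <- unique(v); if (length(u) == 1L) u else NA_character_
  })
  nameMap <- nameMap[!is.na(nameMap)]

  sp <- model@species
  msgs <- list()
  say <- function(severity, entity, text)
    msgs[[length(msgs) + 1L]] <<- data.frame(severity = severity,
                                             entity = entity, text = text,
                                             stringsAsFactors = FALSE)
  outcome <- character(nrow(sp)); target <- rep(NA_character_, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    hit <- NA_character_; how <- "UNMAPPED"
    if (nzchar(sp$annotations[i])) {
      for (ref in strsplit(sp$annotations[i], ";", fixed = TRUE)[[1]]) {
        if (startsWith(ref, "mnx:")) {
          cand <- sub("^mnx:", "", ref)
          if (cand %in% chem$mnx_id) { hit <- cand; how <- "MAPPED_BY_ANNOTATION"; break }
        } else if (ref %in% names(xrefMap)) {
          hit <- unname(xrefMap[[ref]]); how <- "MAPPED_BY_ANNOTATION"; break
        }
      }
    }
    if (is.na(hit)) {
      for (cand in .speciesIdCandidates(sp$id[i], model@compartments)) {
        if (cand %in% chem$mnx_id) { hit <- cand; how <- "MAPPED_BY_ID"; break }
        if (cand %in% names(xrefMap)) { hit <- unname(xrefMap[[cand]]); how <- "MAPPED_BY_ID"; break }
        if (cand %in% names(localMap)) { hit <- unname(localMap[[cand]]); how <- "MAPPED_BY_ID"; break }
      }
    }
    if (is.na(hit)) {
      nn <- normalizeName(sp$name[i])
      if (nzchar(nn) && nn %in% names(nameMap)) {
        hit <- unname(nameMap[[nn]]); how <- "MAPPED_BY_NAME"
      }
    } else {
      ## annotation/id vs name disagreement is worth a warning
      nn <- normalizeName(sp$name[i])
      if (nzchar(nn) && nn %in% names(nameMap) && nameMap[[nn]] != hit)
        say("WARNING", sp$id[i],
            paste0("name '", sp$name[i], "' points to ", nameMap[[nn]],
                   " but ", tolower(how), " gives ", hit))
    }
    outcome[i] <- how; target[i] <- hit
    if (how == "UNMAPPED")
      say("INFO", sp$id[i], "species not found in namespace; keeping model-local id")
  }

  ## rewrite reactions inside model compartments
  mapping <- ifelse(is.na(target), sp$id, target)
  names(mapping) <- sp$id
  rx <- model@reactions
  n <- nrow(rx)
  newEqs <- vector("list", n)
  keys <- character(n)
  unmappedPart <- logical(n)
  emptied <- logical(n)
  for (i in seq_len(n)) {
    eq <- model@equations[[i]]
    unmappedPart[i] <- any(is.na(target[match(c(eq$left$met, eq$right$met), sp$id)]))
    req <- rewriteEquation(eq, mapping)
    newEqs[[i]] <- req
    emptied[i] <- isEmptyEquation(req)
    keys[i] <- canonicalKey(req)$key
    if (emptied[i])
      say("WARNING", rx$id[i],
          "reaction cancels to an empty equation after mapping and will disappear from the mapped model")
  }
  rxOutcome <- rep("ONE_TO_ONE", n)
  rxTarget <- keys
  rxOutcome[unmappedPart] <- "UNMAPPED_PARTICIPANT"
  dupKeys <- names(which(table(keys[!emptied & !unmappedPart]) > 1))
  merged <- !emptied & !unmappedPart & keys %in% dupKeys
  rxOutcome[merged] <- "MERGED"
  rxOutcome[emptied] <- "EMPTIED"
  for (k in dupKeys) {
    ids <- rx$id[merged & keys == k]
    for (id in ids)
      say("WARNING", id,
          paste0("canonical equation collides with ",
                 paste(setdiff(ids, id), collapse = ", "),
                 "; these model reactions merge onto one namespace reaction"))
  }

  ## assemble the mapped model: merged (namespace id, compartment) species
  keep <- !emptied
  spNew <- sp
  spNew$id <- ifelse(is.na(target), sp$id, target)
  spNew$name <- ifelse(is.na(target), sp$name,
                       chem$name[match(target, chem$mnx_id)])
  spNew$formula <- ifelse(is.na(target), sp$formula,
                          chem$formula[match(target, chem$mnx_id)])
  spNew$charge <- ifelse(is.na(target), sp$charge,
                         chem$charge[match(target, chem$mnx_id)])
  spKey <- paste0(spNew$id, "@", spNew$compartment)
  spNew <- spNew[!duplicated(spKey), , drop = FALSE]
  ## species ids must stay unique per compartment in the flat id space
  spNew$id <- paste0(spNew$id, "_", spNew$compartment)
  eqsKept <- lapply(newEqs[keep], function(eq) {
    fix <- function(t) {
      if (nrow(t)) t$met <- paste0(t$met, "_", t$comp)
      t
    }
    .newEquation(fix(eq$left), fix(eq$right), eq$direction)
  })
  used <- unique(unlist(lapply(eqsKept, function(e) c(e$left$met, e$right$met))))
  spNew <- spNew[spNew$id %in% used | spNew$boundary, , drop = FALSE]
  rownames(spNew) <- NULL
  mapped <- new("GsmnModel", modelId = paste0(model@modelId, "_mapped"),
                compartments = model@compartments,
                species = spNew,
                reactions = rx[keep, , drop = FALSE],
                equations = eqsKept,
                objective = model@objective[model@objective %in% rx$id[keep]])

  report <- new("MappingReport",
    species = data.frame(species = sp$id, outcome = outcome, target = target,
                         stringsAsFactors = FALSE),
    reactions = data.frame(reaction = rx$id, outcome = rxOutcome,
                           target = rxTarget, stringsAsFactors = FALSE),
    messages = if (length(msgs)) do.call(rbind, msgs) else
      data.frame(severity = character(0), entity = character(0),
                 text = character(0), stringsAsFactors = FALSE))
  list(model = mapped, report = report)
}

#' Write a mapping report as TSV
#'
#' @param report a [MappingReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMappingReport <- function(report, path) {
  stopifnot(is(report, "MappingReport"))
  rows <- rbind(
    data.frame(entity = report@species$species, kind = "species",
               outcome = report@species$outcome,
               target = report@species$target, stringsAsFactors = FALSE),
    data.frame(entity = report@reactions$reaction, kind = "reaction",
               outcome = report@reactions$outcome,
               target = report@reactions$target, stringsAsFactors = FALSE))
  .writeTsv(rows, path, c("entity", "kind", "outcome", "target"))
  if (nrow(report@messages))
    cat(paste0("# ", report@messages$severity, " ", report@messages$entity,
               ": ", report@messages$text, collapse = "\n"),
        "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
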