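## TAB-delimited I/O: source database TSVs, the four distribution files
## (chem_prop / chem_xref / reac_prop / reac_xref) and structured logging.

## ---- logging ---------------------------------------------------------------

.LOG_LEVELS <- c(DEBUG = 0L, INFO = 1L, WARNING = 2L, ERROR = 3L)

.log <- function(level, ...) {
  min <- getOption("xrefforge.loglevel", "WARNING")
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[min]])
    message("[", level, "] ", ...)
  invisible(NULL)
}

## ---- generic TSV helpers ---------------------------------------------------

.writeTsv <- function(df, path, header) {
  lines <- paste0("#", paste(header, collapse = "\t"))
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    }), sep = "\t"))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")                 # fixed '\n', any platform
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

.readTsv <- function(path, expected) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[1], "#"))
    stop("missing '#' header line in ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  lines <- lines[-1]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, lapply(cells, function(x) {
    length(x) <- length(header); x
  })), stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  extra <- setdiff(header, expected)
  if (length(extra)) {
    .log("WARNING", "ignoring unknown column(s) in ", basename(path), ": ",
         paste(extra, collapse = ", "))
    warning("ignoring unknown column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df
}

## ---- source databases ------------------------------------------------------

#' Read a directory of source database TSVs
#'
#' Each source namespace contributes two files, `<prefix>.chem.tsv`
#' (columns `id`, `name`, `names`, `formula`, `charge`, `inchi`; an
#' optional `xrefs` column of imported metabolite cross-references is
#' read but deliberately never used by the reconciliation) and
#' `<prefix>.reac.tsv` (columns `id`, `equation`, `direction`, `xrefs`).
#'
#' @param dir directory path.
#' @return list with combined `metabolites` and `reactions` tables (each
#'   with a `prefix` column).
#' @export
readSourceDir <- function(dir) {
  chemFiles <- sort(list.files(dir, pattern = "\\.chem\\.tsv$", full.names = TRUE))
  if (!length(chemFiles)) stop("no *.chem.tsv files in ", dir)
  mets <- list(); rxns <- list()
  for (cf in chemFiles) {
    prefix <- sub("\\.chem\\.tsv$", "", basename(cf))
    cdf <- .readTsv(cf, c("id", "name", "names", "formula", "charge",
                          "inchi", "xrefs"))
    mets[[prefix]] <- data.frame(
      prefix = prefix, local_id = cdf$id, name = cdf$name,
      names = if ("names" %in% names(cdf)) cdf$names else NA_character_,
      formula = ifelse(nzchar(cdf$formula), cdf$formula, NA_character_),
      charge = suppressWarnings(as.numeric(cdf$charge)),
      inchi = ifelse(nzchar(cdf$inchi), cdf$inchi, NA_character_),
      stringsAsFactors = FALSE)
    rf <- file.path(dir, paste0(prefix, ".reac.tsv"))
    if (file.exists(rf)) {
      rdf <- .readTsv(rf, c("id", "equation", "direction", "xrefs"))
      rxns[[prefix]] <- data.frame(
        prefix = prefix, local_id = rdf$id, equation = rdf$equation,
        direction = rdf$direction, xrefs = rdf$xrefs,
        stringsAsFactors = FALSE)
    }
  }
  list(metabolites = do.call(rbind, c(mets, list(make.row.names = FALSE))),
       reactions = if (length(rxns))
         do.call(rbind, c(rxns, list(make.row.names = FALSE)))
       else data.frame(prefix = character(0), local_id = character(0),
                       equation = character(0), direction = character(0),
                       xrefs = character(0), stringsAsFactors = FALSE))
}

#' Write source database TSVs
#'
#' Inverse of [readSourceDir()]; used by the fixture generator.
#'
#' @param sources list with `metabolites` and `reactions` tables.
#' @param dir output directory (created if needed).
#' @param metXrefs optional data.frame (`ref`, `xrefs`) of imported
#'   metabolite cross-references to include (they are ignored by the
#'   reconciliation; the column exists to prove it).
#' @return `dir`, invisibly.
#' @export
writeSourceDir <- function(sources, dir, metXrefs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mets <- sources$metabolites
  for (prefix in sort(unique(mets$prefix))) {
    m <- mets[mets$prefix == prefix, , drop = FALSE]
    m <- m[order(m$local_id), , drop = FALSE]
    out <- data.frame(id = m$local_id, name = m$name, names = m$names,
                      formula = m$formula, charge = m$charge, inchi = m$inchi,
                      stringsAsFactors = FALSE)
    header <- c("id", "name", "names", "formula", "charge", "inchi")
    if (!is.null(metXrefs)) {
      ref <- paste0(prefix, ":", m$local_id)
      out$xrefs <- metXrefs$xrefs[match(ref, metXrefs$ref)]
      header <- c(header, "xrefs")
    }
    .writeTsv(out, file.path(dir, paste0(prefix, ".chem.tsv")), header)
    r <- sources$reactions[sources$reactions$prefix == prefix, , drop = FALSE]
    r <- r[order(r$local_id), , drop = FALSE]
    .writeTsv(data.frame(id = r$local_id, equation = r$equation,
                         direction = r$direction, xrefs = r$xrefs,
                         stringsAsFactors = FALSE),
              file.path(dir, paste0(prefix, ".reac.tsv")),
              c("id", "equation", "direction", "xrefs"))
  }
  invisible(dir)
}

## ---- distribution bundle ---------------------------------------------------

#' Write the TAB-delimited namespace distribution
#'
#' Writes `chem_prop.tsv`, `chem_xref.tsv`, `reac_prop.tsv`,
#' `reac_xref.tsv` into `dir`: UTF-8, one `#`-prefixed header line each,
#' rows sorted by ID so re-running writes byte-identical files.
#'
#' @param namespace an [MnxNamespace-class] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeDistribution <- function(namespace, dir) {
  stopifnot(is(namespace, "MnxNamespace"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chem <- namespace@chem[order(namespace@chem$mnx_id), , drop = FALSE]
  .writeTsv(data.frame(ID = chem$mnx_id, name = chem$name,
                       reference = chem$reference, formula = chem$formula,
                       charge = chem$charge, InChI = chem$inchi,
                       stringsAsFactors = FALSE),
            file.path(dir, "chem_prop.tsv"),
            c("ID", "name", "reference", "formula", "charge", "InChI"))
  cx <- namespace@chemXref[order(namespace@chemXref$source), , drop = FALSE]
  .writeTsv(data.frame(source = cx$source, ID = cx$mnx_id,
                       stringsAsFactors = FALSE),
            file.path(dir, "chem_xref.tsv"), c("source", "ID"))
  reac <- namespace@reac[order(namespace@reac$mnx_id), , drop = FALSE]
  .writeTsv(data.frame(ID = reac$mnx_id, equation = reac$equation,
                       direction = reac$direction, reference = reac$reference,
                       is_empty = tolower(as.character(reac$empty)),
                       balance = reac$balance, stringsAsFactors = FALSE),
            file.path(dir, "reac_prop.tsv"),
            c("ID", "equation", "direction", "reference", "is_empty", "balance"))
  rx <- namespace@reacXref[order(namespace@reacXref$source), , drop = FALSE]
  .writeTsv(data.frame(source = rx$source, ID = rx$mnx_id,
                       stringsAsFactors = FALSE),
            file.path(dir, "reac_xref.tsv"), c("source", "ID"))
  invisible(dir)
}

#' Read a TAB-delimited namespace distribution
#'
#' Inverse of [writeDistribution()] up to in-memory equality.  Unknown
#' columns (e.g. `mass`, `InChIKey`, `SMILES` in the public MNXref flat
#' files) are ignored with a warning; `mnx_equation` is accepted as an
#' alias for `equation`.  A cross-reference to a missing ID is an error.
#'
#' @param dir directory containing the four files.
#' @return an [MnxNamespace-class] object.
#' @export
readDistribution <- function(dir) {
  cp <- .readTsv(file.path(dir, "chem_prop.tsv"),
                 c("ID", "name", "reference", "formula", "charge", "InChI"))
  chem <- data.frame(mnx_id = cp$ID, name = cp$name, reference = cp$reference,
                     formula = ifelse(nzchar(cp$formula), cp$formula, NA_character_),
                     charge = suppressWarnings(as.numeric(cp$charge)),
                     inchi = if ("InChI" %in% names(cp))
                       ifelse(nzchar(cp$InChI), cp$InChI, NA_character_)
                     else NA_character_,
                     stringsAsFactors = FALSE)
  cx <- .readTsv(file.path(dir, "chem_xref.tsv"), c("source", "ID", "description"))
  bad <- which(!cx$ID %in% chem$mnx_id)
  if (length(bad))
    stop("chem_xref row ", bad[1], " references missing ID '", cx$ID[bad[1]], "'")
  rp <- .readTsv(file.path(dir, "reac_prop.tsv"),
                 c("ID", "equation", "mnx_equation", "direction", "reference",
                   "is_empty", "balance"))
  eqcol <- if ("equation" %in% names(rp)) rp$equation else rp$mnx_equation
  reac <- data.frame(mnx_id = rp$ID, equation = eqcol,
                     direction = if ("direction" %in% names(rp)) rp$direction
                     else "BIDIRECTIONAL",
                     reference = rp$reference,
                     empty = if ("is_empty" %in% names(rp)) rp$is_empty == "true"
                     else !nzchar(trimws(gsub("=", "", eqcol))),
                     balance = if ("balance" %in% names(rp)) rp$balance
                     else NA_character_,
                     stringsAsFactors = FALSE)
  rx <- .readTsv(file.path(dir, "reac_xref.tsv"), c("source", "ID", "description"))
  bad <- which(!rx$ID %in% reac$mnx_id)
  if (length(bad))
    stop("reac_xref row ", bad[1], " references missing ID '", rx$ID[bad[1]], "'")
  new("MnxNamespace", chem = chem,
      chemXref = data.frame(source = cx$source, mnx_id = cx$ID,
                            stringsAsFactors = FALSE),
      reac = reac,
      reacXref = data.frame(source = rx$source, mnx_id = rx$ID,
                            stringsAsFactors = FALSE))
}

#' Assemble an MnxNamespace from reconciliation outputs
#'
#' @param entries entry table from [assignIds()].
#' @param reactions list from [buildReactionNamespace()] (or `NULL`).
#' @return an [MnxNamespace-class] object.
#' @export
makeNamespace <- function(entries, reactions = NULL) {
  chem <- entries[, c("mnx_id", "name", "reference", "formula", "charge", "inchi")]
  xref <- list()
  for (i in seq_len(nrow(entries))) {
    if (!nzchar(entries$members[i])) next
    for (ref in strsplit(entries$members[i], ";", fixed = TRUE)[[1]])
      xref[[length(xref) + 1L]] <- data.frame(source = ref,
                                              mnx_id = entries$mnx_id[i],
                                              stringsAsFactors = FALSE)
  }
  chemXref <- if (length(xref)) do.call(rbind, xref)
    else data.frame(source = character(0), mnx_id = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(reactions)) {
    reac <- data.frame(mnx_id = character(0), equation = character(0),
                       direction = character(0), reference = character(0),
                       empty = logical(0), balance = character(0),
                       stringsAsFactors = FALSE)
    reacXref <- data.frame(source = character(0), mnx_id = character(0),
                           stringsAsFactors = FALSE)
  } else {
    reac <- reactions$reac[, c("mnx_id", "equation", "direction", "reference",
                               "empty", "balance")]
    reacXref <- reactions$reacXref
  }
  new("MnxNamespace", chem = chem, chemXref = chemXref,
      reac = reac, reacXref = reacXref)
}
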