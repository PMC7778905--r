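## InChI layer handling and structure keys.
##
## A standard InChI is a '/'-separated stack of layers: the Hill formula,
## connectivity (/c), hydrogen (/h), charge (/q), protonation (/p), stereo
## (/b /t /m /s) and isotope (/i...) layers.  The unified namespace merges
## metabolites whose structures differ only in protonation state, isotopic
## labelling or total charge, so the merge key deliberately elides those
## layers; stereochemistry is kept by default and only relaxed for
## reaction-context evidence.

.INCHI_KNOWN_TAGS <- c("c", "h", "q", "p", "b", "t", "m", "s", "i", "f", "r")

## Parse a signed integer layer content such as "+1", "-2" or the
## multi-component form "-1;+2" (optionally "2*-1").
.parseSignedLayer <- function(content, tag) {
  parts <- strsplit(content, ";", fixed = TRUE)[[1]]
  total <- 0
  for (p in parts) {
    if (p == "") next
    mult <- 1
    if (grepl("^[0-9]+\\*", p)) {
      mult <- as.numeric(sub("\\*.*$", "", p))
      p <- sub("^[0-9]+\\*", "", p)
    }
    if (!grepl("^[+-]?[0-9]+$", p))
      stop("non-integer content in /", tag, " layer: '", content, "'")
    total <- total + mult * as.numeric(p)
  }
  total
}

#' Parse an InChI string into its layers
#'
#' Splits a (standard) InChI into its slash-delimited layers.  Layers are
#' kept in input order so that [serializeInchi()] reproduces the original
#' string byte for byte; absent layers are absent (`NULL`), not empty
#' strings.  Everything from the first `/i` onwards is treated as the
#' isotope sublayer block.
#'
#' @param inchi character scalar starting with `"InChI="`.
#' @return an object of class `InChILayers`: a list with `version`,
#'   `formula`, `connectivity`, `h_layer`, `charge`, `protonation`,
#'   `stereo_b`, `stereo_t`, `stereo_m`, `stereo_s`, `isotope`, `raw`,
#'   `segments` (ordered tag/content table) and `unknown` (unrecognized
#'   layer tags).
#' @examples
#' parseInchi("InChI=1S/H2O/h1H2")$formula
#' @export
parseInchi <- function(inchi) {
  stopifnot(is.character(inchi), length(inchi) == 1L)
  if (!startsWith(inchi, "InChI="))
    stop("malformed InChI prefix (must start with 'InChI='): '", inchi, "'")
  body <- substring(inchi, 7L)
  segs <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(segs) < 1L || !segs[1] %in% c("1S", "1"))
    stop("malformed InChI version tag in '", inchi, "'")
  version <- segs[1]
  segs <- segs[-1]
  formula <- ""
  if (length(segs) && grepl("^[0-9]*[A-Z]", segs[1])) {
    formula <- segs[1]
    segs <- segs[-1]
  }
  tags <- substring(segs, 1L, 1L)
  contents <- substring(segs, 2L)
  out <- list(version = version, formula = formula, connectivity = NULL,
              h_layer = NULL, charge = 0L, protonation = 0L,
              stereo_b = NULL, stereo_t = NULL, stereo_m = NULL,
              stereo_s = NULL, isotope = NULL, raw = inchi)
  inIso <- FALSE
  isoParts <- character(0)
  unknown <- character(0)
  for (k in seq_along(tags)) {
    tg <- tags[k]; ct <- contents[k]
    if (inIso && tg %in% c("h", "t", "m", "s", "b")) {
      isoParts <- c(isoParts, segs[k]); next
    }
    switch(tg,
      c = { out$connectivity <- ct },
      h = { out$h_layer <- ct },
      q = { out$charge <- .parseSignedLayer(ct, "q") },
      p = { out$protonation <- .parseSignedLayer(ct, "p") },
      b = { out$stereo_b <- ct },
      t = { out$stereo_t <- ct },
      m = { out$stereo_m <- ct },
      s = { out$stereo_s <- ct },
      i = { inIso <- TRUE; isoParts <- c(isoParts, segs[k]) },
      { unknown <- c(unknown, tg) }
    )
  }
  if (length(isoParts)) out$isotope <- paste(isoParts, collapse = "/")
  out$segments <- data.frame(tag = tags, content = contents,
                             stringsAsFactors = FALSE)
  out$unknown <- unknown
  class(out) <- "InChILayers"
  out
}

#' Reserialize parsed InChI layers
#'
#' Inverse of [parseInchi()]: rebuilds the original string from the
#' ordered layer table (exact round trip for any accepted input).
#'
#' @param layers an `InChILayers` object.
#' @return character scalar.
#' @export
serializeInchi <- function(layers) {
  stopifnot(inherits(layers, "InChILayers"))
  body <- paste0("InChI=", layers$version)
  if (nzchar(layers$formula)) body <- paste0(body, "/", layers$formula)
  if (nrow(layers$segments))
    body <- paste0(body, "/", paste(paste0(layers$segments$tag,
                                           layers$segments$content),
                                    collapse = "/"))
  body
}

#' Structure-key layer policy
#'
#' Controls which InChI layers contribute to a merge key.  The default
#' drops protonation, total charge and isotope layers (so acid/base pairs,
#' isotopologues and charge variants collapse onto one key) while keeping
#' stereodescriptors, which are only relaxed pair-wise in reaction-context
#' evidence.
#'
#' @param drop_protonation,drop_isotopes,drop_charge,drop_stereo logical
#'   flags.
#' @return an object of class `StructureKeyPolicy`.
#' @export
keyPolicy <- function(drop_protonation = TRUE, drop_isotopes = TRUE,
                      drop_stereo = FALSE, drop_charge = TRUE) {
  out <- list(drop_protonation = drop_protonation,
              drop_isotopes = drop_isotopes,
              drop_stereo = drop_stereo,
              drop_charge = drop_charge)
  class(out) <- "StructureKeyPolicy"
  out
}

#' @rdname keyPolicy
#' @export
defaultKeyPolicy <- function() keyPolicy()

.policyId <- function(policy) {
  paste0("p", as.integer(policy$drop_protonation),
         "i", as.integer(policy$drop_isotopes),
         "s", as.integer(policy$drop_stereo),
         "q", as.integer(policy$drop_charge))
}

## Remove the hydrogen-count token from one Hill formula component,
## leaving heavy atoms (and a leading component multiplier) intact.
## 'H' as an element token is never followed by a lowercase letter, which
## distinguishes it from Hg, He, Ho, Hf, Hs.
.elideH <- function(component) {
  sub("H(?![a-z])[0-9]*", "", component, perl = TRUE)
}

#' Compute a normalized structure key
#'
#' The key skeleton is the Hill formula with the hydrogen count elided
#' (protonation changes only H count and charge) plus the connectivity
#' layer.  Multi-component formulas are keyed componentwise and sorted, so
#' salt-order differences cannot break equality.  Layer contributions are
#' included or dropped per the policy.
#'
#' @param layers an `InChILayers` object (see [parseInchi()]).
#' @param policy a `StructureKeyPolicy` (see [keyPolicy()]).
#' @return an object of class `StructureKey` with fields `skeleton`,
#'   `stereo` and `policy_id`.
#' @examples
#' k1 <- structureKey(parseInchi("InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)"))
#' k2 <- structureKey(parseInchi("InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)/p-1"))
#' identical(k1$skeleton, k2$skeleton)   # acid and conjugate base merge
#' @export
structureKey <- function(layers, policy = defaultKeyPolicy()) {
  stopifnot(inherits(layers, "InChILayers"),
            inherits(policy, "StructureKeyPolicy"))
  fcomps <- vapply(strsplit(layers$formula, ".", fixed = TRUE)[[1]],
                   .elideH, character(1))
  conn <- if (is.null(layers$connectivity)) "" else layers$connectivity
  ## keep trailing empty components (strsplit drops them)
  ccomps <- strsplit(paste0(conn, ";\r"), ";", fixed = TRUE)[[1]]
  ccomps <- ccomps[-length(ccomps)]
  if (length(ccomps) == length(fcomps) && length(fcomps) > 1L) {
    ## salt-order differences cannot break equality: sort the
    ## (formula component, connectivity component) pairs jointly
    ord <- order(fcomps, ccomps)
    fcomps <- fcomps[ord]; ccomps <- ccomps[ord]
    conn <- paste(ccomps, collapse = ";")
  } else {
    fcomps <- sort(fcomps)
  }
  skeleton <- paste0(paste(fcomps, collapse = "."), "|c:", conn)
  if (!policy$drop_charge && layers$charge != 0L)
    skeleton <- paste0(skeleton, "|q:", layers$charge)
  if (!policy$drop_protonation && layers$protonation != 0L)
    skeleton <- paste0(skeleton, "|p:", layers$protonation)
  if (!policy$drop_isotopes && !is.null(layers$isotope))
    skeleton <- paste0(skeleton, "|i:", layers$isotope)
  stereo <- ""
  if (!policy$drop_stereo) {
    parts <- c(b = layers$stereo_b, t = layers$stereo_t,
               m = layers$stereo_m, s = layers$stereo_s)
    if (length(parts))
      stereo <- paste(paste0(names(parts), ":", unlist(parts)), collapse = "/")
  }
  out <- list(skeleton = skeleton, stereo = stereo, policy_id = .policyId(policy))
  class(out) <- "StructureKey"
  out
}

#' Compare two structure keys
#'
#' Verdicts: `IDENTICAL` when skeleton and stereodescriptors agree;
#' `STEREO_RELAXED` when the skeletons agree and at least one key has no
#' stereodescriptors (a fully specified stereoisomer against an
#' unspecified one); `DIFFERENT` otherwise.  Two conflicting fully
#' specified stereo strings are `DIFFERENT` and are never merged by
#' reaction-context evidence.
#'
#' @param a,b `StructureKey` objects computed under the same policy.
#' @return character scalar, one of `"IDENTICAL"`, `"STEREO_RELAXED"`,
#'   `"DIFFERENT"`.
#' @export
similarStructures <- function(a, b) {
  stopifnot(inherits(a, "StructureKey"), inherits(b, "StructureKey"))
  if (!identical(a$policy_id, b$policy_id))
    stop("structure keys computed under different policies: ",
         a$policy_id, " vs ", b$policy_id)
  if (identical(a$skeleton, b$skeleton) && identical(a$stereo, b$stereo))
    return("IDENTICAL")
  if (identical(a$skeleton, b$skeleton) &&
      (!nzchar(a$stereo) || !nzchar(b$stereo)))
    return("STEREO_RELAXED")
  "DIFFERENT"
}

## Full key string (skeleton + stereo) for grouping.
.keyString <- function(key) paste0(key$skeleton, "||", key$stereo)
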