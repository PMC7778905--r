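## Shared helpers for the test suite.  Oracles here are deliberately
## independent of the package implementation paths they check.

## terse term-table / equation builders
tTerms <- function(mets, coeffs = rep(1, length(mets)), comp = "") {
  if (length(mets) == 0L)
    return(data.frame(met = character(0), num = numeric(0), den = numeric(0),
                      comp = character(0), stringsAsFactors = FALSE))
  data.frame(met = mets, num = coeffs, den = 1,
             comp = rep_len(comp, length(mets)), stringsAsFactors = FALSE)
}

tEq <- function(left, right, direction = "BIDIRECTIONAL") {
  eq <- list(left = left, right = right, direction = direction)
  class(eq) <- "Equation"
  eq
}

mkMet <- function(prefix, id, name, inchi = NA_character_,
                  formula = NA_character_, charge = 0) {
  data.frame(prefix = prefix, local_id = id, name = name,
             names = NA_character_, formula = formula, charge = charge,
             inchi = inchi, stringsAsFactors = FALSE)
}

mkRxn <- function(prefix, id, equation, direction = "LR", xrefs = "") {
  data.frame(prefix = prefix, local_id = id, equation = equation,
             direction = direction, xrefs = xrefs, stringsAsFactors = FALSE)
}

## independent elemental accounting: count atoms with a regex scan,
## written without the package's parseFormula
countAtoms <- function(formula) {
  out <- c()
  for (m in regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]) {
    el <- gsub("[0-9]", "", m)
    n <- gsub("[A-Za-z]", "", m)
    n <- if (nzchar(n)) as.numeric(n) else 1
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + n
  }
  out
}

## a handful of real standard InChIs plus grammar-generated ones, for
## round-trip and layer-injection tests
realInchis <- c(
  "InChI=1S/H2O/h1H2",
  "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)",
  "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)/p-1",
  "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)/t2-/m0/s1",
  "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)/t2-/m1/s1",
  "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)",
  "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2/t2-,3-,4+,5-,6?/m1/s1",
  "InChI=1S/C10H16N5O13P3/c11-8-5-9(13-2-12-8)15(3-14-5)10-7(17)6(16)4(26-10)1-25-30(21,22)28-31(23,24)27-29(18,19)20/h2-4,6-7,10,16-17H,1H2,(H,21,22)(H,23,24)(H2,11,12,13)(H2,18,19,20)/t4-,6-,7-,10-/m1/s1",
  "InChI=1S/p+1",
  "InChI=1S/2C2H4O2.Ca/c2*1-2(3)4;/h2*1H3,(H,3,4);/q;;+2/p-2",
  "InChI=1/CH4/h1H4",
  "InChI=1S/H2O/h1H2/i/hD2")

grammarInchis <- function(n = 50) {
  vapply(seq_len(n), function(i) {
    cfg <- fixtureConfig(seed = 1)
    xrefforge:::.compoundInchi(i, stereo = i %% 3 == 0, protonated = i %% 2 == 0)
  }, character(1))
}

## build the figure-1 style namespace once for mapping tests
buildToyNamespace <- function() {
  fx <- generateSources(fixturePreset("figure1"))
  rec <- reconcileSources(fx$sources)
  rns <- buildReactionNamespace(
    fx$sources$reactions, rec$mapping,
    chemProps = data.frame(met = rec$entries$mnx_id,
                           formula = rec$entries$formula,
                           charge = rec$entries$charge,
                           stringsAsFactors = FALSE))
  makeNamespace(rec$entries, rns)
}

## minimal GsmnModel construction
mkModel <- function(ids, eqs, lb, ub, species = NULL, modelId = "toy",
                    boundary = FALSE, names = ids) {
  mets <- unique(unlist(lapply(eqs, function(e) c(e$left$met, e$right$met))))
  if (is.null(species))
    species <- data.frame(id = mets, name = mets, compartment = "c",
                          boundary = rep_len(boundary, length(mets)),
                          formula = NA_character_, charge = NA_real_,
                          annotations = "", stringsAsFactors = FALSE)
  methods::new("GsmnModel", modelId = modelId, compartments = "c",
               species = species,
               reactions = data.frame(id = ids, name = names, lb = lb, ub = ub,
                                      reversible = lb < 0,
                                      stringsAsFactors = FALSE),
               equations = eqs, objective = character(0))
}

## truth pairs from a generator ground-truth partition
truthPairKeys <- function(partition) {
  unlist(lapply(partition, function(cls) {
    cls <- sort(cls)
    if (length(cls) < 2) return(NULL)
    cmb <- utils::combn(cls, 2)
    paste(cmb[1, ], cmb[2, ])
  }))
}

mergedPairKeys <- function(partition) {
  mp <- mergedPairs(partition)
  paste(mp$a, mp$b)
}
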