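## SBML reading/writing and model mapping diagnostics.

minimalL3 <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '  xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '  level="3" version="1" fbc:required="false">',
    '<model id="mini" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_c" name="alpha" compartment="c" boundaryCondition="false" constant="false"/>',
    '<species id="M_b_c" name="beta" compartment="c" boundaryCondition="false" constant="false">',
    '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"><rdf:Bag>',
    '<rdf:li rdf:resource="https://identifiers.org/chebi/CHEBI:15377"/>',
    '</rdf:Bag></rdf:RDF></annotation></species>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lb0" value="0" constant="true"/>',
    '<parameter id="ub50" value="50" constant="true"/>',
    '<parameter id="lbm" value="-50" constant="true"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub50">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_b_c" stoichiometry="2" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R2" reversible="true" fast="false" fbc:lowerFluxBound="lbm" fbc:upperFluxBound="ub50">',
    '<listOfReactants><speciesReference species="M_b_c" constant="true"/></listOfReactants>',
    '</reaction>',
    '<reaction id="R3" reversible="true" fast="false" fbc:lowerFluxBound="lbm" fbc:upperFluxBound="ub50">',
    '<listOfProducts><speciesReference species="M_a_c" constant="true"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), path)
  path
}

minimalL2 <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mini2">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="sA" name="A" compartment="c"/>',
    '<species id="sB" name="B" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="sA"/></listOfReactants>',
    '<listOfProducts><speciesReference species="sB"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R2">',
    '<listOfReactants><speciesReference species="sA"/></listOfReactants>',
    '<listOfProducts><speciesReference species="sB"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-7"/>',
    '<parameter id="UPPER_BOUND" value="9"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), path)
  path
}

test_that("level 3 + FBC bounds, stoichiometry and annotations are read", {
  f <- minimalL3(withr::local_tempfile(fileext = ".xml"))
  m <- readSbmlModel(f)
  rx <- reactionTable(m)
  expect_equal(nrow(rx), 3L)
  expect_equal(rx$lb, c(0, -50, -50))
  expect_equal(rx$ub, c(50, 50, 50))
  eq <- modelEquations(m)[[1]]
  expect_equal(eq$right$num, 2)
  expect_equal(speciesTable(m)$annotations[2], "chebi:15377")
  ## R2/R3 have an empty side -> boundary reactions
  prob <- fluxProblem(m)
  expect_equal(prob@boundary, c(FALSE, TRUE, TRUE))
})

test_that("level 2 defaults: reversible attribute and kinetic-law bounds", {
  f <- minimalL2(withr::local_tempfile(fileext = ".xml"))
  m <- readSbmlModel(f)
  rx <- reactionTable(m)
  expect_equal(rx$lb, c(0, -7))         # irreversible default, then explicit
  expect_equal(rx$ub, c(1000, 9))       # big-M default, then explicit
  expect_true(speciesTable(m)$boundary[speciesTable(m)$id == "sB"])
  expect_error(readSbmlModel(withr::local_tempfile(fileext = ".xml")),
               "invalid SBML")
})

test_that("SBML write -> read preserves stoichiometric structure", {
  gm <- generateModel(fixturePreset("status-mix"))
  f <- withr::local_tempfile(fileext = ".xml")
  writeSbmlModel(gm$model, f)
  m2 <- readSbmlModel(f)
  expect_equal(nrow(reactionTable(m2)), nrow(reactionTable(gm$model)))
  expect_equal(reactionTable(m2)$lb, reactionTable(gm$model)$lb)
  expect_equal(reactionTable(m2)$ub, reactionTable(gm$model)$ub)
  ## same S matrix up to row order
  p1 <- fluxProblem(gm$model); p2 <- fluxProblem(m2)
  expect_equal(dim(p1@S), dim(p2@S))
  o1 <- p1@S[order(rownames(p1@S)), ]
  o2 <- p2@S[order(rownames(p2@S)), ]
  expect_equal(unname(o1), unname(o2))
})

test_that("a model already in namespace ids maps one-to-one with no warnings", {
  ns <- buildToyNamespace()
  m <- mkModel(c("R1"), list(tEq(tTerms("MNXM2", comp = "c"),
                                 tTerms("MNXM3", comp = "c"), "LR")),
               lb = 0, ub = 1000)
  mp <- mapModel(m, ns)
  expect_true(all(speciesOutcomes(mp$report)$outcome == "MAPPED_BY_ID"))
  expect_true(all(reactionOutcomes(mp$report)$outcome == "ONE_TO_ONE"))
  expect_equal(nrow(mappingMessages(mp$report)), 0L)
})

test_that("merged species empty a reaction and the report says so", {
  ns <- buildToyNamespace()
  sp <- data.frame(id = c("s_a", "s_c", "s_y"),
                   name = c("xylunate", "unrelated name", "yronate"),
                   compartment = "c", boundary = FALSE,
                   formula = NA_character_, charge = NA_real_,
                   annotations = c("alpha:a", "beta:c", ""),
                   stringsAsFactors = FALSE)
  m <- mkModel(c("R_empty", "R_conv"),
               list(tEq(tTerms("s_a", comp = "c"), tTerms("s_c", comp = "c")),
                    tEq(tTerms("s_a", comp = "c"), tTerms("s_y", comp = "c"), "LR")),
               lb = c(-1000, 0), ub = c(1000, 1000), species = sp)
  mp <- mapModel(m, ns)
  so <- speciesOutcomes(mp$report)
  expect_equal(so$outcome[so$species == "s_a"], "MAPPED_BY_ANNOTATION")
  expect_equal(so$target[so$species %in% c("s_a", "s_c")], c("MNXM2", "MNXM2"))
  expect_equal(so$outcome[so$species == "s_y"], "MAPPED_BY_NAME")
  ro <- reactionOutcomes(mp$report)
  expect_equal(ro$outcome[ro$reaction == "R_empty"], "EMPTIED")
  expect_equal(ro$outcome[ro$reaction == "R_conv"], "ONE_TO_ONE")
  expect_true(any(grepl("disappear", mappingMessages(mp$report)$text)))
  ## the emptied reaction is gone from the mapped model
  expect_equal(reactionTable(mp$model)$id, "R_conv")
})

test_that("unmapped species keep local ids and flag their reactions", {
  ns <- buildToyNamespace()
  m <- mkModel("R1", list(tEq(tTerms("mystery", comp = "c"),
                              tTerms("MNXM3", comp = "c"), "LR")),
               lb = 0, ub = 10)
  mp <- mapModel(m, ns)
  so <- speciesOutcomes(mp$report)
  expect_equal(so$outcome[so$species == "mystery"], "UNMAPPED")
  expect_equal(reactionOutcomes(mp$report)$outcome, "UNMAPPED_PARTICIPANT")
  expect_true("mystery_c" %in% speciesTable(mp$model)$id)
})

test_that("reaction outcome counts are conserved and coefficients unchanged", {
  ns <- buildToyNamespace()
  sp <- data.frame(id = c("s_a", "s_b", "s_y", "s_z"),
                   name = c("xylunate", "XYLUNATE", "yronate", "nobody"),
                   compartment = "c", boundary = FALSE,
                   formula = NA_character_, charge = NA_real_,
                   annotations = c("alpha:a", "beta:b", "alpha:d", ""),
                   stringsAsFactors = FALSE)
  m <- mkModel(c("Rdup1", "Rdup2", "Rzero", "Rext"),
               list(tEq(tTerms("s_a", 2, comp = "c"), tTerms("s_y", 3, comp = "c"), "LR"),
                    tEq(tTerms("s_b", 2, comp = "c"), tTerms("s_y", 3, comp = "c"), "LR"),
                    tEq(tTerms("s_a", comp = "c"), tTerms("s_b", comp = "c")),
                    tEq(tTerms("s_z", comp = "c"), tTerms("s_y", comp = "c"), "LR")),
               lb = c(0, 0, -5, 0), ub = rep(10, 4), species = sp)
  mp <- mapModel(m, ns)
  ro <- reactionOutcomes(mp$report)
  tab <- table(ro$outcome)
  expect_equal(sum(tab), 4L)
  expect_equal(unname(tab["MERGED"]), 2L)       # Rdup1 + Rdup2 collide
  expect_equal(unname(tab["EMPTIED"]), 1L)
  expect_equal(unname(tab["UNMAPPED_PARTICIPANT"]), 1L)
  ## merged reactions keep their coefficients
  eqs <- modelEquations(mp$model)
  expect_equal(eqs[[1]]$left$num, 2)
  expect_equal(eqs[[1]]$right$num, 3)
})

test_that("mapping report TSV is written", {
  ns <- buildToyNamespace()
  m <- mkModel("R1", list(tEq(tTerms("MNXM2", comp = "c"),
                              tTerms("MNXM3", comp = "c"), "LR")),
               lb = 0, ub = 10)
  mp <- mapModel(m, ns)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMappingReport(mp$report, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "#entity"))
  expect_equal(length(lines), 1L + 2L + 1L)   # header + 2 species + 1 reaction
})
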