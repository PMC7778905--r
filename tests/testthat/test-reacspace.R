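test_that("rewriting substitutes, combines, cancels and may empty", {
  idmap <- c(A = "A", B = "B", C = "C")
  eq <- parseEquation("A + B --> C")
  expect_identical(formatEquation(rewriteEquation(eq, idmap)), "A + B --> C")

  ## like-term combination
  eq2 <- rewriteEquation(parseEquation("A + A --> B"), idmap)
  expect_identical(formatEquation(eq2), "2 A --> B")

  ## acid/base merge empties the reaction
  eq3 <- rewriteEquation(parseEquation("Xacid --> Xbase"),
                         c(Xacid = "MNXM7", Xbase = "MNXM7"))
  expect_true(isEmptyEquation(eq3))

  ## partial cancellation removes min(coeff)
  eq4 <- rewriteEquation(parseEquation("2 A + B --> A + C"), idmap)
  expect_identical(formatEquation(eq4), "A + B --> C")

  expect_error(rewriteEquation(parseEquation("A --> Z"), idmap), "unmapped")
  cs <- rewriteEquation(parseEquation("A --> Z"), idmap, partial = TRUE)
  expect_identical(cs$right$met, "Z")
})

test_that("cancellation conserves per-element mass deltas", {
  props <- data.frame(met = c("A", "B", "C"),
                      formula = c("C2H6O", "CH4", "C3H8O"),
                      charge = c(0, -1, 1), stringsAsFactors = FALSE)
  for (txt in c("2 A + B --> A + C", "A + 2 B --> B + C", "3 A --> A + B")) {
    eq <- parseEquation(txt)
    before <- balanceCheck(eq, props)
    after <- balanceCheck(rewriteEquation(eq, c(A = "A", B = "B", C = "C")), props)
    expect_equal(before$element_delta, after$element_delta)
    expect_equal(before$charge_delta, after$charge_delta)
  }
})

test_that("balance verdicts: identity, proton-only, unknown", {
  water <- data.frame(met = "H2O", formula = "H2O", charge = 0,
                      stringsAsFactors = FALSE)
  rep0 <- balanceCheck(parseEquation("H2O = H2O"), water)
  expect_identical(rep0$verdict, "BALANCED")
  expect_equal(length(rep0$element_delta), 0L)

  ## hexokinase written without the proton, physiological charges;
  ## expected deltas recomputed with the independent atom counter
  props <- data.frame(
    met = c("glc", "atp", "g6p", "adp"),
    formula = c("C6H12O6", "C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2"),
    charge = c(0, -4, -2, -3), stringsAsFactors = FALSE)
  eq <- parseEquation("glc + atp --> g6p + adp")
  rep1 <- balanceCheck(eq, props)
  oracle <- c()
  for (i in seq_len(nrow(props))) {
    sgn <- if (props$met[i] %in% c("glc", "atp")) -1 else 1
    for (el in names(countAtoms(props$formula[i])))
      oracle[el] <- (if (el %in% names(oracle)) oracle[[el]] else 0) +
        sgn * countAtoms(props$formula[i])[[el]]
  }
  oracle <- oracle[oracle != 0]
  expect_equal(rep1$element_delta[order(names(rep1$element_delta))],
               oracle[order(names(oracle))])
  expect_equal(unname(rep1$element_delta[["H"]]), -1)
  expect_equal(rep1$charge_delta, -1)
  expect_identical(rep1$verdict, "PROTON_ONLY")

  ## any participant without formula -> UNKNOWN
  rep2 <- balanceCheck(parseEquation("glc + mystery --> g6p"), props)
  expect_identical(rep2$verdict, "UNKNOWN")

  expect_error(balanceCheck(parseEquation("x = x"),
                            data.frame(met = "x", formula = "NotAFormula!",
                                       charge = 0)), "unparseable")
})

test_that("proton balancing adds MNXM1 on the deficient side only", {
  props <- data.frame(
    met = c("glc", "atp", "g6p", "adp", "MNXM1"),
    formula = c("C6H12O6", "C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2", "H"),
    charge = c(0, -4, -2, -3, 1), stringsAsFactors = FALSE)
  eq <- parseEquation("glc + atp --> g6p + adp")
  rep1 <- balanceCheck(eq, props)
  fixed <- protonBalance(eq, rep1)
  expect_true("MNXM1" %in% fixed$right$met)
  expect_identical(balanceCheck(fixed, props)$verdict, "BALANCED")

  ## H delta +1 on the right -> proton goes left
  props2 <- data.frame(met = c("u", "v", "MNXM1"),
                       formula = c("CH4", "CH5", "H"),
                       charge = c(0, 1, 1), stringsAsFactors = FALSE)
  eqLR <- parseEquation("u --> v")
  fixed2 <- protonBalance(eqLR, balanceCheck(eqLR, props2))
  expect_true("MNXM1" %in% fixed2$left$met)
  expect_identical(balanceCheck(fixed2, props2)$verdict, "BALANCED")

  ## n = 2 deficit -> coefficient-2 proton term
  props3 <- data.frame(met = c("w", "z", "MNXM1"),
                       formula = c("CH4", "CH6", "H"),
                       charge = c(0, 2, 1), stringsAsFactors = FALSE)
  eqW <- parseEquation("w --> z")
  fixed3 <- protonBalance(eqW, balanceCheck(eqW, props3))
  i <- which(fixed3$left$met == "MNXM1")
  expect_equal(fixed3$left$num[i], 2)
  expect_identical(balanceCheck(fixed3, props3)$verdict, "BALANCED")

  ## never "fix" a non-proton imbalance
  expect_error(protonBalance(parseEquation("H2O = H2O"),
                             balanceCheck(parseEquation("H2O = H2O"),
                                          data.frame(met = "H2O",
                                                     formula = "H2O",
                                                     charge = 0))),
               "PROTON_ONLY")
})

test_that("transported protons are relabelled by the min rule", {
  eq <- parseEquation("MNXM1@in + X@in --> MNXM1@out + Y@in")
  out <- classifyTransportedProtons(eq)
  expect_true("MNXM01" %in% out$left$met)
  expect_true("MNXM01" %in% out$right$met)
  expect_false("MNXM1" %in% c(out$left$met, out$right$met))

  ## all protons in one compartment: unchanged
  eq2 <- parseEquation("MNXM1@c + X@c --> MNXM1@c + Y@c")
  out2 <- classifyTransportedProtons(eq2)
  expect_false("MNXM01" %in% c(out2$left$met, out2$right$met))

  ## 2 in, 1 out: one pair relabelled, one balancing proton remains
  eq3 <- parseEquation("2 MNXM1@in + X@in --> MNXM1@out + Y@in")
  out3 <- classifyTransportedProtons(eq3)
  l1 <- out3$left[out3$left$met == "MNXM1", ]
  l0 <- out3$left[out3$left$met == "MNXM01", ]
  expect_equal(l1$num, 1); expect_equal(l0$num, 1)
  expect_equal(out3$right$met[out3$right$met != "Y"], "MNXM01")
})

test_that("canonical keys are invariant to scaling, orientation, permutation", {
  k <- function(txt) canonicalKey(parseEquation(txt))$key
  expect_identical(k("2 A --> 2 B"), k("B = A"))
  expect_false(k("A + B --> C") == k("A + B --> D"))
  expect_identical(k("4 A + 2 B --> 2 C"), k("2 A + B --> C"))
  expect_identical(k("A + B = C"), k("B + A = C"))
  expect_identical(k("1/2 A = 1/3 B"), k("3 A = 2 B"))
  expect_identical(canonicalKey(parseEquation(" = "))$key, "EMPTY")

  ## property: random equations, permuted terms and swapped sides
  set.seed(42)
  mets <- paste0("M", 1:6)
  for (i in 1:50) {
    nl <- sample(1:3, 1); nr <- sample(1:3, 1)
    lm <- sample(mets, nl); rm <- sample(setdiff(mets, lm), nr)
    lc <- sample(1:3, nl, TRUE); rc <- sample(1:3, nr, TRUE)
    eq <- tEq(tTerms(lm, lc), tTerms(rm, rc), "LR")
    perm <- tEq(tTerms(rev(rm), rev(rc)), tTerms(rev(lm), rev(lc)), "RL")
    expect_identical(canonicalKey(eq)$key, canonicalKey(perm)$key)
  }
})

test_that("reaction namespace groups by canonical key with Rhea-first references", {
  fx <- generateSources(fixturePreset("figure1"))
  rec <- reconcileSources(fx$sources)
  rns <- buildReactionNamespace(
    fx$sources$reactions, rec$mapping,
    chemProps = data.frame(met = rec$entries$mnx_id,
                           formula = rec$entries$formula,
                           charge = rec$entries$charge,
                           stringsAsFactors = FALSE))
  nonEmpty <- rns$reac[!rns$reac$empty, ]
  expect_equal(nrow(nonEmpty), 1L)
  expect_equal(length(strsplit(nonEmpty$members, ";")[[1]]), 4L)
  ## direction disagreement among members folds to BIDIRECTIONAL
  expect_equal(nonEmpty$direction, "BIDIRECTIONAL")

  ## no merges: one unified reaction per input
  mets <- rbind(mkMet("d1", "A", "a"), mkMet("d1", "B", "b"),
                mkMet("d1", "C", "c"))
  pt <- mergeIdenticalStructures(mets)
  rec2 <- assignIds(pt, mets)
  mapping <- stats::setNames(rec2$mnx_id[match(paste0("d1:", c("A", "B", "C")),
                                               rec2$members)],
                             paste0("d1:", c("A", "B", "C")))
  rxns <- rbind(mkRxn("d1", "r1", "A --> B"), mkRxn("d1", "r2", "B --> C"))
  rns2 <- buildReactionNamespace(rxns, mapping)
  expect_equal(nrow(rns2$reac), 2L)
  expect_equal(nrow(rns2$reacXref), 2L)

  ## a rheaR member wins the reference over alphabetical order
  rxns3 <- rbind(mkRxn("aaa", "r1", "A --> B"), mkRxn("rheaR", "r9", "A2 --> B2"))
  mets3 <- rbind(mkMet("aaa", "A", "a"), mkMet("aaa", "B", "b"),
                 mkMet("rheaR", "A2", "a"), mkMet("rheaR", "B2", "b"))
  map3 <- c("aaa:A" = "MNXM2", "aaa:B" = "MNXM3",
            "rheaR:A2" = "MNXM2", "rheaR:B2" = "MNXM3")
  rns3 <- buildReactionNamespace(rxns3, map3)
  expect_equal(nrow(rns3$reac), 1L)
  expect_equal(rns3$reac$reference, "rheaR:r9")
})

test_that("direction folding across merged members follows the 3x3 table", {
  ## hand oracle: same underlying flow direction -> that direction;
  ## disagreement or any bidirectional partner -> BIDIRECTIONAL
  mets <- rbind(mkMet("d1", "A", "a"), mkMet("d1", "B", "b"),
                mkMet("d2", "A2", "a"), mkMet("d2", "B2", "b"))
  map <- c("d1:A" = "MNXM2", "d1:B" = "MNXM3",
           "d2:A2" = "MNXM2", "d2:B2" = "MNXM3")
  cases <- list(
    list(e1 = "A --> B", e2 = "A2 --> B2", expected = "LR"),
    list(e1 = "A --> B", e2 = "B2 <-- A2", expected = "LR"),
    list(e1 = "A --> B", e2 = "A2 = B2", expected = "BIDIRECTIONAL"),
    list(e1 = "A --> B", e2 = "B2 --> A2", expected = "BIDIRECTIONAL"),
    list(e1 = "A = B", e2 = "B2 = A2", expected = "BIDIRECTIONAL"),
    list(e1 = "B <-- A", e2 = "B2 <-- A2", expected = "LR"))
  for (cs in cases) {
    rx <- rbind(mkRxn("d1", "r1", cs$e1,
                      direction = parseEquation(cs$e1)$direction),
                mkRxn("d2", "r2", cs$e2,
                      direction = parseEquation(cs$e2)$direction))
    out <- buildReactionNamespace(rx, map)
    expect_equal(nrow(out$reac), 1L)
    ## the stored direction is relative to the canonical orientation
    ## (MNXM2 side first); LR here means MNXM2 -> MNXM3
    expect_equal(out$reac$direction, cs$expected,
                 label = paste(cs$e1, "|", cs$e2))
  }
})

test_that("grouping partitions non-empty rewritten reactions", {
  fx <- generateSources(fixtureConfig(seed = 4))
  rec <- reconcileSources(fx$sources)
  rns <- buildReactionNamespace(fx$sources$reactions, rec$mapping)
  nMembers <- sum(vapply(strsplit(rns$reac$members, ";"), length, 1L))
  expect_equal(nMembers, nrow(fx$sources$reactions))
  expect_equal(nrow(rns$reacXref), nrow(fx$sources$reactions))
  expect_false(anyDuplicated(rns$reacXref$source) > 0)
})
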