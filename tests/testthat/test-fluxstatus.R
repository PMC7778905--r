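## A/a/b/B classification against exact rational oracles.

test_that("flux ranges: dead ends, open chains, relaxation regimes", {
  ## isolated "-> X" with X consumed nowhere: zero in every regime
  m <- mkModel("R1", list(tEq(tTerms(character(0)), tTerms("X", comp = "c"), "LR")),
               lb = 0, ub = 1000)
  prob <- fluxProblem(m)
  for (regime in c("ORIGINAL", "BOUNDARY_RELAXED", "ALL_RELAXED"))
    expect_equal(unname(fluxRange(prob, 1, regime)), c(0, 0))

  ## open reversible chain: middle reaction spans [-M, M]
  m2 <- mkModel(c("EX1", "Rmid", "EX2"),
                list(tEq(tTerms(character(0)), tTerms("A", comp = "c")),
                     tEq(tTerms("A", comp = "c"), tTerms("B", comp = "c")),
                     tEq(tTerms("B", comp = "c"), tTerms(character(0)))),
                lb = rep(-1000, 3), ub = rep(1000, 3))
  prob2 <- fluxProblem(m2)
  expect_equal(unname(fluxRange(prob2, "Rmid", "ORIGINAL")), c(-1000, 1000))
})

test_that("status examples: dead end B, gated exchange a, reversed-edge cycle b", {
  ## producer of a dead-end metabolite
  m <- mkModel("R1", list(tEq(tTerms("S", comp = "c"), tTerms("D", comp = "c"), "LR")),
               lb = 0, ub = 10)
  expect_equal(classifyStatus(fluxProblem(m), 1), "B")

  ## runs only when the export-only exchange is reversed
  gm <- generateModel(fixtureConfig(model_blocks = c(A = 2, a = 2, b = 0, B = 0)))
  prob <- fluxProblem(gm$model)
  st <- statusTable(statusProfile(prob))
  expect_equal(sort(st$status[st$reaction %in% c("EX_a", "Ra_hub")]), c("a", "a"))

  ## internal cycle with one reversed edge: b, confirmed by the nullspace oracle
  gm2 <- generateModel(fixtureConfig(model_blocks = c(A = 0, a = 0, b = 3, B = 0)))
  prob2 <- fluxProblem(gm2$model)
  for (r in seq_along(gm2$statuses)) {
    expect_equal(classifyStatus(prob2, r), "b")
    expect_true(nullspaceFluxTest(prob2@S, r))
  }

  ## an irreversible consistent 2-cycle carries loop flux under original
  ## bounds: it is A, not blocked (steady state allows internal loops)
  m3 <- mkModel(c("Rf", "Rr"),
                list(tEq(tTerms("P", comp = "c"), tTerms("Q", comp = "c"), "LR"),
                     tEq(tTerms("Q", comp = "c"), tTerms("P", comp = "c"), "LR")),
                lb = c(0, 0), ub = c(10, 10))
  expect_equal(classifyStatus(fluxProblem(m3), 1), "A")
})

test_that("LP classification agrees with exact vertex enumeration exhaustively", {
  ## every fixture network with <= 8 reactions from the motif catalogue
  blockSets <- list(c(A = 1, a = 0, b = 0, B = 0),
                    c(A = 2, a = 0, b = 0, B = 0),
                    c(A = 0, a = 0, b = 0, B = 2),
                    c(A = 0, a = 0, b = 2, B = 0),
                    c(A = 0, a = 0, b = 4, B = 1),
                    c(A = 2, a = 2, b = 0, B = 0),
                    c(A = 3, a = 2, b = 0, B = 1),
                    c(A = 2, a = 3, b = 0, B = 2),
                    c(A = 4, a = 0, b = 2, B = 2),
                    c(A = 2, a = 2, b = 2, B = 2))
  for (blocks in blockSets) {
    gm <- generateModel(fixtureConfig(model_blocks = blocks))
    expect_lte(length(gm$statuses), 8L)
    prob <- fluxProblem(gm$model, bigM = 10)
    for (r in seq_along(gm$statuses)) {
      lp <- classifyStatus(prob, r)
      exact <- exactClassifyStatus(prob, r)
      expect_identical(lp, exact,
                       label = paste(paste(names(blocks), blocks, collapse = ","),
                                     "reaction", r))
      expect_identical(lp, unname(gm$statuses[r]))
    }
  }
})

test_that("nullspace test agrees with ALL_RELAXED LP ranges on random matrices", {
  set.seed(2024)
  for (trial in 1:200) {
    S <- matrix(sample(-2:2, 48, TRUE, prob = c(.1, .2, .4, .2, .1)), 6, 8)
    prob <- fluxProblemFromMatrices(S, rep(-1000, 8), rep(1000, 8))
    for (r in 1:8) {
      rg <- fluxRange(prob, r, "ALL_RELAXED")
      lp <- rg["max"] > prob@tol || rg["min"] < -prob@tol
      expect_identical(nullspaceFluxTest(S, r), unname(lp))
    }
  }
})

test_that("status can only improve along the relaxation ladder", {
  set.seed(31)
  for (i in 1:40) {
    blocks <- c(A = sample(c(0, 1, 2, 4), 1), a = sample(c(0, 2, 3), 1),
                b = sample(c(0, 2), 1), B = sample(0:2, 1))
    if (blocks["a"] > 0 && blocks["A"] < 2) blocks["A"] <- 2
    if (sum(blocks) == 0) blocks["B"] <- 1
    gm <- generateModel(fixtureConfig(model_blocks = blocks, seed = i))
    prob <- fluxProblem(gm$model)
    for (r in seq_along(gm$statuses)) {
      carries <- vapply(c("ORIGINAL", "BOUNDARY_RELAXED", "ALL_RELAXED"),
                        function(rg) {
                          v <- fluxRange(prob, r, rg)
                          v["max"] > prob@tol || v["min"] < -prob@tol
                        }, logical(1))
      expect_true(all(diff(as.integer(carries)) >= 0),
                  label = paste("monotone regimes, reaction", r))
    }
  }
})

test_that("statuses are invariant under positive column rescaling", {
  gm <- generateModel(fixtureConfig(model_blocks = c(A = 3, a = 2, b = 2, B = 1)))
  prob <- fluxProblem(gm$model)
  base <- statusTable(statusProfile(prob))$status
  set.seed(5)
  for (i in 1:10) {
    k <- sample(ncol(prob@S), 1)
    c0 <- sample(c(2, 5, 10, 0.5), 1)
    S2 <- prob@S; S2[, k] <- S2[, k] * c0
    lb2 <- prob@lb; ub2 <- prob@ub
    lb2[k] <- lb2[k] / c0; ub2[k] <- ub2[k] / c0
    prob2 <- fluxProblemFromMatrices(S2, lb2, ub2, prob@boundary)
    expect_identical(statusTable(statusProfile(prob2))$status, base)
  }
})

test_that("statuses are stable across tolerances", {
  gm <- generateModel(fixtureConfig(model_blocks = c(A = 3, a = 2, b = 2, B = 2)))
  profiles <- lapply(c(1e-9, 1e-7, 1e-5), function(tol)
    statusTable(statusProfile(fluxProblem(gm$model, tol = tol)))$status)
  expect_identical(profiles[[1]], profiles[[2]])
  expect_identical(profiles[[2]], profiles[[3]])
})

test_that("bounds excluding zero are clamped with a warning", {
  m <- mkModel(c("EX1", "R", "EX2"),
               list(tEq(tTerms(character(0)), tTerms("A", comp = "c")),
                    tEq(tTerms("A", comp = "c"), tTerms("B", comp = "c"), "LR"),
                    tEq(tTerms("B", comp = "c"), tTerms(character(0)))),
               lb = c(-10, 2, -10), ub = c(10, 10, 10))
  expect_warning(prob <- fluxProblem(m), "clamped")
  expect_equal(prob@lb[2], 0)
})

test_that("conservation check: identity, theorem case and a planted flip", {
  gm <- generateModel(fixtureConfig(model_blocks = c(A = 3, a = 2, b = 0, B = 1)))
  prof <- statusProfile(fluxProblem(gm$model))
  ids <- statusTable(prof)$reaction
  cc <- conservationCheck(prof, prof, stats::setNames(ids, ids))
  expect_true(cc$conserved)
  expect_equal(nrow(cc$changed), 0L)
  expect_error(conservationCheck(prof, prof, c(nope = "nope")), "not in")

  ## bijective species mapping cannot change statuses (isomorphic S)
  m2 <- gm$model
  sp <- speciesTable(m2); sp$id <- paste0("NS_", sp$id)
  eqs <- lapply(modelEquations(m2), function(eq) {
    fix <- function(t) { if (nrow(t)) t$met <- paste0("NS_", t$met); t }
    tEq(fix(eq$left), fix(eq$right), eq$direction)
  })
  m2 <- mkModel(reactionTable(gm$model)$id, eqs, reactionTable(gm$model)$lb,
                reactionTable(gm$model)$ub, species = sp)
  prof2 <- statusProfile(fluxProblem(m2))
  cc2 <- conservationCheck(prof, prof2, stats::setNames(ids, ids))
  expect_true(cc2$conserved)

  ## merging two metabolites unblocks a reaction that does not involve them
  terms1 <- function(x) tTerms(x, comp = "c")
  before <- mkModel(c("EX1", "R4", "R3", "R5"),
                    list(tEq(terms1(character(0)), terms1("X1")),
                         tEq(terms1("X1"), terms1("Y1"), "LR"),
                         tEq(terms1("Y1"), terms1("Y2"), "LR"),
                         tEq(terms1("Y2"), terms1("X2"), "LR")),
                    lb = c(-10, 0, 0, 0), ub = rep(10, 4))
  after <- mkModel(c("EX1", "R4", "R3", "R5"),
                   list(tEq(terms1(character(0)), terms1("M")),
                        tEq(terms1("M"), terms1("Y1"), "LR"),
                        tEq(terms1("Y1"), terms1("Y2"), "LR"),
                        tEq(terms1("Y2"), terms1("M"), "LR")),
                   lb = c(-10, 0, 0, 0), ub = rep(10, 4))
  pb <- statusProfile(fluxProblem(before))
  pa <- statusProfile(fluxProblem(after))
  ids2 <- statusTable(pb)$reaction
  cc3 <- conservationCheck(pb, pa, stats::setNames(ids2, ids2))
  expect_false(cc3$conserved)
  ## R3 changed although neither X1 nor X2 participates in it
  expect_true("R3" %in% cc3$changed$reaction)
  expect_equal(cc3$changed$before[cc3$changed$reaction == "R3"], "B")
  expect_equal(cc3$changed$after[cc3$changed$reaction == "R3"], "A")
})

test_that("the LP solver matches exact ranges on small random polytopes", {
  set.seed(77)
  for (i in 1:60) {
    m <- sample(2:4, 1); n <- sample(3:6, 1)
    S <- matrix(sample(-2:2, m * n, TRUE), m, n)
    lb <- sample(c(-5L, -3L, 0L), n, TRUE)
    ub <- sample(c(0L, 3L, 5L), n, TRUE)
    r <- sample(n, 1)
    obj <- numeric(n); obj[r] <- 1
    lpMax <- solveFluxLP(obj, S, lb, ub, TRUE)$value
    lpMin <- solveFluxLP(obj, S, lb, ub, FALSE)$value
    exact <- exactFluxRange(S, lb, ub, r)
    expect_equal(lpMax, unname(exact["max"]), tolerance = 1e-7)
    expect_equal(lpMin, unname(exact["min"]), tolerance = 1e-7)
  }
})
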