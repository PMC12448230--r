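# Two-step read simulator: presets, consensus evolution, read emission,
# structural variants, determinism and moment checks.

test_that("error-profile presets reproduce the published aggregate rates", {
  for (lvl in 1:3) {
    expected <- switch(lvl,
                       c(1.30, 0.087, 0.34),
                       c(1.49, 4.0635, 1.75),
                       c(1.68, 8.04, 3.16))
    r <- errorRates(errorProfilePreset(lvl))
    expect_equal(unname(r), expected, tolerance = 1e-12)
  }
  # level 2 is the midpoint of levels 1 and 3, component-wise
  r1 <- errorRates(errorProfilePreset(1))
  r3 <- errorRates(errorProfilePreset(3))
  expect_equal(unname(errorRates(errorProfilePreset(2))), unname((r1 + r3) / 2))
  expect_error(errorProfilePreset(4), "unknown")
})

test_that("evolution and weight presets match the study parameterizations", {
  e2 <- evolutionPreset(2)
  expect_equal(e2@gamma[1, ], c(0.9989, 0.001, 0.0001))
  expect_equal(e2@gamma[1, ], e2@gamma[2, ])
  expect_equal(e2@beta, c(1e-4, 1e-4))
  e3 <- evolutionPreset(3)
  expect_equal(e3@gamma[3, ], c(0.98572, 0.0139, 0.00038))
  expect_equal(e3@beta[3], 0.00038)
  expect_equal(mixtureAlpha(weightsPreset(2)), c(0.6, 0.4))
  expect_equal(mixtureAlpha(weightsPreset(3)), c(0.4, 0.4, 0.2))
})

test_that("consensus evolution honors degenerate and stochastic regimes", {
  ref <- randomRef(300, seed = 2)
  ident <- simulateConsensus(ref, EvolutionParams(gamma = c(1, 0, 0), beta = 0),
                             seed = 1)
  expect_identical(hapStates(ident), strsplit(as.character(ref), "")[[1]])
  expect_length(hapInsertions(ident), 0)

  allSub <- simulateConsensus(ref, EvolutionParams(gamma = c(0, 1, 0), beta = 0),
                              seed = 1)
  expect_true(all(hapStates(allSub) != strsplit(as.character(ref), "")[[1]]))
  expect_false(any(hapStates(allSub) == "-"))
})

test_that("evolved substitution fraction matches the generating rate", {
  # moment check at the study's K=2 evolution rate
  ref <- randomRef(20000, seed = 8)
  params <- EvolutionParams(gamma = c(0.9989, 0.001, 0.0001), beta = 1e-4)
  refCh <- strsplit(as.character(ref), "")[[1]]
  nSub <- 0; nTot <- 0
  for (seed in 1:15) {
    h <- simulateConsensus(ref, params, seed = seed)
    st <- hapStates(h)
    nSub <- nSub + sum(st != refCh & st != "-")
    nTot <- nTot + length(st)
  }
  se <- sqrt(0.001 * 0.999 / nTot)
  expect_lt(abs(nSub / nTot - 0.001), 3 * se)
})

test_that("structural variants follow the configured protocol", {
  ref <- randomRef(1500, seed = 3)
  base <- simulateConsensus(ref, EvolutionParams(gamma = c(1, 0, 0), beta = 0),
                            seed = 1)
  expect_identical(applyStructuralVariants(base, list(n = 0)), base)

  del <- applyStructuralVariants(base, list(n = 1,
                                            typeProbs = c(insertion = 0, deletion = 1,
                                                          duplication = 0, inversion = 0,
                                                          translocation = 0),
                                            lengths = 50L),
                                 seed = 4)
  expect_equal(sum(hapStates(del) == "-") - sum(hapStates(base) == "-"), 50L)

  # SV length uniform over {50, 100, 500}: moment check on 900 draws
  set.seed(9)
  lens <- integer(0)
  for (i in 1:900) {
    sv <- applyStructuralVariants(base, list(n = 1, typeProbs = c(
      insertion = 1, deletion = 0, duplication = 0, inversion = 0,
      translocation = 0)))
    lens <- c(lens, nchar(hapInsertions(sv)[[1]]))
  }
  freq <- table(factor(lens, levels = c(50, 100, 500))) / length(lens)
  se <- sqrt((1 / 3) * (2 / 3) / length(lens))
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  expect_error(applyStructuralVariants(base, list(n = 1, lengths = 2000L)),
               "shorter")
})

test_that("read emission is exact when the profile is error-free", {
  ref <- randomRef(200, seed = 5)
  hap <- simulateConsensus(ref, EvolutionParams(gamma = c(0.95, 0.03, 0.02),
                                                beta = 0.01), seed = 2)
  prof <- SequencingErrorProfile(p2 = 0, p3 = 0, p4 = 0)
  rd <- simulateRead(hap, prof, readLength = 100, start = 21, seed = 3)
  expect_identical(readStates(rd), hapStates(hap)[21:120])
  win <- hapInsertions(hap)
  win <- win[as.integer(names(win)) >= 21 & as.integer(names(win)) <= 119]
  expect_identical(rd@insertions, win[order(as.integer(names(win)))])
})

test_that("generator-recorded events round-trip through the summarizer", {
  ref <- randomRef(400, seed = 6)
  hap <- simulateConsensus(ref, EvolutionParams(gamma = c(0.97, 0.02, 0.01),
                                                beta = 0.005), seed = 7)
  prof <- errorProfilePreset(3)  # heaviest error load
  for (seed in 1:100) {
    out <- simulateRead(hap, prof, readLength = 150, start = 30, seed = seed,
                        withEvents = TRUE)
    ev <- summarizeReadEvents(out$read, hap)
    expect_equal(ev@nCorrect, out$events@nCorrect)
    expect_equal(ev@nMismatch, out$events@nMismatch)
    expect_equal(sort(ev@delSegments), sort(out$events@delSegments))
    expect_equal(sort(ev@insSegments), sort(out$events@insSegments))
    expect_equal(ev@nGapsNoInsertion, out$events@nGapsNoInsertion)
  }
})

test_that("emitted mismatch fraction matches the Level-1 profile", {
  ref <- randomRef(5000, seed = 10)
  hap <- simulateConsensus(ref, evolutionPreset(2), k = 1, seed = 11)
  prof <- errorProfilePreset(1)
  nMis <- 0; nComp <- 0
  for (seed in 1:40) {
    out <- simulateRead(hap, prof, readLength = 5000, start = 1, seed = seed,
                        withEvents = TRUE)
    nMis <- nMis + out$events@nMismatch
    nComp <- nComp + out$events@nCorrect + out$events@nMismatch +
      sum(out$events@delSegments)
  }
  se <- sqrt(0.013 * 0.987 / nComp)
  expect_lt(abs(nMis / nComp - 0.013), 3 * se)
})

test_that("dataset simulation respects weights, counts and determinism", {
  ref <- randomRef(800, seed = 12)
  cfg1 <- SimulationConfig(K = 1, nReads = 50, evolution = EvolutionParams(
    gamma = c(0.99, 0.008, 0.002), beta = 1e-4),
    weights = MixtureWeights(1), profile = errorProfilePreset(1),
    readLength = readLengthModel("fixed", length = 300), seed = 13)
  ds1 <- simulateDataset(ref, cfg1)
  expect_length(datasetReads(ds1), 50)
  expect_true(all(vapply(datasetReads(ds1), function(r) r@truthSource,
                         integer(1)) == 1L))

  # binomial moment check on the K=2 mixing weight alpha = (0.6, 0.4)
  cfg2 <- SimulationConfig(K = 2, nReads = 4000, evolution = evolutionPreset(2),
                           weights = weightsPreset(2),
                           profile = errorProfilePreset(1),
                           readLength = readLengthModel("fixed", length = 200),
                           seed = 14)
  ds2 <- simulateDataset(ref, cfg2)
  frac1 <- mean(vapply(datasetReads(ds2), function(r) r@truthSource,
                       integer(1)) == 1L)
  expect_lt(abs(frac1 - 0.6), 3 * sqrt(0.6 * 0.4 / 4000))

  # bit-identical datasets under the same seed
  dsA <- simulateDataset(ref, cfg1)
  expect_identical(lapply(datasetReads(ds1), readStates),
                   lapply(datasetReads(dsA), readStates))
  expect_identical(datasetTruthSnvs(ds1), datasetTruthSnvs(dsA))

  # truth SNV bookkeeping is consistent with the truth haplotypes
  refCh <- strsplit(as.character(ref), "")[[1]]
  for (k in seq_along(datasetHaplotypes(ds2))) {
    st <- hapStates(datasetHaplotypes(ds2)[[k]])
    expect_identical(datasetTruthSnvs(ds2)[[k]],
                     which(st != refCh & st != "-"))
  }
})

test_that("scenario presets parse and the grid enumerates the full design", {
  cfg <- scenarioConfig("K3-level2", nReads = 70, seed = 3)
  expect_equal(cfg@K, 3L)
  expect_equal(mixtureAlpha(cfg@weights), c(0.4, 0.4, 0.2))
  expect_equal(unname(errorRates(cfg@profile)), c(1.49, 4.0635, 1.75))
  expect_error(scenarioConfig("K4-level1"), "unknown scenario")

  grid <- scenarioGrid()
  expect_equal(nrow(grid), 12L)
  expect_equal(sort(unique(grid$K)), c(2L, 3L))
  expect_equal(sort(unique(grid$level)), 1:3)
  expect_equal(sort(unique(grid$nReads)), c(50L, 100L))
  expect_false(any(duplicated(grid[, c("scenario", "nReads")])))
})

test_that("4-number evolution tuples parse with renormalization", {
  p <- evolutionParamsFromTuple(c(0.9989, 0.001, 0.0001, 0.0001))
  expect_equal(p@gamma[1, ], c(0.9989, 0.001, 0.0001))
  expect_equal(p@beta, 0.0001)
  q <- evolutionParamsFromTuple(c(2, 1, 1, 0.5))  # renormalized simplex
  expect_equal(q@gamma[1, ], c(0.5, 0.25, 0.25))
})
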