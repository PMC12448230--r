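# CAEM fitting: AE/C/M steps, annealing, monotonicity, recovery, and
# cross-validated ploidy selection.

test_that("initialization is deterministic and K=1 gives the plurality call", {
  d <- separableDataset(L0 = 40, nSub = 12, nReads = 12, seed = 21)
  s1 <- initializeState(d$reads, d$ref, K = 2, seed = 9)
  s2 <- initializeState(d$reads, d$ref, K = 2, seed = 9)
  expect_identical(stateResponsibilities(s1), stateResponsibilities(s2))
  expect_identical(hapStates(stateConsensuses(s1)[[1]]),
                   hapStates(stateConsensuses(s2)[[1]]))

  sk1 <- initializeState(d$reads, d$ref, K = 1, seed = 1)
  # single group: plurality over all reads; with error-free reads from two
  # haplotypes every position matches one of the two truths
  plur <- hapStates(stateConsensuses(sk1)[[1]])
  ok <- plur == hapStates(d$haps[[1]]) | plur == hapStates(d$haps[[2]])
  expect_true(all(ok))
  expect_error(initializeState(d$reads[1], d$ref, K = 2), "at least K")
})

test_that("aeStep gives Bayes posteriors at T=1, the closed form for K=2, and
           flattens as T grows", {
  d <- separableDataset(L0 = 30, nSub = 10, nReads = 8, seed = 31)
  st <- initializeState(d$reads, d$ref, K = 2, seed = 2)
  resp <- aeStep(d$reads, st, d$ref)
  expect_equal(rowSums(resp), rep(1, 8))

  # closed form: with responsibilities r1 = 1/(1 + exp(-(logw1 - logw2)))
  prof <- stateProfile(st)
  alpha <- mixtureAlpha(stateWeights(st))
  logw <- vapply(1:2, function(k) log(alpha[k]) +
    readLogLik(summarizeReadEvents(d$reads[[1]], stateConsensuses(st)[[k]],
                                   d$ref), prof), numeric(1))
  expect_equal(resp[1, 1], 1 / (1 + exp(-(logw[1] - logw[2]))),
               tolerance = 1e-12)

  # annealing limit: responsibilities tend to uniform
  stHot <- st
  stHot@temperature <- 1e6
  respHot <- aeStep(d$reads, stHot, d$ref)
  expect_equal(respHot, matrix(0.5, 8, 2), tolerance = 1e-3,
               ignore_attr = TRUE)

  # all-zero-likelihood row is reported with the read name
  stBad <- st
  stBad@profile <- SequencingErrorProfile(p2 = 0, p3 = 0, p4 = 0)
  mut <- d$reads
  badStates <- readStates(mut[[1]])
  badStates[1] <- setdiff(CHARS, c(badStates[1], hapStates(d$haps[[1]])[mut[[1]]@start],
                                   hapStates(d$haps[[2]])[mut[[1]]@start]))[1]
  mut[[1]] <- AlignedRead("oddball", mut[[1]]@start, mut[[1]]@end, badStates)
  expect_error(aeStep(mut, stBad, d$ref), "oddball")
})

test_that("cStep takes the argmax with deterministic tie-breaking", {
  resp <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  expect_identical(cStep(resp), c(1L, 1L, 2L))
  # invariant under strictly monotone row rescaling
  expect_identical(cStep(resp^3 / rowSums(resp^3)), cStep(resp))
})

test_that("mStep recovers closed-form estimates from classified counts", {
  set.seed(41)
  ref <- randomRef(24, seed = 41)
  refCh <- strsplit(as.character(ref), "")[[1]]
  mkRead <- function(nm, st) AlignedRead(nm, 1, 24, st)
  # two perfect reads pin the consensus; one read deletes 1 position, one
  # deletes a 3-run => lambda_del MLE = mean(c(1,3)) - 1 = 1
  st1 <- refCh
  st2 <- refCh; st2[5] <- "-"
  st3 <- refCh; st3[12:14] <- "-"
  reads <- list(mkRead("a", st1), mkRead("b", st1), mkRead("c", st2),
                mkRead("d", st3))
  st <- initializeState(reads, ref, K = 1, labels = rep(1L, 4))
  out <- mStep(reads, rep(1L, 4), ref, st)
  # consensus pinned to the reference by the perfect majority, so the two
  # deletion runs stay read events: lambda_del = mean(c(1, 3)) - 1
  expect_identical(hapStates(stateConsensuses(out)[[1]]), refCh)
  prof <- stateProfile(out)
  expect_equal(prof@lambdaDel, 1.0)
  # objective slot equals the complete-data log-likelihood of the outputs
  obj <- completeDataLogLik(reads, rep(1L, 4), stateConsensuses(out),
                            stateWeights(out), prof, stateEvolution(out), ref)
  expect_equal(stateObjective(out), obj, tolerance = 1e-10)

  # mixture weights are the assignment count ratios
  simple <- list(mkRead("x", st1), mkRead("y", st1), mkRead("z", st1))
  st2K <- initializeState(simple, ref, K = 2, labels = c(1L, 1L, 2L))
  out2 <- mStep(simple, c(1L, 1L, 2L), ref, st2K)
  expect_equal(mixtureAlpha(stateWeights(out2)), c(2 / 3, 1 / 3))
})

test_that("mStep re-seeds empty haplotypes with the worst-fitting read", {
  d <- separableDataset(L0 = 30, nSub = 10, nReads = 6, seed = 51)
  st <- initializeState(d$reads, d$ref, K = 2, seed = 3)
  expect_warning(out <- mStep(d$reads, rep(1L, 6), d$ref, st), "re-seeded")
  expect_equal(sort(unique(cStep(stateResponsibilities(out)))), 1:2)
})

test_that("updated consensus attains the exhaustive-search optimum on a
           masked micro instance", {
  set.seed(61)
  ref <- randomRef(10, seed = 61)
  refCh <- strsplit(as.character(ref), "")[[1]]
  # three reads covering positions 4..8 with two planted substitutions
  st <- refCh[4:8]
  st[2] <- setdiff(CHARS, st[2])[1]
  reads <- list(AlignedRead("a", 4, 8, st),
                AlignedRead("b", 4, 8, st),
                AlignedRead("c", 4, 8, refCh[4:8]))
  labels <- c(1L, 1L, 1L)
  state <- initializeState(reads, ref, K = 1, labels = labels)
  out <- mStep(reads, labels, ref, state)
  entryProf <- stateProfile(state)
  entryEvo <- stateEvolution(state)
  w <- MixtureWeights(1)
  objOf <- function(states) {
    completeDataLogLik(reads, labels, list(ConsensusHaplotype(1, states)), w,
                       entryProf, entryEvo, ref)
  }
  fitted <- hapStates(stateConsensuses(out)[[1]])
  fittedObj <- objOf(fitted)
  # exhaustive search over all 5^5 assignments of the covered positions
  grid <- expand.grid(rep(list(c(CHARS, "-")), 5), stringsAsFactors = FALSE)
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    cand <- refCh
    cand[4:8] <- unlist(grid[r, ])
    best <- max(best, objOf(cand))
  }
  expect_gte(fittedObj + 1e-9, best)
})

test_that("CAEM recovers well-separated haplotypes exactly and is
           deterministic under a fixed seed", {
  d <- separableDataset(L0 = 60, nSub = 20, nReads = 40, seed = 71)
  fit <- runCAEM(d$reads, d$ref, 2, FitConfig(nRestarts = 3, seed = 4))
  expect_equal(cpr(d$haps, fittedHaplotypes(fit), d$ref), 1.0)
  agree <- max(mean(fit@labels == d$truth), mean(fit@labels == 3 - d$truth))
  expect_equal(agree, 1.0)
  # recovered haplotypes equal the truth exactly (up to label permutation)
  chi <- bestMatching(d$haps, fittedHaplotypes(fit), d$ref)
  for (k in 1:2)
    expect_identical(hapStates(fittedHaplotypes(fit)[[k]]),
                     hapStates(d$haps[[chi[k]]]))

  fit2 <- runCAEM(d$reads, d$ref, 2, FitConfig(nRestarts = 3, seed = 4))
  expect_identical(fit@labels, fit2@labels)
  expect_identical(fitTrace(fit), fitTrace(fit2))
  expect_equal(stateObjective(fit@state), stateObjective(fit2@state))
})

test_that("objective trace is non-decreasing at T = 1 and K = 1 fits are
           restart-invariant", {
  for (seed in 1:4) {
    cfg <- separationConfig(K = 2, nReads = 30, level = seed %% 3 + 1,
                            seed = seed)
    ds <- simulateDataset(randomRef(300, seed = seed + 100), cfg)
    fit <- runCAEM(datasetReads(ds), datasetReference(ds), 2,
                   FitConfig(nRestarts = 2, seed = seed))
    tr <- fitTrace(fit)
    for (r in unique(tr$restart)) {
      atFloor <- tr[tr$restart == r & tr$temperature <= 1 + 1e-9, ]
      if (nrow(atFloor) > 1)
        expect_true(all(diff(atFloor$objective) >= -1e-8),
                    label = sprintf("monotone trace, seed %d restart %d", seed, r))
    }
  }

  d <- separableDataset(L0 = 40, nSub = 10, nReads = 10, seed = 81)
  f1 <- runCAEM(d$reads, d$ref, 1, FitConfig(nRestarts = 1, seed = 1))
  f5 <- runCAEM(d$reads, d$ref, 1, FitConfig(nRestarts = 5, seed = 99))
  expect_identical(hapStates(fittedHaplotypes(f1)[[1]]),
                   hapStates(fittedHaplotypes(f5)[[1]]))
})

test_that("label permutation leaves the objective unchanged", {
  d <- separableDataset(L0 = 40, nSub = 14, nReads = 16, seed = 91)
  fit <- runCAEM(d$reads, d$ref, 2, FitConfig(nRestarts = 2, seed = 7))
  st <- fit@state
  obj <- completeDataLogLik(d$reads, fit@labels, stateConsensuses(st),
                            stateWeights(st), stateProfile(st),
                            stateEvolution(st), d$ref)
  swapped <- completeDataLogLik(
    d$reads, 3L - fit@labels, rev(stateConsensuses(st)),
    MixtureWeights(rev(mixtureAlpha(stateWeights(st)))), stateProfile(st),
    EvolutionParams(gamma = stateEvolution(st)@gamma[2:1, , drop = FALSE],
                    beta = stateEvolution(st)@beta[2:1]), d$ref)
  expect_equal(obj, swapped, tolerance = 1e-10)
})

test_that("cross-validated selection recovers the generating ploidy", {
  ref <- randomRef(300, seed = 200)
  ds <- simulateDataset(ref, separationConfig(K = 2, nReads = 50, seed = 17))
  sel <- selectK(datasetReads(ds), ref, 1:3,
                 FitConfig(nRestarts = 2, seed = 5))
  expect_equal(chosenK(sel), 2L)
  expect_equal(nrow(selectionTable(sel)), 3L)

  sel2 <- selectK(datasetReads(ds), ref, 1:3, FitConfig(nRestarts = 2, seed = 5))
  expect_identical(sel@folds, sel2@folds)
  expect_equal(selectionTable(sel), selectionTable(sel2))

  dsK1 <- simulateDataset(ref, separationConfig(K = 1, nReads = 40, seed = 23))
  selK1 <- selectK(datasetReads(dsK1), ref, 1:3, FitConfig(nRestarts = 2, seed = 6))
  expect_equal(chosenK(selK1), 1L)

  expect_warning(selectK(d0 <- datasetReads(ds)[1:4], ref, 1:2,
                         FitConfig(nRestarts = 1, seed = 1)),
                 "in-sample")
})

test_that("tied evolution estimation shares one parameter row across
           haplotypes", {
  d <- separableDataset(L0 = 50, nSub = 16, nReads = 20, seed = 95)
  fit <- runCAEM(d$reads, d$ref, 2,
                 FitConfig(nRestarts = 2, seed = 2, tieEvolution = TRUE))
  evo <- stateEvolution(fit@state)
  expect_equal(evo@gamma[1, ], evo@gamma[2, ])
  expect_equal(evo@beta[1], evo@beta[2])
})
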