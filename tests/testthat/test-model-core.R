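# Event summarization and likelihood terms of the two-stage model.

test_that("consensus-vs-reference events classify positions correctly", {
  ref <- ReferenceSequence("r", "ACGT")

  ident <- summarizeConsensusEvents(ConsensusHaplotype(1, "ACGT"), ref)
  expect_equal(ident@nMatch, 4L)
  expect_equal(ident@nSubstitution, 0L)
  expect_equal(ident@nDeletion, 0L)
  expect_equal(ident@nInsertion, 0L)

  # per-position hand classification: A=match, G!=C sub, G=match, - del
  ev <- summarizeConsensusEvents(ConsensusHaplotype(1, "AGG-"), ref)
  expect_equal(c(ev@nMatch, ev@nSubstitution, ev@nDeletion, ev@nInsertion),
               c(2L, 1L, 1L, 0L))

  ref2 <- ReferenceSequence("r", "AC")
  ev2 <- summarizeConsensusEvents(
    ConsensusHaplotype(1, "AC", insertions = c("1" = "G")), ref2)
  expect_equal(c(ev2@nMatch, ev2@nSubstitution, ev2@nDeletion, ev2@nInsertion),
               c(2L, 0L, 0L, 1L))

  expect_error(summarizeConsensusEvents(ConsensusHaplotype(1, "ACG"), ref),
               "length")
})

test_that("evolution log-likelihood matches the closed form and -Inf rules", {
  # all mass on the observed outcome
  ev0 <- ConsensusEvents(5, 0, 0, 0)
  p0 <- EvolutionParams(gamma = c(1, 0, 0), beta = 1e-300)
  expect_equal(evolutionLogLik(ev0, p0, L0 = 5), 4 * log(1 - 1e-300))

  # the K=2 preset applied to a 5-base identical consensus
  p <- EvolutionParams(gamma = c(0.9989, 0.001, 0.0001), beta = 1e-4)
  expect_equal(evolutionLogLik(ev0, p, L0 = 5),
               5 * log(0.9989) + 4 * log(0.9999), tolerance = 1e-12)

  # impossible event
  evSub <- ConsensusEvents(4, 1, 0, 0)
  expect_identical(evolutionLogLik(evSub, p0, L0 = 5), -Inf)
})

test_that("read-vs-consensus events classify runs and skip consensus deletions", {
  hap <- ConsensusHaplotype(1, "ACGTA")

  ident <- summarizeReadEvents(AlignedRead("r1", 1, 5, "ACGTA"), hap)
  expect_equal(ident@nCorrect, 5L)
  expect_equal(ident@nMismatch, 0L)
  expect_length(ident@delSegments, 0)
  expect_equal(ident@nGapsNoInsertion, 4L)

  # hand run-length classification: 2-long deletion segment
  ev <- summarizeReadEvents(AlignedRead("r2", 1, 5, "AC--A"), hap)
  expect_equal(ev@nCorrect, 3L)
  expect_equal(ev@nMismatch, 0L)
  expect_equal(ev@delSegments, 2L)
  expect_length(ev@insSegments, 0)
  expect_equal(ev@nGapsNoInsertion, 4L)

  # consensus deletion: position skipped from the per-position comparison,
  # the read base observed there becomes an insertion at the adjacent gap
  hapDel <- ConsensusHaplotype(1, "AC-TA")
  evSkip <- summarizeReadEvents(AlignedRead("r3", 1, 5, "AC-TA"), hapDel)
  expect_equal(evSkip@nCorrect, 4L)  # comparable positions only
  expect_length(evSkip@delSegments, 0)
  evOver <- summarizeReadEvents(AlignedRead("r4", 1, 5, "ACGTA"), hapDel)
  expect_equal(evOver@nCorrect, 4L)
  expect_equal(evOver@insSegments, 1L)

  expect_error(summarizeReadEvents(AlignedRead("r5", 4, 6, "ACG"), hap),
               "beyond")
})

test_that("gap insertion comparison follows the matching rules", {
  hap <- ConsensusHaplotype(1, "ACGTA", insertions = c("2" = "GG"))
  # identical insertion: no event, gap counts as no-insertion-error
  evSame <- summarizeReadEvents(
    AlignedRead("r", 1, 5, "ACGTA", insertions = c("2" = "GG")), hap)
  expect_length(evSame@insSegments, 0)
  expect_equal(evSame@nGapsNoInsertion, 4L)
  # read-only insertion elsewhere: one insertion segment
  evR <- summarizeReadEvents(
    AlignedRead("r", 1, 5, "ACGTA", insertions = c("2" = "GG", "3" = "T")), hap)
  expect_equal(evR@insSegments, 1L)
  expect_equal(evR@nGapsNoInsertion, 3L)
  # consensus-only insertion: deletion segment of its length
  evC <- summarizeReadEvents(AlignedRead("r", 1, 5, "ACGTA"), hap)
  expect_equal(evC@delSegments, 2L)
  # differing insertions: mismatch-equivalents per differing base
  evD <- summarizeReadEvents(
    AlignedRead("r", 1, 5, "ACGTA", insertions = c("2" = "GAT")), hap)
  expect_equal(evD@nMismatch, 2L)  # G=G, A!=G, +1 length difference
})

test_that("truncated Poisson log-pmf is the shifted Poisson and normalizes", {
  lam <- 1.7
  expect_equal(truncPoisLogPmf(1L, lam), -lam)
  expect_equal(truncPoisLogPmf(3L, 2.0), 2 * log(2) - 2 - log(2))
  expect_equal(sum(exp(truncPoisLogPmf(1:200, 3.2))), 1, tolerance = 1e-10)
  expect_error(truncPoisLogPmf(0L, 1), "length")
  expect_error(truncPoisLogPmf(2L, 0), "rate")
})

test_that("read log-likelihood matches the term-by-term closed form", {
  perfect <- ReadEvents(5, 0, nGapsNoInsertion = 4)
  degenerate <- SequencingErrorProfile(p2 = 0, p3 = 0, p4 = 0)
  expect_equal(readLogLik(perfect, degenerate), 0)

  ev <- ReadEvents(3, 1, delSegments = 2L, nGapsNoInsertion = 4)
  prof <- SequencingErrorProfile(p2 = 0.05, p3 = 0.05, p4 = 0.01,
                                 lambdaIns = 1, lambdaDel = 1)
  # mismatch carries the uniform-content log(1/3); the deletion segment of
  # length 2 contributes log p3 + dpois(1, 1, log)
  expect_equal(readLogLik(ev, prof),
               3 * log(0.9) + (log(0.05) - log(3)) + log(0.05) +
                 dpois(1, 1, log = TRUE) + 4 * log(0.99),
               tolerance = 1e-12)

  evBad <- ReadEvents(3, 1, nGapsNoInsertion = 4)
  expect_identical(readLogLik(evBad, degenerate), -Inf)
})

test_that("log-likelihoods equal the literal product oracle on random instances", {
  prof <- testProfile()
  for (seed in 1:40) {
    inst <- randomInstance(seed)
    ev <- summarizeReadEvents(inst$read, inst$cons)
    expect_equal(readLogLik(ev, prof),
                 oracleReadLogLik(inst$read, inst$cons, prof),
                 tolerance = 1e-10, label = sprintf("read oracle seed %d", seed))
    gam <- c(0.9, 0.06, 0.04)
    expect_equal(
      evolutionLogLik(summarizeConsensusEvents(inst$cons, inst$ref),
                      EvolutionParams(gamma = gam, beta = 0.1), length(inst$ref)),
      oracleEvoLogLik(inst$cons, inst$ref, gam, 0.1),
      tolerance = 1e-10, label = sprintf("evo oracle seed %d", seed))
  }
})

test_that("event counts conserve comparable positions (indel-gap-free reads)", {
  for (seed in 1:25) {
    set.seed(seed)
    L0 <- 15
    cSt <- sample(c(CHARS, "-"), L0, TRUE, prob = c(rep(0.22, 4), 0.12))
    cSt[1] <- "A"
    cons <- ConsensusHaplotype(1, cSt)
    s <- 2; e <- 13
    rSt <- sample(c(CHARS, "-"), e - s + 1, TRUE, prob = c(rep(0.2, 4), 0.2))
    rSt[1] <- "G"
    rd <- AlignedRead("r", s, e, rSt)
    ev <- summarizeReadEvents(rd, cons)
    comparable <- sum(cSt[s:e] != "-")
    overHang <- sum(cSt[s:e] == "-" & rSt != "-")  # insertion-segment bases
    expect_equal(ev@nCorrect + ev@nMismatch + sum(ev@delSegments), comparable)
    expect_equal(sum(ev@insSegments), overHang)
  }
})

test_that("complete-data log-likelihood decomposes and matches the oracle", {
  set.seed(3)
  ref <- randomRef(8, seed = 3)
  prof <- testProfile()
  evo <- EvolutionParams(gamma = rbind(c(0.8, 0.15, 0.05), c(0.7, 0.2, 0.1)),
                         beta = c(0.05, 0.1))
  w <- MixtureWeights(c(0.55, 0.45))
  haps <- list(ConsensusHaplotype(1, as.character(ref)),
               ConsensusHaplotype(2, "AC-TACGA", insertions = c("5" = "TT")))
  reads <- list(AlignedRead("a", 1, 6, "ACGTAC"),
                AlignedRead("b", 2, 8, "C-TACGA"))
  labels <- c(1L, 2L)

  total <- completeDataLogLik(reads, labels, haps, w, prof, evo, ref)
  # linearity: per-read + per-haplotype terms computed independently
  parts <- sum(vapply(seq_along(reads), function(i)
    log(mixtureAlpha(w)[labels[i]]) +
      readLogLik(summarizeReadEvents(reads[[i]], haps[[labels[i]]], ref), prof),
    numeric(1))) +
    sum(vapply(1:2, function(k)
      evolutionLogLik(summarizeConsensusEvents(haps[[k]], ref), evo,
                      length(ref), k), numeric(1)))
  expect_equal(total, parts, tolerance = 1e-10)

  # independent product oracle
  oracle <- sum(vapply(seq_along(reads), function(i)
    log(mixtureAlpha(w)[labels[i]]) +
      oracleReadLogLik(reads[[i]], haps[[labels[i]]], prof), numeric(1))) +
    sum(vapply(1:2, function(k)
      oracleEvoLogLik(haps[[k]], ref, evo@gamma[k, ], evo@beta[k]), numeric(1)))
  expect_equal(total, oracle, tolerance = 1e-10)

  # one-hot matrix labels and integer labels agree; permutation invariance
  oneHot <- rbind(c(1, 0), c(0, 1))
  expect_equal(completeDataLogLik(reads, oneHot, haps, w, prof, evo, ref), total)
  perm <- completeDataLogLik(rev(reads), rev(labels), haps, w, prof, evo, ref)
  expect_equal(perm, total, tolerance = 1e-12)
})

test_that("degenerate parameters give zero log-likelihood on perfect data", {
  ref <- ReferenceSequence("r", "ACGTACGT")
  hap <- ConsensusHaplotype(1, as.character(ref))
  rd <- AlignedRead("r1", 1, 8, as.character(ref))
  prof <- SequencingErrorProfile(p2 = 0, p3 = 0, p4 = 0)
  evo <- EvolutionParams(gamma = c(1, 0, 0), beta = 0)
  expect_equal(completeDataLogLik(list(rd), 1L, list(hap), MixtureWeights(1),
                                  prof, evo, ref), 0)
})
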