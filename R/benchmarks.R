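## Reproducible simulation studies: the package's own validation suite.
## Each study generates its data, runs the fitting machinery and returns a
## tidy summary; seeds fully determine the results.

#' Micro-instance exhaustive optimality study
#'
#' Builds a micro instance (`n` reads, `K = 2`, short backbone), computes
#' the globally optimal complete-data log-likelihood by enumerating all
#' `2^n` hard labelings — each scored at its conditionally optimal
#' consensuses and parameters (M-step iterated to a fixed point) — and
#' compares it with the best of `nRestarts` CAEM fits.
#'
#' @param seed RNG seed for the instance.
#' @param n number of reads (kept small; the enumeration is `2^n`).
#' @param L0 backbone length.
#' @param nRestarts CAEM restarts.
#' @return list with `exhaustive` and `caem` objectives and their `gap`
#'   (exhaustive minus CAEM; near zero when CAEM finds the optimum).
#' @export
microExhaustiveStudy <- function(seed = 1L, n = 6L, L0 = 12L, nRestarts = 20L) {
  set.seed(seed)
  ref <- ReferenceSequence("micro", paste(
    sample(c("A", "C", "G", "T"), L0, replace = TRUE), collapse = ""))
  refCh <- .decodeStates(ref@code)
  st2 <- refCh
  subs <- sample.int(L0, 4)
  for (p in subs) st2[p] <- .STATE_CHARS[setdiff(1:4, .encodeStates(st2[p]))[1]]
  haps <- list(refCh, st2)
  reads <- lapply(seq_len(n), function(i) {
    k <- 1L + i %% 2L
    s <- sample.int(max(1L, L0 - 7L), 1)
    e <- min(L0, s + 5L + sample.int(2L, 1))
    st <- haps[[k]][s:e]
    if (stats::runif(1) < 0.3) {  # one sprinkled error
      j <- sample.int(length(st), 1)
      st[j] <- .STATE_CHARS[setdiff(1:4, .encodeStates(st[j]))[1]]
    }
    AlignedRead(sprintf("m%02d", i), s, e, st, truthSource = k)
  })
  condObj <- function(labels) {
    st <- initializeState(reads, ref, 2L, labels = labels)
    prev <- -Inf
    for (sweep in 1:50) {
      st <- suppressWarnings(mStep(reads, labels, ref, st))
      if (is.finite(prev) && abs(st@objective - prev) < 1e-10) break
      prev <- st@objective
    }
    st@objective
  }
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    labels <- 1L + as.integer(intToBits(mask)[seq_len(n)] == 1)
    if (length(unique(labels)) < 2L) next  # degenerate labelings excluded
    best <- max(best, condObj(labels))
  }
  fit <- runCAEM(reads, ref, 2L,
                 FitConfig(nRestarts = nRestarts, seed = seed, T0 = 4))
  list(exhaustive = best, caem = stateObjective(fit@state),
       gap = best - stateObjective(fit@state))
}

#' Parameter-recovery study at the reference study conditions
#'
#' Repeats, over `nSeeds` seeds: simulate a two-haplotype dataset at the
#' Level-1 error profile on a 6 kb backbone with 200 reads (the standard
#' evolution and weight presets), fit with CAEM, and record the CPR of the
#' fitted haplotypes and the relative error of the recovered mismatch
#' probability `p2`.
#'
#' @param nSeeds number of replicate seeds.
#' @param seed base RNG seed.
#' @param L0,nReads problem size.
#' @param nRestarts CAEM restarts per fit.
#' @return `data.frame` with one row per seed: `cpr`, `p2`, `p2RelErr`,
#'   `mecr`, `objective`.
#' @export
recoveryStudy <- function(nSeeds = 10L, seed = 1L, L0 = 6000L, nReads = 200L,
                          nRestarts = 2L) {
  p2True <- errorProfilePreset(1)@p2
  out <- vector("list", nSeeds)
  for (i in seq_len(nSeeds)) {
    si <- seed + 101L * i
    set.seed(si)
    ref <- ReferenceSequence("sim", paste(
      sample(c("A", "C", "G", "T"), L0, replace = TRUE), collapse = ""))
    cfg <- SimulationConfig(K = 2L, nReads = nReads,
                            evolution = evolutionPreset(2),
                            weights = weightsPreset(2),
                            profile = errorProfilePreset(1),
                            readLength = readLengthModel(), seed = si + 1L)
    ds <- simulateDataset(ref, cfg)
    fit <- runCAEM(datasetReads(ds), ref, 2L,
                   FitConfig(nRestarts = nRestarts, seed = si + 2L))
    p2Hat <- stateProfile(fit@state)@p2
    out[[i]] <- data.frame(
      seed = si,
      cpr = suppressWarnings(cpr(datasetHaplotypes(ds), fittedHaplotypes(fit),
                                 ref)),
      p2 = p2Hat,
      p2RelErr = abs(p2Hat - p2True) / p2True,
      mecr = as.numeric(mecr(datasetReads(ds), fittedHaplotypes(fit))),
      objective = stateObjective(fit@state))
  }
  do.call(rbind, out)
}

## shared conditions for the compact studies: short backbone, elevated
## substitution rate (well-separated haplotypes), medium-length reads
.compactConfig <- function(K, nReads, level, seed) {
  gam <- c(0.975, 0.02, 0.005)
  SimulationConfig(
    K = K, nReads = nReads,
    evolution = EvolutionParams(gamma = matrix(rep(gam, K), ncol = 3,
                                               byrow = TRUE),
                                beta = rep(1e-4, K)),
    weights = MixtureWeights(rep(1 / K, K)),
    profile = errorProfilePreset(level),
    readLength = readLengthModel("lognormal", medianLength = 220, sdlog = 0.25,
                                 min = 120),
    seed = seed)
}

#' Ploidy-selection recovery study
#'
#' Repeats, over `nRuns` runs cycling the generating ploidy through
#' `{1, 2, 3}`: simulate a well-separated dataset, run five-fold
#' cross-validated selection over `kValues`, and record whether the
#' generating `K` was recovered.
#'
#' @param nRuns number of runs.
#' @param seed base RNG seed.
#' @param kValues candidate ploidies.
#' @param nReads reads per dataset.
#' @param L0 backbone length.
#' @return `data.frame` with one row per run: `trueK`, `chosenK`,
#'   `recovered`.
#' @export
selectionStudy <- function(nRuns = 10L, seed = 1L, kValues = 1:4,
                           nReads = 60L, L0 = 300L) {
  out <- vector("list", nRuns)
  for (i in seq_len(nRuns)) {
    trueK <- ((i - 1L) %% 3L) + 1L
    si <- seed + 211L * i
    set.seed(si)
    ref <- ReferenceSequence("sel", paste(
      sample(c("A", "C", "G", "T"), L0, replace = TRUE), collapse = ""))
    ds <- simulateDataset(ref, .compactConfig(trueK, nReads, level = 1L,
                                              seed = si + 1L))
    sel <- selectK(datasetReads(ds), ref, kValues,
                   FitConfig(nRestarts = 2L, seed = si + 2L))
    out[[i]] <- data.frame(run = i, trueK = trueK, chosenK = chosenK(sel),
                           recovered = chosenK(sel) == trueK)
  }
  do.call(rbind, out)
}

#' MECR-CPR anticorrelation study
#'
#' Simulates triploid datasets over a grid spanning the three error levels
#' and two coverage depths, fits each with CAEM and records both evaluation
#' statistics. Their Spearman correlation is expected to be negative:
#' datasets where the fit degrades (low coverage, unlucky restarts) show
#' both elevated read-vs-haplotype inconsistency (MECR) and reduced phasing
#' accuracy (CPR). The triploid low-coverage regime is used because it is
#' where fit quality genuinely varies; with saturated coverage both scores
#' pin to their ceilings and carry no rank signal.
#'
#' @param seedsPerCell replicate seeds per (level, coverage) cell; the grid
#'   has 6 cells.
#' @param seed base RNG seed.
#' @param nReads length-2 vector of read counts (the coverage axis).
#' @param L0 backbone length.
#' @return `data.frame` with one row per dataset (`level`, `nReads`,
#'   `mecr`, `cpr`) and the Spearman correlation in `attr(, "spearman")`.
#' @export
anticorrelationStudy <- function(seedsPerCell = 6L, seed = 1L,
                                 nReads = c(18L, 48L), L0 = 300L) {
  gam <- c(0.985, 0.012, 0.003)
  rows <- list()
  for (level in 1:3) {
    for (n in nReads) {
      for (j in seq_len(seedsPerCell)) {
        si <- seed + 307L * level + 13L * j + 7L * n
        set.seed(si)
        ref <- ReferenceSequence("ac", paste(
          sample(c("A", "C", "G", "T"), L0, replace = TRUE), collapse = ""))
        cfg <- SimulationConfig(
          K = 3L, nReads = n,
          evolution = EvolutionParams(gamma = matrix(rep(gam, 3), ncol = 3,
                                                     byrow = TRUE),
                                      beta = rep(1e-4, 3)),
          weights = MixtureWeights(c(0.4, 0.4, 0.2)),
          profile = errorProfilePreset(level),
          readLength = readLengthModel("lognormal", medianLength = 150,
                                       sdlog = 0.3, min = 80),
          seed = si + 1L)
        ds <- simulateDataset(ref, cfg)
        fit <- runCAEM(datasetReads(ds), ref, 3L,
                       FitConfig(nRestarts = 1L, seed = si + 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          level = level, nReads = n,
          mecr = as.numeric(mecr(datasetReads(ds), fittedHaplotypes(fit))),
          cpr = suppressWarnings(cpr(datasetHaplotypes(ds),
                                     fittedHaplotypes(fit), ref)))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spearman") <- stats::cor(out$mecr, out$cpr, method = "spearman")
  out
}
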