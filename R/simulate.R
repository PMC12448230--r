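## Two-step read simulator mirroring the generative model: evolve K
## consensus sequences from the reference, then emit error-bearing reads.

#' Error-profile presets for long-read simulations
#'
#' Three aggregate error levels (percent of mismatched, inserted and deleted
#' bases per position): Level 1 = (1.30, 0.087, 0.34), Level 3 =
#' (1.68, 8.04, 3.16), Level 2 the midpoint of the two. The aggregate indel
#' rates are split into per-segment start probabilities and shifted-Poisson
#' length rates with `lambda_ins = lambda_del = 1`, so that
#' `p3 (1 + lambda_del)` and `p4 (1 + lambda_ins)` match the aggregate rates
#' (expected indel bases per position).
#'
#' @param level 1, 2 or 3.
#' @param lambdaIns,lambdaDel segment-length rates used for the split.
#' @return a [SequencingErrorProfile-class].
#' @examples
#' errorRates(errorProfilePreset(2))   # 1.49 4.0635 1.75
#' @export
errorProfilePreset <- function(level, lambdaIns = 1, lambdaDel = 1) {
  rates <- switch(as.character(level),
    "1" = c(mismatch = 1.30,  insertion = 0.087,  deletion = 0.34),
    "2" = c(mismatch = 1.49,  insertion = 4.0635, deletion = 1.75),
    "3" = c(mismatch = 1.68,  insertion = 8.04,   deletion = 3.16),
    stop("unknown error-profile level '", level, "' (valid: 1, 2, 3)"))
  p2 <- rates[["mismatch"]] / 100
  p3 <- rates[["deletion"]] / 100 / (1 + lambdaDel)
  p4 <- rates[["insertion"]] / 100 / (1 + lambdaIns)
  SequencingErrorProfile(p2 = p2, p3 = p3, p4 = p4,
                         lambdaIns = lambdaIns, lambdaDel = lambdaDel)
}

#' Aggregate error rates of a sequencing profile
#'
#' The inverse of the preset split: expected mismatched, inserted and
#' deleted bases per position, in percent.
#'
#' @param profile a [SequencingErrorProfile-class].
#' @return named numeric vector (percent).
#' @export
errorRates <- function(profile) {
  c(mismatch = profile@p2 * 100,
    insertion = profile@p4 * (1 + profile@lambdaIns) * 100,
    deletion = profile@p3 * (1 + profile@lambdaDel) * 100)
}

#' Evolution-parameter presets
#'
#' `K = 2`: two haplotypes with `(gamma1, gamma2, gamma3, beta) =
#' (0.9989, 0.001, 0.0001, 0.0001)`. `K = 3`: the same two plus a
#' higher-mutation third haplotype `(0.98572, 0.0139, 0.00038, 0.00038)`.
#'
#' @param K 2 or 3.
#' @return an [EvolutionParams-class] with `K` rows.
#' @export
evolutionPreset <- function(K) {
  base <- c(0.9989, 0.001, 0.0001)
  if (K == 2L) {
    EvolutionParams(gamma = rbind(base, base, deparse.level = 0),
                    beta = c(1e-4, 1e-4))
  } else if (K == 3L) {
    hot <- c(0.98572, 0.0139, 0.00038)
    EvolutionParams(gamma = rbind(base, base, hot, deparse.level = 0),
                    beta = c(1e-4, 1e-4, 3.8e-4))
  } else stop("evolution presets exist for K = 2 or 3 only")
}

#' Mixture-weight presets
#'
#' `alpha = (0.6, 0.4)` for `K = 2` and `(0.4, 0.4, 0.2)` for `K = 3`.
#'
#' @param K 2 or 3.
#' @return a [MixtureWeights-class].
#' @export
weightsPreset <- function(K) {
  if (K == 2L) MixtureWeights(c(0.6, 0.4))
  else if (K == 3L) MixtureWeights(c(0.4, 0.4, 0.2))
  else stop("weight presets exist for K = 2 or 3 only")
}

#' Read-length models
#'
#' Mapping lengths of simulated reads (in reference coordinates). The
#' default is a log-normal with configurable median, clipped to
#' `[min, L0]`, standing in for an empirical long-read panel length table;
#' an explicit empirical table (`lengths` + `probs`) or a fixed length can
#' be supplied instead.
#'
#' @param type `"lognormal"`, `"empirical"` or `"fixed"`.
#' @param medianLength,sdlog log-normal parameters.
#' @param min lower clip bound (further capped at `L0`).
#' @param lengths,probs empirical table (`probs` defaults to uniform).
#' @param length fixed read length.
#' @return a list describing the model, consumed by [simulateDataset()].
#' @export
readLengthModel <- function(type = c("lognormal", "empirical", "fixed"),
                            medianLength = 1500, sdlog = 0.35, min = 500,
                            lengths = NULL, probs = NULL, length = NULL) {
  type <- match.arg(type)
  if (type == "empirical" && is.null(lengths))
    stop("empirical read-length model needs 'lengths'")
  if (type == "fixed" && is.null(length))
    stop("fixed read-length model needs 'length'")
  list(type = type, medianLength = medianLength, sdlog = sdlog, min = min,
       lengths = lengths, probs = probs, length = length)
}

.drawLengths <- function(model, n, L0) {
  len <- switch(model$type,
    lognormal = round(stats::rlnorm(n, log(model$medianLength), model$sdlog)),
    empirical = sample(model$lengths, n, replace = TRUE, prob = model$probs),
    fixed = rep(model$length, n))
  pmin(pmax(as.integer(len), min(model$min, L0)), L0)
}

#' Simulate one consensus haplotype from the reference
#'
#' Evolution stage: each position is kept, substituted (uniform over the 3
#' alternative bases) or deleted with probabilities `(gamma1, gamma2,
#' gamma3)`; each gap independently receives a single inserted base with
#' probability `beta`. Reference `N` positions emit a uniform base (they
#' count as matches in the model).
#'
#' @param reference a [ReferenceSequence-class].
#' @param params an [EvolutionParams-class].
#' @param k haplotype index (also the row of `params` used).
#' @param seed optional RNG seed.
#' @return a [ConsensusHaplotype-class].
#' @export
simulateConsensus <- function(reference, params, k = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refCode <- reference@code
  L0 <- length(refCode)
  cls <- sample.int(3L, L0, replace = TRUE, prob = params@gamma[k, ])
  st <- refCode
  isN <- refCode == .N_CODE
  if (any(isN)) st[isN] <- sample.int(4L, sum(isN), replace = TRUE)
  sub <- which(cls == 2L & !isN)
  if (length(sub)) {
    ## uniform over the 3 alternatives to the current base
    shift <- sample.int(3L, length(sub), replace = TRUE)
    st[sub] <- ((st[sub] - 1L + shift) %% 4L) + 1L
  }
  st[cls == 3L & !isN] <- .GAP_CODE
  gaps <- which(stats::runif(L0 - 1L) < params@beta[k])
  ins <- character()
  if (length(gaps)) {
    ins <- .STATE_CHARS[sample.int(4L, length(gaps), replace = TRUE)]
    names(ins) <- gaps
  }
  ConsensusHaplotype(k, st, ins)
}

#' Inject structural variants into a consensus haplotype
#'
#' Injects `svConfig$n` structural variants of the five long-variation
#' types (insertion, deletion, duplication, inversion, translocation) at
#' uniformly chosen loci. SV lengths are drawn uniformly from
#' `svConfig$lengths` (default `{50, 100, 500}`); per-type probabilities
#' default to uniform and can be overridden via `svConfig$typeProbs` (a
#' named vector).
#'
#' @param consensus a [ConsensusHaplotype-class].
#' @param svConfig list with `n`, and optionally `typeProbs`, `lengths`.
#' @param seed optional RNG seed.
#' @return the modified [ConsensusHaplotype-class].
#' @export
applyStructuralVariants <- function(consensus, svConfig, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- svConfig$n %||% 0L
  if (n == 0L) return(consensus)
  types <- c("insertion", "deletion", "duplication", "inversion", "translocation")
  probs <- rep(1 / 5, 5)
  if (!is.null(svConfig$typeProbs)) {
    probs <- svConfig$typeProbs[types]
    if (anyNA(probs)) stop("svConfig$typeProbs must name all five SV types")
    probs <- probs / sum(probs)
  }
  lengths <- svConfig$lengths %||% c(50L, 100L, 500L)
  st <- consensus@states
  ins <- consensus@insertions
  L0 <- length(st)
  if (L0 <= max(lengths)) stop("consensus shorter than the maximum SV length")
  addIns <- function(ins, g, str) {
    key <- as.character(g)
    ins[key] <- paste0(if (key %in% names(ins)) ins[[key]] else "", str)
    ins
  }
  spliced <- function(seg) paste(.STATE_CHARS[seg[seg != .GAP_CODE]], collapse = "")
  for (j in seq_len(n)) {
    type <- sample(types, 1L, prob = probs)
    len <- lengths[sample.int(length(lengths), 1L)]
    start <- sample.int(L0 - len + 1L, 1L)
    segIdx <- start:(start + len - 1L)
    switch(type,
      deletion = { st[segIdx] <- .GAP_CODE },
      insertion = {
        g <- sample.int(L0 - 1L, 1L)
        ins <- addIns(ins, g, paste(.STATE_CHARS[sample.int(4L, len, TRUE)],
                                    collapse = ""))
      },
      duplication = {
        content <- spliced(st[segIdx])
        if (nchar(content))
          ins <- addIns(ins, min(start + len - 1L, L0 - 1L), content)
      },
      inversion = {
        keep <- segIdx[st[segIdx] != .GAP_CODE]
        ## reverse complement in place (A<->T, C<->G)
        st[keep] <- rev(5L - st[keep])
      },
      translocation = {
        content <- spliced(st[segIdx])
        st[segIdx] <- .GAP_CODE
        if (nchar(content)) ins <- addIns(ins, sample.int(L0 - 1L, 1L), content)
      })
  }
  ConsensusHaplotype(consensus@index, st, ins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Emit one read from a consensus over [s, e]. Returns list(read, events);
## the events record what the generator injected, derived from its own
## bookkeeping (independent of summarizeReadEvents).
.simulateRead1 <- function(consensus, profile, s, e, name, truth = NA_integer_) {
  stC <- consensus@states[s:e]
  Li <- e - s + 1L
  compIdx <- which(stC != .GAP_CODE)
  ncomp <- length(compIdx)
  stR <- rep(.GAP_CODE, Li)
  nCorrect <- 0L; nMismatch <- 0L
  delRuns <- integer()
  if (ncomp > 0L) {
    cat3 <- sample.int(3L, ncomp, replace = TRUE,
                       prob = c(profile@p1, profile@p2, profile@p3))
    emitted <- integer(ncomp)  # 0 = deleted
    consumed <- rep(FALSE, ncomp)
    dstarts <- which(cat3 == 3L)
    for (d in dstarts) {
      if (consumed[d]) next
      len <- 1L + stats::rpois(1L, profile@lambdaDel)
      consumed[d:min(ncomp, d + len - 1L)] <- TRUE
    }
    keep <- which(!consumed)
    base <- stC[compIdx]
    emitted[keep] <- base[keep]
    mism <- keep[cat3[keep] == 2L]
    if (length(mism)) {
      shift <- sample.int(3L, length(mism), replace = TRUE)
      emitted[mism] <- ((base[mism] - 1L + shift) %% 4L) + 1L
    }
    nCorrect <- as.integer(sum(cat3[keep] == 1L))
    nMismatch <- as.integer(length(mism))
    if (any(consumed)) {
      r <- rle(consumed)
      delRuns <- r$lengths[r$values]
    }
    stR[compIdx[keep]] <- emitted[keep]
  }
  ## gaps: copy consensus insertions verbatim; otherwise insertion errors
  insR <- character()
  insRuns <- integer()
  if (Li > 1L) {
    gapIdx <- s:(e - 1L)
    consIns <- .insInWindow(consensus@insertions, s, e)
    freeGaps <- setdiff(as.character(gapIdx), names(consIns))
    hit <- freeGaps[stats::runif(length(freeGaps)) < profile@p4]
    if (length(hit)) {
      lens <- 1L + stats::rpois(length(hit), profile@lambdaIns)
      segs <- vapply(lens, function(L)
        paste(.STATE_CHARS[sample.int(4L, L, TRUE)], collapse = ""), character(1))
      names(segs) <- hit
      insR <- c(insR, segs)
      insRuns <- lens
    }
    if (length(consIns)) insR <- c(insR, consIns)
  }
  if (all(stR == .GAP_CODE)) return(NULL)  # degenerate; caller retries
  rd <- AlignedRead(name, s, e, stR, insR, truthSource = truth)
  ev <- ReadEvents(nCorrect, nMismatch, as.integer(delRuns),
                   as.integer(insRuns),
                   max(0L, (Li - 1L) - length(insRuns)))
  list(read = rd, events = ev)
}

#' Simulate a single read from a consensus haplotype
#'
#' Sequencing stage: per comparable position the read emits the template
#' base (`p1`), a uniformly chosen alternative base (`p2`), or starts a
#' deletion segment of length `1 + Poi(lambda_del)` (`p3`); per free gap an
#' insertion segment of length `1 + Poi(lambda_ins)` with uniform bases is
#' injected with probability `p4`. Gaps carrying a true consensus insertion
#' are copied verbatim. The injected events are recorded by the generator's
#' own bookkeeping and returned alongside when `withEvents = TRUE`.
#'
#' @param consensus a [ConsensusHaplotype-class].
#' @param profile a [SequencingErrorProfile-class].
#' @param readLength span of the read in reference coordinates.
#' @param start 1-based start position.
#' @param name read identifier.
#' @param seed optional RNG seed.
#' @param withEvents return `list(read, events)` instead of just the read.
#' @return an [AlignedRead-class], or a list when `withEvents = TRUE`.
#' @export
simulateRead <- function(consensus, profile, readLength, start, name = "read",
                         seed = NULL, withEvents = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  L0 <- length(consensus@states)
  e <- start + as.integer(readLength) - 1L
  if (start < 1L || e > L0) stop("read window [", start, ", ", e,
                                 "] outside the reference [1, ", L0, "]")
  out <- .simulateRead1(consensus, profile, as.integer(start), e, name)
  if (is.null(out)) stop("read window covers only deleted consensus positions")
  if (withEvents) out else out$read
}

#' Simulate a complete dataset
#'
#' Draws `K` consensus haplotypes from the reference (optionally with
#' structural variants), then `nReads` reads: each read picks its source
#' haplotype with probability `alpha_k`, a mapping length from the
#' configured length model, and a uniform feasible start. Deterministic
#' given `config@seed`.
#'
#' @param reference a [ReferenceSequence-class].
#' @param config a [SimulationConfig-class].
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(reference, config) {
  set.seed(config@seed)
  K <- config@K
  L0 <- length(reference@code)
  haps <- lapply(seq_len(K), function(k) {
    h <- simulateConsensus(reference, config@evolution, k)
    if (length(config@svConfig) && (config@svConfig$n %||% 0L) > 0L)
      h <- applyStructuralVariants(h, config@svConfig)
    h
  })
  n <- config@nReads
  src <- sample.int(K, n, replace = TRUE, prob = config@weights@alpha)
  lens <- .drawLengths(config@readLength, n, L0)
  reads <- vector("list", n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- sprintf("read%05d", i)
    for (try in 1:100) {
      s <- sample.int(L0 - lens[i] + 1L, 1L)
      out <- .simulateRead1(haps[[src[i]]], config@profile, s,
                            s + lens[i] - 1L, nm, truth = src[i])
      if (!is.null(out)) break
    }
    if (is.null(out)) stop("could not place read ", i, " on non-deleted sequence")
    reads[[i]] <- out$read
    events[[i]] <- out$events
  }
  truthSnvs <- lapply(haps, function(h) {
    which(h@states != .GAP_CODE & reference@code != .N_CODE &
          h@states != reference@code)
  })
  new("SimulatedDataset", reference = reference, haplotypes = haps,
      reads = reads, truthSnvs = truthSnvs, truthEvents = events,
      config = config)
}

#' Named simulation scenarios
#'
#' `scenarioConfig()` builds the preset parameterizations `"K2-level1"` ..
#' `"K3-level3"` (evolution and weight presets for the chosen ploidy, error
#' profile of the chosen level); `scenarioGrid()` enumerates the full
#' simulation design: ploidy `{2, 3}` x error level `{1, 2, 3}` x read count
#' `{50, 100}`, i.e. 12 scenario runs.
#'
#' @param scenario scenario name, e.g. `"K2-level1"`.
#' @param nReads number of reads.
#' @param seed RNG seed.
#' @param readLength read-length model (see [readLengthModel()]).
#' @return `scenarioConfig()` a [SimulationConfig-class]; `scenarioGrid()` a
#'   `data.frame` with columns `scenario`, `K`, `level`, `nReads`.
#' @export
scenarioConfig <- function(scenario, nReads = 50L, seed = 1L,
                           readLength = readLengthModel()) {
  m <- regmatches(scenario, regexec("^K([23])-level([123])$", scenario))[[1L]]
  if (length(m) != 3L)
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(sprintf("K%d-level%d", rep(2:3, each = 3), rep(1:3, 2)),
               collapse = ", "))
  K <- as.integer(m[2L])
  level <- as.integer(m[3L])
  SimulationConfig(K = K, nReads = nReads, evolution = evolutionPreset(K),
                   weights = weightsPreset(K), profile = errorProfilePreset(level),
                   readLength = readLength, seed = seed)
}

#' @rdname scenarioConfig
#' @export
scenarioGrid <- function() {
  g <- expand.grid(K = c(2L, 3L), level = c(1L, 2L, 3L), nReads = c(50L, 100L),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(scenario = sprintf("K%d-level%d", g$K, g$level), g,
             stringsAsFactors = FALSE)
}
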