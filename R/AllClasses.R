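#' @import methods
NULL

## Internal state alphabet. Sequence states are stored as integer codes
## throughout: A=1, C=2, G=3, T=4, "-"=5 (deletion relative to the
## reference), N=6 (reference-only, ambiguous). Codes keep the EM inner
## loops fast; user-facing accessors translate back to characters.
.STATE_CHARS <- c("A", "C", "G", "T", "-", "N")
.GAP_CODE <- 5L
.N_CODE <- 6L

.encodeStates <- function(x, allowN = FALSE, what = "states") {
  if (length(x) == 1L && nchar(x[1L]) != 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  code <- match(toupper(x), .STATE_CHARS)
  if (anyNA(code)) {
    stop("invalid ", what, " character(s): ",
         paste(unique(x[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  if (!allowN && any(code == .N_CODE)) {
    stop(what, " may not contain N", call. = FALSE)
  }
  as.integer(code)
}

.decodeStates <- function(code) .STATE_CHARS[code]

.checkInsertions <- function(ins, maxGap) {
  if (length(ins) == 0L) return(NULL)
  g <- suppressWarnings(as.integer(names(ins)))
  if (anyNA(g)) return("insertion names must be integer gap indices")
  if (any(g < 1L) || (!is.na(maxGap) && any(g > maxGap)))
    return(sprintf("insertion gap indices must lie in [1, %d]", maxGap))
  if (anyDuplicated(g)) return("duplicate insertion gap indices")
  if (any(nchar(ins) == 0L)) return("inserted strings must be non-empty")
  if (any(grepl("[^ACGT]", ins))) return("inserted strings may contain only A, C, G, T")
  NULL
}

## ---------------------------------------------------------------------------
## ReferenceSequence
## ---------------------------------------------------------------------------

#' Reference sequence backbone
#'
#' The genomic backbone of length `L0` to which consensus haplotypes and
#' aligned reads are indexed. Positions are 1-based; the `L0 - 1` inter-base
#' gaps are indexed `1 .. L0 - 1`, gap `g` sitting between positions `g` and
#' `g + 1`.
#'
#' @slot name contig/record identifier.
#' @slot code integer state codes over A, C, G, T, N.
#'
#' @aliases ReferenceSequence-class
#' @export
setClass("ReferenceSequence",
  representation(name = "character", code = "integer"))

setValidity("ReferenceSequence", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@code) < 2L) msg <- c(msg, "reference must have length >= 2")
  if (any(is.na(object@code)) || any(object@code < 1L) ||
      any(object@code == .GAP_CODE) || any(object@code > .N_CODE))
    msg <- c(msg, "reference states must be in {A,C,G,T,N}")
  if (length(msg)) msg else TRUE
})

#' @param name single record identifier.
#' @param bases character: a single string or a vector of single characters
#'   over `{A,C,G,T,N}` (case-insensitive).
#' @return `ReferenceSequence()` returns a [ReferenceSequence-class] object.
#' @rdname ReferenceSequence-class
#' @export
ReferenceSequence <- function(name, bases) {
  new("ReferenceSequence", name = as.character(name),
      code = .encodeStates(bases, allowN = TRUE, what = "reference bases"))
}

#' @rdname ReferenceSequence-class
#' @param x,object a `ReferenceSequence`.
#' @export
setMethod("length", "ReferenceSequence", function(x) length(x@code))

#' @rdname ReferenceSequence-class
#' @export
setMethod("as.character", "ReferenceSequence",
          function(x) paste(.decodeStates(x@code), collapse = ""))

setMethod("show", "ReferenceSequence", function(object) {
  cat("ReferenceSequence", object@name, "of length", length(object@code), "\n")
})

#' @rdname ReferenceSequence-class
#' @export
refName <- function(x) x@name

## ---------------------------------------------------------------------------
## ConsensusHaplotype
## ---------------------------------------------------------------------------

#' Consensus haplotype
#'
#' One of the `K` hidden consensus sequences, represented against the
#' reference: a state per reference position over `{A,C,G,T,-}` (`-` marks a
#' deletion mutation) plus inserted base strings keyed by reference gap
#' index.
#'
#' @slot index haplotype index `k`.
#' @slot states integer state codes, one per reference position.
#' @slot insertions named character vector; names are gap indices, values
#'   inserted strings over `{A,C,G,T}`.
#'
#' @aliases ConsensusHaplotype-class
#' @export
setClass("ConsensusHaplotype",
  representation(index = "integer", states = "integer", insertions = "character"))

setValidity("ConsensusHaplotype", function(object) {
  msg <- character()
  if (length(object@index) != 1L || is.na(object@index) || object@index < 1L)
    msg <- c(msg, "index must be a positive integer")
  if (length(object@states) < 1L || any(is.na(object@states)) ||
      any(object@states < 1L) || any(object@states > .GAP_CODE))
    msg <- c(msg, "states must be codes over {A,C,G,T,-}")
  insMsg <- .checkInsertions(object@insertions, length(object@states) - 1L)
  if (!is.null(insMsg)) msg <- c(msg, insMsg)
  if (length(msg)) msg else TRUE
})

#' @param index haplotype index `k` (positive integer).
#' @param states a string or character vector over `{A,C,G,T,-}`, one state
#'   per reference position.
#' @param insertions named character vector of inserted strings; names are
#'   1-based gap indices.
#' @return `ConsensusHaplotype()` returns a [ConsensusHaplotype-class] object.
#' @rdname ConsensusHaplotype-class
#' @export
ConsensusHaplotype <- function(index, states, insertions = character()) {
  if (length(insertions)) insertions <- insertions[order(as.integer(names(insertions)))]
  new("ConsensusHaplotype", index = as.integer(index),
      states = if (is.numeric(states)) as.integer(states) else
        .encodeStates(states, what = "consensus states"),
      insertions = insertions)
}

#' @rdname ConsensusHaplotype-class
#' @param x,object a `ConsensusHaplotype`.
#' @export
hapStates <- function(x) .decodeStates(x@states)

#' @rdname ConsensusHaplotype-class
#' @export
hapInsertions <- function(x) x@insertions

#' @rdname ConsensusHaplotype-class
#' @export
hapIndex <- function(x) x@index

#' Spliced literal sequence of a consensus haplotype
#'
#' Drops `-` states and splices inserted segments in after their gap
#' position, yielding the literal nucleotide sequence the haplotype carries.
#'
#' @param x a [ConsensusHaplotype-class].
#' @return a single character string.
#' @export
hapSequence <- function(x) {
  st <- x@states
  L0 <- length(st)
  pieces <- character(L0)
  keep <- st != .GAP_CODE
  pieces[keep] <- .STATE_CHARS[st[keep]]
  if (length(x@insertions)) {
    g <- as.integer(names(x@insertions))
    pieces[g] <- paste0(pieces[g], x@insertions)
  }
  paste(pieces, collapse = "")
}

setMethod("length", "ConsensusHaplotype", function(x) length(x@states))

setMethod("show", "ConsensusHaplotype", function(object) {
  cat("ConsensusHaplotype k =", object@index, "over", length(object@states),
      "reference positions;", sum(object@states == .GAP_CODE), "deleted,",
      length(object@insertions), "insertion(s)\n")
})

## ---------------------------------------------------------------------------
## AlignedRead
## ---------------------------------------------------------------------------

#' Aligned read in reference coordinates
#'
#' Per-reference-position observations of one read over its covered interval
#' `[si, ei]` (1-based, inclusive), plus inserted strings keyed by gap index.
#' A `-` state means the read deletes that reference position; `N` states
#' (rare in long-read data) are kept but excluded from model events.
#'
#' @slot name read identifier.
#' @slot start,end covered interval `[si, ei]`.
#' @slot states integer codes of length `ei - si + 1`.
#' @slot insertions named character vector keyed by gap index in
#'   `[si, ei - 1]`.
#' @slot truthSource generating haplotype index (simulation only; `NA`
#'   otherwise).
#'
#' @aliases AlignedRead-class
#' @export
setClass("AlignedRead",
  representation(name = "character", start = "integer", end = "integer",
                 states = "integer", insertions = "character",
                 truthSource = "integer"))

setValidity("AlignedRead", function(object) {
  msg <- character()
  if (object@start < 1L || object@end < object@start)
    msg <- c(msg, "need 1 <= start <= end")
  if (length(object@states) != object@end - object@start + 1L)
    msg <- c(msg, "states length must equal end - start + 1")
  if (any(object@states < 1L) || any(object@states > .N_CODE))
    msg <- c(msg, "read states must be codes over {A,C,G,T,-,N}")
  if (all(object@states == .GAP_CODE))
    msg <- c(msg, "read may not delete every covered position")
  if (length(object@insertions)) {
    insMsg <- .checkInsertions(object@insertions, NA)
    if (!is.null(insMsg)) msg <- c(msg, insMsg)
    g <- as.integer(names(object@insertions))
    if (is.null(insMsg) && (any(g < object@start) || any(g > object@end - 1L)))
      msg <- c(msg, "insertion gaps must lie in [start, end - 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param name read identifier.
#' @param start,end 1-based inclusive covered interval on the reference.
#' @param states string or character vector over `{A,C,G,T,-,N}` of length
#'   `end - start + 1`.
#' @param insertions named character vector (names = gap indices).
#' @param truthSource generating haplotype index, or `NA`.
#' @return `AlignedRead()` returns an [AlignedRead-class] object.
#' @rdname AlignedRead-class
#' @export
AlignedRead <- function(name, start, end, states, insertions = character(),
                        truthSource = NA_integer_) {
  if (length(insertions)) insertions <- insertions[order(as.integer(names(insertions)))]
  new("AlignedRead", name = as.character(name), start = as.integer(start),
      end = as.integer(end),
      states = if (is.numeric(states)) as.integer(states) else
        .encodeStates(states, allowN = TRUE, what = "read states"),
      insertions = insertions, truthSource = as.integer(truthSource))
}

#' @rdname AlignedRead-class
#' @param x,object an `AlignedRead`.
#' @export
readStates <- function(x) .decodeStates(x@states)

#' @rdname AlignedRead-class
#' @export
readInterval <- function(x) c(start = x@start, end = x@end)

setMethod("length", "AlignedRead", function(x) x@end - x@start + 1L)

setMethod("show", "AlignedRead", function(object) {
  cat("AlignedRead", object@name, sprintf("[%d, %d]", object@start, object@end),
      if (!is.na(object@truthSource)) sprintf("(truth: haplotype %d)", object@truthSource),
      "\n")
})

## ---------------------------------------------------------------------------
## Parameter containers
## ---------------------------------------------------------------------------

#' Evolution-stage parameters
#'
#' Per-haplotype mutation probabilities of the evolution stage: the
#' no-mutation / substitution / deletion simplex `(gamma_k1, gamma_k2,
#' gamma_k3)` per reference position and the per-gap insertion probability
#' `beta_k`.
#'
#' @slot gamma `K x 3` matrix, rows on the simplex.
#' @slot beta length-`K` vector of per-gap insertion probabilities.
#'
#' @aliases EvolutionParams-class
#' @export
setClass("EvolutionParams", representation(gamma = "matrix", beta = "numeric"))

setValidity("EvolutionParams", function(object) {
  msg <- character()
  g <- object@gamma
  if (ncol(g) != 3L || nrow(g) < 1L) msg <- c(msg, "gamma must be K x 3")
  else {
    if (any(g < 0) || any(g > 1)) msg <- c(msg, "gamma entries must lie in [0, 1]")
    if (any(abs(rowSums(g) - 1) > 1e-12)) msg <- c(msg, "gamma rows must sum to 1 (tol 1e-12)")
  }
  if (length(object@beta) != nrow(g)) msg <- c(msg, "beta must have one entry per haplotype")
  if (any(object@beta < 0) || any(object@beta >= 1)) msg <- c(msg, "beta must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param gamma `K x 3` matrix (or length-3 vector for `K = 1`); rows must sum
#'   to 1 within `1e-12`.
#' @param beta length-`K` vector in `[0, 1)`.
#' @return `EvolutionParams()` returns an [EvolutionParams-class] object.
#' @rdname EvolutionParams-class
#' @export
EvolutionParams <- function(gamma, beta) {
  if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = 1L)
  new("EvolutionParams", gamma = gamma, beta = as.numeric(beta))
}

#' Parse a 4-number evolution parameter tuple
#'
#' Evolution settings are often quoted as 4 numbers
#' `(gamma1, gamma2, gamma3, beta)`; the first three are renormalised to the
#' simplex if they do not already sum to 1.
#'
#' @param x numeric vector of length 4.
#' @return an [EvolutionParams-class] with `K = 1`.
#' @export
evolutionParamsFromTuple <- function(x) {
  stopifnot(length(x) == 4L)
  g <- x[1:3] / sum(x[1:3])
  EvolutionParams(gamma = g, beta = x[4L])
}

setMethod("show", "EvolutionParams", function(object) {
  cat("EvolutionParams for", nrow(object@gamma), "haplotype(s)\n")
  for (k in seq_len(nrow(object@gamma)))
    cat(sprintf("  k=%d gamma=(%.6g, %.6g, %.6g) beta=%.6g\n", k,
                object@gamma[k, 1], object@gamma[k, 2], object@gamma[k, 3],
                object@beta[k]))
})

#' Sequencing error profile
#'
#' The sequencing-stage parameter vector
#' `psi = (p1, p2, p3, p4, lambda_ins, lambda_del)`: per comparable position
#' a base is emitted correctly (`p1`), mismatched (`p2`) or starts a deletion
#' segment (`p3`), with `p1 + p2 + p3 = 1`; per gap an insertion segment
#' starts with probability `p4`. Indel segment lengths are shifted Poisson,
#' `L - 1 ~ Poi(lambda)`.
#'
#' @slot p1,p2,p3,p4 probabilities as above.
#' @slot lambdaIns,lambdaDel positive segment-length rates.
#'
#' @aliases SequencingErrorProfile-class
#' @export
setClass("SequencingErrorProfile",
  representation(p1 = "numeric", p2 = "numeric", p3 = "numeric", p4 = "numeric",
                 lambdaIns = "numeric", lambdaDel = "numeric"))

setValidity("SequencingErrorProfile", function(object) {
  msg <- character()
  p <- c(object@p1, object@p2, object@p3, object@p4)
  if (any(p < 0) || any(p > 1)) msg <- c(msg, "p1..p4 must lie in [0, 1]")
  if (abs(object@p1 + object@p2 + object@p3 - 1) > 1e-12)
    msg <- c(msg, "p1 + p2 + p3 must equal 1 (tol 1e-12)")
  if (object@lambdaIns <= 0 || object@lambdaDel <= 0)
    msg <- c(msg, "lambdaIns and lambdaDel must be positive")
  if (length(msg)) msg else TRUE
})

#' @param p1,p2,p3,p4,lambdaIns,lambdaDel see slots. `p1` defaults to
#'   `1 - p2 - p3` (the simplex constraint).
#' @return `SequencingErrorProfile()` returns a
#'   [SequencingErrorProfile-class] object.
#' @rdname SequencingErrorProfile-class
#' @export
SequencingErrorProfile <- function(p2, p3, p4, p1 = 1 - p2 - p3,
                                   lambdaIns = 1, lambdaDel = 1) {
  new("SequencingErrorProfile", p1 = p1, p2 = p2, p3 = p3, p4 = p4,
      lambdaIns = lambdaIns, lambdaDel = lambdaDel)
}

setMethod("show", "SequencingErrorProfile", function(object) {
  cat(sprintf(paste0("SequencingErrorProfile: p1=%.6g p2=%.6g p3=%.6g p4=%.6g ",
                     "lambdaIns=%.3g lambdaDel=%.3g\n"),
              object@p1, object@p2, object@p3, object@p4,
              object@lambdaIns, object@lambdaDel))
})

#' Mixture weights over haplotypes
#'
#' The prior probability `alpha_k` that a read is sequenced from consensus
#' `k`.
#'
#' @slot alpha length-`K` probability vector, components in `(0, 1]`, summing
#'   to 1.
#'
#' @aliases MixtureWeights-class
#' @export
setClass("MixtureWeights", representation(alpha = "numeric"))

setValidity("MixtureWeights", function(object) {
  a <- object@alpha
  msg <- character()
  if (length(a) < 1L || any(a <= 0) || any(a > 1))
    msg <- c(msg, "alpha components must lie in (0, 1]")
  if (abs(sum(a) - 1) > 1e-12) msg <- c(msg, "alpha must sum to 1 (tol 1e-12)")
  if (length(msg)) msg else TRUE
})

#' @param alpha numeric probability vector.
#' @return `MixtureWeights()` returns a [MixtureWeights-class] object.
#' @rdname MixtureWeights-class
#' @export
MixtureWeights <- function(alpha) new("MixtureWeights", alpha = as.numeric(alpha))

#' @rdname MixtureWeights-class
#' @param x a `MixtureWeights`.
#' @export
mixtureAlpha <- function(x) x@alpha

setMethod("show", "MixtureWeights", function(object) {
  cat("MixtureWeights:", paste(signif(object@alpha, 4), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Event summaries
## ---------------------------------------------------------------------------

#' Read-vs-consensus event summary
#'
#' Sufficient statistics of one read compared against one consensus
#' haplotype: counts of correctly sequenced and mismatched comparable
#' positions, deletion- and insertion-segment length lists, and the number of
#' gaps without an insertion error (`W`).
#'
#' @slot nCorrect,nMismatch counts of comparable positions.
#' @slot delSegments,insSegments integer vectors of segment lengths (each
#'   `>= 1`).
#' @slot nGapsNoInsertion `W`, the number of no-insertion-error gaps.
#'
#' @aliases ReadEvents-class
#' @export
setClass("ReadEvents",
  representation(nCorrect = "integer", nMismatch = "integer",
                 delSegments = "integer", insSegments = "integer",
                 nGapsNoInsertion = "integer"))

setValidity("ReadEvents", function(object) {
  msg <- character()
  if (object@nCorrect < 0L || object@nMismatch < 0L || object@nGapsNoInsertion < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (any(object@delSegments < 1L) || any(object@insSegments < 1L))
    msg <- c(msg, "segment lengths must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nCorrect,nMismatch,delSegments,insSegments,nGapsNoInsertion see
#'   slots.
#' @return `ReadEvents()` returns a [ReadEvents-class] object.
#' @rdname ReadEvents-class
#' @export
ReadEvents <- function(nCorrect, nMismatch, delSegments = integer(),
                       insSegments = integer(), nGapsNoInsertion = 0L) {
  new("ReadEvents", nCorrect = as.integer(nCorrect),
      nMismatch = as.integer(nMismatch), delSegments = as.integer(delSegments),
      insSegments = as.integer(insSegments),
      nGapsNoInsertion = as.integer(nGapsNoInsertion))
}

setMethod("show", "ReadEvents", function(object) {
  cat(sprintf("ReadEvents: correct=%d mismatch=%d del=[%s] ins=[%s] W=%d\n",
              object@nCorrect, object@nMismatch,
              paste(object@delSegments, collapse = ","),
              paste(object@insSegments, collapse = ","),
              object@nGapsNoInsertion))
})

#' Consensus-vs-reference event summary
#'
#' Evolution-stage sufficient statistics of one consensus haplotype:
#' per-position match / substitution / deletion counts (summing to `L0`), the
#' number of insertion gaps `N_k`, and the total number of inserted bases
#' (used by the inserted-content term of the likelihood).
#'
#' @slot nMatch,nSubstitution,nDeletion per-position counts.
#' @slot nInsertion number of gaps carrying an insertion.
#' @slot nInsertedBases total inserted bases.
#'
#' @aliases ConsensusEvents-class
#' @export
setClass("ConsensusEvents",
  representation(nMatch = "integer", nSubstitution = "integer",
                 nDeletion = "integer", nInsertion = "integer",
                 nInsertedBases = "integer"))

setValidity("ConsensusEvents", function(object) {
  msg <- character()
  counts <- c(object@nMatch, object@nSubstitution, object@nDeletion,
              object@nInsertion, object@nInsertedBases)
  if (any(counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@nInsertedBases < object@nInsertion)
    msg <- c(msg, "inserted bases cannot be fewer than insertion gaps")
  if (length(msg)) msg else TRUE
})

#' @param nMatch,nSubstitution,nDeletion,nInsertion,nInsertedBases see slots.
#' @return `ConsensusEvents()` returns a [ConsensusEvents-class] object.
#' @rdname ConsensusEvents-class
#' @export
ConsensusEvents <- function(nMatch, nSubstitution, nDeletion, nInsertion = 0L,
                            nInsertedBases = nInsertion) {
  new("ConsensusEvents", nMatch = as.integer(nMatch),
      nSubstitution = as.integer(nSubstitution),
      nDeletion = as.integer(nDeletion), nInsertion = as.integer(nInsertion),
      nInsertedBases = as.integer(nInsertedBases))
}

setMethod("show", "ConsensusEvents", function(object) {
  cat(sprintf("ConsensusEvents: match=%d sub=%d del=%d insGaps=%d insBases=%d\n",
              object@nMatch, object@nSubstitution, object@nDeletion,
              object@nInsertion, object@nInsertedBases))
})

## ---------------------------------------------------------------------------
## Fit containers
## ---------------------------------------------------------------------------

#' Model state of the CAEM fit
#'
#' All free quantities of the fit at one point of the algorithm: the `K`
#' consensus haplotypes, mixture weights, sequencing error profile, evolution
#' parameters, the `n x K` responsibility table, the current annealing
#' temperature and the current complete-data log-likelihood.
#'
#' @aliases ModelState-class
#' @export
setClass("ModelState",
  representation(consensuses = "list", weights = "MixtureWeights",
                 profile = "SequencingErrorProfile",
                 evolution = "EvolutionParams",
                 responsibilities = "matrix", temperature = "numeric",
                 objective = "numeric"))

setValidity("ModelState", function(object) {
  msg <- character()
  K <- length(object@consensuses)
  if (!all(vapply(object@consensuses, is, TRUE, "ConsensusHaplotype")))
    msg <- c(msg, "consensuses must be ConsensusHaplotype objects")
  if (length(object@weights@alpha) != K)
    msg <- c(msg, "weights length must equal number of consensuses")
  if (nrow(object@evolution@gamma) != K)
    msg <- c(msg, "evolution parameters must have one row per haplotype")
  if (ncol(object@responsibilities) != K)
    msg <- c(msg, "responsibility table must have K columns")
  if (nrow(object@responsibilities) > 0L &&
      any(abs(rowSums(object@responsibilities) - 1) > 1e-9))
    msg <- c(msg, "responsibility rows must sum to 1 (tol 1e-9)")
  if (object@temperature < 1) msg <- c(msg, "temperature must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param consensuses list of [ConsensusHaplotype-class].
#' @param weights a [MixtureWeights-class].
#' @param profile a [SequencingErrorProfile-class].
#' @param evolution an [EvolutionParams-class].
#' @param responsibilities `n x K` matrix, rows on the simplex.
#' @param temperature annealing temperature `T >= 1`.
#' @param objective complete-data log-likelihood of the state.
#' @return `ModelState()` returns a [ModelState-class] object.
#' @rdname ModelState-class
#' @export
ModelState <- function(consensuses, weights, profile, evolution,
                       responsibilities, temperature = 1, objective = NA_real_) {
  new("ModelState", consensuses = consensuses, weights = weights,
      profile = profile, evolution = evolution,
      responsibilities = responsibilities, temperature = temperature,
      objective = objective)
}

#' @rdname ModelState-class
#' @param x,object a `ModelState`.
#' @export
stateConsensuses <- function(x) x@consensuses

#' @rdname ModelState-class
#' @export
stateWeights <- function(x) x@weights

#' @rdname ModelState-class
#' @export
stateProfile <- function(x) x@profile

#' @rdname ModelState-class
#' @export
stateEvolution <- function(x) x@evolution

#' @rdname ModelState-class
#' @export
stateResponsibilities <- function(x) x@responsibilities

#' @rdname ModelState-class
#' @export
stateObjective <- function(x) x@objective

setMethod("show", "ModelState", function(object) {
  cat(sprintf("ModelState: K=%d, n=%d reads, T=%.3g, objective=%.6g\n",
              length(object@consensuses), nrow(object@responsibilities),
              object@temperature, object@objective))
})

#' Fit configuration for the CAEM loop
#'
#' @slot nRestarts number of random restarts (best final objective wins).
#' @slot maxIter iteration cap per restart.
#' @slot tol relative objective tolerance for convergence at `T = 1`.
#' @slot T0 initial annealing temperature (`>= 1`).
#' @slot cooling multiplicative cooling factor in `(0, 1)`.
#' @slot seed RNG seed.
#' @slot tieEvolution estimate one shared evolution parameter row for all
#'   haplotypes (useful for small data).
#'
#' @aliases FitConfig-class
#' @export
setClass("FitConfig",
  representation(nRestarts = "integer", maxIter = "integer", tol = "numeric",
                 T0 = "numeric", cooling = "numeric", seed = "integer",
                 tieEvolution = "logical"))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (object@T0 < 1) msg <- c(msg, "T0 must be >= 1")
  if (object@cooling <= 0 || object@cooling >= 1) msg <- c(msg, "cooling must be in (0, 1)")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (object@nRestarts < 1L || object@maxIter < 1L)
    msg <- c(msg, "nRestarts and maxIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nRestarts,maxIter,tol,T0,cooling,seed,tieEvolution see slots.
#' @return `FitConfig()` returns a [FitConfig-class] object.
#' @rdname FitConfig-class
#' @export
FitConfig <- function(nRestarts = 10L, maxIter = 500L, tol = 1e-6, T0 = 10,
                      cooling = 0.9, seed = 1L, tieEvolution = FALSE) {
  new("FitConfig", nRestarts = as.integer(nRestarts), maxIter = as.integer(maxIter),
      tol = tol, T0 = T0, cooling = cooling, seed = as.integer(seed),
      tieEvolution = tieEvolution)
}

#' Result of a CAEM fit
#'
#' @slot state the final [ModelState-class] of the best restart.
#' @slot labels hard read-to-haplotype assignment (integer vector).
#' @slot trace per-iteration diagnostics (`data.frame`: restart, iter,
#'   temperature, objective).
#' @slot converged logical convergence flag.
#' @slot bestRestart index of the winning restart.
#' @slot readNames read identifiers, parallel to `labels`.
#'
#' @aliases HaplotypeFit-class
#' @export
setClass("HaplotypeFit",
  representation(state = "ModelState", labels = "integer", trace = "data.frame",
                 converged = "logical", bestRestart = "integer",
                 readNames = "character"))

#' @rdname HaplotypeFit-class
#' @param x,object a `HaplotypeFit`.
#' @export
fittedHaplotypes <- function(x) x@state@consensuses

#' @rdname HaplotypeFit-class
#' @export
readAssignments <- function(x) {
  resp <- x@state@responsibilities
  data.frame(read = x@readNames, haplotype = x@labels,
             responsibility = resp[cbind(seq_along(x@labels), x@labels)],
             stringsAsFactors = FALSE)
}

#' @rdname HaplotypeFit-class
#' @export
fitTrace <- function(x) x@trace

setMethod("show", "HaplotypeFit", function(object) {
  cat(sprintf("HaplotypeFit: K=%d, n=%d reads, objective=%.6g, %s (restart %d)\n",
              length(object@state@consensuses), length(object@labels),
              object@state@objective,
              if (object@converged) "converged" else "NOT converged",
              object@bestRestart))
})

## ---------------------------------------------------------------------------
## Simulation containers
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Everything needed to draw one synthetic dataset: ploidy `K`, number of
#' reads, per-haplotype evolution parameters, mixture weights, a sequencing
#' error profile, a read-length model, an optional structural-variant
#' configuration and a seed.
#'
#' @slot K,nReads integers.
#' @slot evolution an [EvolutionParams-class] with `K` rows.
#' @slot weights a [MixtureWeights-class] of length `K`.
#' @slot profile a [SequencingErrorProfile-class].
#' @slot readLength read-length model list (see [readLengthModel()]).
#' @slot svConfig empty list, or list with `n`, `typeProbs`, `lengths` (see
#'   [applyStructuralVariants()]).
#' @slot seed integer RNG seed.
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
  representation(K = "integer", nReads = "integer", evolution = "EvolutionParams",
                 weights = "MixtureWeights", profile = "SequencingErrorProfile",
                 readLength = "list", svConfig = "list", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (object@nReads < 1L) msg <- c(msg, "nReads must be >= 1")
  if (length(object@weights@alpha) != object@K)
    msg <- c(msg, "weights length must equal K")
  if (nrow(object@evolution@gamma) != object@K)
    msg <- c(msg, "evolution parameters must have K rows")
  if (length(msg)) msg else TRUE
})

#' @param K,nReads,evolution,weights,profile,readLength,svConfig,seed see
#'   slots.
#' @return `SimulationConfig()` returns a [SimulationConfig-class] object.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(K, nReads, evolution, weights, profile,
                             readLength = readLengthModel(), svConfig = list(),
                             seed = 1L) {
  new("SimulationConfig", K = as.integer(K), nReads = as.integer(nReads),
      evolution = evolution, weights = weights, profile = profile,
      readLength = readLength, svConfig = svConfig, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: K=%d, nReads=%d, seed=%d\n",
              object@K, object@nReads, object@seed))
})

#' Simulated dataset with full truth bookkeeping
#'
#' @slot reference the [ReferenceSequence-class] used.
#' @slot haplotypes list of `K` truth [ConsensusHaplotype-class].
#' @slot reads list of [AlignedRead-class] with `truthSource` set.
#' @slot truthSnvs list of integer vectors: per haplotype, the reference
#'   positions where the truth substitutes a base.
#' @slot truthEvents list of [ReadEvents-class], the events the generator
#'   actually injected per read (round-trip oracle).
#' @slot config the [SimulationConfig-class] echo.
#'
#' @aliases SimulatedDataset-class
#' @export
setClass("SimulatedDataset",
  representation(reference = "ReferenceSequence", haplotypes = "list",
                 reads = "list", truthSnvs = "list", truthEvents = "list",
                 config = "SimulationConfig"))

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  K <- length(object@haplotypes)
  src <- vapply(object@reads, function(r) r@truthSource, integer(1))
  if (any(is.na(src)) || any(src < 1L) || any(src > K))
    msg <- c(msg, "every read truthSource must lie in [1, K]")
  if (length(object@truthSnvs) != K)
    msg <- c(msg, "truthSnvs must have one entry per haplotype")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulatedDataset-class
#' @param x,object a `SimulatedDataset`.
#' @export
datasetReads <- function(x) x@reads

#' @rdname SimulatedDataset-class
#' @export
datasetHaplotypes <- function(x) x@haplotypes

#' @rdname SimulatedDataset-class
#' @export
datasetReference <- function(x) x@reference

#' @rdname SimulatedDataset-class
#' @export
datasetTruthSnvs <- function(x) x@truthSnvs

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: K=%d, %d reads over %s (L0=%d)\n",
              length(object@haplotypes), length(object@reads),
              object@reference@name, length(object@reference@code)))
})

## ---------------------------------------------------------------------------
## Evaluation / ingest containers
## ---------------------------------------------------------------------------

#' Evaluation scores with haplotype matching
#'
#' @slot cpr correct phasing ratio in `[0, 1]`, or `NA` when no true SNVs
#'   exist.
#' @slot mecr minimum error correction ratio in `[0, 1]`, or `NA` when not
#'   computed.
#' @slot matching integer bijection: `matching[k]` is the true haplotype
#'   matched to inferred haplotype `k`.
#' @slot perReadBest `data.frame` with per-read best haplotype and mismatch
#'   count.
#'
#' @aliases EvaluationResult-class
#' @export
setClass("EvaluationResult",
  representation(cpr = "numeric", mecr = "numeric", matching = "integer",
                 perReadBest = "data.frame"))

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (!is.na(object@cpr) && (object@cpr < 0 || object@cpr > 1))
    msg <- c(msg, "cpr must lie in [0, 1]")
  if (!is.na(object@mecr) && (object@mecr < 0 || object@mecr > 1))
    msg <- c(msg, "mecr must lie in [0, 1]")
  if (length(object@matching) &&
      !identical(sort(object@matching), seq_along(object@matching)))
    msg <- c(msg, "matching must be a bijection on 1..K")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult: CPR=%s MECR=%s matching=(%s)\n",
              format(object@cpr, digits = 4), format(object@mecr, digits = 4),
              paste(object@matching, collapse = ",")))
})

#' Ingest report for aligned-read loading
#'
#' @slot nTotal,nKept,nDroppedUnmapped,nDroppedSecondary,nDroppedFilters
#'   record counts; `nTotal` equals `nKept` plus all dropped counts.
#' @slot warnings character vector of per-record warnings.
#'
#' @aliases IngestReport-class
#' @export
setClass("IngestReport",
  representation(nTotal = "integer", nKept = "integer",
                 nDroppedUnmapped = "integer", nDroppedSecondary = "integer",
                 nDroppedFilters = "integer", warnings = "character"))

setValidity("IngestReport", function(object) {
  if (object@nTotal != object@nKept + object@nDroppedUnmapped +
      object@nDroppedSecondary + object@nDroppedFilters)
    "nTotal must equal nKept + dropped counts" else TRUE
})

setMethod("show", "IngestReport", function(object) {
  cat(sprintf(paste0("IngestReport: %d records; kept %d, unmapped %d, ",
                     "secondary/supplementary %d, filtered %d; %d warning(s)\n"),
              object@nTotal, object@nKept, object@nDroppedUnmapped,
              object@nDroppedSecondary, object@nDroppedFilters,
              length(object@warnings)))
})
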