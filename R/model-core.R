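## Likelihood core of the two-stage generative model.
##
## Evolution stage: reference r (length L0) -> consensus C_k, with
## per-position no-mutation/substitution/deletion simplex gamma_k and
## per-gap insertion probability beta_k.
## Sequencing stage: consensus C_k -> read R_i over [si, ei], with
## per-position correct/mismatch/deletion-start simplex (p1, p2, p3),
## per-gap insertion probability p4, and shifted-Poisson indel segment
## lengths (L - 1 ~ Poi(lambda)).
##
## Base-content conventions (proper distributions over observed sequences):
## a substituted/mismatched base is uniform over the 3 alternatives and an
## inserted base uniform over 4, so log(1/3) per substitution/mismatch and
## log(1/4) per inserted base enter the log-likelihoods.

## x * log(y) with the 0 * log(0) = 0 convention.
.xlogy <- function(x, y) {
  if (x == 0) return(0)
  x * log(y)
}

.LOG3 <- log(3)
.LOG4 <- log(4)

## --------------------------------------------------------------------------
## Internal fast-path event summaries (plain lists; hot loop of the EM)
## --------------------------------------------------------------------------

## Read-vs-consensus events on integer-coded slices.
## stR: read states over [s, e]; stC: consensus states over [s, e];
## insR/insC: named character vectors restricted to gaps [s, e-1];
## mask: optional logical of length e-s+1, TRUE = position excluded
## (reference N positions).
## Comparable positions are those where the consensus keeps a base and the
## read state is informative (not N, not masked). Deletion segments are
## maximal runs of read-deleted comparable positions, bridging positions the
## consensus itself deletes. Read bases emitted where the consensus has "-"
## are insertion errors at the adjacent gap.
.readEvents <- function(stR, stC, insR, insC, s, e, mask = NULL) {
  informative <- stR != .N_CODE
  if (!is.null(mask)) informative <- informative & !mask
  comp <- stC != .GAP_CODE & informative
  a <- stR[comp]
  b <- stC[comp]
  isdel <- a == .GAP_CODE
  n1 <- sum(!isdel & a == b)
  n2 <- sum(!isdel & a != b)
  if (any(isdel)) {
    r <- rle(isdel)
    dl <- r$lengths[r$values]
  } else dl <- integer()

  ## read bases over consensus-deleted positions -> insertion segments
  over <- stC == .GAP_CODE & stR != .GAP_CODE & informative
  if (any(over)) {
    r2 <- rle(over)
    il <- r2$lengths[r2$values]
  } else il <- integer()

  ## gap events under the insertion-comparison rules
  gR <- names(insR)
  gC <- names(insC)
  if (length(gR) || length(gC)) {
    onlyR <- setdiff(gR, gC)
    onlyC <- setdiff(gC, gR)
    both <- intersect(gR, gC)
    if (length(onlyR)) il <- c(il, nchar(insR[onlyR]))
    if (length(onlyC)) dl <- c(dl, nchar(insC[onlyC]))
    for (g in both) {
      rs <- insR[[g]]
      cs <- insC[[g]]
      if (!identical(rs, cs)) {
        nr <- nchar(rs); nc <- nchar(cs); m <- min(nr, nc)
        rv <- strsplit(rs, "", fixed = TRUE)[[1L]][seq_len(m)]
        cv <- strsplit(cs, "", fixed = TRUE)[[1L]][seq_len(m)]
        n2 <- n2 + sum(rv != cv) + abs(nr - nc)
      }
    }
  }
  V <- length(il)
  W <- max(0L, (e - s) - V)
  list(n1 = as.integer(n1), n2 = as.integer(n2), dl = as.integer(dl),
       il = as.integer(il), W = as.integer(W))
}

.readLogLikC <- function(ev, p1, p2, p3, p4, lIns, lDel) {
  ll <- .xlogy(ev$n1, p1) + if (ev$n2 > 0) ev$n2 * (log(p2) - .LOG3) else 0
  if (length(ev$dl))
    ll <- ll + length(ev$dl) * log(p3) + sum(stats::dpois(ev$dl - 1L, lDel, log = TRUE))
  ll <- ll + .xlogy(ev$W, 1 - p4)
  if (length(ev$il))
    ll <- ll + length(ev$il) * log(p4) +
      sum(stats::dpois(ev$il - 1L, lIns, log = TRUE)) - sum(ev$il) * .LOG4
  ll
}

## Consensus-vs-reference counts. insBases = total inserted bases.
.evoEvents <- function(stC, refCode, nInsGaps, nInsBases) {
  isN <- refCode == .N_CODE
  del <- stC == .GAP_CODE & !isN
  mat <- isN | (!del & stC == refCode)
  n1 <- sum(mat)
  n3 <- sum(del)
  n2 <- length(stC) - n1 - n3
  list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3),
       N = as.integer(nInsGaps), insBases = as.integer(nInsBases))
}

.evoLogLikC <- function(ev, g1, g2, g3, beta, L0) {
  ll <- .xlogy(ev$n1, g1) +
    (if (ev$n2 > 0) ev$n2 * (log(g2) - .LOG3) else 0) +
    .xlogy(ev$n3, g3) +
    .xlogy(L0 - 1L - ev$N, 1 - beta) + .xlogy(ev$N, beta) -
    ev$insBases * .LOG4
  ll
}

## Restrict a consensus insertion table to the gaps seen by a read.
.insInWindow <- function(ins, s, e) {
  if (!length(ins)) return(ins)
  g <- as.integer(names(ins))
  ins[g >= s & g <= e - 1L]
}

## --------------------------------------------------------------------------
## Exported operations
## --------------------------------------------------------------------------

#' Summarize a consensus haplotype against the reference
#'
#' Classifies every reference position as match, substitution or deletion
#' and counts insertion gaps, producing the evolution-stage sufficient
#' statistics. Reference `N` positions count as matches regardless of the
#' consensus state.
#'
#' @param consensus a [ConsensusHaplotype-class].
#' @param reference a [ReferenceSequence-class] of the same length.
#' @return a [ConsensusEvents-class].
#' @examples
#' ref <- ReferenceSequence("r", "ACGT")
#' hap <- ConsensusHaplotype(1, "AGG-")
#' summarizeConsensusEvents(hap, ref)
#' @export
summarizeConsensusEvents <- function(consensus, reference) {
  if (length(consensus@states) != length(reference@code))
    stop("consensus length (", length(consensus@states),
         ") does not match reference length (", length(reference@code), ")")
  ins <- consensus@insertions
  ev <- .evoEvents(consensus@states, reference@code, length(ins),
                   if (length(ins)) sum(nchar(ins)) else 0L)
  ConsensusEvents(ev$n1, ev$n2, ev$n3, ev$N, ev$insBases)
}

#' Evolution-stage log-likelihood of a consensus haplotype
#'
#' Evaluates the log of the evolution likelihood
#' \deqn{(1-\beta_k)^{L_0-1-N_k}\,\beta_k^{N_k} \prod_j \gamma_{k,j}^{n_{k,j}}}
#' with the substituted-base (uniform over 3) and inserted-base (uniform
#' over 4) content terms included. Returns `-Inf` when an observed event has
#' probability zero.
#'
#' @param events a [ConsensusEvents-class].
#' @param params an [EvolutionParams-class].
#' @param L0 reference length.
#' @param k haplotype row of `params` to use.
#' @return log-probability (scalar).
#' @export
evolutionLogLik <- function(events, params, L0, k = 1L) {
  stopifnot(events@nMatch + events@nSubstitution + events@nDeletion == L0)
  ev <- list(n1 = events@nMatch, n2 = events@nSubstitution,
             n3 = events@nDeletion, N = events@nInsertion,
             insBases = events@nInsertedBases)
  .evoLogLikC(ev, params@gamma[k, 1], params@gamma[k, 2], params@gamma[k, 3],
              params@beta[k], as.integer(L0))
}

#' Summarize a read against a consensus haplotype
#'
#' Classifies every comparable position of the covered interval `[si, ei]`
#' (positions where the consensus keeps a base) as correctly sequenced,
#' mismatched, or part of a deletion segment; maximal runs of read-deleted
#' positions form deletion segments. Consensus-deleted positions are skipped
#' from the per-position comparison; read bases observed there count as
#' insertion segments at the adjacent gap. Gap insertions are compared
#' string-wise: a read-only insertion is an insertion error, a
#' consensus-only insertion a deletion segment of its length, and two
#' differing insertions contribute mismatch-equivalents per differing base.
#'
#' @param read an [AlignedRead-class].
#' @param consensus a [ConsensusHaplotype-class] spanning the reference.
#' @param reference optional [ReferenceSequence-class]; when supplied,
#'   reference `N` positions are excluded from event counting.
#' @return a [ReadEvents-class].
#' @examples
#' hap <- ConsensusHaplotype(1, "ACGTA")
#' rd <- AlignedRead("r1", 1, 5, "AC--A")
#' summarizeReadEvents(rd, hap)
#' @export
summarizeReadEvents <- function(read, consensus, reference = NULL) {
  s <- read@start
  e <- read@end
  if (e > length(consensus@states))
    stop("read ", read@name, " extends beyond the reference (end ", e, " > L0 ",
         length(consensus@states), ")")
  idx <- s:e
  mask <- if (!is.null(reference)) reference@code[idx] == .N_CODE else NULL
  ev <- .readEvents(read@states, consensus@states[idx], read@insertions,
                    .insInWindow(consensus@insertions, s, e), s, e, mask)
  ReadEvents(ev$n1, ev$n2, ev$dl, ev$il, ev$W)
}

#' Truncated (shifted) Poisson log-pmf for indel segment lengths
#'
#' Indel segments have length at least 1; the model places `L - 1 ~
#' Poi(lambda)`, so `truncPoisLogPmf(L, lambda)` is
#' `dpois(L - 1, lambda, log = TRUE)`.
#'
#' @param length integer segment length(s), each `>= 1`.
#' @param rate positive Poisson rate.
#' @return log-probability, vectorised over `length`.
#' @export
truncPoisLogPmf <- function(length, rate) {
  if (any(length < 1L)) stop("segment length must be >= 1")
  if (rate <= 0) stop("rate must be positive")
  stats::dpois(length - 1L, rate, log = TRUE)
}

#' Sequencing-stage log-likelihood of a read given a consensus
#'
#' Evaluates the read emission log-likelihood from its event summary:
#' correct positions contribute `log p1`, mismatches `log(p2/3)`, each
#' deletion segment `log p3` plus its truncated-Poisson length term, each
#' insertion segment `log p4` plus its length term and `log(1/4)` per
#' inserted base, and each no-insertion gap `log(1 - p4)`. Returns `-Inf` on
#' zero-probability events.
#'
#' @param events a [ReadEvents-class].
#' @param profile a [SequencingErrorProfile-class].
#' @return log-probability (scalar).
#' @export
readLogLik <- function(events, profile) {
  ev <- list(n1 = events@nCorrect, n2 = events@nMismatch,
             dl = events@delSegments, il = events@insSegments,
             W = events@nGapsNoInsertion)
  .readLogLikC(ev, profile@p1, profile@p2, profile@p3, profile@p4,
               profile@lambdaIns, profile@lambdaDel)
}

#' Complete-data log-likelihood of the full model
#'
#' For hard assignments `z`, sums `log alpha_k + log P(R_i | C_k, psi)` over
#' reads and the evolution log-likelihood over haplotypes.
#'
#' @param reads list of [AlignedRead-class].
#' @param labels integer vector of hard assignments in `1..K` (or an
#'   `n x K` one-hot matrix).
#' @param consensuses list of `K` [ConsensusHaplotype-class].
#' @param weights a [MixtureWeights-class].
#' @param profile a [SequencingErrorProfile-class].
#' @param evolution an [EvolutionParams-class] with `K` rows.
#' @param reference a [ReferenceSequence-class].
#' @return log-probability (scalar).
#' @export
completeDataLogLik <- function(reads, labels, consensuses, weights, profile,
                               evolution, reference) {
  if (is.matrix(labels)) labels <- max.col(labels, ties.method = "first")
  K <- length(consensuses)
  stopifnot(length(labels) == length(reads), all(labels >= 1L), all(labels <= K))
  ll <- 0
  for (i in seq_along(reads)) {
    k <- labels[i]
    ll <- ll + log(weights@alpha[k]) +
      readLogLik(summarizeReadEvents(reads[[i]], consensuses[[k]], reference),
                 profile)
  }
  L0 <- length(reference@code)
  for (k in seq_len(K)) {
    ll <- ll + evolutionLogLik(summarizeConsensusEvents(consensuses[[k]], reference),
                               evolution, L0, k)
  }
  ll
}
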