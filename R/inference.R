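## Classification Annealing EM (CAEM): annealed expectation (AE),
## classification (C) and maximization (M) steps, multi-restart fitting,
## and five-fold cross-validated selection of the ploidy K.
##
## Numerical floors: probability estimates are floored at 1e-12 (simplexes
## renormalised) and segment-length rates at 1e-6, keeping log-likelihoods
## finite on degenerate zero-count fits.

.PMIN <- 1e-12
.LMIN <- 1e-6

## --------------------------------------------------------------------------
## Compiled internal representations (plain lists; the EM hot path)
## --------------------------------------------------------------------------

.compileReads <- function(reads, reference) {
  refCode <- reference@code
  refN <- refCode == .N_CODE
  n <- length(reads)
  s <- vapply(reads, function(r) r@start, integer(1))
  e <- vapply(reads, function(r) r@end, integer(1))
  if (any(e > length(refCode))) stop("read extends beyond the reference")
  list(n = n, L0 = length(refCode), refCode = refCode,
       s = s, e = e,
       st = lapply(reads, function(r) r@states),
       ins = lapply(reads, function(r) r@insertions),
       names = vapply(reads, function(r) r@name, character(1)),
       mask = if (any(refN)) lapply(seq_len(n), function(i) refN[s[i]:e[i]])
              else vector("list", n))
}

.compileCons <- function(hap) list(st = hap@states, ins = hap@insertions)

.consToS4 <- function(c, k) ConsensusHaplotype(k, c$st, c$ins)

.readEventsI <- function(cr, i, cons) {
  s <- cr$s[i]; e <- cr$e[i]
  .readEvents(cr$st[[i]], cons$st[s:e], cr$ins[[i]],
              .insInWindow(cons$ins, s, e), s, e, cr$mask[[i]])
}

## log-likelihood matrix (n x K) under the given consensuses and profile
.llMatrix <- function(cr, consL, prof) {
  K <- length(consL)
  ll <- matrix(0, cr$n, K)
  for (k in seq_len(K)) {
    ck <- consL[[k]]
    for (i in seq_len(cr$n)) {
      ll[i, k] <- .readLogLikC(.readEventsI(cr, i, ck), prof@p1, prof@p2,
                               prof@p3, prof@p4, prof@lambdaIns, prof@lambdaDel)
    }
  }
  ll
}

## --------------------------------------------------------------------------
## Parameter estimation from classified counts (closed forms)
## --------------------------------------------------------------------------

.clampSimplex <- function(p) {
  p <- pmax(p, .PMIN)
  p / sum(p)
}

.profileFromEvents <- function(evList, prev) {
  n1 <- sum(vapply(evList, `[[`, integer(1), "n1"))
  n2 <- sum(vapply(evList, `[[`, integer(1), "n2"))
  dl <- unlist(lapply(evList, `[[`, "dl"), use.names = FALSE)
  il <- unlist(lapply(evList, `[[`, "il"), use.names = FALSE)
  W <- sum(vapply(evList, `[[`, integer(1), "W"))
  U <- length(dl); V <- length(il)
  p123 <- .clampSimplex(c(n1, n2, U) / max(1L, n1 + n2 + U))
  p4 <- min(max(V / max(1L, V + W), .PMIN), 1 - .PMIN)
  lDel <- if (U > 0L) max(mean(dl) - 1, .LMIN) else prev@lambdaDel
  lIns <- if (V > 0L) max(mean(il) - 1, .LMIN) else prev@lambdaIns
  SequencingErrorProfile(p1 = p123[1], p2 = p123[2], p3 = p123[3], p4 = p4,
                         lambdaIns = lIns, lambdaDel = lDel)
}

.evoFromConsensus <- function(consL, refCode, tie = FALSE) {
  L0 <- length(refCode)
  K <- length(consL)
  counts <- t(vapply(consL, function(c) {
    ev <- .evoEvents(c$st, refCode, length(c$ins),
                     if (length(c$ins)) sum(nchar(c$ins)) else 0L)
    c(ev$n1, ev$n2, ev$n3, ev$N)
  }, numeric(4)))
  if (tie) counts <- matrix(colSums(counts), K, 4, byrow = TRUE) / K
  gamma <- t(apply(counts[, 1:3, drop = FALSE] / L0, 1, .clampSimplex))
  beta <- pmin(pmax(counts[, 4] / (L0 - 1L), .PMIN), 1 - .PMIN)
  EvolutionParams(gamma = gamma, beta = beta)
}

.evoLogLikAll <- function(consL, refCode, evo) {
  L0 <- length(refCode)
  total <- 0
  for (k in seq_along(consL)) {
    c <- consL[[k]]
    ev <- .evoEvents(c$st, refCode, length(c$ins),
                     if (length(c$ins)) sum(nchar(c$ins)) else 0L)
    total <- total + .evoLogLikC(ev, evo@gamma[k, 1], evo@gamma[k, 2],
                                 evo@gamma[k, 3], evo@beta[k], L0)
  }
  total
}

## --------------------------------------------------------------------------
## Consensus update (coordinate ascent with exact guarded acceptance)
## --------------------------------------------------------------------------

## 5 x L0 state-count matrix over the assigned reads (N states skipped)
.stateCounts <- function(cr, idx) {
  M <- matrix(0L, 5L, cr$L0)
  for (i in idx) {
    st <- cr$st[[i]]
    keep <- st != .N_CODE
    pos <- (cr$s[i]:cr$e[i])[keep]
    j <- (pos - 1L) * 5L + st[keep]
    M[j] <- M[j] + 1L
  }
  M
}

.evoClassOf <- function(state, ref) {
  if (ref == .N_CODE) return(1L)
  if (state == .GAP_CODE) return(3L)
  if (state == ref) 1L else 2L
}

.evoPriorLp <- function(cls, g) {
  if (cls == 1L) log(g[1]) else if (cls == 2L) log(g[2]) - .LOG3 else log(g[3])
}

## Exact sum of read log-likelihoods of reads `cov` against consensus `cons`
.readSumLL <- function(cr, cov, cons, prof) {
  total <- 0
  for (i in cov) {
    total <- total + .readLogLikC(.readEventsI(cr, i, cons), prof@p1, prof@p2,
                                  prof@p3, prof@p4, prof@lambdaIns, prof@lambdaDel)
  }
  total
}

## One consensus update for haplotype k: vectorised per-position proposal,
## then exact full-likelihood acceptance per differing position and
## insertion calls at supported gaps. Never decreases the complete-data
## objective contribution of this haplotype.
.updateConsensus <- function(cr, idx, cons, prof, gammaK, betaK) {
  L0 <- cr$L0
  ref <- cr$refCode
  M <- .stateCounts(cr, idx)
  nbase <- colSums(M[1:4, , drop = FALSE])
  ngap <- M[5L, ]
  lp1 <- log(prof@p1); lp2 <- log(prof@p2) - .LOG3
  cDel <- log(prof@p3) - prof@lambdaDel
  cIns <- log(prof@p4) - prof@lambdaIns - .LOG4
  prior <- matrix(log(gammaK[2]) - .LOG3, 5L, L0)
  prior[5L, ] <- log(gammaK[3])
  isBase <- ref <= 4L
  prior[cbind(ref[isBase], which(isBase))] <- log(gammaK[1])
  if (any(!isBase)) prior[, !isBase] <- log(gammaK[1])  # reference N: flat
  sc <- prior
  for (b in 1:4)
    sc[b, ] <- sc[b, ] + M[b, ] * lp1 + (nbase - M[b, ]) * lp2 + ngap * cDel
  sc[5L, ] <- sc[5L, ] + nbase * cIns
  cur <- cons$st
  sc[cbind(cur, seq_len(L0))] <- sc[cbind(cur, seq_len(L0))] + 1e-9  # keep current on ties
  prop <- max.col(t(sc), ties.method = "first")
  changed <- which(prop != cur)

  st <- cur
  for (l in changed) {
    cov <- idx[cr$s[idx] <= l & cr$e[idx] >= l]
    cand <- st; cand[l] <- prop[l]
    dPrior <- .evoPriorLp(.evoClassOf(prop[l], ref[l]), gammaK) -
      .evoPriorLp(.evoClassOf(st[l], ref[l]), gammaK)
    if (length(cov)) {
      before <- .readSumLL(cr, cov, list(st = st, ins = cons$ins), prof)
      after <- .readSumLL(cr, cov, list(st = cand, ins = cons$ins), prof)
      delta <- after - before + dPrior
    } else delta <- dPrior
    if (delta > 1e-12) st <- cand
  }

  ## insertion calls: gaps where at least half the covering reads insert
  ins <- cons$ins
  readGaps <- unlist(lapply(idx, function(i) names(cr$ins[[i]])), use.names = FALSE)
  candGaps <- unique(c(names(ins),
                       names(which(table(readGaps) >= 2L))))
  for (g in candGaps) {
    gi <- as.integer(g)
    cov <- idx[cr$s[idx] <= gi & cr$e[idx] >= gi + 1L]
    if (!length(cov)) { ins <- ins[setdiff(names(ins), g)]; next }
    strs <- unlist(lapply(cov, function(i) cr$ins[[i]][g]), use.names = FALSE)
    strs <- strs[!is.na(strs)]
    support <- length(strs) / length(cov)
    cands <- unique(c(NA_character_,
                      if (g %in% names(ins)) ins[[g]],
                      if (length(strs) && support >= 0.5)
                        names(sort(table(strs), decreasing = TRUE))[1L]))
    if (length(cands) < 2L) next
    best <- NULL; bestVal <- -Inf
    for (cnd in cands) {
      insC <- ins[setdiff(names(ins), g)]
      if (!is.na(cnd)) insC[g] <- cnd
      insC <- insC[order(as.integer(names(insC)))]
      val <- .readSumLL(cr, cov, list(st = st, ins = insC), prof) +
        (if (is.na(cnd)) log(1 - betaK)
         else log(betaK) - nchar(cnd) * .LOG4)
      if (val > bestVal + 1e-12) { bestVal <- val; best <- insC }
    }
    if (!is.null(best)) ins <- best
  }
  if (length(ins)) ins <- ins[order(as.integer(names(ins)))]
  list(st = st, ins = ins)
}

## --------------------------------------------------------------------------
## Core M step and objective
## --------------------------------------------------------------------------

## Returns updated parameters/consensuses plus the complete-data objective
## under the (possibly re-seeded) labels.
.mStepCore <- function(cr, labels, consL, prof, evo, tie = FALSE,
                       updateCons = TRUE, warn = TRUE) {
  K <- length(consL)
  n <- cr$n
  ## re-seed empty components with the worst-fitting read
  for (k in seq_len(K)) {
    if (!any(labels == k)) {
      ll <- .llMatrix(cr, consL, prof)
      fit <- apply(ll, 1, max)
      movable <- which(tabulate(labels, K)[labels] > 1L)
      worst <- movable[which.min(fit[movable])]
      labels[worst] <- k
      if (warn)
        warning("empty haplotype ", k, " re-seeded with read ", cr$names[worst],
                call. = FALSE)
    }
  }
  alpha <- tabulate(labels, K) / n
  if (updateCons) {
    for (k in seq_len(K)) {
      consL[[k]] <- .updateConsensus(cr, which(labels == k), consL[[k]], prof,
                                     evo@gamma[k, ], evo@beta[k])
    }
  }
  evList <- lapply(seq_len(n), function(i) .readEventsI(cr, i, consL[[labels[i]]]))
  prof <- .profileFromEvents(evList, prof)
  evo <- .evoFromConsensus(consL, cr$refCode, tie = tie)
  readLL <- vapply(evList, function(ev)
    .readLogLikC(ev, prof@p1, prof@p2, prof@p3, prof@p4,
                 prof@lambdaIns, prof@lambdaDel), numeric(1))
  obj <- sum(log(alpha[labels])) + sum(readLL) +
    .evoLogLikAll(consL, cr$refCode, evo)
  list(labels = labels, alpha = alpha, consL = consL, prof = prof, evo = evo,
       objective = obj)
}

.annealedResp <- function(ll, alpha, temperature, names) {
  logW <- sweep(ll, 2L, log(alpha), "+")
  rowMax <- apply(logW, 1L, max)
  bad <- !is.finite(rowMax)
  if (any(bad))
    stop("read(s) with zero likelihood under every haplotype: ",
         paste(names[bad], collapse = ", "))
  resp <- exp((logW - rowMax) / temperature)
  resp / rowSums(resp)
}

## --------------------------------------------------------------------------
## Exported steps
## --------------------------------------------------------------------------

#' Initialize a CAEM model state
#'
#' Reads are randomly hard-partitioned into `K` groups (or assigned by
#' `labels` when given); each consensus is initialized to the
#' reference-projected plurality call of its group (uncovered positions
#' revert to the reference), and the parameters to closed-form estimates
#' from the resulting global event counts.
#'
#' @param reads list of [AlignedRead-class].
#' @param reference a [ReferenceSequence-class].
#' @param K number of haplotypes.
#' @param seed RNG seed for the random partition.
#' @param labels optional explicit integer assignment overriding the random
#'   partition.
#' @return a [ModelState-class].
#' @export
initializeState <- function(reads, reference, K, seed = 1L, labels = NULL) {
  K <- as.integer(K)
  if (length(reads) < K) stop("need at least K reads to initialize K haplotypes")
  cr <- .compileReads(reads, reference)
  if (is.null(labels)) {
    set.seed(seed)
    labels <- sample.int(K, cr$n, replace = TRUE)
    missing <- setdiff(seq_len(K), unique(labels))
    for (k in missing) labels[sample.int(cr$n, 1L)] <- k
    while (length(setdiff(seq_len(K), unique(labels)))) {
      k <- setdiff(seq_len(K), unique(labels))[1L]
      labels[sample.int(cr$n, 1L)] <- k
    }
  } else labels <- as.integer(labels)
  consL <- lapply(seq_len(K), function(k) .pluralityCons(cr, which(labels == k)))
  prof0 <- SequencingErrorProfile(p2 = 0.01, p3 = 0.005, p4 = 0.005)
  evList <- lapply(seq_len(cr$n), function(i) .readEventsI(cr, i, consL[[labels[i]]]))
  prof <- .profileFromEvents(evList, prof0)
  evo <- .evoFromConsensus(consL, cr$refCode)
  alpha <- tabulate(labels, K) / cr$n
  resp <- matrix(0, cr$n, K)
  resp[cbind(seq_len(cr$n), labels)] <- 1
  obj <- sum(log(alpha[labels])) +
    sum(vapply(evList, function(ev)
      .readLogLikC(ev, prof@p1, prof@p2, prof@p3, prof@p4,
                   prof@lambdaIns, prof@lambdaDel), numeric(1))) +
    .evoLogLikAll(consL, cr$refCode, evo)
  ModelState(consensuses = lapply(seq_len(K), function(k) .consToS4(consL[[k]], k)),
             weights = MixtureWeights(alpha), profile = prof, evolution = evo,
             responsibilities = resp, temperature = 1, objective = obj)
}

## plurality consensus of a read group, projected on the reference
.pluralityCons <- function(cr, idx) {
  M <- .stateCounts(cr, idx)
  cov <- colSums(M)
  ## ties and zero coverage resolve toward the reference state
  refRow <- ifelse(cr$refCode <= 4L, cr$refCode, 1L)
  M[cbind(refRow, seq_len(cr$L0))] <- M[cbind(refRow, seq_len(cr$L0))] + 0.5
  st <- max.col(t(M), ties.method = "first")
  st[cov == 0L] <- refRow[cov == 0L]
  ins <- character()
  readGaps <- unlist(lapply(idx, function(i) names(cr$ins[[i]])), use.names = FALSE)
  for (g in names(which(table(readGaps) >= 2L))) {
    gi <- as.integer(g)
    cov2 <- idx[cr$s[idx] <= gi & cr$e[idx] >= gi + 1L]
    strs <- unlist(lapply(cov2, function(i) cr$ins[[i]][g]), use.names = FALSE)
    strs <- strs[!is.na(strs)]
    if (length(strs) > length(cov2) / 2)
      ins[g] <- names(sort(table(strs), decreasing = TRUE))[1L]
  }
  list(st = st, ins = ins)
}

#' Annealed expectation (AE) step
#'
#' Computes responsibilities proportional to
#' `(alpha_k P(R_i | C_k, psi))^(1/T)`, normalized per read in log-space.
#' At `T = 1` this is the standard posterior; as `T` grows the rows tend to
#' uniform.
#'
#' @param reads list of [AlignedRead-class].
#' @param state a [ModelState-class] (its `temperature` slot supplies `T`).
#' @param reference optional [ReferenceSequence-class] for `N` masking.
#' @return `n x K` responsibility matrix.
#' @export
aeStep <- function(reads, state, reference = NULL) {
  cr <- .compileReads(reads, .refFromState(state, reference))
  consL <- lapply(state@consensuses, .compileCons)
  ll <- .llMatrix(cr, consL, state@profile)
  .annealedResp(ll, state@weights@alpha, state@temperature, cr$names)
}

## reads only need the reference for N masking and bounds; reconstruct a
## plain A-backbone when not supplied (consensus length fixes L0)
.refFromState <- function(state, reference) {
  if (!is.null(reference)) return(reference)
  L0 <- length(state@consensuses[[1L]]@states)
  new("ReferenceSequence", name = "ref", code = rep(1L, L0))
}

#' Classification (C) step
#'
#' Per-read argmax of the responsibility table; ties break toward the
#' lowest haplotype index.
#'
#' @param responsibilities `n x K` matrix.
#' @return integer label vector.
#' @export
cStep <- function(responsibilities) {
  max.col(responsibilities, ties.method = "first")
}

#' Maximization (M) step
#'
#' Closed-form parameter updates from the classified counts (mixture
#' weights, sequencing profile, evolution parameters) and a coordinate
#' consensus update: each reference position moves to the state maximizing
#' the read-emission terms of the assigned reads plus the evolution prior,
#' accepted only if the exact complete-data log-likelihood does not
#' decrease; insertions are called at gaps supported by the assigned reads.
#' Empty haplotypes are re-seeded with the worst-fitting read (with a
#' warning).
#'
#' @param reads list of [AlignedRead-class].
#' @param labels integer hard assignment in `1..K`.
#' @param reference a [ReferenceSequence-class].
#' @param state the current [ModelState-class].
#' @param tieEvolution estimate a single shared evolution row.
#' @return the updated [ModelState-class]; its `objective` slot holds the
#'   complete-data log-likelihood under `labels` and the new parameters.
#' @export
mStep <- function(reads, labels, reference, state, tieEvolution = FALSE) {
  cr <- .compileReads(reads, reference)
  consL <- lapply(state@consensuses, .compileCons)
  res <- .mStepCore(cr, as.integer(labels), consL, state@profile,
                    state@evolution, tie = tieEvolution)
  resp <- matrix(0, cr$n, length(consL))
  resp[cbind(seq_len(cr$n), res$labels)] <- 1
  ModelState(consensuses = lapply(seq_along(res$consL),
                                  function(k) .consToS4(res$consL[[k]], k)),
             weights = MixtureWeights(res$alpha), profile = res$prof,
             evolution = res$evo, responsibilities = resp,
             temperature = state@temperature, objective = res$objective)
}

#' Fit the model by Classification Annealing EM
#'
#' Loops AE, C and M steps under a geometric temperature schedule
#' `T_{t+1} = max(1, cooling * T_t)`. While `T > 1` the classification step
#' samples labels from the annealed responsibilities (a stochastic search
#' that the cooling gradually hardens); at `T = 1` it is the deterministic
#' argmax, giving monotone classification-EM iterations. The fit stops when
#' the relative objective change at `T = 1` drops below `tol` or `maxIter`
#' is reached, and the best of `nRestarts` random restarts (by final
#' objective) is returned.
#'
#' @param reads list of [AlignedRead-class].
#' @param reference a [ReferenceSequence-class].
#' @param K number of haplotypes.
#' @param config a [FitConfig-class].
#' @return a [HaplotypeFit-class].
#' @export
runCAEM <- function(reads, reference, K, config = FitConfig()) {
  K <- as.integer(K)
  cr <- .compileReads(reads, reference)
  if (cr$n < K) stop("need at least K reads to fit K haplotypes")
  best <- NULL
  traceAll <- list()
  for (r in seq_len(config@nRestarts)) {
    set.seed(config@seed + r - 1L)
    labels <- sample.int(K, cr$n, replace = TRUE)
    for (k in setdiff(seq_len(K), unique(labels)))
      labels[sample.int(cr$n, 1L)] <- k
    consL <- lapply(seq_len(K), function(k) .pluralityCons(cr, which(labels == k)))
    prof <- .profileFromEvents(
      lapply(seq_len(cr$n), function(i) .readEventsI(cr, i, consL[[labels[i]]])),
      SequencingErrorProfile(p2 = 0.01, p3 = 0.005, p4 = 0.005))
    evo <- .evoFromConsensus(consL, cr$refCode)
    alpha <- tabulate(labels, K) / cr$n
    temp <- config@T0
    prevObj <- -Inf
    converged <- FALSE
    trace <- data.frame(restart = integer(), iter = integer(),
                        temperature = numeric(), objective = numeric())
    res <- NULL
    for (iter in seq_len(config@maxIter)) {
      ll <- .llMatrix(cr, consL, prof)
      resp <- .annealedResp(ll, alpha, temp, cr$names)
      if (temp > 1 + 1e-9) {
        labels <- vapply(seq_len(cr$n), function(i)
          sample.int(K, 1L, prob = resp[i, ]), integer(1))
      } else {
        labels <- max.col(resp, ties.method = "first")
      }
      res <- .mStepCore(cr, labels, consL, prof, evo, tie = config@tieEvolution,
                        warn = FALSE)
      labels <- res$labels; consL <- res$consL; prof <- res$prof
      evo <- res$evo; alpha <- res$alpha
      trace <- rbind(trace, data.frame(restart = r, iter = iter,
                                       temperature = temp,
                                       objective = res$objective))
      if (temp <= 1 + 1e-9) {
        if (is.finite(prevObj) &&
            abs(res$objective - prevObj) <= config@tol * max(1, abs(prevObj))) {
          converged <- TRUE
          break
        }
        prevObj <- res$objective
      }
      temp <- max(1, config@cooling * temp)
    }
    ## final polish: one deterministic C step under the final parameters
    ll <- .llMatrix(cr, consL, prof)
    resp <- .annealedResp(ll, alpha, 1, cr$names)
    labels <- max.col(resp, ties.method = "first")
    if (length(unique(labels)) == K) {
      res <- .mStepCore(cr, labels, consL, prof, evo, tie = config@tieEvolution,
                        updateCons = FALSE, warn = FALSE)
      labels <- res$labels; consL <- res$consL; prof <- res$prof
      evo <- res$evo; alpha <- res$alpha
      ll <- .llMatrix(cr, consL, prof)
      resp <- .annealedResp(ll, alpha, 1, cr$names)
    }
    traceAll[[r]] <- trace
    if (is.null(best) || res$objective > best$objective + 1e-12) {
      best <- list(objective = res$objective, labels = labels, consL = consL,
                   prof = prof, evo = evo, alpha = alpha, resp = resp,
                   converged = converged, restart = r)
    }
  }
  if (!best$converged)
    warning("CAEM did not converge within maxIter; returning best state",
            call. = FALSE)
  state <- ModelState(
    consensuses = lapply(seq_len(K), function(k) .consToS4(best$consL[[k]], k)),
    weights = MixtureWeights(best$alpha), profile = best$prof,
    evolution = best$evo, responsibilities = best$resp, temperature = 1,
    objective = best$objective)
  new("HaplotypeFit", state = state, labels = as.integer(best$labels),
      trace = do.call(rbind, traceAll), converged = best$converged,
      bestRestart = as.integer(best$restart), readNames = cr$names)
}

## --------------------------------------------------------------------------
## Model selection
## --------------------------------------------------------------------------

#' Result of cross-validated ploidy selection
#'
#' @slot chosenK selected number of haplotypes.
#' @slot table per-K cross-validated MECR summary (`data.frame`: K,
#'   meanMECR, seMECR).
#' @slot folds fold assignment used.
#'
#' @aliases KSelection-class
#' @export
setClass("KSelection",
  representation(chosenK = "integer", table = "data.frame", folds = "integer"))

setMethod("show", "KSelection", function(object) {
  cat("KSelection: chosen K =", object@chosenK, "\n")
  print(object@table, row.names = FALSE)
})

#' @rdname KSelection-class
#' @param x a `KSelection`.
#' @export
chosenK <- function(x) x@chosenK

#' @rdname KSelection-class
#' @export
selectionTable <- function(x) x@table

#' Choose the number of haplotypes by cross-validated MECR
#'
#' Reads are partitioned into five folds (seeded by `config@seed`); for
#' each candidate `K` the model is fitted on four folds and the MECR of the
#' held-out reads against the fitted haplotypes is recorded. The chosen `K`
#' minimizes the mean held-out MECR, with near-ties (within one standard
#' error of the minimizer) resolved toward the smallest `K` — held-out MECR
#' typically improves only marginally beyond the true ploidy.
#'
#' @param reads list of [AlignedRead-class].
#' @param reference a [ReferenceSequence-class].
#' @param kValues integer vector of candidate ploidies.
#' @param config a [FitConfig-class] (used for every fold fit).
#' @param nFolds number of folds.
#' @return a [KSelection-class].
#' @export
selectK <- function(reads, reference, kValues, config = FitConfig(),
                    nFolds = 5L) {
  n <- length(reads)
  kValues <- sort(as.integer(kValues))
  if (n < nFolds) {
    warning("fewer than ", nFolds, " reads; falling back to in-sample MECR",
            call. = FALSE)
    scores <- vapply(kValues, function(K) {
      fit <- runCAEM(reads, reference, K, config)
      mecr(reads, fittedHaplotypes(fit))
    }, numeric(1))
    tab <- data.frame(K = kValues, meanMECR = scores, seMECR = NA_real_)
    return(new("KSelection", chosenK = kValues[which.min(scores)], table = tab,
               folds = rep(1L, n)))
  }
  set.seed(config@seed)
  folds <- sample(rep_len(seq_len(nFolds), n))
  if (any(tabulate(folds, nFolds) > n - max(kValues)))
    stop("each fold must leave at least K reads in training")
  scores <- matrix(NA_real_, length(kValues), nFolds)
  for (ki in seq_along(kValues)) {
    K <- kValues[ki]
    for (f in seq_len(nFolds)) {
      train <- reads[folds != f]
      test <- reads[folds == f]
      fit <- runCAEM(train, reference, K, config)
      scores[ki, f] <- mecr(test, fittedHaplotypes(fit))
    }
  }
  meanMECR <- rowMeans(scores)
  seMECR <- apply(scores, 1, stats::sd) / sqrt(nFolds)
  iMin <- which.min(meanMECR)
  eligible <- which(meanMECR <= meanMECR[iMin] + seMECR[iMin])
  chosen <- kValues[min(eligible)]
  tab <- data.frame(K = kValues, meanMECR = meanMECR, seMECR = seMECR)
  new("KSelection", chosenK = as.integer(chosen), table = tab,
      folds = as.integer(folds))
}
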