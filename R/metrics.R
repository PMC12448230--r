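## Evaluation statistics: correct phasing ratio (CPR) under the optimal
## one-to-one haplotype matching, minimum error correction ratio (MECR),
## and the SNV-calling byproduct.

.permutations <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (p in .permutations(K - 1L)) {
      q <- seq_len(K)[-i]
      out[[length(out) + 1L]] <- c(i, q[p])
    }
  }
  out
}

## substitution positions of a haplotype relative to the reference
.snvPositions <- function(hap, reference) {
  which(hap@states != .GAP_CODE & reference@code != .N_CODE &
        hap@states != reference@code)
}

#' Optimal one-to-one haplotype matching
#'
#' Returns the bijection `chi` from inferred to true haplotype indices that
#' maximizes the total per-position agreement over the SNV sets, found by
#' exhaustive search over the `K!` permutations.
#'
#' @param trueHaps,inferredHaps lists of [ConsensusHaplotype-class] of equal
#'   length.
#' @param reference a [ReferenceSequence-class].
#' @param snvSets optional list of integer position vectors, one per true
#'   haplotype; defaults to each true haplotype's substitution positions.
#' @return integer vector `chi`; `chi[k]` is the true haplotype matched to
#'   inferred haplotype `k`.
#' @export
bestMatching <- function(trueHaps, inferredHaps, reference, snvSets = NULL) {
  K <- length(trueHaps)
  if (length(inferredHaps) != K)
    stop("true and inferred haplotype counts differ (", K, " vs ",
         length(inferredHaps), ")")
  if (is.null(snvSets))
    snvSets <- lapply(trueHaps, .snvPositions, reference = reference)
  agree <- matrix(0L, K, K)  # agree[k, t]: inferred k vs true t over D_t
  for (t in seq_len(K)) {
    D <- snvSets[[t]]
    for (k in seq_len(K)) {
      agree[k, t] <- sum(inferredHaps[[k]]@states[D] == trueHaps[[t]]@states[D])
    }
  }
  perms <- .permutations(K)
  tot <- vapply(perms, function(p) sum(agree[cbind(seq_len(K), p)]), numeric(1))
  as.integer(perms[[which.max(tot)]])
}

#' Correct phasing ratio (CPR)
#'
#' The fraction of true-SNV alleles reproduced by the inferred haplotypes
#' under the optimal one-to-one matching:
#' \deqn{\mathrm{CPR} = \frac{\sum_k \sum_{j \in D_{\chi(k)}}
#'   1(\hat H_k(j) = H^T_{\chi(k)}(j))}{\sum_k |D_{\chi(k)}|}.}
#' `D_t` defaults to the positions where true haplotype `t` substitutes a
#' base relative to the reference.
#'
#' @inheritParams bestMatching
#' @return a number in `[0, 1]`, or `NA` when the union of true SNV sets is
#'   empty (CPR undefined).
#' @export
cpr <- function(trueHaps, inferredHaps, reference, snvSets = NULL) {
  if (is.null(snvSets))
    snvSets <- lapply(trueHaps, .snvPositions, reference = reference)
  total <- sum(lengths(snvSets))
  if (total == 0L) {
    warning("no true SNV positions; CPR undefined", call. = FALSE)
    return(NA_real_)
  }
  chi <- bestMatching(trueHaps, inferredHaps, reference, snvSets)
  agree <- 0L
  for (k in seq_along(inferredHaps)) {
    D <- snvSets[[chi[k]]]
    agree <- agree + sum(inferredHaps[[k]]@states[D] ==
                         trueHaps[[chi[k]]]@states[D])
  }
  agree / total
}

## per-read best-haplotype mismatch counts over the interest sets
.mecrCore <- function(reads, consL, sites = NULL) {
  K <- length(consL)
  n <- length(reads)
  mism <- integer(n)
  bestK <- integer(n)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    r <- reads[[i]]
    pos <- r@start:r@end
    keep <- r@states != .N_CODE
    if (!is.null(sites)) keep <- keep & (pos %in% sites)
    st <- r@states[keep]
    posK <- pos[keep]
    sizes[i] <- length(st)
    if (length(st) == 0L) { mism[i] <- 0L; bestK[i] <- 1L; next }
    counts <- vapply(consL, function(c) sum(st != c$st[posK]), integer(1))
    bestK[i] <- which.min(counts)
    mism[i] <- counts[bestK[i]]
  }
  list(mism = mism, bestK = bestK, sizes = sizes)
}

#' Minimum error correction ratio (MECR)
#'
#' The per-base inconsistency rate between reads and their best-matching
#' inferred haplotype:
#' \deqn{\mathrm{MECR} = \frac{\sum_i \min_k \sum_{j \in O_i}
#'   1(R_i(j) \neq \hat H_k(j))}{\sum_i |O_i|},}
#' where the interest set `O_i` defaults to all reference positions covered
#' by read `i` and can be restricted to a site list. Deleted positions
#' compare as ordinary symbols (a read gap against a haplotype base counts
#' as one inconsistency); read `N` positions are excluded.
#'
#' @param reads list of [AlignedRead-class].
#' @param inferredHaps list of [ConsensusHaplotype-class].
#' @param sites optional integer vector of 1-based reference positions
#'   restricting the interest sets.
#' @return a number in `[0, 1]`, with the per-read minima available via
#'   `attr(, "perReadBest")`.
#' @export
mecr <- function(reads, inferredHaps, sites = NULL) {
  consL <- lapply(inferredHaps, .compileCons)
  res <- .mecrCore(reads, consL, sites)
  total <- sum(res$sizes)
  if (total == 0L) stop("all interest sets are empty")
  out <- sum(res$mism) / total
  attr(out, "perReadBest") <- data.frame(
    read = vapply(reads, function(r) r@name, character(1)),
    haplotype = res$bestK, mismatches = res$mism, interestSize = res$sizes,
    stringsAsFactors = FALSE)
  out
}

#' Evaluate inferred haplotypes against truth and reads
#'
#' Convenience wrapper computing CPR (when truth is available), MECR (when
#' reads are available) and the optimal matching in one
#' [EvaluationResult-class].
#'
#' @param inferredHaps list of [ConsensusHaplotype-class].
#' @param reference a [ReferenceSequence-class].
#' @param trueHaps optional list of true [ConsensusHaplotype-class].
#' @param reads optional list of [AlignedRead-class].
#' @param sites optional site restriction for MECR.
#' @param snvSets optional true-SNV sets for CPR.
#' @return an [EvaluationResult-class].
#' @export
evaluateHaplotypes <- function(inferredHaps, reference, trueHaps = NULL,
                               reads = NULL, sites = NULL, snvSets = NULL) {
  cprVal <- NA_real_
  matching <- integer()
  if (!is.null(trueHaps)) {
    cprVal <- suppressWarnings(cpr(trueHaps, inferredHaps, reference, snvSets))
    matching <- bestMatching(trueHaps, inferredHaps, reference, snvSets)
  }
  mecrVal <- NA_real_
  perRead <- data.frame()
  if (!is.null(reads)) {
    m <- mecr(reads, inferredHaps, sites)
    perRead <- attr(m, "perReadBest")
    mecrVal <- as.numeric(m)
  }
  new("EvaluationResult", cpr = cprVal, mecr = mecrVal, matching = matching,
      perReadBest = perRead)
}

#' Call SNVs (and consensus indels) from inferred haplotypes
#'
#' The byproduct of direct haplotype inference: any reference position where
#' at least one haplotype carries a substitution yields an SNV record with
#' per-haplotype alleles; consensus deletions and insertions are reported as
#' separate rows flagged by `class` (`"del"` / `"ins"`, not SNVs).
#'
#' @param inferredHaps list of [ConsensusHaplotype-class].
#' @param reference a [ReferenceSequence-class].
#' @return a `data.frame` with columns `pos`, `ref`, `alt` (comma-separated
#'   alternate alleles), `class` (`"snv"`, `"del"` or `"ins"`), `genotype`
#'   (pipe-separated per-haplotype allele indices, 0 = reference) and one
#'   `hapK` allele column per haplotype.
#' @export
callSnvs <- function(inferredHaps, reference) {
  K <- length(inferredHaps)
  L0 <- length(reference@code)
  stM <- vapply(inferredHaps, function(h) h@states, integer(L0))
  if (is.null(dim(stM))) stM <- matrix(stM, ncol = K)
  refC <- reference@code
  isSub <- stM != refC & stM != .GAP_CODE & refC != .N_CODE
  isDel <- stM == .GAP_CODE & refC != .N_CODE
  rows <- list()
  mkRow <- function(pos, class) {
    alleles <- .STATE_CHARS[stM[pos, ]]
    refB <- .STATE_CHARS[refC[pos]]
    alt <- setdiff(unique(alleles), refB)
    gt <- match(alleles, c(refB, alt)) - 1L
    row <- data.frame(pos = pos, ref = refB,
                      alt = paste(alt, collapse = ","), class = class,
                      genotype = paste(gt, collapse = "|"),
                      stringsAsFactors = FALSE)
    for (k in seq_len(K)) row[[paste0("hap", k)]] <- alleles[k]
    row
  }
  for (pos in which(rowSums(isSub) > 0L)) rows[[length(rows) + 1L]] <- mkRow(pos, "snv")
  for (pos in which(rowSums(isDel) > 0L & rowSums(isSub) == 0L))
    rows[[length(rows) + 1L]] <- mkRow(pos, "del")
  insGaps <- sort(unique(as.integer(unlist(lapply(inferredHaps, function(h)
    names(h@insertions))))))
  for (g in insGaps) {
    key <- as.character(g)
    strs <- vapply(inferredHaps, function(h)
      if (key %in% names(h@insertions)) h@insertions[[key]] else "", character(1))
    row <- data.frame(pos = g, ref = .STATE_CHARS[refC[g]],
                      alt = paste(unique(strs[strs != ""]), collapse = ","),
                      class = "ins", genotype = paste(as.integer(strs != ""),
                                                      collapse = "|"),
                      stringsAsFactors = FALSE)
    for (k in seq_len(K)) row[[paste0("hap", k)]] <- strs[k]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(pos = integer(), ref = character(), alt = character(),
                      class = character(), genotype = character(),
                      stringsAsFactors = FALSE)
    for (k in seq_len(K)) out[[paste0("hap", k)]] <- character()
    return(out)
  }
  out <- do.call(rbind, rows)
  out[order(out$pos, out$class), , drop = FALSE]
}
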