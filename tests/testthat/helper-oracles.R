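# Independent brute-force oracles: literal position-by-position product
# evaluation of the generative model, written with character states and
# explicit loops, sharing no code with the package internals.

CHARS <- c("A", "C", "G", "T")

# literal product form of the read emission probability
oracleReadLogLik <- function(read, cons, prof) {
  s <- readInterval(read)[["start"]]
  e <- readInterval(read)[["end"]]
  rSt <- readStates(read)
  cSt <- hapStates(cons)[s:e]
  p1 <- prof@p1; p2 <- prof@p2; p3 <- prof@p3; p4 <- prof@p4
  lIns <- prof@lambdaIns; lDel <- prof@lambdaDel
  ll <- 0
  # deletion segments: maximal "-" runs over the comparable positions
  compR <- rSt[cSt != "-" & rSt != "N"]
  i <- 1
  while (i <= length(compR)) {
    if (compR[i] == "-") {
      L <- 0
      while (i <= length(compR) && compR[i] == "-") { L <- L + 1; i <- i + 1 }
      ll <- ll + log(p3) + dpois(L - 1, lDel, log = TRUE)
    } else i <- i + 1
  }
  # per-position correct/mismatch terms
  for (j in seq_along(cSt)) {
    if (cSt[j] == "-" || rSt[j] == "N" || rSt[j] == "-") next
    if (rSt[j] == cSt[j]) ll <- ll + log(p1)
    else ll <- ll + log(p2 / 3)
  }
  # read bases over consensus-deleted positions: insertion segments
  over <- cSt == "-" & rSt != "-" & rSt != "N"
  j <- 1
  nIns <- 0
  while (j <= length(over)) {
    if (over[j]) {
      L <- 0
      while (j <= length(over) && over[j]) { L <- L + 1; j <- j + 1 }
      ll <- ll + log(p4) + dpois(L - 1, lIns, log = TRUE) + L * log(1 / 4)
      nIns <- nIns + 1
    } else j <- j + 1
  }
  # gap insertion events
  rIns <- read@insertions
  cIns <- cons@insertions
  cIns <- cIns[as.integer(names(cIns)) >= s & as.integer(names(cIns)) <= e - 1]
  for (g in union(names(rIns), names(cIns))) {
    inR <- g %in% names(rIns)
    inC <- g %in% names(cIns)
    if (inR && !inC) {
      L <- nchar(rIns[[g]])
      ll <- ll + log(p4) + dpois(L - 1, lIns, log = TRUE) + L * log(1 / 4)
      nIns <- nIns + 1
    } else if (!inR && inC) {
      L <- nchar(cIns[[g]])
      ll <- ll + log(p3) + dpois(L - 1, lDel, log = TRUE)
    } else if (!identical(rIns[[g]], cIns[[g]])) {
      a <- strsplit(rIns[[g]], "")[[1]]
      b <- strsplit(cIns[[g]], "")[[1]]
      m <- min(length(a), length(b))
      nDiff <- sum(a[seq_len(m)] != b[seq_len(m)]) + abs(length(a) - length(b))
      ll <- ll + nDiff * log(p2 / 3)
    }
  }
  Li <- e - s + 1
  ll + (Li - 1 - nIns) * log(1 - p4)
}

# literal product form of the evolution probability of a consensus
oracleEvoLogLik <- function(cons, ref, gamma, beta) {
  cSt <- hapStates(cons)
  rSt <- strsplit(as.character(ref), "")[[1]]
  ll <- 0
  for (l in seq_along(rSt)) {
    if (rSt[l] == "N") { ll <- ll + log(gamma[1]); next }
    if (cSt[l] == "-") ll <- ll + log(gamma[3])
    else if (cSt[l] == rSt[l]) ll <- ll + log(gamma[1])
    else ll <- ll + log(gamma[2] / 3)
  }
  ins <- cons@insertions
  for (g in seq_len(length(rSt) - 1)) {
    if (as.character(g) %in% names(ins))
      ll <- ll + log(beta) + nchar(ins[[as.character(g)]]) * log(1 / 4)
    else ll <- ll + log(1 - beta)
  }
  ll
}

# conditionally optimal objective for a fixed hard labeling: iterate the
# M step to a fixed point
conditionalObjective <- function(reads, ref, labels, K, maxSweeps = 50) {
  st <- initializeState(reads, ref, K, labels = labels)
  prev <- -Inf
  for (sweep in seq_len(maxSweeps)) {
    st <- suppressWarnings(mStep(reads, labels, ref, st))
    if (is.finite(prev) && abs(stateObjective(st) - prev) < 1e-10) break
    prev <- stateObjective(st)
  }
  stateObjective(st)
}
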