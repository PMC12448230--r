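# Programmatic fixtures shared across test files.

randomRef <- function(L0, seed = 1, name = "ref") {
  set.seed(seed)
  ReferenceSequence(name, paste(sample(CHARS, L0, replace = TRUE), collapse = ""))
}

# small random consensus/read instances for the product-oracle sweeps
randomInstance <- function(seed, L0 = 12) {
  set.seed(seed)
  ref <- ReferenceSequence("r", paste(sample(CHARS, L0, TRUE), collapse = ""))
  cSt <- sample(c(CHARS, "-"), L0, TRUE, prob = c(rep(0.22, 4), 0.12))
  if (all(cSt == "-")) cSt[1] <- "A"
  cIns <- character()
  for (g in seq_len(L0 - 1)) {
    if (runif(1) < 0.15)
      cIns[as.character(g)] <- paste(sample(CHARS, 1 + rpois(1, 0.7), TRUE),
                                     collapse = "")
  }
  cons <- ConsensusHaplotype(1, cSt, cIns)
  s <- sample.int(L0 - 4, 1)
  e <- min(L0, s + 3 + sample.int(6, 1))
  rSt <- sample(c(CHARS, "-"), e - s + 1, TRUE, prob = c(rep(0.22, 4), 0.12))
  if (all(rSt == "-")) rSt[1] <- "C"
  rIns <- character()
  if (e - s >= 1) {
    for (g in s:(e - 1)) {
      if (runif(1) < 0.15)
        rIns[as.character(g)] <- paste(sample(CHARS, 1 + rpois(1, 0.7), TRUE),
                                       collapse = "")
    }
  }
  list(ref = ref, cons = cons,
       read = AlignedRead("rd", s, e, rSt, rIns))
}

testProfile <- function() {
  SequencingErrorProfile(p2 = 0.05, p3 = 0.04, p4 = 0.03,
                         lambdaIns = 0.8, lambdaDel = 1.3)
}

# well-separated two-haplotype instance with error-free reads: haplotypes
# differ by `nSub` substitutions, reads are exact copies of segments
separableDataset <- function(L0 = 60, nSub = 20, nReads = 40, seed = 5) {
  set.seed(seed)
  ref <- ReferenceSequence("ref", paste(sample(CHARS, L0, TRUE), collapse = ""))
  st1 <- strsplit(as.character(ref), "")[[1]]
  st2 <- st1
  subPos <- sort(sample.int(L0, nSub))
  for (p in subPos) st2[p] <- sample(setdiff(CHARS, st2[p]), 1)
  haps <- list(ConsensusHaplotype(1, st1), ConsensusHaplotype(2, st2))
  reads <- lapply(seq_len(nReads), function(i) {
    k <- 1 + (i %% 2)
    s <- sample.int(L0 %/% 2, 1)
    e <- min(L0, s + L0 %/% 2 + sample.int(L0 %/% 4, 1))
    AlignedRead(sprintf("r%03d", i), s, e,
                hapStates(haps[[k]])[s:e], truthSource = k)
  })
  list(ref = ref, haps = haps, reads = reads,
       truth = vapply(reads, function(r) r@truthSource, integer(1)))
}

# simulation conditions for the small model-selection and anticorrelation
# studies: short backbone, elevated substitution rate, full-ish reads
separationConfig <- function(K, nReads, level = 1, seed = 1) {
  gam <- c(0.975, 0.02, 0.005)
  SimulationConfig(
    K = K, nReads = nReads,
    evolution = EvolutionParams(gamma = matrix(rep(gam, K), ncol = 3, byrow = TRUE),
                                beta = rep(1e-4, K)),
    weights = MixtureWeights(rep(1 / K, K)),
    profile = errorProfilePreset(level),
    readLength = readLengthModel("lognormal", medianLength = 220, sdlog = 0.25,
                                 min = 120),
    seed = seed)
}

# serialize AlignedReads to a SAM file (inverse of the ingest bridge)
samFromReads <- function(reads, ref, path) {
  recs <- vapply(reads, function(r) {
    st <- readStates(r)
    ins <- r@insertions
    ops <- character(0)
    lens <- integer(0)
    seqParts <- character(0)
    push <- function(op, len) {
      if (length(ops) && ops[length(ops)] == op)
        lens[length(lens)] <<- lens[length(lens)] + len
      else { ops[length(ops) + 1L] <<- op; lens[length(lens) + 1L] <<- len }
    }
    for (j in seq_along(st)) {
      p <- r@start + j - 1L
      if (st[j] == "-") push("D", 1L)
      else { push("M", 1L); seqParts <- c(seqParts, st[j]) }
      key <- as.character(p)
      if (p < r@end && key %in% names(ins)) {
        push("I", nchar(ins[[key]]))
        seqParts <- c(seqParts, ins[[key]])
      }
    }
    cigar <- paste0(lens, ops, collapse = "")
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*", r@name, refName(ref),
            r@start, cigar, paste(seqParts, collapse = ""))
  }, character(1))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", refName(ref), length(ref)),
               recs), path)
  path
}

writeRefFasta <- function(ref, path) {
  writeLines(c(paste0(">", refName(ref)), as.character(ref)), path)
  path
}
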