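## Bridges between standard formats and the domain types. Coordinates are
## 1-based inclusive internally; conversions happen only at the SAM
## (0-based alignment start in the raw file, 1-based in R) and BED (0-based
## half-open) boundaries.

#' Read a reference sequence from FASTA
#'
#' Loads the first record (or a named record) of a FASTA file, uppercased.
#'
#' @param path FASTA file.
#' @param contig optional record name to select (matched against the header
#'   up to the first whitespace).
#' @return a [ReferenceSequence-class].
#' @export
readReference <- function(path, contig = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  idx <- 1L
  if (!is.null(contig)) {
    idx <- match(contig, nm)
    if (is.na(idx)) stop("contig '", contig, "' not found in ", path,
                         " (available: ", paste(nm, collapse = ", "), ")")
  }
  ReferenceSequence(nm[idx], toupper(as.character(set[[idx]])))
}

.parseRegion <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("region must have the form contig:start-end, got '", region, "'")
  list(contig = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

#' Load aligned reads from SAM/BAM
#'
#' Walks each record's CIGAR to produce per-reference-position states
#' (`M/=/X` emit the read base, `D` a `-`, `I` an insertion at the
#' preceding gap, `S`/`H` are clipped away); mismatches are resolved
#' against the mandatory reference sequence. Unmapped, secondary and
#' supplementary records are dropped and counted; records with skipped
#' regions (`N`), inconsistent CIGAR/sequence lengths, or extending beyond
#' the reference are skipped with a warning. Plain-text SAM input is
#' converted on the fly. An optional `region` (`contig:start-end`)
#' restricts ingest; reads overlapping the region boundary are clipped to
#' it.
#'
#' @param path SAM or BAM file.
#' @param reference a [ReferenceSequence-class]; records mapped to other
#'   contigs are counted as filtered, and an input containing none mapped
#'   to `refName(reference)` is an error.
#' @param region optional `contig:start-end` string.
#' @return `list(reads = <list of AlignedRead>, report = <IngestReport>)`.
#' @export
loadAlignedReads <- function(path, reference, region = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  reg <- if (!is.null(region)) .parseRegion(region) else NULL
  if (!is.null(reg) && reg$contig != reference@name)
    stop("region contig '", reg$contig, "' does not match the reference '",
         reference@name, "'")
  what <- c("qname", "flag", "rname", "pos", "cigar", "seq")
  param <- Rsamtools::ScanBamParam(what = what)
  rec <- Rsamtools::scanBam(path, param = param)[[1L]]
  nTotal <- length(rec$qname)
  flag <- rec$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  keep <- !unmapped & !secondary
  onContig <- !is.na(rec$rname) & as.character(rec$rname) == reference@name
  if (!any(keep & onContig))
    stop("no mapped records on contig '", reference@name, "' in input")
  nFilter <- sum(keep & !onContig)
  keep <- keep & onContig
  warnings <- character()
  reads <- list()
  L0 <- length(reference@code)
  refChars <- .STATE_CHARS[reference@code]
  for (j in which(keep)) {
    walked <- tryCatch(
      .walkCigar(rec$qname[j], rec$pos[j], rec$cigar[j],
                 as.character(rec$seq[j]), L0),
      error = function(e) conditionMessage(e))
    if (is.character(walked)) {
      warnings <- c(warnings, walked)
      nFilter <- nFilter + 1L
      next
    }
    if (!is.null(reg)) {
      walked <- .clipToRegion(walked, reg$start, reg$end)
      if (is.null(walked)) { nFilter <- nFilter + 1L; next }
    }
    reads[[length(reads) + 1L]] <-
      AlignedRead(walked$name, walked$start, walked$end, walked$states,
                  walked$ins)
  }
  report <- new("IngestReport", nTotal = nTotal, nKept = length(reads),
                nDroppedUnmapped = sum(unmapped),
                nDroppedSecondary = sum(secondary & !unmapped),
                nDroppedFilters = as.integer(nTotal - length(reads) -
                                             sum(unmapped) -
                                             sum(secondary & !unmapped)),
                warnings = warnings)
  if (length(warnings)) warning(length(warnings), " record(s) skipped; see report",
                                call. = FALSE)
  list(reads = reads, report = report)
}

.walkCigar <- function(name, pos, cigar, seq, L0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  if (any(ops == "N")) stop("read ", name, ": N (skipped region) unsupported")
  qlen <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  if (!is.na(seq) && seq != "*" && nchar(seq) != qlen)
    stop("read ", name, ": CIGAR consumes ", qlen, " query bases but SEQ has ",
         nchar(seq))
  qseq <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  span <- sum(lens[ops %in% c("M", "=", "X", "D")])
  if (pos + span - 1L > L0)
    stop("read ", name, ": alignment extends beyond the reference")
  states <- character(span)
  ins <- character()
  rcur <- 1L  # cursor within [pos, pos+span-1]
  qcur <- 1L
  for (t in seq_along(ops)) {
    op <- ops[t]; len <- lens[t]
    if (op %in% c("M", "=", "X")) {
      states[rcur:(rcur + len - 1L)] <- qseq[qcur:(qcur + len - 1L)]
      rcur <- rcur + len; qcur <- qcur + len
    } else if (op == "D") {
      states[rcur:(rcur + len - 1L)] <- "-"
      rcur <- rcur + len
    } else if (op == "I") {
      g <- pos + rcur - 2L  # gap between previous and current ref position
      if (g >= pos && g <= L0 - 1L)
        ins[as.character(g)] <- paste(qseq[qcur:(qcur + len - 1L)], collapse = "")
      qcur <- qcur + len
    } else if (op == "S") {
      qcur <- qcur + len
    }  # H, P consume nothing here
  }
  list(name = name, start = pos, end = pos + span - 1L, states = states,
       ins = ins)
}

.clipToRegion <- function(w, rs, re) {
  if (w$end < rs || w$start > re) return(NULL)
  s <- max(w$start, rs); e <- min(w$end, re)
  states <- w$states[(s - w$start + 1L):(e - w$start + 1L)]
  if (all(states == "-")) return(NULL)
  ins <- w$ins
  if (length(ins)) {
    g <- as.integer(names(ins))
    ins <- ins[g >= s & g <= e - 1L]
  }
  list(name = w$name, start = s, end = e, states = states, ins = ins)
}

#' Write haplotypes as FASTA plus a per-position state table
#'
#' The FASTA holds the literal spliced sequences (deletions removed,
#' insertions spliced in); the companion TSV preserves the
#' reference-indexed representation (`states` string over `ACGT-` and a
#' `gap:seq` insertion list) and round-trips exactly via
#' [readHaplotypeTable()].
#'
#' @param haps list of [ConsensusHaplotype-class].
#' @param fastaPath output FASTA path.
#' @param tsvPath output TSV path (default: `fastaPath` + `.states.tsv`).
#' @param prefix record-name prefix.
#' @return invisibly, the two paths.
#' @export
writeHaplotypes <- function(haps, fastaPath, tsvPath = paste0(fastaPath, ".states.tsv"),
                            prefix = "haplotype") {
  seqs <- Biostrings::DNAStringSet(vapply(haps, hapSequence, character(1)))
  names(seqs) <- sprintf("%s%d", prefix, vapply(haps, hapIndex, integer(1)))
  Biostrings::writeXStringSet(seqs, fastaPath)
  tab <- data.frame(
    haplotype = vapply(haps, hapIndex, integer(1)),
    states = vapply(haps, function(h) paste(hapStates(h), collapse = ""), character(1)),
    insertions = vapply(haps, function(h) {
      ins <- h@insertions
      if (!length(ins)) "." else paste(sprintf("%s:%s", names(ins), ins), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fastaPath, tsv = tsvPath))
}

#' @rdname writeHaplotypes
#' @param path a TSV written by `writeHaplotypes()`.
#' @return `readHaplotypeTable()` returns the list of
#'   [ConsensusHaplotype-class].
#' @export
readHaplotypeTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character", "character"))
  lapply(seq_len(nrow(tab)), function(r) {
    ins <- character()
    if (tab$insertions[r] != ".") {
      parts <- strsplit(strsplit(tab$insertions[r], ";", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
      ins <- vapply(parts, `[`, character(1), 2L)
      names(ins) <- vapply(parts, `[`, character(1), 1L)
    }
    ConsensusHaplotype(tab$haplotype[r], tab$states[r], ins)
  })
}

#' Write SNV calls as VCF 4.2
#'
#' Substitution records from [callSnvs()] are written with `CHROM` set to
#' the reference name, 1-based `POS`, and one sample column `HAPS` carrying
#' the phased per-haplotype genotype (`GT`, allele indices separated by
#' `|`). Indel rows of the call table are not written (they are flagged
#' non-SNV in the table).
#'
#' @param variants the `data.frame` from [callSnvs()].
#' @param reference a [ReferenceSequence-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSnvVcf <- function(variants, reference, path) {
  snvs <- variants[variants$class == "snv", , drop = FALSE]
  snvs <- snvs[order(snvs$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplomix",
    sprintf("##contig=<ID=%s,length=%d>", reference@name, length(reference@code)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased per-haplotype genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tHAPS")
  body <- if (nrow(snvs)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                                  reference@name, snvs$pos, snvs$ref, snvs$alt,
                                  snvs$genotype) else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a site list from TSV or BED
#'
#' TSV files (any extension except `.bed`) are 1-based with the position in
#' the last of two columns (contig, pos) or a single position column; BED
#' files are 0-based half-open and expand to all covered positions. The
#' dialect is chosen by file extension.
#'
#' @param path input file.
#' @return sorted integer vector of 1-based reference positions.
#' @export
readSiteList <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    pos <- unlist(lapply(seq_len(nrow(tab)), function(r)
      (tab[r, 2L] + 1L):tab[r, 3L]))
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    pos <- tab[[ncol(tab)]]
  }
  sort(unique(as.integer(pos)))
}

#' Write read-to-haplotype assignments as TSV
#'
#' @param fit a [HaplotypeFit-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAssignments <- function(fit, path) {
  utils::write.table(readAssignments(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable fit report as JSON
#'
#' Records the package version, seeds, configuration echo, fitted
#' parameters, convergence diagnostics and the per-iteration objective
#' trace.
#'
#' @param fit a [HaplotypeFit-class].
#' @param config the [FitConfig-class] used.
#' @param path output path.
#' @param extra optional named list merged into the report.
#' @return invisibly, `path`.
#' @export
writeFitReport <- function(fit, config, path, extra = list()) {
  st <- fit@state
  report <- c(list(
    package = "haplomix",
    version = as.character(utils::packageVersion("haplomix")),
    seed = config@seed,
    config = list(nRestarts = config@nRestarts, maxIter = config@maxIter,
                  tol = config@tol, T0 = config@T0, cooling = config@cooling,
                  tieEvolution = config@tieEvolution),
    K = length(st@consensuses),
    converged = fit@converged,
    bestRestart = fit@bestRestart,
    objective = st@objective,
    alpha = st@weights@alpha,
    profile = list(p1 = st@profile@p1, p2 = st@profile@p2, p3 = st@profile@p3,
                   p4 = st@profile@p4, lambdaIns = st@profile@lambdaIns,
                   lambdaDel = st@profile@lambdaDel),
    evolution = list(gamma = st@evolution@gamma, beta = st@evolution@beta),
    trace = fit@trace), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write simulated-dataset artifacts
#'
#' Writes the truth haplotypes (FASTA + state TSV), the reads (FASTA of
#' literal read sequences), a truth table (TSV: read, source haplotype,
#' start, end) and a config echo (JSON) into a directory.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(haplotypes = file.path(dir, "truth_haplotypes.fasta"),
             reads = file.path(dir, "reads.fasta"),
             truth = file.path(dir, "truth_reads.tsv"),
             config = file.path(dir, "config.json"))
  writeHaplotypes(dataset@haplotypes, paths[["haplotypes"]])
  readSeq <- function(r) {
    st <- r@states
    pieces <- character(length(st))
    keep <- st != .GAP_CODE
    pieces[keep] <- .STATE_CHARS[st[keep]]
    if (length(r@insertions)) {
      g <- as.integer(names(r@insertions)) - r@start + 1L
      pieces[g] <- paste0(pieces[g], r@insertions)
    }
    paste(pieces, collapse = "")
  }
  seqs <- Biostrings::DNAStringSet(vapply(dataset@reads, readSeq, character(1)))
  names(seqs) <- vapply(dataset@reads, function(r) r@name, character(1))
  Biostrings::writeXStringSet(seqs, paths[["reads"]])
  truth <- data.frame(
    read = names(seqs),
    haplotype = vapply(dataset@reads, function(r) r@truthSource, integer(1)),
    start = vapply(dataset@reads, function(r) r@start, integer(1)),
    end = vapply(dataset@reads, function(r) r@end, integer(1)))
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- dataset@config
  jsonlite::write_json(list(
    K = cfg@K, nReads = cfg@nReads, seed = cfg@seed,
    alpha = cfg@weights@alpha,
    gamma = cfg@evolution@gamma, beta = cfg@evolution@beta,
    profile = as.list(errorRates(cfg@profile)), readLength = cfg@readLength[
      !vapply(cfg@readLength, is.null, logical(1))]),
    paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
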