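# ---- alignment ingestion, filtering and pileup ------------------------------

#' Read-filtering and pileup parameters
#'
#' Defaults follow common organellar RNA-seq practice: per-base Phred >= 20,
#' read length >= 30 bp, alignment identity >= 90 percent, uniquely mapped
#' reads only.  Per-base quality filtering is applied at pileup time; the
#' read-level filters in [filter_reads()] use the remaining three.
#'
#' @param min_base_quality Minimum Phred base quality counted in pileups.
#' @param min_read_length Minimum read length in bp.
#' @param min_identity Minimum alignment identity in percent, computed from
#'   the CIGAR and `NM` tag when present.
#' @param unique_only Keep only uniquely mapped reads (mapping quality > 0).
#' @return A list of class `ingest_params`.
#' @export
ingest_params <- function(min_base_quality = 20L, min_read_length = 30L,
                          min_identity = 90, unique_only = TRUE) {
  stopifnot(min_base_quality >= 0, min_read_length >= 0, min_identity >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_read_length = as.integer(min_read_length),
                 min_identity = as.numeric(min_identity),
                 unique_only = isTRUE(unique_only)),
            class = "ingest_params")
}

#' Read alignments from a SAM or BAM file
#'
#' SAM text files are converted through [Rsamtools::asBam()] and loaded with
#' [Rsamtools::scanBam()].  Unmapped records are dropped.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data frame with one row per mapped read: `qname`, `flag`,
#'   `pos`, `mapq`, `strand`, `cigar`, `seq`, `qual` (Phred+33 string) and
#'   `nm` (edit distance, `NA` when the tag is absent).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  what <- c("qname", "flag", "strand", "pos", "mapq", "cigar", "seq", "qual")
  p <- Rsamtools::ScanBamParam(what = what, tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !bitwAnd(res$flag, 4L)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$flag))
  data.frame(qname = res$qname, flag = res$flag, pos = res$pos,
             mapq = res$mapq,
             strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
             cigar = res$cigar, seq = as.character(res$seq),
             qual = as.character(res$qual), nm = nm,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

valid_cigar <- function(cigar) grepl("^([0-9]+[MIDNSHP=X])+$", cigar)

# per-read alignment identity in percent from CIGAR + NM:
# 100 * (1 - NM / alignment columns), columns = M/=/X + I + D
alignment_identity <- function(cigar, nm) {
  cols <- vapply(GenomicAlignments::explodeCigarOpLengths(
    cigar, ops = c("M", "=", "X", "I", "D")), sum, 0L)
  100 * (1 - nm / pmax(cols, 1L))
}

#' Filter aligned reads
#'
#' Retains reads meeting the length, identity and uniqueness criteria of
#' `params`; per-base quality filtering is deferred to [build_pileup()].
#' Reads with an unparseable CIGAR are skipped with a warning.  Reads
#' lacking an `NM` tag cannot be identity-checked and are kept, with a
#' one-time warning.
#'
#' @param reads Data frame of reads as from [read_alignments()] or
#'   [simulate_reads()].
#' @param params An [ingest_params()].
#' @return The filtered data frame.  Idempotent: filtering a filtered set
#'   changes nothing.
#' @export
filter_reads <- function(reads, params = ingest_params()) {
  if (!nrow(reads)) return(reads)
  ok_cigar <- valid_cigar(reads$cigar)
  if (any(!ok_cigar))
    warning(sum(!ok_cigar), " read(s) skipped: unparseable CIGAR")
  reads <- reads[ok_cigar, , drop = FALSE]
  keep <- nchar(reads$seq) >= params$min_read_length
  if (params$unique_only) keep <- keep & reads$mapq > 0L
  nm <- if ("nm" %in% names(reads)) reads$nm else rep(NA_integer_, nrow(reads))
  has_nm <- !is.na(nm)
  if (any(!has_nm) && params$min_identity > 0)
    warning(sum(!has_nm), " read(s) lack an NM tag; identity not checked")
  if (any(has_nm)) {
    idv <- rep(100, nrow(reads))
    idv[has_nm] <- alignment_identity(reads$cigar[has_nm], nm[has_nm])
    keep <- keep & (!has_nm | idv >= params$min_identity)
  }
  reads[keep, , drop = FALSE]
}

# ---- pileup -----------------------------------------------------------------

#' Build a strand-oriented base pileup
#'
#' Tallies plus-strand-oriented read bases per genome position.  Read `T`s
#' are recorded in the `U` column (RNA convention).  Bases below
#' `min_base_quality` are excluded; deletions contribute nothing and inserted
#' bases are ignored.  Alignments running past the sequence end are wrapped
#' onto the circle for circular genomes and are an error otherwise.
#'
#' @param reads Data frame of aligned reads (see [read_alignments()]).
#' @param genome An [annotated_plastome()].
#' @param params An [ingest_params()]; only `min_base_quality` is used here.
#' @return A data frame of pileup columns, one row per covered position:
#'   `pos`, `ref` (plus-strand reference base), `A`, `C`, `G`, `U`, `depth`,
#'   `mean_qual`.
#' @export
build_pileup <- function(reads, genome, params = ingest_params()) {
  L <- genome$length
  empty <- data.frame(pos = integer(), ref = character(), A = integer(),
                      C = integer(), G = integer(), U = integer(),
                      depth = integer(), mean_qual = numeric())
  if (!nrow(reads)) return(empty)
  if (any(!valid_cigar(reads$cigar))) reads <- filter_reads(reads, params)
  if (!nrow(reads)) return(empty)

  ops <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = ops)
  qq <- GenomicAlignments::cigarRangesAlongQuerySpace(
    reads$cigar, ops = ops)
  nop <- S4Vectors::elementNROWS(rr)
  rr <- unlist(rr, use.names = FALSE)
  qq <- unlist(qq, use.names = FALSE)
  w <- IRanges::width(rr)
  read_of_op <- rep(seq_len(nrow(reads)), nop)
  refpos <- sequence(w, from = IRanges::start(rr))
  qidx <- sequence(w, from = IRanges::start(qq))
  read_of_base <- rep(read_of_op, w)

  if (any(refpos > L)) {
    if (!genome$circular)
      stop("alignment extends past the end of a non-circular genome")
    refpos <- wrap_position(refpos, L)
  }

  allseq <- paste(reads$seq, collapse = "")
  allqual <- paste(reads$qual, collapse = "")
  off <- cumsum(c(0L, nchar(reads$seq)))[read_of_base]
  base <- strsplit(allseq, "", fixed = TRUE)[[1L]][off + qidx]
  phred <- as.integer(charToRaw(allqual))[off + qidx] - 33L

  ok <- phred >= params$min_base_quality
  base <- base[ok]; refpos <- refpos[ok]; phred <- phred[ok]
  bi <- match(base, c("A", "C", "G", "T"))
  keep <- !is.na(bi)
  bi <- bi[keep]; refpos <- refpos[keep]; phred <- phred[keep]
  if (!length(bi)) return(empty)

  counts <- matrix(tabulate((refpos - 1L) * 4L + bi, nbins = 4L * L),
                   ncol = 4L, byrow = TRUE)
  colnames(counts) <- c("A", "C", "G", "U")
  depth <- rowSums(counts)
  covered <- which(depth > 0L)
  qsum <- numeric(L)
  qagg <- rowsum(as.numeric(phred), refpos)
  qsum[as.integer(rownames(qagg))] <- qagg[, 1L]
  refchars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]

  data.frame(pos = covered, ref = refchars[covered],
             A = counts[covered, "A"], C = counts[covered, "C"],
             G = counts[covered, "G"], U = counts[covered, "U"],
             depth = as.integer(depth[covered]),
             mean_qual = qsum[covered] / depth[covered])
}

#' Per-base depth array from a pileup
#'
#' @param pileup Pileup data frame from [build_pileup()].
#' @param genome_length Genome length in bp.
#' @return Integer vector of length `genome_length`; uncovered positions 0.
#' @export
depth_vector <- function(pileup, genome_length) {
  d <- integer(genome_length)
  if (nrow(pileup)) d[pileup$pos] <- pileup$depth
  d
}

#' Export / import a pileup as TSV
#'
#' @param pileup Pileup data frame.
#' @param path Output (or input) path.
#' @return `write_pileup_tsv` returns `path` invisibly; `read_pileup_tsv`
#'   returns the pileup data frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
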