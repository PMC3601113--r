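# ---- intron splicing detection from gapped alignments -----------------------

#' Extract splice junctions from gapped alignments
#'
#' Every `N` (reference-skip) operation in a read's CIGAR is evidence that
#' an intron was removed.  A junction is reported as the exon-adjacent base
#' pair: `donor` is the last aligned base before the skip and `acceptor` the
#' first aligned base after it.  Reads with several skips contribute one
#' junction per skip; identical (donor, acceptor) pairs are pooled with
#' summed support.
#'
#' @param reads Data frame of aligned reads (needs `pos` and `cigar`).
#' @return Data frame `donor`, `acceptor`, `support`, sorted by donor.
#' @export
extract_junctions <- function(reads) {
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      support = integer())
  if (!nrow(reads)) return(empty)
  has_gap <- grepl("N", reads$cigar, fixed = TRUE)
  if (!any(has_gap)) return(empty)
  sub <- reads[has_gap, , drop = FALSE]
  nr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    sub$cigar, pos = sub$pos, ops = "N")
  skips <- unlist(nr, use.names = FALSE)
  donor <- IRanges::start(skips) - 1L
  acceptor <- IRanges::end(skips) + 1L
  key <- paste(donor, acceptor)
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  out <- data.frame(donor = as.integer(parts[, 1L]),
                    acceptor = as.integer(parts[, 2L]),
                    support = as.integer(agg))
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score annotated introns as spliced or unspliced
#'
#' An intron is `spliced` when a junction matches its boundaries within
#' `tolerance` bp: the donor must sit at the last base of the upstream exon
#' and the acceptor at the first base of the downstream exon.  When a depth
#' vector is supplied, introns with zero read coverage are reported
#' `no_data`; otherwise introns without a matching junction are
#' `unspliced`.
#'
#' @param junctions Data frame from [extract_junctions()].
#' @param genome An [annotated_plastome()] with intron-containing features.
#' @param tolerance Boundary tolerance in bp (default 0, exact).
#' @param depth Optional per-base depth vector used to distinguish
#'   `unspliced` from `no_data`.
#' @return Data frame with one row per annotated intron: `gene`, `copy`,
#'   `intron` (index within the gene), `start`, `end`, `donor_exon_end`,
#'   `acceptor_exon_start`, `support`, `status`.
#' @export
score_introns <- function(junctions, genome, tolerance = 0L, depth = NULL) {
  rows <- list()
  for (f in genome$features) {
    ins <- feature_introns(f)
    if (!nrow(ins)) next
    for (k in seq_len(nrow(ins))) {
      dend <- ins[k, 1L] - 1L        # last base of upstream exon
      astart <- ins[k, 2L] + 1L      # first base of downstream exon
      m <- integer()
      if (nrow(junctions))
        m <- which(abs(junctions$donor - dend) <= tolerance &
                     abs(junctions$acceptor - astart) <= tolerance)
      support <- if (length(m)) sum(junctions$support[m]) else 0L
      status <- if (support > 0L) "spliced" else if (!is.null(depth) &&
          all(depth[ins[k, 1L]:ins[k, 2L]] == 0L)) "no_data" else "unspliced"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = f$name, copy = f$copy, intron = k,
        start = ins[k, 1L], end = ins[k, 2L],
        donor_exon_end = dend, acceptor_exon_start = astart,
        support = support, status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(data.frame()), rows))
  if (!is.null(out) && nrow(out)) rownames(out) <- NULL
  if (is.null(out) || !nrow(out))
    out <- data.frame(gene = character(), copy = integer(),
                      intron = integer(), start = integer(),
                      end = integer(), donor_exon_end = integer(),
                      acceptor_exon_start = integer(), support = integer(),
                      status = character())
  out
}

#' Export junctions as BED
#'
#' Standard 0-based half-open BED; each record spans the skipped interval
#' (intron), scored by read support.
#'
#' @param junctions Data frame from [extract_junctions()].
#' @param genome_id Sequence name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, genome_id, path) {
  df <- data.frame(genome_id,
                   junctions$donor,            # 0-based start of intron
                   junctions$acceptor - 1L,    # half-open end
                   sprintf("junction_%d", seq_len(nrow(junctions))),
                   junctions$support, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
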