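# ---- genome-wide transcription coverage profiling ---------------------------

#' Profile transcription coverage of a plastome
#'
#' Computes the consensus covered fraction (positions with depth at least
#' `cover_min` over genome length), mean depth over covered positions, and
#' per-feature depth statistics.
#'
#' @param depth Integer vector of per-base read depth, length equal to the
#'   genome length.
#' @param genome An [annotated_plastome()].
#' @param cover_min Minimum depth for a position to count as covered
#'   (default 1: any mapped read).
#' @return A list of class `coverage_profile`: `depth`, `cover_min`,
#'   `covered_length`, `covered_fraction`, `percent_covered` (rounded to
#'   0.1), `mean_depth` (over covered positions) and `per_feature` (data
#'   frame with `name`, `kind`, `strand`, `length`, `mean_depth`,
#'   `covered_fraction`).
#' @export
profile_coverage <- function(depth, genome, cover_min = 1L) {
  if (length(depth) != genome$length)
    stop("depth length (", length(depth), ") != genome length (",
         genome$length, ")")
  covered <- depth >= cover_min
  covered_length <- sum(covered)
  feats <- genome$features
  per_feature <- data.frame(
    name = vapply(feats, function(f) f$name, ""),
    copy = vapply(feats, function(f) f$copy, 1L),
    kind = vapply(feats, function(f) f$kind, ""),
    strand = vapply(feats, function(f) f$strand, ""),
    length = vapply(feats, feature_length, 1L),
    mean_depth = vapply(feats, function(f) {
      idx <- exon_positions(f)
      mean(depth[idx])
    }, 1),
    covered_fraction = vapply(feats, function(f) {
      idx <- exon_positions(f)
      mean(covered[idx])
    }, 1),
    stringsAsFactors = FALSE)
  structure(list(depth = depth, cover_min = as.integer(cover_min),
                 covered_length = covered_length,
                 covered_fraction = covered_length / genome$length,
                 percent_covered = round(100 * covered_length /
                                           genome$length, 1L),
                 mean_depth = if (covered_length) mean(depth[covered]) else 0,
                 per_feature = per_feature),
            class = "coverage_profile")
}

exon_positions <- function(f)
  unlist(lapply(seq_len(nrow(f$exons)),
                function(i) f$exons[i, 1L]:f$exons[i, 2L]))

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile: ", format(x$covered_length, big.mark = ","),
      " / ", format(length(x$depth), big.mark = ","), " bp covered (",
      sprintf("%.1f%%", 100 * x$covered_fraction), ") at depth >= ",
      x$cover_min, "; mean covered depth ",
      sprintf("%.1f", x$mean_depth), "x\n", sep = "")
  invisible(x)
}

#' Features with no transcription evidence
#'
#' @param profile A [profile_coverage()] result.
#' @param min_feature_fraction Features whose covered fraction is below this
#'   threshold are reported as untranscribed (default 0.05).
#' @return Data frame of untranscribed features, sorted by name.
#' @export
untranscribed_features <- function(profile, min_feature_fraction = 0.05) {
  pf <- profile$per_feature
  out <- pf[pf$covered_fraction < min_feature_fraction, , drop = FALSE]
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent of the genome occupied by coding regions
#'
#' The union of exon intervals of the included features divided by the
#' genome length.  Introns are excluded (exon union); the usual plastome
#' summary-table convention counts protein-coding, tRNA and rRNA genes and
#' both inverted repeat gene copies, but both choices are exposed as flags
#' because conventions differ.
#'
#' @param genome An [annotated_plastome()].
#' @param include `"all_genes"` (CDS + tRNA + rRNA) or `"protein_only"`.
#' @param count_ir_copies Count duplicated IR gene copies (`copy > 1`)?
#' @return Percent of genome length, rounded to one decimal.
#' @export
percent_coding <- function(genome, include = c("all_genes", "protein_only"),
                           count_ir_copies = TRUE) {
  include <- match.arg(include)
  kinds <- if (include == "protein_only") "CDS" else c("CDS", "tRNA", "rRNA")
  feats <- Filter(function(f) {
    f$kind %in% kinds && (count_ir_copies || f$copy == 1L)
  }, genome$features)
  if (!length(feats)) return(0)
  ex <- do.call(rbind, lapply(feats, function(f) f$exons))
  ir <- IRanges::reduce(IRanges::IRanges(ex[, 1L], ex[, 2L]))
  round(100 * sum(IRanges::width(ir)) / genome$length, 1L)
}

#' Reads overlapping each feature
#'
#' Simple per-feature read counts (a read counts for every feature whose
#' exons its aligned span overlaps).
#'
#' @param reads Aligned reads data frame.
#' @param genome An [annotated_plastome()].
#' @return Data frame `name`, `copy`, `n_reads`.
#' @export
feature_read_counts <- function(reads, genome) {
  spans <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  rstart <- reads$pos; rend <- reads$pos + spans - 1L
  data.frame(
    name = vapply(genome$features, function(f) f$name, ""),
    copy = vapply(genome$features, function(f) f$copy, 1L),
    n_reads = vapply(genome$features, function(f) {
      hit <- Reduce(`|`, lapply(seq_len(nrow(f$exons)), function(i)
        rstart <= f$exons[i, 2L] & rend >= f$exons[i, 1L]))
      sum(hit)
    }, 1L),
    stringsAsFactors = FALSE)
}

#' Export a depth vector as bedGraph
#'
#' @param depth Per-base depth vector.
#' @param genome_id Sequence name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, genome_id, path) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths       # bedGraph is 0-based half-open
  keep <- r$values > 0
  df <- data.frame(genome_id, starts[keep], ends[keep], r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
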