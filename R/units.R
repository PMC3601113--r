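# ---- polycistronic transcription-unit delineation ---------------------------

#' Delineate polycistronic transcription units from coverage
#'
#' Segments the genome into maximal runs of positions with depth at least
#' `d_min`; runs separated by at most `max_gap` uncovered bp are merged, and
#' runs meeting across the origin of the circular genome are joined.  Member
#' genes are the features whose exons overlap the unit interval; the unit's
#' presumed strand is the majority strand of its protein-coding members
#' (all members when no CDS member exists; `mixed` on a tie), and each
#' member is `sense` when its strand equals the presumed strand,
#' `antisense` otherwise.
#'
#' @param depth Per-base depth vector (length = genome length).
#' @param genome An [annotated_plastome()].
#' @param d_min Minimum depth inside a unit (default 1).
#' @param max_gap Maximum uncovered gap merged into a unit (default 0, the
#'   most conservative reading of contiguous-transcript evidence).
#' @return A list of class `transcription_units`; each element has
#'   `interval` (`c(start, end)`, `end < start` when spanning the origin),
#'   `presumed_strand`, `mean_depth` and `members` (data frame `name`,
#'   `copy`, `kind`, `strand`, `orientation`, `pseudogene`).
#' @export
delineate_units <- function(depth, genome, d_min = 1L, max_gap = 0L) {
  L <- genome$length
  if (length(depth) != L) stop("depth length != genome length")
  cov <- depth >= d_min
  units <- list()
  if (!any(cov)) return(structure(units, class = "transcription_units"))
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  # merge runs separated by small gaps
  if (nrow(iv) > 1L && max_gap > 0L) {
    merged <- iv[1L, , drop = FALSE]
    for (i in 2L:nrow(iv)) {
      if (iv[i, 1L] - merged[nrow(merged), 2L] - 1L <= max_gap)
        merged[nrow(merged), 2L] <- iv[i, 2L]
      else merged <- rbind(merged, iv[i, , drop = FALSE])
    }
    iv <- merged
  }
  # circular wrap: join last and first runs when the origin gap is small
  if (genome$circular && nrow(iv) > 1L) {
    origin_gap <- (iv[1L, 1L] - 1L) + (L - iv[nrow(iv), 2L])
    if (origin_gap <= max_gap ||
        (iv[1L, 1L] == 1L && iv[nrow(iv), 2L] == L)) {
      iv[1L, 1L] <- iv[nrow(iv), 1L]   # wrapped interval: end < start
      iv <- iv[-nrow(iv), , drop = FALSE]
    }
  }
  units <- lapply(seq_len(nrow(iv)), function(i) {
    interval <- c(unname(iv[i, 1L]), unname(iv[i, 2L]))
    pos <- interval_positions(interval, L)
    members <- unit_members(genome, interval)
    cds <- members[members$kind %in% c("CDS", "pseudogene"), , drop = FALSE]
    base <- if (nrow(cds)) cds else members
    strand <- if (!nrow(base)) "mixed" else {
      np <- sum(base$strand == "+"); nm <- sum(base$strand == "-")
      if (np > nm) "+" else if (nm > np) "-" else "mixed"
    }
    members$orientation <- ifelse(members$strand == strand, "sense",
                                  ifelse(strand == "mixed", NA, "antisense"))
    list(interval = interval, presumed_strand = strand,
         mean_depth = mean(depth[pos]), members = members)
  })
  structure(units, class = "transcription_units")
}

interval_positions <- function(interval, L) {
  if (interval[2L] >= interval[1L]) interval[1L]:interval[2L]
  else c(interval[1L]:L, 1L:interval[2L])
}

# features whose exons overlap a (possibly wrapped) interval
unit_members <- function(genome, interval) {
  L <- genome$length
  segs <- if (interval[2L] >= interval[1L]) {
    matrix(interval, ncol = 2L)
  } else {
    rbind(c(interval[1L], L), c(1L, interval[2L]))
  }
  hit <- vapply(genome$features, function(f) {
    any(vapply(seq_len(nrow(f$exons)), function(i)
      any(f$exons[i, 1L] <= segs[, 2L] & f$exons[i, 2L] >= segs[, 1L]),
      TRUE))
  }, TRUE)
  feats <- genome$features[hit]
  out <- data.frame(
    name = vapply(feats, function(f) f$name, ""),
    copy = vapply(feats, function(f) f$copy, 1L),
    kind = vapply(feats, function(f) f$kind, ""),
    strand = vapply(feats, function(f) f$strand, ""),
    pseudogene = vapply(feats, function(f) f$kind == "pseudogene", TRUE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.transcription_units <- function(x, ...) {
  cat("transcription_units:", length(x), "unit(s)\n")
  for (i in seq_along(x)) {
    u <- x[[i]]
    cat(sprintf("  [%d] %d-%d (%s) depth %.1f: %s\n", i, u$interval[1L],
                u$interval[2L], u$presumed_strand, u$mean_depth,
                paste(u$members$name, collapse = ", ")))
  }
  invisible(x)
}

#' Tabular transcription-unit membership report
#'
#' One row per (unit, member gene) with orientation and pseudogene flags.
#'
#' @param units A [delineate_units()] result.
#' @param genome An [annotated_plastome()] (used for interval lengths).
#' @return Data frame with `unit`, `start`, `end`, `unit_strand`,
#'   `mean_depth`, `member`, `copy`, `kind`, `member_strand`, `orientation`,
#'   `pseudogene`.
#' @export
unit_report <- function(units, genome) {
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    if (!nrow(u$members))
      return(data.frame(unit = i, start = u$interval[1L],
                        end = u$interval[2L],
                        unit_strand = u$presumed_strand,
                        mean_depth = u$mean_depth, member = NA_character_,
                        copy = NA_integer_, kind = NA_character_,
                        member_strand = NA_character_,
                        orientation = NA_character_, pseudogene = NA,
                        stringsAsFactors = FALSE))
    data.frame(unit = i, start = u$interval[1L], end = u$interval[2L],
               unit_strand = u$presumed_strand, mean_depth = u$mean_depth,
               member = u$members$name, copy = u$members$copy,
               kind = u$members$kind, member_strand = u$members$strand,
               orientation = u$members$orientation,
               pseudogene = u$members$pseudogene, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export transcription units as GFF3
#'
#' Units are written as `transcribed_region` features.  Origin-spanning
#' units are split into their two arcs with a shared `ID`.
#'
#' @param units A [delineate_units()] result.
#' @param genome An [annotated_plastome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_units_gff3 <- function(units, genome, path) {
  rows <- do.call(rbind, lapply(seq_along(units), function(i) {
    u <- units[[i]]
    segs <- if (u$interval[2L] >= u$interval[1L])
      matrix(u$interval, ncol = 2L)
    else rbind(c(u$interval[1L], genome$length), c(1L, u$interval[2L]))
    data.frame(start = segs[, 1L], end = segs[, 2L],
               strand = if (u$presumed_strand %in% c("+", "-"))
                 u$presumed_strand else "*",
               ID = sprintf("TU%03d", i))
  }))
  gr <- GenomicRanges::GRanges(genome$id,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "plastoscope", type = "transcribed_region", ID = rows$ID)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}
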