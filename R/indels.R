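# ---- comparative indel cataloguing ------------------------------------------

#' Catalog indels between aligned plastome sequences
#'
#' Scans an equal-length (gapped) alignment and records every maximal gap
#' run as one indel relative to the reference sequence: a gap run in a
#' non-reference sequence is a deletion, a gap run in the reference an
#' insertion.  The reported position is the ungapped reference coordinate of
#' the base immediately before the gap run (0 when the run starts at the
#' alignment's first column).  Adjacent but distinct gap runs separated by
#' at least one match column are separate indels.
#'
#' @param alignment A [Biostrings::DNAStringSet] of aligned sequences of
#'   equal width, or the path of an aligned multi-FASTA file.
#' @param reference_index Which sequence is the reference (default 1).
#' @param genome Optional [annotated_plastome()] matching the ungapped
#'   reference, used to classify each indel's region.
#' @return Data frame with one row per indel: `query` (the non-reference
#'   sequence name), `position`, `length`, `kind` (`insertion`/`deletion`),
#'   `region`, `locus` (gene or spacer label, when `genome` given).
#' @export
catalog_indels <- function(alignment, reference_index = 1L, genome = NULL) {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- Biostrings::readDNAStringSet(alignment)
  if (length(alignment) < 2L)
    stop("alignment must contain at least two sequences")
  widths <- Biostrings::width(alignment)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same (gapped) length")
  mat <- do.call(rbind, strsplit(toupper(as.character(alignment)), ""))
  if (any(colSums(mat == "-") == nrow(mat)))
    stop("alignment contains all-gap columns")
  ref <- mat[reference_index, ]
  refcoord <- cumsum(ref != "-")     # ungapped reference coordinate per column
  nms <- names(alignment)
  if (is.null(nms)) nms <- paste0("seq", seq_along(alignment))

  rows <- list()
  for (qi in setdiff(seq_len(nrow(mat)), reference_index)) {
    qry <- mat[qi, ]
    for (kind in c("deletion", "insertion")) {
      gap <- if (kind == "deletion") qry == "-" & ref != "-"
             else ref == "-" & qry != "-"
      if (!any(gap)) next
      r <- rle(gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        col0 <- starts[k]
        pos <- if (col0 == 1L) 0L else refcoord[col0 - 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          query = nms[qi], position = as.integer(pos),
          length = r$lengths[k], kind = kind, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), position = integer(),
               length = integer(), kind = character())
  out <- out[order(out$query, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(genome) && nrow(out)) {
    cls <- lapply(pmax(out$position, 1L),
                  function(p) classify_position(genome, p))
    out$region <- vapply(cls, function(x)
      if (x$label %in% c("CDS", "tRNA", "rRNA", "pseudogene")) "genic"
      else x$label, "")
    out$locus <- vapply(cls, function(x) x$name, "")
  }
  out
}

#' Summarize an indel catalog
#'
#' @param records Data frame from [catalog_indels()].
#' @return List with `count`, `min`, `max`, `mean` (one decimal),
#'   `mean_rounded` (nearest integer), `total` and `per_region` (table;
#'   empty when regions were not classified).
#' @export
indel_summary <- function(records) {
  if (!nrow(records))
    return(list(count = 0L, min = 0L, max = 0L, mean = 0, mean_rounded = 0L,
                total = 0L, per_region = table(character())))
  list(count = nrow(records),
       min = min(records$length),
       max = max(records$length),
       mean = round(mean(records$length), 1L),
       mean_rounded = as.integer(round(mean(records$length))),
       total = sum(records$length),
       per_region = if ("region" %in% names(records))
         table(records$region) else table(character()))
}
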