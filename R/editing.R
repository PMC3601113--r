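# ---- C-to-U RNA editing site calling ----------------------------------------

#' Editing-caller parameters
#'
#' Thresholds for accepting a pileup column as a C-to-U editing site: a site
#' must have read depth in `[min_depth, max_depth]`, at least `min_support`
#' edited-base reads and an editing frequency (support/depth) of at least
#' `min_frequency`.
#'
#' `orientation_mode` controls how edited-base support is counted for
#' minus-strand features.  A C-to-U edit on a minus-strand transcript appears
#' on the plus strand as G-to-A, so `strict` counts plus-strand `A` reads.
#' Unstranded libraries, however, can report the edited base in either
#' orientation; `lenient` (the default) therefore counts
#' `max(A, U)` for minus-strand features.
#'
#' @param min_depth Minimum read depth (default 10).
#' @param min_support Minimum edited-base read support (default 5).
#' @param min_frequency Minimum editing frequency in (0, 1] (default 0.5).
#' @param min_base_quality Phred threshold the pileup was built with.
#' @param max_depth Maximum read depth (default 2000).
#' @param orientation_mode `"lenient"` or `"strict"`.
#' @return A list of class `editing_params`.
#' @export
editing_params <- function(min_depth = 10L, min_support = 5L,
                           min_frequency = 0.5, min_base_quality = 20L,
                           max_depth = 2000L,
                           orientation_mode = c("lenient", "strict")) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(min_frequency > 0, min_frequency <= 1,
            min_support <= min_depth, min_depth <= max_depth)
  structure(list(min_depth = as.integer(min_depth),
                 min_support = as.integer(min_support),
                 min_frequency = as.numeric(min_frequency),
                 min_base_quality = as.integer(min_base_quality),
                 max_depth = as.integer(max_depth),
                 orientation_mode = orientation_mode),
            class = "editing_params")
}

#' Edited-base support of a pileup column
#'
#' For a plus-strand feature the reference base must be `C` and support is
#' the `U` count.  For a minus-strand feature the reference (plus-strand)
#' base must be `G`; support is the `A` count in `strict` mode and
#' `max(A, U)` in `lenient` mode (unstranded libraries may report the edited
#' base in transcript orientation).  Any other reference base yields support
#' zero: only C-to-U (plus-strand mirror G-to-A) is considered.
#'
#' @param column One pileup row (list or one-row data frame with `ref`,
#'   `A`, `C`, `G`, `U`).
#' @param feature_strand `"+"` or `"-"`: strand of the transcribed feature.
#' @param mode `"lenient"` or `"strict"`.
#' @return List with `support` (reads) and `edited_base_plus` (`"U"`, `"A"`
#'   or `NA` when there is no candidate).
#' @export
edited_support <- function(column, feature_strand,
                           mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (feature_strand == "+") {
    if (column$ref != "C")
      return(list(support = 0L, edited_base_plus = NA_character_))
    return(list(support = as.integer(column$U), edited_base_plus = "U"))
  }
  if (column$ref != "G")
    return(list(support = 0L, edited_base_plus = NA_character_))
  if (mode == "strict" || column$A >= column$U)
    list(support = as.integer(column$A), edited_base_plus = "A")
  else
    list(support = as.integer(column$U), edited_base_plus = "U")
}

#' Call C-to-U RNA editing sites from a pileup
#'
#' A pileup column becomes a call iff its depth lies in
#' `[min_depth, max_depth]`, its edited-base support is at least
#' `min_support` and `support/depth >= min_frequency`.  A site is
#' `complete` when every read carries the edited base (`support == depth`),
#' `partial` otherwise.  Calls are returned sorted by position.
#'
#' The candidate strand of each column is taken from the annotation when a
#' `genome` with features is supplied (the owning feature's strand; for
#' intergenic positions the strand on which the reference base is a `C`).
#' Alternatively an explicit per-column `strand` vector may be given, e.g.
#' when replaying published per-site base counts without the genome.
#'
#' @param pileup Pileup data frame from [build_pileup()] (columns `pos`,
#'   `ref`, `A`, `C`, `G`, `U`; `depth` recomputed if absent).
#' @param genome Optional [annotated_plastome()] used for strand, region and
#'   codon annotation.
#' @param params An [editing_params()].
#' @param strand Optional character vector (length `nrow(pileup)`) of
#'   candidate strands, used when `genome` is `NULL`.
#' @param region Optional character vector of region labels parallel to
#'   `pileup`, used when `genome` is `NULL`.
#' @param gene Optional character vector of gene/region names parallel to
#'   `pileup`, used when `genome` is `NULL`.
#' @return Data frame of accepted calls: `gene`, `region`, `strand`, `pos`,
#'   `ref`, `A`, `C`, `G`, `U`, `support`, `depth`, `frequency`,
#'   `completeness`, `codon_change`, `aa_change`.
#' @export
call_editing_sites <- function(pileup, genome = NULL,
                               params = editing_params(), strand = NULL,
                               region = NULL, gene = NULL) {
  empty <- data.frame(gene = character(), region = character(),
                      strand = character(), pos = integer(),
                      ref = character(), A = integer(), C = integer(),
                      G = integer(), U = integer(), support = integer(),
                      depth = integer(), frequency = numeric(),
                      completeness = character(),
                      codon_change = character(), aa_change = character())
  if (!nrow(pileup)) return(empty)
  depth <- if ("depth" %in% names(pileup)) pileup$depth else
    pileup$A + pileup$C + pileup$G + pileup$U

  # cheap necessary conditions: candidate base, depth window, and enough
  # edited-base reads in the best case (support <= max(A, U) always)
  cand <- pileup$ref %in% c("C", "G") &
    depth >= params$min_depth & depth <= params$max_depth &
    pmax(pileup$A, pileup$U) >= params$min_support
  if (!is.null(strand)) strand <- rep_len(strand, nrow(pileup))[cand]
  if (!is.null(region)) region <- rep_len(region, nrow(pileup))[cand]
  if (!is.null(gene)) gene <- rep_len(gene, nrow(pileup))[cand]
  pileup <- pileup[cand, , drop = FALSE]
  depth <- depth[cand]
  if (!nrow(pileup)) return(empty)

  n <- nrow(pileup)
  if (is.null(strand)) {
    strand <- character(n); region <- character(n); gene <- character(n)
    for (i in seq_len(n)) {
      if (!pileup$ref[i] %in% c("C", "G")) { strand[i] <- NA; next }
      if (!is.null(genome)) {
        cls <- classify_position(genome, pileup$pos[i])
        if (!is.null(cls$feature)) {
          strand[i] <- cls$feature$strand
          region[i] <- cls$label
          gene[i] <- cls$name
          next
        }
        region[i] <- "IGS"; gene[i] <- cls$name
      } else {
        region[i] <- NA_character_; gene[i] <- NA_character_
      }
      strand[i] <- if (pileup$ref[i] == "C") "+" else "-"
    }
  } else {
    if (is.null(region)) region <- rep(NA_character_, n)
    if (is.null(gene)) gene <- rep(NA_character_, n)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(strand[i])) next
    es <- edited_support(pileup[i, ], strand[i], params$orientation_mode)
    d <- depth[i]
    if (es$support < params$min_support) next
    if (d < params$min_depth || d > params$max_depth) next
    if (es$support / d < params$min_frequency) next
    rows[[i]] <- data.frame(
      gene = gene[i], region = region[i], strand = strand[i],
      pos = pileup$pos[i], ref = pileup$ref[i],
      A = as.integer(pileup$A[i]), C = as.integer(pileup$C[i]),
      G = as.integer(pileup$G[i]), U = as.integer(pileup$U[i]),
      support = es$support, depth = as.integer(d),
      frequency = es$support / d,
      completeness = if (es$support == d) "complete" else "partial",
      codon_change = NA_character_, aa_change = NA_character_,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, c(list(empty), rows[!vapply(rows, is.null, TRUE)]))
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(genome) && length(genome$features) && nrow(calls))
    calls <- annotate_codon_change(calls, genome)
  calls
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Amino-acid change implied by a codon change
#'
#' @param from,to Codons (3-mers, transcript orientation).
#' @return String `"X -> Y"` under the standard genetic code (`*` = stop).
#' @export
aa_change <- function(from, to)
  paste(translate_codon(from), "->", translate_codon(to))

#' Annotate codon and amino-acid changes on editing calls
#'
#' For calls in CDS regions, reads the codon containing the site in
#' transcript orientation (spliced across exon junctions,
#' reverse-complemented for minus-strand genes), substitutes the edited base
#' with `U` (written `T`) and translates both codons with the standard
#' genetic code.  Calls outside codon frames (introns, spacers, tRNA/rRNA,
#' pseudogenes) are retained with empty codon fields.
#'
#' @param calls Data frame from [call_editing_sites()].
#' @param genome An [annotated_plastome()] with features.
#' @return `calls` with `codon_change` (`"XYZ -> XYZ"`) and `aa_change`
#'   (`"X -> Y"`) filled in for CDS calls.
#' @export
annotate_codon_change <- function(calls, genome) {
  for (i in seq_len(nrow(calls))) {
    cls <- classify_position(genome, calls$pos[i])
    if (cls$label != "CDS") next
    ctx <- codon_context(genome, cls$feature, calls$pos[i])
    before <- ctx$codon
    after <- before
    substr(after, ctx$offset, ctx$offset) <- "T"
    if (substr(before, ctx$offset, ctx$offset) != "C") next  # not a C in frame
    calls$codon_change[i] <- paste(before, "->", after)
    calls$aa_change[i] <- aa_change(before, after)
    calls$gene[i] <- cls$feature$name
    calls$region[i] <- "CDS"
  }
  calls
}

#' Summarize editing calls
#'
#' @param calls Data frame from [call_editing_sites()].
#' @return List with `total`, `coding` (calls in CDS), `noncoding`,
#'   `complete`, `partial` and `per_region` (table of region labels).
#' @export
summarize_calls <- function(calls) {
  list(total = nrow(calls),
       coding = sum(calls$region == "CDS", na.rm = TRUE),
       noncoding = nrow(calls) - sum(calls$region == "CDS", na.rm = TRUE),
       complete = sum(calls$completeness == "complete"),
       partial = sum(calls$completeness == "partial"),
       per_region = table(calls$region, useNA = "no"))
}

#' Export editing calls
#'
#' `write_edit_table` writes a TSV mirroring the per-site report columns
#' (gene, strand, position, base, A, C, G, U, codon change, amino-acid
#' change).  `write_edit_vcf` writes a minimal VCF-style file with one
#' record per call; `INFO` carries support, depth and frequency.
#'
#' @param calls Data frame from [call_editing_sites()].
#' @param path Output path.
#' @param genome_id Reference name used in the VCF records.
#' @return `path`, invisibly.
#' @export
write_edit_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edit_table
#' @export
write_edit_vcf <- function(calls, path, genome_id = "plastome") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Edited-base support\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=EF,Number=1,Type=Float,Description=\"Editing frequency\">",
           "##INFO=<ID=STR,Number=1,Type=String,Description=\"Feature strand\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  alt <- ifelse(calls$strand == "+", "T", "A")
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSUP=%d;DP=%d;EF=%.4f;STR=%s",
                  genome_id, calls$pos, calls$ref, alt, calls$support,
                  calls$depth, calls$frequency, calls$strand)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
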