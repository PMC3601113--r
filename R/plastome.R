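# ---- annotated plastome container -------------------------------------------

#' Construct an annotated plastome
#'
#' An `annotated_plastome` holds a circular plastid genome sequence together
#' with its gene features and, optionally, a detected quadripartite structure.
#' All coordinates throughout the package are 1-based inclusive on the plus
#' strand; positions on the circle are normalized modulo the genome length.
#'
#' @param id Identifier for the genome record.
#' @param sequence Genome sequence: a single character string or a
#'   [Biostrings::DNAString] over `A,C,G,T,N`.
#' @param features List of gene features created with [gene_feature()].
#' @param structure Optional quadripartite structure as returned by
#'   [detect_quadripartite()].
#' @param circular Logical; plastomes are circular molecules (default `TRUE`).
#' @return An object of class `annotated_plastome` with elements `id`,
#'   `sequence` (character), `length`, `features`, `structure`, `circular`.
#' @seealso [gene_feature()], [read_plastome()], [detect_quadripartite()]
#' @export
annotated_plastome <- function(id, sequence, features = list(),
                               structure = NULL, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) == 0L)
    stop("'sequence' must be a single non-empty string")
  if (grepl("[^ACGTN]", sequence))
    stop("'sequence' may only contain A, C, G, T, N")
  len <- nchar(sequence)
  features <- lapply(features, as_gene_feature)
  for (f in features) {
    if (any(f$exons > len) || any(f$exons < 1L))
      stop("feature '", f$name, "' has exons outside [1, ", len, "]")
  }
  nm <- vapply(features, function(f) f$name, "")
  if (anyDuplicated(paste(nm, vapply(features, function(f) f$copy, 1L))))
    stop("feature names must be unique per (name, copy) pair")
  structure(list(id = as.character(id), sequence = sequence, length = len,
                 features = features, structure = structure,
                 circular = isTRUE(circular)),
            class = "annotated_plastome")
}

#' @export
print.annotated_plastome <- function(x, ...) {
  cat("annotated_plastome '", x$id, "': ", format(x$length, big.mark = ","),
      " bp, ", length(x$features), " features",
      if (!is.null(x$structure)) ", quadripartite" else "", "\n", sep = "")
  invisible(x)
}

#' Construct a gene feature
#'
#' Features live on the plus-strand coordinate system of the genome; a
#' feature on the minus strand still lists its exons as plus-strand intervals,
#' ordered by plus-strand position.  A CDS with more than one exon is an
#' intron-containing gene; the intervals between consecutive exons are its
#' introns.
#'
#' @param name Gene name (e.g. `"matK"`, `"trnL-CAA"`).
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"pseudogene"`.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 1-based inclusive
#'   plus-strand intervals, or a vector `c(start, end)` for a single exon.
#' @param phase Codon offset (0, 1 or 2) of the first transcribed exon base.
#' @param copy Copy index, used to distinguish the two copies of genes
#'   duplicated in the inverted repeats (default 1).
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(name, kind, strand, exons, phase = 0L, copy = 1L) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "pseudogene"))
  strand <- match.arg(strand, c("+", "-"))
  if (is.null(dim(exons))) exons <- matrix(exons, ncol = 2L, byrow = TRUE)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L]))
    stop("exon end before start in feature '", name, "'")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("overlapping exons in feature '", name, "'")
  structure(list(name = as.character(name), kind = kind, strand = strand,
                 exons = exons, phase = as.integer(phase),
                 copy = as.integer(copy)),
            class = "gene_feature")
}

as_gene_feature <- function(x) {
  if (inherits(x, "gene_feature")) return(x)
  do.call(gene_feature, x)
}

#' @export
print.gene_feature <- function(x, ...) {
  cat("gene_feature ", x$name, " [", x$kind, x$strand, "] ",
      paste(apply(x$exons, 1L, paste, collapse = "-"), collapse = ","),
      "\n", sep = " ")
  invisible(x)
}

feature_length <- function(f) sum(f$exons[, 2L] - f$exons[, 1L] + 1L)

feature_span <- function(f) c(min(f$exons[, 1L]), max(f$exons[, 2L]))

#' Introns of a feature
#'
#' @param feature A [gene_feature()].
#' @return Integer matrix (start, end) of plus-strand intron intervals, one
#'   row per interval between consecutive exons; zero rows for single-exon
#'   features.
#' @export
feature_introns <- function(feature) {
  ex <- feature$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), 2L] + 1L, end = ex[-1L, 1L] - 1L)
}

# circular position normalization: maps any integer onto [1, len]
wrap_position <- function(pos, len) ((pos - 1L) %% len) + 1L

# substring on the circle; pos may exceed len (wraps)
circular_substr <- function(seq, start, width) {
  len <- nchar(seq)
  start <- wrap_position(start, len)
  end <- start + width - 1L
  if (end <= len) return(substr(seq, start, end))
  paste0(substr(seq, start, len), circular_substr(seq, 1L, end - len))
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# ---- region classification --------------------------------------------------

#' Classify a genome position by annotation
#'
#' Assigns every position exactly one label.  A position inside an exon gets
#' the feature's kind; a position between consecutive exons of one feature is
#' `intron`; anything else is intergenic (`IGS`), labelled with its flanking
#' gene names as `"geneA - geneB"` in plus-strand order around the circle.
#' When features overlap, the priority CDS > tRNA > rRNA > pseudogene decides
#' deterministically.
#'
#' @param genome An [annotated_plastome()].
#' @param position 1-based position (normalized onto the circle).
#' @return A list with `label` (one of `CDS`, `tRNA`, `rRNA`, `pseudogene`,
#'   `intron`, `IGS`), `feature` (the owning [gene_feature()] or `NULL`) and
#'   `name` (feature name, or the `"geneA - geneB"` spacer label for IGS).
#' @export
classify_position <- function(genome, position) {
  position <- wrap_position(as.integer(position), genome$length)
  prio <- c(CDS = 1L, tRNA = 2L, rRNA = 3L, pseudogene = 4L)
  exon_hit <- NULL; intron_hit <- NULL
  for (f in genome$features) {
    ex <- f$exons
    if (any(position >= ex[, 1L] & position <= ex[, 2L])) {
      if (is.null(exon_hit) || prio[[f$kind]] < prio[[exon_hit$kind]])
        exon_hit <- f
    } else {
      ins <- feature_introns(f)
      if (nrow(ins) && any(position >= ins[, 1L] & position <= ins[, 2L])) {
        if (is.null(intron_hit)) intron_hit <- f
      }
    }
  }
  if (!is.null(exon_hit))
    return(list(label = exon_hit$kind, feature = exon_hit,
                name = exon_hit$name))
  if (!is.null(intron_hit))
    return(list(label = "intron", feature = intron_hit,
                name = intron_hit$name))
  list(label = "IGS", feature = NULL,
       name = igs_label(genome, position))
}

# flanking gene names "upstream - downstream" on the plus strand, circularly
igs_label <- function(genome, position) {
  if (!length(genome$features)) return("IGS")
  sp <- t(vapply(genome$features, feature_span, integer(2L)))
  nm <- vapply(genome$features, function(f) f$name, "")
  len <- genome$length
  dist_up <- (position - sp[, 2L]) %% len    # from feature end forward to pos
  dist_dn <- (sp[, 1L] - position) %% len    # from pos forward to feature start
  paste(nm[which.min(dist_up)], "-", nm[which.min(dist_dn)])
}

# ---- codon context ----------------------------------------------------------

# spliced transcript sequence of a feature, in transcript orientation
feature_transcript <- function(genome, feature) {
  ex <- feature$exons
  parts <- vapply(seq_len(nrow(ex)), function(i)
    substr(genome$sequence, ex[i, 1L], ex[i, 2L]), "")
  s <- paste(parts, collapse = "")
  if (feature$strand == "-") s <- revcomp(s)
  s
}

# map a plus-strand genome position into transcript coordinates (1-based);
# NA when the position is not exonic for this feature
transcript_index <- function(feature, position) {
  ex <- feature$exons
  widths <- ex[, 2L] - ex[, 1L] + 1L
  hit <- which(position >= ex[, 1L] & position <= ex[, 2L])
  if (!length(hit)) return(NA_integer_)
  plus_idx <- sum(widths[seq_len(hit - 1L)]) + (position - ex[hit, 1L] + 1L)
  as.integer(if (feature$strand == "+") plus_idx
             else sum(widths) - plus_idx + 1L)
}

#' Codon context of a coding position
#'
#' Reads the codon containing `position` in transcript orientation: exons are
#' spliced together and reverse-complemented for minus-strand genes, so the
#' returned codon is what the ribosome would see.
#'
#' @param genome An [annotated_plastome()].
#' @param feature A CDS [gene_feature()] containing the position in an exon.
#' @param position Plus-strand genome position.
#' @return List with `codon` (3-mer, transcript orientation), `offset`
#'   (1, 2 or 3: the queried base's place within the codon) and
#'   `transcript_pos`.
#' @export
codon_context <- function(genome, feature, position) {
  if (feature$kind == "pseudogene")
    stop("no codon frame: '", feature$name, "' is a pseudogene")
  if (feature$kind != "CDS")
    stop("no codon frame: '", feature$name, "' is not protein-coding")
  position <- wrap_position(as.integer(position), genome$length)
  tpos <- transcript_index(feature, position)
  if (is.na(tpos))
    stop("position ", position, " is not exonic in '", feature$name, "'")
  tx <- feature_transcript(genome, feature)
  k <- tpos - feature$phase          # 1-based index within the framed CDS
  if (k < 1L) stop("position precedes the codon frame of '", feature$name, "'")
  codon_i <- (k - 1L) %/% 3L
  offset <- as.integer((k - 1L) %% 3L + 1L)
  codon <- substr(tx, feature$phase + codon_i * 3L + 1L,
                  feature$phase + codon_i * 3L + 3L)
  if (nchar(codon) < 3L)
    stop("incomplete terminal codon in '", feature$name, "'")
  list(codon = codon, offset = offset, transcript_pos = tpos)
}
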