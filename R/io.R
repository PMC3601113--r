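# ---- reading and writing annotated plastomes --------------------------------

#' Read an annotated plastome from standard files
#'
#' Two input routes are supported: a GenBank flat file carrying both sequence
#' and annotation, or a FASTA sequence plus a GFF3 annotation.  Coordinates
#' are normalized to 1-based inclusive plus-strand intervals;
#' `join(...)`/`complement(...)` locations are decomposed into exon lists
#' with strand.
#'
#' @param path Path to the GenBank file, or to the FASTA file when
#'   `format = "fasta+gff3"`.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff3 Path to the GFF3 annotation (required for `"fasta+gff3"`).
#' @return An [annotated_plastome()].
#' @export
read_plastome <- function(path, format = c("genbank", "fasta+gff3"),
                          gff3 = NULL) {
  format <- match.arg(format)
  if (format == "genbank") return(read_genbank_plastome(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequence records in ", path)
  id <- sub("\\s.*", "", names(seqs)[1L])
  features <- if (!is.null(gff3)) read_features_gff3(gff3) else list()
  annotated_plastome(id, as.character(seqs[[1L]]), features)
}

#' Write an annotated plastome as FASTA + GFF3
#'
#' @param genome An [annotated_plastome()].
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the genome.
#' @export
write_plastome <- function(genome, fasta, gff3) {
  seqs <- Biostrings::DNAStringSet(structure(genome$sequence,
                                             names = genome$id))
  Biostrings::writeXStringSet(seqs, fasta)
  write_features_gff3(genome, gff3)
  invisible(genome)
}

feature_id <- function(f)
  if (f$copy > 1L) paste0(f$name, "#", f$copy) else f$name

write_features_gff3 <- function(genome, path) {
  feats <- genome$features
  if (!length(feats)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(feats, function(f) {
    data.frame(start = f$exons[, 1L], end = f$exons[, 2L],
               strand = f$strand, type = f$kind,
               ID = feature_id(f), Name = f$name,
               phase = if (f$kind == "CDS") f$phase else NA_integer_,
               copy = f$copy)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "plastoscope", type = rows$type, phase = rows$phase,
    ID = rows$ID, Name = rows$Name, copy = rows$copy)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

read_features_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  kind_map <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                pseudogene = "pseudogene",
                pseudogenic_region = "pseudogene")
  keep <- as.character(gr$type) %in% names(kind_map)
  gr <- gr[keep]
  if (!length(gr)) return(list())
  mc <- S4Vectors::mcols(gr)
  group <- if (!is.null(mc$ID) && !all(is.na(mc$ID))) {
    as.character(mc$ID)
  } else if (!is.null(mc$Parent) && length(unlist(mc$Parent))) {
    vapply(as.list(mc$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, "")
  } else paste0("feat", seq_along(gr))
  group[is.na(group)] <- paste0("feat", which(is.na(group)))
  feats <- lapply(split(seq_along(gr), group)[unique(group)], function(i) {
    sub <- gr[i]
    msub <- S4Vectors::mcols(sub)
    nm <- if (!is.null(msub$Name) && !is.na(msub$Name[1L]))
      as.character(msub$Name[1L]) else sub("#.*$", "", group[i[1L]])
    phase <- if (!is.null(msub$phase)) {
      ph <- suppressWarnings(as.integer(as.character(msub$phase)))
      if (all(is.na(ph))) 0L else ph[which.min(GenomicRanges::start(sub))]
    } else 0L
    copy <- if (!is.null(msub$copy) && !is.na(msub$copy[1L]))
      as.integer(msub$copy[1L]) else 1L
    gene_feature(
      name = nm,
      kind = kind_map[[as.character(msub$type[1L])]],
      strand = as.character(GenomicRanges::strand(sub))[1L],
      exons = cbind(GenomicRanges::start(sub), GenomicRanges::end(sub)),
      phase = if (is.na(phase)) 0L else phase,
      copy = copy)
  })
  unname(feats)
}

# ---- minimal GenBank flat-file reader ---------------------------------------
# Parses LOCUS/FEATURES/ORIGIN of a single-record flat file: enough for
# plastome records (CDS/tRNA/rRNA keys, join/complement locations, /gene,
# /pseudo, /codon_start qualifiers).

read_genbank_plastome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("parse error: no LOCUS line in ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("parse error: no ORIGIN section in ", path)
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- list()
  if (length(fstart)) {
    fend <- ostart[1L] - 1L
    flines <- lines[(fstart[1L] + 1L):fend]
    # a new feature starts with a key in column 6; continuations are deeper
    is_key <- grepl("^     \\S", flines)
    idx <- cumsum(is_key)
    for (block in split(flines[idx > 0L], idx[idx > 0L])) {
      key <- sub("^\\s*(\\S+).*", "\\1", block[1L])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      body <- paste(c(trimws(sub("^\\s*\\S+\\s*", "", block[1L])),
                      trimws(block[-1L])), collapse = "\n")
      # location: everything up to the first qualifier line
      parts <- strsplit(body, "\n/")[[1L]]
      loc_str <- gsub("[\n ]", "", parts[1L])
      quals <- parts[-1L]
      loc <- tryCatch(parse_genbank_location(loc_str),
                      error = function(e)
                        stop("parse error in feature '", key, "': ",
                             conditionMessage(e)))
      gene <- sub('^gene="?([^"\n]*)"?.*$', "\\1",
                  grep("^gene=", quals, value = TRUE)[1L])
      if (is.na(gene)) gene <- paste0(key, "_", loc$exons[1L, 1L])
      pseudo <- any(grepl("^pseudo\\b", quals))
      cs <- grep("^codon_start=", quals, value = TRUE)
      phase <- if (length(cs))
        as.integer(sub("^codon_start=([0-9]+).*$", "\\1", cs[1L])) - 1L else 0L
      kind <- if (pseudo) "pseudogene" else key
      features[[length(features) + 1L]] <-
        gene_feature(gene, kind, loc$strand, loc$exons, phase)
    }
  }
  # duplicate IR gene copies share names: assign copy indices
  nm <- vapply(features, function(f) f$name, "")
  for (dup in unique(nm[duplicated(nm)])) {
    at <- which(nm == dup)
    for (k in seq_along(at)) features[[at[k]]]$copy <- k
  }
  annotated_plastome(id, sequence, features)
}

parse_genbank_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join", loc))
    stop("unsupported nested location '", loc, "'")
  spans <- strsplit(loc, ",")[[1L]]
  m <- regmatches(spans, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", spans))
  single <- regmatches(spans, regexec("^(\\d+)$", spans))
  exons <- t(vapply(seq_along(spans), function(i) {
    if (length(m[[i]]) == 3L) as.integer(m[[i]][2:3])
    else if (length(single[[i]]) == 2L) rep(as.integer(single[[i]][2L]), 2L)
    else stop("cannot parse location span '", spans[i], "'")
  }, integer(2L)))
  list(strand = strand, exons = exons)
}
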