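# shared fixtures and independent oracles, all built in code

rc <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# a small hand-built plastome: two plus-strand CDS separated by a spacer,
# one minus-strand CDS, a two-exon (intron) CDS, a tRNA and a pseudogene
tiny_genome <- function() {
  chars <- rep("A", 1200L)
  stamp <- function(chars, at, s) {
    chars[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]
    chars
  }
  psbK <- paste0("ATG", "TCAGGTCAT", "CCGTTCGAT", "TAA")     # 24 bp, + strand
  psbI <- paste0("ATG", "CATCCAGCT", "TAA")                  # 15 bp, + strand
  mk <- paste0("ATG", "CATTCTACT", "TGG", "TAA")             # 18 bp, - strand
  ex1 <- "ATGGATTC"                                          # split codon: TC|A
  ex2 <- paste0("ACGT", "TAA")                               # spliced: ATG GAT TCA CGT TAA
  trna <- rand_seq(40L)
  pseu <- paste0("ATG", "AAACCC", "TAA", "GGG", "TAA")       # internal stop
  chars <- stamp(chars, 101L, psbK)
  chars <- stamp(chars, 201L, psbI)
  chars <- stamp(chars, 301L, rc(mk))
  chars <- stamp(chars, 401L, ex1)
  chars <- stamp(chars, 501L, ex2)                           # intron 409..500
  chars <- stamp(chars, 601L, trna)
  chars <- stamp(chars, 701L, pseu)
  annotated_plastome("tiny", paste(chars, collapse = ""), list(
    gene_feature("psbK", "CDS", "+", c(101L, 124L)),
    gene_feature("psbI", "CDS", "+", c(201L, 215L)),
    gene_feature("matK", "CDS", "-", c(301L, 318L)),
    gene_feature("rps16", "CDS", "+", rbind(c(401L, 408L), c(501L, 507L))),
    gene_feature("trnW-CCA", "tRNA", "+", c(601L, 640L)),
    gene_feature("ycf68", "pseudogene", "+", c(701L, 717L))))
}

# one-row aligned-read data frame
make_read <- function(pos, seq, cigar = paste0(nchar(seq), "M"),
                      qual = NULL, strand = "+", mapq = 42L, nm = 0L,
                      qname = "r") {
  if (is.null(qual))
    qual <- paste(rep(rawToChar(as.raw(33L + 35L)), nchar(seq)),
                  collapse = "")
  data.frame(qname = qname, flag = if (strand == "-") 16L else 0L,
             pos = as.integer(pos), mapq = as.integer(mapq),
             strand = strand, cigar = cigar, seq = seq, qual = qual,
             nm = as.integer(nm), stringsAsFactors = FALSE)
}

# independent pileup oracle: per-read nested loop with its own CIGAR walker
naive_pileup <- function(reads, genome, min_q = 20L) {
  L <- genome$length
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "U")))
  qsum <- numeric(L)
  for (r in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[r],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[r]))[[1L]]
    refp <- reads$pos[r]; qp <- 1L
    sq <- strsplit(reads$seq[r], "")[[1L]]
    qv <- as.integer(charToRaw(reads$qual[r])) - 33L
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          p <- ((refp - 1L) %% L) + 1L
          if (qv[qp] >= min_q) {
            b <- sq[qp]
            if (b == "T") b <- "U"
            if (b %in% colnames(counts)) {
              counts[p, b] <- counts[p, b] + 1L
              qsum[p] <- qsum[p] + qv[qp]
            }
          }
          refp <- refp + 1L; qp <- qp + 1L
        }
      } else if (type %in% c("D", "N")) refp <- refp + n
      else if (type %in% c("I", "S")) qp <- qp + n
    }
  }
  depth <- rowSums(counts)
  covered <- which(depth > 0L)
  refchars <- strsplit(genome$sequence, "")[[1L]]
  data.frame(pos = covered, ref = refchars[covered],
             A = counts[covered, "A"], C = counts[covered, "C"],
             G = counts[covered, "G"], U = counts[covered, "U"],
             depth = as.integer(depth[covered]),
             mean_qual = qsum[covered] / depth[covered],
             row.names = NULL)
}

# exhaustive inverted-repeat oracle for tiny circular sequences:
# maximal length of a pair of disjoint exact inverted repeats
brute_force_ir_length <- function(s) {
  L <- nchar(s)
  sd <- paste0(s, s)
  best <- 0L
  for (len in seq_len(L %/% 2L)) {
    found <- FALSE
    for (i in seq_len(L)) {
      sub1 <- substr(sd, i, i + len - 1L)
      target <- rc(sub1)
      for (j in seq_len(L)) {
        if (len * 2L > L) next
        # disjoint on the circle?
        g1 <- (j - (i + len - 1L) - 1L) %% L
        g2 <- (i - (j + len - 1L) - 1L) %% L
        if (2L * len + g1 + g2 != L) next
        if (substr(sd, j, j + len - 1L) == target) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) best <- len else break
  }
  best
}

# independent indel oracle: literal column scan of a pairwise alignment
scan_indels <- function(ref, qry) {
  r <- strsplit(ref, "")[[1L]]; q <- strsplit(qry, "")[[1L]]
  refcoord <- cumsum(r != "-")
  out <- list()
  run_kind <- NULL; run_start <- NULL
  for (i in seq_along(r)) {
    kind <- if (q[i] == "-" && r[i] != "-") "deletion"
            else if (r[i] == "-" && q[i] != "-") "insertion" else NA
    if (!is.na(kind) && (is.null(run_kind) || kind != run_kind ||
                         run_last + 1L != i)) {
      if (!is.null(run_kind))
        out[[length(out) + 1L]] <- list(kind = run_kind,
                                        pos = if (run_start == 1L) 0L else
                                          refcoord[run_start - 1L],
                                        len = run_last - run_start + 1L)
      run_kind <- kind; run_start <- i
    }
    if (!is.na(kind)) run_last <- i
    if (is.na(kind) && !is.null(run_kind)) {
      out[[length(out) + 1L]] <- list(kind = run_kind,
                                      pos = if (run_start == 1L) 0L else
                                        refcoord[run_start - 1L],
                                      len = run_last - run_start + 1L)
      run_kind <- NULL
    }
  }
  if (!is.null(run_kind))
    out[[length(out) + 1L]] <- list(kind = run_kind,
                                    pos = if (run_start == 1L) 0L else
                                      refcoord[run_start - 1L],
                                    len = run_last - run_start + 1L)
  do.call(rbind, lapply(out, function(x)
    data.frame(position = x$pos, length = x$len, kind = x$kind,
               stringsAsFactors = FALSE)))
}

# sorted member-name sets per truth unit (overlap of feature span)
truth_unit_members <- function(truth, genome) {
  lapply(seq_len(nrow(truth$units)), function(i) {
    u1 <- truth$units$start[i]; u2 <- truth$units$end[i]
    nm <- vapply(genome$features, function(f) {
      hit <- any(f$exons[, 1L] <= u2 & f$exons[, 2L] >= u1)
      if (hit) paste0(f$name, "#", f$copy) else NA_character_
    }, "")
    sort(nm[!is.na(nm)])
  })
}
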