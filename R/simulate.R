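# ---- synthetic plastome / transcriptome simulator ---------------------------

#' Simulation configuration
#'
#' Parameters for [generate_plastome()] and [simulate_reads()].  Defaults
#' describe a plastome-like circular genome at reduced scale: a pair of
#' exact inverted repeats separating a large and a small single-copy region,
#' genes on both strands including intron-containing genes and pseudogenes,
#' polycistronic transcription covering most of the circle, C-to-U editing
#' at mostly-edited sites, partially spliced introns, 100 bp reads from an
#' unstranded library and a small base-error rate.
#'
#' @param seed Integer seed threaded through every sampling step.
#' @param genome_length Total circle length in bp.
#' @param ir_length Length of each inverted repeat (0 = no repeat).
#' @param n_genes Total number of distinct genes (all kinds).
#' @param intron_genes How many protein-coding genes carry one intron.
#' @param pseudogenes How many genes carry an internal stop codon.
#' @param n_untranscribed How many genes are left out of every transcription
#'   unit (picked as one protein-coding gene plus tRNAs when available).
#' @param transcribed_fraction Target fraction of the genome inside
#'   transcription units.
#' @param operons Optional explicit operon table (`start`, `end`, `strand`,
#'   `expression`); `NULL` lets the generator group consecutive genes.
#' @param edit_sites Optional explicit edit table (`position`, `fraction`,
#'   `strand`); `NULL` plants `n_edits` sites in transcribed coding exons.
#' @param n_edits Number of editing sites planted automatically.
#' @param edit_fraction_range Range the per-site editing fractions are drawn
#'   from.
#' @param splice_fractions Per-intron splicing fractions, recycled over the
#'   intron-containing genes in positional order (default 0.8 for all).
#' @param expression_levels Relative expression multipliers transcription
#'   units are sampled from (rRNA-containing units get twice theirs).
#' @param read_length Read length in bp.
#' @param target_depth Mean read depth over transcribed positions.
#' @param base_error_rate Per-base sequencing error probability.
#' @param unstranded Emit each read on a random strand (probability 0.5),
#'   emulating an unstranded cDNA library.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_length = 20000L,
                              ir_length = 2000L, n_genes = 18L,
                              intron_genes = 2L, pseudogenes = 2L,
                              n_untranscribed = 3L,
                              transcribed_fraction = 0.95,
                              operons = NULL, edit_sites = NULL,
                              n_edits = 10L,
                              edit_fraction_range = c(0.6, 1),
                              splice_fractions = 0.8,
                              expression_levels = c(1, 1.5, 2),
                              read_length = 100L, target_depth = 40L,
                              base_error_rate = 0.002, unstranded = TRUE) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              ir_length = as.integer(ir_length),
              n_genes = as.integer(n_genes),
              intron_genes = as.integer(intron_genes),
              pseudogenes = as.integer(pseudogenes),
              n_untranscribed = as.integer(n_untranscribed),
              transcribed_fraction = as.numeric(transcribed_fraction),
              operons = operons, edit_sites = edit_sites,
              n_edits = as.integer(n_edits),
              edit_fraction_range = as.numeric(edit_fraction_range),
              splice_fractions = as.numeric(splice_fractions),
              expression_levels = as.numeric(expression_levels),
              read_length = as.integer(read_length),
              target_depth = as.numeric(target_depth),
              base_error_rate = as.numeric(base_error_rate),
              unstranded = isTRUE(unstranded))
  stopifnot(cfg$genome_length > 0, cfg$ir_length >= 0,
            cfg$genome_length > 2L * cfg$ir_length,
            cfg$transcribed_fraction >= 0, cfg$transcribed_fraction <= 1,
            all(cfg$edit_fraction_range >= 0),
            all(cfg$edit_fraction_range <= 1),
            all(cfg$splice_fractions >= 0), all(cfg$splice_fractions <= 1),
            cfg$base_error_rate >= 0, cfg$base_error_rate < 1,
            cfg$read_length > 0, cfg$target_depth >= 0)
  structure(cfg, class = "simulation_config")
}

# sample() without the scalar-x surprise
resample <- function(x, n, replace = FALSE)
  x[sample.int(length(x), n, replace = replace)]

random_dna <- function(n, gc = 0.37)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")

# sense-strand CDS string: ATG + stop-free codons + TAA; pseudogenes get an
# internal stop planted mid-frame
build_cds_seq <- function(n_codons, pseudo = FALSE) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  safe <- setdiff(all_codons, c("TAA", "TAG", "TGA", "ATG"))
  body <- sample(safe, n_codons - 2L, replace = TRUE)
  if (pseudo) body[ceiling(length(body) / 2)] <- "TAA"
  paste(c("ATG", body, "TAA"), collapse = "")
}

sim_gene_pools <- function() list(
  cds = c("psbA", "rbcL", "atpA", "atpB", "atpE", "ndhF", "rpoB", "rpoC2",
          "psaA", "psaB", "psbB", "psbC", "psbD", "petA", "petD", "rps2",
          "rps4", "rps18", "rpl20", "rpl33", "ccsA", "cemA", "ycf4",
          "accD", "matK", "petL"),
  intron_cds = c("rps16", "ycf3", "clpP", "atpF", "ndhA", "petB", "rpl16",
                 "ndhB", "rpl2", "rpoC1", "matK"),
  trna = c("trnL-UAA", "trnK-UUU", "trnT-GGU", "trnT-UGU", "trnE-UUC",
           "trnL-CAA", "trnV-GAC", "trnI-GAU", "trnF-GAA", "trnS-GCU",
           "trnQ-UUG", "trnW-CCA"),
  rrna = c("rrn16", "rrn23", "rrn4.5", "rrn5"),
  pseudo = c("ycf68", "orf56", "orf188", "lhbA", "ycf15"))

#' Generate an annotated synthetic plastome with truth
#'
#' Builds a circular genome with the requested quadripartite layout
#' (LSC-IRb-SSC-IRa; the IRa segment is the exact reverse complement of
#' IRb, and the flanking bases are forced to break the repeat so the planted
#' boundaries are maximal), plants genes on both strands (protein-coding,
#' tRNA, rRNA, intron-containing and pseudogenes; genes placed inside IRb
#' are mirrored into IRa as copy 2), groups them into polycistronic
#' transcription units separated by untranscribed spacers, and chooses
#' editing sites and splicing fractions.  Deterministic under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (an [annotated_plastome()]) and `truth`
#'   (class `synthetic_truth`: `structure`, `features`, `units`, `edits`,
#'   `junctions`, `untranscribed`, `transcribed_fraction`, `config`).
#' @export
generate_plastome <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  ir <- config$ir_length
  sc <- L - 2L * ir
  lsc_len <- if (ir > 0L) round(sc * 0.82) else L
  ssc_len <- sc - lsc_len
  lsc <- c(1L, lsc_len)
  irb <- if (ir > 0L) c(lsc_len + 1L, lsc_len + ir) else NULL
  ssc <- if (ir > 0L) c(lsc_len + ir + 1L, L - ir) else NULL
  ira <- if (ir > 0L) c(L - ir + 1L, L) else NULL

  chars <- strsplit(random_dna(L), "", fixed = TRUE)[[1L]]
  pools <- sim_gene_pools()

  # ---- allocate gene specs --------------------------------------------------
  n_trna <- max(2L, round(config$n_genes * 0.2))
  has_ir_genes <- ir >= 2000L
  n_rrna <- if (has_ir_genes) 1L else 0L
  n_cds <- config$n_genes - config$intron_genes - config$pseudogenes -
    n_trna - n_rrna
  if (n_cds < 1L)
    stop("infeasible packing: n_genes too small for the requested ",
         "intron/pseudogene/tRNA mix")
  spec <- function(kind, name, intron = FALSE, pseudo = FALSE)
    list(kind = kind, name = name, intron = intron, pseudo = pseudo)
  specs <- c(
    lapply(pools$cds[seq_len(n_cds)], function(nm) spec("CDS", nm)),
    lapply(pools$intron_cds[seq_len(config$intron_genes)],
           function(nm) spec("CDS", nm, intron = TRUE)),
    lapply(if (config$pseudogenes > 0L)
      pools$pseudo[seq_len(config$pseudogenes)] else character(),
      function(nm) spec("pseudogene", nm, pseudo = TRUE)),
    lapply(pools$trna[seq_len(n_trna)], function(nm) spec("tRNA", nm)))
  specs <- sample(specs)                   # shuffle placement order
  ir_specs <- if (has_ir_genes)
    list(spec("rRNA", pools$rrna[1L])) else list()

  # ---- place genes ----------------------------------------------------------
  margin <- 30L
  features <- list()
  place <- function(specs, region, features) {
    cursor <- region[1L] + margin + sample(40:100, 1L)
    for (sp in specs) {
      if (sp$kind == "CDS" || sp$kind == "pseudogene") {
        n_codons <- sample(50:120, 1L)
        s <- build_cds_seq(n_codons, pseudo = sp$pseudo)
        if (sp$intron) {
          cut <- sample(4:(nchar(s) - 4L), 1L)
          il <- sample(60:150, 1L)
          intron_seq <- paste0("GT", random_dna(il - 4L), "AG")
          exon_loc <- rbind(c(1L, cut), c(cut + il + 1L, nchar(s) + il))
          s <- paste0(substr(s, 1L, cut), intron_seq,
                      substr(s, cut + 1L, nchar(s)))
        } else exon_loc <- rbind(c(1L, nchar(s)))
      } else if (sp$kind == "tRNA") {
        s <- random_dna(sample(72:85, 1L))
        exon_loc <- rbind(c(1L, nchar(s)))
      } else {                             # rRNA
        s <- random_dna(sample(1000:1400, 1L))
        exon_loc <- rbind(c(1L, nchar(s)))
      }
      glen <- nchar(s)
      if (cursor + glen - 1L > region[2L] - margin)
        stop("infeasible packing: gene '", sp$name,
             "' does not fit in region [", region[1L], ",", region[2L], "]")
      strand <- sample(c("+", "-"), 1L)
      stamped <- if (strand == "+") s else revcomp(s)
      chars[cursor:(cursor + glen - 1L)] <<-
        strsplit(stamped, "", fixed = TRUE)[[1L]]
      exons <- if (strand == "+") {
        cbind(cursor + exon_loc[, 1L] - 1L, cursor + exon_loc[, 2L] - 1L)
      } else {
        g2 <- cursor + glen - 1L
        m <- cbind(g2 - exon_loc[, 2L] + 1L, g2 - exon_loc[, 1L] + 1L)
        m[order(m[, 1L]), , drop = FALSE]
      }
      features[[length(features) + 1L]] <-
        gene_feature(sp$name, sp$kind, strand, exons)
      cursor <- cursor + glen + sample(50:180, 1L)
    }
    features
  }

  # split single-copy specs between LSC (most) and SSC, respecting capacity
  n_ssc <- if (ir == 0L || length(specs) <= 4L) 0L
    else if (ssc_len >= 1600L) 2L else if (ssc_len >= 900L) 1L else 0L
  ssc_specs <- if (n_ssc) specs[seq_len(n_ssc)] else list()
  lsc_specs <- specs[setdiff(seq_along(specs), seq_len(n_ssc))]
  features <- place(lsc_specs, lsc, features)
  if (length(ssc_specs)) features <- place(ssc_specs, ssc, features)
  if (length(ir_specs)) features <- place(ir_specs, irb, features)

  # ---- inverted repeat: IRa := revcomp(IRb), mirror IRb features ------------
  if (ir > 0L) {
    irb_seq <- paste(chars[irb[1L]:irb[2L]], collapse = "")
    chars[ira[1L]:ira[2L]] <-
      strsplit(revcomp(irb_seq), "", fixed = TRUE)[[1L]]
    for (f in features) {
      if (f$exons[1L, 1L] >= irb[1L] && max(f$exons[, 2L]) <= irb[2L]) {
        m <- cbind(ira[2L] - (f$exons[, 2L] - irb[1L]),
                   ira[2L] - (f$exons[, 1L] - irb[1L]))
        features[[length(features) + 1L]] <- gene_feature(
          f$name, f$kind, if (f$strand == "+") "-" else "+",
          m[order(m[, 1L]), , drop = FALSE], copy = 2L)
      }
    }
    # break the repeat at both boundaries so planted coordinates are maximal
    comp1 <- function(b) chartr("ACGTN", "TGCAN", b)
    if (chars[lsc_len] == comp1(chars[1L]))
      chars[lsc_len] <- setdiff(c("A", "C", "G", "T"),
                                c(comp1(chars[1L]), chars[lsc_len]))[1L]
    if (chars[ssc[1L]] == comp1(chars[ssc[2L]]))
      chars[ssc[1L]] <- setdiff(c("A", "C", "G", "T"),
                                c(comp1(chars[ssc[2L]]), chars[ssc[1L]]))[1L]
  }

  genome <- annotated_plastome(
    sprintf("synthetic_plastome_seed%d", config$seed),
    paste(chars, collapse = ""), features)

  planted_structure <- if (ir > 0L)
    structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                   ir_length = ir, genome_length = L),
              class = "quadripartite_structure") else NULL

  # ---- transcription units --------------------------------------------------
  ord <- order(vapply(features, function(f) f$exons[1L, 1L], 1L))
  feats_ord <- features[ord]
  n_feats <- length(feats_ord)
  untr_idx <- integer()
  if (config$n_untranscribed > 0L && n_feats > config$n_untranscribed + 2L) {
    inner <- 2:(n_feats - 1L)               # keep origin-flanking genes
    single <- inner[vapply(feats_ord[inner], function(f)
      f$copy == 1L && nrow(f$exons) == 1L, TRUE)]
    cds_c <- single[vapply(feats_ord[single],
                           function(f) f$kind == "CDS", TRUE)]
    trna_c <- single[vapply(feats_ord[single],
                            function(f) f$kind == "tRNA", TRUE)]
    pick <- c(if (length(cds_c)) resample(cds_c, 1L),
              if (length(trna_c))
                resample(trna_c, min(length(trna_c),
                                     config$n_untranscribed - 1L)))
    untr_idx <- sort(utils::head(pick, config$n_untranscribed))
  }
  untranscribed <- vapply(feats_ord[untr_idx], function(f) f$name, "")

  units <- config$operons
  if (is.null(units)) {
    groups <- list(); cur <- integer(); target <- sample(2:5, 1L)
    prev_end <- NA_integer_
    for (i in seq_len(n_feats)) {
      fs <- feats_ord[[i]]$exons[1L, 1L]
      if (i %in% untr_idx ||
          (length(cur) && fs - prev_end > 1500L)) {
        if (length(cur)) groups[[length(groups) + 1L]] <- cur
        cur <- integer(); target <- sample(2:5, 1L)
        if (i %in% untr_idx) { prev_end <- max(feats_ord[[i]]$exons[, 2L]); next }
      }
      cur <- c(cur, i)
      prev_end <- max(feats_ord[[i]]$exons[, 2L])
      if (length(cur) >= target) {
        groups[[length(groups) + 1L]] <- cur
        cur <- integer(); target <- sample(2:5, 1L)
      }
    }
    if (length(cur)) groups[[length(groups) + 1L]] <- cur
    g <- length(groups)
    gs <- vapply(groups, function(ix)
      min(vapply(feats_ord[ix], function(f) f$exons[1L, 1L], 1L)), 1L)
    ge <- vapply(groups, function(ix)
      max(vapply(feats_ord[ix], function(f) max(f$exons[, 2L]), 1L)), 1L)
    # holes: one per inter-group gap plus one across the origin
    gap_lo <- c(ge[g] + 1L, ge[-g] + 1L)        # gap i precedes group i
    gap_hi <- c(gs[1L] - 1L + L, gs[-1L] - 1L)
    gap_len <- gap_hi - gap_lo + 1L
    mand <- integer(g)
    for (i in seq_len(g)) {
      u_in <- untr_idx[vapply(feats_ord[untr_idx], function(f)
        f$exons[1L, 1L] >= gap_lo[i] && max(f$exons[, 2L]) <= gap_hi[i],
        TRUE)]
      mand[i] <- if (length(u_in)) {
        span <- range(unlist(lapply(feats_ord[u_in], function(f)
          c(f$exons[1L, 1L], max(f$exons[, 2L])))))
        span[2L] - span[1L] + 1L + 40L
      } else 1L
    }
    w <- pmax(mand, 1L)
    budget <- round((1 - config$transcribed_fraction) * L) - sum(w)
    if (budget > 0L) {
      room <- pmax(gap_len - 10L - w, 0L)
      add <- pmin(room, round(budget * room / max(sum(room), 1L)))
      w <- w + add
    }
    w <- pmin(w, gap_len - 2L)
    hole <- matrix(0L, g, 2L)
    for (i in seq_len(g)) {
      u_in <- untr_idx[vapply(feats_ord[untr_idx], function(f)
        f$exons[1L, 1L] >= gap_lo[i] && max(f$exons[, 2L]) <= gap_hi[i],
        TRUE)]
      center <- if (length(u_in)) {
        span <- range(unlist(lapply(feats_ord[u_in], function(f)
          c(f$exons[1L, 1L], max(f$exons[, 2L])))))
        mean(span)
      } else if (i == 1L) L + 0.5 else mean(c(gap_lo[i], gap_hi[i]))
      h1 <- max(gap_lo[i] + 1L, round(center - w[i] / 2))
      h2 <- min(gap_hi[i] - 1L, h1 + w[i] - 1L)
      h1 <- max(gap_lo[i] + 1L, h2 - w[i] + 1L)
      if (length(u_in)) {
        span <- range(unlist(lapply(feats_ord[u_in], function(f)
          c(f$exons[1L, 1L], max(f$exons[, 2L])))))
        h1 <- min(h1, span[1L] - 1L); h2 <- max(h2, span[2L] + 1L)
      }
      hole[i, ] <- c(h1, h2)
    }
    nxt_hole <- c(seq_len(g)[-1L], 1L)
    op_start <- wrap_position(hole[, 2L] + 1L, L)
    op_end <- wrap_position(hole[nxt_hole, 1L] - 1L, L)
    strands <- vapply(seq_len(g), function(i) {
      ss <- vapply(feats_ord[groups[[i]]], function(f) f$strand, "")
      np <- sum(ss == "+"); nm <- sum(ss == "-")
      if (np > nm) "+" else if (nm > np) "-" else sample(c("+", "-"), 1L)
    }, "")
    has_rrna <- vapply(groups, function(ix)
      any(vapply(feats_ord[ix], function(f) f$kind == "rRNA", TRUE)), TRUE)
    units <- data.frame(start = op_start, end = op_end, strand = strands,
                        expression = resample(config$expression_levels, g,
                                              replace = TRUE) *
                          ifelse(has_rrna, 2, 1),
                        stringsAsFactors = FALSE)
    if (any(units$end < units$start))
      stop("internal error: generated operon wraps the origin")
  }

  # ---- editing sites --------------------------------------------------------
  edits <- config$edit_sites
  if (is.null(edits) && config$n_edits > 0L) {
    cand <- list()
    for (f in features) {
      if (f$kind != "CDS" || f$copy != 1L || f$name %in% untranscribed) next
      fs <- f$exons[1L, 1L]; fe <- max(f$exons[, 2L])
      inside <- any(units$start <= fs & units$end >= fe)
      if (!inside) next
      want <- if (f$strand == "+") "C" else "G"
      pos <- exon_positions(f)
      pos <- pos[chars[pos] == want]
      if (length(pos))
        cand[[length(cand) + 1L]] <-
          data.frame(position = pos, strand = f$strand, gene = f$name)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) < config$n_edits)
      stop("infeasible packing: not enough editable C positions for ",
           config$n_edits, " edit sites")
    sel <- cand[sample(nrow(cand), config$n_edits), ]
    sel <- sel[order(sel$position), ]
    edits <- data.frame(position = sel$position,
                        fraction = runif(config$n_edits,
                                         config$edit_fraction_range[1L],
                                         config$edit_fraction_range[2L]),
                        strand = sel$strand, gene = sel$gene,
                        stringsAsFactors = FALSE)
  } else if (is.null(edits)) {
    edits <- data.frame(position = integer(), fraction = numeric(),
                        strand = character(), gene = character())
  }

  # ---- splice junction truth ------------------------------------------------
  jrows <- list()
  intron_feats <- Filter(function(f) nrow(f$exons) > 1L && f$copy == 1L,
                         features)
  intron_feats <- intron_feats[order(vapply(intron_feats,
                                            function(f) f$exons[1L, 1L], 1L))]
  sf <- rep_len(config$splice_fractions,
                max(length(intron_feats), 1L))
  for (i in seq_along(intron_feats)) {
    f <- intron_feats[[i]]
    ins <- feature_introns(f)
    for (k in seq_len(nrow(ins)))
      jrows[[length(jrows) + 1L]] <- data.frame(
        gene = f$name, donor = ins[k, 1L] - 1L, acceptor = ins[k, 2L] + 1L,
        fraction = sf[i], stringsAsFactors = FALSE)
  }
  junctions <- if (length(jrows)) do.call(rbind, jrows) else
    data.frame(gene = character(), donor = integer(), acceptor = integer(),
               fraction = numeric())

  covered <- logical(L)
  for (i in seq_len(nrow(units)))
    covered[interval_positions(c(units$start[i], units$end[i]), L)] <- TRUE

  truth <- structure(
    list(structure = planted_structure, features = features, units = units,
         edits = edits, junctions = junctions,
         untranscribed = untranscribed,
         transcribed_fraction = mean(covered), config = config),
    class = "synthetic_truth")
  list(genome = genome, truth = truth)
}

#' Simulate transcriptome reads with ground-truth placements
#'
#' Samples reads uniformly from each transcription unit with depth
#' proportional to its expression level.  At a planted editing site an
#' overlapping read carries the edited base with the site's editing
#' fraction (plus-strand `T` for plus-strand sites, `A` for minus-strand
#' sites).  Reads crossing an intron skip it with the intron's splicing
#' fraction, producing an `N` gap in the CIGAR.  Each base is corrupted
#' with probability `base_error_rate`.  Placements are ground truth: no
#' aligner is involved, every read is uniquely placed (mapping quality 42).
#'
#' @param genome,truth Output of [generate_plastome()].
#' @param config The same [simulation_config()].
#' @return List with `reads` (alignment data frame compatible with
#'   [build_pileup()]), `per_read` (truth records: origin unit, strand,
#'   edits and errors applied, identity) and `junction_reads` (planted
#'   junction support counts).
#' @export
simulate_reads <- function(genome, truth, config = truth$config) {
  set.seed(config$seed + 1L)
  L <- genome$length
  rl <- config$read_length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  units <- truth$units
  if (!nrow(units) || config$target_depth == 0)
    return(list(reads = empty_reads(), per_read = data.frame(),
                junction_reads = data.frame(donor = integer(),
                                            acceptor = integer(),
                                            support = integer())))
  spans <- units$end - units$start + 1L
  scale <- config$target_depth * sum(spans) /
    sum(units$expression * spans)
  n_per_unit <- pmax(0L, round(units$expression * scale * spans / rl))

  # introns (with splicing fractions) per unit
  unit_introns <- lapply(seq_len(nrow(units)), function(i) {
    j <- truth$junctions
    if (!nrow(j)) return(j)
    j[j$donor >= units$start[i] & j$acceptor <= units$end[i], , drop = FALSE]
  })

  edits <- truth$edits
  bases <- c("A", "C", "G", "T")
  N <- sum(n_per_unit)
  v_pos <- integer(N); v_flag <- integer(N); v_nm <- integer(N)
  v_strand <- character(N); v_cigar <- character(N)
  v_seq <- character(N); v_qual <- character(N)
  v_unit <- integer(N); v_end <- integer(N); v_nedit <- integer(N)
  v_nerr <- integer(N); v_ngap <- integer(N); v_len <- integer(N)
  jcount <- new.env(parent = emptyenv())
  ridx <- 0L
  for (ui in seq_len(nrow(units))) {
    n <- n_per_unit[ui]
    if (n == 0L) next
    u1 <- units$start[ui]; u2 <- units$end[ui]
    introns <- unit_introns[[ui]]
    # fragment starts may overhang the unit 5' end; reads are clipped to the
    # unit so coverage is flat across it (transcript ends are hard edges)
    starts <- resample((u1 - rl + 1L):u2, n, replace = TRUE)
    for (s00 in starts) {
      ridx <- ridx + 1L
      s0 <- max(s00, u1)
      rl_eff <- rl - (s0 - s00)
      # per-molecule splicing decisions
      spliced <- if (nrow(introns))
        introns[runif(nrow(introns)) < introns$fraction &
                  !(s0 > introns$donor & s0 < introns$acceptor), ,
                drop = FALSE]
      else introns
      pos <- s0; remaining <- rl_eff
      blocks <- list(); gaps <- list(); consumed <- integer()
      while (remaining > 0L && pos <= u2) {
        nxt <- if (nrow(spliced)) {
          cand <- spliced[spliced$donor >= pos, , drop = FALSE]
          if (nrow(cand)) cand[which.min(cand$donor), ] else NULL
        } else NULL
        seg_end <- min(u2, pos + remaining - 1L,
                       if (!is.null(nxt)) nxt$donor else u2)
        if (seg_end >= pos) {
          blocks[[length(blocks) + 1L]] <- c(pos, seg_end)
          consumed <- c(consumed, pos:seg_end)
          remaining <- remaining - (seg_end - pos + 1L)
        }
        if (remaining > 0L && !is.null(nxt) && seg_end == nxt$donor) {
          gaps[[length(gaps) + 1L]] <-
            c(nxt$donor, nxt$acceptor, nxt$acceptor - nxt$donor - 1L)
          pos <- nxt$acceptor
        } else break
      }
      refbase <- chars[consumed]
      readbase <- refbase
      n_edit <- 0L
      if (nrow(edits)) {
        hit <- match(consumed, edits$position)
        hi <- which(!is.na(hit))
        for (h in hi) {
          e <- edits[hit[h], ]
          if (runif(1L) < e$fraction) {
            readbase[h] <- if (e$strand == "+") "T" else "A"
            n_edit <- n_edit + 1L
          }
        }
      }
      err <- which(runif(length(readbase)) < config$base_error_rate)
      for (h in err)
        readbase[h] <- sample(setdiff(bases, readbase[h]), 1L)
      nm <- sum(readbase != refbase)
      cig <- character()
      for (b in seq_along(blocks)) {
        cig <- c(cig, paste0(blocks[[b]][2L] - blocks[[b]][1L] + 1L, "M"))
        if (b <= length(gaps)) cig <- c(cig, paste0(gaps[[b]][3L], "N"))
      }
      strand <- if (config$unstranded) sample(c("+", "-"), 1L)
        else if (units$strand[ui] %in% c("+", "-")) units$strand[ui] else "+"
      qual <- paste(rawToChar(as.raw(33L + sample(32:40, length(readbase),
                                                  replace = TRUE))),
                    collapse = "")
      v_pos[ridx] <- s0
      v_flag[ridx] <- if (strand == "-") 16L else 0L
      v_strand[ridx] <- strand
      v_cigar[ridx] <- paste(cig, collapse = "")
      v_seq[ridx] <- paste(readbase, collapse = "")
      v_qual[ridx] <- qual
      v_nm[ridx] <- nm
      v_unit[ridx] <- ui
      v_end[ridx] <- consumed[length(consumed)]
      v_nedit[ridx] <- n_edit
      v_nerr[ridx] <- length(err)
      v_ngap[ridx] <- length(gaps)
      v_len[ridx] <- length(readbase)
      for (gp in gaps) {
        key <- paste(gp[1L], gp[2L])
        jcount[[key]] <- (if (is.null(jcount[[key]])) 0L
                          else jcount[[key]]) + 1L
      }
    }
  }
  qnames <- sprintf("sim_%06d", seq_len(ridx))
  idx <- seq_len(ridx)
  reads <- data.frame(qname = qnames, flag = v_flag[idx], pos = v_pos[idx],
                      mapq = 42L, strand = v_strand[idx],
                      cigar = v_cigar[idx], seq = v_seq[idx],
                      qual = v_qual[idx], nm = v_nm[idx],
                      stringsAsFactors = FALSE)
  per_read <- data.frame(qname = qnames, unit = v_unit[idx],
                         start = v_pos[idx], end = v_end[idx],
                         strand = v_strand[idx], n_edits = v_nedit[idx],
                         n_errors = v_nerr[idx], n_gaps = v_ngap[idx],
                         identity = 100 * (1 - v_nm[idx] / v_len[idx]),
                         stringsAsFactors = FALSE)
  keys <- ls(jcount)
  jr <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    data.frame(donor = as.integer(parts[, 1L]),
               acceptor = as.integer(parts[, 2L]),
               support = vapply(keys, function(k) jcount[[k]], 1L))
  } else data.frame(donor = integer(), acceptor = integer(),
                    support = integer())
  rownames(jr) <- NULL
  list(reads = reads, per_read = per_read, junction_reads = jr)
}

empty_reads <- function()
  data.frame(qname = character(), flag = integer(), pos = integer(),
             mapq = integer(), strand = character(), cigar = character(),
             seq = character(), qual = character(), nm = integer(),
             stringsAsFactors = FALSE)

#' Write simulated reads as SAM
#'
#' @param reads Read data frame from [simulate_reads()].
#' @param genome The [annotated_plastome()] the reads are placed on.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length))
  reads <- reads[order(reads$pos), , drop = FALSE]
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  reads$qname, reads$flag, genome$id, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual, reads$nm)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Reads reported on the minus strand are reverse-complemented back to
#' sequencing orientation.
#'
#' @param reads Read data frame from [simulate_reads()].
#' @param path Output path (`.fastq`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- reads$seq; quals <- reads$qual
  neg <- reads$strand == "-"
  if (any(neg)) {
    seqs[neg] <- vapply(seqs[neg], revcomp, "")
    quals[neg] <- vapply(quals[neg], function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1L]]), collapse = ""), "")
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$qname)
  out[seq(2L, length(out), 4L)] <- seqs
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- quals
  writeLines(out, path)
  invisible(path)
}
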