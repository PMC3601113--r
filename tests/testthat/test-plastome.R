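test_that("gene_feature validates exon geometry", {
  expect_error(gene_feature("x", "CDS", "+", rbind(c(10, 5))), "end before")
  expect_error(gene_feature("x", "CDS", "+", rbind(c(1, 10), c(5, 20))),
               "overlapping")
  f <- gene_feature("x", "CDS", "-", rbind(c(50, 60), c(10, 20)))
  expect_equal(f$exons[, 1], c(10, 50))  # exons sorted by plus coordinate
  expect_equal(nrow(feature_introns(f)), 1L)
  expect_equal(unname(feature_introns(f)[1, ]), c(21, 49))
})

test_that("annotated_plastome rejects inconsistent input", {
  expect_error(annotated_plastome("x", "ACGTQ"), "may only contain")
  expect_error(annotated_plastome("x", "ACGT", list(
    gene_feature("g", "CDS", "+", c(2, 10)))), "outside")
  expect_error(annotated_plastome("x", strrep("ACGT", 10), list(
    gene_feature("g", "CDS", "+", c(1, 6)),
    gene_feature("g", "CDS", "+", c(11, 16)))), "unique")
})

test_that("classify_position assigns exon, intron, spacer and priority", {
  g <- tiny_genome()
  expect_equal(classify_position(g, 110)$label, "CDS")
  expect_equal(classify_position(g, 110)$name, "psbK")
  expect_equal(classify_position(g, 450)$label, "intron")
  expect_equal(classify_position(g, 450)$name, "rps16")
  igs <- classify_position(g, 150)
  expect_equal(igs$label, "IGS")
  expect_equal(igs$name, "psbK - psbI")
  expect_equal(classify_position(g, 620)$label, "tRNA")
  expect_equal(classify_position(g, 710)$label, "pseudogene")
  # CDS wins over tRNA at an overlap
  g2 <- annotated_plastome("o", strrep("ACGT", 30), list(
    gene_feature("a", "CDS", "+", c(10, 30)),
    gene_feature("b", "tRNA", "+", c(20, 60))))
  expect_equal(classify_position(g2, 25)$label, "CDS")
})

test_that("classify_position partitions every position exactly once", {
  g <- tiny_genome()
  labs <- vapply(seq_len(g$length),
                 function(p) classify_position(g, p)$label, "")
  expect_true(all(labs %in% c("CDS", "tRNA", "rRNA", "pseudogene",
                              "intron", "IGS")))
  # exon positions of highest-priority features are labelled by kind
  expect_equal(sum(labs == "intron"), 92)   # planted rps16 intron 409..500
})

test_that("codon_context reads codons in transcript orientation", {
  g <- tiny_genome()
  psbK <- g$features[[1]]
  expect_equal(codon_context(g, psbK, 101),
               list(codon = "ATG", offset = 1L, transcript_pos = 1L))
  # minus-strand gene: plus-strand G at 315 is the C of codon CAT
  matK <- g$features[[3]]
  ctx <- codon_context(g, matK, 315)
  expect_equal(ctx$codon, "CAT")
  expect_equal(ctx$offset, 1L)
  expect_equal(substr(g$sequence, 315, 315), "G")
  # pseudogenes carry no frame
  expect_error(codon_context(g, g$features[[6]], 710), "no codon frame")
})

test_that("codon_context splices across exon junctions", {
  g <- tiny_genome()
  rps16 <- g$features[[4]]
  ctx <- codon_context(g, rps16, 408)       # last base of exon 1
  expect_equal(ctx$codon, "TCA")
  expect_equal(ctx$offset, 2L)
  # oracle: rebuild the full mRNA naively and index into it
  mrna <- paste0(substr(g$sequence, 401, 408), substr(g$sequence, 501, 507))
  k <- ctx$transcript_pos
  expect_equal(ctx$codon, substr(mrna, 3 * ((k - 1) %/% 3) + 1,
                                 3 * ((k - 1) %/% 3) + 3))
})

test_that("codon_context agrees with naive mRNA rebuild on simulated genomes", {
  gp <- generate_plastome(simulation_config(seed = 3, genome_length = 12000,
                                            ir_length = 1500))
  g <- gp$genome
  cds <- Filter(function(f) f$kind == "CDS", g$features)
  set.seed(5)
  n_checked <- 0
  for (f in cds) {
    ex <- f$exons
    pos_pool <- unlist(lapply(seq_len(nrow(ex)), function(i)
      ex[i, 1]:ex[i, 2]))
    for (p in sample(pos_pool, min(25, length(pos_pool)))) {
      ctx <- codon_context(g, f, p)
      parts <- vapply(seq_len(nrow(ex)), function(i)
        substr(g$sequence, ex[i, 1], ex[i, 2]), "")
      mrna <- paste(parts, collapse = "")
      if (f$strand == "-") mrna <- rc(mrna)
      k <- ctx$transcript_pos
      expect_equal(ctx$codon, substr(mrna, 3 * ((k - 1) %/% 3) + 1,
                                     3 * ((k - 1) %/% 3) + 3))
      expect_equal(substr(ctx$codon, ctx$offset, ctx$offset),
                   substr(mrna, k, k))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("FASTA+GFF3 round-trip preserves the feature set", {
  gp <- generate_plastome(simulation_config(seed = 9))
  g <- gp$genome
  fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
  write_plastome(g, fa, gf)
  g2 <- read_plastome(fa, "fasta+gff3", gff3 = gf)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$length, g$length)
  expect_equal(length(g2$features), length(g$features))
  key <- function(f) paste(f$name, f$copy)
  f2 <- g2$features[order(vapply(g2$features, key, ""))]
  f1 <- g$features[order(vapply(g$features, key, ""))]
  for (i in seq_along(f1)) {
    expect_equal(f2[[i]]$name, f1[[i]]$name)
    expect_equal(f2[[i]]$kind, f1[[i]]$kind)
    expect_equal(f2[[i]]$strand, f1[[i]]$strand)
    expect_equal(unname(f2[[i]]$exons), unname(f1[[i]]$exons))
    expect_equal(f2[[i]]$copy, f1[[i]]$copy)
  }
})

test_that("minimal GenBank records parse with locations decomposed", {
  gb <- tempfile(fileext = ".gb")
  seqline <- paste(rep("acgtacgtac", 12), collapse = "")  # 120 bp
  writeLines(c(
    "LOCUS       TESTREC                  120 bp    DNA     circular PLN",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             11..100",
    '                     /gene="psbA"',
    "     tRNA            complement(join(20..40,60..70))",
    '                     /gene="trnX"',
    "     CDS             30..50",
    "                     /pseudo",
    '                     /gene="ycf15"',
    "ORIGIN",
    paste("        1", seqline),
    "//"), gb)
  g <- read_plastome(gb, "genbank")
  expect_equal(g$id, "TESTREC")
  expect_equal(g$length, 120L)
  expect_equal(length(g$features), 3L)
  cds <- g$features[[1]]
  expect_equal(cds$name, "psbA")
  expect_equal(unname(cds$exons), matrix(c(11L, 100L), 1))
  trn <- g$features[[2]]
  expect_equal(trn$strand, "-")
  expect_equal(unname(trn$exons), cbind(c(20L, 60L), c(40L, 70L)))
  expect_equal(g$features[[3]]$kind, "pseudogene")
})
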