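test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 30)
  a <- generate_plastome(cfg)
  b <- generate_plastome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth$units, b$truth$units)
  expect_identical(a$truth$edits, b$truth$edits)
  fa1 <- tempfile(); gf1 <- tempfile(); fa2 <- tempfile(); gf2 <- tempfile()
  write_plastome(a$genome, fa1, gf1)
  write_plastome(b$genome, fa2, gf2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gf1), readLines(gf2))
  ra <- simulate_reads(a$genome, a$truth, cfg)
  rb <- simulate_reads(b$genome, b$truth, cfg)
  expect_identical(ra$reads, rb$reads)
})

test_that("ir_length 0 produces a repeat-free single-copy genome", {
  cfg <- simulation_config(seed = 31, ir_length = 0, genome_length = 9000,
                           n_genes = 10)
  gp <- generate_plastome(cfg)
  expect_null(gp$truth$structure)
  expect_null(detect_quadripartite(gp$genome, 1000))
  expect_true(all(vapply(gp$genome$features, function(f) f$copy, 1L) == 1L))
})

test_that("detector output equals planted structure across random configs", {
  set.seed(77)
  for (k in 1:6) {
    cfg <- simulation_config(seed = 100 + k,
                             genome_length = sample(9000:14000, 1),
                             ir_length = sample(1200:2200, 1),
                             n_genes = 12, intron_genes = 1,
                             pseudogenes = 1)
    gp <- generate_plastome(cfg)
    qs <- detect_quadripartite(gp$genome)
    expect_identical(as.data.frame(qs), as.data.frame(gp$truth$structure))
  }
})

test_that("pseudogenes carry an internal stop codon", {
  gp <- generate_plastome(simulation_config(seed = 33))
  ps <- Filter(function(f) f$kind == "pseudogene", gp$genome$features)
  expect_gt(length(ps), 0L)
  for (f in ps) {
    tx <- Biostrings::DNAString(plastoscope:::feature_transcript(gp$genome, f))
    aa <- as.character(Biostrings::translate(tx))
    expect_true(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("error-free unedited reads produce a mismatch-free pileup", {
  cfg <- simulation_config(seed = 34, base_error_rate = 0, n_edits = 0,
                           splice_fractions = 0, target_depth = 10)
  gp <- generate_plastome(cfg)
  sr <- simulate_reads(gp$genome, gp$truth, cfg)
  pu <- build_pileup(sr$reads, gp$genome)
  ref_count <- vapply(seq_len(nrow(pu)), function(i) {
    b <- pu$ref[i]
    if (b == "T") b <- "U"
    pu[[b]][i]
  }, 1L)
  expect_equal(ref_count, pu$depth)
  expect_true(all(sr$reads$nm == 0L))
})

test_that("a fully edited site reaches support equal to depth", {
  base_cfg <- simulation_config(seed = 35, base_error_rate = 0,
                                target_depth = 50)
  gp0 <- generate_plastome(base_cfg)
  site <- gp0$truth$edits[1, ]
  cfg <- simulation_config(seed = 35, base_error_rate = 0,
                           target_depth = 50,
                           edit_sites = data.frame(position = site$position,
                                                   fraction = 1,
                                                   strand = site$strand))
  gp <- generate_plastome(cfg)
  sr <- simulate_reads(gp$genome, gp$truth, cfg)
  pu <- build_pileup(sr$reads, gp$genome)
  row <- pu[pu$pos == site$position, ]
  sup <- if (site$strand == "+") row$U else row$A
  expect_gt(row$depth, 0L)
  expect_equal(sup, row$depth)
})

test_that("observed editing fraction sits in the binomial interval", {
  base_cfg <- simulation_config(seed = 36, target_depth = 200)
  gp0 <- generate_plastome(base_cfg)
  site <- gp0$truth$edits[1, ]
  cfg <- simulation_config(seed = 36, target_depth = 200,
                           edit_sites = data.frame(position = site$position,
                                                   fraction = 0.6,
                                                   strand = site$strand))
  gp <- generate_plastome(cfg)
  sr <- simulate_reads(gp$genome, gp$truth, cfg)
  pu <- build_pileup(sr$reads, gp$genome)
  row <- pu[pu$pos == site$position, ]
  sup <- if (site$strand == "+") row$U else row$A
  # 99.9% binomial interval around 0.6 at the observed depth
  ci <- qbinom(c(0.0005, 0.9995), row$depth, 0.6) / row$depth
  expect_gte(sup / row$depth, ci[1])
  expect_lte(sup / row$depth, ci[2])
})

test_that("unstranded libraries emit reads on both strands", {
  cfg <- simulation_config(seed = 37, target_depth = 10)
  gp <- generate_plastome(cfg)
  sr <- simulate_reads(gp$genome, gp$truth, cfg)
  tab <- table(sr$reads$strand)
  expect_true(all(c("+", "-") %in% names(tab)))
  expect_gt(min(tab) / sum(tab), 0.4)
  # FASTQ export reverse-complements minus-strand reads
  fq <- tempfile(fileext = ".fastq")
  write_fastq(utils::head(sr$reads, 4), fq)
  lines <- readLines(fq)
  expect_length(lines, 16L)
  expect_true(all(grepl("^@sim_", lines[seq(1, 16, 4)])))
})

test_that("truth bookkeeping matches the emitted reads", {
  cfg <- simulation_config(seed = 38, target_depth = 15)
  gp <- generate_plastome(cfg)
  sr <- simulate_reads(gp$genome, gp$truth, cfg)
  expect_equal(nrow(sr$per_read), nrow(sr$reads))
  # per-read identity consistent with NM and read length
  expect_equal(sr$per_read$identity,
               100 * (1 - sr$reads$nm / nchar(sr$reads$seq)))
  # junction truth support equals the gapped reads emitted
  jx <- extract_junctions(sr$reads)
  if (nrow(sr$junction_reads)) {
    m <- merge(jx, sr$junction_reads, by = c("donor", "acceptor"))
    expect_equal(m$support.x, m$support.y)
  }
  expect_equal(sum(sr$per_read$n_gaps), sum(sr$junction_reads$support))
})

test_that("transcribed fraction of the truth tracks the configured target", {
  for (sd in c(39, 40)) {
    cfg <- simulation_config(seed = sd, transcribed_fraction = 0.9)
    gp <- generate_plastome(cfg)
    expect_lt(abs(gp$truth$transcribed_fraction - 0.9), 0.03)
  }
})
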