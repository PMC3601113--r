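col <- function(ref, A = 0, C = 0, G = 0, U = 0)
  list(ref = ref, A = A, C = C, G = G, U = U)

test_that("edited_support follows the strand orientation rules", {
  # minus-strand gene, plus-strand G: support is the A count
  expect_equal(edited_support(col("G", A = 21, G = 1), "-")$support, 21L)
  # plus-strand gene, plus-strand C: support is the U count
  expect_equal(edited_support(col("C", C = 28, U = 29), "+")$support, 29L)
  expect_equal(edited_support(col("G"), "-")$support, 0L)
  # wrong reference base for the strand: no candidate
  expect_equal(edited_support(col("A", A = 50), "+")$support, 0L)
  expect_equal(edited_support(col("C", U = 50), "-")$support, 0L)
  # lenient mode takes the larger of A/U for minus-strand features
  trnL <- col("G", G = 16, U = 60)
  expect_equal(edited_support(trnL, "-", "strict")$support, 0L)
  expect_equal(edited_support(trnL, "-", "lenient")$support, 60L)
  expect_equal(edited_support(trnL, "-", "lenient")$edited_base_plus, "U")
})

test_that("call thresholds are enforced exactly at the boundaries", {
  p <- function(A = 0, C = 0, G = 0, U = 0)
    data.frame(pos = 1L, ref = "C", A = A, C = C, G = G, U = U)
  prm <- editing_params()
  # depth 9, support 9: fails depth >= 10
  expect_equal(nrow(call_editing_sites(p(U = 9), strand = "+",
                                       params = prm)), 0L)
  # depth 10, support 5, frequency 0.5: boundary accepted
  got <- call_editing_sites(p(C = 5, U = 5), strand = "+", params = prm)
  expect_equal(nrow(got), 1L)
  expect_equal(got$frequency, 0.5)
  expect_equal(got$completeness, "partial")
  # support 4 fails min_support even at high frequency
  expect_equal(nrow(call_editing_sites(p(C = 1, U = 4), strand = "+",
                                       params = prm)), 0L)
  # frequency below 0.5 fails
  expect_equal(nrow(call_editing_sites(p(C = 7, U = 6), strand = "+",
                                       params = prm)), 0L)
  # depth above max_depth pruned
  expect_equal(nrow(call_editing_sites(p(U = 3000), strand = "+",
                                       params = prm)), 0L)
  # support == depth is a complete site
  got2 <- call_editing_sites(p(U = 12), strand = "+", params = prm)
  expect_equal(got2$completeness, "complete")
})

test_that("every accepted call satisfies all four predicates post hoc", {
  set.seed(31)
  pu <- data.frame(pos = 1:300,
                   ref = sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   A = rpois(300, 8), C = rpois(300, 8),
                   G = rpois(300, 8), U = rpois(300, 8))
  pu$depth <- pu$A + pu$C + pu$G + pu$U
  strands <- sample(c("+", "-"), 300, replace = TRUE)
  prm <- editing_params(min_depth = 20, min_support = 8,
                        min_frequency = 0.25, max_depth = 45)
  calls <- call_editing_sites(pu, strand = strands, params = prm)
  expect_true(all(calls$depth >= 20 & calls$depth <= 45))
  expect_true(all(calls$support >= 8))
  expect_true(all(calls$support / calls$depth >= 0.25))
  expect_true(all(diff(calls$pos) > 0))   # sorted by position
})

test_that("raising any threshold never increases the number of calls", {
  set.seed(32)
  pu <- data.frame(pos = 1:400,
                   ref = sample(c("C", "G"), 400, replace = TRUE),
                   A = rpois(400, 6), C = rpois(400, 6),
                   G = rpois(400, 6), U = rpois(400, 6))
  pu$depth <- pu$A + pu$C + pu$G + pu$U
  strands <- sample(c("+", "-"), 400, replace = TRUE)
  n_at <- function(...) nrow(call_editing_sites(
    pu, strand = strands, params = editing_params(...)))
  base <- n_at(min_depth = 8, min_support = 3, min_frequency = 0.2)
  expect_lte(n_at(min_depth = 12, min_support = 3, min_frequency = 0.2), base)
  expect_lte(n_at(min_depth = 8, min_support = 6, min_frequency = 0.2), base)
  expect_lte(n_at(min_depth = 8, min_support = 3, min_frequency = 0.4), base)
  expect_lte(n_at(min_depth = 8, min_support = 3, min_frequency = 0.2,
                  max_depth = 30), base)
})

test_that("strict-mode calls are a subset of lenient-mode calls", {
  set.seed(33)
  pu <- data.frame(pos = 1:400,
                   ref = sample(c("C", "G"), 400, replace = TRUE),
                   A = rpois(400, 7), C = rpois(400, 3),
                   G = rpois(400, 3), U = rpois(400, 7))
  pu$depth <- pu$A + pu$C + pu$G + pu$U
  strands <- sample(c("+", "-"), 400, replace = TRUE)
  strict <- call_editing_sites(pu, strand = strands,
                               params = editing_params(
                                 min_depth = 10, orientation_mode = "strict"))
  lenient <- call_editing_sites(pu, strand = strands,
                                params = editing_params(
                                  min_depth = 10,
                                  orientation_mode = "lenient"))
  expect_true(all(strict$pos %in% lenient$pos))
})

test_that("codon changes are annotated in transcript orientation", {
  g <- tiny_genome()
  pu <- data.frame(pos = c(105L, 315L, 118L),
                   ref = c("C", "G", "C"),
                   A = c(0L, 30L, 0L), C = c(10L, 0L, 8L),
                   G = c(0L, 2L, 0L), U = c(22L, 0L, 14L))
  pu$depth <- pu$A + pu$C + pu$G + pu$U
  calls <- call_editing_sites(pu, g)
  expect_equal(nrow(calls), 3L)
  # plus-strand TCA -> TTA inside psbK
  expect_equal(calls$codon_change[calls$pos == 105], "TCA -> TTA")
  expect_equal(calls$aa_change[calls$pos == 105], "S -> L")
  # minus-strand gene: plus-strand G is an edited C in codon CAT
  expect_equal(calls$gene[calls$pos == 315], "matK")
  expect_equal(calls$codon_change[calls$pos == 315], "CAT -> TAT")
  expect_equal(calls$aa_change[calls$pos == 315], "H -> Y")
  # codon offset 3 can be synonymous
  expect_equal(calls$codon_change[calls$pos == 118], "TTC -> TTT")
  expect_equal(calls$aa_change[calls$pos == 118], "F -> F")
})

test_that("noncoding calls keep empty codon fields", {
  g <- tiny_genome()
  pu <- data.frame(pos = 150L, ref = "C", A = 0L, C = 10L, G = 0L, U = 15L,
                   depth = 25L)
  calls <- call_editing_sites(pu, g)
  expect_equal(calls$region, "IGS")
  expect_equal(calls$gene, "psbK - psbI")
  expect_true(is.na(calls$codon_change))
})

test_that("summaries partition calls into coding and noncoding", {
  expect_equal(summarize_calls(call_editing_sites(
    data.frame(pos = integer(), ref = character(), A = integer(),
               C = integer(), G = integer(), U = integer())))$total, 0L)
  sites <- camellia_editing_sites()
  calls <- call_editing_sites(sites_as_pileup(sites),
                              strand = sites$strand, region = sites$region,
                              gene = sites$gene)
  s <- summarize_calls(calls)
  expect_equal(s$total, 31L)
  expect_equal(s$coding, 26L)
  expect_equal(s$noncoding, 5L)
})

test_that("planted coding and intron edits are summarized by region", {
  cfg0 <- simulation_config(seed = 17, intron_genes = 2)
  gp0 <- generate_plastome(cfg0)
  # choose 3 intron positions and 8 coding C sites from the generated truth
  intron_feats <- Filter(function(f) nrow(f$exons) > 1 && f$copy == 1,
                         gp0$genome$features)
  chars <- strsplit(gp0$genome$sequence, "")[[1]]
  ipos <- unlist(lapply(intron_feats, function(f) {
    ins <- feature_introns(f)
    want <- if (f$strand == "+") "C" else "G"
    pp <- ins[1, 1]:ins[1, 2]
    pp[chars[pp] == want][1:2]
  }))[1:3]
  istrand <- unlist(lapply(intron_feats, function(f) rep(f$strand, 2)))[1:3]
  cpos <- gp0$truth$edits$position[1:8]
  cstrand <- gp0$truth$edits$strand[1:8]
  cfg <- simulation_config(seed = 17, intron_genes = 2, target_depth = 50,
                           edit_sites = data.frame(
                             position = c(cpos, ipos),
                             fraction = 0.9,
                             strand = c(cstrand, istrand)),
                           splice_fractions = 0)
  gp <- generate_plastome(cfg)
  sr <- simulate_reads(gp$genome, gp$truth, cfg)
  pu <- build_pileup(sr$reads, gp$genome)
  calls <- call_editing_sites(pu, gp$genome)
  s <- summarize_calls(calls)
  expect_equal(s$coding, 8L)
  expect_equal(s$noncoding, 3L)
  expect_equal(unname(s$per_region["intron"]), 3L)
})
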