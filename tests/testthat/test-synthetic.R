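test_that("regeneration from the same seed is byte-identical on disk", {
  g1 <- generate_caspase16_like_locus(101)
  g2 <- generate_caspase16_like_locus(101)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_fasta(g1$locus, f1); write_fasta(g2$locus, f2)
  write_gff3(g1$model, f3); write_gff3(g2$model, f4)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(f3), readLines(f4))
  g3 <- generate_caspase16_like_locus(102)
  expect_false(identical(g1$locus$residues, g3$locus$residues))
})

test_that("generated loci satisfy their own manifest invariants", {
  for (s in c(1, 77, 3141)) {
    g <- generate_caspase16_like_locus(s)
    cds <- build_transcript(g$model, g$locus, coding_only = TRUE)$seq
    tr <- translate_cds(cds)
    pr <- tr$peptide$residues
    expect_equal(nchar(pr), 470L)
    expect_true(tr$stop_found)
    expect_equal(tr$stop_codon_index + 1L, 471L) # terminal stop only
    expect_equal(substr(pr, 290, 290), "H")
    expect_equal(substr(pr, 332, 332), "C")
    expect_equal(which(strsplit(pr, "")[[1]] == "M"), c(1L, 288L))
    # dyad absent from the prodomain copy
    expect_false(substr(pr, 93, 93) == "H" && substr(pr, 135, 135) == "C")
    expect_identical(pr, g$manifest$derived_protein$residues)
  }
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(generate_caspase16_like_locus(1, copy_divergence = 0.9), "0.6")
  expect_error(diverge_orthologs(nuc_seq("x", "ACGT"), p_sub = 0.5), "0.3")
  expect_error(diverge_orthologs(nuc_seq("x", "ACGT"), p_sub = 0,
                                 p_indel = 0.2), "0.05")
})

test_that("substitution-only divergence matches the binomial expectation", {
  set.seed(61)
  ref <- nuc_seq("r", random_nt(10000))
  d0 <- diverge_orthologs(ref, p_sub = 0, p_indel = 0, seed = 1)
  expect_identical(d0$seq$residues, ref$residues)
  expect_equal(d0$expected_identity, 100)
  d <- diverge_orthologs(ref, p_sub = 0.02, p_indel = 0, seed = 2)
  ident <- percent_identity(global_align(ref, d$seq,
                                         alignment_params("nucleotide")))
  sd3 <- 3 * 100 * sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(ident - 98), sd3)
})

test_that("injected indels are recovered at exact left-aligned positions", {
  set.seed(62)
  ref <- nuc_seq("r", random_nt(6000))
  d <- diverge_orthologs(ref, p_sub = 0.02, p_indel = 0.002, seed = 3)
  expect_gt(nrow(d$events), 3)
  called <- call_indels(global_align(ref, d$seq,
                                     alignment_params("nucleotide")),
                        reference = "a")
  key <- function(e) paste(e$kind, e$ref_pos, e$length)
  expect_gte(mean(key(d$events) %in% key(called)), 0.95)
})

test_that("protected intervals are never mutated", {
  set.seed(63)
  ref <- nuc_seq("r", random_nt(2000))
  prot <- data.frame(start = c(100, 900), end = c(400, 1200))
  d <- diverge_orthologs(ref, p_sub = 0.2, p_indel = 0, seed = 4,
                         protect = prot)
  expect_identical(substr(d$seq$residues, 100, 400),
                   substr(ref$residues, 100, 400))
  expect_identical(substr(d$seq$residues, 900, 1200),
                   substr(ref$residues, 900, 1200))
  di <- diverge_orthologs(ref, p_sub = 0, p_indel = 0.02, seed = 5,
                          protect = prot)
  expect_false(any(di$events$ref_pos >= 95 & di$events$ref_pos <= 400))
})

test_that("lesion injection shifts downstream coordinates consistently", {
  g <- generate_caspase16_like_locus(71)
  inj <- inject_lesions(g$locus, g$model,
                        data.frame(type = "deletion", exon = 3,
                                   position = 156, length = 1))
  expect_equal(nchar(inj$locus$residues), nchar(g$locus$residues) - 1L)
  expect_equal(coding_lengths(inj$model)[[3]],
               coding_lengths(g$model)[[3]] - 1L)
  expect_equal(inj$model$exons$genomic_start[4],
               g$model$exons$genomic_start[4] - 1L)
  # downstream exon sequences are untouched
  e7 <- with(inj$model$exons, substr(inj$locus$residues, genomic_start[7],
                                     genomic_end[7]))
  e7_ref <- with(g$model$exons, substr(g$locus$residues, genomic_start[7],
                                       genomic_end[7]))
  expect_identical(e7, e7_ref)
  expect_error(inject_lesions(g$locus, g$model,
                              data.frame(type = "deletion", exon = 3,
                                         position = 279, length = 5)),
               "last 10|outside")
})

test_that("the lesion grid manifests carry the right expected status", {
  want <- c("human-casp16p" = "pseudogene", "inframe-deletion" = "intact",
            "dyad-knockout" = "pseudogene", "compensated-indels" = "intact")
  for (s in names(want)) {
    sc <- simulate_pseudogene_scenario(81, s)
    expect_equal(sc$manifest$expected_status, unname(want[[s]]),
                 label = s)
  }
})

test_that("the cassette arithmetic holds: 6 triplets to the stop, 105 residues", {
  sc <- simulate_pseudogene_scenario(82, "human-casp16p")
  cds <- build_transcript(sc$query$model, sc$query$locus,
                          coding_only = TRUE)$seq
  aa <- oracle_translate(cds$residues)
  expect_equal(which(aa == "*")[1], 106L)
  expect_equal(sum(aa[1:105] != "*"), 105L)
})
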