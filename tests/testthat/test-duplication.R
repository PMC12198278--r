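test_that("per-exon peptides tile the protein, junction codons to the 2-of-3 exon", {
  # two exons of 9 + 9 coding nt -> 3 + 3 residues
  tg <- toy_gene(c("ATGGCCCAC", "TGCAAAGAG"))
  prot <- translate_cds(oracle_isoform_cds(tg$model, tg$locus, 1:2),
                        to_first_stop = FALSE)$peptide
  segs <- split_by_exon(prot, tg$model)
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(s) nchar(s$peptide$residues), integer(1)),
               c(3L, 3L))
  # single-exon CDS -> one segment covering everything
  tg1 <- toy_gene("ATGGCCCACTGC")
  p1 <- translate_cds("ATGGCCCACTGC", to_first_stop = FALSE)$peptide
  expect_equal(split_by_exon(p1, tg1$model)[[1]]$ref_residue_span, c(1L, 4L))
  # random models: concatenation reconstitutes the translation
  set.seed(51)
  for (i in 1:25) {
    g <- random_coding_gene(5000 + i, n_exons = sample(2:6, 1))
    cds <- oracle_isoform_cds(g$model, g$locus, g$model$exons$index)
    prot <- translate_cds(cds)$peptide
    segs <- split_by_exon(prot, g$model)
    expect_equal(paste(vapply(segs, function(s) s$peptide$residues,
                              character(1)), collapse = ""), prot$residues)
  }
  expect_error(split_by_exon(pep_seq("p", "MA"), g$model), "inconsistent")
})

test_that("an exact tandem repeat is found at 100% identity with exact spans", {
  unit <- "WHENINDISGRACEWITHFRTNESEYES"
  p <- pep_seq("rep", paste0(unit, unit))
  hits <- self_compare(p, min_len = 10, n_permutations = 100, seed = 4)
  expect_gte(length(hits), 1)
  h <- hits[[1]]
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_span, c(1L, nchar(unit)))
  expect_equal(h$subject_span, c(nchar(unit) + 1L, 2L * nchar(unit)))
  expect_lt(h$empirical_p, 0.05)
  # a duplication split across two exons maps exon 1 to exon 2
  cds <- c("ATGGCCTGCAAGGAGCTGTTT", "ATGGCCTGCAAGGAGCTGTTT")
  tg <- toy_gene(cds)
  prot <- translate_cds(paste(cds, collapse = ""), to_first_stop = FALSE)$peptide
  hh <- self_compare(prot, min_len = 5, n_permutations = 0)
  mm <- map_exon_homology(hh, tg$model, prot)
  expect_true(all(mm$query_exon == 1 & mm$subject_exon == 2))
})

test_that("too-short proteins warn and random proteins rarely reach p <= 0.05", {
  expect_warning(out <- self_compare(pep_seq("s", "MKL"), min_len = 10,
                                     n_permutations = 0), "short")
  expect_length(out, 0)
  set.seed(52)
  ps <- replicate(30, {
    p <- pep_seq("null", random_aa(80))
    h <- self_compare(p, min_len = 10, n_permutations = 60, seed = 7)
    if (length(h)) h[[1]]$empirical_p else 1
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("self_compare is deterministic under seed and spans never overlap", {
  g <- generate_caspase16_like_locus(31)
  pr <- g$manifest$derived_protein
  h1 <- self_compare(pr, n_permutations = 50, seed = 10)
  h2 <- self_compare(pr, n_permutations = 50, seed = 10)
  expect_identical(h1, h2)
  for (h in h1) expect_lt(h$query_span[2], h$subject_span[1])
})

test_that("the generated duplication is recovered and mapped to the plan", {
  ok <- 0
  for (s in 1:10) {
    g <- generate_caspase16_like_locus(600 + s, copy_divergence = 0.4)
    pr <- g$manifest$derived_protein
    hits <- self_compare(pr, min_len = 20, n_permutations = 0)
    mm <- map_exon_homology(hits, g$model, pr)
    mm <- mm[mm$n_columns >= 10, ]
    best <- tapply(mm$n_columns, mm$query_exon,
                   function(x) mm$subject_exon[mm$query_exon ==
                     mm$query_exon[which(mm$n_columns == max(x))[1]]][
                     which.max(x)])
    plan <- g$manifest$duplication_plan
    want <- setNames(plan$source_exon, plan$copy_exon)
    got <- vapply(c("2", "3", "4", "5"), function(q) {
      sub <- mm[mm$query_exon == as.integer(q), ]
      if (!nrow(sub)) return(NA_integer_)
      sub$subject_exon[which.max(sub$n_columns)]
    }, integer(1))
    if (identical(unname(got), unname(want[c("2", "3", "4", "5")]))) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("degrading a repeat lowers identity; divergence-0 copies are near-identical", {
  g0 <- generate_caspase16_like_locus(41, copy_divergence = 0)
  h0 <- self_compare(g0$manifest$derived_protein, n_permutations = 0)[[1]]
  # identity over the matched residues: everything but the 4 engineered edits
  expect_gte(percent_identity(h0$alignment, "shorter_sequence"), 97)
  g4 <- generate_caspase16_like_locus(41, copy_divergence = 0.4)
  h4 <- self_compare(g4$manifest$derived_protein, n_permutations = 0)[[1]]
  expect_lt(h4$identity_pct, h0$identity_pct)
})

test_that("phase signatures: identity, duplicated blocks, ancestral overlap", {
  g <- generate_caspase16_like_locus(43)
  tab <- phase_signature_compare(list(g$model, g$model))
  expect_equal(tab$agreement, 1)
  # the duplicated block's phases appear twice in the derived signature
  sig <- phase_signature(g$model)$phases
  expect_equal(sig[1:2], sig[5:6]) # exons 2,3 mirror exons 6,7
  tab2 <- phase_signature_compare(list(g$model, g$manifest$ancestral_model))
  expect_equal(tab2$lcs, 6L) # the whole ancestral signature is embedded
  m1 <- gene_model("one", "c", "+",
                   data.frame(index = 1, genomic_start = 1, genomic_end = 9,
                              coding_start = 1, coding_end = 9))
  expect_error(suppressWarnings(phase_signature_compare(list(m1, m1))),
               "fewer than two")
})
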