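nuc_p <- alignment_params("nucleotide")
simple_p <- alignment_params("nucleotide", match = 1, mismatch = -1,
                             gap_open = 2, gap_extend = 1)

test_that("worked examples: perfect match and the forced single gap", {
  a <- global_align("ACGT", "ACGT", simple_p)
  expect_equal(a$score, 4)
  expect_false(grepl("-", paste0(a$aligned_a, a$aligned_b)))
  b <- global_align("AAAA", "AAA", simple_p)
  expect_equal(b$score, 3 * 1 - 2) # 3 matches minus one gap opening
  expect_equal(nchar(gsub("[^-]", "", b$aligned_b)), 1L)
  expect_error(global_align("", "ACGT", simple_p), "empty")
})

test_that("local alignment pulls out the shared motif and can be empty", {
  pp <- alignment_params("protein")
  l <- local_align(pep_seq("x", "XXXMQTIFWXXX"), pep_seq("y", "YYMQTIFWYY"), pp)
  expect_equal(gsub("-", "", l$aligned_a), "MQTIFW")
  expect_equal(l$a_start, 4); expect_equal(l$a_end, 9)
  l0 <- local_align("AAAA", "TTTT", nuc_p)
  expect_equal(l0$score, 0)
  expect_equal(l0$a_start, 0)
  expect_equal(nchar(l0$aligned_a), 0L)
})

test_that("global and local scores equal exhaustive path enumeration", {
  set.seed(31)
  lk <- pseudocasp:::score_lookup(nuc_p)
  for (i in 1:150) {
    a <- paste(sample(c("A", "C"), sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C"), sample(1:6, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b, nuc_p)$score,
                 pseudocasp:::.enum_global_score_cpp(a, b, lk, 5L, 2L))
  }
  for (i in 1:60) {
    a <- random_nt(sample(2:8, 1)); b <- random_nt(sample(2:8, 1))
    expect_equal(local_align(a, b, nuc_p)$score,
                 pseudocasp:::.enum_local_score_cpp(a, b, lk, 5L, 2L))
  }
})

test_that("scores agree with an independent implementation on random pairs", {
  # Biostrings charges opening + extension per gap column; ours charges the
  # opening on the first column only, so their opening = open - extend
  mat <- matrix(-3L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  diag(mat) <- 2L
  set.seed(32)
  for (k in 1:40) {
    x <- random_nt(sample(10:80, 1)); y <- random_nt(sample(10:80, 1))
    expect_equal(global_align(x, y, nuc_p)$score,
                 Biostrings::score(Biostrings::pairwiseAlignment(
                   x, y, substitutionMatrix = mat, gapOpening = 3,
                   gapExtension = 2, type = "global")))
    expect_equal(local_align(x, y, nuc_p)$score,
                 Biostrings::score(Biostrings::pairwiseAlignment(
                   x, y, substitutionMatrix = mat, gapOpening = 3,
                   gapExtension = 2, type = "local")))
  }
})

test_that("score symmetry and identity invariance under swapping a and b", {
  set.seed(33)
  for (k in 1:25) {
    x <- random_nt(sample(5:50, 1)); y <- random_nt(sample(5:50, 1))
    f <- global_align(x, y, nuc_p); r <- global_align(y, x, nuc_p)
    expect_equal(f$score, r$score)
    expect_equal(percent_identity(f), percent_identity(r))
  }
})

test_that("percent identity worked examples and denominators", {
  expect_equal(percent_identity(global_align("ACGT", "ACGT", nuc_p)), 100)
  expect_equal(percent_identity(global_align("ACGT", "ACGA", nuc_p)), 75)
  a <- global_align("AAAA", "AA", simple_p)
  expect_equal(percent_identity(a, "columns"), 50)
  expect_equal(percent_identity(a, "shorter_sequence"), 100)
  expect_error(percent_identity(local_align("AAAA", "TTTT", nuc_p)), "empty")
})

test_that("indel calling: canonical events, left-alignment, self-emptiness", {
  # gap-free
  expect_equal(nrow(call_indels(global_align("ACGT", "ACGT", nuc_p))), 0L)
  # self-alignment of any sequence has no events
  set.seed(34)
  s <- random_nt(300)
  expect_equal(nrow(call_indels(global_align(s, s, nuc_p))), 0L)
  # one deleted base in a homopolymer run left-aligns to the run start
  ref <- "TTCAGGGGGACT"
  qry <- "TTCAGGGGACT" # one G of the 5-G run lost
  ev <- call_indels(global_align(ref, qry, nuc_p), reference = "a")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$ref_pos, 4L) # shifted left of the G run
  expect_equal(ev$length, 1L)
  expect_equal(ev$frame_shift, 1L)
  # insertion relative to the reference
  ev2 <- call_indels(global_align(qry, ref, nuc_p), reference = "a")
  expect_equal(ev2$kind, "insertion")
  expect_equal(ev2$ref_pos, 4L)
  # local input refused
  expect_error(call_indels(local_align(ref, qry, nuc_p)), "global")
})

test_that("overlap mode finds an interior match with free end gaps", {
  pp <- alignment_params("protein"); pp$mode <- "overlap"
  a <- global_align(pep_seq("q", "QRSTVW"), pep_seq("r", "AAAAQRSTVWCCCC"), pp)
  cols <- alignment_columns(a)
  inside <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  expect_equal(range(cols$b_pos[inside]), c(5L, 10L))
})
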