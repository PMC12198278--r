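# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation is a per-codon table lookup on
# Biostrings' genetic code, phases are a plain cumulative sum, transcripts a
# naive per-exon paste.

oracle_translate <- function(nt, offset = 0) {
  tab <- Biostrings::GENETIC_CODE
  nt <- substr(nt, offset + 1, nchar(nt))
  k <- nchar(nt) %/% 3
  if (k == 0) return(character(0))
  sapply(seq_len(k), function(i) {
    cod <- substr(nt, 3 * i - 2, 3 * i)
    if (grepl("N", cod)) "X" else unname(tab[cod])
  })
}

# translation-to-first-stop on a spliced isoform assembled by naive pasting
oracle_isoform_cds <- function(model, locus, included) {
  ex <- model$exons
  ex <- ex[ex$index %in% included & !is.na(ex$coding_start), , drop = FALSE]
  paste(substring(locus$residues, ex$coding_start, ex$coding_end),
        collapse = "")
}

# does translation of the isoform reach a stop exactly at its end?
oracle_terminal_stop <- function(nt) {
  aa <- oracle_translate(nt)
  stops <- which(aa == "*")
  length(stops) > 0 && stops[1] == length(aa) && nchar(nt) %% 3 == 0
}

oracle_phases <- function(coding_lens) cumsum(coding_lens) %% 3

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

random_aa <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                      n, replace = TRUE), collapse = "")

# a tiny two/three-exon plus-strand gene built by hand around a given CDS
toy_gene <- function(cds_pieces, intron = "GTAAGTAG", utr5 = "", utr3 = "") {
  locus <- utr5
  rows <- list()
  pos <- nchar(utr5) + 1L
  for (i in seq_along(cds_pieces)) {
    w <- nchar(cds_pieces[i])
    rows[[i]] <- data.frame(index = i, genomic_start = pos,
                            genomic_end = pos + w - 1L,
                            coding_start = pos, coding_end = pos + w - 1L)
    locus <- paste0(locus, cds_pieces[i])
    pos <- pos + w
    if (i < length(cds_pieces)) {
      locus <- paste0(locus, intron)
      pos <- pos + nchar(intron)
    }
  }
  locus <- paste0(locus, utr3)
  list(locus = nuc_seq("toy", locus),
       model = gene_model("toy_gene", "toy", "+", do.call(rbind, rows)))
}
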