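# Sequence containers, FASTA I/O and conceptual translation.
#
# Coordinates are 0-based half-open internally only where stated; everything
# user-facing is 1-based inclusive (GenBank/GFF3 convention).

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Nucleotide sequence
#'
#' A light container for one nucleotide sequence over `A,C,G,T,N`
#' (uppercase canonical, no gap characters).
#'
#' @param id record identifier.
#' @param residues character scalar of residues; lowercase is normalised,
#'   `U` is mapped to `T`.
#' @param description optional free-text description.
#' @return An object of class `nuc_seq` with fields `id`, `residues`,
#'   `description`.
#' @examples
#' nuc_seq("a", "acgt")
#' @export
nuc_seq <- function(id, residues, description = NULL) {
  residues <- chartr("u", "t", toupper(residues))
  residues <- chartr("U", "T", residues)
  bad <- bad_residue_pos(residues, NUC_ALPHABET)
  if (length(bad))
    stop(sprintf("record '%s': illegal nucleotide '%s' at position %d",
                 id, substr(residues, bad[1], bad[1]), bad[1]))
  structure(list(id = as.character(id), residues = residues,
                 description = description),
            class = c("nuc_seq", "bio_seq"))
}

#' Peptide sequence
#'
#' A light container for one protein sequence over the 20 amino acids plus
#' `X` (unknown) and `*` (stop).
#'
#' @inheritParams nuc_seq
#' @return An object of class `pep_seq`.
#' @examples
#' pep_seq("p", "MQACRG")
#' @export
pep_seq <- function(id, residues, description = NULL) {
  residues <- toupper(residues)
  bad <- bad_residue_pos(residues, AA_ALPHABET)
  if (length(bad))
    stop(sprintf("record '%s': illegal amino acid '%s' at position %d",
                 id, substr(residues, bad[1], bad[1]), bad[1]))
  structure(list(id = as.character(id), residues = residues,
                 description = description),
            class = c("pep_seq", "bio_seq"))
}

bad_residue_pos <- function(residues, alphabet) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  which(!ch %in% alphabet)
}

#' @export
print.bio_seq <- function(x, ...) {
  kind <- if (inherits(x, "nuc_seq")) "nuc_seq" else "pep_seq"
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<%s> %s (%d residues)\n%s\n", kind, x$id, n, shown))
  invisible(x)
}

seq_string <- function(x) {
  if (inherits(x, "bio_seq")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a bio_seq or a single character string")
}

#' Read a FASTA file
#'
#' Parses a multi-record FASTA file into a list of [nuc_seq()] or
#' [pep_seq()] objects. Residues are uppercased; for nucleotide records `U`
#' is mapped to `T`. Ambiguity codes other than `N` are rejected so that
#' translation stays deterministic.
#'
#' @param path path to an existing FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A list of sequence objects, in file order. An empty file yields an
#'   empty list with a warning.
#' @export
parse_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("FASTA file with no records: ", path)
    return(list())
  }
  hdr <- names(set)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    d <- if (is.na(desc[k])) NULL else desc[k]
    r <- as.character(set[[k]])
    out[[k]] <- if (alphabet == "nucleotide") nuc_seq(ids[k], r, d)
                else pep_seq(ids[k], r, d)
  }
  out
}

#' Write sequences to FASTA
#'
#' Writes a list of sequence objects as multi-record FASTA, wrapped at 60
#' columns. `parse_fasta(write_fasta(x))` is the identity on valid records.
#'
#' @param seqs a single sequence object or a list of them.
#' @param path output file path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (inherits(seqs, "bio_seq")) seqs <- list(seqs)
  strs <- vapply(seqs, function(s) s$residues, character(1))
  hdr <- vapply(seqs, function(s) {
    if (is.null(s$description)) s$id else paste(s$id, s$description)
  }, character(1))
  set <- Biostrings::BStringSet(strs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# genetic-code lookup (standard table 1), built once from Biostrings
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Conceptual translation with frame tracking
#'
#' Translates a nucleotide sequence with the standard genetic code, reading
#' codons from a frame offset. Codons containing `N` translate to `X`.
#'
#' @param seq a [nuc_seq()] or character scalar.
#' @param offset frame offset, 0, 1 or 2 (number of nucleotides skipped
#'   before the first codon).
#' @param to_first_stop if `TRUE` (default) translation ends at the first
#'   stop codon; the peptide excludes the stop. If `FALSE` the whole window
#'   is translated and stops appear as `*`.
#' @return A `translation_outcome`: list with `peptide` ([pep_seq()]),
#'   `stop_found`, `stop_codon_index` (0-based codon ordinal of the first
#'   stop, or `NULL`), and `trailing_nt` (0-2 leftover nucleotides after the
#'   last complete codon of the translated window).
#' @examples
#' translate_cds("ATGTAA")          # peptide "M", stop at codon index 1
#' translate_cds("ATGGCC", offset = 1)  # "W", trailing_nt 2
#' @export
translate_cds <- function(seq, offset = 0, to_first_stop = TRUE) {
  s <- seq_string(seq)
  n <- nchar(s)
  if (offset < 0 || offset > 2) stop("offset must be 0, 1 or 2")
  if (offset >= n && n > 0) stop("offset must be smaller than the sequence length")
  win <- substr(s, offset + 1, n)
  wl <- nchar(win)
  ncod <- wl %/% 3
  tab <- codon_table()
  if (ncod == 0) {
    return(structure(list(peptide = pep_seq(seq_id_of(seq), ""),
                          stop_found = FALSE, stop_codon_index = NULL,
                          trailing_nt = wl),
                     class = "translation_outcome"))
  }
  starts <- seq(1L, by = 3L, length.out = ncod)
  codons <- substring(win, starts, starts + 2L)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  stop_idx <- which(aa == "*")
  first_stop <- if (length(stop_idx)) stop_idx[1] else NA_integer_
  if (to_first_stop) {
    if (!is.na(first_stop)) {
      pep <- paste(aa[seq_len(first_stop - 1L)], collapse = "")
      out <- list(peptide = pep_seq(seq_id_of(seq), pep),
                  stop_found = TRUE, stop_codon_index = first_stop - 1L,
                  trailing_nt = 0L)
    } else {
      pep <- paste(aa, collapse = "")
      out <- list(peptide = pep_seq(seq_id_of(seq), pep),
                  stop_found = FALSE, stop_codon_index = NULL,
                  trailing_nt = wl %% 3L)
    }
  } else {
    pep <- paste(aa, collapse = "")
    out <- list(peptide = pep_seq(seq_id_of(seq), pep),
                stop_found = !is.na(first_stop),
                stop_codon_index = if (!is.na(first_stop)) first_stop - 1L else NULL,
                trailing_nt = wl %% 3L)
  }
  structure(out, class = "translation_outcome")
}

seq_id_of <- function(x) if (inherits(x, "bio_seq")) x$id else "seq"

#' @export
print.translation_outcome <- function(x, ...) {
  cat(sprintf("translation: %d aa, stop %s%s, trailing %d nt\n",
              nchar(x$peptide$residues),
              if (x$stop_found) "found" else "not found",
              if (x$stop_found) sprintf(" (codon index %d)", x$stop_codon_index)
              else "",
              x$trailing_nt))
  invisible(x)
}

#' Reverse complement
#'
#' @param seq a [nuc_seq()] or character scalar.
#' @return Object of the same kind with reverse-complemented residues.
#' @export
reverse_complement <- function(seq) {
  s <- seq_string(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (inherits(seq, "nuc_seq")) nuc_seq(seq$id, rc, seq$description) else rc
}
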