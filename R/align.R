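# From-scratch pairwise alignment with affine gaps, percent identity and
# indel calling.
#
# Default scoring mirrors the tools it replaces: nucleotide +2/-3 with gap
# open 5 / extend 2 (BLASTn-like), protein BLOSUM62 with gap open 11 /
# extend 1. A gap of length L costs open + (L-1)*extend.

#' Alignment parameters
#'
#' @param alphabet `"nucleotide"` or `"protein"`; chooses the default scoring
#'   scheme.
#' @param match,mismatch nucleotide match/mismatch scores (ignored when a
#'   substitution matrix is used).
#' @param substitution_matrix a named protein matrix (`"BLOSUM62"`) or a
#'   square numeric matrix with residue dimnames; `NULL` for match/mismatch
#'   scoring.
#' @param gap_open,gap_extend affine gap penalties (positive numbers,
#'   `gap_open >= gap_extend >= 0`).
#' @param mode `"global"` (Needleman-Wunsch), `"local"` (Smith-Waterman) or
#'   `"overlap"` (global with free end gaps).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(alphabet = c("nucleotide", "protein"),
                             match = NULL, mismatch = NULL,
                             substitution_matrix = NULL,
                             gap_open = NULL, gap_extend = NULL,
                             mode = c("global", "local", "overlap")) {
  alphabet <- match.arg(alphabet)
  mode <- match.arg(mode)
  if (alphabet == "nucleotide") {
    if (is.null(match)) match <- 2
    if (is.null(mismatch)) mismatch <- -3
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
  } else {
    if (is.null(substitution_matrix)) substitution_matrix <- "BLOSUM62"
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
  }
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(alphabet = alphabet, match = match, mismatch = mismatch,
                 substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), mode = mode),
            class = "alignment_params")
}

# 128x128 integer lookup over ASCII codes, flattened row-major
score_lookup <- function(params) {
  lk <- matrix(0L, 128, 128)
  if (params$alphabet == "nucleotide") {
    res <- c("A", "C", "G", "T")
    for (x in res) for (y in res)
      lk[utf8ToInt(x) + 1, utf8ToInt(y) + 1] <-
        if (x == y) as.integer(params$match) else as.integer(params$mismatch)
    # N scores 0 against everything (unknown base)
  } else {
    sm <- params$substitution_matrix
    if (is.character(sm)) {
      if (!identical(sm, "BLOSUM62"))
        stop("unknown substitution matrix: ", sm)
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      sm <- e$BLOSUM62
    }
    res <- rownames(sm)
    for (x in res) for (y in res)
      lk[utf8ToInt(x) + 1, utf8ToInt(y) + 1] <- as.integer(sm[x, y])
  }
  as.integer(lk)
}

new_alignment <- function(raw, a, b, params) {
  structure(list(aligned_a = raw$aligned_a, aligned_b = raw$aligned_b,
                 score = raw$score,
                 a_start = raw$a_start, a_end = raw$a_end,
                 b_start = raw$b_start, b_end = raw$b_end,
                 a_id = seq_id_of(a), b_id = seq_id_of(b),
                 params = params),
            class = "pairwise_alignment")
}

run_align <- function(a, b, params, mode_code) {
  sa <- seq_string(a); sb <- seq_string(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("cannot align empty sequences")
  raw <- .align_pair_cpp(sa, sb, score_lookup(params),
                         params$gap_open, params$gap_extend, mode_code)
  new_alignment(raw, a, b, params)
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gaps and a deterministic traceback
#' (ties resolved diagonal first, then gap-in-b, then gap-in-a). With
#' `params$mode == "overlap"`, terminal gaps are free.
#'
#' @param a,b sequences ([nuc_seq()], [pep_seq()] or character).
#' @param params an [alignment_params()].
#' @return A `pairwise_alignment`: gapped strings `aligned_a`/`aligned_b`,
#'   `score`, and 1-based aligned span coordinates.
#' @examples
#' global_align("ACGT", "ACGT")$score  # 4 matches * 2
#' @export
global_align <- function(a, b, params = alignment_params("nucleotide")) {
  run_align(a, b, params, if (params$mode == "overlap") 2L else 0L)
}

#' Local pairwise alignment
#'
#' Smith-Waterman alignment with affine gaps. An empty alignment (score 0) is
#' returned when nothing scores positively.
#'
#' @inheritParams global_align
#' @return A `pairwise_alignment` (spans `0` when empty).
#' @export
local_align <- function(a, b, params = alignment_params("nucleotide")) {
  params$mode <- "local"
  run_align(a, b, params, 1L)
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: score %d, %d columns\n",
              x$a_id, x$b_id, x$score, nchar(x$aligned_a)))
  if (nchar(x$aligned_a) == 0) { cat("(empty alignment)\n"); return(invisible(x)) }
  cat(sprintf("a[%d-%d]  b[%d-%d]\n", x$a_start, x$a_end, x$b_start, x$b_end))
  n <- nchar(x$aligned_a)
  for (off in seq(1, n, by = width)) {
    to <- min(off + width - 1, n)
    sa <- substr(x$aligned_a, off, to)
    sb <- substr(x$aligned_b, off, to)
    mk <- paste(ifelse(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]] &
                       strsplit(sa, "")[[1]] != "-", "|", " "), collapse = "")
    cat(sa, "\n", mk, "\n", sb, "\n", sep = "")
    if (to < n) cat("\n")
  }
  invisible(x)
}

#' Per-column coordinate map of an alignment
#'
#' @param aln a `pairwise_alignment`.
#' @return Data frame with one row per column: `a_pos`, `b_pos` (1-based
#'   sequence positions, `NA` at gaps).
#' @export
alignment_columns <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  a_pos <- ifelse(ca == "-", NA_integer_,
                  aln$a_start - 1L + cumsum(ca != "-"))
  b_pos <- ifelse(cb == "-", NA_integer_,
                  aln$b_start - 1L + cumsum(cb != "-"))
  data.frame(a_pos = as.integer(a_pos), b_pos = as.integer(b_pos))
}

#' Percent identity of an alignment
#'
#' @param aln a non-empty `pairwise_alignment`.
#' @param denominator `"columns"` (all alignment columns, MultAlin-like
#'   default) or `"shorter_sequence"`. Gap columns never count as identical.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln,
                             denominator = c("columns", "shorter_sequence")) {
  denominator <- match.arg(denominator)
  n <- nchar(aln$aligned_a)
  if (n == 0) stop("percent identity is undefined for an empty alignment")
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  ident <- sum(ca == cb & ca != "-")
  den <- if (denominator == "columns") n
         else min(sum(ca != "-"), sum(cb != "-"))
  100 * ident / den
}

# VCF-style left normalisation of an indel against the reference string.
# p: 1-based reference position after which the event occurs;
# alt: the deleted (reference) or inserted (novel) bases.
left_align_indel <- function(ref, p, alt) {
  L <- nchar(alt)
  while (p >= 1 && substr(ref, p, p) == substr(alt, L, L)) {
    alt <- paste0(substr(ref, p, p), substr(alt, 1, L - 1))
    p <- p - 1L
  }
  list(ref_pos = as.integer(p), seq = alt)
}

#' Call indels from a global alignment
#'
#' Maximal runs of gap columns become single events, reported on the
#' designated reference and left-aligned within repeat runs so each event has
#' a single canonical coordinate.
#'
#' @param aln a global `pairwise_alignment` (local alignments are rejected:
#'   they do not cover the sequences).
#' @param reference `"a"` or `"b"`: the intact sequence events are reported
#'   against. A `deletion` means the other (query) sequence lost reference
#'   bases; an `insertion` means it gained bases absent from the reference.
#' @return Data frame of class `indel_events` with columns `kind`, `ref_pos`
#'   (1-based reference position after which the event occurs), `length`,
#'   `frame_shift` (`length %% 3`) and `seq` (the deleted/inserted bases).
#' @export
call_indels <- function(aln, reference = c("a", "b")) {
  reference <- match.arg(reference)
  if (aln$params$mode == "local" || aln$a_start == 0)
    stop("indel calling needs a global alignment (full sequence coverage)")
  cols <- alignment_columns(aln)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  if (reference == "b") { tmp <- ca; ca <- cb; cb <- tmp
                          cols <- data.frame(a_pos = cols$b_pos,
                                             b_pos = cols$a_pos) }
  ref_str <- paste(ca[ca != "-"], collapse = "")
  gap_q <- cb == "-" # query gap => deletion relative to reference
  gap_r <- ca == "-" # reference gap => insertion
  events <- list()
  runs <- function(flags) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values],
               len = r$lengths[r$values])
  }
  for (rr in seq_len(nrow(runs(gap_q)))) {
    rn <- runs(gap_q)[rr, ]
    del <- paste(ca[rn$start:rn$end], collapse = "")
    p <- cols$a_pos[rn$start] - 1L
    la <- left_align_indel(ref_str, p, del)
    events[[length(events) + 1]] <- data.frame(
      kind = "deletion", ref_pos = la$ref_pos, length = rn$len,
      frame_shift = rn$len %% 3L, seq = la$seq)
  }
  for (rr in seq_len(nrow(runs(gap_r)))) {
    rn <- runs(gap_r)[rr, ]
    ins <- paste(cb[rn$start:rn$end], collapse = "")
    prev <- cols$a_pos[seq_len(rn$start - 1L)]
    p <- if (any(!is.na(prev))) max(prev, na.rm = TRUE) else 0L
    la <- left_align_indel(ref_str, p, ins)
    events[[length(events) + 1]] <- data.frame(
      kind = "insertion", ref_pos = la$ref_pos, length = rn$len,
      frame_shift = rn$len %% 3L, seq = la$seq)
  }
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(kind = character(), ref_pos = integer(),
                         length = integer(), frame_shift = integer(),
                         seq = character())
  out <- out[order(out$ref_pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("indel_events", "data.frame")
  out
}

# net query-coordinate offset of reference position r given events 5' of it:
# query_pos = ref_pos - deletions_before + insertions_before
ref_to_query_pos <- function(r, events) {
  if (is.null(events) || nrow(events) == 0) return(r)
  del <- sum(events$length[events$kind == "deletion" & events$ref_pos < r])
  ins <- sum(events$length[events$kind == "insertion" & events$ref_pos < r])
  r - del + ins
}

query_to_ref_pos <- function(q, events) {
  if (is.null(events) || nrow(events) == 0) return(q)
  # invert piecewise: walk events in reference order
  ev <- events[order(events$ref_pos), , drop = FALSE]
  shift <- 0L # query = ref + shift locally
  r_edge <- 0L
  for (k in seq_len(nrow(ev))) {
    q_event <- ev$ref_pos[k] + shift
    if (ev$kind[k] == "insertion") {
      if (q <= q_event) return(q - shift)
      if (q <= q_event + ev$length[k]) return(NA_integer_) # inside insertion
      shift <- shift + ev$length[k]
    } else {
      if (q <= q_event) return(q - shift)
      shift <- shift - ev$length[k]
    }
    r_edge <- ev$ref_pos[k]
  }
  q - shift
}
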