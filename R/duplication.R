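# Intragenic domain duplication: per-exon peptides, off-diagonal
# self-alignment with permutation significance, exon homology mapping and
# splice-phase signatures.

#' Split a protein into exon-encoded segments
#'
#' Cuts the conceptual translation into the peptide fragments encoded by each
#' coding exon. A codon spanning a junction is assigned to the exon that
#' contributes at least 2 of its 3 nucleotides, so the segments tile the
#' protein exactly once.
#'
#' @param protein the translation of the model's CDS ([pep_seq()]).
#' @param model the [gene_model()].
#' @return List of `exon_segment`s: `exon_ordinal`, `peptide`,
#'   `ref_residue_span` (first/last residue on the full protein; a zero-length
#'   segment has span `c(x+1, x)`).
#' @export
split_by_exon <- function(protein, model) {
  p <- seq_string(protein)
  cl <- coding_lengths(model)
  total <- sum(cl)
  nres <- nchar(p)
  if (total %/% 3L != nres && total %/% 3L != nres + 1L) # +1: stop codon
    stop(sprintf("protein length %d inconsistent with total coding length %d",
                 nres, total))
  cum <- cumsum(cl)
  segs <- list()
  prev_end <- 0L
  for (i in seq_along(cl)) {
    if (cl[i] == 0) next
    # residue r (codon nt 3r-2..3r) belongs to exon i if >=2 nt fall inside,
    # i.e. the codon's second nucleotide (3r-1) is within the exon's span
    last_r <- min((cum[i] + 1L) %/% 3L, nres) # 3r-1 <= cum[i]
    span <- c(prev_end + 1L, last_r)
    pep <- if (span[1] > span[2]) "" else substr(p, span[1], span[2])
    segs[[length(segs) + 1]] <- structure(
      list(exon_ordinal = model$exons$index[i],
           peptide = pep_seq(sprintf("%s_exon%d", protein$id,
                                     model$exons$index[i]), pep),
           ref_residue_span = as.integer(span)),
      class = "exon_segment")
    prev_end <- last_r
  }
  segs
}

# residue -> exon ordinal lookup built from split_by_exon
exon_of_residue <- function(segments, nres) {
  out <- rep(NA_integer_, nres)
  for (s in segments) {
    sp <- s$ref_residue_span
    if (sp[1] <= sp[2]) out[sp[1]:sp[2]] <- s$exon_ordinal
  }
  out
}

#' Detect intragenic domain duplication by self-comparison
#'
#' Finds the best local alignments between disjoint N-terminal and C-terminal
#' windows of one protein (the query span strictly precedes and never
#' overlaps the subject span; the trivial self-diagonal is excluded by
#' construction). The statistic is the maximum, over split points, of the
#' Smith-Waterman score of prefix-vs-suffix; significance is the fraction of
#' residue-shuffled proteins whose best off-diagonal score reaches the
#' observed one (`(r+1)/(n+1)` estimator, so `empirical_p` is in (0, 1]).
#'
#' @param protein a [pep_seq()] of length at least `2 * min_len`.
#' @param params protein [alignment_params()].
#' @param min_len minimum residues per side (and per reported span).
#' @param n_permutations permutations for the null; 0 skips the test
#'   (`empirical_p = NA`).
#' @param seed RNG seed for shuffling (required when `n_permutations > 0`).
#' @param max_hits maximum number of non-overlapping hits returned (further
#'   hits are found after masking earlier ones).
#' @param split_step grid step for candidate split points (`NULL`: about 50
#'   candidates, at least step 1).
#' @param tie_break `"conservative"` (default; ties between the observed and
#'   null scores count against the hit, the usual permutation estimator) or
#'   `"randomized"` (ties broken uniformly, giving exactly uniform p-values
#'   under the null -- the standard device for calibration checks on a
#'   discrete test statistic).
#' @return List of `duplication_hit`s sorted by score: `query_span`,
#'   `subject_span`, `alignment`, `identity_pct`, `score`, `empirical_p`.
#'   Empty (with a warning) when the protein is too short.
#' @export
self_compare <- function(protein, params = alignment_params("protein"),
                         min_len = 20, n_permutations = 1000, seed = NULL,
                         max_hits = 3, split_step = NULL,
                         tie_break = c("conservative", "randomized")) {
  tie_break <- match.arg(tie_break)
  p <- seq_string(protein)
  n <- nchar(p)
  if (n < 2 * min_len) {
    warning("protein too short for self-comparison")
    return(list())
  }
  lk <- score_lookup(params)
  if (is.null(split_step)) split_step <- max(1L, n %/% 50L)
  splits <- unique(c(seq(min_len, n - min_len, by = split_step), n - min_len))
  statistic <- function(s)
    max(.split_best_scores_cpp(s, lk, params$gap_open, params$gap_extend,
                               as.integer(splits)))
  obs_scores <- .split_best_scores_cpp(p, lk, params$gap_open,
                                       params$gap_extend, as.integer(splits))
  null_scores <- NULL
  if (n_permutations > 0) {
    if (is.null(seed)) stop("a seed is required when n_permutations > 0")
    null_scores <- local_seed(seed, {
      ch <- strsplit(p, "", fixed = TRUE)[[1]]
      vapply(seq_len(n_permutations), function(i)
        statistic(paste(sample(ch), collapse = "")), numeric(1))
    })
  }
  emp_p <- function(score) {
    if (is.null(null_scores)) return(NA_real_)
    n <- length(null_scores)
    if (tie_break == "conservative")
      (sum(null_scores >= score) + 1) / (n + 1)
    else
      (sum(null_scores > score) +
         runif(1) * (1 + sum(null_scores == score))) / (n + 1)
  }

  hits <- list()
  masked <- p
  loc_params <- params; loc_params$mode <- "local"
  for (h in seq_len(max_hits)) {
    sc <- if (h == 1) obs_scores
          else .split_best_scores_cpp(masked, lk, params$gap_open,
                                      params$gap_extend, as.integer(splits))
    best_k <- which.max(sc)
    if (sc[best_k] <= 0) break
    s <- splits[best_k]
    aln <- local_align(pep_seq("nterm", substr(masked, 1, s)),
                       pep_seq("cterm", substr(masked, s + 1, n)), loc_params)
    if (aln$score <= 0) break
    q_span <- c(aln$a_start, aln$a_end)
    s_span <- c(aln$b_start + s, aln$b_end + s)
    hits[[length(hits) + 1]] <- structure(
      list(query_span = q_span, subject_span = s_span, alignment = aln,
           identity_pct = percent_identity(aln), score = aln$score,
           empirical_p = emp_p(aln$score)),
      class = "duplication_hit")
    # the best hit is always reported (its p-value judges it); iteration
    # continues only while hits span at least min_len residues
    if (diff(q_span) + 1 < min_len || diff(s_span) + 1 < min_len) break
    # mask both spans so later iterations find other duplications
    for (i in c(q_span[1]:q_span[2], s_span[1]:s_span[2]))
      substr(masked, i, i) <- "X"
  }
  hits
}

# run an expression under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.duplication_hit <- function(x, ...) {
  cat(sprintf(
    "duplication hit: residues %d-%d ~ %d-%d, score %d, identity %.1f%%, p = %s\n",
    x$query_span[1], x$query_span[2], x$subject_span[1], x$subject_span[2],
    x$score, x$identity_pct,
    if (is.na(x$empirical_p)) "NA" else format(x$empirical_p, digits = 3)))
  invisible(x)
}

#' Attribute duplication hits to exons
#'
#' Intersects each hit's aligned residue pairs with the exon residue spans
#' and reports which query exons correspond to which subject exons.
#'
#' @param hits list of `duplication_hit`s from [self_compare()].
#' @param model the [gene_model()] of the same protein.
#' @param protein the protein the hits were computed on.
#' @return Data frame: `hit`, `query_exon`, `subject_exon`, `n_columns`
#'   (aligned residue pairs in that exon pair) and `query_fraction` (share of
#'   the query exon's aligned columns falling in that subject exon).
#' @export
map_exon_homology <- function(hits, model, protein) {
  segs <- split_by_exon(protein, model)
  nres <- nchar(seq_string(protein))
  res_exon <- exon_of_residue(segs, nres)
  rows <- list()
  for (h in seq_along(hits)) {
    hit <- hits[[h]]
    cols <- alignment_columns(hit$alignment)
    ok <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
    # spans were computed on prefix/suffix; shift to protein coordinates
    qa <- cols$a_pos[ok] + hit$query_span[1] - hit$alignment$a_start
    sb <- cols$b_pos[ok] + hit$subject_span[1] - hit$alignment$b_start
    qe <- res_exon[qa]; se <- res_exon[sb]
    tab <- table(qe, se)
    if (!length(tab)) next
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("query_exon", "subject_exon", "n_columns")
    df <- df[df$n_columns > 0, , drop = FALSE]
    df$query_exon <- as.integer(df$query_exon)
    df$subject_exon <- as.integer(df$subject_exon)
    per_q <- tapply(df$n_columns, df$query_exon, sum)
    df$query_fraction <- df$n_columns / as.numeric(per_q[as.character(df$query_exon)])
    df$hit <- h
    rows[[length(rows) + 1]] <- df[, c("hit", "query_exon", "subject_exon",
                                       "n_columns", "query_fraction")]
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(hit = integer(), query_exon = integer(),
                         subject_exon = integer(), n_columns = integer(),
                         query_fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Splice-phase signature of a gene
#'
#' @param model a [gene_model()].
#' @return Object of class `phase_signature`: `gene_id` and `phases`
#'   (ordered junction end-phases over the coding junctions).
#' @export
phase_signature <- function(model) {
  jp <- compute_splice_phases(model)
  structure(list(gene_id = model$gene_id, phases = jp$end_phase),
            class = "phase_signature")
}

# longest common subsequence of two integer vectors (classic DP)
lcs_length <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) return(0L)
  d <- matrix(0L, m + 1, n + 1)
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1, j + 1] <- if (x[i] == y[j]) d[i, j] + 1L
                       else max(d[i, j + 1], d[i + 1, j])
  d[m + 1, n + 1]
}

#' Compare splice-phase signatures across genes
#'
#' For every pair of gene models, computes the longest common subsequence of
#' their junction end-phase vectors -- the shared-phase evidence used to
#' argue common exon origin.
#'
#' @param models list of [gene_model()]s (at least 2). Models without coding
#'   junctions are skipped with a warning.
#' @return Data frame: `gene_a`, `gene_b`, `n_a`, `n_b` (junction counts),
#'   `lcs` and `agreement` (`lcs / min(n_a, n_b)`), plus the phase strings.
#' @export
phase_signature_compare <- function(models) {
  if (length(models) < 2) stop("need at least two gene models")
  sigs <- list()
  for (m in models) {
    s <- tryCatch(phase_signature(m), error = function(e) NULL)
    if (is.null(s) || length(s$phases) == 0) {
      warning("model without coding junctions skipped: ", m$gene_id)
      next
    }
    sigs[[length(sigs) + 1]] <- s
  }
  if (length(sigs) < 2) stop("fewer than two models with coding junctions")
  rows <- list()
  for (i in seq_len(length(sigs) - 1)) for (j in seq(i + 1, length(sigs))) {
    a <- sigs[[i]]; b <- sigs[[j]]
    l <- lcs_length(a$phases, b$phases)
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = a$gene_id, gene_b = b$gene_id,
      n_a = length(a$phases), n_b = length(b$phases), lcs = l,
      agreement = l / min(length(a$phases), length(b$phases)),
      phases_a = paste(a$phases, collapse = ""),
      phases_b = paste(b$phases, collapse = ""))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
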