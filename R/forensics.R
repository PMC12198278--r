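# Pseudogene forensics: propagate frameshifts, locate premature stops,
# evaluate exon-skipping rescue, map rescue ORFs, check the catalytic dyad
# and classify gene status.
#
# Counting conventions (reported in all outputs):
#  * codons_downstream_to_stop counts complete triplets strictly after the
#    codon disrupted by the lesion, in the shifted frame, with the stop
#    triplet included as the terminating ordinal;
#  * truncated lengths count from the annotated initiator methionine,
#    Met = residue 1.

# reference-frame exon coding lengths: mutant lengths with event lengths
# added back (deletions) or removed (insertions), attributing each event to
# the exon that contains its query-side position
reference_coding_lengths <- function(model, events) {
  cl <- coding_lengths(model)
  if (is.null(events) || nrow(events) == 0) return(cl)
  cum <- cumsum(cl)
  for (k in seq_len(nrow(events))) {
    # first query base after the event start (the deleted base itself has no
    # query coordinate, so map the base before the event and step right)
    q <- ref_to_query_pos(events$ref_pos[k], events) + 1L
    exon <- which(cum >= q)[1]
    if (is.na(exon)) exon <- length(cl)
    delta <- if (events$kind[k] == "deletion") events$length[k]
             else -events$length[k]
    cl[exon] <- cl[exon] + delta
  }
  cl
}

# exon (ordinal) containing query CDS position q
exon_of_cds_pos <- function(model, q) {
  cl <- coding_lengths(model)
  cum <- cumsum(cl)
  idx <- which(cum >= q & cl > 0)
  if (length(idx)) model$exons$index[idx[1]] else NA_integer_
}

#' Locate a premature termination codon
#'
#' Translates the query's full spliced CDS from the annotated start codon.
#' The frame before the first frameshifting event is the ortholog frame;
#' after each event the frame shifts by its `frame_shift`. The first stop
#' after the first frameshifting event is the premature termination codon.
#'
#' @param model the query [gene_model()] (the mutant gene, all exons).
#' @param locus the query genomic sequence.
#' @param events an `indel_events` frame from [call_indels()], with positions
#'   on the intact ortholog CDS.
#' @return A `ptc_report`: `causal_event` (row of `events`, or `NULL` for a
#'   pure stop-gain), `codons_downstream_to_stop`, `truncated_peptide`,
#'   `truncated_length`, `stop_codon_ordinal` (1-based codon of the mutant
#'   CDS), `stop_exon`. Returns `NULL` when translation reaches the terminal
#'   stop cleanly despite in-frame events. With no events and no premature
#'   stop, an error is raised ("no lesion to locate").
#' @export
locate_ptc <- function(model, locus, events = NULL) {
  cds <- spliced_cds(model, locus)
  n <- nchar(cds$seq$residues)
  tr <- translate_cds(cds$seq, 0, to_first_stop = TRUE)
  terminal_codon <- n %/% 3L
  stop_ordinal <- if (tr$stop_found) tr$stop_codon_index + 1L else NA_integer_
  premature <- tr$stop_found && stop_ordinal < terminal_codon
  fs_events <- if (!is.null(events) && nrow(events))
    events[events$frame_shift != 0, , drop = FALSE] else NULL
  has_fs <- !is.null(fs_events) && nrow(fs_events) > 0

  if (!premature) {
    if (!has_fs)
      stop("no lesion to locate: no frameshifting event and no stop substitution")
    return(NULL) # frame compensated and the stop is terminal
  }

  causal <- NULL
  codons_downstream <- NA_integer_
  if (has_fs) {
    causal <- fs_events[1, , drop = FALSE]
    q <- ref_to_query_pos(causal$ref_pos, events) # query pos of last base before event
    disrupted_codon <- q %/% 3L + 1L              # codon containing q+1
    codons_downstream <- stop_ordinal - disrupted_codon
  }
  trunc_pep <- tr$peptide
  structure(list(causal_event = causal,
                 codons_downstream_to_stop = codons_downstream,
                 truncated_peptide = trunc_pep,
                 truncated_length = nchar(trunc_pep$residues),
                 stop_codon_ordinal = stop_ordinal,
                 stop_exon = exon_of_cds_pos(model, stop_ordinal * 3L)),
            class = "ptc_report")
}

#' @export
print.ptc_report <- function(x, ...) {
  cat(sprintf(
    "premature stop at CDS codon %d (exon %s): %s codons downstream of the lesion;\ntruncated product: %d aa (Met = residue 1)\n",
    x$stop_codon_ordinal, x$stop_exon,
    if (is.na(x$codons_downstream_to_stop)) "stop-gain,"
    else x$codons_downstream_to_stop,
    x$truncated_length))
  invisible(x)
}

#' Evaluate exon-skipping frame rescue
#'
#' Decides whether skipping one internal coding exon removes the lesion and
#' restores the reading frame. Phases are computed on the pre-lesion
#' (reference) exon architecture; the verdict is cross-validated by
#' conceptual translation of the skip isoform (frame restored only if the
#' isoform translates to the terminal stop without premature termination).
#'
#' @inheritParams locate_ptc
#' @param skipped_exon ordinal of the exon to skip (internal, coding, and
#'   not the start-codon exon).
#' @return A `skip_verdict`: `skipped_exon`, `removes_lesion`,
#'   `frame_restored`, and `explanation` (junction phases used).
#' @export
evaluate_exon_skip <- function(model, locus, skipped_exon, events = NULL) {
  ex <- model$exons
  cl <- coding_lengths(model)
  k <- which(ex$index == skipped_exon)
  if (!length(k)) stop("no such exon: ", skipped_exon)
  if (skipped_exon == model$start_codon_exon)
    stop("cannot skip the start-codon exon")
  if (k == 1 || k == nrow(ex)) stop("skipped exon must be internal")
  if (cl[k] == 0) stop("skipped exon is non-coding")
  coding_idx <- which(cl > 0)
  if (k == max(coding_idx)) stop("cannot skip the stop-codon exon")

  ref_cl <- reference_coding_lengths(model, events)
  up <- max(coding_idx[coding_idx < k])
  down <- min(coding_idx[coding_idx > k])
  end_phase_up <- as.integer(sum(ref_cl[seq_len(up)]) %% 3)
  start_phase_down <- as.integer(sum(ref_cl[seq_len(down - 1)]) %% 3)
  phases_match <- end_phase_up == start_phase_down

  # lesion bookkeeping (positions on the reference CDS, reference lengths)
  removes <- TRUE
  net_remaining <- 0L
  if (!is.null(events) && nrow(events)) {
    ref_cum <- cumsum(ref_cl)
    exon_of_ref <- function(r) which(ref_cum >= r)[1]
    ev_exon <- vapply(events$ref_pos + 1L, exon_of_ref, integer(1))
    fs <- events$frame_shift != 0
    removes <- all(ev_exon[fs] == k)
    outside <- events[ev_exon != k, , drop = FALSE]
    net_remaining <- as.integer(sum(outside$frame_shift) %% 3)
  } else {
    removes <- FALSE # nothing to remove
  }

  # translation cross-check on the skip isoform of the (mutant) gene
  iso <- spliced_cds(model, locus,
                     included_exons = setdiff(ex$index, skipped_exon))
  tr <- translate_cds(iso$seq, 0, to_first_stop = TRUE)
  n_iso <- nchar(iso$seq$residues)
  translation_ok <- tr$stop_found && n_iso %% 3L == 0L &&
    (tr$stop_codon_index + 1L) == n_iso %/% 3L

  frame_restored <- phases_match && net_remaining == 0L
  if (frame_restored != translation_ok)
    warning(sprintf(
      "phase arithmetic (%s) and translation of the skip isoform (%s) disagree for exon %d",
      frame_restored, translation_ok, skipped_exon))
  structure(list(skipped_exon = skipped_exon,
                 removes_lesion = removes,
                 frame_restored = frame_restored && translation_ok,
                 explanation = sprintf(
                   "exon %d ends in splicing phase %d; exon %d begins in splicing phase %d; net remaining frame shift %d",
                   ex$index[up], end_phase_up, ex$index[down],
                   start_phase_down, net_remaining)),
            class = "skip_verdict")
}

#' @export
print.skip_verdict <- function(x, ...) {
  cat(sprintf("skip exon %d: removes lesion = %s, frame restored = %s\n  (%s)\n",
              x$skipped_exon, x$removes_lesion, x$frame_restored,
              x$explanation))
  invisible(x)
}

#' Find a rescue open reading frame
#'
#' Scans the spliced transcript 3' of the premature stop for the earliest
#' `ATG` that is in frame with the ortholog-defined downstream frame,
#' translates the resulting ORF to its stop, and maps it onto the intact
#' ortholog protein by overlap (free-end-gap) alignment.
#'
#' For a gene with no disabling lesion the annotated CDS itself is returned
#' (`ref_start_residue` 1).
#'
#' @inheritParams locate_ptc
#' @param reference_protein the intact ortholog's full-length protein
#'   ([pep_seq()]).
#' @param params protein [alignment_params()] for the mapping step.
#' @return A `rescue_orf` (`start_codon_exon`, `orf_peptide`,
#'   `ref_start_residue`, `ref_end_residue`) or `NULL` when no in-frame ATG
#'   exists downstream of the stop.
#' @export
find_rescue_orf <- function(model, locus, reference_protein, events = NULL,
                            params = alignment_params("protein")) {
  cds <- spliced_cds(model, locus)
  s <- cds$seq$residues
  ptc <- tryCatch(locate_ptc(model, locus, events), error = function(e) NULL)
  if (is.null(ptc)) {
    tr <- translate_cds(cds$seq, 0, to_first_stop = TRUE)
    orf <- tr$peptide
    first_exon <- model$start_codon_exon
    map <- map_orf_to_reference(orf, reference_protein, params)
    return(structure(list(start_codon_exon = first_exon, orf_peptide = orf,
                          ref_start_residue = map$start,
                          ref_end_residue = map$end),
                     class = "rescue_orf"))
  }
  q0 <- ptc$stop_codon_ordinal * 3L + 1L
  n <- nchar(s)
  q <- q0
  start_q <- NA_integer_
  while (q + 2L <= n) {
    if (substr(s, q, q + 2L) == "ATG") {
      r <- query_to_ref_pos(q, events)
      if (!is.na(r) && r %% 3L == 1L) { start_q <- q; break }
    }
    q <- q + 1L
  }
  if (is.na(start_q)) return(NULL)
  tr <- translate_cds(substr(s, start_q, n), 0, to_first_stop = TRUE)
  orf <- pep_seq(paste0(model$gene_id, "_rescue"), tr$peptide$residues)
  map <- map_orf_to_reference(orf, reference_protein, params)
  structure(list(start_codon_exon = exon_of_cds_pos(model, start_q),
                 orf_peptide = orf,
                 ref_start_residue = map$start, ref_end_residue = map$end),
            class = "rescue_orf")
}

map_orf_to_reference <- function(orf, reference_protein, params) {
  params$mode <- "overlap"
  aln <- global_align(orf, reference_protein, params)
  cols <- alignment_columns(aln)
  aligned <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  if (!any(aligned)) return(list(start = NA_integer_, end = NA_integer_))
  list(start = min(cols$b_pos[aligned]), end = max(cols$b_pos[aligned]))
}

#' @export
print.rescue_orf <- function(x, ...) {
  cat(sprintf(
    "rescue ORF: start codon in exon %d, %d aa, homologous to reference residues %d-%d\n",
    x$start_codon_exon, nchar(x$orf_peptide$residues),
    x$ref_start_residue, x$ref_end_residue))
  invisible(x)
}

#' Check the catalytic dyad
#'
#' Maps the reference histidine and cysteine positions through a global
#' protein alignment and reports whether the aligned query residues are
#' H and C. Alignment-anchored on purpose: robust to degenerate prodomain
#' copies where the dyad is absent.
#'
#' @param protein query protein ([pep_seq()]).
#' @param reference intact reference protein.
#' @param ref_his,ref_cys 1-based dyad positions on the reference.
#' @param params protein [alignment_params()].
#' @return A `dyad_report`: `his_pos`, `cys_pos` (query positions or `NA`),
#'   `intact` (both present).
#' @export
check_catalytic_dyad <- function(protein, reference, ref_his, ref_cys,
                                 params = alignment_params("protein")) {
  nref <- nchar(seq_string(reference))
  if (ref_his < 1 || ref_his > nref || ref_cys < 1 || ref_cys > nref)
    stop("reference dyad positions outside the reference protein")
  params$mode <- "overlap"
  aln <- global_align(protein, reference, params)
  cols <- alignment_columns(aln)
  qs <- strsplit(seq_string(protein), "", fixed = TRUE)[[1]]
  probe <- function(rpos, want) {
    col <- which(cols$b_pos == rpos)
    if (!length(col)) return(NA_integer_)
    qpos <- cols$a_pos[col[1]]
    if (is.na(qpos)) return(NA_integer_)
    if (qs[qpos] == want) qpos else NA_integer_
  }
  his <- probe(ref_his, "H")
  cys <- probe(ref_cys, "C")
  structure(list(his_pos = his, cys_pos = cys,
                 intact = !is.na(his) && !is.na(cys)),
            class = "dyad_report")
}

#' @export
print.dyad_report <- function(x, ...) {
  cat(sprintf("catalytic dyad: His %s, Cys %s -> %s\n",
              ifelse(is.na(x$his_pos), "lost", x$his_pos),
              ifelse(is.na(x$cys_pos), "lost", x$cys_pos),
              if (x$intact) "intact" else "not intact"))
  invisible(x)
}

#' Classify gene status
#'
#' Combines the forensic reports into a verdict. `intact`: no premature stop
#' and the dyad is conserved. `pseudogene`: a premature stop that no
#' single-exon skip rescues and whose rescue ORF is absent or starts inside
#' the catalytic-domain window (precluding a complete domain), or loss of the
#' catalytic dyad. Anything else is `truncated_coding`.
#'
#' @param ptc a `ptc_report` or `NULL`.
#' @param skips list of `skip_verdict`s considered (may be empty).
#' @param rescue a `rescue_orf` or `NULL`.
#' @param dyad a `dyad_report`.
#' @param domain_window length-2 vector: first and last reference residue of
#'   the catalytic domain.
#' @param reference_length optional reference protein length, used to reject
#'   contradictory inputs (a "truncated" peptide longer than the reference).
#' @return A `gene_status`: `verdict` and `evidence` (character vector of
#'   the rules that fired).
#' @export
classify_gene_status <- function(ptc, skips, rescue, dyad, domain_window,
                                 reference_length = NULL) {
  if (!is.null(ptc) && !is.null(reference_length) &&
      ptc$truncated_length >= reference_length)
    stop("contradictory inputs: truncated peptide is not shorter than the reference")
  ev <- character()
  if (is.null(ptc)) ev <- c(ev, "no premature termination codon")
  else ev <- c(ev, sprintf("premature stop, truncated product %d aa",
                           ptc$truncated_length))
  any_rescue_skip <- length(skips) > 0 &&
    any(vapply(skips, function(s) isTRUE(s$frame_restored), logical(1)))
  if (!is.null(ptc))
    ev <- c(ev, if (any_rescue_skip) "an exon skip restores the reading frame"
            else "no evaluated exon skip restores the reading frame")
  rescue_blocks_domain <- is.null(rescue) ||
    is.na(rescue$ref_start_residue) ||
    rescue$ref_start_residue > domain_window[1]
  if (!is.null(ptc))
    ev <- c(ev, if (is.null(rescue)) "no rescue ORF"
            else sprintf("rescue ORF maps to reference residues %d-%d (catalytic domain %d-%d)",
                         rescue$ref_start_residue, rescue$ref_end_residue,
                         domain_window[1], domain_window[2]))
  ev <- c(ev, if (dyad$intact) "catalytic dyad intact" else "catalytic dyad lost")

  verdict <- if (is.null(ptc) && dyad$intact) "intact"
  else if ((!is.null(ptc) && !any_rescue_skip && rescue_blocks_domain) ||
           !dyad$intact) "pseudogene"
  else "truncated_coding"
  structure(list(verdict = verdict, evidence = ev), class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat("verdict:", x$verdict, "\n")
  for (e in x$evidence) cat(" -", e, "\n")
  invisible(x)
}

#' Full gene-structure forensics of a query gene against an intact ortholog
#'
#' The central analysis. Aligns the query CDS to the ortholog CDS, calls
#' indels, locates the premature stop, evaluates single-exon skips of every
#' exon carrying a frameshifting lesion, finds the rescue ORF, checks the
#' catalytic dyad and classifies the gene.
#'
#' @param query_model,query_locus the query gene and its genomic sequence.
#' @param ref_model,ref_locus the intact ortholog gene and sequence.
#' @param ref_his,ref_cys catalytic dyad positions on the ortholog protein.
#' @param domain_window first and last ortholog residue of the catalytic
#'   domain; defaults to `c(1, <reference length>)`, i.e. any internal rescue
#'   start counts as domain-truncating.
#' @param nuc_params,prot_params [alignment_params()] for the nucleotide and
#'   protein steps.
#' @return A `gene_forensics` object: `events`, `identity_pct`, `ptc`,
#'   `skips`, `rescue`, `dyad`, `status`, `reference_protein` plus the inputs'
#'   ids. Has `print()` and `summary()` methods.
#' @export
gene_forensics <- function(query_model, query_locus, ref_model, ref_locus,
                           ref_his, ref_cys, domain_window = NULL,
                           nuc_params = alignment_params("nucleotide"),
                           prot_params = alignment_params("protein")) {
  ref_cds <- spliced_cds(ref_model, ref_locus)
  query_cds <- spliced_cds(query_model, query_locus)
  ref_tr <- translate_cds(ref_cds$seq, 0, to_first_stop = TRUE)
  ref_protein <- pep_seq(paste0(ref_model$gene_id, "_protein"),
                         ref_tr$peptide$residues)
  if (is.null(domain_window))
    domain_window <- c(1L, nchar(ref_protein$residues))

  aln <- global_align(ref_cds$seq, query_cds$seq, nuc_params)
  events <- call_indels(aln, reference = "a")
  identity <- percent_identity(aln)

  ptc <- tryCatch(locate_ptc(query_model, query_locus, events),
                  error = function(e) NULL)
  skips <- list()
  if (!is.null(ptc) && nrow(events)) {
    ref_cl <- reference_coding_lengths(query_model, events)
    ref_cum <- cumsum(ref_cl)
    fs <- events[events$frame_shift != 0, , drop = FALSE]
    lesion_exons <- unique(vapply(fs$ref_pos + 1L,
                                  function(r) which(ref_cum >= r)[1],
                                  integer(1)))
    lesion_exons <- query_model$exons$index[lesion_exons]
    for (k in lesion_exons) {
      v <- tryCatch(evaluate_exon_skip(query_model, query_locus, k, events),
                    error = function(e) NULL)
      if (!is.null(v)) skips[[length(skips) + 1]] <- v
    }
  }
  rescue <- find_rescue_orf(query_model, query_locus, ref_protein, events,
                            prot_params)
  dyad_target <- if (is.null(ptc)) {
    translate_cds(query_cds$seq, 0, to_first_stop = TRUE)$peptide
  } else if (!is.null(rescue)) rescue$orf_peptide else ptc$truncated_peptide
  dyad <- check_catalytic_dyad(dyad_target, ref_protein, ref_his, ref_cys,
                               prot_params)
  status <- classify_gene_status(ptc, skips, rescue, dyad, domain_window,
                                 reference_length = nchar(ref_protein$residues))
  structure(list(query_id = query_model$gene_id, ref_id = ref_model$gene_id,
                 events = events, identity_pct = identity, ptc = ptc,
                 skips = skips, rescue = rescue, dyad = dyad, status = status,
                 domain_window = domain_window,
                 reference_protein = ref_protein),
            class = "gene_forensics")
}

#' @export
print.gene_forensics <- function(x, ...) {
  cat(sprintf("gene forensics: %s vs intact ortholog %s\n", x$query_id, x$ref_id))
  cat(sprintf("  CDS identity: %.2f%%; %d indel event(s)\n",
              x$identity_pct, nrow(x$events)))
  print(x$status)
  invisible(x)
}

#' @export
summary.gene_forensics <- function(object, ...) {
  x <- object
  cat(sprintf("gene forensics: %s vs intact ortholog %s\n", x$query_id, x$ref_id))
  cat(sprintf("CDS identity %.2f%%\n", x$identity_pct))
  if (nrow(x$events)) { cat("indel events:\n"); print.data.frame(x$events, row.names = FALSE) }
  if (!is.null(x$ptc)) print(x$ptc)
  for (s in x$skips) print(s)
  if (!is.null(x$rescue)) print(x$rescue)
  print(x$dyad)
  print(x$status)
  invisible(x)
}
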