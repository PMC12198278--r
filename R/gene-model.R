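# Gene architecture: exons, coding segments, splicing phases, transcript
# assembly, GFF3 I/O and the local-synteny check.
#
# Exon ordinals are 1-based in transcription order. "End phase p" of an exon
# means the cumulative coding length through that exon is p (mod 3), i.e.
# phase 0 <=> the last nucleotide of the exon is position 3 of a codon.
# The GFF3 "phase" column counts nucleotides to the next codon start and is
# converted on read; both conventions are reported by compute_splice_phases().

#' Gene model
#'
#' Exon/CDS architecture of one gene on one sequence.
#'
#' @param gene_id gene identifier.
#' @param seq_id identifier of the parent (genomic) sequence.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with columns `index` (1-based ordinal in
#'   transcription order), `genomic_start`, `genomic_end` (1-based inclusive
#'   on the parent sequence) and optional `coding_start`, `coding_end`
#'   (`NA` for fully untranslated exons). The coding interval must lie within
#'   its exon; exons must be non-overlapping and ordered in transcription
#'   direction.
#' @param start_codon_exon ordinal of the exon holding the start codon;
#'   defaults to the first coding exon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand = "+", exons,
                       start_codon_exon = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)
  if (is.null(exons$coding_start)) exons$coding_start <- NA_integer_
  if (is.null(exons$coding_end)) exons$coding_end <- NA_integer_
  if (is.null(exons$index)) exons$index <- seq_len(nrow(exons))
  exons <- exons[order(exons$index),
                 c("index", "genomic_start", "genomic_end",
                   "coding_start", "coding_end")]
  with(exons, stopifnot(all(genomic_start <= genomic_end)))
  cod <- !is.na(exons$coding_start)
  if (any(cod)) {
    stopifnot(all(exons$coding_start[cod] >= exons$genomic_start[cod]),
              all(exons$coding_end[cod] <= exons$genomic_end[cod]),
              all(exons$coding_start[cod] <= exons$coding_end[cod]))
  }
  # transcription order: increasing genomic position on +, decreasing on -
  gs <- exons$genomic_start
  if (nrow(exons) > 1) {
    ordered_ok <- if (strand == "+") all(diff(gs) > 0) else all(diff(gs) < 0)
    if (!ordered_ok)
      stop("exons are not ordered in transcription direction")
    # non-overlap
    lo <- pmin(exons$genomic_start, exons$genomic_end)
    hi <- pmax(exons$genomic_start, exons$genomic_end)
    o <- order(lo)
    if (any(lo[o][-1] <= hi[o][-length(hi)]))
      stop("exons overlap")
  }
  if (any(cod) && sum(coding_lengths_df(exons)) < 3)
    stop("total coding length must be >= 3 when any coding segment exists")
  if (is.null(start_codon_exon))
    start_codon_exon <- if (any(cod)) exons$index[cod][1] else NA_integer_
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, start_codon_exon = start_codon_exon),
            class = "gene_model")
}

coding_lengths_df <- function(exons) {
  ifelse(is.na(exons$coding_start), 0L,
         abs(exons$coding_end - exons$coding_start) + 1L)
}

#' Per-exon coding lengths
#' @param model a [gene_model()].
#' @return Integer vector of coding nucleotides per exon (0 for untranslated
#'   exons), in transcription order.
#' @export
coding_lengths <- function(model) {
  setNames(as.integer(coding_lengths_df(model$exons)),
           model$exons$index)
}

#' @export
print.gene_model <- function(x, ...) {
  cl <- coding_lengths(x)
  cat(sprintf("<gene_model> %s on %s (%s strand), %d exons, %d coding nt\n",
              x$gene_id, x$seq_id, x$strand, nrow(x$exons), sum(cl)))
  print(x$exons, row.names = FALSE)
  invisible(x)
}

#' Splicing phases at exon junctions
#'
#' Computes, for every junction between the first and last coding exon, the
#' end phase of the upstream exon and the start phase of the downstream exon.
#' The end phase is the cumulative coding length through the upstream exon
#' mod 3 (phase 0 means the junction falls between complete codons); the
#' start phase of an exon is the cumulative coding length before it mod 3.
#' The equivalent GFF3 phase of the downstream exon
#' (`(3 - start_phase) %% 3`) is reported alongside.
#'
#' @param model a [gene_model()] with at least one coding segment.
#' @return A data frame of class `junction_phases` with columns
#'   `upstream_exon`, `downstream_exon`, `end_phase`, `start_phase`,
#'   `gff3_phase`.
#' @export
compute_splice_phases <- function(model) {
  cl <- coding_lengths(model)
  if (sum(cl) == 0) stop("gene model has no coding segments")
  idx <- model$exons$index
  coding_idx <- which(cl > 0)
  first_c <- min(coding_idx); last_c <- max(coding_idx)
  cum <- cumsum(cl)
  rows <- list()
  for (i in seq_len(nrow(model$exons) - 1)) {
    if (i < first_c || i >= last_c) next
    rows[[length(rows) + 1]] <- data.frame(
      upstream_exon = idx[i], downstream_exon = idx[i + 1],
      end_phase = as.integer(cum[i] %% 3),
      start_phase = as.integer(cum[i] %% 3), # frame unbroken at annotation level
      gff3_phase = as.integer((3 - cum[i] %% 3) %% 3))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("junction_phases", "data.frame")
  out
}

#' @export
print.junction_phases <- function(x, ...) {
  cat("splice phases (end phase = cumulative coding nt mod 3):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# start phase of a given exon = cumulative coding nt before it, mod 3
exon_start_phase <- function(coding_len, exon) {
  as.integer(sum(coding_len[seq_len(exon - 1)]) %% 3)
}

#' Assemble a (possibly exon-skipped) transcript
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for minus-strand genes) and retains a per-base map from transcript
#' position to genomic position.
#'
#' @param model a [gene_model()].
#' @param locus the parent sequence ([nuc_seq()] or character).
#' @param included_exons ordinals of exons to include (default: all).
#' @param coding_only if `TRUE`, concatenate only the coding intervals
#'   (a spliced CDS) instead of whole exons.
#' @return List with `seq` (a [nuc_seq()]) and `map` (integer vector; genomic
#'   position of each transcript base).
#' @export
build_transcript <- function(model, locus, included_exons = NULL,
                             coding_only = FALSE) {
  s <- seq_string(locus)
  ex <- model$exons
  if (is.null(included_exons)) included_exons <- ex$index
  if (length(included_exons) == 0) stop("empty exon inclusion set")
  if (!all(included_exons %in% ex$index))
    stop("included_exons must be a subset of the model's exons")
  ex <- ex[ex$index %in% included_exons, , drop = FALSE]
  if (coding_only) {
    ex <- ex[!is.na(ex$coding_start), , drop = FALSE]
    if (nrow(ex) == 0) stop("no coding segments among the included exons")
    starts <- ex$coding_start; ends <- ex$coding_end
  } else {
    starts <- ex$genomic_start; ends <- ex$genomic_end
  }
  # rows are already in transcription order; on the minus strand each piece
  # is reverse-complemented in place
  pieces <- substring(s, pmin(starts, ends), pmax(starts, ends))
  maps <- Map(seq.int, pmin(starts, ends), pmax(starts, ends))
  if (model$strand == "-") {
    pieces <- vapply(pieces,
                     function(p) as.character(
                       Biostrings::reverseComplement(Biostrings::DNAString(p))),
                     character(1), USE.NAMES = FALSE)
    maps <- lapply(maps, rev)
  }
  seqstr <- paste(pieces, collapse = "")
  lab <- paste0(model$gene_id, if (coding_only) "_cds" else "_mrna")
  list(seq = nuc_seq(lab, seqstr), map = as.integer(unlist(maps)))
}

# spliced CDS shortcut
spliced_cds <- function(model, locus, included_exons = NULL) {
  build_transcript(model, locus, included_exons, coding_only = TRUE)
}

# exon ordinal containing a genomic position (NA if intronic/outside)
exon_of_genomic <- function(model, gpos) {
  ex <- model$exons
  hit <- which(gpos >= pmin(ex$genomic_start, ex$genomic_end) &
               gpos <= pmax(ex$genomic_start, ex$genomic_end))
  if (length(hit)) ex$index[hit[1]] else NA_integer_
}

#' Check flanking synteny
#'
#' Tests whether the nearest annotated neighbour of a target gene on a given
#' side (in the target's transcription orientation) is the expected gene --
#' the local-synteny evidence used for orthology.
#'
#' @param locus_genes data frame with columns `gene_id` and `start`
#'   (representative coordinate of each gene on the locus).
#' @param target target gene id (must be present).
#' @param expected_neighbor expected neighbour gene id.
#' @param side `"5prime"` or `"3prime"`, relative to the target's orientation.
#' @param target_strand strand of the target gene.
#' @return `TRUE` or `FALSE`.
#' @examples
#' loc <- data.frame(gene_id = c("ZNF213", "CASP16"), start = c(100, 500))
#' check_flanking_synteny(loc, "CASP16", "ZNF213", "5prime")
#' @export
check_flanking_synteny <- function(locus_genes, target, expected_neighbor,
                                   side = c("5prime", "3prime"),
                                   target_strand = "+") {
  side <- match.arg(side)
  stopifnot(target_strand %in% c("+", "-"))
  lg <- as.data.frame(locus_genes)
  k <- which(lg$gene_id == target)
  if (!length(k)) stop("target gene not present in locus annotation: ", target)
  t_start <- lg$start[k[1]]
  upstream <- (side == "5prime") == (target_strand == "+")
  others <- lg[lg$gene_id != target, , drop = FALSE]
  cand <- if (upstream) others[others$start < t_start, , drop = FALSE]
          else others[others$start > t_start, , drop = FALSE]
  if (nrow(cand) == 0)
    stop(sprintf("no neighbour annotated on the %s side of %s", side, target))
  nearest <- cand$gene_id[which.min(abs(cand$start - t_start))]
  identical(nearest, expected_neighbor)
}

# ---- GFF3 I/O -------------------------------------------------------------

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with Parent attributes and the
#' standard CDS phase column (nucleotides to the next codon start).
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @param locus_length optional sequence length for the `##sequence-region`
#'   directive.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path, locus_length = NULL) {
  ex <- model$exons
  mrna_id <- paste0(model$gene_id, ".t1")
  cod <- !is.na(ex$coding_start)
  cl <- coding_lengths(model)
  cum_before <- cumsum(c(0L, cl))[seq_len(nrow(ex))]
  gff3_phase <- (3L - cum_before %% 3L) %% 3L

  gstart <- min(ex$genomic_start, ex$genomic_end)
  gend <- max(ex$genomic_start, ex$genomic_end)
  lines <- c("##gff-version 3")
  if (!is.null(locus_length))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", model$seq_id,
                              as.integer(locus_length)))
  fmt <- function(type, s, e, phase, attrs)
    sprintf("%s\tpseudocasp\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            model$seq_id, type, s, e, model$strand, phase, attrs)
  lines <- c(lines,
             fmt("gene", gstart, gend, ".",
                 sprintf("ID=%s;Name=%s", model$gene_id, model$gene_id)),
             fmt("mRNA", gstart, gend, ".",
                 sprintf("ID=%s;Parent=%s", mrna_id, model$gene_id)))
  for (i in seq_len(nrow(ex))) {
    lines <- c(lines, fmt("exon", min(ex$genomic_start[i], ex$genomic_end[i]),
                          max(ex$genomic_start[i], ex$genomic_end[i]), ".",
                          sprintf("ID=%s.exon%d;Parent=%s", mrna_id,
                                  ex$index[i], mrna_id)))
    if (cod[i]) {
      lines <- c(lines, fmt("CDS", min(ex$coding_start[i], ex$coding_end[i]),
                            max(ex$coding_start[i], ex$coding_end[i]),
                            as.character(gff3_phase[i]),
                            sprintf("ID=%s.cds;Parent=%s", mrna_id, mrna_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read one gene from a GFF3 file
#'
#' Builds a [gene_model()] from the exon and CDS features of a gene's first
#' mRNA. The GFF3 phase column, when present, is validated against the phase
#' recomputed from cumulative coding lengths; mismatches produce a warning
#' quoting both values.
#'
#' @param path path to a GFF3 file.
#' @param gene_id gene to extract (matched against `ID`/`Name` of gene
#'   features, or `gene_id` attributes).
#' @return A [gene_model()].
#' @export
parse_gff3_gene <- function(path, gene_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  type <- as.character(md$type)
  gene_rows <- which(type == "gene" &
                     (ids == gene_id |
                      (!is.null(md$Name) & as.character(md$Name) == gene_id)))
  if (!length(gene_rows)) stop("gene not found in GFF3: ", gene_id)
  gid <- ids[gene_rows[1]]
  parent_of <- function(k) {
    p <- md$Parent[[k]]
    if (length(p)) as.character(p)[1] else NA_character_
  }
  parents <- vapply(seq_along(gr), parent_of, character(1))
  mrna_rows <- which(type %in% c("mRNA", "transcript") & parents == gid)
  if (!length(mrna_rows)) stop("no mRNA feature for gene ", gene_id)
  mid <- ids[mrna_rows[1]]
  strand <- as.character(GenomicRanges::strand(gr)[gene_rows[1]])
  if (!strand %in% c("+", "-")) strand <- "+"
  seq_id <- as.character(GenomicRanges::seqnames(gr)[gene_rows[1]])

  exon_rows <- which(type == "exon" & parents == mid)
  cds_rows <- which(type == "CDS" & parents == mid)
  if (!length(exon_rows)) stop("no exon features for mRNA ", mid)
  es <- GenomicRanges::start(gr)[exon_rows]
  ee <- GenomicRanges::end(gr)[exon_rows]
  o <- if (strand == "+") order(es) else order(-es)
  es <- es[o]; ee <- ee[o]
  cs <- rep(NA_integer_, length(es)); ce <- rep(NA_integer_, length(es))
  cds_phase <- rep(NA_integer_, length(es))
  if (length(cds_rows)) {
    ph_raw <- md$phase[cds_rows]
    for (k in seq_along(cds_rows)) {
      s0 <- GenomicRanges::start(gr)[cds_rows[k]]
      e0 <- GenomicRanges::end(gr)[cds_rows[k]]
      host <- which(es <= s0 & ee >= e0)
      if (!length(host))
        stop(sprintf("CDS %d-%d lies outside every exon of %s", s0, e0, mid))
      cs[host[1]] <- s0; ce[host[1]] <- e0
      ph <- suppressWarnings(as.integer(ph_raw[k]))
      cds_phase[host[1]] <- if (length(ph)) ph else NA_integer_
    }
  }
  model <- gene_model(gene_id, seq_id, strand,
                      data.frame(index = seq_along(es), genomic_start = es,
                                 genomic_end = ee, coding_start = cs,
                                 coding_end = ce))
  # validate declared phases against recomputed ones
  if (any(!is.na(cds_phase))) {
    cl <- coding_lengths(model)
    cum_before <- cumsum(c(0L, cl))[seq_along(cl)]
    expect <- (3L - cum_before %% 3L) %% 3L
    for (i in which(!is.na(cds_phase) & cl > 0)) {
      if (cds_phase[i] != expect[i])
        warning(sprintf(
          "exon %d: GFF3 phase %d disagrees with recomputed phase %d",
          i, cds_phase[i], expect[i]))
    }
  }
  model
}
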