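# Seed-reproducible generator of caspase-16-like loci with truth manifests.
#
# The default derived gene reproduces the architecture of the primate
# caspase-16 locus: 11 exons with exon 1 fully untranslated, a 470-residue
# protein whose prodomain (residues 1-197, exons 2-5) is a degenerate copy
# of the catalytic large (exons 6-7) and small (exons 10-11) subunits, a
# twice-encoded inter-subunit linker (exons 8-9), the catalytic dyad at
# His290/Cys332 (only in the C-terminal copy), the sole internal in-frame
# ATG at residue 288 inside exon 7, phase-0/phase-1 junctions flanking exon
# 3, and an exon-3 region where a 1-nt deletion at CDS position 300 shifts
# the frame into a stop at the 6th downstream triplet, truncating the
# product to 105 residues. The ancestral 8-exon gene (UTR exon, 2 prodomain
# exons, 2 large-subunit exons, 1 linker exon, 2 small-subunit exons) plays
# the CASP1-like role in the duplication plan.

# coding widths of the derived exons 2..11 and the ancestral exons 2..8
DERIVED_CODING_WIDTHS <- c(144L, 280L, 90L, 77L, 144L, 280L, 114L, 114L, 90L, 80L)
ANCESTRAL_CODING_WIDTHS <- c(120L, 132L, 144L, 280L, 114L, 90L, 80L)

ALL_CODONS <- local({
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
})
STOP_CODONS <- c("TAA", "TAG", "TGA")
ALLOWED_CODONS <- setdiff(ALL_CODONS, c("ATG", STOP_CODONS))

sample_codons <- function(n) sample(ALLOWED_CODONS, n, replace = TRUE)

codon_for <- function(aa) {
  # fixed codon per amino acid for planted motifs (deterministic)
  c(Q = "CAA", A = "GCC", M = "ATG", S = "TCT", H = "CAC", C = "TGC",
    R = "AGA", G = "GGT", L = "CTG", K = "AAA")[[aa]]
}

random_codon_other_aa <- function(codon) {
  tab <- codon_table()
  aa <- tab[[codon]]
  pool <- ALLOWED_CODONS[tab[ALLOWED_CODONS] != aa]
  sample(pool, 1)
}

random_noncoding <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

set_substr <- function(s, at, value) {
  substr(s, at, at + nchar(value) - 1L) <- value
  s
}

codon_at <- function(cds, k) substr(cds, 3 * k - 2, 3 * k)

# assemble a genomic locus from coding widths + UTR configuration;
# utr_exon1 = 0 drops the untranslated first exon entirely
assemble_locus <- function(gene_id, seq_id, cds, coding_widths, gc,
                           intron_range, utr_exon1, utr5, utr3, flank) {
  has_utr_exon <- utr_exon1 > 0L
  n_exons <- length(coding_widths) + as.integer(has_utr_exon)
  introns <- vapply(seq_len(n_exons - 1L), function(i) {
    len <- sample(seq(intron_range[1], intron_range[2]), 1)
    paste0("GT", random_noncoding(len - 4L, gc), "AG")
  }, character(1))
  pieces <- character(0)
  rows <- list()
  pos <- 1L
  append_piece <- function(p) { pieces <<- c(pieces, p); pos <<- pos + nchar(p) }
  append_piece(random_noncoding(flank, gc))
  cds_cut <- cumsum(c(0L, coding_widths))
  first_coding <- 1L + as.integer(has_utr_exon)
  for (e in seq_len(n_exons)) {
    if (has_utr_exon && e == 1L) {
      exon_seq <- random_noncoding(utr_exon1, gc)
      cstart <- NA_integer_; cend <- NA_integer_
    } else {
      w <- e - first_coding + 1L
      coding_piece <- substr(cds, cds_cut[w] + 1L, cds_cut[w + 1L])
      lead <- if (e == first_coding) random_noncoding(utr5, gc) else ""
      tailp <- if (e == n_exons) random_noncoding(utr3, gc) else ""
      exon_seq <- paste0(lead, coding_piece, tailp)
      cstart <- pos + nchar(lead)
      cend <- cstart + nchar(coding_piece) - 1L
    }
    rows[[e]] <- data.frame(index = e, genomic_start = pos,
                            genomic_end = pos + nchar(exon_seq) - 1L,
                            coding_start = cstart, coding_end = cend)
    append_piece(exon_seq)
    if (e < n_exons) append_piece(introns[e])
  }
  append_piece(random_noncoding(flank, gc))
  locus <- nuc_seq(seq_id, paste(pieces, collapse = ""))
  model <- gene_model(gene_id, seq_id, "+", do.call(rbind, rows))
  list(locus = locus, model = model)
}

# ancestral CDS (960 nt including stop) with planted motifs; blocks:
# prodomain 1-252, large 253-676, linker 677-790, small 791-957, stop 958-960
build_ancestral_cds <- function() {
  codons <- sample_codons(319L)
  codons[1] <- "ATG"
  plant <- function(codons, at, residues) {
    for (i in seq_along(residues)) codons[at + i - 1L] <- codon_for(residues[i])
    codons
  }
  # large-subunit block starts at codon 85; large codon k = codon 84 + k
  codons <- plant(codons, 84L + 89L, c("Q", "A", "M", "S", "H")) # Met 91, His 93
  codons <- plant(codons, 84L + 133L, c("Q", "A", "C", "R", "G")) # Cys 135
  # frameshift cassette, large codons 99-107: a 1-nt deletion in codon 100
  # shifts the frame so the 6th downstream triplet reads TAA; codon 99 ends
  # in a non-G so the G run (and the left-aligned deletion) starts in codon
  # 100 for every seed
  cassette <- c("CCT", "GGG", "GGC", "GGC", "GGC", "GGC", "GGC", "CTA", "AAA")
  for (i in seq_along(cassette)) codons[84L + 98L + i] <- cassette[i]
  cds <- paste(c(codons, "TAA"), collapse = "")
  # the linker's last base mirrors the large subunit's last base so that the
  # codon-142 junction of the prodomain copy reproduces an ancestral codon
  cds <- set_substr(cds, 790L, substr(cds, 676L, 676L))
  k <- 264L # codon containing nt 790
  while (codon_at(cds, k) %in% c("ATG", STOP_CODONS)) {
    cds <- set_substr(cds, 791L, paste(sample(c("A", "C", "G", "T"), 2,
                                              replace = TRUE), collapse = ""))
  }
  cds
}

# prodomain copy: nucleotide copy of large+small, start codon planted,
# dyad (and the copied rescue Met) knocked out, then codon-level divergence
build_prodomain_copy <- function(large_nt, small_nt, divergence) {
  copy <- paste0(large_nt, small_nt) # 591 nt = 197 codons
  forced <- c(1L, 91L, 93L, 135L)
  copy <- set_substr(copy, 1L, "ATG")
  for (k in c(91L, 93L, 135L))
    copy <- set_substr(copy, 3L * k - 2L, random_codon_other_aa(codon_at(copy, k)))
  protected <- c(forced, 100L:107L) # cassette stays exact
  for (k in setdiff(seq_len(197L), protected)) {
    if (runif(1) < divergence)
      copy <- set_substr(copy, 3L * k - 2L, random_codon_other_aa(codon_at(copy, k)))
  }
  copy
}

#' Generate a caspase-16-like locus with known truth
#'
#' Builds an ancestral 8-exon caspase gene, applies the exon-duplication
#' plan (large- and small-subunit exons copied 5'-ward to form the
#' prodomain, the linker exon duplicated in place) and returns the derived
#' 11-exon locus together with a truth manifest describing everything the
#' forensic pipeline should recover. Sequences are codon-aware: the coding
#' frame contains no internal stop and exactly two in-frame ATGs (the start
#' codon and the rescue Met at residue 288).
#'
#' @param seed integer seed; regeneration from the same seed is
#'   byte-identical.
#' @param copy_divergence per-residue substitution probability applied to
#'   the duplicated prodomain copy (0-0.6).
#' @param gc GC content of non-coding sequence.
#' @param intron_range length-2 integer range of intron lengths.
#' @return List with `locus` (derived genomic [nuc_seq()]), `model`
#'   (derived [gene_model()]) and `manifest` (a `truth_manifest`: seed,
#'   parameters, ancestral locus/model, derived protein, duplication plan,
#'   dyad and rescue coordinates, frameshift-cassette coordinates, domain
#'   window and expected splice phases).
#' @export
generate_caspase16_like_locus <- function(seed, copy_divergence = 0.4,
                                          gc = 0.45,
                                          intron_range = c(80L, 150L)) {
  if (copy_divergence < 0 || copy_divergence > 0.6)
    stop("copy_divergence must be within [0, 0.6]")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  local_seed(seed, {
    anc_cds <- build_ancestral_cds()
    large_nt <- substr(anc_cds, 253L, 676L)
    linker_nt <- substr(anc_cds, 677L, 790L)
    small_nt <- substr(anc_cds, 791L, 957L)
    copy <- build_prodomain_copy(large_nt, small_nt, copy_divergence)
    linker_copy <- diverge_linker_copy(linker_nt, copy_divergence)
    der_cds <- paste0(copy, large_nt, linker_copy, linker_nt, small_nt, "TAA")
    der_cds <- clean_linker_copy_frame(der_cds)

    anc <- assemble_locus("CASP1like", "anc_locus", anc_cds,
                          ANCESTRAL_CODING_WIDTHS, gc, intron_range,
                          utr_exon1 = 150L, utr5 = 20L, utr3 = 120L,
                          flank = 30L)
    der <- assemble_locus("CASP16like", "der_locus", der_cds,
                          DERIVED_CODING_WIDTHS, gc, intron_range,
                          utr_exon1 = 150L, utr5 = 20L, utr3 = 120L,
                          flank = 30L)
    protein <- translate_cds(der_cds, 0, to_first_stop = TRUE)$peptide
    protein$id <- "CASP16like_protein"
    manifest <- structure(list(
      seed = seed,
      params = list(copy_divergence = copy_divergence, gc = gc,
                    intron_range = intron_range),
      ancestral_locus = anc$locus, ancestral_model = anc$model,
      derived_protein = protein,
      duplication_plan = data.frame(source_exon = c(6L, 7L, 10L, 11L, 8L),
                                    copy_exon = c(2L, 3L, 4L, 5L, 9L)),
      dyad = c(his = 290L, cys = 332L),
      domain_window = c(198L, 470L),
      prodomain_span = c(1L, 197L),
      rescue = list(met_residue = 288L, exon = 7L, ref_end = 470L),
      cassette = list(exon = 3L, deletion_cds_pos = 300L,
                      left_aligned_ref_pos = 297L,
                      codons_downstream_to_stop = 6L,
                      truncated_length = 105L),
      expected_phases = list(exon2_end = 0L, exon4_start = 1L)),
      class = "truth_manifest")
    list(locus = der$locus, model = der$model, manifest = manifest)
  })
}

# nucleotide-level divergence of the in-place linker duplicate (the block
# starts mid-codon, so codon-level substitution does not apply cleanly)
diverge_linker_copy <- function(linker_nt, divergence) {
  ch <- strsplit(linker_nt, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < divergence * 0.5
  for (i in which(hit)) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# resample linker-copy bases of any in-frame ATG/stop codon they created
clean_linker_copy_frame <- function(der_cds) {
  lc_span <- c(1016L, 1129L)
  repeat {
    bad <- integer(0)
    for (k in setdiff(2L:470L, 288L)) { # codon 288 is the planted rescue ATG
      if (codon_at(der_cds, k) %in% c("ATG", STOP_CODONS)) bad <- c(bad, k)
    }
    if (!length(bad)) return(der_cds)
    for (k in bad) {
      nts <- (3L * k - 2L):(3L * k)
      inside <- nts[nts >= lc_span[1] & nts <= lc_span[2]]
      if (!length(inside))
        stop("internal error: illegal codon outside the linker copy")
      for (i in inside)
        der_cds <- set_substr(der_cds, i, sample(c("A", "C", "G", "T"), 1))
    }
  }
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf(
    "truth manifest (seed %d): derived 11-exon locus, copy divergence %.2f\n",
    x$seed, x$params$copy_divergence))
  cat(sprintf("  dyad His%d/Cys%d, rescue Met at residue %d (exon %d)\n",
              x$dyad["his"], x$dyad["cys"], x$rescue$met_residue,
              x$rescue$exon))
  if (!is.null(x$lesions)) {
    cat("  lesions:\n"); print.data.frame(x$lesions, row.names = FALSE)
  }
  invisible(x)
}

#' Inject lesions into a gene locus
#'
#' Applies deletions, insertions, substitutions or a dyad knockout to the
#' coding sequence of a plus-strand gene model, updating the model
#' coordinates, and records the expected downstream consequences (frame
#' shift, first out-of-frame stop from direct translation) in the manifest.
#'
#' @param locus genomic [nuc_seq()].
#' @param model plus-strand [gene_model()].
#' @param lesions data frame with columns `type`
#'   (`deletion`/`insertion`/`substitution`/`dyad_knockout`), `exon`,
#'   `position` (1-based offset within the exon's coding interval), `length`,
#'   and `alt` (inserted/replacement bases; ignored for deletions). A
#'   `dyad_knockout` row may leave `exon`/`position` empty when `manifest`
#'   carries dyad coordinates (the catalytic Cys codon is then mutated to
#'   alanine).
#' @param manifest optional `truth_manifest` to update.
#' @return List with mutated `locus`, updated `model` and `manifest` (the
#'   manifest gains `lesions` and `expected_status`).
#' @export
inject_lesions <- function(locus, model, lesions, manifest = NULL) {
  if (model$strand != "+") stop("lesion injection supports + strand models")
  lesions <- as.data.frame(lesions)
  if (is.null(lesions$alt)) lesions$alt <- NA_character_
  if (is.null(lesions$length)) lesions$length <- 1L
  cl <- coding_lengths(model)
  cum <- cumsum(cl)

  # resolve dyad knockouts to a concrete substitution (catalytic Cys -> Ala)
  for (r in seq_len(nrow(lesions))) {
    if (lesions$type[r] == "dyad_knockout") {
      if (is.null(manifest)) stop("dyad_knockout needs a truth manifest")
      cys_cds <- 3L * manifest$dyad[["cys"]] - 2L
      ex <- which(cum >= cys_cds)[1]
      lesions$exon[r] <- model$exons$index[ex]
      lesions$position[r] <- cys_cds - c(0L, cum)[ex]
      lesions$length[r] <- 3L
      lesions$alt[r] <- "GCC"
      lesions$type[r] <- "substitution"
    }
  }

  s <- seq_string(locus)
  ex <- model$exons
  g_pos <- integer(nrow(lesions))
  for (r in seq_len(nrow(lesions))) {
    k <- which(ex$index == lesions$exon[r])
    if (!length(k) || is.na(ex$coding_start[k]))
      stop("lesion exon is not a coding exon: ", lesions$exon[r])
    width <- ex$coding_end[k] - ex$coding_start[k] + 1L
    p <- lesions$position[r]; L <- lesions$length[r]
    if (p < 1 || p + L - 1L > width)
      stop("lesion outside the exon's coding interval (splice sites are out of modelled scope)")
    g_pos[r] <- ex$coding_start[k] + p - 1L
  }
  o <- order(g_pos, decreasing = TRUE)
  for (r in o) {
    g <- g_pos[r]; L <- lesions$length[r]
    shift <- 0L
    if (lesions$type[r] == "deletion") {
      s <- paste0(substr(s, 1, g - 1L), substr(s, g + L, nchar(s)))
      shift <- -L
    } else if (lesions$type[r] == "insertion") {
      s <- paste0(substr(s, 1, g), lesions$alt[r], substr(s, g + 1L, nchar(s)))
      shift <- L
    } else if (lesions$type[r] == "substitution") {
      s <- set_substr(s, g, lesions$alt[r])
    } else stop("unknown lesion type: ", lesions$type[r])
    if (shift != 0L) {
      adj <- function(v) ifelse(!is.na(v) & v > g, v + shift, v)
      ex$genomic_start <- adj(ex$genomic_start)
      ex$genomic_end <- adj(ex$genomic_end)
      ex$coding_start <- adj(ex$coding_start)
      ex$coding_end <- adj(ex$coding_end)
    }
  }
  new_model <- gene_model(model$gene_id, model$seq_id, "+", ex,
                          model$start_codon_exon)
  new_locus <- nuc_seq(locus$id, s, locus$description)
  if (!is.null(manifest)) {
    manifest$lesions <- lesions
    manifest$expected_status <- expected_status_simulation(
      new_model, new_locus, lesions, manifest)
  }
  list(locus = new_locus, model = new_model, manifest = manifest)
}

# direct simulation of the expected verdict from first principles:
# translation of the mutant CDS + frame arithmetic on the manifest truth
expected_status_simulation <- function(model, locus, lesions, manifest) {
  cds <- spliced_cds(model, locus)$seq
  n <- nchar(cds$residues)
  tr <- translate_cds(cds, 0, to_first_stop = TRUE)
  premature <- tr$stop_found && (tr$stop_codon_index + 1L) < n %/% 3L
  if (!premature) {
    # frame reaches the terminal stop; check the dyad by direct inspection
    net_before <- function(res_pos) {
      cds_pos <- 3L * res_pos - 2L
      sum(ifelse(lesions$type == "deletion", -lesions$length,
                 ifelse(lesions$type == "insertion", lesions$length, 0L)) *
            (lesion_cds_pos(model, lesions) < cds_pos))
    }
    pep <- tr$peptide$residues
    his_at <- manifest$dyad[["his"]] + net_before(manifest$dyad[["his"]]) %/% 3L
    cys_at <- manifest$dyad[["cys"]] + net_before(manifest$dyad[["cys"]]) %/% 3L
    dyad_ok <- his_at >= 1 && cys_at <= nchar(pep) &&
      substr(pep, his_at, his_at) == "H" && substr(pep, cys_at, cys_at) == "C"
    return(if (dyad_ok) "intact" else "pseudogene")
  }
  # premature stop: rescued only if skipping the (single) lesion exon
  # restores the frame, or the rescue ORF precedes the catalytic domain
  fs <- lesions[lesions$type %in% c("deletion", "insertion") &
                  lesions$length %% 3L != 0L, , drop = FALSE]
  # pre-lesion coding width of an exon: mutant width with events undone
  ref_width <- function(exon) {
    k <- which(model$exons$index == exon)
    w <- coding_lengths(model)[k]
    here <- lesions$exon == exon
    w + sum(lesions$length[here & lesions$type == "deletion"]) -
      sum(lesions$length[here & lesions$type == "insertion"])
  }
  skip_ok <- nrow(fs) > 0 && length(unique(fs$exon)) == 1L &&
    ref_width(unique(fs$exon)) %% 3L == 0L
  rescue_ok <- manifest$rescue$met_residue <= manifest$domain_window[1]
  if (skip_ok || rescue_ok) "truncated_coding" else "pseudogene"
}

lesion_cds_pos <- function(model, lesions) {
  cl <- coding_lengths(model)
  cum <- cumsum(c(0L, cl))
  vapply(seq_len(nrow(lesions)), function(r) {
    k <- which(model$exons$index == lesions$exon[r])
    cum[k] + lesions$position[r]
  }, numeric(1))
}

#' Diverge an ortholog copy of a sequence
#'
#' Produces a mutated copy of a sequence under per-site substitution and
#' indel probabilities, together with the truth list of injected events
#' (left-aligned, on reference coordinates) and the expected identity.
#' Indels have length 1-3, are kept at least `min_sep` bases apart and never
#' touch protected intervals.
#'
#' @param locus reference [nuc_seq()].
#' @param p_sub per-site substitution probability (0-0.3).
#' @param p_indel per-site indel probability.
#' @param seed RNG seed.
#' @param protect optional data frame of 1-based inclusive intervals
#'   (`start`, `end`) that must not be mutated (e.g. coding segments or the
#'   dyad codons).
#' @param min_sep minimum spacing between injected indels.
#' @return List with `seq` (mutated [nuc_seq()]), `events` (truth
#'   `indel_events` frame) and `expected_identity` (percent, substitution
#'   component only).
#' @export
diverge_orthologs <- function(locus, p_sub, p_indel = 0, seed = NULL,
                              protect = NULL, min_sep = 20L) {
  if (p_sub < 0 || p_sub > 0.3) stop("p_sub must be within [0, 0.3]")
  if (p_indel < 0 || p_indel > 0.05) stop("p_indel must be within [0, 0.05]")
  run <- function() {
    ref <- seq_string(locus)
    n <- nchar(ref)
    protected <- rep(FALSE, n)
    if (!is.null(protect) && nrow(protect))
      for (r in seq_len(nrow(protect)))
        protected[protect$start[r]:protect$end[r]] <- TRUE
    # choose indel sites first; substitutions are then kept clear of them
    # (an indel with a substitution in its immediate neighbourhood is not
    # identifiable from a pairwise alignment, so the truth would be ill-posed)
    chosen <- integer(0)
    n_indel <- stats::rbinom(1, n, p_indel)
    if (n_indel > 0) {
      candidates <- sample(n)
      for (p in candidates) {
        if (length(chosen) >= n_indel) break
        if (p <= min_sep || p + min_sep + 3L > n) next
        if (any(abs(chosen - p) < min_sep)) next
        if (any(protected[max(1, p - 3L):min(n, p + 6L)])) next
        chosen <- c(chosen, p)
      }
    }
    near_indel <- rep(FALSE, n)
    for (p in chosen)
      near_indel[max(1, p - 5L):min(n, p + 8L)] <- TRUE
    ch <- strsplit(ref, "", fixed = TRUE)[[1]]
    subs <- which(runif(n) < p_sub & !protected & !near_indel)
    for (i in subs) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    mutated <- paste(ch, collapse = "")

    events <- data.frame(kind = character(), ref_pos = integer(),
                         length = integer(), frame_shift = integer(),
                         seq = character())
    if (length(chosen) > 0) {
      chosen <- sort(chosen, decreasing = TRUE)
      for (p in chosen) {
        L <- sample(1:3, 1)
        if (runif(1) < 0.5) { # deletion of ref[p+1 .. p+L]
          alt <- substr(ref, p + 1L, p + L)
          mutated <- paste0(substr(mutated, 1, p),
                            substr(mutated, p + L + 1L, nchar(mutated)))
          la <- left_align_indel(ref, p, alt)
          events <- rbind(events, data.frame(
            kind = "deletion", ref_pos = la$ref_pos, length = L,
            frame_shift = L %% 3L, seq = la$seq))
        } else { # insertion after ref[p]
          alt <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = "")
          mutated <- paste0(substr(mutated, 1, p), alt,
                            substr(mutated, p + 1L, nchar(mutated)))
          la <- left_align_indel(ref, p, alt)
          events <- rbind(events, data.frame(
            kind = "insertion", ref_pos = la$ref_pos, length = L,
            frame_shift = L %% 3L, seq = la$seq))
        }
      }
    }
    events <- events[order(events$ref_pos, events$kind), , drop = FALSE]
    rownames(events) <- NULL
    class(events) <- c("indel_events", "data.frame")
    list(seq = nuc_seq(paste0(locus$id, "_ortholog"), mutated),
         events = events,
         expected_identity = 100 * (1 - p_sub))
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Simulate a pseudogenization scenario
#'
#' Generates a derived caspase-16-like locus as the intact reference
#' ("chimpanzee-like") ortholog and a query ("human-like") copy carrying a
#' defined lesion scenario on a background of non-coding divergence.
#'
#' Scenarios: `"human-casp16p"` (the 1-nt deletion in exon 3; expected
#' verdict pseudogene), `"inframe-deletion"` (3-nt deletion, intact),
#' `"dyad-knockout"` (catalytic Cys to Ala, pseudogene),
#' `"compensated-indels"` (-1 then +1 in exon 3, intact), `"none"` (no
#' lesion).
#'
#' @param seed integer seed.
#' @param scenario scenario name.
#' @param p_sub_noncoding substitution rate applied outside coding segments
#'   and splice dinucleotides (human-chimp scale by default).
#' @param copy_divergence forwarded to [generate_caspase16_like_locus()].
#' @return List with `reference` (list: locus, model, protein), `query`
#'   (list: locus, model) and `manifest` (with `lesions` and
#'   `expected_status` filled in for lesion scenarios).
#' @export
simulate_pseudogene_scenario <- function(seed,
                                         scenario = c("human-casp16p",
                                                      "inframe-deletion",
                                                      "dyad-knockout",
                                                      "compensated-indels",
                                                      "none"),
                                         p_sub_noncoding = 0.01,
                                         copy_divergence = 0.4) {
  scenario <- match.arg(scenario)
  gen <- generate_caspase16_like_locus(seed, copy_divergence = copy_divergence)
  ref <- gen
  # protect coding intervals and the splice dinucleotides flanking each exon
  ex <- gen$model$exons
  prot <- data.frame(start = ex$coding_start[!is.na(ex$coding_start)],
                     end = ex$coding_end[!is.na(ex$coding_end)])
  splice <- data.frame(start = c(ex$genomic_end + 1L, ex$genomic_start - 2L),
                       end = c(ex$genomic_end + 2L, ex$genomic_start - 1L))
  prot <- rbind(prot, splice)
  div <- diverge_orthologs(gen$locus, p_sub = p_sub_noncoding, p_indel = 0,
                           seed = seed + 1000003L, protect = prot)
  qlocus <- nuc_seq("query_locus", div$seq$residues)
  qmodel <- gen$model
  qmodel$gene_id <- "CASP16P_like"
  qmodel$seq_id <- "query_locus"

  lesions <- switch(scenario,
    "human-casp16p" = data.frame(type = "deletion", exon = 3L,
                                 position = 156L, length = 1L),
    "inframe-deletion" = data.frame(type = "deletion", exon = 3L,
                                    position = 156L, length = 3L),
    "dyad-knockout" = data.frame(type = "dyad_knockout", exon = NA_integer_,
                                 position = NA_integer_, length = NA_integer_),
    "compensated-indels" = data.frame(
      type = c("deletion", "insertion"), exon = c(3L, 3L),
      position = c(156L, 171L), length = c(1L, 1L),
      alt = c(NA_character_, "A")),
    "none" = NULL)
  manifest <- gen$manifest
  if (!is.null(lesions)) {
    inj <- inject_lesions(qlocus, qmodel, lesions, manifest)
    qlocus <- inj$locus; qmodel <- inj$model; manifest <- inj$manifest
  } else {
    manifest$expected_status <- "intact"
  }
  list(reference = list(locus = ref$locus, model = ref$model,
                        protein = gen$manifest$derived_protein),
       query = list(locus = qlocus, model = qmodel),
       manifest = manifest, scenario = scenario)
}

#' Random multi-exon coding gene (property-test workhorse)
#'
#' Generates a small plus-strand gene whose CDS starts with ATG, ends with a
#' stop codon and contains no internal in-frame stop, split across exons of
#' random (not frame-aligned) coding lengths.
#'
#' @param seed integer seed.
#' @param n_exons number of exons (all coding).
#' @param codon_range range of the number of sense codons.
#' @param gc GC content of introns.
#' @return List with `locus`, `model`.
#' @export
random_coding_gene <- function(seed, n_exons = 5, codon_range = c(40L, 80L),
                               gc = 0.45) {
  local_seed(seed, {
    n_codons <- sample(seq(codon_range[1], codon_range[2]), 1)
    cds <- paste(c("ATG", sample_codons(n_codons - 1L), "TAA"), collapse = "")
    total <- nchar(cds)
    # exon widths >= 15 nt so interior lesions stay placeable; additionally,
    # no single-exon skip may fuse two partial codons into an incidental
    # stop, so that frame restoration depends on phase arithmetic alone
    repeat {
      cuts <- sort(sample(seq_len(total - 1L), n_exons - 1L))
      widths <- diff(c(0L, cuts, total))
      if (any(widths < 15L)) next
      cum <- cumsum(widths)
      junction_stop <- FALSE
      for (k in seq_len(n_exons - 2L) + 1L) {
        if (widths[k] %% 3L != 0L) next # frame-shifting skip: stop expected
        iso <- paste0(substr(cds, 1L, cum[k - 1L]),
                      substr(cds, cum[k] + 1L, total))
        aa <- translate_cds(iso, 0, to_first_stop = TRUE)
        if (aa$stop_found &&
            (aa$stop_codon_index + 1L) < nchar(iso) %/% 3L) {
          junction_stop <- TRUE
          break
        }
      }
      if (!junction_stop) break
    }
    assemble_locus("randgene", "rand_locus", cds, widths, gc,
                   intron_range = c(40L, 80L), utr_exon1 = 0L,
                   utr5 = 0L, utr3 = 0L, flank = 10L)[c("locus", "model")]
  })
}
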