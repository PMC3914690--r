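#' Default thresholds for pseudogene classification
#'
#' The rule set used to call a derived CDS intact or pseudogenized against
#' its reference ortholog: an ORF passes the fast path when it shows more
#' than 90% protein identity over more than 80% of the reference length
#' with no inactivating mutation; otherwise the search is repeated with
#' flanking context (default 2,500 nt on either end) to catch mis-annotated
#' boundaries, and the final span rule admits as intact only ORFs spanning
#' more than 99% of the reference ORF (more than 90% for reference ORFs
#' under 300 nt) with no inactivating mutation.
#'
#' @param min_identity Fast-path protein identity threshold (fraction).
#' @param min_length_fraction Fast-path aligned-length threshold (fraction).
#' @param span_long Span threshold for ORFs >= `short_orf_nt` (fraction).
#' @param span_short Span threshold for shorter ORFs (fraction).
#' @param short_orf_nt Reference ORF size (nt) below which `span_short`
#'   applies.
#' @param context_nt Flanking context added on either end of the candidate
#'   ORF during the extended search.
#' @return Named list of thresholds.
#' @export
classify_thresholds <- function(min_identity = 0.9,
                                min_length_fraction = 0.8,
                                span_long = 0.99, span_short = 0.90,
                                short_orf_nt = 300L, context_nt = 2500L) {
  list(min_identity = min_identity,
       min_length_fraction = min_length_fraction,
       span_long = span_long, span_short = span_short,
       short_orf_nt = short_orf_nt, context_nt = context_nt)
}

START_CODONS <- c("ATG", "GTG", "TTG")

# cached nucleotide scoring matrix (avoids per-call matrix construction)
dna_submat <- function() {
  if (is.null(.symdegen_cache$dna_submat)) {
    .symdegen_cache$dna_submat <-
      Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                               baseOnly = FALSE)
  }
  .symdegen_cache$dna_submat
}

# global (in pattern) / local (in subject) DNA alignment, returned as the
# two gapped strings
align_dna <- function(pattern, subject, type = "global-local",
                      gapOpening = 8, gapExtension = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = type, substitutionMatrix = dna_submat(),
    gapOpening = gapOpening, gapExtension = gapExtension)
  pat <- Biostrings::pattern(aln)
  sa <- strsplit(as.character(pat), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  # the fast extractors clip pattern overhangs; restore them as terminal
  # deletions so the pattern is represented globally
  p_start <- Biostrings::start(pat)
  p_end <- Biostrings::end(pat)
  if (p_start > 1L) {
    pre <- strsplit(substr(pattern, 1L, p_start - 1L), "")[[1]]
    sa <- c(pre, sa)
    sb <- c(rep("-", length(pre)), sb)
  }
  if (p_end < nchar(pattern)) {
    post <- strsplit(substr(pattern, p_end + 1L, nchar(pattern)), "")[[1]]
    sa <- c(sa, post)
    sb <- c(sb, rep("-", length(post)))
  }
  list(sa = sa, sb = sb)
}

is_valid_orf <- function(cds) {
  n <- nchar(cds)
  n >= 6L && n %% 3L == 0L &&
    substr(cds, 1L, 3L) %in% START_CODONS &&
    substr(cds, n - 2L, n) %in% STOP_CODONS &&
    !any(split_codons(substr(cds, 1L, n - 3L)) %in% STOP_CODONS)
}

#' Detect inactivating mutations in a derived coding sequence
#'
#' Aligns a derived sequence (optionally carrying flanking context) against
#' an intact reference ORF and reports every inactivating mutation:
#' \describe{
#'   \item{frameshift_indel}{an indel whose length is not a multiple of 3,
#'     reported at the first affected reference codon. Compensating indels
#'     that restore the frame downstream are still reported individually.}
#'   \item{premature_stop}{an in-frame stop codon (frame offset zero at
#'     that codon) upstream of the reference stop. Stops within the final
#'     three codons before the reference stop are ignored as stop-adjacent
#'     noise.}
#'   \item{truncation}{loss of a substantial 3' portion of the ORF: either
#'     a long deletion reaching the reference 3' end, or a premature stop
#'     after which the remaining sequence no longer resembles the
#'     reference.}
#'   \item{is_interruption}{an insertion inside the ORF that matches an
#'     element of the supplied IS library.}
#' }
#'
#' @param der_seq Derived sequence in coding orientation, optionally with
#'   flanking context.
#' @param ref_cds Reference ORF (start codon, in-frame, terminal stop).
#' @param is_library Optional named character vector of IS consensus
#'   sequences used to recognise IS interruptions.
#' @return Tibble with columns `type`, `position_codon`, `detail`, sorted
#'   by codon position. Zero rows when the derived sequence is cleanly
#'   intact.
#' @export
detect_mutations <- function(der_seq, ref_cds, is_library = NULL,
                             .aln = NULL) {
  if (!is_valid_orf(ref_cds)) {
    abort("reference is not a valid ORF (start codon, in-frame, terminal stop)")
  }
  muts <- list()
  # IS elements inside the sequence are found by homology and excised
  # before alignment: a linear-gap aligner will not open a kilobase gap,
  # so interruptions must be recognised up front
  if (!is.null(is_library)) {
    exc <- excise_is_segments(der_seq, is_library)
    if (length(exc$junctions)) {
      der_seq <- exc$seq
      .aln <- NULL
    }
  } else {
    exc <- list(junctions = integer())
  }
  aln <- .aln %||% align_dna(ref_cds, der_seq)
  sa <- aln$sa
  sb <- aln$sb
  ref_len <- nchar(ref_cds)
  n_cod <- ref_len %/% 3L
  ref_pos <- cumsum(sa != "-")           # ref coordinate per column
  if (length(exc$junctions)) {
    der_pos <- cumsum(sb != "-")
    for (jn in exc$junctions) {
      col <- which(der_pos >= jn)[1] %||% length(der_pos)
      if (is.na(col)) col <- length(der_pos)
      codon <- min(max(ref_pos[col], 1L) %/% 3L + 1L, n_cod)
      muts[[length(muts) + 1L]] <- tibble(
        type = "is_interruption", position_codon = codon,
        detail = "IS library element excised at this junction")
    }
  }
  # --- indel runs ---
  runs <- indel_runs(sa, sb)
  for (k in seq_len(nrow(runs))) {
    r <- runs[k, ]
    codon <- min((max(ref_pos[r$from], 1L) - 1L) %/% 3L + 1L, n_cod)
    if (r$what == "del") {
      terminal3 <- ref_pos[r$to] >= ref_len - 3L
      terminal5 <- ref_pos[r$from] <= 4L
      if (terminal3 && r$len >= 60L) {
        muts[[length(muts) + 1L]] <- tibble(
          type = "truncation", position_codon = codon,
          detail = sprintf("deletion of %d nt reaching the reference 3' end",
                           r$len))
        next
      }
      # ragged alignment ends are not frameshifts: nothing downstream
      # (or upstream) of a terminal deletion is shifted out of frame
      if (terminal3 || terminal5) next
    }
    if (r$len %% 3L != 0L) {
      muts[[length(muts) + 1L]] <- tibble(
        type = "frameshift_indel", position_codon = codon,
        detail = sprintf("%s of %d nt",
                         if (r$what == "ins") "insertion" else "deletion",
                         r$len))
    }
  }
  # --- in-frame premature stops ---
  offset <- frame_offset(sa, sb)
  der_in_ref <- sb[sa != "-"]
  off_in_ref <- offset[sa != "-"]
  for (cod in seq_len(max(0L, n_cod - 4L))) {
    cols <- (3L * cod - 2L):(3L * cod)
    trip <- der_in_ref[cols]
    if (any(trip == "-")) next
    if (off_in_ref[cols[1]] %% 3L != 0L) next
    codon_str <- paste(trip, collapse = "")
    if (codon_str %in% STOP_CODONS) {
      # is the downstream still recognisably the reference gene?
      down <- which(sa != "-")
      down_cols <- down[ref_pos[down] > 3L * cod & ref_pos[down] <= ref_len]
      down_id <- if (length(down_cols) >= 30L) {
        mean(sa[down_cols] == sb[down_cols])
      } else 1
      if (down_id < 0.6) {
        muts[[length(muts) + 1L]] <- tibble(
          type = "truncation", position_codon = cod,
          detail = sprintf("premature stop %s with diverged 3' remainder",
                           codon_str))
      } else {
        muts[[length(muts) + 1L]] <- tibble(
          type = "premature_stop", position_codon = cod,
          detail = sprintf("stop codon %s", codon_str))
      }
    }
  }
  if (!length(muts)) {
    return(tibble(type = character(), position_codon = integer(),
                  detail = character()))
  }
  bind_rows(muts) %>% distinct() %>% arrange(.data$position_codon)
}

# runs of gap characters in either aligned string
indel_runs <- function(sa, sb) {
  out <- list()
  collect <- function(gaps, what) {
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    if (length(idx)) {
      tibble(from = starts[idx], to = ends[idx],
             len = r$lengths[idx], what = what)
    } else NULL
  }
  bind_rows(collect(sa == "-", "ins"), collect(sb == "-", "del")) %||%
    tibble(from = integer(), to = integer(), len = integer(),
           what = character())
}

# net (insertion - deletion) nt preceding each alignment column
frame_offset <- function(sa, sb) {
  ins <- cumsum(sa == "-")
  del <- cumsum(sb == "-")
  c(0L, (ins - del)[-length(sa)])
}

# locate IS library elements embedded in a sequence (exact k-mer seeding,
# both strands) and remove them; returns the excised sequence and the
# 0-based junction positions in post-excision coordinates
excise_is_segments <- function(seq, is_library) {
  hits <- list()
  for (fam in names(is_library)) {
    h <- seed_candidates(seq, is_library[[fam]])
    if (nrow(h)) hits[[fam]] <- h
  }
  hits <- bind_rows(hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(seq = seq, junctions = integer()))
  }
  hits <- arrange(hits, dplyr::desc(.data$start))
  junctions <- integer()
  removed <- 0L
  for (i in seq_len(nrow(hits))) {
    seq <- paste0(substr(seq, 1L, hits$start[i]),
                  substr(seq, hits$end[i] + 1L, nchar(seq)))
  }
  # junction positions after all excisions (hits sorted by start desc)
  starts <- rev(hits$start)
  lens <- rev(hits$end - hits$start)
  shift <- c(0L, cumsum(lens))[seq_along(starts)]
  list(seq = seq, junctions = as.integer(starts - shift))
}

#' Classify one derived CDS against its reference ortholog
#'
#' Applies the three-stage rule set (see [classify_thresholds()]): fast
#' path on identity/length with no mutations; extended search with flanking
#' context; final span rule. The verdict is `intact` only when no
#' inactivating mutation is present and the span requirement holds.
#'
#' @param ref_locus,der_locus Locus tags of a reciprocal ortholog pair.
#' @param der,ref [annotated_genome()] objects.
#' @param thresholds List from [classify_thresholds()].
#' @param is_library Optional IS consensus library (named character
#'   vector) for typing IS interruptions.
#' @return One-row tibble: `der_locus`, `ref_locus`, `verdict`,
#'   `rule_fired`, `protein_identity`, `length_fraction`, `n_mutations`
#'   and a `mutations` list-column of [detect_mutations()] tables.
#' @export
classify_cds <- function(ref_locus, der_locus, der, ref,
                         thresholds = classify_thresholds(),
                         is_library = NULL) {
  th <- thresholds
  ref_cds <- cds_seq(ref, ref_locus)
  if (!is_valid_orf(ref_cds)) {
    abort(sprintf("reference ORF %s is not a valid ORF", ref_locus))
  }
  ref_len <- nchar(ref_cds)
  der_cds <- cds_seq(der, der_locus)
  aln0 <- align_dna(ref_cds, der_cds)
  muts <- detect_mutations(der_cds, ref_cds, is_library = is_library,
                           .aln = aln0)
  p_ident <- aa_identity_from_aln(aln0)
  lf <- aligned_span(ref_cds, der_cds, .aln = aln0)
  if (p_ident > th$min_identity && lf > th$min_length_fraction &&
      nrow(muts) == 0L) {
    return(classification_row(der_locus, ref_locus, "intact", "fast_path",
                              p_ident, lf, muts))
  }
  span_th <- if (ref_len < th$short_orf_nt) th$span_short else th$span_long
  rule <- if (ref_len < th$short_orf_nt) "short_orf_rule" else "span_rule"
  if (lf > span_th) {
    # the annotated sequence already spans the reference ORF, so the
    # context extension cannot change the outcome; apply the span rule
    # to the fast-path alignment directly
    if (nrow(muts) == 0L) {
      return(classification_row(der_locus, ref_locus, "intact", rule,
                                p_ident, lf, muts))
    }
    return(classification_row(der_locus, ref_locus, "pseudogene",
                              "extended_search", p_ident, lf, muts))
  }
  # extended search with flanking context
  fi <- match(der_locus, der$features$locus_tag)
  f <- der$features[fi, ]
  ext_seq <- context_seq(der, f, th$context_nt)
  aln1 <- align_dna(ref_cds, ext_seq)
  muts_ext <- detect_mutations(ext_seq, ref_cds, is_library = is_library,
                               .aln = aln1)
  span <- aligned_span(ref_cds, ext_seq, .aln = aln1)
  if (nrow(muts_ext) == 0L && span > span_th) {
    return(classification_row(der_locus, ref_locus, "intact", rule,
                              p_ident, span, muts_ext))
  }
  classification_row(der_locus, ref_locus, "pseudogene",
                     if (nrow(muts_ext) > 0L) "extended_search" else rule,
                     p_ident, span, muts_ext)
}

classification_row <- function(der_locus, ref_locus, verdict, rule,
                               identity, lf, muts) {
  tibble(der_locus = der_locus, ref_locus = ref_locus, verdict = verdict,
         rule_fired = rule, protein_identity = identity,
         length_fraction = lf, n_mutations = nrow(muts),
         mutations = list(muts))
}

# protein identity of the in-frame, ungapped codon columns of a
# reference-anchored nucleotide alignment
aa_identity_from_aln <- function(aln) {
  sa <- aln$sa; sb <- aln$sb
  keep <- sa != "-"
  off <- frame_offset(sa, sb)[keep]
  ra <- sa[keep]; rb <- sb[keep]
  n_cod <- length(ra) %/% 3L
  if (n_cod < 1L) return(0)
  idx <- seq_len(3L * n_cod)
  ca <- matrix(ra[idx], nrow = 3L)
  cb <- matrix(rb[idx], nrow = 3L)
  ok <- colSums(cb == "-") == 0L & off[seq(1L, 3L * n_cod, 3L)] %% 3L == 0L
  if (!any(ok)) return(0)
  gc_map <- Biostrings::GENETIC_CODE
  aa_a <- gc_map[paste0(ca[1, ok], ca[2, ok], ca[3, ok])]
  aa_b <- gc_map[paste0(cb[1, ok], cb[2, ok], cb[3, ok])]
  mean(!is.na(aa_a) & !is.na(aa_b) & aa_a == aa_b)
}

# fraction of reference positions aligned to a residue of the derived seq
aligned_span <- function(ref_cds, der_seq, .aln = NULL) {
  aln <- .aln %||% align_dna(ref_cds, der_seq)
  sum(aln$sa != "-" & aln$sb != "-") / nchar(ref_cds)
}

context_seq <- function(genome, f, ctx) {
  L <- genome_length(genome)
  width <- f$end - f$start
  start <- f$start - ctx
  end <- f$end + ctx
  if (genome$circular) {
    start_m <- start %% L
    return(feature_seq(genome, start_m, start_m + width + 2L * ctx,
                       f$strand))
  }
  feature_seq(genome, max(0L, start), min(L, end), f$strand)
}

#' Classify every derived CDS in a genome
#'
#' Runs [classify_cds()] over a table of reciprocal ortholog pairs and
#' reports per-CDS verdicts plus genome totals. Derived CDS features
#' without a reciprocal ortholog are reported as `unresolved` and excluded
#' from the pseudogene fraction denominator.
#'
#' @param der,ref [annotated_genome()] objects.
#' @param pairs Tibble from [find_orthologs()].
#' @param thresholds List from [classify_thresholds()].
#' @param is_library Optional IS consensus library.
#' @return Object of class `classification_report`: list with `per_cds`
#'   (tibble) and `totals` (one-row tibble with `n_cds`, `n_intact`,
#'   `n_pseudo`, `n_unresolved`, `fraction_pseudo`).
#' @export
classify_genome <- function(der, ref, pairs,
                            thresholds = classify_thresholds(),
                            is_library = NULL) {
  cand <- ortho_candidates(der)
  pairs <- dplyr::filter(pairs, .data$reciprocal)
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    dl <- cand$locus_tag[i]
    j <- match(dl, pairs$der_locus)
    if (is.na(j)) {
      rows[[i]] <- classification_row(dl, NA_character_, "unresolved",
                                      "fast_path", NA_real_, NA_real_,
                                      detect_mutations("ATGTAA", "ATGAAATAA")[0, ])
    } else {
      rows[[i]] <- classify_cds(pairs$ref_locus[j], dl, der, ref,
                                thresholds, is_library)
    }
  }
  per_cds <- bind_rows(rows)
  n_int <- sum(per_cds$verdict == "intact")
  n_ps <- sum(per_cds$verdict == "pseudogene")
  totals <- tibble(
    n_cds = nrow(per_cds), n_intact = n_int, n_pseudo = n_ps,
    n_unresolved = sum(per_cds$verdict == "unresolved"),
    fraction_pseudo = if (n_int + n_ps > 0) n_ps / (n_int + n_ps) else NA_real_)
  structure(list(per_cds = per_cds, totals = totals),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<classification_report> %d CDS: %d intact, %d pseudogenes (%.1f%%), %d unresolved\n",
    t$n_cds, t$n_intact, t$n_pseudo, 100 * t$fraction_pseudo,
    t$n_unresolved))
  invisible(x)
}

#' @rdname classify_genome
#' @param x A `classification_report`.
#' @param ... Unused.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$per_cds

#' @rdname classify_genome
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) x$totals

#' Re-type classified pseudogenes in a genome's feature table
#'
#' Returns a copy of the genome whose CDS features called `pseudogene` by
#' a classification report carry kind `pseudogene`, ready for GFF3
#' emission with [write_genome()].
#'
#' @param genome The derived [annotated_genome()].
#' @param report A `classification_report` from [classify_genome()].
#' @return An [annotated_genome()] with re-typed features.
#' @export
retype_pseudogenes <- function(genome, report) {
  ps <- report$per_cds$der_locus[report$per_cds$verdict == "pseudogene"]
  f <- genome$features
  f$kind[f$locus_tag %in% ps & f$kind == "CDS"] <- "pseudogene"
  annotated_genome(genome$id, genome$sequence, f,
                   circular = genome$circular)
}
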