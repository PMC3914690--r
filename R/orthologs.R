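#' Map one-to-one orthologs between a reference and a derived genome
#'
#' Establishes reciprocal-best-hit (RBH) orthology between the CDS
#' complements of a free-living reference and a degenerating derived
#' genome, anchoring all downstream classification and substitution-rate
#' analysis. Protein translations are aligned globally
#' (Needleman-Wunsch, BLOSUM62); the best hit of every derived gene among
#' the reference genes and vice versa is computed, mutual best hits are
#' retained, and pairs below the identity or coverage thresholds are
#' discarded. Suitable at the low divergence (~2% synonymous) typical of a
#' nascent symbiont and its free-living sister lineage.
#'
#' Candidate pairs are pre-selected by exact 24-nt probe matching (several
#' probes per gene, both directions) purely to avoid the all-vs-all
#' quadratic alignment cost; best hits are decided on alignment score with
#' deterministic tie-breaking (higher identity, then lexicographic locus
#' tag).
#'
#' @param ref,der [annotated_genome()] objects. Features of kind `CDS` and
#'   `pseudogene` are candidates; IS elements and prophage are never
#'   considered.
#' @param min_identity Minimum protein identity (default 0.9).
#' @param min_coverage Minimum fraction of the reference protein aligned
#'   (default 0.8).
#' @return Tibble with columns `ref_locus`, `der_locus`,
#'   `protein_identity`, `coverage_ref`, `reciprocal`. Each locus appears
#'   in at most one reciprocal pair.
#' @export
find_orthologs <- function(ref, der, min_identity = 0.9,
                           min_coverage = 0.8) {
  rf <- ortho_candidates(ref)
  df <- ortho_candidates(der)
  if (nrow(rf) == 0L || nrow(df) == 0L) {
    warn("no CDS candidates in one of the genomes; empty ortholog set")
    return(tibble(ref_locus = character(), der_locus = character(),
                  protein_identity = numeric(), coverage_ref = numeric(),
                  reciprocal = logical()))
  }
  rseq <- vapply(rf$locus_tag, function(lt) cds_seq(ref, lt), character(1))
  dseq <- vapply(df$locus_tag, function(lt) cds_seq(der, lt), character(1))
  pairs <- candidate_pairs(rseq, dseq)
  if (nrow(pairs) == 0L) {
    return(tibble(ref_locus = character(), der_locus = character(),
                  protein_identity = numeric(), coverage_ref = numeric(),
                  reciprocal = logical()))
  }
  rprot <- vapply(rseq, translate_to_protein, character(1))
  dprot <- vapply(dseq, translate_to_protein, character(1))
  stats <- pmap(list(pairs$ri, pairs$di), function(ri, di) {
    protein_align_stats(rprot[[ri]], dprot[[di]])
  })
  pairs$score <- map_dbl(stats, "score")
  pairs$identity <- map_dbl(stats, "identity")
  pairs$coverage <- map_dbl(stats, "coverage")
  pairs$ref_locus <- rf$locus_tag[pairs$ri]
  pairs$der_locus <- df$locus_tag[pairs$di]
  best_for_der <- pairs %>%
    arrange(.data$di, dplyr::desc(.data$score), dplyr::desc(.data$identity),
            .data$ref_locus) %>%
    group_by(.data$di) %>% dplyr::slice(1) %>% ungroup()
  best_for_ref <- pairs %>%
    arrange(.data$ri, dplyr::desc(.data$score), dplyr::desc(.data$identity),
            .data$der_locus) %>%
    group_by(.data$ri) %>% dplyr::slice(1) %>% ungroup()
  rbh <- dplyr::inner_join(
    select(best_for_der, "ri", "di"),
    select(best_for_ref, "ri", "di"),
    by = c("ri", "di"))
  out <- dplyr::inner_join(pairs, rbh, by = c("ri", "di")) %>%
    dplyr::filter(.data$identity >= min_identity,
                  .data$coverage >= min_coverage) %>%
    mutate(reciprocal = TRUE) %>%
    select(ref_locus = "ref_locus", der_locus = "der_locus",
           protein_identity = "identity", coverage_ref = "coverage",
           "reciprocal") %>%
    arrange(.data$ref_locus)
  out
}

ortho_candidates <- function(genome) {
  dplyr::filter(genome$features, .data$kind %in% c("CDS", "pseudogene"))
}

# exact 24-nt probe pre-filter; returns tibble of candidate (ri, di) indices
candidate_pairs <- function(rseq, dseq, probe_len = 24L, n_probes = 5L) {
  probes_of <- function(s) {
    L <- nchar(s)
    if (L < probe_len) return(character())
    starts <- unique(round(seq(1L, L - probe_len + 1L,
                               length.out = min(n_probes, L - probe_len + 1L))))
    substring(s, starts, starts + probe_len - 1L)
  }
  hit_pairs <- function(qseqs, sseqs) {
    plist <- lapply(qseqs, probes_of)
    qidx <- rep(seq_along(plist), lengths(plist))
    probes <- unlist(plist, use.names = FALSE)
    keep <- !grepl("N", probes, fixed = TRUE)
    probes <- probes[keep]; qidx <- qidx[keep]
    if (!length(probes)) {
      return(tibble(q = integer(), s = integer()))
    }
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes))
    hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(sseqs))
    sidx <- rep(seq_along(hits), lengths(hits))
    qhit <- qidx[unlist(hits, use.names = FALSE)]
    distinct(tibble(q = qhit, s = sidx))
  }
  fwd <- hit_pairs(dseq, rseq)   # der probes vs ref genes
  rev <- hit_pairs(rseq, dseq)   # ref probes vs der genes
  distinct(bind_rows(
    tibble(ri = fwd$s, di = fwd$q),
    tibble(ri = rev$q, di = rev$s)))
}

# trims to a codon multiple and translates by table lookup; internal
# stops become '*', ambiguous codons 'X'
translate_to_protein <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return("")
  aa <- Biostrings::GENETIC_CODE[split_codons(substr(cds, 1L, n))]
  aa[is.na(aa)] <- "X"
  p <- paste(aa, collapse = "")
  sub("\\*$", "", p)
}

blosum62 <- function() {
  if (is.null(.symdegen_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .symdegen_cache$blosum62 <- e$BLOSUM62
  }
  .symdegen_cache$blosum62
}

protein_align_stats <- function(pa, pb) {
  if (nchar(pa) == 0L || nchar(pb) == 0L) {
    return(list(score = -Inf, identity = 0, coverage = 0))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  sa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  both <- sa != "-" & sb != "-"
  ident <- if (any(both)) mean(sa[both] == sb[both]) else 0
  cover <- sum(both) / nchar(pa)
  list(score = Biostrings::score(aln), identity = ident, coverage = cover)
}
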