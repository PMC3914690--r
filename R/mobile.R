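#' Annotate insertion-sequence elements from a consensus library
#'
#' Finds copies of each IS family consensus in the genome by exact 20-mer
#' seeding followed by per-candidate global alignment, keeping hits at or
#' above `min_identity` over at least `min_coverage` of the consensus
#' length. The transposase ORF of each copy is classified `intact` or
#' `disrupted` by running the inactivating-mutation detector against the
#' consensus ORF.
#'
#' @param genome An [annotated_genome()].
#' @param is_library Named character vector of family consensus sequences.
#' @param min_identity Minimum nucleotide identity to the consensus
#'   (default 0.94, the within-family identity floor typical of a recent
#'   expansion).
#' @param min_coverage Minimum consensus coverage (default 0.8).
#' @return Tibble: `family`, `start`, `end` (0-based half-open), `strand`,
#'   `identity`, `transposase_state`.
#' @export
annotate_is <- function(genome, is_library, min_identity = 0.94,
                        min_coverage = 0.8) {
  if (length(is_library) == 0L) abort("IS library is empty")
  if (is.null(names(is_library)) || any(!nzchar(names(is_library)))) {
    abort("IS library must be a named character vector")
  }
  out <- imap(as.list(is_library), function(cons, fam) {
    annotate_is_family(genome, cons, fam, min_identity, min_coverage)
  })
  res <- bind_rows(out)
  if (nrow(res)) res <- arrange(res, .data$start)
  res
}

annotate_is_family <- function(genome, cons, fam, min_identity,
                               min_coverage, k = 20L) {
  L <- genome_length(genome)
  clen <- nchar(cons)
  cand <- seed_candidates(genome$sequence, cons, k)
  if (nrow(cand) == 0L) {
    return(tibble(family = character(), start = integer(),
                  end = integer(), strand = character(),
                  identity = numeric(), transposase_state = character()))
  }
  orf <- consensus_orf(cons)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    s <- max(0L, cand$start[i] - 30L)
    e <- min(L, cand$end[i] + 30L)
    region <- substr(genome$sequence, s + 1L, e)
    qry <- if (cand$strand[i] == "-") revcomp(region) else region
    al <- align_dna(cons, qry)
    pa <- al$sa
    pb <- al$sb
    both <- pa != "-" & pb != "-"
    # identity over all alignment columns, so indels count as differences
    ident <- sum(pa == pb & pa != "-") / length(pa)
    cover <- sum(both) / clen
    if (ident < min_identity || cover < min_coverage) next
    state <- if (is.null(orf)) "intact" else {
      muts <- detect_mutations(qry, orf)
      if (nrow(muts)) "disrupted" else "intact"
    }
    rows[[length(rows) + 1L]] <- tibble(
      family = fam, start = s, end = e, strand = cand$strand[i],
      identity = ident, transposase_state = state)
  }
  res <- bind_rows(rows)
  if (nrow(res) > 1L) {
    # collapse overlapping candidate windows for the same family
    res <- arrange(res, .data$start)
    keep <- c(TRUE, res$start[-1] >= res$end[-nrow(res)] - 30L)
    res <- res[keep, , drop = FALSE]
  }
  res
}

# exact k-mer seeding of a consensus against both genome strands,
# chained into candidate intervals
seed_candidates <- function(seq, cons, k = 20L) {
  clen <- nchar(cons)
  # probe dictionaries are cached per consensus: the same IS library is
  # scanned once per gene during classification
  key <- paste0(k, "|", cons)
  if (is.null(.symdegen_cache$pdicts)) {
    .symdegen_cache$pdicts <- new.env(parent = emptyenv())
  }
  cached <- .symdegen_cache$pdicts[[key]]
  if (is.null(cached)) {
    starts <- seq.int(1L, clen - k + 1L, by = max(1L, k %/% 2L))
    probes <- substring(cons, starts, starts + k - 1L)
    ok <- !grepl("N", probes, fixed = TRUE)
    probes <- probes[ok]; starts <- starts[ok]
    if (!length(probes)) {
      return(tibble(start = integer(), end = integer(),
                    strand = character()))
    }
    cached <- list(pd = Biostrings::PDict(Biostrings::DNAStringSet(probes)),
                   starts = starts)
    .symdegen_cache$pdicts[[key]] <- cached
  }
  pd <- cached$pd
  starts <- cached$starts
  subject <- Biostrings::DNAString(seq)
  L <- nchar(seq)
  hit_one <- function(subj, strand) {
    hits <- Biostrings::matchPDict(pd, subj)
    n <- lengths(hits)
    if (sum(n) == 0L) return(NULL)
    gpos <- unlist(lapply(hits, Biostrings::start), use.names = FALSE) - 1L
    cpos <- rep(starts - 1L, n)
    tibble(gpos = gpos, cpos = cpos, strand = strand)
  }
  m <- bind_rows(hit_one(subject, "+"),
                 hit_one(Biostrings::reverseComplement(subject), "-"))
  if (is.null(m) || nrow(m) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character()))
  }
  # anchor = genome position of the consensus start implied by the seed
  m$anchor <- m$gpos - m$cpos
  m <- arrange(m, .data$strand, .data$anchor, .data$gpos)
  grp <- cumsum(c(TRUE, m$strand[-1] != m$strand[-nrow(m)] |
                    diff(m$anchor) > 40L))
  m$grp <- grp
  cand <- m %>%
    group_by(.data$grp) %>%
    summarise(strand = .data$strand[1],
              a = round(stats::median(.data$anchor)),
              n_seeds = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n_seeds >= 2L)
  if (nrow(cand) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character()))
  }
  # convert reverse-strand anchors (positions on the revcomp) back to
  # forward coordinates
  start_f <- ifelse(cand$strand == "+", cand$a, L - (cand$a + clen))
  tibble(start = pmax(0L, as.integer(start_f)),
         end = pmin(L, as.integer(start_f) + clen),
         strand = cand$strand)
}

# longest valid ORF of a consensus (frame 0 whole-element ORF preferred)
consensus_orf <- function(cons) {
  if (is_valid_orf(cons)) return(cons)
  best <- NULL
  for (frame in 0:2) {
    s <- substr(cons, frame + 1L, nchar(cons))
    s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    cods <- split_codons(s)
    starts <- which(cods %in% START_CODONS)
    stops <- which(cods %in% STOP_CODONS)
    for (st in starts) {
      nxt <- stops[stops > st]
      if (!length(nxt)) next
      orf <- paste(cods[st:nxt[1]], collapse = "")
      if (is.null(best) || nchar(orf) > nchar(best)) best <- orf
    }
  }
  if (!is.null(best) && nchar(best) >= 150L) best else NULL
}

#' Permutation test for intergenic clustering of IS elements
#'
#' Tests whether IS elements preferentially occupy intergenic space.
#' The observed statistic is the fraction of IS element midpoints falling
#' in intergenic regions (the complement of CDS, pseudogene, rRNA and tRNA
#' intervals); the null places the same number of midpoints uniformly on
#' the chromosome. One-sided p-value for enrichment, computed as
#' `(1 + exceedances) / (n_perm + 1)`; bit-reproducible given `seed`.
#'
#' @param is_sites Tibble with a `start` and `end` column (e.g. from
#'   [annotate_is()]), or the IS features of a genome.
#' @param genome [annotated_genome()] supplying the gene map.
#' @param n_perm Number of permutation replicates (>= 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed_intergenic_fraction`,
#'   `expected_fraction`, `p_value`, `n_is`, `n_perm`.
#' @export
intergenic_clustering_test <- function(is_sites, genome, n_perm = 10000L,
                                       seed = 1L) {
  if (n_perm < 1000L) abort("n_perm must be >= 1000")
  if (nrow(is_sites) == 0L) abort("no IS sites supplied")
  L <- genome_length(genome)
  ig <- intergenic_ranges(genome)
  expected <- sum(ig$end - ig$start) / L
  mids <- ((is_sites$start + is_sites$end) %/% 2L) %% L
  obs <- mean(in_ranges(mids, ig))
  n_is <- length(mids)
  set.seed(seed)
  draws <- matrix(sample.int(L, n_is * n_perm, replace = TRUE) - 1L,
                  nrow = n_is)
  hit <- matrix(in_ranges(as.vector(draws), ig), nrow = n_is)
  perm_frac <- colMeans(hit)
  p <- (1 + sum(perm_frac >= obs - 1e-12)) / (n_perm + 1)
  tibble(observed_intergenic_fraction = obs, expected_fraction = expected,
         p_value = p, n_is = n_is, n_perm = as.integer(n_perm))
}

# membership of 0-based positions in a tibble of 0-based half-open ranges
in_ranges <- function(pos, ranges) {
  if (nrow(ranges) == 0L) return(rep(FALSE, length(pos)))
  o <- order(ranges$start)
  s <- ranges$start[o]; e <- ranges$end[o]
  idx <- findInterval(pos, s)
  idx > 0 & pos < e[pmax(idx, 1L)]
}

#' Detect large duplicated chromosomal regions
#'
#' Finds pairs of long, highly similar repeats (segmental duplications) by
#' chaining genome k-mers that occur exactly twice (IS elements and
#' prophage are masked first, so mobile elements themselves are not
#' reported). Substitutions and indels between the two copies are counted
#' by aligning the short inter-anchor gap segments, and each pair is
#' checked for bounding same-family IS elements within `flank_nt` of both
#' copies.
#'
#' @param genome An [annotated_genome()] whose IS elements are annotated
#'   as features (used for masking and for the bounded-by-IS check).
#' @param min_len Minimum duplication length in nt (default 2500, >= 500).
#' @param min_identity Minimum identity between the copies (default 0.99).
#' @param k Seed k-mer length (default 20).
#' @param max_gap,diag_tol Chaining parameters, as in [chain_blocks()].
#' @param flank_nt Window on either flank searched for bounding IS
#'   elements (default 2000).
#' @return Tibble: `start_a`, `end_a`, `start_b`, `end_b`, `length_nt`,
#'   `identity`, `n_substitutions`, `n_indels`, `bounded_by_is`,
#'   `bounding_family`.
#' @export
detect_duplications <- function(genome, min_len = 2500L,
                                min_identity = 0.99, k = 20L,
                                max_gap = 1000L, diag_tol = 50L,
                                flank_nt = 2000L) {
  if (min_len < 500L) abort("min_len must be >= 500")
  seq <- mask_features(genome, c("IS_element", "phage"))
  L <- nchar(seq)
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  ok <- which(!grepl("N", kmers, fixed = TRUE))
  ks <- kmers[ok]
  o <- order(ks)
  s <- ks[o]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  two <- which(r$lengths == 2L)
  if (!length(two)) return(empty_dup_tbl())
  p_first <- ok[o[ends[two] - 1L]] - 1L      # 0-based positions of the
  p_second <- ok[o[ends[two]]] - 1L          # two occurrences
  pos1 <- pmin(p_first, p_second)
  pos2 <- pmax(p_first, p_second)
  m <- tibble(ref_pos = as.integer(pos1), der_pos = as.integer(pos2),
              strand = "+")
  blocks <- chain_blocks(m, k = k, max_gap = max_gap, diag_tol = diag_tol)
  blocks <- dplyr::filter(blocks,
                          .data$ref_end - .data$ref_start >= min_len,
                          .data$der_start >= .data$ref_end)
  if (nrow(blocks) == 0L) return(empty_dup_tbl())
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    anchors <- m %>%
      dplyr::filter(.data$ref_pos >= b$ref_start,
                    .data$ref_pos + k <= b$ref_end,
                    .data$der_pos >= b$der_start,
                    .data$der_pos + k <= b$der_end) %>%
      arrange(.data$ref_pos)
    d <- gap_divergence(seq, anchors, k)
    alen <- b$ref_end - b$ref_start
    ident <- 1 - (d$subs + d$indel_nt) / alen
    if (ident < min_identity) next
    bb <- bounding_is(genome, b, flank_nt)
    rows[[length(rows) + 1L]] <- tibble(
      start_a = b$ref_start, end_a = b$ref_end,
      start_b = b$der_start, end_b = b$der_end,
      length_nt = alen, identity = ident,
      n_substitutions = d$subs, n_indels = d$indels,
      bounded_by_is = bb$bounded, bounding_family = bb$family)
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0L) return(empty_dup_tbl())
  res
}

empty_dup_tbl <- function() {
  tibble(start_a = integer(), end_a = integer(), start_b = integer(),
         end_b = integer(), length_nt = integer(), identity = numeric(),
         n_substitutions = integer(), n_indels = integer(),
         bounded_by_is = logical(), bounding_family = character())
}

# count substitutions and indels in the unanchored gaps between
# consecutive k-mer anchors of one duplication pair
gap_divergence <- function(seq, anchors, k) {
  subs <- 0L; indels <- 0L; indel_nt <- 0L
  a <- anchors$ref_pos; b <- anchors$der_pos
  for (i in seq_len(nrow(anchors) - 1L)) {
    ga_s <- a[i] + k; ga_e <- a[i + 1L]
    gb_s <- b[i] + k; gb_e <- b[i + 1L]
    la <- ga_e - ga_s; lb <- gb_e - gb_s
    if (la == lb) {
      if (la <= 0L) next
      sa <- substr(seq, ga_s + 1L, ga_e)
      sb <- substr(seq, gb_s + 1L, gb_e)
      subs <- subs + sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
    } else if (la <= 0L || lb <= 0L) {
      indels <- indels + 1L
      indel_nt <- indel_nt + abs(la - lb)
    } else {
      sa <- substr(seq, ga_s + 1L, ga_e)
      sb <- substr(seq, gb_s + 1L, gb_e)
      al <- align_dna(sa, sb, type = "global", gapOpening = 4,
                      gapExtension = 1)
      pa <- al$sa
      pb <- al$sb
      both <- pa != "-" & pb != "-"
      subs <- subs + sum(pa[both] != pb[both])
      gap_runs <- indel_runs(pa, pb)
      indels <- indels + nrow(gap_runs)
      indel_nt <- indel_nt + sum(gap_runs$len)
    }
  }
  list(subs = subs, indels = indels, indel_nt = indel_nt)
}

bounding_is <- function(genome, b, flank_nt) {
  is_f <- dplyr::filter(genome$features, .data$kind == "IS_element")
  if (nrow(is_f) == 0L) return(list(bounded = FALSE, family = NA_character_))
  near <- function(pos) {
    hit <- is_f$end >= pos - flank_nt & is_f$start <= pos + flank_nt
    is_f$family[hit]
  }
  fams <- list(near(b$ref_start), near(b$ref_end),
               near(b$der_start), near(b$der_end))
  common <- Reduce(intersect, fams)
  if (length(common) && !all(is.na(common))) {
    list(bounded = TRUE, family = common[1])
  } else if (all(lengths(fams) > 0L)) {
    list(bounded = TRUE, family = NA_character_)
  } else {
    list(bounded = FALSE, family = NA_character_)
  }
}
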