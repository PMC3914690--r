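#' Exact shared k-mer matches between two masked genomes
#'
#' Finds every k-mer (default k = 20, the scale at which a bacterial
#' genome's k-mers are essentially unique) that occurs exactly once in the
#' reference and exactly once in the derived genome, on either strand, and
#' reports the match with its strand. Sequences should first be masked of
#' repetitive DNA with [mask_features()]; k-mers containing `N` are
#' excluded, and the unique-in-both filter removes any residual repeat
#' ambiguity deterministically.
#'
#' @param ref_masked,der_masked Masked genome sequences (character
#'   scalars).
#' @param k k-mer length (default 20; must be >= 8 and <= both sequence
#'   lengths).
#' @return Tibble with 0-based `ref_pos`, `der_pos` (start of the k-mer on
#'   the forward strand of each genome) and `strand` (`"+"` when the match
#'   is on the same strand, `"-"` when on opposite strands), sorted by
#'   `ref_pos`.
#' @export
kmer_matches <- function(ref_masked, der_masked, k = 20L) {
  k <- as.integer(k)
  if (k < 8L) abort("k must be >= 8")
  Lr <- nchar(ref_masked)
  Ld <- nchar(der_masked)
  if (k > Lr || k > Ld) abort("k exceeds a sequence length")
  ref_k <- substring(ref_masked, 1:(Lr - k + 1L), k:Lr)
  der_f <- substring(der_masked, 1:(Ld - k + 1L), k:Ld)
  der_rc_seq <- revcomp(der_masked)
  der_r <- substring(der_rc_seq, 1:(Ld - k + 1L), k:Ld)
  ok_ref <- !grepl("N", ref_k, fixed = TRUE)
  # occurrence counts of each ref k-mer in ref
  ref_cnt <- table_count(ref_k[ok_ref])
  uniq_ref <- names(ref_cnt)[ref_cnt == 1L]
  # counts in der over both strands
  der_all <- c(der_f, der_r)
  ok_der <- !grepl("N", der_all, fixed = TRUE)
  der_cnt <- table_count(der_all[ok_der])
  shared <- uniq_ref[uniq_ref %in% names(der_cnt)[der_cnt == 1L]]
  if (!length(shared)) {
    return(tibble(ref_pos = integer(), der_pos = integer(),
                  strand = character()))
  }
  rp <- match(shared, ref_k) - 1L           # 0-based ref start
  fwd <- match(shared, der_f)
  rev <- match(shared, der_r)
  strand <- ifelse(!is.na(fwd), "+", "-")
  # position of a k-mer found at 1-based index j of the reverse complement,
  # mapped back to 0-based forward coordinates: Ld - j + 1 - k
  dp <- ifelse(!is.na(fwd), fwd - 1L, Ld - rev + 1L - k)
  tibble(ref_pos = rp, der_pos = as.integer(dp), strand = strand) %>%
    arrange(.data$ref_pos)
}

table_count <- function(x) {
  t <- table(x)
  setNames(as.integer(t), names(t))
}

#' Chain k-mer matches into synteny blocks
#'
#' Merges maximal runs of matches that are collinear in both genomes (same
#' strand, consistent diagonal within `diag_tol`, adjacent matches within
#' `max_gap` nt in the reference) into blocks. Deterministic: blocks are
#' reported sorted by reference start.
#'
#' @param matches Tibble from [kmer_matches()].
#' @param k k-mer length used to produce the matches.
#' @param max_gap Maximum reference-coordinate gap between consecutive
#'   matches of one block (default 1000 nt).
#' @param diag_tol Tolerated drift of the alignment diagonal within a
#'   block (default 20 nt).
#' @return Tibble of blocks: `ref_start`, `ref_end`, `der_start`,
#'   `der_end` (0-based half-open), `orientation` (`same_strand` /
#'   `opposite_strand`), `n_kmers`.
#' @export
chain_blocks <- function(matches, k = 20L, max_gap = 1000L, diag_tol = 20L) {
  if (nrow(matches) == 0L) {
    return(tibble(ref_start = integer(), ref_end = integer(),
                  der_start = integer(), der_end = integer(),
                  orientation = character(), n_kmers = integer()))
  }
  m <- arrange(matches, .data$ref_pos)
  diag <- ifelse(m$strand == "+", m$der_pos - m$ref_pos,
                 m$der_pos + m$ref_pos)
  new_block <- c(TRUE,
                 m$strand[-1] != m$strand[-nrow(m)] |
                   diff(m$ref_pos) > max_gap |
                   abs(diff(diag)) > diag_tol)
  m$block <- cumsum(new_block)
  m %>%
    group_by(.data$block) %>%
    summarise(ref_start = min(.data$ref_pos),
              ref_end = max(.data$ref_pos) + k,
              der_start = min(.data$der_pos),
              der_end = max(.data$der_pos) + k,
              orientation = ifelse(.data$strand[1] == "+", "same_strand",
                                   "opposite_strand"),
              n_kmers = dplyr::n(), .groups = "drop") %>%
    select(-"block") %>%
    arrange(.data$ref_start)
}

#' Classify replichore symmetry of synteny blocks
#'
#' In an unrearranged chromosome pair, replication symmetry requires
#' same-strand matches to stay on the same replichore and opposite-strand
#' matches to switch replichore. Each block is probed at two interior
#' points (25% and 75% of its span, mapped orientation-aware between the
#' genomes): a block is `symmetric` when both probes obey the rule,
#' `violating` when both break it, and `indeterminate` when the probes
#' disagree (e.g. a block genuinely spanning ori or ter in one genome
#' only). An inversion centred on the ori-ter axis, which swaps
#' replichores, is therefore correctly reported as symmetric.
#'
#' @param blocks Tibble from [chain_blocks()].
#' @param ref_ori,ref_ter 0-based ori and ter positions in the reference.
#' @param der_ori,der_ter Same for the derived genome.
#' @param ref_len,der_len Genome lengths (needed for circular arithmetic).
#' @return List with `blocks` (input plus `symmetry_class`) and
#'   `violation_fraction` (violating / classified k-mers over classified
#'   blocks).
#' @export
classify_symmetry <- function(blocks, ref_ori, ref_ter, der_ori, der_ter,
                              ref_len, der_len) {
  if (ref_ori == ref_ter || der_ori == der_ter) {
    abort("ori and ter positions must differ")
  }
  repl <- function(pos, ori, ter, L) {
    arc1 <- (ter - ori) %% L
    ((pos - ori) %% L) < arc1
  }
  b <- blocks
  cls <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    same_strand <- b$orientation[i] == "same_strand"
    w <- b$ref_end[i] - b$ref_start[i]
    probes_ref <- b$ref_start[i] + round(c(0.25, 0.75) * w)
    frac_der <- if (same_strand) c(0.25, 0.75) else c(0.75, 0.25)
    probes_der <- b$der_start[i] +
      round(frac_der * (b$der_end[i] - b$der_start[i]))
    ok <- logical(2)
    for (j in 1:2) {
      r1 <- repl(probes_ref[j], ref_ori, ref_ter, ref_len)
      r2 <- repl(probes_der[j], der_ori, der_ter, der_len)
      ok[j] <- if (same_strand) r1 == r2 else r1 != r2
    }
    cls[i] <- if (all(ok)) "symmetric"
              else if (!any(ok)) "violating" else "indeterminate"
  }
  b$symmetry_class <- cls
  cl <- dplyr::filter(b, .data$symmetry_class != "indeterminate")
  vf <- if (nrow(cl)) {
    sum(cl$n_kmers[cl$symmetry_class == "violating"]) / sum(cl$n_kmers)
  } else NA_real_
  list(blocks = b, violation_fraction = vf)
}

#' Whole-genome synteny analysis
#'
#' Convenience pipeline: mask repetitive kinds, find unique shared k-mers,
#' chain blocks, and (when ori/ter positions are supplied) classify
#' replichore symmetry.
#'
#' @param ref,der [annotated_genome()] objects.
#' @param k,max_gap,diag_tol See [kmer_matches()] and [chain_blocks()].
#' @param mask_kinds Feature kinds masked before matching (default IS
#'   elements and prophage).
#' @param ref_ori,ref_ter,der_ori,der_ter Optional replichore anchors; if
#'   any is `NULL` symmetry is not classified.
#' @return List with `matches`, `blocks` and (optionally)
#'   `violation_fraction`.
#' @export
synteny_map <- function(ref, der, k = 20L, max_gap = 1000L, diag_tol = 20L,
                        mask_kinds = c("IS_element", "phage"),
                        ref_ori = NULL, ref_ter = NULL,
                        der_ori = NULL, der_ter = NULL) {
  rm_seq <- mask_features(ref, mask_kinds)
  dm_seq <- mask_features(der, mask_kinds)
  matches <- kmer_matches(rm_seq, dm_seq, k = k)
  blocks <- chain_blocks(matches, k = k, max_gap = max_gap,
                         diag_tol = diag_tol)
  out <- list(matches = matches, blocks = blocks)
  if (!is.null(ref_ori) && !is.null(ref_ter) && !is.null(der_ori) &&
      !is.null(der_ter)) {
    cs <- classify_symmetry(blocks, ref_ori, ref_ter, der_ori, der_ter,
                            genome_length(ref), genome_length(der))
    out$blocks <- cs$blocks
    out$violation_fraction <- cs$violation_fraction
  }
  out
}

#' Export synteny blocks as BEDPE
#'
#' One row per block pairing the reference and derived intervals, with
#' the orientation in the strand columns (reference always `+`).
#'
#' @param blocks Tibble from [chain_blocks()] or [synteny_map()].
#' @param path Output file.
#' @param ref_name,der_name Replicon names for the two genomes.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(blocks, path, ref_name = "ref", der_name = "der") {
  df <- data.frame(
    chrom1 = ref_name, start1 = blocks$ref_start, end1 = blocks$ref_end,
    chrom2 = der_name, start2 = blocks$der_start, end2 = blocks$der_end,
    name = sprintf("block_%04d", seq_len(nrow(blocks))),
    score = blocks$n_kmers, strand1 = "+",
    strand2 = ifelse(blocks$orientation == "same_strand", "+", "-"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
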