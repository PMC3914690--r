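#' Align a query 16S rRNA gene to a reference
#'
#' Global nucleotide alignment projected onto reference coordinates: for
#' every reference position the aligned query state is reported (`-` for a
#' deletion); query insertions are counted separately.
#'
#' @param ref_16s,query_16s rRNA gene sequences (DNA representation).
#' @return List with `query_at` (character vector, one state per reference
#'   position) and `n_insertions` (nt inserted in the query).
#' @export
align_16s <- function(ref_16s, query_16s) {
  al <- align_dna(ref_16s, query_16s, type = "global", gapOpening = 10,
                  gapExtension = 1)
  sa <- al$sa
  sb <- al$sb
  list(query_at = sb[sa != "-"], n_insertions = sum(sa == "-"))
}

WC_GU_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Classify 16S rRNA stem mutations as conservative or disruptive
#'
#' Every substituted reference position is classified by its structural
#' context: substitutions at unpaired positions are `loop`; at paired
#' (stem) positions the *realized* base pair — using the query state of
#' both members of the pair — is evaluated, and the substitution is
#' `conservative` when the new pair is Watson-Crick or G·U wobble (G·T in
#' DNA representation), `disruptive` otherwise. A compensatory double
#' substitution that restores pairing therefore scores as conservative at
#' both positions. Positions gapped in the query (or whose pairing partner
#' is gapped) are excluded from the stem classification and counted
#' separately; indels are never silently dropped.
#'
#' @param ref_16s,query_16s rRNA gene sequences.
#' @param pairing Tibble with 1-based reference positions `i`, `j`
#'   (`i < j`, each position in at most one pair).
#' @return List with `counts` (one-row tibble: `conservative`,
#'   `disruptive`, `loop`, `gapped_excluded`, `n_deletions`,
#'   `n_insertions`, `disruptive_conservative_ratio`) and `per_site`
#'   (tibble of classified substitutions).
#' @export
classify_stem_mutations <- function(ref_16s, query_16s, pairing) {
  n <- nchar(ref_16s)
  check_pairing(pairing, n)
  refv <- strsplit(toupper(ref_16s), "")[[1]]
  al <- align_16s(ref_16s, query_16s)
  qv <- al$query_at
  partner <- integer(n)
  partner[pairing$i] <- pairing$j
  partner[pairing$j] <- pairing$i
  sub_pos <- which(qv != refv & qv != "-" & refv != "N" & qv != "N")
  rows <- list()
  for (p in sub_pos) {
    if (partner[p] == 0L) {
      cls <- "loop"
      pair_txt <- NA_character_
    } else {
      q_partner <- qv[partner[p]]
      if (q_partner == "-") {
        cls <- "gapped_excluded"
        pair_txt <- NA_character_
      } else {
        realized <- if (p < partner[p]) paste0(qv[p], q_partner)
                    else paste0(q_partner, qv[p])
        cls <- if (realized %in% WC_GU_PAIRS) "conservative" else "disruptive"
        pair_txt <- paste0(substr(realized, 1, 1), "·",
                           substr(realized, 2, 2))
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      position = p, ref_base = refv[p], query_base = qv[p],
      class = cls, realized_pair = pair_txt)
  }
  per_site <- if (length(rows)) bind_rows(rows) else {
    tibble(position = integer(), ref_base = character(),
           query_base = character(), class = character(),
           realized_pair = character())
  }
  cons <- sum(per_site$class == "conservative")
  disr <- sum(per_site$class == "disruptive")
  counts <- tibble(
    conservative = cons, disruptive = disr,
    loop = sum(per_site$class == "loop"),
    gapped_excluded = sum(per_site$class == "gapped_excluded"),
    n_deletions = sum(qv == "-"),
    n_insertions = al$n_insertions,
    disruptive_conservative_ratio = if (cons > 0) disr / cons else NA_real_)
  list(counts = counts, per_site = per_site)
}

check_pairing <- function(pairing, n) {
  stopifnot(all(c("i", "j") %in% names(pairing)))
  if (any(pairing$i >= pairing$j)) abort("pairing requires i < j")
  pos <- c(pairing$i, pairing$j)
  if (any(pos < 1L) || any(pos > n)) {
    abort("pairing index outside the reference sequence")
  }
  if (anyDuplicated(pos)) abort("a position may belong to at most one pair")
  invisible(TRUE)
}

#' Bin 16S rRNA substitutions by per-site variability class
#'
#' Classifies each substitution by the variability class of its reference
#' position (ordinal 1 = invariant .. 6 = hypervariable). An excess of
#' substitutions in the rare (low-variability) classes indicates relaxed
#' functional constraint on the molecule.
#'
#' @param ref_16s,query_16s rRNA gene sequences.
#' @param vmap Tibble with columns `pos` (1-based) and `class` (1-6),
#'   covering every reference position.
#' @param rare_classes Classes counted as rare sites (default 1:2).
#' @return One-row tibble: `rare_site_subs`, `common_site_subs`,
#'   `total_subs`, `rare_fraction`.
#' @export
classify_variability <- function(ref_16s, query_16s, vmap,
                                 rare_classes = c(1L, 2L)) {
  n <- nchar(ref_16s)
  if (!all(seq_len(n) %in% vmap$pos)) {
    abort("variability map must cover every reference position")
  }
  cls <- vmap$class[match(seq_len(n), vmap$pos)]
  refv <- strsplit(toupper(ref_16s), "")[[1]]
  qv <- align_16s(ref_16s, query_16s)$query_at
  sub_pos <- which(qv != refv & qv != "-" & refv != "N" & qv != "N")
  rare <- sum(cls[sub_pos] %in% rare_classes)
  tot <- length(sub_pos)
  tibble(rare_site_subs = rare, common_site_subs = tot - rare,
         total_subs = tot,
         rare_fraction = if (tot > 0) rare / tot else NA_real_)
}

#' Read a stem pairing map from TSV
#' @param path Two-column TSV (`i`, `j`) with a header line.
#' @return Tibble with `i`, `j`.
#' @export
read_pairing_map <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t"))
}

#' Read a per-site variability map from TSV
#' @param path Two-column TSV (`pos`, `class`) with a header line.
#' @return Tibble with `pos`, `class`.
#' @export
read_variability_map <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t"))
}
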