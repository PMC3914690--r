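#' Windowed GC skew track
#'
#' Computes (G - C)/(G + C) in sliding windows. In an unrearranged
#' bacterial chromosome the skew is positive on one replichore and
#' negative on the other, flipping sign at the replication origin and
#' terminus; a degenerate, rearranged chromosome loses this polarization.
#'
#' @param seq Genome sequence (character scalar).
#' @param window Window size in nt (default 10,000; must be >= 100).
#' @param step Step between window starts (default `window/2`).
#' @return Tibble with `pos` (0-based window midpoint), `win_start`,
#'   `win_end` (0-based half-open window bounds), `skew`, and `flagged`
#'   (`TRUE` for windows with no G or C, whose skew is recorded as 0).
#' @export
gc_skew <- function(seq, window = 10000L, step = window %/% 2L) {
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 100L) abort("window must be >= 100 nt")
  if (step > window) abort("step must not exceed window")
  L <- nchar(seq)
  if (window > L) abort("window exceeds genome length")
  starts <- seq.int(1L, L - window + 1L, by = step)
  v <- Biostrings::Views(Biostrings::DNAString(seq), start = starts,
                         width = window)
  fr <- Biostrings::letterFrequency(v, c("G", "C"))
  g <- fr[, "G"]; cc <- fr[, "C"]
  tot <- g + cc
  skew <- ifelse(tot == 0, 0, (g - cc) / pmax(tot, 1))
  tibble(pos = starts - 1L + window %/% 2L,
         win_start = starts - 1L, win_end = starts - 1L + window,
         skew = as.numeric(skew), flagged = tot == 0)
}

#' Export a skew track as bedGraph
#' @param track Tibble from [gc_skew()].
#' @param path Output file.
#' @param chrom Chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  df <- data.frame(chrom = chrom, start = track$win_start,
                   end = track$win_end, value = track$skew)
  write.table(df, path, sep = "	", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export KOPS sites as BED6
#' @param sites Tibble from [find_kops()].
#' @param path Output file.
#' @param chrom Chromosome name.
#' @param motif_len Site length (default 8).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(sites, path, chrom = "chr", motif_len = 8L) {
  df <- data.frame(chrom = chrom, start = sites$position,
                   end = sites$position + motif_len,
                   name = sprintf("KOPS_%04d", seq_len(nrow(sites))),
                   score = 0L, strand = sites$strand)
  write.table(df, path, sep = "	", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Locate ori and ter from cumulative GC skew
#'
#' The cumulative sum of windowed skew reaches its global minimum at the
#' replication origin and its global maximum at the terminus (circular
#' convention, leading strands G-enriched).
#'
#' @param track Tibble from [gc_skew()].
#' @return Named list `ori`, `ter` (0-based positions of the extremal
#'   window midpoints).
#' @export
cumulative_skew_extrema <- function(track) {
  cs <- cumsum(track$skew)
  list(ori = track$pos[which.min(cs)], ter = track$pos[which.max(cs)])
}

#' GC-skew polarization index
#'
#' Fraction of (non-flagged) windows whose skew sign agrees with the
#' two-replichore model given ori and ter, with the sign orientation
#' chosen to maximize agreement. 1 means perfectly polarized; an
#' extensively rearranged chromosome decays towards 0.5.
#'
#' @param track Tibble from [gc_skew()].
#' @param ori,ter 0-based ori/ter positions.
#' @param genome_len Genome length (defaults to span of the track).
#' @return Fraction in \[0, 1\].
#' @export
skew_polarization_index <- function(track, ori, ter,
                                    genome_len = max(track$pos) + 1L) {
  if (ori == ter) abort("ori and ter must differ")
  t2 <- dplyr::filter(track, !.data$flagged, .data$skew != 0)
  if (nrow(t2) == 0L) abort("all windows flagged")
  arc1 <- (ter - ori) %% genome_len
  on_r1 <- ((t2$pos - ori) %% genome_len) < arc1
  expect_pos <- ifelse(on_r1, 1, -1)
  agree <- mean(sign(t2$skew) == expect_pos)
  max(agree, 1 - agree)
}

#' Scan for KOPS motifs
#'
#' Finds all occurrences of the FtsK-orienting polar sequence motif
#' (IUPAC, default `GGGNAGGG`) on both strands.
#'
#' @param seq Genome sequence.
#' @param motif IUPAC motif (default `"GGGNAGGG"`).
#' @return Tibble with 0-based `position` (forward-strand start) and
#'   `strand`.
#' @export
find_kops <- function(seq, motif = "GGGNAGGG") {
  subject <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(motif, subject, fixed = FALSE)
  rev <- Biostrings::matchPattern(revcomp(motif), subject, fixed = FALSE)
  bind_rows(
    tibble(position = Biostrings::start(fwd) - 1L, strand = "+"),
    tibble(position = Biostrings::start(rev) - 1L, strand = "-")) %>%
    arrange(.data$position)
}

#' KOPS polarity with respect to replichores
#'
#' A KOPS site is polarized when its strand points from ori toward ter
#' along its replichore: forward-strand sites on the ori-to-ter arc,
#' reverse-strand sites on the other arc. Returns the polarized fraction;
#' 1.0 is the unrearranged expectation.
#'
#' @param sites Tibble from [find_kops()].
#' @param ori,ter 0-based ori/ter positions.
#' @param genome_len Genome length.
#' @return Fraction in \[0, 1\] (`NA` when no sites).
#' @export
kops_polarity <- function(sites, ori, ter, genome_len) {
  if (nrow(sites) == 0L) return(NA_real_)
  arc1 <- (ter - ori) %% genome_len
  on_r1 <- ((sites$position - ori) %% genome_len) < arc1
  mean(ifelse(on_r1, sites$strand == "+", sites$strand == "-"))
}

#' The canonical enterobacterial dif site
#'
#' 28-nt XerCD recombination site at the replication terminus of
#' enterobacteria; the default query of [find_dif()].
#' @export
DIF_SITE <- "AGTACGCATAATACATATTATGTTAAAT"

#' Search for the dif site
#'
#' Ungapped best-placement search of a dif query on both strands. A
#' degenerating chromosome that has lost its terminus region returns no
#' hit.
#'
#' @param seq Genome sequence.
#' @param dif_query Query sequence (default [DIF_SITE]).
#' @param max_mismatch Maximum allowed mismatches (default 4; must be at
#'   most a quarter of the query length).
#' @return One-row tibble `position` (0-based), `strand`, `mismatches`,
#'   or a zero-row tibble when no placement is within `max_mismatch`.
#'   Ties are resolved to the leftmost, forward-strand-first placement.
#' @export
find_dif <- function(seq, dif_query = DIF_SITE, max_mismatch = 4L) {
  if (nchar(dif_query) == 0L) abort("dif_query must be non-empty")
  if (max_mismatch > nchar(dif_query) / 4) {
    abort("max_mismatch must be <= query length / 4")
  }
  subject <- Biostrings::DNAString(seq)
  hit_tbl <- function(query, strand) {
    m <- Biostrings::matchPattern(query, subject,
                                  max.mismatch = max_mismatch)
    if (length(m) == 0L) {
      return(tibble(position = integer(), strand = character(),
                    mismatches = integer()))
    }
    mm <- vapply(seq_along(m), function(i) {
      sum(strsplit(as.character(m[[i]]), "")[[1]] !=
            strsplit(query, "")[[1]])
    }, integer(1))
    tibble(position = Biostrings::start(m) - 1L, strand = strand,
           mismatches = mm)
  }
  hits <- bind_rows(hit_tbl(dif_query, "+"),
                    hit_tbl(revcomp(dif_query), "-"))
  if (nrow(hits) == 0L) return(hits)
  hits %>%
    arrange(.data$mismatches, .data$position,
            dplyr::desc(.data$strand)) %>%
    head(1L)
}

#' Full chromosome-architecture summary
#'
#' GC skew track, inferred (or supplied) ori/ter, polarization index,
#' KOPS sites and polarity, and dif placement for one genome.
#'
#' @param genome An [annotated_genome()].
#' @param window,step [gc_skew()] parameters.
#' @param motif KOPS motif.
#' @param dif_query,max_mismatch [find_dif()] parameters.
#' @param ori,ter Optional externally supplied ori/ter (e.g. carried over
#'   from a syntenic relative when the genome's own skew is disrupted);
#'   inferred from cumulative skew when `NULL`.
#' @return List: `track`, `ori`, `ter`, `polarization_index`,
#'   `kops_sites`, `kops_polarity`, `dif`.
#' @export
chromosome_architecture <- function(genome, window = 10000L,
                                    step = window %/% 2L,
                                    motif = "GGGNAGGG",
                                    dif_query = DIF_SITE,
                                    max_mismatch = 4L,
                                    ori = NULL, ter = NULL) {
  track <- gc_skew(genome$sequence, window, step)
  if (is.null(ori) || is.null(ter)) {
    ext <- cumulative_skew_extrema(track)
    ori <- ori %||% ext$ori
    ter <- ter %||% ext$ter
  }
  L <- genome_length(genome)
  sites <- find_kops(genome$sequence, motif)
  list(track = track, ori = ori, ter = ter,
       polarization_index = skew_polarization_index(track, ori, ter, L),
       kops_sites = sites,
       kops_polarity = kops_polarity(sites, ori, ter, L),
       dif = find_dif(genome$sequence, dif_query, max_mismatch))
}
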