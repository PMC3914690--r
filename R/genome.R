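#' Annotated genome container
#'
#' An `annotated_genome` bundles a (typically circular) DNA sequence with a
#' feature table. It is the common input type of every analysis in the
#' package. Coordinates in the feature table are 0-based half-open
#' `[start, end)` internally; the I/O layer converts to and from the 1-based
#' inclusive convention of GenBank and GFF3.
#'
#' @param id Single string, the genome/replicon identifier.
#' @param sequence Single string over the alphabet `A`, `C`, `G`, `T`, `N`.
#'   Lower-case input is uppercased; any other character is an error.
#' @param features A tibble as produced by [feature_table()]. May be empty.
#' @param circular Is the replicon circular? Default `TRUE`, the usual case
#'   for bacterial chromosomes.
#'
#' @return An object of class `annotated_genome`: a list with elements `id`,
#'   `sequence` (character scalar), `circular` (logical) and `features`
#'   (tibble).
#'
#' @details
#' A feature that spans the circular origin is stored with `end > start`
#' extending past the sequence length (so `end - start` is its true width)
#' and `wraps_origin = TRUE`; all interval arithmetic elsewhere treats
#' coordinates modulo the genome length.
#'
#' @examples
#' g <- annotated_genome("toy", "ATGAAATAA",
#'   feature_table(kind = "CDS", start = 0, end = 9, strand = "+",
#'                 locus_tag = "t0001"))
#' g
#' @export
annotated_genome <- function(id, sequence, features = feature_table(),
                             circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.logical(circular), length(circular) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) abort("genome sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    abort(sprintf("sequence contains characters outside {A,C,G,T,N}: '%s'",
                  substr(bad, 1L, 10L)))
  }
  features <- validate_features(features, nchar(sequence))
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "annotated_genome")
}

FEATURE_KINDS <- c("CDS", "pseudogene", "rRNA_16S", "rRNA_23S", "rRNA_5S",
                   "tRNA", "IS_element", "phage", "other")

#' Build a feature table
#'
#' Constructs the tibble of typed features carried by an
#' [annotated_genome()]. Missing optional columns are filled with `NA`.
#'
#' @param kind Feature kind, one of
#'   `r paste0('\x60', FEATURE_KINDS, '\x60', collapse = ", ")`.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param locus_tag Unique identifier per feature.
#' @param product Optional free-text product description.
#' @param family Optional IS family label (IS elements only).
#' @param wraps_origin Does the feature span the circular origin?
#' @return A tibble with one row per feature.
#' @export
feature_table <- function(kind = character(), start = integer(),
                          end = integer(), strand = character(),
                          locus_tag = character(), product = NA_character_,
                          family = NA_character_, wraps_origin = FALSE) {
  n <- length(kind)
  tibble(kind = as.character(kind),
         start = as.integer(start), end = as.integer(end),
         strand = as.character(strand),
         locus_tag = as.character(locus_tag),
         product = rep_len(as.character(product), n),
         family = rep_len(as.character(family), n),
         wraps_origin = rep_len(as.logical(wraps_origin), n))
}

validate_features <- function(features, genome_len) {
  features <- as_tibble(features)
  needed <- c("kind", "start", "end", "strand", "locus_tag")
  miss <- setdiff(needed, names(features))
  if (length(miss)) abort(paste("feature table lacks columns:",
                                paste(miss, collapse = ", ")))
  if (!"product" %in% names(features)) features$product <- NA_character_
  if (!"family" %in% names(features)) features$family <- NA_character_
  if (!"wraps_origin" %in% names(features)) features$wraps_origin <- FALSE
  features <- features[, c(needed, "product", "family", "wraps_origin")]
  if (nrow(features) == 0L) return(features)
  if (!all(features$kind %in% FEATURE_KINDS)) {
    abort(paste("unknown feature kind(s):",
                paste(setdiff(unique(features$kind), FEATURE_KINDS),
                      collapse = ", ")))
  }
  if (!all(features$strand %in% c("+", "-"))) abort("strand must be + or -")
  if (anyDuplicated(features$locus_tag)) {
    abort("locus_tag values must be unique within a genome")
  }
  if (any(features$start < 0L) || any(features$start >= genome_len)) {
    abort("feature start outside [0, genome length)")
  }
  wid <- features$end - features$start
  if (any(wid <= 0L)) abort("feature end must exceed start")
  if (any(wid > genome_len)) abort("feature longer than the genome")
  over <- features$end > genome_len
  if (any(over & !features$wraps_origin)) {
    abort("feature end beyond genome length without wraps_origin = TRUE")
  }
  features
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d features\n",
              x$id, format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features)) print(dplyr::count(x$features, .data$kind))
  invisible(x)
}

#' Genome length in nucleotides
#' @param genome An [annotated_genome()].
#' @return Integer scalar.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Extract the sequence of one feature interval
#'
#' Returns the forward- or reverse-strand sequence of a (possibly
#' origin-wrapping) interval.
#'
#' @param genome An [annotated_genome()].
#' @param start,end 0-based half-open interval; `end` may exceed the genome
#'   length for origin-wrapping features on a circular genome.
#' @param strand `"+"` (default) or `"-"`; `"-"` returns the reverse
#'   complement.
#' @return Character scalar.
#' @export
feature_seq <- function(genome, start, end, strand = "+") {
  L <- genome_length(genome)
  if (end <= L) {
    s <- substr(genome$sequence, start + 1L, end)
  } else {
    if (!genome$circular) abort("interval wraps origin of a linear genome")
    s <- paste0(substr(genome$sequence, start + 1L, L),
                substr(genome$sequence, 1L, end - L))
  }
  if (strand == "-") revcomp(s) else s
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Rotate a circular genome to a new origin
#'
#' Linearizes a circular genome starting at `new_origin`, shifting all
#' feature coordinates accordingly. Features that end up spanning the new
#' origin get `wraps_origin = TRUE`.
#'
#' @param genome An [annotated_genome()]; must be circular.
#' @param new_origin 0-based position that becomes position 0.
#' @return A rotated [annotated_genome()].
#' @export
rotate_genome <- function(genome, new_origin) {
  L <- genome_length(genome)
  new_origin <- as.integer(new_origin %% L)
  if (!genome$circular) abort("cannot rotate a linear genome")
  if (new_origin == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, new_origin + 1L, L),
                 substr(genome$sequence, 1L, new_origin))
  f <- genome$features
  if (nrow(f)) {
    width <- f$end - f$start
    f$start <- (f$start - new_origin) %% L
    f$end <- f$start + width
    f$wraps_origin <- f$end > L
  }
  annotated_genome(genome$id, seq2, f, circular = TRUE)
}

#' Mask selected feature kinds with N
#'
#' Replaces every position covered by a feature of one of the requested
#' kinds with `N`, leaving all other positions untouched. Used to remove
#' mobile and repetitive DNA (IS elements, prophage) before whole-genome
#' k-mer matching, the same preprocessing applied before plotting
#' genome-wide synteny.
#'
#' @param genome An [annotated_genome()].
#' @param kinds Character vector of feature kinds to mask (subset of
#'   `FEATURE_KINDS`). Empty set returns the sequence unchanged.
#' @return Masked sequence as a character scalar (same length as input).
#' @export
mask_features <- function(genome, kinds) {
  stopifnot(all(kinds %in% FEATURE_KINDS))
  seq <- genome$sequence
  if (length(kinds) == 0L) return(seq)
  f <- dplyr::filter(genome$features, .data$kind %in% kinds)
  if (nrow(f) == 0L) return(seq)
  L <- nchar(seq)
  ir <- features_to_ranges(f, L)
  ir <- IRanges::reduce(ir)
  pos <- unlist(mapply(seq.int, IRanges::start(ir), IRanges::end(ir),
                       SIMPLIFY = FALSE), use.names = FALSE)
  raw <- charToRaw(seq)
  raw[pos] <- charToRaw("N")
  rawToChar(raw)
}

# 1-based IRanges of features, splitting origin-wrapping ones
features_to_ranges <- function(f, L) {
  w <- f$end > L
  plain <- f[!w, , drop = FALSE]
  ir <- IRanges::IRanges(start = plain$start + 1L, end = plain$end)
  if (any(w)) {
    wf <- f[w, , drop = FALSE]
    ir <- c(ir,
            IRanges::IRanges(start = wf$start + 1L, end = L),
            IRanges::IRanges(start = 1L, end = wf$end - L))
  }
  ir
}

#' Intergenic intervals of a genome
#'
#' The complement of all CDS, pseudogene, rRNA and tRNA features; used as
#' the "intergenic space" definition of the IS clustering test.
#'
#' @param genome An [annotated_genome()].
#' @return Tibble with 0-based half-open `start`, `end` columns.
#' @export
intergenic_ranges <- function(genome) {
  L <- genome_length(genome)
  genic_kinds <- c("CDS", "pseudogene", "rRNA_16S", "rRNA_23S", "rRNA_5S",
                   "tRNA")
  f <- dplyr::filter(genome$features, .data$kind %in% genic_kinds)
  if (nrow(f) == 0L) return(tibble(start = 0L, end = L))
  ir <- IRanges::reduce(features_to_ranges(f, L))
  gap <- IRanges::gaps(ir, start = 1L, end = L)
  tibble(start = IRanges::start(gap) - 1L, end = IRanges::end(gap))
}

#' Sequence of a feature identified by locus tag
#'
#' Strand-aware coding-direction sequence of a single feature.
#'
#' @param genome An [annotated_genome()].
#' @param locus_tag Locus tag of the feature.
#' @return Character scalar.
#' @export
cds_seq <- function(genome, locus_tag) {
  i <- match(locus_tag, genome$features$locus_tag)
  if (is.na(i)) abort(sprintf("no feature with locus_tag '%s'", locus_tag))
  f <- genome$features[i, ]
  feature_seq(genome, f$start, f$end, f$strand)
}
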