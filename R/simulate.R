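#' Configuration for the synthetic ancestor genome
#'
#' Describes a gene-dense bacterial chromosome with two replichores and the
#' compositional signals the architecture analyses rely on: strand-biased
#' G/C composition producing polarized GC skew, ori-to-ter polarized KOPS
#' motifs, a dif site at the terminus, and rRNA operons with a known stem
#' pairing map. Defaults emulate a free-living enterobacterial relative at
#' desk scale: ~55% GC, ~85% coding density, mean CDS around 900 nt.
#'
#' @param n_genes Number of protein-coding genes.
#' @param gene_len_mean,gene_len_sd,gene_len_min Gene length distribution
#'   (nt; rounded to codon multiples, includes start and stop codons).
#' @param intergenic_fraction Fraction of the chromosome outside genes.
#' @param skew_bias Per-base excess G probability on the leading strand
#'   (replichore-polarized composition bias).
#' @param n_kops Number of planted KOPS motifs.
#' @param kops_polarity Fraction of planted KOPS oriented ori-to-ter.
#' @param n_rrna_operons Number of 16S rRNA gene copies.
#' @param rrna_len Length of the synthetic 16S gene (nt).
#' @param gc_content Genomic GC fraction.
#' @param genome_length Optional total length; derived from the gene
#'   complement and `intergenic_fraction` when `NULL`. An explicit length
#'   too small to hold the genes is an error.
#' @param seed Integer seed; the generator is fully deterministic per seed.
#' @return Named list of class `ancestor_config`.
#' @export
ancestor_config <- function(n_genes = 200L, gene_len_mean = 900,
                            gene_len_sd = 200, gene_len_min = 300,
                            intergenic_fraction = 0.15, skew_bias = 0.05,
                            n_kops = 150L, kops_polarity = 1.0,
                            n_rrna_operons = 2L, rrna_len = 1500L,
                            gc_content = 0.55, genome_length = NULL,
                            seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), gene_len_mean = gene_len_mean,
              gene_len_sd = gene_len_sd, gene_len_min = gene_len_min,
              intergenic_fraction = intergenic_fraction,
              skew_bias = skew_bias, n_kops = as.integer(n_kops),
              kops_polarity = kops_polarity,
              n_rrna_operons = as.integer(n_rrna_operons),
              rrna_len = as.integer(rrna_len), gc_content = gc_content,
              genome_length = genome_length, seed = as.integer(seed))
  stopifnot(cfg$intergenic_fraction >= 0, cfg$intergenic_fraction < 1,
            cfg$kops_polarity >= 0, cfg$kops_polarity <= 1,
            cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$skew_bias >= 0, cfg$skew_bias < cfg$gc_content / 2)
  class(cfg) <- "ancestor_config"
  cfg
}

# forward-strand base probabilities at a leading/lagging position
strand_base_probs <- function(gc, b, leading) {
  g <- if (leading) gc / 2 + b else gc / 2 - b
  c(A = (1 - gc) / 2, C = gc - g, G = g, T = (1 - gc) / 2)
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

# codon sampling weights under a coding-strand base composition
codon_weights <- function(probs) {
  cods <- sense_codons()
  w <- vapply(cods, function(cd) {
    prod(probs[strsplit(cd, "")[[1]]])
  }, numeric(1))
  w / sum(w)
}

#' Generate a synthetic ancestor genome
#'
#' Builds the chromosome described by an [ancestor_config()]: valid ORFs
#' (start codon, no internal stop, terminal stop) with replichore-biased
#' codon composition, biased intergenic spacers, planted polarized KOPS
#' sites (chance motif occurrences are removed where possible so the
#' planted polarity is exact), a dif site at the terminus, and identical
#' 16S rRNA copies with a consistent stem pairing map and variability map.
#'
#' @param cfg An [ancestor_config()].
#' @return List with `genome` ([annotated_genome()]) and `meta` (list:
#'   `ori`, `ter`, `dif_pos`, `kops` tibble, `pairing_map`,
#'   `variability_map`, `rrna_seq`, `config`).
#' @export
generate_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "ancestor_config"))
  set.seed(cfg$seed)
  glens <- pmax(cfg$gene_len_min,
                round(rnorm(cfg$n_genes, cfg$gene_len_mean,
                            cfg$gene_len_sd)))
  glens <- as.integer(glens - glens %% 3L)
  glens <- pmax(glens, 150L)
  rr <- make_synthetic_16s(cfg$rrna_len, gc = cfg$gc_content)
  item_len <- sum(glens) + cfg$n_rrna_operons * nchar(rr$seq)
  L <- cfg$genome_length %||%
    as.integer(ceiling(item_len / (1 - cfg$intergenic_fraction)))
  if (item_len >= L) abort("genes do not fit in the requested genome length")
  ter <- L %/% 2L
  n_items <- cfg$n_genes + cfg$n_rrna_operons
  spacer_total <- L - item_len
  sp <- as.vector(rmultinom(1L, spacer_total, rep(1, n_items + 1L)))
  # interleave rRNA operons among the genes
  kinds <- c(rep("gene", cfg$n_genes), rep("rrna", cfg$n_rrna_operons))
  kinds <- kinds[sample.int(n_items)]
  lens <- integer(n_items)
  lens[kinds == "gene"] <- glens
  lens[kinds == "rrna"] <- nchar(rr$seq)
  leading_probs_A <- strand_base_probs(cfg$gc_content, cfg$skew_bias, TRUE)
  lagging_probs_A <- strand_base_probs(cfg$gc_content, cfg$skew_bias, FALSE)
  w_lead <- codon_weights(leading_probs_A)
  w_lagg <- codon_weights(lagging_probs_A)
  cods <- sense_codons()
  pieces <- character(2L * n_items + 1L)
  feats <- vector("list", n_items)
  pos <- 0L
  gi <- 0L
  spacer_iv <- list()
  for (i in seq_len(n_items + 1L)) {
    # spacer before item i
    if (sp[i] > 0L) {
      on_A <- (pos + sp[i] %/% 2L) < ter
      pr <- if (on_A) leading_probs_A else lagging_probs_A
      pieces[2L * i - 1L] <- paste(sample(names(pr), sp[i], replace = TRUE,
                                          prob = pr), collapse = "")
      spacer_iv[[length(spacer_iv) + 1L]] <- c(pos, pos + sp[i])
    }
    pos <- pos + sp[i]
    if (i > n_items) break
    if (kinds[i] == "rrna") {
      pieces[2L * i] <- rr$seq
      feats[[i]] <- feature_table(kind = "rRNA_16S", start = pos,
                                  end = pos + lens[i], strand = "+",
                                  locus_tag = sprintf("anc_r%02d",
                                                      sum(kinds[1:i] == "rrna")))
    } else {
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      on_A <- (pos + lens[i] %/% 2L) < ter
      # coding strand drawn with leading-strand bias when the gene is
      # co-oriented with its replichore's leading strand
      lead_coding <- (strand == "+") == on_A
      w <- if (lead_coding) w_lead else w_lagg
      ncod <- lens[i] %/% 3L
      body <- sample(cods, ncod - 2L, replace = TRUE, prob = w)
      body[body %in% STOP_CODONS] <- "CTG"
      cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
      pieces[2L * i] <- if (strand == "+") cds else revcomp(cds)
      feats[[i]] <- feature_table(kind = "CDS", start = pos,
                                  end = pos + lens[i], strand = strand,
                                  locus_tag = sprintf("anc_g%04d", gi))
    }
    pos <- pos + lens[i]
  }
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == L)
  features <- bind_rows(feats)
  # --- plant KOPS, dif; remove chance motifs ---
  planted <- plant_signals(seq, features, spacer_iv, cfg, L, ter)
  genome <- annotated_genome("ancestor", planted$seq, features)
  vm <- tibble(pos = seq_len(nchar(rr$seq)),
               class = sample(1:6, nchar(rr$seq), replace = TRUE,
                              prob = c(0.25, 0.2, 0.18, 0.15, 0.12, 0.1)))
  list(genome = genome,
       meta = list(ori = 0L, ter = ter, dif_pos = planted$dif_pos,
                   kops = planted$kops, pairing_map = rr$pairing,
                   variability_map = vm, rrna_seq = rr$seq, config = cfg))
}

# plants KOPS motifs and the dif site in intergenic spacers and removes
# chance KOPS motif occurrences (synonymous codon swap inside genes where
# possible, direct substitution in intergenic DNA)
plant_signals <- function(seq, features, spacer_iv, cfg, L, ter,
                          motif = "GGGNAGGG") {
  raw <- charToRaw(seq)
  # eligible spacer slots of >= 34 nt, margin 3 nt
  slots <- purrr::keep(spacer_iv, ~ (.x[2] - .x[1]) >= 40L)
  if (length(slots) < 2L) abort("not enough intergenic space for signals")
  # dif near ter: pick the slot whose midpoint is closest to ter
  mid <- vapply(slots, function(s) (s[1] + s[2]) / 2, numeric(1))
  dif_slot <- slots[[which.min(abs(mid - ter))]]
  dif_pos <- (dif_slot[1] + dif_slot[2] - nchar(DIF_SITE)) %/% 2L
  raw[(dif_pos + 1L):(dif_pos + nchar(DIF_SITE))] <-
    charToRaw(DIF_SITE)
  # KOPS placements: sample positions inside slots, non-overlapping
  cand <- purrr::map(slots, function(s) {
    lo <- s[1] + 3L; hi <- s[2] - 11L
    if (hi <= lo) return(integer())
    seq.int(lo, hi, by = 12L)
  })
  cand <- unlist(cand)
  cand <- setdiff(cand, seq.int(dif_pos - 12L, dif_pos + nchar(DIF_SITE)))
  if (length(cand) < cfg$n_kops) {
    abort("not enough intergenic space for the requested KOPS count")
  }
  kpos <- sort(sample(cand, cfg$n_kops))
  on_A <- kpos < ter
  polarized <- runif(cfg$n_kops) < cfg$kops_polarity
  strand <- ifelse(xor(on_A, polarized), "-", "+")
  for (i in seq_along(kpos)) {
    inst <- sub("N", sample(c("A", "C", "G", "T"), 1L), motif)
    s <- if (strand[i] == "+") inst else revcomp(inst)
    raw[(kpos[i] + 1L):(kpos[i] + 8L)] <- charToRaw(s)
  }
  seq2 <- rawToChar(raw)
  seq2 <- scrub_chance_kops(seq2, features, kpos, motif)
  list(seq = seq2, dif_pos = dif_pos,
       kops = tibble(position = kpos, strand = strand))
}

scrub_chance_kops <- function(seq, features, planted_pos, motif) {
  hits <- find_kops(seq, motif)
  chance <- dplyr::filter(hits, !(.data$position %in% planted_pos))
  if (nrow(chance) == 0L) return(seq)
  raw <- charToRaw(seq)
  cds <- dplyr::filter(features, .data$kind == "CDS")
  for (i in seq_len(nrow(chance))) {
    p <- chance$position[i]              # 0-based motif start (fwd coords)
    # which gene (if any) covers the motif?
    j <- which(cds$start <= p & cds$end >= p + 8L)
    if (!length(j)) {
      # free DNA (or partially genic boundary): break the motif at a
      # position outside any gene if one exists
      cols <- (p + 1L):(p + 8L)
      in_gene <- vapply(cols - 1L, function(q) {
        any(cds$start <= q & q < cds$end)
      }, logical(1))
      free <- cols[!in_gene]
      if (!length(free)) next
      q <- free[(length(free) + 1L) %/% 2L]
      cur <- rawToChar(raw[q])
      raw[q] <- charToRaw(switch(cur, G = "C", C = "G", A = "T", T = "A",
                                 N = "N"))
    } else {
      raw <- scrub_motif_in_gene(raw, p, cds[j[1], ])
    }
  }
  seq2 <- rawToChar(raw)
  # a swap can occasionally create a new chance motif; one more pass
  left <- dplyr::filter(find_kops(seq2, motif),
                        !(.data$position %in% planted_pos))
  if (nrow(left) > 0L && nrow(left) < nrow(chance)) {
    seq2 <- scrub_chance_kops(seq2, features, planted_pos, motif)
  }
  seq2
}

# attempt a synonymous codon swap that destroys a chance motif inside a CDS
scrub_motif_in_gene <- function(raw, p, gene) {
  gc_map <- Biostrings::GENETIC_CODE
  for (col in (p + 1L):(p + 8L)) {
    # codon (coding orientation) covering genome column col
    off <- (col - 1L) - gene$start
    if (gene$strand == "+") {
      ci <- off %/% 3L                     # 0-based codon index
      cs <- gene$start + 3L * ci
      codon <- rawToChar(raw[(cs + 1L):(cs + 3L)])
      within <- off %% 3L + 1L
    } else {
      off_r <- (gene$end - 1L - (col - 1L))
      ci <- off_r %/% 3L
      ce <- gene$end - 3L * ci
      codon <- revcomp(rawToChar(raw[(ce - 2L):ce]))
      within <- off_r %% 3L + 1L
    }
    if (ci == 0L) next                     # never touch the start codon
    syn <- names(gc_map)[gc_map == gc_map[codon]]
    syn <- setdiff(syn, c(codon, STOP_CODONS))
    syn <- syn[substr(syn, within, within) != substr(codon, within, within)]
    if (!length(syn)) next
    new_codon <- syn[1]
    if (gene$strand == "+") {
      raw[(cs + 1L):(cs + 3L)] <- charToRaw(new_codon)
    } else {
      raw[(ce - 2L):ce] <- charToRaw(revcomp(new_codon))
    }
    return(raw)
  }
  raw
}

#' Synthetic 16S rRNA gene with a stem pairing map
#'
#' Generates a random rRNA-like sequence in which designated stem regions
#' are strictly complementary (Watson-Crick) between arms, and returns the
#' pairing map that records those constraints.
#'
#' @param len Gene length (nt).
#' @param n_stems Number of stems (default `len %/% 75`).
#' @param stem_len Arm length of each stem (nt).
#' @param gc GC content.
#' @return List `seq`, `pairing` (tibble `i`, `j`, 1-based).
#' @export
make_synthetic_16s <- function(len, n_stems = len %/% 75L, stem_len = 8L,
                               gc = 0.55) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(probs), len, replace = TRUE, prob = probs)
  # lay out stems as hairpins: arm1 at a, arm2 at a + stem_len + loop
  span <- 3L * stem_len + 6L
  anchors <- seq.int(2L, len - span - 2L, length.out = n_stems)
  pairs <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (a in round(anchors)) {
    i1 <- a:(a + stem_len - 1L)
    j1 <- (a + 2L * stem_len + 6L):(a + stem_len + 7L)  # reversed partner
    s[j1] <- comp[s[i1]]
    pairs[[length(pairs) + 1L]] <- tibble(i = i1, j = j1)
  }
  pairing <- bind_rows(pairs) %>% arrange(.data$i)
  list(seq = paste(s, collapse = ""), pairing = pairing)
}

#' Generate an IS element consensus library
#'
#' Two synthetic IS families, each a transposase ORF spanning the whole
#' element, used both by the degeneration simulator and as input to
#' [annotate_is()].
#'
#' @param seed Integer seed.
#' @param lengths Named integer vector of element lengths (codon
#'   multiples).
#' @param gc GC content.
#' @return Named character vector of consensus sequences.
#' @export
generate_is_library <- function(seed = 1L,
                                lengths = c(ISSyn1 = 999L, ISSyn2 = 1200L),
                                gc = 0.5) {
  set.seed(seed + 777L)
  cods <- sense_codons()
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- codon_weights(probs)
  vapply(lengths, function(len) {
    ncod <- len %/% 3L
    body <- sample(cods, ncod - 2L, replace = TRUE, prob = w)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
}

#' Write all artifacts of a simulated genome pair
#'
#' Emits the ancestor and derived genomes (FASTA + GFF3), the IS consensus
#' library (FASTA), the 16S stem pairing and variability maps (TSV) and
#' the event/truth ledger (JSON) into a directory, so a simulation can be
#' re-analysed from files alone.
#'
#' @param ancestor Output of [generate_ancestor()].
#' @param derived Output of [degenerate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(ancestor, derived, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  suppressWarnings({
    write_genome(ancestor$genome, file.path(dir, "ancestor"), "fasta+gff3")
    write_genome(derived$genome, file.path(dir, "derived"), "fasta+gff3")
  })
  lib <- Biostrings::DNAStringSet(derived$is_library)
  Biostrings::writeXStringSet(lib, file.path(dir, "is_library.fasta"))
  write.table(ancestor$meta$pairing_map,
              file.path(dir, "pairing_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ancestor$meta$variability_map,
              file.path(dir, "variability_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(events = derived$ledger$events,
         truth = derived$ledger$truth,
         params = unclass(derived$ledger$params)),
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read back a ledger event list written by [write_simulation()]
#' @param path Path to `ledger.json`.
#' @return List with `events` (replayable via [replay_ledger()]) and
#'   `truth`.
#' @export
read_ledger <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  ev <- lapply(j$events, function(e) {
    if (!is.null(e$features)) {
      rows <- lapply(e$features, function(row) {
        as_tibble(lapply(row, function(x) if (is.null(x)) NA else x))
      })
      e$features <- bind_rows(rows)
    }
    e
  })
  list(events = ev, truth = j$truth)
}
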