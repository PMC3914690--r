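#' Parameters of the genome degeneration process
#'
#' Controls the event menu applied to an ancestor genome, mirroring the
#' degenerative processes observed in nascent endosymbionts: per-gene
#' inactivation (frameshift / premature stop / truncation), IS element
#' insertions with an intergenic bias, inversions and translocations that
#' disturb replichore symmetry, IS-bounded tandem duplications, deletions,
#' and a background of (within genes, synonymous-only) substitutions.
#'
#' @param p_pseudo Per-gene inactivation probability.
#' @param mix Named weights for inactivation types
#'   (`frameshift_indel`, `premature_stop`, `truncation`); normalised to
#'   sum to 1.
#' @param n_is_insertions Number of IS element insertions.
#' @param is_intergenic_bias Probability that an insertion targets
#'   intergenic space rather than a gene body.
#' @param n_inversions,n_translocations Numbers of rearrangements. Their
#'   breakpoints always fall in feature-free DNA, and segment lengths are
#'   drawn at the IS-pair spacing scale (inversions 2-10 kb,
#'   translocations 1-15 kb), the scale at which IS-mediated
#'   recombination operates.
#' @param n_duplications Number of IS-bounded tandem duplications.
#' @param duplication_length,duplication_subs,duplication_indels Length of
#'   the duplicated region and the divergence (substitutions, single-nt
#'   indels) applied to the second copy.
#' @param n_deletions,deletion_length Segmental deletions.
#' @param mu Background substitution rate per site; applied as synonymous
#'   codon exchanges inside CDS so that background divergence never
#'   inactivates a gene.
#' @param seed Integer seed.
#' @return Named list of class `degeneration_params`.
#' @export
degeneration_params <- function(p_pseudo = 0.4,
                                mix = c(frameshift_indel = 0.4,
                                        premature_stop = 0.4,
                                        truncation = 0.2),
                                n_is_insertions = 30L,
                                is_intergenic_bias = 0.85,
                                n_inversions = 2L, n_translocations = 1L,
                                n_duplications = 0L,
                                duplication_length = 13476L,
                                duplication_subs = 13L,
                                duplication_indels = 4L,
                                n_deletions = 0L, deletion_length = 5000L,
                                mu = 0.005, seed = 1L) {
  stopifnot(p_pseudo >= 0, p_pseudo <= 1,
            is_intergenic_bias >= 0, is_intergenic_bias <= 1, mu >= 0)
  p <- list(p_pseudo = p_pseudo, mix = mix / sum(mix),
            n_is_insertions = as.integer(n_is_insertions),
            is_intergenic_bias = is_intergenic_bias,
            n_inversions = as.integer(n_inversions),
            n_translocations = as.integer(n_translocations),
            n_duplications = as.integer(n_duplications),
            duplication_length = as.integer(duplication_length),
            duplication_subs = as.integer(duplication_subs),
            duplication_indels = as.integer(duplication_indels),
            n_deletions = as.integer(n_deletions),
            deletion_length = as.integer(deletion_length),
            mu = mu, seed = as.integer(seed))
  class(p) <- "degeneration_params"
  p
}

# ---- genome-edit primitives (state = list(seq, features)) -------------------

gs_substitute <- function(state, pos, base) {
  raw <- charToRaw(state$seq)
  raw[pos + 1L] <- charToRaw(paste(base, collapse = ""))
  state$seq <- rawToChar(raw)
  state
}

gs_insert <- function(state, pos, seq, new_features = NULL) {
  len <- nchar(seq)
  f <- state$features
  if (nrow(f)) {
    contained <- f$start < pos & pos < f$end
    downstream <- f$start >= pos
    f$end[contained] <- f$end[contained] + len
    f$start[downstream] <- f$start[downstream] + len
    f$end[downstream] <- f$end[downstream] + len
  }
  if (!is.null(new_features) && nrow(new_features)) {
    nf <- new_features
    nf$start <- nf$start + pos
    nf$end <- nf$end + pos
    f <- bind_rows(f, nf)
  }
  state$features <- arrange(f, .data$start)
  state$seq <- paste0(substr(state$seq, 1L, pos), seq,
                      substr(state$seq, pos + 1L, nchar(state$seq)))
  state
}

gs_delete <- function(state, start, end) {
  len <- end - start
  f <- state$features
  dropped <- NULL
  if (nrow(f)) {
    inside <- f$start >= start & f$end <= end
    contains <- f$start < start & f$end > end    # deletion inside feature
    downstream <- f$start >= end
    partial <- !inside & !contains & !downstream & f$end > start
    if (any(partial)) abort("deletion would bisect a feature")
    dropped <- f[inside, , drop = FALSE]
    f$end[contains] <- f$end[contains] - len
    f$start[downstream] <- f$start[downstream] - len
    f$end[downstream] <- f$end[downstream] - len
    f <- f[!inside, , drop = FALSE]
  }
  state$features <- f
  state$seq <- paste0(substr(state$seq, 1L, start),
                      substr(state$seq, end + 1L, nchar(state$seq)))
  state$dropped <- dropped
  state
}

gs_invert <- function(state, start, end) {
  f <- state$features
  if (nrow(f)) {
    inside <- f$start >= start & f$end <= end
    straddle <- !inside & f$start < end & f$end > start
    if (any(straddle)) abort("inversion breakpoint inside a feature")
    ns <- start + (end - f$end[inside])
    ne <- start + (end - f$start[inside])
    f$start[inside] <- ns
    f$end[inside] <- ne
    f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
    state$features <- arrange(f, .data$start)
  }
  seg <- revcomp(substr(state$seq, start + 1L, end))
  state$seq <- paste0(substr(state$seq, 1L, start), seg,
                      substr(state$seq, end + 1L, nchar(state$seq)))
  state
}

gs_translocate <- function(state, start, end, dest) {
  seg <- substr(state$seq, start + 1L, end)
  f <- state$features
  inside <- f$start >= start & f$end <= end
  straddle <- !inside & f$start < end & f$end > start
  if (any(straddle)) abort("translocation breakpoint inside a feature")
  moved <- f[inside, , drop = FALSE]
  moved$start <- moved$start - start
  moved$end <- moved$end - start
  state$features <- f[!inside, , drop = FALSE]
  state <- gs_delete_plain(state, start, end)
  gs_insert(state, dest, seg, moved)
}

# deletion that assumes the moved features were already removed
gs_delete_plain <- function(state, start, end) {
  len <- end - start
  f <- state$features
  if (nrow(f)) {
    contains <- f$start < start & f$end > end
    downstream <- f$start >= end
    f$end[contains] <- f$end[contains] - len
    f$start[downstream] <- f$start[downstream] - len
    f$end[downstream] <- f$end[downstream] - len
    state$features <- f
  }
  state$seq <- paste0(substr(state$seq, 1L, start),
                      substr(state$seq, end + 1L, nchar(state$seq)))
  state
}

apply_event <- function(state, ev) {
  switch(ev$op,
         subs = gs_substitute(state, ev$pos, ev$base),
         ins = gs_insert(state, ev$pos, ev$seq,
                         if (!is.null(ev$features)) as_tibble(ev$features)),
         del = gs_delete(state, ev$start, ev$end),
         inv = gs_invert(state, ev$start, ev$end),
         translocate = gs_translocate(state, ev$start, ev$end, ev$dest),
         abort(sprintf("unknown ledger op '%s'", ev$op)))
}

#' Replay a truth ledger
#'
#' Applies the recorded event list to the ancestor genome; by construction
#' the result is byte-identical to the derived genome produced by
#' [degenerate()].
#'
#' @param ancestor An [annotated_genome()] (the ancestor).
#' @param events Event list from a [degenerate()] ledger.
#' @return The derived [annotated_genome()].
#' @export
replay_ledger <- function(ancestor, events) {
  state <- list(seq = ancestor$sequence, features = ancestor$features)
  for (ev in events) state <- apply_event(state, ev)
  annotated_genome("derived", state$seq, state$features)
}

# map truth coordinates through a coordinate-shifting event ------------------

map_point <- function(p, ev) {
  if (is.na(p)) return(NA_integer_)
  switch(ev$op,
         subs = p,
         ins = if (p >= ev$pos) p + nchar(ev$seq) else p,
         del = {
           if (p >= ev$start && p < ev$end) NA_integer_
           else if (p >= ev$end) p - (ev$end - ev$start) else p
         },
         inv = {
           if (p >= ev$start && p < ev$end) ev$start + (ev$end - 1L - p)
           else p
         },
         translocate = {
           len <- ev$end - ev$start
           if (p >= ev$start && p < ev$end) {
             q <- p - ev$start
             ev$dest + q
           } else {
             q <- if (p >= ev$end) p - len else p
             if (q >= ev$dest) q + len else q
           }
         },
         p)
}

map_interval <- function(s, e, ev) {
  if (is.na(s) || is.na(e)) return(c(NA_integer_, NA_integer_))
  if (ev$op == "inv" && s >= ev$start && e <= ev$end) {
    return(c(ev$start + (ev$end - e), ev$start + (ev$end - s)))
  }
  a <- map_point(s, ev)
  b <- map_point(e - 1L, ev)
  if (is.na(a) || is.na(b) || b < a) return(c(NA_integer_, NA_integer_))
  c(a, b + 1L)
}

# ---- free (feature-less) DNA helpers ---------------------------------------

free_ranges <- function(state, margin = 3L) {
  L <- nchar(state$seq)
  f <- state$features
  if (nrow(f) == 0L) return(tibble(start = 0L, end = L))
  ir <- IRanges::reduce(IRanges::IRanges(f$start + 1L - margin,
                                         f$end + margin))
  gap <- IRanges::gaps(ir, start = 1L, end = L)
  out <- tibble(start = IRanges::start(gap) - 1L, end = IRanges::end(gap))
  dplyr::filter(out, .data$end - .data$start >= 2L)
}

sample_free_point <- function(state) {
  fr <- free_ranges(state)
  w <- fr$end - fr$start
  i <- sample.int(nrow(fr), 1L, prob = w)
  fr$start[i] + sample.int(w[i], 1L) - 1L
}

# free point as close as possible to `target`
nearest_free_point <- function(state, target) {
  fr <- free_ranges(state)
  cand <- pmin(pmax(target, fr$start), fr$end - 1L)
  cand[which.min(abs(cand - target))]
}

# truth-coordinate bookkeeping -----------------------------------------------

empty_truth <- function() {
  list(
    inactivated = tibble(locus = character(), type = character()),
    is_insertions = tibble(locus_tag = character(), pos = integer(),
                           family = character(), strand = character(),
                           target = character(), gene_locus = character()),
    inversions = tibble(start = integer(), end = integer()),
    translocations = tibble(start = integer(), end = integer(),
                            dest = integer()),
    duplications = tibble(start_a = integer(), end_a = integer(),
                          start_b = integer(), end_b = integer(),
                          n_subs = integer(), n_indels = integer(),
                          family = character(), length_nt = integer()),
    deletions = tibble(start = integer(), end = integer()),
    deleted_loci = character())
}

shift_truth <- function(truth, ev) {
  if (!ev$op %in% c("ins", "del", "inv", "translocate")) return(truth)
  miv <- function(s, e) {
    if (!length(s)) return(list(s = s, e = e))
    m <- t(mapply(function(a, b) map_interval(a, b, ev), s, e))
    list(s = as.integer(m[, 1]), e = as.integer(m[, 2]))
  }
  ii <- miv(truth$inversions$start, truth$inversions$end)
  truth$inversions$start <- ii$s; truth$inversions$end <- ii$e
  tt <- miv(truth$translocations$dest,
            truth$translocations$dest +
              (truth$translocations$end - truth$translocations$start))
  truth$translocations$dest <- tt$s
  da <- miv(truth$duplications$start_a, truth$duplications$end_a)
  db <- miv(truth$duplications$start_b, truth$duplications$end_b)
  truth$duplications$start_a <- da$s; truth$duplications$end_a <- da$e
  truth$duplications$start_b <- db$s; truth$duplications$end_b <- db$e
  if (nrow(truth$is_insertions)) {
    truth$is_insertions$pos <- vapply(truth$is_insertions$pos, map_point,
                                      integer(1), ev = ev)
  }
  truth
}

# coding-space -> genome-space coordinate for one gene feature
coding_to_genome <- function(f, i) {
  if (f$strand == "+") f$start + i else f$end - 1L - i
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

#' Apply a degeneration process to an ancestor genome
#'
#' Draws and applies the event series described by a
#' [degeneration_params()] in a fixed order (background substitutions,
#' gene inactivations, duplications, IS insertions, inversions,
#' translocations, deletions), recording every event in a ledger whose
#' replay ([replay_ledger()]) reproduces the derived genome byte-exactly.
#' Ground-truth records (inactivated loci with mutation types, IS
#' insertion sites, rearranged intervals, duplication divergence) are kept
#' in final derived-genome coordinates for recovery scoring.
#'
#' @param ancestor Output of [generate_ancestor()] (or an
#'   [annotated_genome()]).
#' @param params A [degeneration_params()].
#' @param is_library Optional named IS consensus vector; defaults to
#'   [generate_is_library()] seeded from `params$seed`.
#' @return List: `genome` (derived [annotated_genome()]), `ledger` (list
#'   with `events` and `truth`), `is_library`.
#' @export
degenerate <- function(ancestor, params = degeneration_params(),
                       is_library = NULL) {
  genome <- if (inherits(ancestor, "annotated_genome")) ancestor
            else ancestor$genome
  set.seed(params$seed)
  lib <- is_library %||% generate_is_library(params$seed)
  state <- list(seq = genome$sequence, features = genome$features)
  events <- list()
  truth <- empty_truth()
  push <- function(ev) {
    events[[length(events) + 1L]] <<- ev
    state <<- apply_event(state, ev)
    truth <<- shift_truth(truth, ev)
  }
  # 1. background substitutions -----------------------------------------
  bg <- background_substitutions(state, params$mu)
  if (length(bg$pos)) push(list(op = "subs", pos = bg$pos, base = bg$base))
  # 2. gene inactivations ------------------------------------------------
  genes <- dplyr::filter(state$features, .data$kind == "CDS")
  hit <- genes$locus_tag[runif(nrow(genes)) < params$p_pseudo]
  for (lt in hit) {
    type <- sample(names(params$mix), 1L, prob = params$mix)
    evs <- inactivation_events(state, lt, type)
    for (ev in evs) push(ev)
    truth$inactivated <- bind_rows(truth$inactivated,
                                   tibble(locus = lt, type = type))
  }
  # 3. duplications ------------------------------------------------------
  is_counter <- 0L
  for (d in seq_len(params$n_duplications)) {
    dup <- plan_duplication(state, params, lib)
    if (is.null(dup)) next
    il <- nchar(dup$is_seq)
    isf <- function(n) {
      feature_table(kind = "IS_element", start = 0L, end = il,
                    strand = "+", locus_tag = n, family = dup$family)
    }
    payload_feats <- bind_rows(
      isf(sprintf("is_d%03da", d)),
      mutate(dup$copy_features, start = .data$start + il,
             end = .data$end + il),
      mutate(isf(sprintf("is_d%03db", d)),
             start = il + nchar(dup$copy),
             end = 2L * il + nchar(dup$copy)))
    push(list(op = "ins", pos = dup$e0,
              seq = paste0(dup$is_seq, dup$copy, dup$is_seq),
              features = payload_feats))
    push(list(op = "ins", pos = dup$s0, seq = dup$is_seq,
              features = isf(sprintf("is_d%03dc", d))))
    clen <- nchar(dup$copy)
    truth$duplications <- bind_rows(truth$duplications, tibble(
      start_a = dup$s0 + il, end_a = dup$e0 + il,
      start_b = dup$e0 + 2L * il, end_b = dup$e0 + 2L * il + clen,
      n_subs = params$duplication_subs,
      n_indels = params$duplication_indels,
      family = dup$family, length_nt = dup$e0 - dup$s0))
    # inactivation status of copied genes follows the originals; copies
    # are paralogs and are left out of the truth gene set
  }
  # 4. IS insertions ------------------------------------------------------
  for (i in seq_len(params$n_is_insertions)) {
    fam <- sample(names(lib), 1L)
    strand <- sample(c("+", "-"), 1L)
    is_seq <- if (strand == "+") lib[[fam]] else revcomp(lib[[fam]])
    intergenic <- runif(1) < params$is_intergenic_bias
    gene_locus <- NA_character_
    if (intergenic) {
      fr <- free_ranges(state)
      j <- sample.int(nrow(fr), 1L, prob = fr$end - fr$start)
      pos <- fr$start[j] + sample.int(fr$end[j] - fr$start[j], 1L) - 1L
    } else {
      genes <- dplyr::filter(state$features, .data$kind == "CDS",
                             .data$end - .data$start >= 150L)
      g <- genes[sample.int(nrow(genes), 1L), ]
      pos <- g$start + 45L + sample.int(g$end - g$start - 90L, 1L) - 1L
      gene_locus <- g$locus_tag
      if (!gene_locus %in% truth$inactivated$locus) {
        truth$inactivated <- bind_rows(
          truth$inactivated,
          tibble(locus = gene_locus, type = "is_interruption"))
      }
    }
    is_counter <- is_counter + 1L
    tag <- sprintf("is_%03d", is_counter)
    push(list(op = "ins", pos = pos, seq = is_seq,
              features = feature_table(kind = "IS_element", start = 0L,
                                       end = nchar(is_seq),
                                       strand = strand, locus_tag = tag,
                                       family = fam)))
    truth$is_insertions <- bind_rows(truth$is_insertions, tibble(
      locus_tag = tag, pos = pos, family = fam, strand = strand,
      target = if (intergenic) "intergenic" else "genic",
      gene_locus = gene_locus))
  }
  # 5. inversions ---------------------------------------------------------
  # segment lengths at the IS-pair spacing scale (a few kb): IS-mediated
  # recombination acts between nearby elements, not across half the
  # chromosome
  for (i in seq_len(params$n_inversions)) {
    bp <- sample_breakpoints(state, min_len = 2000L, max_len = 10000L)
    if (is.null(bp)) next
    push(list(op = "inv", start = bp[1], end = bp[2]))
    truth$inversions <- bind_rows(truth$inversions,
                                  tibble(start = bp[1], end = bp[2]))
  }
  # 6. translocations ------------------------------------------------------
  for (i in seq_len(params$n_translocations)) {
    bp <- sample_breakpoints(state, min_len = 1000L, max_len = 15000L)
    if (is.null(bp)) next
    len <- bp[2] - bp[1]
    dest <- NULL
    for (try in 1:20) {
      cand <- sample_free_point(state)
      if (cand < bp[1] - 10L || cand > bp[2] + 10L) { dest <- cand; break }
    }
    if (is.null(dest)) next
    dest_post <- if (dest > bp[2]) dest - len else dest
    push(list(op = "translocate", start = bp[1], end = bp[2],
              dest = dest_post))
    truth$translocations <- bind_rows(
      truth$translocations,
      tibble(start = bp[1], end = bp[2], dest = dest_post))
  }
  # 7. deletions -----------------------------------------------------------
  for (i in seq_len(params$n_deletions)) {
    s <- sample_free_point(state)
    e <- nearest_free_point(state, s + params$deletion_length)
    if (e <= s + 100L) next
    pre <- state$features
    push(list(op = "del", start = s, end = e))
    gone <- setdiff(pre$locus_tag, state$features$locus_tag)
    truth$deletions <- bind_rows(truth$deletions,
                                 tibble(start = s, end = e))
    truth$deleted_loci <- c(truth$deleted_loci, gone)
  }
  derived <- annotated_genome("derived", state$seq, state$features)
  list(genome = derived,
       ledger = list(events = events, truth = truth, params = params),
       is_library = lib)
}

# two feature-free breakpoints, minimum (and optional maximum) separation
sample_breakpoints <- function(state, min_len = 2000L, max_len = NULL) {
  for (try in 1:40) {
    a <- sample_free_point(state)
    b <- if (is.null(max_len)) sample_free_point(state)
         else nearest_free_point(state, a + sample.int(max_len - min_len,
                                                       1L) + min_len)
    s <- min(a, b); e <- max(a, b)
    if (e - s >= min_len && (is.null(max_len) || e - s <= max_len * 2L)) {
      return(c(s, e))
    }
  }
  NULL
}

# synonymous-only background substitutions within CDS, free substitutions
# elsewhere; returns genome positions (0-based) and replacement bases
background_substitutions <- function(state, mu) {
  if (mu <= 0) return(list(pos = integer(), base = character()))
  gc_map <- Biostrings::GENETIC_CODE
  pos_all <- integer(); base_all <- character()
  genes <- dplyr::filter(state$features, .data$kind == "CDS")
  genic <- logical(nchar(state$seq))
  for (gi in seq_len(nrow(genes))) {
    f <- genes[gi, ]
    genic[(f$start + 1L):f$end] <- TRUE
    cds <- if (f$strand == "+") substr(state$seq, f$start + 1L, f$end)
           else revcomp(substr(state$seq, f$start + 1L, f$end))
    ncod <- nchar(cds) %/% 3L
    body <- 2:(ncod - 1L)
    chosen <- body[runif(length(body)) < 3 * mu]
    for (ci in chosen) {
      codon <- substr(cds, 3L * ci - 2L, 3L * ci)
      syn <- names(gc_map)[gc_map == gc_map[codon]]
      syn <- setdiff(syn, c(codon, STOP_CODONS))
      if (!length(syn)) next
      new_codon <- sample(syn, 1L)
      delta <- which(strsplit(codon, "")[[1]] !=
                       strsplit(new_codon, "")[[1]])
      for (k in delta) {
        cp <- 3L * (ci - 1L) + (k - 1L)      # 0-based coding position
        gp <- coding_to_genome(f, cp)
        nb <- substr(new_codon, k, k)
        if (f$strand == "-") nb <- complement_base(nb)
        pos_all <- c(pos_all, gp); base_all <- c(base_all, nb)
      }
    }
  }
  # non-CDS space (includes rRNA, spacers): free substitutions
  free_pos <- which(!genic) - 1L
  n_bg <- rbinom(1L, length(free_pos), mu)
  if (n_bg > 0L) {
    sel <- sample(free_pos, n_bg)
    cur <- strsplit(substr(state$seq, 1L, nchar(state$seq)), "")[[1]][sel + 1L]
    new <- vapply(cur, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    pos_all <- c(pos_all, sel); base_all <- c(base_all, unname(new))
  }
  o <- order(pos_all)
  list(pos = pos_all[o], base = base_all[o])
}

# events implementing one gene inactivation of the requested type
inactivation_events <- function(state, locus, type) {
  f <- state$features[match(locus, state$features$locus_tag), ]
  cds <- if (f$strand == "+") substr(state$seq, f$start + 1L, f$end)
         else revcomp(substr(state$seq, f$start + 1L, f$end))
  ncod <- nchar(cds) %/% 3L
  if (type == "frameshift_indel") {
    ci <- sample(4:(ncod - 4L), 1L)          # 1-based codon index
    len <- sample(c(1L, 1L, 2L), 1L)
    cp <- 3L * (ci - 1L)                     # 0-based coding position
    if (runif(1) < 0.5) {                    # deletion
      gp <- if (f$strand == "+") f$start + cp else f$end - cp - len
      return(list(list(op = "del", start = gp, end = gp + len)))
    }
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    gp <- if (f$strand == "+") f$start + cp else f$end - cp
    gseq <- if (f$strand == "+") ins else revcomp(ins)
    return(list(list(op = "ins", pos = gp, seq = gseq)))
  }
  # premature stop (alone, or followed by a downstream scramble)
  ci <- if (type == "truncation") {
    sample(seq(max(4L, round(0.3 * ncod)), round(0.7 * ncod)), 1L)
  } else {
    sample(4:(ncod - 4L), 1L)
  }
  stop_ev <- make_stop_event(cds, ci, f)
  if (type == "premature_stop") return(list(stop_ev))
  # truncation: scramble the coding sequence downstream of the new stop
  from <- 3L * ci                             # 0-based coding pos after stop
  to <- 3L * (ncod - 1L) - 1L                 # keep the terminal stop codon
  cp <- from:to
  new <- sample(c("A", "C", "G", "T"), length(cp), replace = TRUE)
  gp <- vapply(cp, function(p) coding_to_genome(f, p), numeric(1))
  nb <- if (f$strand == "-") complement_base(new) else new
  o <- order(gp)
  list(stop_ev,
       list(op = "subs", pos = as.integer(gp[o]), base = nb[o]))
}

# substitution event converting codon `ci` (1-based) of a gene to a stop
make_stop_event <- function(cds, ci, f) {
  codon <- substr(cds, 3L * ci - 2L, 3L * ci)
  cv <- strsplit(codon, "")[[1]]
  best <- NULL
  for (stp in STOP_CODONS) {
    d <- which(cv != strsplit(stp, "")[[1]])
    if (is.null(best) || length(d) < length(best$d)) {
      best <- list(stop = stp, d = d)
    }
  }
  sv <- strsplit(best$stop, "")[[1]]
  pos <- integer(); base <- character()
  for (k in best$d) {
    cp <- 3L * (ci - 1L) + (k - 1L)
    gp <- coding_to_genome(f, cp)
    nb <- if (f$strand == "-") complement_base(sv[k]) else sv[k]
    pos <- c(pos, gp); base <- c(base, nb)
  }
  o <- order(pos)
  list(op = "subs", pos = pos[o], base = base[o])
}

# plan one IS-bounded tandem duplication; NULL when no placement found
plan_duplication <- function(state, params, lib) {
  target <- params$duplication_length
  for (try in 1:20) {
    s0 <- sample_free_point(state)
    if (s0 + target + 2000L > nchar(state$seq)) next
    e0 <- nearest_free_point(state, s0 + target)
    if (abs((e0 - s0) - target) > 2500L || e0 - s0 < 3000L) next
    overl <- dplyr::filter(state$features, .data$end > s0,
                           .data$start < e0)
    if (any(startsWith(overl$kind, "rRNA"))) next
    seg <- substr(state$seq, s0 + 1L, e0)
    copy <- mutate_copy(seg, params$duplication_subs,
                        params$duplication_indels)
    inside <- dplyr::filter(state$features, .data$start >= s0,
                            .data$end <= e0)
    cf <- if (nrow(inside)) {
      mutate(inside, start = .data$start - s0, end = .data$end - s0,
             locus_tag = paste0(.data$locus_tag, "_dup"))
    } else feature_table()
    fam <- sample(names(lib), 1L)
    return(list(s0 = s0, e0 = e0, copy = copy, copy_features = cf,
                family = fam, is_seq = lib[[fam]]))
  }
  warn("no suitable placement found for a duplication; skipped")
  NULL
}

# diverge a duplicated copy: n_subs substitutions + n_indels single-nt indels
mutate_copy <- function(seg, n_subs, n_indels) {
  v <- strsplit(seg, "")[[1]]
  sub_pos <- sample.int(length(v) - 60L, n_subs) + 30L
  for (p in sub_pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  out <- v
  if (n_indels > 0L) {
    ind_pos <- sort(sample(setdiff(seq(31L, length(v) - 30L),
                                   c(sub_pos - 1L, sub_pos, sub_pos + 1L)),
                           n_indels), decreasing = TRUE)
    for (p in ind_pos) {
      if (runif(1) < 0.5) {
        out <- out[-p]
      } else {
        out <- append(out, sample(c("A", "C", "G", "T"), 1L), after = p)
      }
    }
  }
  paste(out, collapse = "")
}

#' Simulate ortholog pairs under a synonymous/nonsynonymous rate dial
#'
#' Generates random ORFs and diverged copies under a simple
#' accept/reject substitution process: proposals are uniform single-base
#' changes in the codon body; changes creating stop codons are rejected,
#' and nonsynonymous changes are accepted with probability `omega`.
#' `omega = 1` gives neutral evolution (equal per-site synonymous and
#' nonsynonymous substitution probability); small `omega` gives purifying
#' selection.
#'
#' @param n_genes Number of gene pairs.
#' @param n_codons Codons per gene.
#' @param rate Expected substitution attempts per site.
#' @param omega Acceptance probability for nonsynonymous changes.
#' @param gc GC content of the ancestral ORFs.
#' @param seed Integer seed.
#' @return Tibble with `locus`, `ref`, `der` coding sequences.
#' @export
simulate_selection_pairs <- function(n_genes, n_codons, rate = 0.02,
                                     omega = 1, gc = 0.5, seed = 1L) {
  set.seed(seed)
  cods <- sense_codons()
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- codon_weights(probs)
  gc_map <- Biostrings::GENETIC_CODE
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    body <- sample(cods, n_codons - 2L, replace = TRUE, prob = w)
    ref <- c("ATG", body, "TAA")
    der <- ref
    n_att <- round(3 * n_codons * rate)
    sites <- sample(3L * (n_codons - 2L), n_att, replace = TRUE)
    for (s in sites) {
      ci <- (s - 1L) %/% 3L + 2L              # codon index in der
      k <- (s - 1L) %% 3L + 1L
      codon <- der[ci]
      alt <- sample(setdiff(c("A", "C", "G", "T"),
                            substr(codon, k, k)), 1L)
      cand <- codon
      substr(cand, k, k) <- alt
      if (cand %in% STOP_CODONS) next
      if (gc_map[cand] != gc_map[codon] && runif(1) > omega) next
      der[ci] <- cand
    }
    out[[g]] <- tibble(locus = sprintf("sim_g%04d", g),
                       ref = paste(ref, collapse = ""),
                       der = paste(der, collapse = ""))
  }
  bind_rows(out)
}
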