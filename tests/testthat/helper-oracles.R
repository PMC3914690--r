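# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (direct enumeration, closed forms)
# rather than calling the package's internal tables.

GENCODE <- Biostrings::GENETIC_CODE
STOPS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# a random valid ORF of n_codons codons (incl. start + stop)
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(GENCODE), STOPS)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# --- NG86 oracle: direct enumeration -----------------------------------

oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (mut %in% STOPS) next
      valid <- valid + 1
      if (GENCODE[[mut]] == GENCODE[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# enumerate every ordering of the differing positions recursively
oracle_paths <- function(from, to) {
  diffs <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(diffs)) return(list())
  walk <- function(cur, remaining, steps, stopped) {
    if (!length(remaining)) {
      return(list(list(steps = steps, stopped = stopped)))
    }
    out <- list()
    for (i in seq_along(remaining)) {
      p <- remaining[i]
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      syn <- GENCODE[[nxt]] == GENCODE[[cur]]
      out <- c(out, walk(nxt, remaining[-i],
                         c(steps, syn),
                         stopped || (nxt %in% STOPS && nxt != to)))
    }
    out
  }
  walk(from, diffs, logical(), FALSE)
}

oracle_pair_diffs <- function(from, to) {
  if (from == to) return(c(sd = 0, nd = 0))
  paths <- oracle_paths(from, to)
  ok <- Filter(function(p) !p$stopped, paths)
  if (!length(ok)) ok <- paths
  sd <- mean(vapply(ok, function(p) sum(p$steps), numeric(1)))
  nd <- mean(vapply(ok, function(p) sum(!p$steps), numeric(1)))
  c(sd = sd, nd = nd)
}

oracle_dnds <- function(ref_codons, der_codons) {
  S <- (sum(vapply(ref_codons, oracle_syn_sites, numeric(1))) +
          sum(vapply(der_codons, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ref_codons) - S
  d <- mapply(oracle_pair_diffs, ref_codons, der_codons)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(if (S > 0) Sd / S else 0),
       dN = jc(if (N > 0) Nd / N else 0))
}

# --- dif search oracle: all-position mismatch count --------------------

oracle_dif_scan <- function(seq, query, max_mismatch) {
  qlen <- nchar(query)
  qv <- strsplit(query, "")[[1]]
  rv <- strsplit(symdegen::revcomp(query), "")[[1]]
  best <- NULL
  sv <- strsplit(seq, "")[[1]]
  for (p in seq_len(nchar(seq) - qlen + 1L)) {
    win <- sv[p:(p + qlen - 1L)]
    for (st in c("+", "-")) {
      mm <- sum(win != if (st == "+") qv else rv)
      if (mm <= max_mismatch &&
          (is.null(best) || mm < best$mm ||
             (mm == best$mm && p - 1L < best$pos))) {
        if (is.null(best) || mm < best$mm || p - 1L < best$pos) {
          best <- list(pos = p - 1L, strand = st, mm = mm)
        }
      }
    }
  }
  best
}

# small annotated genome with one embedded valid ORF per spec of features
toy_genome <- function(orfs, spacer = 120L, seed = 1L, circular = TRUE,
                       kinds = NULL, strands = NULL) {
  set.seed(seed)
  n <- length(orfs)
  kinds <- kinds %||% rep("CDS", n)
  strands <- strands %||% rep("+", n)
  pieces <- character(2L * n + 1L)
  feats <- list()
  pos <- 0L
  for (i in seq_len(n)) {
    sp <- random_dna(spacer)
    pieces[2L * i - 1L] <- sp
    pos <- pos + spacer
    s <- if (strands[i] == "-") symdegen::revcomp(orfs[i]) else orfs[i]
    pieces[2L * i] <- s
    feats[[i]] <- symdegen::feature_table(
      kind = kinds[i], start = pos, end = pos + nchar(orfs[i]),
      strand = strands[i], locus_tag = sprintf("g%03d", i))
    pos <- pos + nchar(orfs[i])
  }
  pieces[2L * n + 1L] <- random_dna(spacer)
  symdegen::annotated_genome("toy", paste(pieces, collapse = ""),
                             dplyr::bind_rows(feats), circular = circular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
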