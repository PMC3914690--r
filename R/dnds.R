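#' @section Nei-Gojobori substitution-rate estimation:
#' Synonymous and nonsynonymous substitution rates are estimated by
#' unweighted pathway counting (the classical NG86 scheme): synonymous and
#' nonsynonymous *sites* are counted per codon by enumerating all nine
#' single-nucleotide changes and taking the synonymous fraction among those
#' that do not create a stop codon; *differences* between codons that differ
#' at more than one position are averaged over all minimal mutational
#' pathways, excluding pathways that pass through a stop codon (falling back
#' to all pathways when every one is blocked). Proportions are corrected for
#' multiple hits with the Jukes-Cantor formula
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}.
#' @name symdegen-dnds
#' @keywords internal
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Lazily built lookup tables: synonymous sites per codon, and per ordered
# codon pair the pathway-averaged (syn diffs, nonsyn diffs).
dnds_tables <- function() {
  if (!is.null(.symdegen_cache$dnds)) return(.symdegen_cache$dnds)
  codons <- all_codons()
  sense <- setdiff(codons, STOP_CODONS)
  syn_sites <- setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))
      muts <- vapply(alts, function(b) {
        x <- cd; substr(x, pos, pos) <- b; x
      }, character(1))
      muts <- muts[!muts %in% STOP_CODONS]
      if (length(muts)) {
        s <- s + mean(codon_aa(muts) == codon_aa(cd))
      }
    }
    syn_sites[cd] <- s
  }
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- pathway_counts(sense[i], sense[j])
      sd_mat[i, j] <- cnt[1]
      nd_mat[i, j] <- cnt[2]
    }
  }
  .symdegen_cache$dnds <- list(syn_sites = syn_sites, sd = sd_mat,
                               nd = nd_mat)
  .symdegen_cache$dnds
}

# average (syn, nonsyn) step counts over minimal mutational pathways between
# two sense codons; stop-passing pathways excluded unless all are blocked
pathway_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  orders <- perms(pos)
  res <- matrix(NA_real_, nrow = length(orders), ncol = 2)
  blocked <- logical(length(orders))
  for (k in seq_along(orders)) {
    cur <- c1
    s <- 0; ns <- 0
    for (p in orders[[k]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS && nxt != c2) blocked[k] <- TRUE
      if (codon_aa(nxt) == codon_aa(cur)) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    res[k, ] <- c(s, ns)
  }
  use <- if (all(blocked)) res else res[!blocked, , drop = FALSE]
  colMeans(use)
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Codon alignment of two coding sequences
#'
#' Builds a gap-free codon alignment from two in-frame coding sequences by
#' aligning their translations globally (BLOSUM62) and back-mapping gaps to
#' codons; codon columns containing a gap in either sequence are dropped.
#' Terminal stop codons are removed before alignment.
#'
#' @param ref_cds,der_cds In-frame coding sequences (length divisible by 3,
#'   no internal stop codons).
#' @return An object of class `codon_alignment`: list with `ref_codons`,
#'   `der_codons` (equal-length character vectors) and `n_codons`.
#' @export
codon_align <- function(ref_cds, der_cds) {
  rc <- split_codons(strip_stop(ref_cds))
  dc <- split_codons(strip_stop(der_cds))
  check_no_internal_stops(rc)
  check_no_internal_stops(dc)
  pa <- translate_codons(rc)
  pb <- translate_codons(dc)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(pa, collapse = "")),
    Biostrings::AAString(paste(pb, collapse = "")),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  sa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- cumsum(sa != "-")
  ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  make_codon_alignment(rc[ia[keep]], dc[ib[keep]])
}

#' Construct a codon alignment from codon vectors
#' @param ref_codons,der_codons Equal-length character vectors of codons
#'   (no gaps, no stop codons).
#' @return A `codon_alignment` object.
#' @export
make_codon_alignment <- function(ref_codons, der_codons) {
  stopifnot(length(ref_codons) == length(der_codons))
  check_no_internal_stops(ref_codons)
  check_no_internal_stops(der_codons)
  structure(list(ref_codons = ref_codons, der_codons = der_codons,
                 n_codons = length(ref_codons)),
            class = "codon_alignment")
}

strip_stop <- function(cds) {
  if (nchar(cds) %% 3 != 0) abort("coding sequence length not divisible by 3")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (last %in% STOP_CODONS) substr(cds, 1L, nchar(cds) - 3L) else cds
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character())
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

check_no_internal_stops <- function(codons) {
  if (any(codons %in% STOP_CODONS)) {
    abort("internal stop codon in coding sequence")
  }
  invisible(TRUE)
}

#' Estimate dN and dS for one codon alignment
#'
#' NG86 pathway counting with Jukes-Cantor correction (see the package
#' vignette for the model). `omega` is `dN/dS`; it is `Inf` when `dS = 0`
#' and `dN > 0`, and `NA` when both are zero or when a Jukes-Cantor
#' proportion reaches its 3/4 singularity (flagged in `saturated`).
#'
#' @param aln A [codon_align()] result (or [make_codon_alignment()]).
#' @return One-row tibble with columns `n_codons`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `orf_len_nt`, `saturated`.
#' @export
estimate_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons < 1L) abort("alignment has no codons")
  tb <- dnds_tables()
  rc <- aln$ref_codons
  dc <- aln$der_codons
  if (any(grepl("N", rc)) || any(grepl("N", dc))) {
    keep <- !grepl("N", rc) & !grepl("N", dc)
    rc <- rc[keep]; dc <- dc[keep]
  }
  S <- (sum(tb$syn_sites[rc]) + sum(tb$syn_sites[dc])) / 2
  N <- 3 * length(rc) - S
  diff <- rc != dc
  Sd <- sum(tb$sd[cbind(rc[diff], dc[diff])])
  Nd <- sum(tb$nd[cbind(rc[diff], dc[diff])])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  omega <- if (saturated) NA_real_
  else if (dS > 0) dN / dS
  else if (dN > 0) Inf
  else NA_real_
  tibble(n_codons = length(rc), S = S, N = N, Sd = Sd, Nd = Nd,
         pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
         orf_len_nt = 3L * aln$n_codons, saturated = saturated)
}

#' Codon-bootstrap standard errors for dN and dS
#'
#' Resamples codon columns with replacement and re-estimates the rates;
#' close ortholog pairs carry few differences, so these standard errors can
#' be large relative to the estimates and should accompany any per-gene
#' interpretation.
#'
#' @param aln A `codon_alignment`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return One-row tibble with `se_dS`, `se_dN`, `n_boot`.
#' @export
dnds_bootstrap <- function(aln, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(aln, "codon_alignment"))
  set.seed(seed)
  n <- aln$n_codons
  draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), ncol = n_boot)
  res <- apply(draws, 2, function(idx) {
    est <- estimate_dnds(make_codon_alignment(aln$ref_codons[idx],
                                              aln$der_codons[idx]))
    c(est$dS, est$dN)
  })
  tibble(se_dS = sd(res[1, ], na.rm = TRUE),
         se_dN = sd(res[2, ], na.rm = TRUE), n_boot = n_boot)
}

#' Estimate dN/dS for a table of ortholog pairs
#'
#' Convenience wrapper: builds codon alignments for reciprocal ortholog
#' pairs whose coding sequences are in-frame in both genomes (pairs with
#' frameshifted or internally stopped derived sequences are skipped, as
#' pseudogenes are excluded from substitution-rate analysis) and estimates
#' rates per pair.
#'
#' @param pairs Tibble from [find_orthologs()].
#' @param ref,der [annotated_genome()] objects.
#' @return Tibble: one row per analysed pair with the [estimate_dnds()]
#'   columns plus `ref_locus`, `der_locus` and `product`.
#' @export
dnds_pairs <- function(pairs, ref, der) {
  pairs <- dplyr::filter(pairs, .data$reciprocal)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rs <- cds_seq(ref, pairs$ref_locus[i])
    ds <- cds_seq(der, pairs$der_locus[i])
    if (nchar(ds) %% 3 != 0) next
    rc <- split_codons(strip_stop(rs))
    dc <- split_codons(strip_stop(ds))
    if (any(rc %in% STOP_CODONS) || any(dc %in% STOP_CODONS)) next
    est <- estimate_dnds(codon_align(rs, ds))
    est$ref_locus <- pairs$ref_locus[i]
    est$der_locus <- pairs$der_locus[i]
    rows[[i]] <- est
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    prods <- ref$features[match(out$ref_locus, ref$features$locus_tag),
                          "product", drop = TRUE]
    out$product <- prods
    out <- select(out, "ref_locus", "der_locus", dplyr::everything())
  }
  out
}

#' Screen for cryptic pseudogenes by elevated dN/dS
#'
#' Splits genes at the relaxed-selection threshold (default
#' `omega >= 0.3`): the flagged ("red") set are candidate cryptic
#' pseudogenes, ORFs not yet disrupted by any mutation but apparently
#' evolving with little constraint. Genes at or above `threshold_label`
#' (default 0.4) are listed with products for annotation. Mean ORF lengths
#' of the two sets and their ratio quantify the observation that
#' weakly-constrained genes tend to be shorter. Infinite omega values
#' (dS = 0, dN > 0) count as flagged but are excluded from mean omega.
#'
#' @param estimates Tibble from [dnds_pairs()] (or rows of
#'   [estimate_dnds()] with an `omega` column).
#' @param threshold_flag Flagging threshold on omega (default 0.3).
#' @param threshold_label Labelling threshold (default 0.4).
#' @return Object of class `cryptic_screen`: list with `estimates` (input +
#'   `flagged` column), `labeled` (subset at/above `threshold_label`) and
#'   `summary` (one-row tibble).
#' @export
screen_cryptic <- function(estimates, threshold_flag = 0.3,
                           threshold_label = 0.4) {
  if (nrow(estimates) == 0L) abort("no estimates supplied")
  est <- mutate(estimates,
                flagged = !is.na(.data$omega) & .data$omega >= threshold_flag)
  usable <- dplyr::filter(est, !is.na(.data$omega))
  if (nrow(usable) == 0L) abort("omega undefined for every gene")
  finite <- dplyr::filter(usable, is.finite(.data$omega))
  labeled <- dplyr::filter(usable, .data$omega >= threshold_label)
  mean_len <- function(d) if (nrow(d)) mean(d$orf_len_nt) else NA_real_
  flag_set <- dplyr::filter(usable, .data$flagged)
  green_set <- dplyr::filter(usable, !.data$flagged)
  summary <- tibble(
    n_genes = nrow(usable),
    n_flagged = nrow(flag_set),
    n_labeled = nrow(labeled),
    mean_omega = mean(finite$omega),
    mean_len_flagged = mean_len(flag_set),
    mean_len_unflagged = mean_len(green_set),
    len_ratio = mean_len(flag_set) / mean_len(green_set))
  structure(list(estimates = est, labeled = labeled, summary = summary),
            class = "cryptic_screen")
}

#' @export
print.cryptic_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cryptic_screen> %d genes: %d flagged (omega >= threshold), %d labeled\n",
    s$n_genes, s$n_flagged, s$n_labeled))
  cat(sprintf("  mean omega %.3f; mean ORF length flagged/unflagged = %.0f/%.0f nt\n",
              s$mean_omega, s$mean_len_flagged, s$mean_len_unflagged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname screen_cryptic
#' @param x A `cryptic_screen` object.
#' @param ... Unused.
#' @method tidy cryptic_screen
#' @export
tidy.cryptic_screen <- function(x, ...) x$estimates

#' @rdname screen_cryptic
#' @method glance cryptic_screen
#' @export
glance.cryptic_screen <- function(x, ...) x$summary
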