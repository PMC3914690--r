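is_host <- function(lib, inserts, seed = 140, spacer = 3000L) {
  # random genome with IS copies at known intergenic positions
  set.seed(seed)
  pieces <- random_dna(spacer)
  feats <- list()
  pos <- nchar(pieces)
  for (i in seq_along(inserts)) {
    s <- inserts[[i]]
    pieces <- paste0(pieces, s, random_dna(spacer))
    pos <- pos
    feats[[i]] <- c(start = pos, end = pos + nchar(s))
    pos <- pos + nchar(s) + spacer
  }
  list(seq = pieces, spans = feats)
}

test_that("exact consensus insertions are annotated intact at identity 1", {
  lib <- generate_is_library(seed = 141)
  host <- is_host(lib, list(lib[["ISSyn1"]], lib[["ISSyn1"]],
                            lib[["ISSyn2"]]))
  g <- annotated_genome("h", host$seq)
  ann <- annotate_is(g, lib)
  expect_equal(nrow(ann), 3L)
  expect_true(all(ann$identity == 1))
  expect_true(all(ann$transposase_state == "intact"))
  expect_equal(sum(ann$family == "ISSyn1"), 2L)
  # boundaries recovered within the seeding slack
  for (i in seq_along(host$spans)) {
    d <- min(abs(ann$start - host$spans[[i]]["start"]))
    expect_lte(d, 30L)
  }
})

test_that("a frameshifted transposase is annotated as disrupted", {
  lib <- generate_is_library(seed = 142)
  broken <- lib[["ISSyn1"]]
  broken <- paste0(substr(broken, 1, 500), substr(broken, 502,
                                                  nchar(broken)))
  host <- is_host(lib, list(broken), seed = 143)
  ann <- annotate_is(annotated_genome("h", host$seq), lib)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$transposase_state, "disrupted")
})

test_that("hits below the identity floor are not annotated", {
  lib <- generate_is_library(seed = 144)
  cons <- lib[["ISSyn1"]]
  v <- strsplit(cons, "")[[1]]
  # ~10% divergence concentrated in two internal patches (as recombination
  # or decay would leave it), so exact seeds still exist elsewhere
  set.seed(154)
  idx <- c(seq(151, 250), seq(601, 650))
  for (p in idx) v[p] <- sample(setdiff(BASES, v[p]), 1)
  weak <- paste(v, collapse = "")
  host <- is_host(lib, list(weak), seed = 145)
  g <- annotated_genome("h", host$seq)
  expect_equal(nrow(annotate_is(g, lib, min_identity = 0.94)), 0L)
  expect_equal(nrow(annotate_is(g, lib, min_identity = 0.85)), 1L)
  expect_error(annotate_is(g, character()), "empty")
})

test_that("annotation counts survive rotation and reverse complement", {
  lib <- generate_is_library(seed = 146)
  host <- is_host(lib, list(lib[["ISSyn1"]], lib[["ISSyn2"]]), seed = 147)
  g <- annotated_genome("h", host$seq)
  n0 <- nrow(annotate_is(g, lib))
  g_rc <- annotated_genome("h", revcomp(host$seq))
  expect_equal(nrow(annotate_is(g_rc, lib)), n0)
  g_rot <- rotate_genome(g, 1500)
  expect_equal(nrow(annotate_is(g_rot, lib)), n0)
})

test_that("the permutation p-value matches the closed-form binomial", {
  # genome 20% intergenic: one gene covering 80% of 50 kb
  L <- 50000L
  g <- annotated_genome(
    "t", random_dna(L, seed = 148),
    feature_table(kind = "CDS", start = 0L, end = 40000L, strand = "+",
                  locus_tag = "big"))
  ig <- intergenic_ranges(g)
  expect_equal(sum(ig$end - ig$start) / L, 0.2)
  # 10 IS midpoints, all intergenic
  pos <- seq(41000L, 49000L, length.out = 10)
  sites <- tibble::tibble(start = as.integer(pos), end = as.integer(pos))
  n_perm <- 100000L
  res <- intergenic_clustering_test(sites, g, n_perm = n_perm, seed = 7)
  expect_equal(res$observed_intergenic_fraction, 1)
  expect_equal(res$expected_fraction, 0.2)
  # raw exceedance count vs Binomial(n_perm, 0.2^10) within 3 MC SEs
  p0 <- 0.2^10
  k <- res$p_value * (n_perm + 1) - 1
  expect_lte(abs(k / n_perm - p0), 3 * sqrt(p0 * (1 - p0) / n_perm))
  # bit-exact reproducibility
  res2 <- intergenic_clustering_test(sites, g, n_perm = n_perm, seed = 7)
  expect_identical(res, res2)
})

test_that("an all-intergenic genome gives p = 1", {
  g <- annotated_genome("t", random_dna(20000, seed = 149))
  sites <- tibble::tibble(start = c(100L, 5000L, 9000L),
                          end = c(101L, 5001L, 9001L))
  res <- intergenic_clustering_test(sites, g, n_perm = 1000, seed = 1)
  expect_equal(res$observed_intergenic_fraction, 1)
  expect_equal(res$expected_fraction, 1)
  expect_equal(res$p_value, 1)
  expect_error(intergenic_clustering_test(sites[0, ], g), "no IS")
  expect_error(intergenic_clustering_test(sites, g, n_perm = 10), "1000")
})

test_that("an injected diverged tandem duplication is recovered exactly", {
  cfg <- ancestor_config(n_genes = 150, seed = 150)
  anc <- generate_ancestor(cfg)
  par <- degeneration_params(p_pseudo = 0, n_is_insertions = 0,
                             n_duplications = 1, n_inversions = 0,
                             n_translocations = 0, mu = 0.005, seed = 151)
  deg <- degenerate(anc$genome, par)
  dup <- detect_duplications(deg$genome)
  truth <- deg$ledger$truth$duplications
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$n_substitutions, truth$n_subs)
  expect_equal(dup$n_indels, truth$n_indels)
  expect_true(dup$bounded_by_is)
  expect_equal(dup$bounding_family, truth$family)
  expect_lte(abs(dup$start_a - truth$start_a), 50L)
  expect_lte(abs(dup$end_b - truth$end_b), 50L)
  expect_gte(dup$identity, 0.99)
})

test_that("random genomes without duplications report none", {
  g <- annotated_genome("r", random_dna(60000, seed = 152))
  expect_equal(nrow(detect_duplications(g)), 0L)
  expect_error(detect_duplications(g, min_len = 100), "min_len")
})

test_that("duplications below the identity threshold are excluded", {
  base <- random_dna(40000, seed = 153)
  seg <- substr(base, 10000, 14999)
  v <- strsplit(seg, "")[[1]]
  for (p in seq(10, length(v) - 10, by = 25)) {  # ~4% divergence
    v[p] <- setdiff(BASES, v[p])[1]
  }
  far <- paste(v, collapse = "")
  g <- annotated_genome("d", paste0(base, far))
  expect_equal(nrow(detect_duplications(g, min_len = 2500,
                                        min_identity = 0.99)), 0L)
  found <- detect_duplications(g, min_len = 2500, min_identity = 0.90)
  expect_equal(nrow(found), 1L)
  expect_false(found$bounded_by_is)
})
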