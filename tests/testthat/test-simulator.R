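test_that("ancestor generation is deterministic per seed", {
  cfg <- ancestor_config(n_genes = 25, seed = 170)
  a1 <- generate_ancestor(cfg)
  a2 <- generate_ancestor(cfg)
  expect_identical(a1$genome$sequence, a2$genome$sequence)
  expect_identical(as.data.frame(a1$genome$features),
                   as.data.frame(a2$genome$features))
  a3 <- generate_ancestor(ancestor_config(n_genes = 25, seed = 171))
  expect_false(identical(a1$genome$sequence, a3$genome$sequence))
})

test_that("generated genes are valid ORFs and packing is checked", {
  cfg <- ancestor_config(n_genes = 30, seed = 172)
  anc <- generate_ancestor(cfg)
  genes <- dplyr::filter(anc$genome$features, kind == "CDS")
  for (lt in genes$locus_tag) {
    cds <- cds_seq(anc$genome, lt)
    expect_true(symdegen:::is_valid_orf(cds))
  }
  expect_error(generate_ancestor(
    ancestor_config(n_genes = 30, genome_length = 1000L, seed = 1)),
    "fit")
})

test_that("an ancestor without compositional signals has no polarization", {
  # KOPS motifs are G-rich and strand-polarized, so they alone polarize
  # skew; the no-signal control removes both the bias and the motifs
  cfg <- ancestor_config(n_genes = 80, skew_bias = 0, n_kops = 0,
                         seed = 173)
  anc <- generate_ancestor(cfg)
  tr <- gc_skew(anc$genome$sequence, 5000, 2500)
  pol <- skew_polarization_index(tr, 0, anc$meta$ter,
                                 genome_length(anc$genome))
  expect_lt(pol, 0.75)   # ~0.5 + sampling noise
})

test_that("zero-parameter degeneration is the identity", {
  cfg <- ancestor_config(n_genes = 20, seed = 174)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome,
                    degeneration_params(p_pseudo = 0, n_is_insertions = 0,
                                        n_inversions = 0,
                                        n_translocations = 0,
                                        n_deletions = 0, mu = 0,
                                        seed = 174))
  expect_identical(deg$genome$sequence, anc$genome$sequence)
  expect_equal(length(deg$ledger$events), 0L)
})

test_that("ledger replay reproduces the derived genome byte-exactly", {
  cfg <- ancestor_config(n_genes = 60, seed = 175)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome,
                    degeneration_params(seed = 175, n_is_insertions = 10,
                                        n_duplications = 1,
                                        n_deletions = 1))
  rep <- replay_ledger(anc$genome, deg$ledger$events)
  expect_identical(rep$sequence, deg$genome$sequence)
  expect_identical(as.data.frame(rep$features),
                   as.data.frame(deg$genome$features))
})

test_that("the written simulation bundle replays from JSON", {
  cfg <- ancestor_config(n_genes = 25, seed = 176)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome,
                    degeneration_params(seed = 176, n_is_insertions = 5))
  td <- withr::local_tempdir()
  write_simulation(anc, deg, td)
  expect_true(all(file.exists(file.path(td, c(
    "ancestor.fasta", "ancestor.gff3", "derived.fasta", "derived.gff3",
    "is_library.fasta", "pairing_map.tsv", "variability_map.tsv",
    "ledger.json")))))
  led <- read_ledger(file.path(td, "ledger.json"))
  rep <- replay_ledger(anc$genome, led$events)
  expect_identical(rep$sequence, deg$genome$sequence)
  # the emitted files parse back into the same genomes
  anc2 <- read_genome(file.path(td, "ancestor"), "fasta+gff3")
  expect_identical(anc2$sequence, anc$genome$sequence)
})

test_that("per-gene inactivation counts follow the Bernoulli model", {
  cfg <- ancestor_config(n_genes = 200, seed = 177)
  anc <- generate_ancestor(cfg)
  # realized inactivation fractions across seeds at p = 0.4
  fr <- vapply(1:12, function(s) {
    deg <- degenerate(anc$genome,
                      degeneration_params(p_pseudo = 0.4,
                                          n_is_insertions = 0,
                                          n_inversions = 0,
                                          n_translocations = 0, mu = 0,
                                          seed = 1000 + s))
    nrow(deg$ledger$truth$inactivated) / 200
  }, numeric(1))
  se <- sqrt(0.4 * 0.6 / 200)
  expect_lte(abs(mean(fr) - 0.4), 3 * se / sqrt(length(fr)))
  # counts differ across seeds (independent draws)
  expect_gt(stats::sd(fr), 0)
})

test_that("every inactivated gene carries at least one injected lesion", {
  cfg <- ancestor_config(n_genes = 60, seed = 178)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome,
                    degeneration_params(seed = 178, n_is_insertions = 8))
  truth <- deg$ledger$truth$inactivated
  expect_gt(nrow(truth), 0)
  for (i in seq_len(nrow(truth))) {
    anc_cds <- cds_seq(anc$genome, truth$locus[i])
    der_cds <- cds_seq(deg$genome, truth$locus[i])
    expect_false(identical(anc_cds, der_cds))
  }
  # and untouched genes with no background mutation remain valid ORFs
  genes <- dplyr::filter(deg$genome$features, kind == "CDS")
  untouched <- setdiff(genes$locus_tag, truth$locus)
  ok <- vapply(untouched, function(lt) {
    symdegen:::is_valid_orf(cds_seq(deg$genome, lt))
  }, logical(1))
  expect_true(all(ok))
})

test_that("the selection simulator hits its omega dial", {
  sim_n <- simulate_selection_pairs(30, 300, rate = 0.2, omega = 1,
                                    seed = 179)
  sim_c <- simulate_selection_pairs(30, 300, rate = 0.2, omega = 0.05,
                                    seed = 180)
  est <- function(s) {
    dplyr::bind_rows(purrr::map2(s$ref, s$der, function(r, d) {
      estimate_dnds(codon_align(r, d))
    }))
  }
  on <- est(sim_n)$omega
  oc <- est(sim_c)$omega
  expect_gt(mean(on[is.finite(on)]), 0.7)
  expect_lt(mean(oc[is.finite(oc)], na.rm = TRUE), 0.2)
})
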