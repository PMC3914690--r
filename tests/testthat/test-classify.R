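# brute-force localisation of a frameshift: translate the derived sequence
# in the reference frame and find the first diverged codon
oracle_divergence_codon <- function(ref_cds, der_cds) {
  n <- min(nchar(ref_cds), nchar(der_cds))
  n <- n - n %% 3L
  rc <- substring(ref_cds, seq(1, n, 3), seq(3, n, 3))
  dc <- substring(der_cds, seq(1, n, 3), seq(3, n, 3))
  which(GENCODE[rc] != GENCODE[dc])[1]
}

test_that("a derived sequence identical to the reference has no mutations", {
  orf <- random_orf(100, seed = 70)
  expect_equal(nrow(detect_mutations(orf, orf)), 0L)
})

test_that("a single-nucleotide deletion is typed as a frameshift at its codon", {
  orf <- random_orf(100, seed = 71)
  v <- strsplit(orf, "")[[1]]
  der <- paste(v[-148], collapse = "")          # delete 1 nt in codon 50
  muts <- detect_mutations(der, orf)
  expect_equal(muts$type, "frameshift_indel")
  # brute-force check: translations diverge at (or just after) codon 50
  div <- oracle_divergence_codon(orf, der)
  expect_lte(abs(muts$position_codon - 50L), 1L)
  expect_gte(div, muts$position_codon)
})

test_that("a nonsense substitution is typed as a premature stop at its codon", {
  # codon 30 = CAA so that C->T creates TAA
  orf <- random_orf(100, seed = 72)
  substr(orf, 88, 90) <- "CAA"
  der <- orf
  substr(der, 88, 88) <- "T"
  muts <- detect_mutations(der, orf)
  expect_equal(muts$type, "premature_stop")
  expect_equal(muts$position_codon, 30L)
  # brute-force: first stop of the derived translation is codon 30
  dc <- substring(der, seq(1, nchar(der), 3), seq(3, nchar(der), 3))
  expect_equal(which(dc %in% STOPS)[1], 30L)
})

test_that("an IS-library insertion inside an ORF is typed as interruption", {
  orf <- random_orf(120, seed = 73)
  lib <- generate_is_library(seed = 99)
  der <- paste0(substr(orf, 1, 150), lib[["ISSyn1"]],
                substr(orf, 151, nchar(orf)))
  muts <- detect_mutations(der, orf, is_library = lib)
  expect_true("is_interruption" %in% muts$type)
  # without the library the same insertion is at best a non-call (length
  # is a codon multiple), never an interruption call
  muts2 <- detect_mutations(der, orf)
  expect_false("is_interruption" %in% muts2$type)
})

test_that("classify_cds applies fast path, span rule and short-ORF rule", {
  # (a) near-identical pair: intact via fast path
  orf <- random_orf(100, seed = 74)
  ref <- toy_genome(orf, seed = 75)
  der <- annotated_genome("d", ref$sequence, ref$features)
  cls <- classify_cds("g001", "g001", der, ref)
  expect_equal(cls$verdict, "intact")
  expect_equal(cls$rule_fired, "fast_path")
  # (b) 300-nt reference, derived spans only 200 nt: pseudogene
  orf300 <- random_orf(100, seed = 76)
  frag <- substr(orf300, 1, 200)
  ref_b <- toy_genome(orf300, seed = 77)
  der_b <- toy_genome(frag, seed = 78)   # toy genome annotates the fragment
  cls_b <- classify_cds("g001", "g001", der_b, ref_b,
                        classify_thresholds(context_nt = 100L))
  expect_equal(cls_b$verdict, "pseudogene")
  expect_lt(cls_b$length_fraction, 0.99)
  # (c) 240-nt reference (<300), derived spans 220 nt, no mutations: intact
  orf240 <- random_orf(80, seed = 79)
  der_c_orf <- substr(orf240, 1, 220)
  ref_c <- toy_genome(orf240, seed = 80)
  der_c <- toy_genome(der_c_orf, seed = 81)
  cls_c <- classify_cds("g001", "g001", der_c, ref_c,
                        classify_thresholds(context_nt = 100L))
  expect_equal(cls_c$verdict, "intact")
  expect_true(cls_c$rule_fired %in% c("fast_path", "short_orf_rule"))
  expect_gt(cls_c$length_fraction, 0.9)
})

test_that("verdicts obey the mutation invariant", {
  cfg <- ancestor_config(n_genes = 50, seed = 82)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome, degeneration_params(seed = 82))
  pairs <- find_orthologs(anc$genome, deg$genome, 0, 0)
  rep <- classify_genome(deg$genome, anc$genome, pairs,
                         is_library = deg$is_library)
  per <- rep$per_cds
  # intact => no mutations
  expect_true(all(per$n_mutations[per$verdict == "intact"] == 0L))
  # pseudogene => mutations present or span below threshold
  ps <- per[per$verdict == "pseudogene", ]
  expect_true(all(ps$n_mutations > 0L | ps$length_fraction <= 0.99))
  # totals are column sums
  expect_equal(rep$totals$n_intact, sum(per$verdict == "intact"))
  expect_equal(rep$totals$n_pseudo, sum(per$verdict == "pseudogene"))
  expect_equal(rep$totals$fraction_pseudo,
               rep$totals$n_pseudo /
                 (rep$totals$n_intact + rep$totals$n_pseudo))
  # tidy/glance accessors
  expect_identical(generics::tidy(rep), per)
  expect_identical(generics::glance(rep), rep$totals)
})

test_that("raising thresholds never converts pseudogene verdicts to intact", {
  cfg <- ancestor_config(n_genes = 30, seed = 83)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome, degeneration_params(seed = 83))
  pairs <- find_orthologs(anc$genome, deg$genome, 0, 0)
  lax <- classify_genome(deg$genome, anc$genome, pairs,
                         classify_thresholds(span_long = 0.95,
                                             span_short = 0.85))
  strict <- classify_genome(deg$genome, anc$genome, pairs,
                            classify_thresholds(min_identity = 0.95,
                                                min_length_fraction = 0.9))
  was_pseudo <- lax$per_cds$der_locus[lax$per_cds$verdict == "pseudogene"]
  now <- strict$per_cds[match(was_pseudo, strict$per_cds$der_locus), ]
  expect_true(all(now$verdict != "intact"))
})

test_that("a genome identical to its reference has zero pseudogenes", {
  orfs <- vapply(1:5, function(i) random_orf(60, seed = 90 + i),
                 character(1))
  ref <- toy_genome(orfs, seed = 96)
  der <- annotated_genome("d", ref$sequence, ref$features)
  pairs <- find_orthologs(ref, der)
  rep <- classify_genome(der, ref, pairs)
  expect_equal(rep$totals$fraction_pseudo, 0)
  expect_equal(rep$totals$n_intact, 5L)
})

test_that("pseudogene verdicts re-type features for GFF3 emission", {
  cfg <- ancestor_config(n_genes = 20, seed = 97)
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome, degeneration_params(seed = 97,
                                                    n_is_insertions = 0))
  pairs <- find_orthologs(anc$genome, deg$genome, 0, 0)
  rep <- classify_genome(deg$genome, anc$genome, pairs)
  re <- retype_pseudogenes(deg$genome, rep)
  ps <- rep$per_cds$der_locus[rep$per_cds$verdict == "pseudogene"]
  expect_setequal(re$features$locus_tag[re$features$kind == "pseudogene"],
                  ps)
  expect_identical(re$sequence, deg$genome$sequence)
})
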