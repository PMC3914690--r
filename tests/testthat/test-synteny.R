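test_that("the identity case yields one full-length diagonal of matches", {
  ref <- random_dna(3000, seed = 120)
  # verify the precondition: all 20-mers unique on both strands
  kmers <- substring(ref, 1:(3000 - 19), 20:3000)
  stopifnot(!anyDuplicated(c(kmers, revcomp(kmers))))
  m <- kmer_matches(ref, ref, 20)
  expect_equal(nrow(m), 3000 - 20 + 1)
  expect_true(all(m$strand == "+"))
  expect_equal(m$der_pos, m$ref_pos)
  b <- chain_blocks(m)
  expect_equal(nrow(b), 1L)
  expect_equal(b$ref_start, 0L)
  expect_equal(b$ref_end, 3000L)
})

test_that("a reverse-complemented genome mirrors every match", {
  L <- 2000L
  ref <- random_dna(L, seed = 121)
  der <- revcomp(ref)
  m <- kmer_matches(ref, der, 20)
  expect_equal(nrow(m), L - 20 + 1)
  expect_true(all(m$strand == "-"))
  expect_equal(m$der_pos, L - 20L - m$ref_pos)
})

test_that("duplicated k-mers are excluded by the uniqueness rule", {
  core <- random_dna(1000, seed = 122)
  repeat_seq <- substr(core, 100, 160)
  ref <- paste0(core, repeat_seq)        # 61-nt repeat occurs twice
  m <- kmer_matches(ref, ref, 20)
  # no match may start within the repeated segment's k-mers
  dup_starts <- c(99:(160 - 20), (1000 + 0):(1060 - 20))
  expect_false(any(m$ref_pos %in% dup_starts))
})

test_that("N-containing k-mers never match", {
  ref <- random_dna(500, seed = 123)
  masked <- paste0(substr(ref, 1, 200),
                   strrep("N", 50), substr(ref, 251, 500))
  m <- kmer_matches(masked, masked, 20)
  bad <- m$ref_pos > 200 - 20 & m$ref_pos < 250
  expect_false(any(bad))
})

test_that("a central inversion produces three blocks with exact breakpoints", {
  ref <- random_dna(10000, seed = 124)
  der <- paste0(substr(ref, 1, 4000), revcomp(substr(ref, 4001, 6000)),
                substr(ref, 6001, 10000))
  b <- chain_blocks(kmer_matches(ref, der, 20))
  expect_equal(nrow(b), 3L)
  expect_equal(b$orientation, c("same_strand", "opposite_strand",
                                "same_strand"))
  mid <- b[2, ]
  expect_lte(abs(mid$ref_start - 4000L), 20L)
  expect_lte(abs(mid$ref_end - 6000L), 20L)
  expect_lte(abs(mid$der_start - 4000L), 20L)
  # match-count conservation across chaining
  m <- kmer_matches(ref, der, 20)
  expect_equal(sum(b$n_kmers), nrow(m))
})

test_that("matches separated beyond max_gap split into blocks", {
  m <- tibble::tibble(ref_pos = c(0L, 100L, 5000L),
                      der_pos = c(0L, 100L, 5000L), strand = "+")
  b <- chain_blocks(m, k = 20, max_gap = 1000)
  expect_equal(nrow(b), 2L)
  # and a diagonal jump beyond tolerance also splits
  m2 <- tibble::tibble(ref_pos = c(0L, 100L), der_pos = c(0L, 400L),
                       strand = "+")
  expect_equal(nrow(chain_blocks(m2, k = 20)), 2L)
})

test_that("reverse-complementing the derived genome flips all orientations", {
  ref <- random_dna(6000, seed = 125)
  der <- paste0(substr(ref, 1, 3000), revcomp(substr(ref, 3001, 4500)),
                substr(ref, 4501, 6000))
  b1 <- chain_blocks(kmer_matches(ref, der, 20))
  b2 <- chain_blocks(kmer_matches(ref, revcomp(der), 20))
  expect_equal(nrow(b1), nrow(b2))
  flip <- c(same_strand = "opposite_strand",
            opposite_strand = "same_strand")
  expect_setequal(b2$orientation, unname(flip[b1$orientation]))
})

test_that("replichore symmetry follows the strand/replichore rule", {
  ref <- random_dna(10000, seed = 126)
  der <- paste0(substr(ref, 1, 4000), revcomp(substr(ref, 4001, 6000)),
                substr(ref, 6001, 10000))
  b <- chain_blocks(kmer_matches(ref, der, 20))
  # identity: everything symmetric, violation fraction 0
  bi <- chain_blocks(kmer_matches(ref, ref, 20))
  ci <- classify_symmetry(bi, 0, 5000, 0, 5000, 10000, 10000)
  expect_true(all(ci$blocks$symmetry_class == "symmetric"))
  expect_equal(ci$violation_fraction, 0)
  # inversion inside one replichore (ter at 8000): violating
  cv <- classify_symmetry(b, 0, 8000, 0, 8000, 10000, 10000)
  expect_equal(cv$blocks$symmetry_class[2], "violating")
  expect_gt(cv$violation_fraction, 0)
  # inversion centred on the ori-ter axis (ori at 5000): symmetric
  cs <- classify_symmetry(b, 5000, 0, 5000, 0, 10000, 10000)
  expect_equal(cs$blocks$symmetry_class[2], "symmetric")
  # degenerate anchors are rejected
  expect_error(classify_symmetry(b, 100, 100, 0, 5000, 10000, 10000),
               "differ")
})

test_that("violation fraction grows with the number of inversions", {
  cfg <- ancestor_config(n_genes = 45, seed = 127)   # ~50 kb
  anc <- generate_ancestor(cfg)
  vf <- vapply(c(0L, 4L), function(k) {
    deg <- degenerate(anc$genome,
                      degeneration_params(p_pseudo = 0, n_is_insertions = 0,
                                          n_inversions = k,
                                          n_translocations = 0, mu = 0,
                                          seed = 128))
    sm <- synteny_map(anc$genome, deg$genome,
                      ref_ori = 0, ref_ter = anc$meta$ter,
                      der_ori = 0, der_ter = anc$meta$ter)
    sm$violation_fraction
  }, numeric(1))
  expect_equal(vf[1], 0)
  expect_gt(vf[2], 0)
})

test_that("synteny blocks export as BEDPE", {
  ref <- random_dna(3000, seed = 141)
  b <- chain_blocks(kmer_matches(ref, ref, 20))
  td <- withr::local_tempdir()
  write_bedpe(b, file.path(td, "blocks.bedpe"))
  pe <- read.table(file.path(td, "blocks.bedpe"), sep = "\t")
  expect_equal(nrow(pe), nrow(b))
  expect_equal(pe$V10, ifelse(b$orientation == "same_strand", "+", "-"))
})
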