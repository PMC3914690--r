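test_that("window skew follows the closed-form definition", {
  expect_equal(gc_skew(strrep("G", 200), 100, 100)$skew, c(1, 1))
  expect_equal(gc_skew(strrep("C", 200), 100, 100)$skew, c(-1, -1))
  at <- gc_skew(strrep("AT", 100), 100, 100)
  expect_equal(at$skew, c(0, 0))
  expect_true(all(at$flagged))
  # direct formula on a single window: GGC repeated
  one <- gc_skew(strrep("GGC", 100), 300, 300)
  expect_equal(one$skew, (200 - 100) / 300)
  expect_error(gc_skew("ACGT", 100), "window")
})

test_that("skew is antisymmetric under reverse complement", {
  seq <- random_dna(5000, seed = 130, gc = 0.6)
  fwd <- gc_skew(seq, 500, 500)
  rev <- gc_skew(revcomp(seq), 500, 500)
  expect_equal(rev$skew, -rev(fwd$skew))
})

test_that("ori and ter are recovered from cumulative skew on biased genomes", {
  cfg <- ancestor_config(n_genes = 180, seed = 131)   # ~200 kb, b = 0.05
  anc <- generate_ancestor(cfg)
  L <- genome_length(anc$genome)
  tr <- gc_skew(anc$genome$sequence)
  ex <- cumulative_skew_extrema(tr)
  circ_dist <- function(a, b) min((a - b) %% L, (b - a) %% L)
  expect_lte(circ_dist(ex$ori, 0L), 2L * 10000L)
  expect_lte(circ_dist(ex$ter, anc$meta$ter), 2L * 10000L)
  # polarization with the construction's own anchors is near-perfect
  pol <- skew_polarization_index(tr, 0L, anc$meta$ter, L)
  expect_gte(pol, 0.9)
  # an unbiased random sequence has no polarization signal
  rnd <- gc_skew(random_dna(100000, seed = 132), 5000, 5000)
  pol_rnd <- skew_polarization_index(rnd, 0, 50000, 100000)
  expect_lt(pol_rnd, 0.75)
})

test_that("KOPS motifs are found on both strands with IUPAC wildcards", {
  s <- "TTGGGAAGGGTT"
  hits <- find_kops(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 2L)
  expect_equal(hits$strand, "+")
  hits_rc <- find_kops(revcomp(s))
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
})

test_that("KOPS counting is rotation invariant and polarity relabels cleanly", {
  cfg <- ancestor_config(n_genes = 60, seed = 133)
  anc <- generate_ancestor(cfg)
  g <- anc$genome
  L <- genome_length(g)
  h0 <- find_kops(g$sequence)
  rot <- rotate_genome(g, 12345)
  h1 <- find_kops(rot$sequence)
  # rotation may split at most one site across the junction
  expect_lte(abs(nrow(h1) - nrow(h0)), 1L)
  # constructed polarity is exactly 1 (chance motifs scrubbed)
  expect_equal(kops_polarity(h0, 0, anc$meta$ter, L), 1.0)
  # relabeling ori<->ter swaps both replichores, so every site now points
  # against the (relabelled) ori->ter direction: polarity maps p -> 1 - p
  expect_equal(kops_polarity(h0, anc$meta$ter, 0, L),
               1 - kops_polarity(h0, 0, anc$meta$ter, L))
})

test_that("polarity and polarization decay after inter-replichore inversions", {
  cfg <- ancestor_config(n_genes = 60, seed = 134)
  anc <- generate_ancestor(cfg)
  L <- genome_length(anc$genome)
  deg <- degenerate(anc$genome,
                    degeneration_params(p_pseudo = 0, n_is_insertions = 0,
                                        n_inversions = 8,
                                        n_translocations = 0, mu = 0,
                                        seed = 135))
  pol0 <- kops_polarity(find_kops(anc$genome$sequence), 0, anc$meta$ter, L)
  pol1 <- kops_polarity(find_kops(deg$genome$sequence), 0, anc$meta$ter,
                        genome_length(deg$genome))
  expect_lt(pol1, pol0)
  tr0 <- gc_skew(anc$genome$sequence, 5000, 2500)
  tr1 <- gc_skew(deg$genome$sequence, 5000, 2500)
  expect_lt(skew_polarization_index(tr1, 0, anc$meta$ter,
                                    genome_length(deg$genome)),
            skew_polarization_index(tr0, 0, anc$meta$ter, L))
})

test_that("dif search equals the brute-force scan and honours bounds", {
  base <- random_dna(10000, seed = 136)
  target <- DIF_SITE
  seq <- paste0(substr(base, 1, 4000), target,
                substr(base, 4001 + nchar(target), 10000))
  hit <- find_dif(seq)
  expect_equal(hit$position, 4000L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)
  # agreement with an exhaustive scan, including a mismatched planting
  mut <- target
  substr(mut, 5, 5) <- "C"; substr(mut, 20, 20) <- "G"
  seq2 <- paste0(substr(base, 1, 7000), mut,
                 substr(base, 7001 + nchar(mut), 10000))
  hit2 <- find_dif(seq2, max_mismatch = 4)
  oracle <- oracle_dif_scan(seq2, target, 4)
  expect_equal(hit2$position, oracle$pos)
  expect_equal(hit2$mismatches, oracle$mm)
  # exactly max_mismatch mismatches is still found
  mut4 <- target
  for (p in c(3, 9, 15, 22)) substr(mut4, p, p) <- "A"
  mm4 <- sum(strsplit(mut4, "")[[1]] != strsplit(target, "")[[1]])
  seq3 <- paste0(substr(base, 1, 2000), mut4,
                 substr(base, 2001 + nchar(mut4), 10000))
  hit3 <- find_dif(seq3, max_mismatch = mm4)
  expect_equal(hit3$position, 2000L)
  # absent when no placement is close enough
  expect_equal(nrow(find_dif(random_dna(5000, seed = 137),
                             max_mismatch = 2)), 0L)
  expect_error(find_dif(seq, max_mismatch = 10), "max_mismatch")
})

test_that("track and site exporters emit valid browser formats", {
  td <- withr::local_tempdir()
  tr <- gc_skew(random_dna(2000, seed = 138), 500, 500)
  write_bedgraph(tr, file.path(td, "skew.bedgraph"), chrom = "toy")
  bg <- read.table(file.path(td, "skew.bedgraph"), sep = "\t")
  expect_equal(nrow(bg), nrow(tr))
  expect_equal(bg$V3 - bg$V2, rep(500L, nrow(tr)))
  sites <- find_kops(paste0("TTGGGAAGGG", random_dna(500, seed = 139)))
  write_bed6(sites, file.path(td, "kops.bed"), chrom = "toy")
  bed <- read.table(file.path(td, "kops.bed"), sep = "\t")
  expect_equal(ncol(bed), 6L)
  expect_true(all(bed$V6 %in% c("+", "-")))
})
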