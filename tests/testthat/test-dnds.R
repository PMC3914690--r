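test_that("identical sequences give zero substitution rates", {
  aln <- make_codon_alignment(rep("GCT", 20), rep("GCT", 20))
  est <- estimate_dnds(aln)
  expect_equal(est$Sd, 0)
  expect_equal(est$Nd, 0)
  expect_equal(est$dS, 0)
  expect_equal(est$dN, 0)
  expect_true(is.na(est$omega))
})

test_that("a single synonymous change matches the closed-form rates", {
  # 11 GAT codons, one third-position GAT->GAC change
  aln <- make_codon_alignment(rep("GAT", 11), c(rep("GAT", 10), "GAC"))
  est <- estimate_dnds(aln)
  expect_equal(est$S, 11 / 3)
  expect_equal(est$N, 33 - 11 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 3 / 11)
  expect_equal(est$dS, -0.75 * log(1 - 4 / 3 * 3 / 11))
  expect_equal(est$dN, 0)
})

test_that("per-codon site fractions match direct enumeration", {
  tb <- symdegen:::dnds_tables()
  # TTT (Phe): only the third position is partially synonymous (1/3)
  expect_equal(unname(tb$syn_sites["TTT"]), 1 / 3)
  # every sense codon agrees with the oracle enumeration
  for (cd in names(tb$syn_sites)) {
    expect_equal(unname(tb$syn_sites[cd]), oracle_syn_sites(cd),
                 tolerance = 1e-12)
  }
})

test_that("site counts are conserved: S + N = 3 x n_codons, every gene", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    sense <- setdiff(names(GENCODE), STOPS)
    aln <- make_codon_alignment(sample(sense, n, replace = TRUE),
                                sample(sense, n, replace = TRUE))
    est <- estimate_dnds(aln)
    expect_equal(est$S + est$N, 3 * n)
  }
})

test_that("the estimator is symmetric in the two sequences", {
  set.seed(102)
  sense <- setdiff(names(GENCODE), STOPS)
  a <- sample(sense, 40, replace = TRUE)
  b <- sample(sense, 40, replace = TRUE)
  e1 <- estimate_dnds(make_codon_alignment(a, b))
  e2 <- estimate_dnds(make_codon_alignment(b, a))
  expect_equal(e1$dS, e2$dS)
  expect_equal(e1$dN, e2$dN)
  expect_equal(e1$Sd, e2$Sd)
})

test_that("pathway counting agrees exactly with brute-force enumeration", {
  sense <- setdiff(names(GENCODE), STOPS)
  tb <- symdegen:::dnds_tables()
  # every single-codon pair differing at <= 2 positions
  n_checked <- 0L
  for (c1 in sense) {
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(c1, pos, pos))) {
        c2 <- c1
        substr(c2, pos, pos) <- b
        if (c2 %in% STOPS) next
        o <- oracle_pair_diffs(c1, c2)
        expect_equal(unname(tb$sd[c1, c2]), unname(o["sd"]))
        expect_equal(unname(tb$nd[c1, c2]), unname(o["nd"]))
        n_checked <- n_checked + 1L
        for (pos2 in setdiff(1:3, pos)) {
          for (b2 in setdiff(BASES, substr(c2, pos2, pos2))) {
            c3 <- c2
            substr(c3, pos2, pos2) <- b2
            if (c3 %in% STOPS) next
            o2 <- oracle_pair_diffs(c1, c3)
            expect_equal(unname(tb$sd[c1, c3]), unname(o2["sd"]),
                         tolerance = 1e-12)
            expect_equal(unname(tb$nd[c1, c3]), unname(o2["nd"]),
                         tolerance = 1e-12)
            n_checked <- n_checked + 1L
          }
        }
      }
    }
  }
  expect_gt(n_checked, 2000L)
})

test_that("two-codon alignments match the brute-force oracle exactly", {
  set.seed(103)
  sense <- setdiff(names(GENCODE), STOPS)
  for (i in 1:200) {
    c1 <- sample(sense, 2, replace = TRUE)
    c2 <- c1
    # distribute up to 2 substitutions over the two codons
    for (s in seq_len(sample(0:2, 1))) {
      ci <- sample(1:2, 1)
      pos <- sample(1:3, 1)
      b <- sample(setdiff(BASES, substr(c2[ci], pos, pos)), 1)
      cand <- c2[ci]
      substr(cand, pos, pos) <- b
      if (!cand %in% STOPS) c2[ci] <- cand
    }
    est <- estimate_dnds(make_codon_alignment(c1, c2))
    o <- oracle_dnds(c1, c2)
    expect_equal(est$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(est$Nd, o$Nd, tolerance = 1e-12)
    expect_equal(est$S, o$S, tolerance = 1e-12)
    if (!is.na(o$dS)) expect_equal(est$dS, o$dS, tolerance = 1e-12)
  }
})

test_that("omega handles the degenerate denominators", {
  # dS = 0, dN > 0: +Inf sentinel
  est <- estimate_dnds(make_codon_alignment(c("GCT", "GCT"),
                                            c("TCT", "GCT")))
  expect_true(is.infinite(est$omega))
  # internal stop codons are rejected
  expect_error(make_codon_alignment(c("GCT", "TAA"), c("GCT", "GCT")),
               "stop")
})

test_that("codon alignment drops gap columns and strips terminal stops", {
  ref <- paste0("ATG", "GCTGCAGAA", "TAA")
  # derived lost one codon
  der <- paste0("ATG", "GCTGAA", "TAA")
  aln <- codon_align(ref, der)
  expect_equal(aln$n_codons, 3L)
  expect_false(any(c(aln$ref_codons, aln$der_codons) %in% STOPS))
})

test_that("cryptic screen partitions at the thresholds", {
  est <- tibble::tibble(omega = c(0.05, 0.25, 0.31, 0.45),
                        orf_len_nt = c(900, 1200, 300, 450),
                        dS = 0.02, dN = 0.01,
                        product = c("a", "b", "c", "d"))
  scr <- screen_cryptic(est)
  expect_equal(scr$summary$n_flagged, 2L)
  expect_equal(scr$summary$n_labeled, 1L)
  expect_equal(scr$labeled$product, "d")
  expect_equal(scr$summary$mean_len_flagged, mean(c(300, 450)))
  expect_equal(scr$summary$mean_len_unflagged, mean(c(900, 1200)))
  # all-constrained set: empty flag set
  scr2 <- screen_cryptic(dplyr::mutate(est, omega = 0.1))
  expect_equal(scr2$summary$n_flagged, 0L)
  expect_identical(generics::tidy(scr)$flagged, scr$estimates$flagged)
})

test_that("bootstrap standard errors are reproducible and positive", {
  set.seed(104)
  sim <- simulate_selection_pairs(1, 200, rate = 0.05, omega = 0.5,
                                  seed = 11)
  aln <- codon_align(sim$ref, sim$der)
  b1 <- dnds_bootstrap(aln, n_boot = 200, seed = 3)
  b2 <- dnds_bootstrap(aln, n_boot = 200, seed = 3)
  expect_identical(b1, b2)
  expect_gt(b1$se_dS, 0)
})
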