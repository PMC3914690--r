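#' Run the full comparative degeneration analysis
#'
#' Orchestrates every stage in dependency order — ortholog mapping,
#' pseudogene classification, dN/dS estimation and cryptic-pseudogene
#' screen, masked k-mer synteny with replichore-symmetry classification,
#' chromosome architecture (GC skew, KOPS, dif) for both genomes, IS
#' annotation with the intergenic clustering test, duplication detection,
#' and 16S rRNA mutation classification — and returns a result bundle
#' with a one-row summary of headline statistics. Optionally writes every
#' stage's table (TSV) and the summary (JSON) to `out_dir`.
#'
#' @param ref,der [annotated_genome()] objects (reference = free-living
#'   relative; derived = degenerating genome).
#' @param is_library Optional named IS consensus vector; enables the IS
#'   stages.
#' @param pairing_map,variability_map Optional 16S structure/variability
#'   maps (tibbles) for the rRNA stage.
#' @param thresholds [classify_thresholds()] list.
#' @param anchor_min_identity,anchor_min_coverage Permissive thresholds
#'   used when anchoring classification: heavily degraded pseudogenes
#'   (truncations, IS interruptions, early frameshifts) can fall to
#'   arbitrarily low protein identity, so anchoring defaults to unfiltered
#'   reciprocal best hits while the dN/dS stage keeps the strict 0.9/0.8
#'   filter.
#' @param k Synteny k-mer length.
#' @param n_perm Permutations for the IS clustering test.
#' @param dup_min_len Minimum duplication length.
#' @param seed Seed for the permutation test.
#' @param out_dir Optional output directory.
#' @return Object of class `degen_run`: list of stage results plus
#'   `summary` (one-row tibble).
#' @export
run_pipeline <- function(ref, der, is_library = NULL, pairing_map = NULL,
                         variability_map = NULL,
                         thresholds = classify_thresholds(), k = 20L,
                         n_perm = 10000L, dup_min_len = 2500L, seed = 1L,
                         anchor_min_identity = 0,
                         anchor_min_coverage = 0, out_dir = NULL) {
  res <- list()
  message("stage: ortholog mapping")
  res$orthologs <- find_orthologs(ref, der, anchor_min_identity,
                                  anchor_min_coverage)
  message("stage: pseudogene classification")
  res$classification <- classify_genome(der, ref, res$orthologs,
                                        thresholds, is_library)
  message("stage: dN/dS")
  strict <- dplyr::filter(res$orthologs, .data$protein_identity >= 0.9,
                          .data$coverage_ref >= 0.8)
  res$dnds <- dnds_pairs(strict, ref, der)
  res$screen <- if (nrow(res$dnds) && any(!is.na(res$dnds$omega))) {
    screen_cryptic(res$dnds)
  } else NULL
  message("stage: chromosome architecture")
  res$arch_ref <- chromosome_architecture(ref)
  res$arch_der <- chromosome_architecture(der)
  message("stage: synteny")
  res$synteny <- synteny_map(
    ref, der, k = k,
    ref_ori = res$arch_ref$ori, ref_ter = res$arch_ref$ter,
    der_ori = res$arch_der$ori, der_ter = res$arch_der$ter)
  if (!is.null(is_library)) {
    message("stage: IS elements")
    res$is_annotations <- annotate_is(der, is_library)
    if (nrow(res$is_annotations)) {
      res$is_clustering <- intergenic_clustering_test(
        res$is_annotations, der, n_perm = n_perm, seed = seed)
    }
  }
  message("stage: duplications")
  res$duplications <- detect_duplications(der, min_len = dup_min_len)
  ref_16s <- rrna_seqs(ref)
  der_16s <- rrna_seqs(der)
  if (length(ref_16s) && length(der_16s)) {
    message("stage: 16S rRNA mutations")
    if (!is.null(pairing_map)) {
      res$rrna_stem <- classify_stem_mutations(ref_16s[1], der_16s[1],
                                               pairing_map)
    }
    if (!is.null(variability_map)) {
      res$rrna_var <- classify_variability(ref_16s[1], der_16s[1],
                                           variability_map)
    }
  }
  res$summary <- pipeline_summary(res, der)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  structure(res, class = "degen_run")
}

rrna_seqs <- function(genome) {
  f <- dplyr::filter(genome$features, .data$kind == "rRNA_16S")
  vapply(seq_len(nrow(f)), function(i) {
    feature_seq(genome, f$start[i], f$end[i], f$strand[i])
  }, character(1))
}

pipeline_summary <- function(res, der) {
  cls <- res$classification$totals
  ig <- intergenic_ranges(der)
  tibble(
    n_orthologs = nrow(res$orthologs),
    n_cds = cls$n_cds, n_intact = cls$n_intact, n_pseudo = cls$n_pseudo,
    fraction_pseudo = cls$fraction_pseudo,
    mean_omega = if (!is.null(res$screen)) res$screen$summary$mean_omega
                 else NA_real_,
    n_flagged = if (!is.null(res$screen)) res$screen$summary$n_flagged
                else NA_integer_,
    violation_fraction = res$synteny$violation_fraction %||% NA_real_,
    polarization_ref = res$arch_ref$polarization_index,
    polarization_der = res$arch_der$polarization_index,
    kops_polarity_ref = res$arch_ref$kops_polarity,
    kops_polarity_der = res$arch_der$kops_polarity,
    dif_found_der = nrow(res$arch_der$dif) > 0,
    n_is = if (!is.null(res$is_annotations)) nrow(res$is_annotations)
           else NA_integer_,
    is_intergenic_fraction = if (!is.null(res$is_clustering))
      res$is_clustering$observed_intergenic_fraction else NA_real_,
    is_clustering_p = if (!is.null(res$is_clustering))
      res$is_clustering$p_value else NA_real_,
    intergenic_fraction = sum(ig$end - ig$start) / genome_length(der),
    n_duplications = nrow(res$duplications),
    rrna_disruptive_conservative_ratio = if (!is.null(res$rrna_stem))
      res$rrna_stem$counts$disruptive_conservative_ratio else NA_real_,
    rrna_rare_fraction = if (!is.null(res$rrna_var))
      res$rrna_var$rare_fraction else NA_real_)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tsv(res$orthologs, "orthologs")
  tsv(select(res$classification$per_cds, -"mutations"), "classification")
  if (nrow(res$dnds)) tsv(res$dnds, "dnds")
  if (!is.null(res$screen)) tsv(res$screen$estimates, "cryptic_screen")
  tsv(res$synteny$blocks, "synteny_blocks")
  tsv(res$arch_ref$track, "gc_skew_ref")
  tsv(res$arch_der$track, "gc_skew_der")
  if (!is.null(res$is_annotations)) tsv(res$is_annotations, "is_elements")
  if (nrow(res$duplications)) tsv(res$duplications, "duplications")
  jsonlite::write_json(as.list(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.degen_run <- function(x, ...) {
  cat("<degen_run>\n")
  print(tidyr::pivot_longer(x$summary, dplyr::everything(),
                            names_to = "statistic",
                            values_transform = as.character), n = 25)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `degen_run` object.
#' @param ... Unused.
#' @method glance degen_run
#' @export
glance.degen_run <- function(x, ...) x$summary

#' Simulate an ancestor/derived pair and analyse it
#'
#' Convenience wrapper chaining [generate_ancestor()], [degenerate()] and
#' [run_pipeline()]; the simulation's own pairing and variability maps and
#' IS library feed the corresponding analysis stages.
#'
#' @param cfg An [ancestor_config()].
#' @param params A [degeneration_params()].
#' @param ... Passed to [run_pipeline()].
#' @return List with `ancestor`, `derived` (the [degenerate()] output) and
#'   `run` (the `degen_run`).
#' @export
simulate_and_analyse <- function(cfg = ancestor_config(),
                                 params = degeneration_params(), ...) {
  anc <- generate_ancestor(cfg)
  deg <- degenerate(anc$genome, params)
  run <- run_pipeline(anc$genome, deg$genome, is_library = deg$is_library,
                      pairing_map = anc$meta$pairing_map,
                      variability_map = anc$meta$variability_map, ...)
  list(ancestor = anc, derived = deg, run = run)
}
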