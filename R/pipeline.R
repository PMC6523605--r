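#' Run the full synthetic pipeline end-to-end
#'
#' Desk-scale demonstration binding every stage: simulate the DGMS
#' recurrent-selection gene pool, genotype it alongside founder-taxon
#' reference panels, classify allele provenance, compute diversity
#' statistics and a neighbor-joining tree, call introgression on a DH panel
#' against the recurrent parent, merge segments, and summarize trait gains.
#' All outputs are plain text (TSV, BED, newick) plus a run-config echo.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param n_markers marker loci in the simulated genome.
#' @param n_rounds rounds of recurrent selection.
#' @param pop_size plants per round.
#' @param overwrite allow replacing existing outputs.
#' @return invisibly, a list with the main in-memory results and the paths
#'   written.
#' @export
run_demo <- function(out_dir, seed = 1, n_markers = 200, n_rounds = 3,
                     pop_size = 120, overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  msg <- function(...) message(sprintf(...))

  genome <- brassica_genome(n_markers, n_b_markers = 4)
  panel <- make_founders(genome, founder_config(novel_rate = 0.002),
                         seed = seed)
  scheme <- breeding_scheme(n_founders = 12, n_dgms = 12,
                            n_rounds = n_rounds, pop_size = pop_size,
                            sel_fraction = 0.3,
                            traits = list(trait_model(name = "OC", h2 = 0.6)))
  msg("simulating %d rounds of recurrent selection (%d plants/round)",
      n_rounds, pop_size)
  res <- simulate_recurrent_selection(panel, scheme, genome, seed = seed + 1)
  gt <- genotype_markers(res$final, missing_rate = 0.02, seed = seed + 2)
  write_genotype_table(gt, p("genotypes.tsv"), overwrite = overwrite)
  write_bed(res$truth, p("ancestry_truth.bed"), overwrite = overwrite)

  refs <- list(
    B_rapa = sample_taxon_panel(panel, "B_rapa", 12, seed = seed + 3),
    B_carinata = sample_taxon_panel(panel, "B_carinata", 12, seed = seed + 4),
    T_napus = sample_taxon_panel(panel, "T_napus", 12, seed = seed + 5))
  g_all <- bind_genotypes(refs$B_rapa, refs$B_carinata, refs$T_napus, gt)
  panels <- c(lapply(refs, function(r) r$samples$sample),
              list(new_type = gt$samples$sample))
  hits <- data.frame(marker = genome$markers$marker,
                     genome = genome$markers$genome,
                     chrom = genome$markers$chrom,
                     pos = genome$markers$pos, stringsAsFactors = FALSE)
  msg("classifying allele provenance at %d assays", nrow(hits))
  cls <- classify_markers(g_all, hits, panels)
  utils::write.table(cls, p("classification.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  intro <- summarize_introgressed_loci(g_all, cls,
                                       samples = gt$samples$sample)
  msg("loci with specific introgression: %d of %d (%.1f%%)",
      intro$n_specific_loci, intro$n_loci_detected,
      100 * intro$fraction_specific)

  part <- stats::setNames(genome$markers$genome, genome$markers$marker)
  div <- diversity_summary(g_all, partition = part,
                           reference_group = "T_napus", max_units = 10)
  utils::write.table(div, p("diversity_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  units <- c(gt$samples$sample[1:8], refs$B_rapa$samples$sample[1:6],
             refs$T_napus$samples$sample[1:6])
  mkA <- genome$markers$marker[genome$markers$genome == "A"]
  gA <- new_genotypes(g_all$calls[g_all$calls$locus %in% mkA, ],
                      g_all$samples)
  d <- nei_distance_matrix(subset_samples(gA, units))
  nj <- build_nj_tree(d)
  write_newick(nj, p("nj_tree.nwk"), overwrite = overwrite)

  msg("calling introgression on a DH panel vs HS3")
  dh <- simulate_dh_panel(n_lines = 24, genome = genome,
                          missing_rate = 0.05, seed = seed + 6)
  dh_f <- filter_missing(dh, 0.5, parent = "HS3")
  track <- call_vs_parent(dh_f, "HS3")
  utils::write.table(track$per_line, p("introgression_per_line.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flagged <- flag_b_genome_markers(dh_f,
                                   grep("^Tnap", colnames(dh_f$geno),
                                        value = TRUE))
  segs <- merge_segments(track, max_gap_markers = 0, b_flagged = flagged)
  write_bed(segs, p("segments.bed"), overwrite = overwrite)
  msg("mean per-line differing fraction %.3f; union %.3f; %d segments",
      mean(track$per_line$fraction), track$union_fraction, nrow(segs))

  summ <- generation_summary(res$trait_table)
  utils::write.table(summ$stats, p("trait_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  test <- generation_difference_test(res$trait_table, "OC")
  msg("trait OC generation test: F = %.2f, p = %.3g", test$statistic,
      test$p_value)

  write_run_config(list(seed = seed, n_markers = n_markers,
                        n_rounds = n_rounds, pop_size = pop_size),
                   p("run_config.tsv"), overwrite = overwrite)
  invisible(list(result = res, classification = cls, introgression = intro,
                 diversity = div, track = track, segments = segs,
                 trait_summary = summ, test = test, out_dir = out_dir))
}
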