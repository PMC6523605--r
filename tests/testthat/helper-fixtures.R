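# Shared fixture builders. Everything is generated in code at test time.

# minimal A-genome-only model: 10 chromosomes, one locus each
tiny_a_genome <- function(n_loci = 10L) {
  stopifnot(n_loci <= 10L)
  chroms <- data.frame(chrom = sprintf("A%02d", 1:10), genome = "A",
                       length_bp = 1e6, map_length_m = 1,
                       stringsAsFactors = FALSE)
  markers <- data.frame(marker = sprintf("L%02d", seq_len(n_loci)),
                        chrom = sprintf("A%02d", seq_len(n_loci)),
                        pos = 5e5, stringsAsFactors = FALSE)
  genome_model(chroms, markers)
}

# small full A+C(+B) model for simulator tests
small_genome <- function(n_markers = 100L, n_b = 3L, include_b = TRUE) {
  brassica_genome(n_markers, n_b_markers = n_b, include_b = include_b)
}

# Idealized fully-ascertained reference panel: pseudo-accessions of one
# taxon jointly carrying every allele of that taxon, packed two per sample.
full_reference_panel <- function(panel, taxon) {
  fr <- panel$freqs[panel$freqs$taxon == taxon & panel$freqs$freq > 0, ]
  loci <- split(fr$allele, fr$marker)
  n_samp <- max(vapply(loci, function(a) ceiling(length(a) / 2), numeric(1)))
  ids <- sprintf("%s_ref%02d", taxon, seq_len(n_samp))
  calls <- do.call(rbind, lapply(names(loci), function(m) {
    a <- loci[[m]]
    a1 <- a[seq(1, length(a), by = 2)]
    a2 <- a[pmin(seq(2, length(a) + 1, by = 2), length(a))]
    k <- length(a1)
    data.frame(sample = ids[seq_len(k)], marker = m, locus = m,
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  }))
  # samples not covering a locus stay absent (no row): treated as missing
  new_genotypes(calls, data.frame(sample = ids, taxon = taxon,
                                  stringsAsFactors = FALSE))
}

# hit table straight from a genome model (one hit per single-locus marker)
hits_from_genome <- function(genome) {
  data.frame(marker = genome$markers$marker, genome = genome$markers$genome,
             chrom = genome$markers$chrom, pos = genome$markers$pos,
             stringsAsFactors = FALSE)
}

# cache one medium simulation across test files
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function() {
  if (is.null(sim_cache$res)) {
    g <- small_genome(100, 3)
    p <- make_founders(g, founder_config(novel_rate = 0.005), seed = 11)
    sch <- breeding_scheme(n_founders = 10, n_dgms = 10, n_rounds = 2,
                           pop_size = 80, sel_fraction = 0.4)
    sim_cache$genome <- g
    sim_cache$panel <- p
    sim_cache$res <- simulate_recurrent_selection(p, sch, g, seed = 12)
  }
  list(genome = sim_cache$genome, panel = sim_cache$panel,
       res = sim_cache$res)
}
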