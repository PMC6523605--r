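#' Founder diversity configuration
#'
#' Parameters controlling the simulated allele pools of the three founder
#' taxa: *B. rapa* (A genome), *B. carinata* (B and C genomes) and traditional
#' *B. napus* (A and C genomes).
#'
#' @param alleles_per_locus integer vector of length 1 or 2; number (or
#'   inclusive range) of distinct alleles segregating at each marker locus.
#' @param private_prop probability that an allele is private to a single
#'   taxon among the taxa carrying that locus's genome.
#' @param novel_rate per-gamete, per-locus probability of a novel allele
#'   (one absent from all founder taxa) arising in derived material.
#' @return a list of class `diversity_config`.
#' @export
founder_config <- function(alleles_per_locus = 4L, private_prop = 0.25,
                           novel_rate = 0.001) {
  assert_that(all(alleles_per_locus >= 1) && length(alleles_per_locus) <= 2,
              "`alleles_per_locus` must be a positive count or range")
  assert_that(private_prop >= 0 && private_prop <= 1,
              "`private_prop` must be in [0, 1]")
  assert_that(novel_rate >= 0 && novel_rate < 1,
              "`novel_rate` must be in [0, 1)")
  structure(list(alleles_per_locus = as.integer(alleles_per_locus),
                 private_prop = private_prop, novel_rate = novel_rate),
            class = "diversity_config")
}

# Taxa carrying each basic genome. Specificity of alleles is defined over the
# taxa in which a locus can amplify at all.
TAXA <- c("B_rapa", "B_carinata", "T_napus")

taxa_for_genome <- function(genome) {
  switch(genome,
         A = c("B_rapa", "T_napus"),
         C = c("B_carinata", "T_napus"),
         B = "B_carinata",
         abort(sprintf("unknown genome '%s'", genome)))
}

#' Simulate founder allele pools
#'
#' Draws, for every marker locus of the genome model, an allele set shared by
#' the taxa that carry the locus's genome, assigns a configurable proportion
#' of alleles as taxon-private, and samples Dirichlet-style allele frequencies
#' per taxon. Private alleles are the substrate for downstream provenance
#' calls: an A-locus allele private to *B. rapa* is an Ar-specific allele, a
#' C-locus allele private to *B. carinata* is Cc-specific, and every B-locus
#' allele is carried only by *B. carinata* (Bc).
#'
#' @param genome a [genome_model()].
#' @param config a [founder_config()].
#' @param seed integer seed; identical seeds give identical panels.
#' @return an object of class `founder_panel`: list with `freqs` (data.frame
#'   taxon, marker, allele, freq), `private` (data.frame allele, marker,
#'   taxon), `novel_rate`, and the marker table.
#' @export
make_founders <- function(genome, config = founder_config(), seed) {
  assert_that(inherits(genome, "genome_model"), "`genome` must be a genome_model")
  assert_that(inherits(config, "diversity_config"),
              "`config` must come from founder_config()")
  with_seed(seed, {
    mk <- genome$markers
    rng <- config$alleles_per_locus
    k_per <- if (length(rng) == 2L) {
      sample(seq(rng[1], rng[2]), nrow(mk), replace = TRUE)
    } else rep(rng, nrow(mk))
    freq_rows <- vector("list", nrow(mk))
    priv_rows <- vector("list", nrow(mk))
    for (i in seq_len(nrow(mk))) {
      m <- mk$marker[i]
      taxa <- taxa_for_genome(mk$genome[i])
      k <- k_per[i]
      alleles <- sprintf("%s.a%d", m, seq_len(k))
      # allele -> owner taxon, or NA for shared among all carrier taxa
      owner <- rep(NA_character_, k)
      if (length(taxa) > 1L) {
        is_priv <- stats::runif(k) < config$private_prop
        owner[is_priv] <- sample(taxa, sum(is_priv), replace = TRUE)
        # every carrier taxon must retain at least one allele
        for (tx in taxa) {
          if (!any(is.na(owner) | owner == tx)) {
            owner[sample.int(k, 1L)] <- NA_character_
          }
        }
      } else {
        owner[] <- taxa  # single-carrier genome: all alleles are private
      }
      rows <- do.call(rbind, lapply(taxa, function(tx) {
        mine <- which(is.na(owner) | owner == tx)
        w <- stats::rgamma(length(mine), shape = 1)
        data.frame(taxon = tx, marker = m, allele = alleles[mine],
                   freq = w / sum(w), stringsAsFactors = FALSE)
      }))
      freq_rows[[i]] <- rows
      if (any(!is.na(owner))) {
        j <- which(!is.na(owner))
        priv_rows[[i]] <- data.frame(allele = alleles[j], marker = m,
                                     taxon = owner[j], stringsAsFactors = FALSE)
      }
    }
    freqs <- do.call(rbind, freq_rows)
    private <- do.call(rbind, priv_rows) %||%
      data.frame(allele = character(), marker = character(),
                 taxon = character(), stringsAsFactors = FALSE)
    validate_founder_panel(freqs)
    structure(list(freqs = freqs, private = private,
                   novel_rate = config$novel_rate, markers = mk),
              class = "founder_panel")
  })
}

validate_founder_panel <- function(freqs) {
  assert_that(all(freqs$freq >= 0), "negative allele frequency")
  sums <- tapply(freqs$freq, paste(freqs$taxon, freqs$marker), sum)
  assert_that(all(abs(sums - 1) < 1e-8),
              "allele frequencies must sum to 1 per taxon and locus")
  invisible(TRUE)
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(unique(x$freqs$marker)), "loci,",
      nrow(x$private), "taxon-private alleles, novel-allele rate",
      x$novel_rate, "\n")
  invisible(x)
}

# frequency lookup table: environment keyed by taxon|marker -> named freq vec
panel_lookup <- function(panel) {
  key <- paste(panel$freqs$taxon, panel$freqs$marker, sep = "|")
  split_idx <- split(seq_len(nrow(panel$freqs)), key)
  env <- new.env(parent = emptyenv(), size = length(split_idx))
  for (k in names(split_idx)) {
    i <- split_idx[[k]]
    v <- panel$freqs$freq[i]
    names(v) <- panel$freqs$allele[i]
    assign(k, v, envir = env)
  }
  env
}
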