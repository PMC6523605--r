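test_that("founder panels carry the configured number of private alleles", {
  g <- tiny_a_genome(10)
  cfg <- founder_config(alleles_per_locus = 4L, private_prop = 0.25)
  counts <- vapply(1:100, function(s) {
    nrow(make_founders(g, cfg, seed = s)$private)
  }, numeric(1))
  # expectation: 10 loci x 4 alleles x 25% = 10 private alleles
  expect_gt(mean(counts), 9)
  expect_lt(mean(counts), 11)
})

test_that("zero private proportion yields no taxon-unique allele", {
  g <- tiny_a_genome(10)
  p <- make_founders(g, founder_config(private_prop = 0), seed = 5)
  expect_identical(nrow(p$private), 0L)
  # every allele has nonzero frequency in both carrier taxa
  tab <- table(p$freqs$allele)
  expect_true(all(tab == 2L))
})

test_that("founder panels are reproducible under the seed and frequencies are valid", {
  g <- tiny_a_genome(6)
  p1 <- make_founders(g, founder_config(), seed = 42)
  p2 <- make_founders(g, founder_config(), seed = 42)
  expect_identical(p1, p2)
  sums <- tapply(p1$freqs$freq, paste(p1$freqs$taxon, p1$freqs$marker), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # a private allele has nonzero frequency in exactly one taxon
  for (i in seq_len(nrow(p1$private))) {
    a <- p1$private$allele[i]
    expect_identical(unique(p1$freqs$taxon[p1$freqs$allele == a]),
                     p1$private$taxon[i])
  }
})

test_that("DGMS progeny of a sterile x fertile mating segregate 1:1", {
  geno <- sim_dgms_progeny(10000, seed = 7)
  frac <- mean(is_sterile(geno))
  expect_true(abs(frac - 0.5) < 0.01)
  # fertile mother gives no sterile progeny, sterile father is rejected
  expect_true(all(sim_dgms_progeny(100, seed = 1, mother = "msms") == "msms"))
  expect_error(sim_dgms_progeny(10, seed = 1, father = "Msms"), "pollen")
})

test_that("segregation holds in every simulated round", {
  sim <- cached_sim()
  for (pop in sim$res$rounds[-1]) {
    n <- length(pop$dgms)
    frac <- mean(is_sterile(pop$dgms))
    expect_lt(abs(frac - 0.5), 2 / sqrt(n))
  }
})

test_that("zero rounds returns the base population unchanged", {
  g <- small_genome(60, 2)
  p <- make_founders(g, founder_config(), seed = 3)
  sch <- breeding_scheme(n_founders = 5, n_dgms = 5, n_rounds = 0,
                         pop_size = 50)
  res <- simulate_recurrent_selection(p, sch, g, seed = 4)
  expect_length(res$rounds, 1L)
  expect_identical(res$final$generation, 0L)
  expect_true(all(res$final$subpop %in% c("DGMS", "Poly_Ar", "Poly_Cc")))
})

test_that("simulations are byte-identical under the same seed", {
  g <- small_genome(60, 2)
  p <- make_founders(g, founder_config(), seed = 3)
  sch <- breeding_scheme(n_founders = 6, n_dgms = 6, n_rounds = 1,
                         pop_size = 40, sel_fraction = 0.5)
  r1 <- simulate_recurrent_selection(p, sch, g, seed = 9)
  r2 <- simulate_recurrent_selection(p, sch, g, seed = 9)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$trait_table, r2$trait_table)
})

test_that("selection at full heritability never decreases the mean phenotype", {
  g <- small_genome(60, 0, include_b = FALSE)
  p <- make_founders(g, founder_config(novel_rate = 0), seed = 21)
  sch <- breeding_scheme(n_founders = 8, n_dgms = 8, n_rounds = 5,
                         pop_size = 60, sel_fraction = 0.25,
                         traits = list(trait_model(h2 = 1, n_qtl = 15)))
  for (s in 1:20) {
    res <- simulate_recurrent_selection(p, sch, g, seed = 100 + s)
    mu <- tapply(res$trait_table$value, res$trait_table$generation, mean)
    mu <- mu[order(as.integer(sub("RS", "", names(mu))))]
    expect_true(all(diff(mu) >= 0),
                info = sprintf("seed %d: %s", s, paste(round(mu, 3),
                                                       collapse = " -> ")))
  }
})

test_that("an over-tight selection fraction fails loudly", {
  g <- small_genome(60, 0, include_b = FALSE)
  p <- make_founders(g, founder_config(), seed = 3)
  sch <- breeding_scheme(n_founders = 5, n_dgms = 5, n_rounds = 1,
                         pop_size = 30, sel_fraction = 0.01)
  expect_error(simulate_recurrent_selection(p, sch, g, seed = 1),
               "selection fraction")
})

test_that("marker genotyping respects missingness and ancestry", {
  sim <- cached_sim()
  pop <- sim$res$final
  gt0 <- genotype_markers(pop, missing_rate = 0)
  expect_false(any(is.na(gt0$calls$allele1) & gt0$calls$locus %in%
                     colnames(pop$hap_allele[[1]])))
  gt2 <- genotype_markers(pop, missing_rate = 0.3, seed = 2)
  ac <- gt2$calls$locus %in% colnames(pop$hap_allele[[1]])
  miss <- mean(is.na(gt2$calls$allele1[ac]))
  expect_lt(abs(miss - 0.3), 0.03)
  # B-genome loci: call present exactly where the truth track has a segment
  tr <- sim$res$truth
  bloci <- colnames(pop$b_pres)
  bcalls <- gt0$calls[gt0$calls$locus %in% bloci, ]
  pos <- sim$genome$markers
  for (k in sample(nrow(bcalls), 200)) {
    row <- bcalls[k, ]
    pchrom <- pos$chrom[pos$marker == row$locus]
    ppos <- pos$pos[pos$marker == row$locus]
    seg <- tr[tr$sample == row$sample & tr$chrom == pchrom &
                tr$origin == "Bc" & tr$start <= ppos & tr$end >= ppos, ]
    expect_identical(!is.na(row$allele1), nrow(seg) > 0L)
  }
  expect_error(genotype_markers(pop, panel = data.frame(marker = "x",
                                                        locus = "nope")),
               "unknown loci")
})

test_that("every genotyped allele traces to the founder panel or is flagged novel", {
  sim <- cached_sim()
  gt <- genotype_markers(sim$res$final)
  alleles <- stats::na.omit(unique(c(gt$calls$allele1, gt$calls$allele2)))
  known <- alleles %in% sim$panel$freqs$allele
  novel <- grepl("\\.nov", alleles)
  expect_true(all(known | novel))
  # novel fraction among allele copies is of the order of the mutation rate
  copies <- c(gt$calls$allele1, gt$calls$allele2)
  nov_frac <- mean(grepl("\\.nov", stats::na.omit(copies)))
  expect_lt(nov_frac, 20 * sim$panel$novel_rate)
})

test_that("ancestry truth tiles A/C chromosomes and confines Bc to B chromosomes", {
  sim <- cached_sim()
  tr <- sim$res$truth
  expect_true(all(tr$origin[substr(tr$chrom, 1, 1) == "B"] == "Bc"))
  expect_false(any(tr$origin[substr(tr$chrom, 1, 1) != "B"] == "Bc"))
  chrlen <- sim$genome$chromosomes
  one <- tr[tr$sample == tr$sample[1] & tr$chrom == "A01" & tr$homologue == 1, ]
  one <- one[order(one$start), ]
  expect_identical(one$start[1], 1)
  expect_identical(one$end[nrow(one)],
                   chrlen$length_bp[chrlen$chrom == "A01"])
  if (nrow(one) > 1) {
    expect_true(all(one$start[-1] == one$end[-nrow(one)] + 1))
  }
})
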