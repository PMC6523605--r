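# helpers to build compact patterns: flags given as strings over r/c/n/x
# (x = new-type); hits given as genome letters
pat <- function(..., hits, map_chrom = NULL) {
  flag_strs <- c(...)
  al <- data.frame(
    allele = sprintf("a%d", seq_along(flag_strs)),
    in_rapa = grepl("r", flag_strs), in_carinata = grepl("c", flag_strs),
    in_napus = grepl("n", flag_strs), in_newtype = grepl("x", flag_strs),
    stringsAsFactors = FALSE)
  hdf <- data.frame(genome = hits,
                    chrom = paste0(hits, "01"), pos = 1000,
                    stringsAsFactors = FALSE)
  presence_pattern(al, hdf, map_chrom = map_chrom)
}

test_that("rules i, ii, iii and iv fire on their canonical patterns", {
  # (i) napus+carinata alleles aligned to C -> one C-specific locus
  a <- assign_locus_genome(pat("n", "c", "cn", hits = "C"))
  expect_identical(a$status, "assigned")
  expect_identical(a$loci$genome, "C")
  expect_identical(a$loci$rule, "i")
  # (ii) napus+rapa alleles aligned to A -> one A-specific locus
  a <- assign_locus_genome(pat("n", "r", hits = "A"))
  expect_identical(a$loci$genome, "A")
  expect_identical(a$loci$rule, "ii")
  # (iii) split allele groups on an A+C alignment -> C locus and A locus
  a <- assign_locus_genome(pat("c", "cn", "r", "rn", hits = c("A", "C")))
  expect_identical(a$status, "assigned")
  expect_setequal(a$loci$genome, c("A", "C"))
  expect_identical(unique(a$loci$rule), "iii")
  expect_identical(unname(a$allele_locus[c("a1", "a3")]),
                   c("locus_C", "locus_A"))
  # (iv) all three taxa with A and B alignments -> A/B locus pair
  a <- assign_locus_genome(pat("c", "r", "n", "rn", hits = c("A", "B")))
  expect_setequal(a$loci$genome, c("A", "B"))
  expect_identical(unique(a$loci$rule), "iv")
  expect_identical(unname(a$allele_locus["a1"]), "locus_B")
})

test_that("contradictory evidence is flagged conflict, never silently assigned", {
  a <- assign_locus_genome(pat("r", hits = "C"))
  expect_identical(a$status, "conflict")
  expect_match(a$reason, "rapa")
  a <- assign_locus_genome(pat("c", "n", hits = "A"))
  expect_identical(a$status, "conflict")
  # allele in both rapa and carinata under a split alignment
  a <- assign_locus_genome(pat("rc", "n", hits = c("A", "C")))
  expect_identical(a$status, "conflict")
})

test_that("ambiguous multi-hit alignments defer to the genetic map or stay unassigned", {
  hdf <- data.frame(genome = c("C", "C"), chrom = c("C03", "C07"), pos = 1,
                    stringsAsFactors = FALSE)
  al <- data.frame(allele = "a1", in_rapa = FALSE, in_carinata = TRUE,
                   in_napus = TRUE, in_newtype = FALSE)
  expect_identical(
    assign_locus_genome(presence_pattern(al, hdf))$status, "unassigned")
  a <- assign_locus_genome(presence_pattern(al, hdf, map_chrom = "C07"))
  expect_identical(a$status, "assigned")
  expect_identical(a$loci$chrom, "C07")
})

test_that("assignment equals the hand-enumerated rule table", {
  # expected outcome for every reference-taxa subset x alignment-genome set;
  # "A","C" = that single locus, "A+C"/"A+B" = pair, "U" = unassigned,
  # "X" = conflict. Derived by hand from the four published rules plus the
  # consistency requirements (rapa needs an A hit, carinata a B or C hit).
  expected <- list(
    n =  c(A = "A", B = "U", C = "C", AB = "U", AC = "U", BC = "U", ABC = "U"),
    r =  c(A = "A", B = "X", C = "X", AB = "U", AC = "U", BC = "X", ABC = "U"),
    c =  c(A = "X", B = "U", C = "C", AB = "U", AC = "U", BC = "U", ABC = "U"),
    rn = c(A = "A", B = "X", C = "X", AB = "U", AC = "U", BC = "X", ABC = "U"),
    cn = c(A = "X", B = "U", C = "C", AB = "U", AC = "U", BC = "U", ABC = "U"),
    rc = c(A = "X", B = "X", C = "X", AB = "U", AC = "A+C", BC = "X", ABC = "U"),
    rcn = c(A = "X", B = "X", C = "X", AB = "A+B", AC = "A+C", BC = "X",
            ABC = "U")
  )
  gsets <- list(A = "A", B = "B", C = "C", AB = c("A", "B"),
                AC = c("A", "C"), BC = c("B", "C"), ABC = c("A", "B", "C"))
  # one allele per involved taxon keeps rule-(iii) splits conflict-free
  flag_sets <- list(n = "n", r = "r", c = "c", rn = c("r", "n"),
                    cn = c("c", "n"), rc = c("r", "c"),
                    rcn = c("r", "c", "n"))
  for (tx in names(expected)) {
    for (gs in names(gsets)) {
      a <- assign_locus_genome(do.call(pat, c(as.list(flag_sets[[tx]]),
                                              list(hits = gsets[[gs]]))))
      want <- expected[[tx]][[gs]]
      got <- switch(a$status, conflict = "X", unassigned = "U",
                    paste(sort(a$loci$genome), collapse = "+"))
      expect_identical(got, want,
                       label = sprintf("taxa {%s} x hits {%s}: %s", tx, gs, got))
    }
  }
})

test_that("novel-only patterns fall back on the alignment", {
  a <- assign_locus_genome(pat("x", hits = "A"))
  expect_identical(a$status, "assigned")
  expect_identical(a$loci$rule, "alignment_only")
  expect_identical(assign_locus_genome(pat("x", hits = c("A", "C")))$status,
                   "unassigned")
})

test_that("allele origins follow locus genome and presence", {
  p <- pat("r", "n", "rn", "x", hits = "A")
  cls <- classify_allele_origin(assign_locus_genome(p), p)
  expect_identical(as.character(cls$origin),
                   c("Ar_specific", "An_specific", "shared", "novel"))
  p <- pat("c", "n", "cnx", hits = "C")
  cls <- classify_allele_origin(assign_locus_genome(p), p)
  expect_identical(as.character(cls$origin),
                   c("Cc_specific", "Cn_specific", "shared"))
  p <- pat("c", "r", "n", hits = c("A", "B"))
  cls <- classify_allele_origin(assign_locus_genome(p), p)
  expect_identical(as.character(cls$origin),
                   c("Bc_specific", "Ar_specific", "An_specific"))
  # every retained allele receives exactly one label
  expect_false(anyNA(cls$origin))
})

test_that("classification is invariant to sample order", {
  sim <- cached_sim()
  gt <- genotype_markers(sim$res$final)
  ref <- lapply(c("B_rapa", "B_carinata", "T_napus"), function(tx) {
    full_reference_panel(sim$panel, tx)
  })
  g <- do.call(bind_genotypes, c(ref, list(gt)))
  panels <- list(B_rapa = ref[[1]]$samples$sample,
                 B_carinata = ref[[2]]$samples$sample,
                 T_napus = ref[[3]]$samples$sample,
                 new_type = gt$samples$sample)
  hits <- hits_from_genome(sim$genome)
  sub <- unique(g$calls$marker)[1:15]
  g_sub <- function(gg) new_genotypes(gg$calls[gg$calls$marker %in% sub, ],
                                      gg$samples)
  c1 <- classify_markers(g_sub(g), hits, panels)
  shuffled <- g$calls[sample(nrow(g$calls)), ]
  c2 <- classify_markers(g_sub(new_genotypes(shuffled, g$samples)), hits,
                         panels)
  a1 <- c1[order(c1$marker, c1$allele), ]
  a2 <- c2[order(c2$marker, c2$allele), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_identical(a1, a2)
})

test_that("planted specific and novel alleles are recovered exactly", {
  sim <- cached_sim()
  gt <- genotype_markers(sim$res$final)  # zero missingness
  ref <- lapply(c("B_rapa", "B_carinata", "T_napus"), function(tx) {
    full_reference_panel(sim$panel, tx)
  })
  g <- do.call(bind_genotypes, c(ref, list(gt)))
  panels <- list(B_rapa = ref[[1]]$samples$sample,
                 B_carinata = ref[[2]]$samples$sample,
                 T_napus = ref[[3]]$samples$sample,
                 new_type = gt$samples$sample)
  mk <- sim$genome$markers
  # B loci are assayed as A/B markers (amplified with an A-genome homologue)
  b_loci <- mk$marker[mk$genome == "B"]
  a_loci <- mk$marker[mk$genome == "A"][seq_along(b_loci)]
  single <- setdiff(mk$marker, c(b_loci, a_loci))
  panel_df <- rbind(
    data.frame(marker = single, locus = single, stringsAsFactors = FALSE),
    data.frame(marker = paste0("AB_", seq_along(b_loci)),
               locus = a_loci, stringsAsFactors = FALSE),
    data.frame(marker = paste0("AB_", seq_along(b_loci)),
               locus = b_loci, stringsAsFactors = FALSE))
  # rebuild observed genotypes under that assay panel
  remap <- function(gg) {
    m <- match(gg$calls$locus, panel_df$locus)
    gg$calls$marker <- panel_df$marker[m]
    gg
  }
  g2 <- new_genotypes(remap(g)$calls, g$samples)
  hits <- do.call(rbind, lapply(split(panel_df, panel_df$marker), function(d) {
    data.frame(marker = d$marker[1],
               genome = mk$genome[match(d$locus, mk$marker)],
               chrom = mk$chrom[match(d$locus, mk$marker)],
               pos = mk$pos[match(d$locus, mk$marker)],
               stringsAsFactors = FALSE)
  }))
  cls <- classify_markers(g2, hits, panels)
  expect_true(all(cls$status == "assigned"))
  # ground truth from the founder registry
  reg <- sim$panel$private
  truth_origin <- function(allele) {
    if (grepl("\\.nov", allele)) return("novel")
    i <- match(allele, reg$allele)
    if (is.na(i)) return("shared")
    gme <- mk$genome[match(reg$marker[i], mk$marker)]
    switch(paste0(gme, reg$taxon[i]),
           AB_rapa = "Ar_specific", AT_napus = "An_specific",
           CB_carinata = "Cc_specific", CT_napus = "Cn_specific",
           BB_carinata = "Bc_specific", "shared")
  }
  want <- vapply(cls$allele, truth_origin, character(1))
  expect_identical(as.character(cls$origin), unname(want))
})

test_that("introgressed-locus tallies match hand counts", {
  # 10 loci; 4 carry one Cc-specific allele each -> fraction 0.4
  calls <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(sample = c("s1", "s2"), marker = paste0("m", i),
               locus = paste0("m", i), allele1 = paste0("m", i, ".a1"),
               allele2 = paste0("m", i, c(".a1", ".a2")),
               stringsAsFactors = FALSE)
  }))
  g <- new_genotypes(calls, data.frame(sample = c("s1", "s2"), taxon = "RS"))
  cls <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(marker = paste0("m", i), locus = paste0("m", i),
               allele = paste0("m", i, c(".a1", ".a2")),
               origin = c("shared", if (i <= 4) "Cc_specific" else "shared"),
               stringsAsFactors = FALSE)
  }))
  s <- summarize_introgressed_loci(g, cls)
  expect_identical(s$n_loci_detected, 10L)
  expect_identical(s$n_specific_loci, 4L)
  expect_identical(s$n_multi_specific_loci, 0L)
  expect_equal(s$fraction_specific, 0.4)
  # no specific alleles -> fraction 0
  cls0 <- cls; cls0$origin <- "shared"
  expect_identical(summarize_introgressed_loci(g, cls0)$n_specific_loci, 0L)
})
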