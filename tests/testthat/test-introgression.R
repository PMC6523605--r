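toy_matrix <- function(geno_rows, samples, chrom = "A01",
                       genome = substr(chrom, 1, 1), pos = NULL,
                       source = "napus_AC") {
  n <- length(geno_rows)
  markers <- data.frame(marker = sprintf("m%02d", seq_len(n)),
                        source = source, genome = genome,
                        chrom = chrom,
                        pos = pos %||% seq(1e5, by = 1e5, length.out = n),
                        stringsAsFactors = FALSE)
  geno <- do.call(rbind, geno_rows)
  dimnames(geno) <- list(markers$marker, samples)
  marker_matrix(markers, geno)
}

test_that("marker-set harmonization tallies matched and additional markers", {
  napus <- data.frame(marker = paste0("n", 1:4), source = "napus_AC",
                      genome = "A", chrom = "A01", pos = 1:4 * 100)
  alt <- data.frame(marker = paste0("r", 1:5), source = "rapa_A",
                    genome = "A", chrom = "A01", pos = 1:5 * 90)
  match_tab <- data.frame(alt_marker = c("r1", "r2", "r3"),
                          napus_marker = c("n1", "n2", "n3"))
  u <- harmonize_marker_sets(napus, alt, match_tab)
  expect_identical(unname(attr(u, "counts")), c(4L, 3L, 2L, 0L))
  expect_identical(sum(u$status == "additional_specific"), 2L)
  # empty alt set: unified = primary set
  u0 <- harmonize_marker_sets(napus, alt[0, ],
                              match_tab[0, ])
  expect_identical(nrow(u0), 4L)
  # all matched -> no additional markers
  mt_all <- data.frame(alt_marker = paste0("r", 1:5),
                       napus_marker = paste0("n", c(1, 2, 3, 4, 4)))
  u1 <- harmonize_marker_sets(napus, alt, mt_all)
  expect_identical(sum(u1$status == "additional_specific"), 0L)
  # ambiguous double match is excluded with a message
  mt_amb <- data.frame(alt_marker = c("r1", "r1"),
                       napus_marker = c("n1", "n2"))
  expect_message(u2 <- harmonize_marker_sets(napus, alt, mt_amb), "multiple")
  expect_identical(unname(attr(u2, "counts")["ambiguous"]), 1L)
  expect_false("r1" %in% u2$marker)
})

test_that("B-genome markers are flagged only when every traditional line is missing", {
  trad <- paste0("T", 1:11)
  dh <- paste0("D", 1:3)
  rows <- list(c(rep(NA_character_, 11), "1/1", "1/1", NA),  # all trad missing
               c("0/0", rep(NA_character_, 10), "1/1", NA, NA),  # 1 trad called
               rep(NA_character_, 14))                       # nobody called
  mm <- toy_matrix(rows, c(trad, dh), chrom = "B04")
  flagged <- flag_b_genome_markers(mm, trad)
  expect_setequal(flagged, c("m01", "m03"))
  # non-B markers are never flagged
  mm_a <- toy_matrix(rows, c(trad, dh), chrom = "A01")
  expect_identical(flag_b_genome_markers(mm_a, trad), character())
})

test_that("missing-rate filtering uses a strict threshold and is monotone and idempotent", {
  samples <- paste0("s", 1:10)
  rows <- lapply(0:10, function(k) {
    c(rep(NA_character_, k), rep("0/0", 10 - k))
  })
  mm <- toy_matrix(rows, samples)
  f <- filter_missing(mm, 0.5)
  # missing in exactly 5 of 10 (50%) is removed: keep k = 0..4
  expect_identical(nrow(f$markers), 5L)
  # threshold 1.0 removes nothing except the fully-missing marker
  expect_identical(nrow(filter_missing(mm, 1.0)$markers), 10L)
  kept <- vapply(seq(0.1, 1, by = 0.1), function(th) {
    nrow(filter_missing(mm, th)$markers)
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
  expect_identical(filter_missing(f, 0.5), f)  # idempotent
  # parent entirely missing -> error
  mm2 <- toy_matrix(list(c(NA, "0/0"), c(NA, "1/1")), c("HS3", "d1"))
  expect_error(filter_missing(mm2, 0.5, parent = "HS3"), "parent")
})

test_that("difference calls against the parent follow allele-set comparison", {
  samples <- c("HS3", "same", "diff", "het", "gap")
  rows <- list(c("0/0", "0/0", "1/1", "0/1", NA),
               c("0/1", "1/0", "0/0", "0/1", "0/0"),
               c("1/1", "1/1", "1/1", "1/1", NA))
  mm <- toy_matrix(rows, samples)
  tr <- call_vs_parent(mm, "HS3")
  expect_identical(unname(tr$states[, "same"]), rep("same_as_parent", 3))
  expect_identical(unname(tr$states[1:2, "diff"]), c("differs", "differs"))
  expect_identical(unname(tr$states[, "het"]),
                   c("differs", "same_as_parent", "same_as_parent"))
  expect_identical(unname(tr$states[c(1, 3), "gap"]), rep("missing", 2))
  pl <- tr$per_line
  expect_equal(pl$fraction[pl$sample == "same"], 0)
  expect_equal(pl$fraction[pl$sample == "het"], 1 / 3)
  # union counts a marker once if any line differs (m1, m2 but not m3)
  expect_equal(tr$union_fraction, 2 / 3)
  expect_error(call_vs_parent(mm, "nope"), "parent")
})

test_that("union fraction dominates per-line fractions and single-line union collapses", {
  sim <- simulate_dh_panel(n_lines = 12, genome = brassica_genome(120, 4),
                           missing_rate = 0.1, seed = 5)
  mm <- filter_missing(sim, 0.5, parent = "HS3")
  tr <- call_vs_parent(mm, "HS3")
  expect_true(tr$union_fraction >= max(tr$per_line$fraction, na.rm = TRUE))
  one <- marker_matrix(mm$markers,
                       mm$geno[, c("HS3", "DH_001"), drop = FALSE])
  tr1 <- call_vs_parent(one, "HS3")
  expect_equal(tr1$union_fraction,
               tr1$per_line$fraction[tr1$per_line$sample == "DH_001"])
})

test_that("planted exotic ancestry fractions are recovered at zero noise", {
  sim <- simulate_dh_panel(n_lines = 40, genome = brassica_genome(300, 6),
                           exotic_range = c(0.30, 0.65), missing_rate = 0,
                           seed = 8)
  truth <- attr(sim, "truth")
  tr <- call_vs_parent(sim, "HS3")
  est <- tr$per_line[match(truth$sample, tr$per_line$sample), ]
  # restrict the comparison to informative A/C markers: the per-line
  # fraction also counts B markers, so recompute over AC rows
  ac <- sim$markers$genome != "B"
  st <- tr$states[ac, truth$sample]
  frac_ac <- colSums(st == "differs") /
    (colSums(st == "differs") + colSums(st == "same_as_parent"))
  expect_true(all(abs(frac_ac - truth$true_fraction) < 0.05))
  expect_true(tr$union_fraction > max(frac_ac))
})

test_that("segment merging spans supporting markers and honors gaps", {
  samples <- c("HS3", "d1")
  # 7 markers: differs at 1,2,3, same at 4, differs at 5, same at 6,7
  g <- list(c("0/0", "1/1"), c("0/0", "1/1"), c("0/0", "1/1"),
            c("0/0", "0/0"), c("0/0", "1/1"), c("0/0", "0/0"),
            c("0/0", "0/0"))
  mm <- toy_matrix(g, samples)
  tr <- call_vs_parent(mm, "HS3")
  seg0 <- merge_segments(tr, max_gap_markers = 0)
  expect_identical(nrow(seg0), 2L)
  expect_identical(seg0$n_markers, c(3L, 1L))
  seg1 <- merge_segments(tr, max_gap_markers = 1)
  expect_identical(nrow(seg1), 1L)
  expect_identical(seg1$n_markers, 4L)
  expect_equal(seg1$start, 1e5)
  expect_equal(seg1$end, 5e5)
  # single isolated supporting marker is a 1-marker segment
  expect_identical(seg0$n_markers[2], 1L)
  expect_equal(seg0$length_bp[2], 0)
  # every differing call lies in exactly one segment at gap 0
  expect_identical(sum(seg0$n_markers), sum(tr$states[, "d1"] == "differs"))
  # min_markers filters singletons
  expect_identical(nrow(merge_segments(tr, min_markers = 2)), 1L)
})

test_that("unsorted marker tables are rejected rather than silently re-sorted", {
  mm <- toy_matrix(list(c("0/0", "1/1"), c("0/0", "1/1")), c("HS3", "d1"),
                   pos = c(200, 100))
  tr <- call_vs_parent(mm, "HS3")
  expect_error(merge_segments(tr), "not sorted")
})

test_that("flagged B-genome markers support segments through their own calls", {
  trad <- paste0("T", 1:3)
  samples <- c("HS3", trad, "d1")
  rows <- list(c(NA, NA, NA, NA, "1/1"),
               c(NA, NA, NA, NA, "1/1"),
               c(NA, NA, NA, NA, NA))
  mm <- toy_matrix(rows, samples, chrom = "B04", source = "nigra_B",
                   pos = c(3563715, 3650000, 3723750))
  flagged <- flag_b_genome_markers(mm, trad)
  expect_setequal(flagged, c("m01", "m02", "m03"))
  tr <- call_vs_parent(mm, "HS3")
  seg <- merge_segments(tr, b_flagged = flagged)
  seg <- seg[seg$sample == "d1", ]
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$n_markers, 2L)  # third marker not called in d1
  expect_equal(seg$start, 3563715)
  expect_equal(seg$end, 3650000)
})

test_that("planted B segments are recovered to within one marker interval", {
  sim <- simulate_dh_panel(n_lines = 30, genome = brassica_genome(200, 6),
                           b_line_frac = 0.4, missing_rate = 0, seed = 13)
  b_truth <- attr(sim, "b_truth")
  trad <- grep("^Tnap", colnames(sim$geno), value = TRUE)
  flagged <- flag_b_genome_markers(sim, trad)
  tr <- call_vs_parent(sim, "HS3")
  segs <- merge_segments(tr, b_flagged = flagged)
  segs <- segs[substr(segs$chrom, 1, 1) == "B", ]
  for (i in seq_len(nrow(b_truth))) {
    got <- segs[segs$sample == b_truth$sample[i] &
                  segs$chrom == b_truth$chrom[i], ]
    expect_identical(nrow(got), 1L)
    expect_equal(got$start, b_truth$start[i])
    expect_equal(got$end, b_truth$end[i])
  }
})
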