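#' Genome model for a Brassica A/B/C complement
#'
#' A `genome_model` records the chromosome complement and the marker loci the
#' simulator and downstream analyses operate on. The diploidized model carries
#' the 10 A-genome chromosomes (A01-A10) and 9 C-genome chromosomes (C01-C09)
#' of *B. napus*; B-genome material (B01-B08, from *B. carinata*) is tracked as
#' hemizygous presence/absence segments rather than paired homologues.
#'
#' @param chromosomes data.frame with columns `chrom`, `genome` (one of
#'   "A","B","C"), `length_bp`, `map_length_m` (map length in Morgans).
#' @param markers data.frame with columns `marker`, `chrom`, `pos` (1-based
#'   bp); positions must be strictly increasing within a chromosome.
#'
#' @return An object of class `genome_model` with elements `chromosomes` and
#'   `markers` (markers gain a `genome` column).
#' @seealso [brassica_genome()] for the default desk-scale model.
#' @export
genome_model <- function(chromosomes, markers) {
  req <- c("chrom", "genome", "length_bp", "map_length_m")
  assert_that(is.data.frame(chromosomes) && all(req %in% names(chromosomes)),
              "`chromosomes` needs columns chrom, genome, length_bp, map_length_m")
  assert_that(all(chromosomes$genome %in% c("A", "B", "C")),
              "chromosome genome labels must be A, B or C")
  assert_that(!anyDuplicated(chromosomes$chrom),
              "duplicated chromosome names")
  assert_that(all(chromosomes$length_bp > 0) && all(chromosomes$map_length_m > 0),
              "chromosome physical and map lengths must be positive")
  for (g in c("A", "B", "C")) {
    n <- sum(chromosomes$genome == g)
    expected <- c(A = 10L, C = 9L, B = 8L)[[g]]
    if (n > 0L && n != expected) {
      abort(sprintf("genome %s must have %d chromosomes when present (got %d)",
                    g, expected, n))
    }
  }
  assert_that(is.data.frame(markers) &&
                all(c("marker", "chrom", "pos") %in% names(markers)),
              "`markers` needs columns marker, chrom, pos")
  assert_that(all(markers$chrom %in% chromosomes$chrom),
              "marker on unknown chromosome")
  assert_that(!anyDuplicated(markers$marker), "duplicated marker ids")
  markers <- markers[order(match(markers$chrom, chromosomes$chrom), markers$pos), ,
                     drop = FALSE]
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    assert_that(all(diff(p) > 0),
                sprintf("marker positions on %s not strictly increasing", ch))
    assert_that(all(p >= 1) &&
                  all(p <= chromosomes$length_bp[chromosomes$chrom == ch]),
                sprintf("marker position off chromosome %s", ch))
  }
  markers$genome <- chromosomes$genome[match(markers$chrom, chromosomes$chrom)]
  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_model")
}

#' Default desk-scale Brassica genome
#'
#' Builds a reduced model of the *B. napus* AC genome plus the eight
#' *B. nigra*-type B chromosomes, with evenly spaced marker loci. Physical
#' sizes are scaled-down but keep the field's proportions (C chromosomes
#' larger than A); map lengths of roughly one Morgan per chromosome match
#' typical Brassica linkage maps.
#'
#' @param n_markers total number of marker loci to distribute over the A and C
#'   chromosomes (proportionally to physical length).
#' @param n_b_markers marker loci per B chromosome.
#' @param include_b include the B-genome chromosomes (default TRUE).
#' @return a [genome_model()].
#' @export
brassica_genome <- function(n_markers = 500, n_b_markers = 6, include_b = TRUE) {
  assert_that(n_markers >= 19, "need at least one marker per AC chromosome")
  a_len <- round(seq(24e6, 34e6, length.out = 10))
  c_len <- round(seq(36e6, 60e6, length.out = 9))
  chroms <- data.frame(
    chrom = c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9)),
    genome = c(rep("A", 10), rep("C", 9)),
    length_bp = c(a_len, c_len),
    map_length_m = c(rep(1.0, 10), rep(1.2, 9)),
    stringsAsFactors = FALSE
  )
  if (include_b) {
    chroms <- rbind(chroms, data.frame(
      chrom = sprintf("B%02d", 1:8), genome = "B",
      length_bp = round(seq(40e6, 55e6, length.out = 8)),
      map_length_m = 1.0, stringsAsFactors = FALSE
    ))
  }
  ac <- chroms[chroms$genome != "B", ]
  n_per <- pmax(1L, round(n_markers * ac$length_bp / sum(ac$length_bp)))
  mk <- do.call(rbind, lapply(seq_len(nrow(ac)), function(i) {
    k <- n_per[i]
    pos <- round(seq(1, ac$length_bp[i], length.out = k + 2L))[2:(k + 1L)]
    data.frame(chrom = ac$chrom[i], pos = pos, stringsAsFactors = FALSE)
  }))
  if (include_b && n_b_markers > 0) {
    bc <- chroms[chroms$genome == "B", ]
    mkb <- do.call(rbind, lapply(seq_len(nrow(bc)), function(i) {
      pos <- round(seq(1, bc$length_bp[i],
                       length.out = n_b_markers + 2L))[2:(n_b_markers + 1L)]
      data.frame(chrom = bc$chrom[i], pos = pos, stringsAsFactors = FALSE)
    }))
    mk <- rbind(mk, mkb)
  }
  mk$marker <- sprintf("M_%s_%04d", mk$chrom, stats::ave(mk$pos, mk$chrom,
                                                         FUN = seq_along))
  genome_model(chroms, mk[, c("marker", "chrom", "pos")])
}

#' @export
print.genome_model <- function(x, ...) {
  tab <- table(x$chromosomes$genome)
  cat("genome_model:", nrow(x$chromosomes), "chromosomes (",
      paste(names(tab), tab, sep = ":", collapse = ", "), "),",
      nrow(x$markers), "marker loci\n")
  invisible(x)
}

# markers of one genome partition
markers_of <- function(genome, which_genome) {
  genome$markers[genome$markers$genome %in% which_genome, , drop = FALSE]
}
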