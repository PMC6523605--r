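#' Simulate a doubled-haploid panel with planted exotic ancestry
#'
#' Generates a GBS-style biallelic [marker_matrix()] emulating the
#' introgression-analysis design: the recurrent parent (default "HS3"), a
#' panel of traditional *B. napus* lines, and fully homozygous DH lines with
#' known mosaic exotic ancestry. At every A/C marker the exotic ancestry
#' carries the alternative allele, so markers are fully informative; the
#' realized (planted) exotic fraction of each line is returned as ground
#' truth. A subset of DH lines carries hemizygous B-genome segments: their B
#' markers amplify inside the segment and are missing outside, while the
#' parent and all traditional lines are missing at every B marker.
#'
#' @param n_lines number of DH lines.
#' @param genome a [genome_model()] (positions of the simulated markers).
#' @param exotic_range range the per-line target exotic fraction is drawn
#'   from, default the 0.30-0.65 band typical of reconstituted material.
#' @param mean_block mean ancestry block length in markers.
#' @param n_traditional traditional *B. napus* reference lines (default 11).
#' @param trad_poly_rate per-marker probability a traditional line differs
#'   from the parent (residual intraspecific polymorphism).
#' @param b_line_frac fraction of DH lines carrying a B-genome segment.
#' @param missing_rate per-cell missing probability applied to every sample
#'   except the parent.
#' @param parent_id sample id of the recurrent parent.
#' @param seed integer seed.
#' @return a `marker_matrix` with attributes `truth` (data.frame sample,
#'   true_fraction over A/C markers) and `b_truth` (data.frame sample,
#'   chrom, start, end of planted B segments, marker-span coordinates).
#' @export
simulate_dh_panel <- function(n_lines = 40L,
                              genome = brassica_genome(300, 6),
                              exotic_range = c(0.30, 0.65),
                              mean_block = 8, n_traditional = 11L,
                              trad_poly_rate = 0.02, b_line_frac = 0.3,
                              missing_rate = 0, parent_id = "HS3", seed) {
  assert_that(n_lines >= 1, "`n_lines` must be at least 1")
  assert_that(length(exotic_range) == 2 && all(exotic_range >= 0) &&
                all(exotic_range <= 1) && exotic_range[1] <= exotic_range[2],
              "`exotic_range` must be an ordered pair in [0, 1]")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "`missing_rate` must be in [0, 1)")
  with_seed(seed, {
    mk <- genome$markers
    ac <- which(mk$genome != "B")
    bb <- which(mk$genome == "B")
    markers <- data.frame(
      marker = mk$marker,
      source = ifelse(mk$genome == "B", "nigra_B", "napus_AC"),
      genome = mk$genome, chrom = mk$chrom, pos = mk$pos,
      stringsAsFactors = FALSE)
    lines <- sprintf("DH_%03d", seq_len(n_lines))
    trads <- if (n_traditional > 0) sprintf("Tnap_%02d", seq_len(n_traditional))
             else character()
    samples <- c(parent_id, trads, lines)
    geno <- matrix(NA_character_, nrow(mk), length(samples),
                   dimnames = list(mk$marker, samples))
    geno[ac, parent_id] <- "0/0"
    for (s in trads) {
      g <- rep("0/0", length(ac))
      g[stats::runif(length(ac)) < trad_poly_rate] <- "1/1"
      geno[ac, s] <- g
    }
    # mosaic exotic ancestry: alternating blocks with geometric lengths,
    # each block exotic with the line's target probability
    target <- stats::runif(n_lines, exotic_range[1], exotic_range[2])
    true_frac <- numeric(n_lines)
    chrom_of_ac <- mk$chrom[ac]
    for (j in seq_len(n_lines)) {
      state <- logical(length(ac))
      for (ch in unique(chrom_of_ac)) {
        sel <- which(chrom_of_ac == ch)
        i <- 1L
        while (i <= length(sel)) {
          len <- 1L + stats::rgeom(1, 1 / mean_block)
          ex <- stats::runif(1) < target[j]
          state[sel[i:min(i + len - 1L, length(sel))]] <- ex
          i <- i + len
        }
      }
      true_frac[j] <- mean(state)
      geno[ac, lines[j]] <- ifelse(state, "1/1", "0/0")
    }
    # planted hemizygous B segments in a subset of lines
    b_truth <- list()
    if (length(bb) && b_line_frac > 0) {
      carriers <- lines[stats::runif(n_lines) < b_line_frac]
      b_chroms <- unique(mk$chrom[bb])
      for (s in carriers) {
        ch <- sample(b_chroms, 1L)
        sel <- bb[mk$chrom[bb] == ch]
        bounds <- sort(sample(seq_along(sel), 2L, replace = TRUE))
        seg <- sel[bounds[1]:bounds[2]]
        geno[seg, s] <- "1/1"
        b_truth[[length(b_truth) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = mk$pos[seg[1]],
          end = mk$pos[seg[length(seg)]], stringsAsFactors = FALSE)
      }
    }
    if (missing_rate > 0) {
      maskable <- setdiff(samples, parent_id)
      mask <- matrix(stats::runif(nrow(geno) * length(maskable)) < missing_rate,
                     nrow(geno), length(maskable))
      geno[, maskable][mask] <- NA_character_
    }
    mm <- marker_matrix(markers, geno)
    attr(mm, "truth") <- data.frame(sample = lines, true_fraction = true_frac,
                                    stringsAsFactors = FALSE)
    attr(mm, "b_truth") <- do.call(rbind, b_truth) %||% data.frame(
      sample = character(), chrom = character(), start = integer(),
      end = integer(), stringsAsFactors = FALSE)
    mm
  })
}
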