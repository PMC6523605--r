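# GBS-stage containers and operations: biallelic-style marker matrices from
# one or more reference genomes, per-line difference calls against the
# recurrent parent (HS3 in the study design), and marker-supported segment
# merging.

#' SNP/Indel marker matrix
#'
#' Markers-by-samples genotype container for the GBS-stage analyses. Each
#' cell is an unordered genotype string ("a/b", alleles sorted) or NA for
#' missing. Marker metadata carry the source reference each marker was
#' discovered against.
#'
#' @param markers data.frame with columns `marker`, `source` (e.g.
#'   "napus_AC", "rapa_A", "oleracea_C", "nigra_B"), `genome` ("A","B","C"),
#'   `chrom`, `pos` (1-based).
#' @param geno character matrix, rows = markers (rownames = marker ids),
#'   columns = samples.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(markers, geno) {
  req <- c("marker", "source", "genome", "chrom", "pos")
  assert_that(is.data.frame(markers) && all(req %in% names(markers)),
              "`markers` needs columns marker, source, genome, chrom, pos")
  assert_that(!anyDuplicated(markers$marker), "duplicated marker ids")
  assert_that(is.matrix(geno) && is.character(geno),
              "`geno` must be a character matrix")
  assert_that(identical(rownames(geno), markers$marker),
              "geno rownames must equal markers$marker")
  assert_that(!is.null(colnames(geno)) && !anyDuplicated(colnames(geno)),
              "geno needs unique sample column names")
  structure(list(markers = markers, geno = normalize_geno(geno)),
            class = "marker_matrix")
}

# canonical unordered genotype string: alleles sorted within the call
normalize_geno <- function(geno) {
  u <- unique(as.vector(geno))
  u <- u[!is.na(u)]
  map <- vapply(u, function(g) {
    paste(sort(strsplit(g, "/", fixed = TRUE)[[1]]), collapse = "/")
  }, character(1))
  out <- geno
  out[] <- map[match(as.vector(geno), u)]
  out
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$markers), "markers x", ncol(x$geno),
      "samples;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  src <- table(x$markers$source)
  cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Harmonize marker sets discovered against multiple reference genomes
#'
#' Merges markers discovered against alternative reference genomes into the
#' set discovered against the primary (*B. napus*) reference, following a
#' precomputed cross-reference match table. Matched alternative markers are
#' collapsed onto their primary marker (primary coordinates canonical);
#' unmatched ones are kept as additional species-specific markers with their
#' own coordinates; a marker matched to more than one primary marker is
#' ambiguous and dropped with a message.
#'
#' @param napus_set marker data.frame (columns as in [marker_matrix()])
#'   discovered against the primary reference.
#' @param alt_sets one marker data.frame, or a list of them, from
#'   alternative references.
#' @param match_table data.frame with columns `alt_marker`, `napus_marker`
#'   (NA for no hit); alt markers absent from the table count as no-hit.
#' @return data.frame of the unified set with extra columns `status`
#'   ("primary", "matched", "additional_specific") and `matched_to`;
#'   attribute `counts` tallies the classes (including `ambiguous`).
#' @export
harmonize_marker_sets <- function(napus_set, alt_sets, match_table) {
  if (is.data.frame(alt_sets)) alt_sets <- list(alt_sets)
  alt <- do.call(rbind, alt_sets)
  assert_that(all(c("alt_marker", "napus_marker") %in% names(match_table)),
              "`match_table` needs columns alt_marker and napus_marker")
  hits <- match_table[!is.na(match_table$napus_marker), , drop = FALSE]
  bad <- !hits$napus_marker %in% napus_set$marker
  assert_that(!any(bad), "match table references unknown primary markers")
  n_hits <- table(hits$alt_marker)
  ambiguous <- names(n_hits)[n_hits > 1L]
  if (length(ambiguous)) {
    message(length(ambiguous),
            " alt marker(s) matched to multiple primary markers; excluded")
  }
  matched_ids <- setdiff(hits$alt_marker, ambiguous)
  unmatched <- alt[!alt$marker %in% c(matched_ids, ambiguous), , drop = FALSE]
  primary <- napus_set
  primary$status <- "primary"
  primary$matched_to <- NA_character_
  m1 <- match(matched_ids, hits$alt_marker)
  matched_to <- stats::setNames(hits$napus_marker[m1], matched_ids)
  # matched alt markers collapse onto the primary marker: flag the primary
  primary$status[primary$marker %in% matched_to] <- "matched"
  if (nrow(unmatched)) {
    unmatched$status <- "additional_specific"
    unmatched$matched_to <- NA_character_
  }
  out <- rbind(primary, unmatched)
  rownames(out) <- NULL
  attr(out, "counts") <- c(primary = nrow(napus_set),
                           matched = length(matched_ids),
                           additional_specific = nrow(unmatched),
                           ambiguous = length(ambiguous))
  out
}

#' Flag B-genome markers specific to *B. carinata* introgression
#'
#' A B-genome marker is recorded as a *B. carinata*-specific B-genomic
#' marker when every sample of the traditional *B. napus* reference panel is
#' missing at it (traditional lines carry no B-genome template, so the
#' marker can only amplify from introgressed material).
#'
#' @param mm a [marker_matrix()].
#' @param traditional_panel character vector of traditional *B. napus*
#'   sample ids present in `mm`.
#' @return character vector of flagged marker ids.
#' @export
flag_b_genome_markers <- function(mm, traditional_panel) {
  assert_that(inherits(mm, "marker_matrix"), "`mm` must be a marker_matrix")
  assert_that(length(traditional_panel) >= 1,
              "`traditional_panel` must be nonempty")
  missing_ids <- setdiff(traditional_panel, colnames(mm$geno))
  assert_that(length(missing_ids) == 0,
              paste("traditional panel samples absent from matrix:",
                    paste(utils::head(missing_ids, 5), collapse = ", ")))
  b_rows <- which(mm$markers$genome == "B")
  if (!length(b_rows)) return(character())
  sub <- mm$geno[b_rows, traditional_panel, drop = FALSE]
  all_missing <- rowSums(!is.na(sub)) == 0L
  mm$markers$marker[b_rows[all_missing]]
}

#' Filter markers by missing rate
#'
#' Retains markers whose missing fraction across samples is strictly less
#' than `max_missing_rate` (a marker missing in exactly half the samples is
#' removed at the default 0.5).
#'
#' @param mm a [marker_matrix()].
#' @param max_missing_rate threshold in (0, 1].
#' @param parent optional recurrent-parent sample id; an error is raised if
#'   the parent is missing at every marker (comparisons undefined).
#' @return the filtered `marker_matrix`.
#' @export
filter_missing <- function(mm, max_missing_rate = 0.5, parent = NULL) {
  assert_that(inherits(mm, "marker_matrix"), "`mm` must be a marker_matrix")
  assert_that(max_missing_rate > 0 && max_missing_rate <= 1,
              "`max_missing_rate` must be in (0, 1]")
  if (!is.null(parent)) {
    assert_that(parent %in% colnames(mm$geno), "unknown parent sample")
    if (all(is.na(mm$geno[, parent]))) {
      abort("parent sample is missing at every marker; comparisons undefined")
    }
  }
  miss <- rowMeans(is.na(mm$geno))
  keep <- miss < max_missing_rate
  marker_matrix(mm$markers[keep, , drop = FALSE],
                mm$geno[keep, , drop = FALSE])
}

#' Call per-line differences from the recurrent parent
#'
#' For every line and marker, compares the unordered allele set with the
#' recurrent parent's: `differs` records introgressed allelic variation,
#' `same_as_parent` identity, and `missing` covers markers where either call
#' is absent (markers at which the parent is missing are missing for every
#' line). Per-line introgression fraction = differs / (differs + same). The
#' population union fraction counts a marker once if at least one line
#' differs there, divided by the markers informative in at least one line.
#'
#' @param mm a [marker_matrix()].
#' @param parent_id recurrent-parent sample id (the parent is excluded from
#'   the line set).
#' @return object of class `introgression_track`: list with `states`
#'   (markers x lines character matrix), `per_line` (data.frame sample,
#'   n_same, n_differ, fraction), `union_fraction`, `markers`, `parent`.
#' @export
call_vs_parent <- function(mm, parent_id) {
  assert_that(inherits(mm, "marker_matrix"), "`mm` must be a marker_matrix")
  assert_that(parent_id %in% colnames(mm$geno),
              sprintf("parent '%s' not in matrix", parent_id))
  lines <- setdiff(colnames(mm$geno), parent_id)
  parent <- mm$geno[, parent_id]
  states <- matrix("missing", nrow(mm$geno), length(lines),
                   dimnames = list(rownames(mm$geno), lines))
  for (s in lines) {
    g <- mm$geno[, s]
    ok <- !is.na(g) & !is.na(parent)
    states[ok, s] <- ifelse(g[ok] == parent[ok], "same_as_parent", "differs")
  }
  n_same <- colSums(states == "same_as_parent")
  n_diff <- colSums(states == "differs")
  per_line <- data.frame(sample = lines, n_same = n_same, n_differ = n_diff,
                         fraction = ifelse(n_same + n_diff > 0,
                                           n_diff / (n_same + n_diff), NA_real_),
                         row.names = NULL, stringsAsFactors = FALSE)
  informative <- rowSums(states != "missing") > 0
  any_diff <- rowSums(states == "differs") > 0
  union_fraction <- if (any(informative)) {
    sum(any_diff) / sum(informative)
  } else NA_real_
  structure(list(states = states, per_line = per_line,
                 union_fraction = union_fraction, markers = mm$markers,
                 called = !is.na(mm$geno[, lines, drop = FALSE]),
                 parent = parent_id),
            class = "introgression_track")
}

#' @export
print.introgression_track <- function(x, ...) {
  cat("introgression_track vs parent", x$parent, ":",
      ncol(x$states), "lines x", nrow(x$states), "markers\n")
  cat(sprintf("  per-line differing fraction: mean %.4f (range %.4f-%.4f); union %.4f\n",
              mean(x$per_line$fraction, na.rm = TRUE),
              min(x$per_line$fraction, na.rm = TRUE),
              max(x$per_line$fraction, na.rm = TRUE), x$union_fraction))
  invisible(x)
}

#' Merge difference calls into marker-supported segments
#'
#' Per line and chromosome, consecutive supporting markers ("differs" calls,
#' plus any non-missing call at a marker flagged B-genome-specific) are
#' merged into segments, tolerating up to `max_gap_markers` intervening
#' non-supporting markers. Segment coordinates span the first to the last
#' supporting marker (1-based inclusive) and `length_bp = end - start`, the
#' distance between the outermost supporting markers.
#'
#' @param track an `introgression_track` from [call_vs_parent()].
#' @param max_gap_markers maximum run of non-supporting markers bridged
#'   inside one segment (default 0).
#' @param min_markers minimum supporting markers per reported segment.
#' @param b_flagged optional marker ids from [flag_b_genome_markers()];
#'   non-missing calls there count as supporting.
#' @return data.frame: sample, chrom, start, end, n_markers, length_bp,
#'   length_kb, frac_differ (supporting / spanned markers).
#' @export
merge_segments <- function(track, max_gap_markers = 0L, min_markers = 1L,
                           b_flagged = character()) {
  assert_that(inherits(track, "introgression_track"),
              "`track` must come from call_vs_parent()")
  assert_that(max_gap_markers >= 0 && min_markers >= 1,
              "invalid gap/min-marker parameters")
  mk <- track$markers
  for (ch in unique(mk$chrom)) {
    p <- mk$pos[mk$chrom == ch]
    if (is.unsorted(p, strictly = FALSE)) {
      abort(sprintf("markers on %s are not sorted by position", ch))
    }
  }
  out <- list()
  for (s in colnames(track$states)) {
    st <- track$states[, s]
    supp <- st == "differs"
    # flagged B markers are missing in the parent (state "missing" for every
    # line); the line's own amplified call there is the supporting evidence
    if (length(b_flagged)) {
      bsel <- mk$marker %in% b_flagged
      supp[bsel] <- supp[bsel] | track$called[bsel, s]
    }
    for (ch in unique(mk$chrom)) {
      sel <- which(mk$chrom == ch)
      v <- supp[sel]
      if (!any(v)) next
      pos <- mk$pos[sel]
      hits <- which(v)
      # split supporting markers where more than max_gap_markers
      # non-supporting markers intervene
      grp <- cumsum(c(1L, diff(hits) > max_gap_markers + 1L))
      for (g in unique(grp)) {
        h <- hits[grp == g]
        if (length(h) < min_markers) next
        span <- h[1]:h[length(h)]
        out[[length(out) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = pos[h[1]], end = pos[h[length(h)]],
          n_markers = length(h),
          length_bp = pos[h[length(h)]] - pos[h[1]],
          frac_differ = length(h) / length(span),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out) %||% data.frame(
    sample = character(), chrom = character(), start = integer(),
    end = integer(), n_markers = integer(), length_bp = numeric(),
    frac_differ = numeric(), stringsAsFactors = FALSE)
  res$length_kb <- res$length_bp / 1000
  rownames(res) <- NULL
  res
}
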