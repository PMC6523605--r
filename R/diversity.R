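# Population diversity statistics over multi-allelic marker data: allele
# frequencies, gene diversity (expected heterozygosity), observed
# heterozygosity, and Nei's genetic distance between frequency profiles.

#' Per-locus allele frequencies
#'
#' Counts allele copies per locus over a sample subset, excluding missing
#' calls from the denominators. Hemizygous (B-genome style) calls contribute
#' two identical copies like any homozygote.
#'
#' @param g a `genotypes` object.
#' @param subset sample ids to tally (default all).
#' @return named list over loci; each element a named numeric frequency
#'   vector summing to 1, or NULL where the subset is entirely missing
#'   (undefined locus).
#' @export
allele_frequencies <- function(g, subset = NULL) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  subset <- subset %||% g$samples$sample
  assert_that(length(subset) >= 1, "`subset` must be nonempty")
  unknown <- setdiff(subset, g$samples$sample)
  assert_that(length(unknown) == 0,
              paste("unknown samples:", paste(utils::head(unknown, 3),
                                              collapse = ", ")))
  calls <- g$calls[g$calls$sample %in% subset, , drop = FALSE]
  loci <- unique(g$calls$locus)
  out <- stats::setNames(vector("list", length(loci)), loci)
  obs <- calls[!is.na(calls$allele1), , drop = FALSE]
  copies <- data.frame(locus = c(obs$locus, obs$locus),
                       allele = c(obs$allele1, obs$allele2),
                       stringsAsFactors = FALSE)
  for (loc in unique(copies$locus)) {
    tab <- table(copies$allele[copies$locus == loc])
    out[[loc]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  out
}

#' Gene diversity (expected heterozygosity)
#'
#' Per-locus gene diversity D = 1 - sum(p_i^2) over the allele frequencies,
#' the plain frequency-plug-in estimator; the small-sample correction
#' 2n/(2n-1) * D is available via `n`.
#'
#' @param freqs a single frequency vector, or a list of per-locus vectors as
#'   returned by [allele_frequencies()].
#' @param n optional number of diploid samples for the unbiased correction.
#' @return for a vector input, a single value; for a list, a list with
#'   `per_locus` (named numeric, NA for undefined loci) and `mean`
#'   (unweighted over defined loci).
#' @export
gene_diversity <- function(freqs, n = NULL) {
  one <- function(p) {
    if (is.null(p) || !length(p)) return(NA_real_)
    assert_that(all(p >= 0) && abs(sum(p) - 1) < 1e-6,
                "frequencies must be nonnegative and sum to 1")
    d <- 1 - sum(p^2)
    if (!is.null(n)) d <- d * 2 * n / (2 * n - 1)
    d
  }
  if (is.numeric(freqs)) return(one(freqs))
  per <- vapply(freqs, one, numeric(1))
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Mean number of alleles per locus
#'
#' @param freqs list of per-locus frequency vectors.
#' @return list with `per_locus` counts and `mean` over defined loci.
#' @export
alleles_per_locus <- function(freqs) {
  per <- vapply(freqs, function(p) if (is.null(p)) NA_real_ else length(p),
                numeric(1))
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Observed heterozygosity
#'
#' Per locus, the fraction of non-missing samples whose two allele calls
#' differ, and the unweighted mean over defined loci.
#'
#' @inheritParams allele_frequencies
#' @return list with `per_locus` (named numeric) and `mean`.
#' @export
observed_heterozygosity <- function(g, subset = NULL) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  subset <- subset %||% g$samples$sample
  calls <- g$calls[g$calls$sample %in% subset & !is.na(g$calls$allele1), ,
                   drop = FALSE]
  loci <- unique(g$calls$locus)
  per <- stats::setNames(rep(NA_real_, length(loci)), loci)
  if (nrow(calls)) {
    het <- tapply(calls$allele1 != calls$allele2, calls$locus, mean)
    per[names(het)] <- as.numeric(het)
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Nei's genetic distance between two frequency profiles
#'
#' Standard (1972) normalized-identity distance
#' D = -ln( Jxy / sqrt(Jx * Jy) ) with Jxy, Jx, Jy summed over co-defined
#' loci; alternatively Nei et al.'s (1983) DA distance
#' 1 - mean_l sum_i sqrt(p_xi p_yi). Zero shared identity (infinite 1972
#' distance) is capped at `max_distance` with a warning.
#'
#' @param freqs_x,freqs_y per-locus frequency vectors ([allele_frequencies()]
#'   output), or single vectors for a one-locus comparison.
#' @param method "nei1972" (default) or "da".
#' @param max_distance cap for infinite distances.
#' @return a nonnegative distance.
#' @export
nei_distance <- function(freqs_x, freqs_y, method = c("nei1972", "da"),
                         max_distance = 10) {
  method <- match.arg(method)
  if (is.numeric(freqs_x)) freqs_x <- list(locus = freqs_x)
  if (is.numeric(freqs_y)) freqs_y <- list(locus = freqs_y)
  loci <- intersect(names(freqs_x), names(freqs_y))
  loci <- loci[vapply(loci, function(l) !is.null(freqs_x[[l]]) &&
                        !is.null(freqs_y[[l]]), logical(1))]
  assert_that(length(loci) >= 1, "no co-defined loci between the profiles")
  pair <- function(l) {
    px <- freqs_x[[l]]; py <- freqs_y[[l]]
    alleles <- union(names(px), names(py))
    x <- stats::setNames(rep(0, length(alleles)), alleles)
    y <- x
    x[names(px)] <- px; y[names(py)] <- py
    cbind(x, y)
  }
  if (method == "nei1972") {
    jxy <- jx <- jy <- 0
    for (l in loci) {
      m <- pair(l)
      jxy <- jxy + sum(m[, 1] * m[, 2])
      jx <- jx + sum(m[, 1]^2)
      jy <- jy + sum(m[, 2]^2)
    }
    i_norm <- jxy / sqrt(jx * jy)
    if (i_norm <= exp(-max_distance)) {
      warning("zero (or near-zero) shared identity; distance capped at ",
              max_distance)
      return(max_distance)
    }
    -log(i_norm)
  } else {
    da <- vapply(loci, function(l) {
      m <- pair(l)
      1 - sum(sqrt(m[, 1] * m[, 2]))
    }, numeric(1))
    mean(da)
  }
}

#' Pairwise Nei distance matrix
#'
#' Computes all pairwise [nei_distance()]s between units, where a unit is
#' either a group of samples (frequencies estimated per group) or a single
#' accession treated as a population of one diploid individual (frequencies
#' in {0, 0.5, 1}), the convention used for accession-level clustering.
#'
#' @param g a `genotypes` object.
#' @param units named list of sample-id vectors; defaults to one unit per
#'   sample (accession-level).
#' @param max_distance cap used both for zero shared identity and for unit
#'   pairs without any co-defined locus (e.g. taxa whose genomes share no
#'   amplifying marker); such pairs are reported in a message.
#' @param ... passed to [nei_distance()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_distance_matrix <- function(g, units = NULL, max_distance = 10, ...) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  if (is.null(units)) {
    units <- stats::setNames(as.list(g$samples$sample), g$samples$sample)
  }
  freqs <- lapply(units, function(ids) allele_frequencies(g, ids))
  defined <- lapply(freqs, function(f) {
    names(f)[!vapply(f, is.null, logical(1))]
  })
  n <- length(units)
  d <- matrix(0, n, n, dimnames = list(names(units), names(units)))
  n_disjoint <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!length(intersect(defined[[i]], defined[[j]]))) {
        d[i, j] <- d[j, i] <- max_distance
        n_disjoint <- n_disjoint + 1L
        next
      }
      d[i, j] <- d[j, i] <- suppressWarnings(
        nei_distance(freqs[[i]], freqs[[j]], max_distance = max_distance, ...))
    }
  }
  if (n_disjoint > 0L) {
    message(n_disjoint,
            " unit pair(s) share no co-defined locus; distance capped at ",
            max_distance)
  }
  d
}

# capped pairwise distance: profiles without co-defined loci (taxa whose
# genomes share no amplifying marker) get the cap instead of an error
nei_or_cap <- function(fa, fb, max_distance = 10, ...) {
  da <- names(fa)[!vapply(fa, is.null, logical(1))]
  db <- names(fb)[!vapply(fb, is.null, logical(1))]
  if (!length(intersect(da, db))) return(max_distance)
  suppressWarnings(nei_distance(fa, fb, max_distance = max_distance, ...))
}

#' Table-1-style diversity summary per subpopulation
#'
#' For each group and genome partition (whole, A-genome loci, C-genome
#' loci), reports the mean number of alleles per locus, mean gene diversity,
#' mean observed heterozygosity, the within-group range of pairwise
#' accession-level Nei distances, and the range of cross distances to a
#' reference group. A/B-assigned loci count as A-genome loci.
#'
#' @param g a `genotypes` object with group labels in `samples$taxon`.
#' @param partition named character vector locus -> genome ("A","B","C");
#'   loci absent from it enter only the whole-genome partition.
#' @param reference_group group name the cross-distance range is computed
#'   against (NA where group == reference).
#' @param max_units cap on accessions per group used for the distance
#'   ranges (first `max_units` samples; keeps the pair count desk-scale).
#' @return data.frame: partition, group, n_samples, alleles_per_locus,
#'   gene_diversity, heterozygosity, dist_within_min/max,
#'   dist_cross_min/max.
#' @export
diversity_summary <- function(g, partition = NULL,
                              reference_group = "T_napus", max_units = 25L) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  groups <- split(g$samples$sample, g$samples$taxon)
  all_loci <- unique(g$calls$locus)
  parts <- list(whole = all_loci)
  if (!is.null(partition)) {
    pg <- partition[names(partition) %in% all_loci]
    pg[pg == "B"] <- "A"  # A/B loci are designated A-genome markers
    parts$A <- names(pg)[pg == "A"]
    parts$C <- names(pg)[pg == "C"]
  }
  restrict <- function(gg, loci) {
    new_genotypes(gg$calls[gg$calls$locus %in% loci, , drop = FALSE],
                  gg$samples)
  }
  rows <- list()
  for (pn in names(parts)) {
    if (!length(parts[[pn]])) next
    gp <- restrict(g, parts[[pn]])
    dmat_units <- lapply(groups, function(ids) utils::head(ids, max_units))
    for (gr in names(groups)) {
      ids <- groups[[gr]]
      fr <- allele_frequencies(gp, ids)
      apl <- alleles_per_locus(fr)$mean
      gd <- gene_diversity(fr)$mean
      het <- observed_heterozygosity(gp, ids)$mean
      u <- dmat_units[[gr]]
      dw <- if (length(u) >= 2) {
        dm <- nei_distance_matrix(subset_samples(gp, u))
        range(dm[upper.tri(dm)])
      } else c(NA_real_, NA_real_)
      dx <- c(NA_real_, NA_real_)
      if (!is.na(reference_group) && gr != reference_group &&
          reference_group %in% names(groups)) {
        ur <- dmat_units[[reference_group]]
        dcross <- vapply(u, function(a) {
          fa <- allele_frequencies(gp, a)
          vapply(ur, function(b) {
            nei_or_cap(fa, allele_frequencies(gp, b), 10)
          }, numeric(1))
        }, numeric(length(ur)))
        dx <- range(dcross)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        partition = pn, group = gr, n_samples = length(ids),
        alleles_per_locus = apl, gene_diversity = gd, heterozygosity = het,
        dist_within_min = dw[1], dist_within_max = dw[2],
        dist_cross_min = dx[1], dist_cross_max = dx[2],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
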