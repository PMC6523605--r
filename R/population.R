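# Population representation
#
# A diploidized population: two homologues per A/C chromosome, stored as
# marker-level matrices (individuals x AC markers) of allele symbols and of
# subgenome-origin labels (Ar/An on A chromosomes, Cc/Cn on C chromosomes).
# B-genome material from B. carinata is hemizygous: a logical presence matrix
# over B markers plus the allele symbol carried where present. Hemizygous
# segments have no pairing partner, so they do not recombine and each B
# chromosome's pattern transmits to half the gametes.

new_population <- function(hap_allele, hap_origin, b_pres, b_allele, dgms,
                           id, subpop, generation, genome, novel_rate) {
  structure(list(hap_allele = hap_allele, hap_origin = hap_origin,
                 b_pres = b_pres, b_allele = b_allele, dgms = dgms,
                 id = id, subpop = subpop, generation = generation,
                 genome = genome, novel_rate = novel_rate),
            class = "rs_population")
}

#' @export
print.rs_population <- function(x, ...) {
  cat("rs_population: ", length(x$id), " plants (generation ", x$generation,
      "), ", sum(x$dgms == "Msms"), " sterile / ", sum(x$dgms == "msms"),
      " fertile, ", ncol(x$hap_allele[[1]]), " AC marker loci\n", sep = "")
  invisible(x)
}

n_plants <- function(pop) length(pop$id)

# subset individuals, keeping all marker columns
pop_subset <- function(pop, idx) {
  new_population(
    lapply(pop$hap_allele, function(m) m[idx, , drop = FALSE]),
    lapply(pop$hap_origin, function(m) m[idx, , drop = FALSE]),
    pop$b_pres[idx, , drop = FALSE], pop$b_allele[idx, , drop = FALSE],
    pop$dgms[idx], pop$id[idx], pop$subpop[idx], pop$generation,
    pop$genome, pop$novel_rate)
}

origin_labels_for <- function(genome_letter, exotic) {
  if (genome_letter == "A") ifelse(exotic, "Ar", "An") else ifelse(exotic, "Cc", "Cn")
}

origin_taxon <- function(origin) {
  c(Ar = "B_rapa", An = "T_napus", Cc = "B_carinata", Cn = "T_napus")[origin]
}

# chromosome/marker index cache used by founder construction and meiosis
genome_index <- function(genome) {
  ac <- markers_of(genome, c("A", "C"))
  b <- markers_of(genome, "B")
  ac_chroms <- unique(ac$chrom)
  list(
    ac = ac, b = b, ac_chroms = ac_chroms,
    ac_cols = lapply(ac_chroms, function(ch) which(ac$chrom == ch)),
    ac_pos = lapply(ac_chroms, function(ch) ac$pos[ac$chrom == ch]),
    chrom_info = genome$chromosomes,
    b_chroms = unique(b$chrom),
    b_cols = lapply(unique(b$chrom), function(ch) which(b$chrom == ch))
  )
}

# --- founder genome construction -------------------------------------------

# One founder haplotype set: per A/C chromosome, a block mosaic with exotic
# origin probability p_a (A chromosomes -> Ar) / p_c (C chromosomes -> Cc).
# Blocks break at ~Poisson(mean_blocks) uniform positions, emulating the
# interspecific pedigree mosaic of the inbred founder lines.
draw_founder_haplotype <- function(idx, lookup, p_a, p_c, mean_blocks = 2) {
  m <- nrow(idx$ac)
  origin <- character(m)
  allele <- character(m)
  for (k in seq_along(idx$ac_chroms)) {
    ch <- idx$ac_chroms[k]
    cols <- idx$ac_cols[[k]]
    pos <- idx$ac_pos[[k]]
    g <- substr(ch, 1, 1)
    p_ex <- if (g == "A") p_a else p_c
    len <- idx$chrom_info$length_bp[idx$chrom_info$chrom == ch]
    nb <- stats::rpois(1, mean_blocks)
    breaks <- sort(stats::runif(nb, 0, len))
    block <- findInterval(pos, breaks) + 1L
    exotic_block <- stats::runif(nb + 1L) < p_ex
    origin[cols] <- origin_labels_for(g, exotic_block[block])
  }
  for (j in seq_len(m)) {
    fv <- get(paste(origin_taxon(origin[j]), idx$ac$marker[j], sep = "|"),
              envir = lookup)
    allele[j] <- if (length(fv) == 1L) names(fv) else
      sample(names(fv), 1L, prob = fv)
  }
  list(origin = origin, allele = allele)
}

# Hemizygous B-genome content: each B chromosome present with prob b_rate; a
# present chromosome carries a random contiguous marker interval.
draw_founder_b <- function(idx, lookup, b_rate) {
  mB <- nrow(idx$b)
  pres <- rep(FALSE, mB)
  allele <- rep(NA_character_, mB)
  for (k in seq_along(idx$b_chroms)) {
    if (stats::runif(1) >= b_rate) next
    cols <- idx$b_cols[[k]]
    bounds <- sort(sample(seq_along(cols), 2L, replace = TRUE))
    seg <- cols[bounds[1]:bounds[2]]
    pres[seg] <- TRUE
    for (j in seg) {
      fv <- get(paste("B_carinata", idx$b$marker[j], sep = "|"), envir = lookup)
      allele[j] <- if (length(fv) == 1L) names(fv) else
        sample(names(fv), 1L, prob = fv)
    }
  }
  list(pres = pres, allele = allele)
}

# Base population: DGMS seed-parent lines (Msms) in a new-type background
# plus fertile inbred lines (msms) of the Poly-Ar and Poly-Cc subpopulations.
make_base_population <- function(panel, genome, scheme) {
  idx <- genome_index(genome)
  lookup <- panel_lookup(panel)
  specs <- rbind(
    data.frame(subpop = "DGMS", n = scheme$n_dgms,
               p_a = 0.5, p_c = 0.5, dgms = "Msms"),
    data.frame(subpop = "Poly_Ar", n = scheme$n_founders,
               p_a = 0.75, p_c = 0.40, dgms = "msms"),
    data.frame(subpop = "Poly_Cc", n = scheme$n_founders,
               p_a = 0.40, p_c = 0.75, dgms = "msms")
  )
  n_tot <- sum(specs$n)
  mAC <- nrow(idx$ac); mB <- nrow(idx$b)
  hap_allele <- list(matrix(NA_character_, n_tot, mAC,
                            dimnames = list(NULL, idx$ac$marker)),
                     matrix(NA_character_, n_tot, mAC,
                            dimnames = list(NULL, idx$ac$marker)))
  hap_origin <- list(matrix(NA_character_, n_tot, mAC),
                     matrix(NA_character_, n_tot, mAC))
  b_pres <- matrix(FALSE, n_tot, mB,
                   dimnames = list(NULL, if (mB) idx$b$marker))
  b_allele <- matrix(NA_character_, n_tot, mB,
                     dimnames = list(NULL, if (mB) idx$b$marker))
  dgms <- character(n_tot); subpop <- character(n_tot)
  r <- 0L
  for (s in seq_len(nrow(specs))) {
    for (i in seq_len(specs$n[s])) {
      r <- r + 1L
      for (h in 1:2) {
        hp <- draw_founder_haplotype(idx, lookup, specs$p_a[s], specs$p_c[s])
        hap_allele[[h]][r, ] <- hp$allele
        hap_origin[[h]][r, ] <- hp$origin
      }
      if (mB) {
        bb <- draw_founder_b(idx, lookup, scheme$b_seg_rate)
        b_pres[r, ] <- bb$pres
        b_allele[r, ] <- bb$allele
      }
      dgms[r] <- specs$dgms[s]
      subpop[r] <- specs$subpop[s]
    }
  }
  new_population(hap_allele, hap_origin, b_pres, b_allele, dgms,
                 id = sprintf("F0_%04d", seq_len(n_tot)), subpop = subpop,
                 generation = 0L, genome = genome,
                 novel_rate = panel$novel_rate)
}

# --- meiosis ----------------------------------------------------------------

# Gamete from individual i: per A/C chromosome, crossover count ~
# Poisson(map length in Morgans), crossover positions uniform, no
# interference; B chromosomes transmit whole (hemizygous, unpaired) with
# probability 1/2; novel alleles arise per locus at rate novel_rate.
make_gamete <- function(pop, i, idx) {
  mAC <- ncol(pop$hap_allele[[1]])
  allele <- character(mAC); origin <- character(mAC)
  for (k in seq_along(idx$ac_chroms)) {
    cols <- idx$ac_cols[[k]]
    pos <- idx$ac_pos[[k]]
    ch <- idx$ac_chroms[k]
    map_m <- idx$chrom_info$map_length_m[idx$chrom_info$chrom == ch]
    len <- idx$chrom_info$length_bp[idx$chrom_info$chrom == ch]
    nco <- stats::rpois(1, map_m)
    start_hap <- sample.int(2L, 1L)
    if (nco == 0L) {
      use <- rep(start_hap, length(cols))
    } else {
      breaks <- sort(stats::runif(nco, 0, len))
      use <- (start_hap - 1L + findInterval(pos, breaks)) %% 2L + 1L
    }
    for (h in 1:2) {
      sel <- cols[use == h]
      if (length(sel)) {
        allele[sel] <- pop$hap_allele[[h]][i, sel]
        origin[sel] <- pop$hap_origin[[h]][i, sel]
      }
    }
  }
  if (pop$novel_rate > 0) {
    mut <- which(stats::runif(mAC) < pop$novel_rate)
    if (length(mut)) {
      allele[mut] <- sprintf("%s.nov%d", colnames(pop$hap_allele[[1]])[mut],
                             sample.int(.Machine$integer.max, length(mut)))
    }
  }
  mB <- ncol(pop$b_pres)
  b_pres <- rep(FALSE, mB); b_allele <- rep(NA_character_, mB)
  if (mB) {
    for (k in seq_along(idx$b_chroms)) {
      if (stats::runif(1) < 0.5) {
        cols <- idx$b_cols[[k]]
        b_pres[cols] <- pop$b_pres[i, cols]
        b_allele[cols] <- pop$b_allele[i, cols]
      }
    }
  }
  dg <- if (pop$dgms[i] == "Msms") {
    if (stats::runif(1) < 0.5) "Ms" else "ms"
  } else "ms"
  list(allele = allele, origin = origin, b_pres = b_pres,
       b_allele = b_allele, dgms = dg)
}

#' Mendelian segregation at the dominant male-sterility locus
#'
#' Simulates progeny genotypes at the single dominant genic male sterility
#' (DGMS) locus. Sterile plants are heterozygous Msms and set no pollen, so
#' every mating is Msms (seed parent) x msms (pollen parent) and progeny
#' segregate 1:1 sterile (Msms) : fertile (msms).
#'
#' @param n number of progeny.
#' @param seed integer seed.
#' @param mother,father parental genotypes ("Msms" or "msms"); a sterile
#'   (Msms) father is rejected because sterile plants produce no pollen.
#' @return character vector of progeny genotypes ("Msms"/"msms").
#' @examples
#' g <- sim_dgms_progeny(1000, seed = 1)
#' mean(g == "Msms")  # close to 0.5
#' @export
sim_dgms_progeny <- function(n, seed, mother = "Msms", father = "msms") {
  assert_that(n >= 1, "`n` must be at least 1")
  assert_that(mother %in% c("Msms", "msms") && father %in% c("Msms", "msms"),
              "parent genotypes must be 'Msms' or 'msms'")
  assert_that(father != "Msms",
              "sterile (Msms) plants set no pollen and cannot be the father")
  with_seed(seed, {
    from_mother <- if (mother == "Msms") {
      ifelse(stats::runif(n) < 0.5, "Ms", "ms")
    } else rep("ms", n)
    paste0(ifelse(from_mother == "Ms", "Ms", "ms"), "ms")
  })
}

#' Is a plant male-sterile?
#'
#' @param dgms_genotype character vector of DGMS genotypes.
#' @return logical; TRUE where the dominant Ms allele is carried.
#' @export
is_sterile <- function(dgms_genotype) grepl("^Ms", dgms_genotype)

# --- marker ascertainment ---------------------------------------------------

#' Genotype a population at a marker panel
#'
#' Reads each sample's alleles at the panel loci, emulating SSR-style
#' multi-locus amplification: one marker (primer pair) may interrogate
#' several genome-specific loci and then yields one call per locus. A/C loci
#' report the two homologous alleles; hemizygous B-genome loci report their
#' single allele (duplicated into both call slots) where the segment is
#' present and a missing call where it is absent. Calls are masked missing
#' independently with probability `missing_rate`.
#'
#' @param pop an `rs_population`.
#' @param panel data.frame with columns `marker` (assay id) and `locus`
#'   (genome-model marker id); defaults to one single-locus assay per locus.
#' @param missing_rate per-call missing probability in [0, 1).
#' @param seed integer seed (only consulted when `missing_rate > 0`).
#' @return a `genotypes` object: list with `calls` (data.frame sample,
#'   marker, locus, allele1, allele2) and `samples` (data.frame sample,
#'   taxon).
#' @export
genotype_markers <- function(pop, panel = NULL, missing_rate = 0, seed = 0L) {
  assert_that(inherits(pop, "rs_population"), "`pop` must be an rs_population")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "`missing_rate` must be in [0, 1)")
  all_loci <- c(colnames(pop$hap_allele[[1]]), colnames(pop$b_pres))
  if (is.null(panel)) {
    panel <- data.frame(marker = all_loci, locus = all_loci,
                        stringsAsFactors = FALSE)
  }
  assert_that(all(c("marker", "locus") %in% names(panel)),
              "`panel` needs columns marker and locus")
  unknown <- setdiff(panel$locus, all_loci)
  if (length(unknown)) {
    abort(sprintf("panel references unknown loci: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  n <- n_plants(pop)
  blocks <- lapply(seq_len(nrow(panel)), function(r) {
    loc <- panel$locus[r]
    if (loc %in% colnames(pop$hap_allele[[1]])) {
      a1 <- pop$hap_allele[[1]][, loc]
      a2 <- pop$hap_allele[[2]][, loc]
    } else {
      pres <- pop$b_pres[, loc]
      a1 <- ifelse(pres, pop$b_allele[, loc], NA_character_)
      a2 <- a1
    }
    data.frame(sample = pop$id, marker = panel$marker[r], locus = loc,
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, blocks)
  if (missing_rate > 0) {
    calls <- with_seed(seed, {
      drop <- stats::runif(nrow(calls)) < missing_rate
      calls$allele1[drop] <- NA_character_
      calls$allele2[drop] <- NA_character_
      calls
    })
  }
  rownames(calls) <- NULL
  new_genotypes(calls,
                data.frame(sample = pop$id, taxon = pop$subpop,
                           stringsAsFactors = FALSE))
}

#' Sample a reference accession panel of a pure founder taxon
#'
#' Draws unrelated diploid accessions of one founder taxon under
#' Hardy-Weinberg proportions from the founder allele frequencies. Loci whose
#' genome the taxon does not carry yield missing calls (no amplification),
#' and hemizygous B-genome loci yield a single allele.
#'
#' @param panel a [founder_panel()].
#' @param taxon one of "B_rapa", "B_carinata", "T_napus".
#' @param n number of accessions.
#' @param seed integer seed.
#' @return a `genotypes` object.
#' @export
sample_taxon_panel <- function(panel, taxon, n, seed) {
  assert_that(inherits(panel, "founder_panel"), "`panel` must be a founder_panel")
  assert_that(taxon %in% TAXA, "unknown taxon")
  assert_that(n >= 1, "`n` must be at least 1")
  with_seed(seed, {
    lookup <- panel_lookup(panel)
    ids <- sprintf("%s_%03d", taxon, seq_len(n))
    mk <- panel$markers
    blocks <- lapply(seq_len(nrow(mk)), function(j) {
      m <- mk$marker[j]
      carriers <- taxa_for_genome(mk$genome[j])
      if (!taxon %in% carriers) {
        return(data.frame(sample = ids, marker = m, locus = m,
                          allele1 = NA_character_, allele2 = NA_character_,
                          stringsAsFactors = FALSE))
      }
      fv <- get(paste(taxon, m, sep = "|"), envir = lookup)
      draw <- function(k) sample(names(fv), k, replace = TRUE, prob = fv)
      if (mk$genome[j] == "B") {
        a <- draw(n)
        data.frame(sample = ids, marker = m, locus = m, allele1 = a,
                   allele2 = a, stringsAsFactors = FALSE)
      } else {
        data.frame(sample = ids, marker = m, locus = m, allele1 = draw(n),
                   allele2 = draw(n), stringsAsFactors = FALSE)
      }
    })
    new_genotypes(do.call(rbind, blocks),
                  data.frame(sample = ids, taxon = taxon,
                             stringsAsFactors = FALSE))
  })
}

# --- ancestry truth ---------------------------------------------------------

#' Extract the true ancestry track of a simulated population
#'
#' Collapses the marker-level subgenome-origin labels of each homologue into
#' BED-like intervals. A/C segments span whole chromosomes with boundaries at
#' midpoints between flanking markers of different origin; hemizygous
#' B-genome (Bc) segments are marker-supported spans on B chromosomes with
#' homologue 0. Coordinates are 1-based inclusive; see [write_bed()] for the
#' 0-based half-open export.
#'
#' @param pop an `rs_population`.
#' @return data.frame (class `ancestry_truth`): sample, chrom, start, end,
#'   homologue, origin, generation; plus the DGMS genotype per sample as
#'   attribute `dgms`.
#' @export
ancestry_truth <- function(pop) {
  assert_that(inherits(pop, "rs_population"), "`pop` must be an rs_population")
  idx <- genome_index(pop$genome)
  out <- list()
  for (k in seq_along(idx$ac_chroms)) {
    ch <- idx$ac_chroms[k]
    cols <- idx$ac_cols[[k]]
    pos <- idx$ac_pos[[k]]
    len <- idx$chrom_info$length_bp[idx$chrom_info$chrom == ch]
    for (h in 1:2) {
      om <- pop$hap_origin[[h]][, cols, drop = FALSE]
      for (i in seq_len(n_plants(pop))) {
        r <- rle(om[i, ])
        ends_i <- cumsum(r$lengths)
        starts_i <- c(1L, utils::head(ends_i, -1L) + 1L)
        prev_pos <- c(NA_real_, pos)[starts_i]      # pos[starts_i - 1]
        next_pos <- c(pos, NA_real_)[ends_i + 1L]   # pos[ends_i + 1]
        seg_start <- ifelse(starts_i == 1L, 1,
                            floor((prev_pos + pos[starts_i]) / 2) + 1)
        seg_end <- ifelse(ends_i == length(pos), len,
                          floor((pos[ends_i] + next_pos) / 2))
        out[[length(out) + 1L]] <- data.frame(
          sample = pop$id[i], chrom = ch, start = seg_start, end = seg_end,
          homologue = h, origin = r$values, stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_along(idx$b_chroms)) {
    ch <- idx$b_chroms[k]
    cols <- idx$b_cols[[k]]
    pos <- idx$b$pos[cols]
    for (i in seq_len(n_plants(pop))) {
      pres <- pop$b_pres[i, cols]
      if (!any(pres)) next
      r <- rle(pres)
      ends_i <- cumsum(r$lengths)
      starts_i <- c(1L, utils::head(ends_i, -1L) + 1L)
      keep <- which(r$values)
      out[[length(out) + 1L]] <- data.frame(
        sample = pop$id[i], chrom = ch, start = pos[starts_i[keep]],
        end = pos[ends_i[keep]], homologue = 0L, origin = "Bc",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$generation <- pop$generation
  rownames(res) <- NULL
  attr(res, "dgms") <- stats::setNames(pop$dgms, pop$id)
  class(res) <- c("ancestry_truth", "data.frame")
  res
}
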