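# Provenance of marker loci and alleles in the reconstituted gene pool.
#
# An SSR/Indel assay can amplify one or more genome-specific loci. The locus
# a marker interrogates is inferred jointly from (a) which reference taxa its
# alleles appear in (B. rapa, B. carinata, traditional B. napus) and (b) the
# genome its primer sequence aligns to. Allele origin is then read off the
# presence pattern: an allele private to B. rapa at an A-genome locus is an
# Ar-specific introgression, and so on. New-type (gene pool) samples never
# contribute to reference presence; alleles seen only there are novel.

ORIGIN_LEVELS <- c("Ar_specific", "An_specific", "Cc_specific",
                   "Cn_specific", "Bc_specific", "shared", "novel")

#' Presence pattern of one marker
#'
#' @param alleles data.frame with columns `allele`, `in_rapa`,
#'   `in_carinata`, `in_napus`, `in_newtype` (logical observed-in flags).
#' @param hits data.frame of alignment hits with columns `genome`
#'   ("A","B","C"), `chrom`, `pos`; a `reference` column is optional.
#' @param map_chrom optional genetic-map chromosome of the marker, used to
#'   resolve multiple hits within one genome.
#' @return an object of class `presence_pattern`.
#' @export
presence_pattern <- function(alleles, hits, map_chrom = NULL) {
  req <- c("allele", "in_rapa", "in_carinata", "in_napus", "in_newtype")
  assert_that(is.data.frame(alleles) && all(req %in% names(alleles)),
              "`alleles` needs columns allele, in_rapa, in_carinata, in_napus, in_newtype")
  assert_that(nrow(alleles) >= 1, "pattern needs at least one allele")
  flags <- alleles[, c("in_rapa", "in_carinata", "in_napus", "in_newtype")]
  assert_that(all(rowSums(flags) >= 1),
              "every retained allele must be observed somewhere")
  assert_that(is.data.frame(hits) && all(c("genome", "chrom") %in% names(hits)),
              "`hits` needs columns genome and chrom")
  assert_that(nrow(hits) >= 1, "pattern needs at least one alignment hit")
  assert_that(all(hits$genome %in% c("A", "B", "C")),
              "alignment genomes must be A, B or C")
  structure(list(alleles = alleles, hits = hits, map_chrom = map_chrom),
            class = "presence_pattern")
}

# hit chromosomes per genome after map-based disambiguation; NULL when a
# genome's hits stay ambiguous
resolve_hits <- function(pattern) {
  hits <- pattern$hits
  out <- list()
  ambiguous <- character()
  for (g in unique(hits$genome)) {
    ch <- unique(hits$chrom[hits$genome == g])
    if (length(ch) > 1L) {
      if (!is.null(pattern$map_chrom) && pattern$map_chrom %in% ch) {
        ch <- pattern$map_chrom
      } else {
        ambiguous <- c(ambiguous, g)
        next
      }
    }
    out[[g]] <- ch
  }
  list(by_genome = out, ambiguous = ambiguous)
}

#' Assign a marker's amplified loci to genomes
#'
#' Applies the joint presence/alignment rules: (i) alleles confined to
#' *B. napus* / *B. carinata* with a C-genome alignment define one
#' C-specific locus; (ii) alleles confined to *B. napus* / *B. rapa* with an
#' A-genome alignment define one A-specific locus; (iii) alleles splitting
#' into a carinata-involved group and a rapa-involved group with A and C
#' alignments define a C locus plus an A locus; (iv) alleles across all
#' three taxa with A and B alignments define an A/B locus pair. Patterns
#' matching no rule come back "unassigned" with a reason; contradictory
#' evidence (e.g. rapa-only alleles aligning only to C) comes back
#' "conflict" rather than being silently assigned.
#'
#' @param pattern a [presence_pattern()].
#' @return object of class `locus_assignment`: list with `status`
#'   ("assigned"/"unassigned"/"conflict"), `reason`, `loci` (data.frame
#'   locus, genome, chrom, rule) and `allele_locus` (named character vector
#'   allele -> locus id, NA where no locus can be attributed).
#' @export
assign_locus_genome <- function(pattern) {
  assert_that(inherits(pattern, "presence_pattern"),
              "`pattern` must be a presence_pattern")
  al <- pattern$alleles
  ref_present <- al$in_rapa | al$in_carinata | al$in_napus
  taxa <- c(rapa = any(al$in_rapa), carinata = any(al$in_carinata),
            napus = any(al$in_napus))
  res <- resolve_hits(pattern)
  if (length(res$ambiguous)) {
    return(unassigned_result(al, sprintf(
      "multiple %s-genome hits unresolved by the genetic map",
      paste(res$ambiguous, collapse = "/"))))
  }
  G <- sort(names(res$by_genome))
  allele_locus <- stats::setNames(rep(NA_character_, nrow(al)), al$allele)
  locus_id <- function(g) paste0("locus_", g)
  if (!any(ref_present)) {
    # no reference taxon carries any allele: fall back on the alignment
    if (length(G) == 1L) {
      allele_locus[] <- locus_id(G)
      return(assigned_result(al, data.frame(
        locus = locus_id(G), genome = G, chrom = res$by_genome[[G]],
        rule = "alignment_only", stringsAsFactors = FALSE), allele_locus))
    }
    return(unassigned_result(al, "no reference presence and multi-genome alignment"))
  }
  # consistency: rapa presence needs an A hit; carinata needs C or B
  if (taxa[["rapa"]] && !"A" %in% G) {
    return(conflict_result(al, "rapa presence without an A-genome alignment"))
  }
  if (taxa[["carinata"]] && !any(c("B", "C") %in% G)) {
    return(conflict_result(al, "carinata presence without a C/B-genome alignment"))
  }
  if (!taxa[["rapa"]] && identical(G, "C")) {
    # rule (i): napus/carinata alleles on a C alignment
    allele_locus[ref_present] <- locus_id("C")
    return(assigned_result(al, data.frame(
      locus = locus_id("C"), genome = "C", chrom = res$by_genome[["C"]],
      rule = "i", stringsAsFactors = FALSE), allele_locus))
  }
  if (!taxa[["carinata"]] && identical(G, "A")) {
    # rule (ii): napus/rapa alleles on an A alignment
    allele_locus[ref_present] <- locus_id("A")
    return(assigned_result(al, data.frame(
      locus = locus_id("A"), genome = "A", chrom = res$by_genome[["A"]],
      rule = "ii", stringsAsFactors = FALSE), allele_locus))
  }
  if (taxa[["rapa"]] && taxa[["carinata"]] && identical(G, c("A", "C"))) {
    # rule (iii): the marker amplifies a C locus (carinata-involved alleles)
    # and an A locus (rapa-involved alleles); an allele in both taxa would
    # contradict the split
    both <- al$in_rapa & al$in_carinata
    if (any(both)) {
      return(conflict_result(al, "allele shared by rapa and carinata under a split A/C alignment"))
    }
    allele_locus[al$in_carinata] <- locus_id("C")
    allele_locus[al$in_rapa] <- locus_id("A")
    # napus-only alleles cannot be attributed to either amplified locus
    # without fragment-size information; they stay unplaced (non-specific)
    loci <- data.frame(locus = c(locus_id("C"), locus_id("A")),
                       genome = c("C", "A"),
                       chrom = c(res$by_genome[["C"]], res$by_genome[["A"]]),
                       rule = "iii", stringsAsFactors = FALSE)
    return(assigned_result(al, loci, allele_locus))
  }
  if (all(taxa) && identical(G, c("A", "B"))) {
    # rule (iv): A/B locus pair; carinata-only alleles belong to the
    # B-genome homologue, the rest to the A locus
    carinata_only <- al$in_carinata & !al$in_rapa & !al$in_napus
    allele_locus[carinata_only] <- locus_id("B")
    allele_locus[ref_present & !carinata_only] <- locus_id("A")
    loci <- data.frame(locus = c(locus_id("A"), locus_id("B")),
                       genome = c("A", "B"),
                       chrom = c(res$by_genome[["A"]], res$by_genome[["B"]]),
                       rule = "iv", stringsAsFactors = FALSE)
    return(assigned_result(al, loci, allele_locus))
  }
  unassigned_result(al, sprintf(
    "presence pattern {%s} with alignment {%s} matches no rule",
    paste(names(taxa)[taxa], collapse = ","), paste(G, collapse = ",")))
}

assigned_result <- function(al, loci, allele_locus) {
  structure(list(status = "assigned", reason = NA_character_, loci = loci,
                 allele_locus = allele_locus),
            class = "locus_assignment")
}

unassigned_result <- function(al, reason) {
  structure(list(status = "unassigned", reason = reason,
                 loci = data.frame(locus = character(), genome = character(),
                                   chrom = character(), rule = character(),
                                   stringsAsFactors = FALSE),
                 allele_locus = stats::setNames(rep(NA_character_, nrow(al)),
                                                al$allele)),
            class = "locus_assignment")
}

conflict_result <- function(al, reason) {
  out <- unassigned_result(al, reason)
  out$status <- "conflict"
  out
}

#' @export
print.locus_assignment <- function(x, ...) {
  cat("locus_assignment:", x$status,
      if (x$status == "assigned") {
        paste0("(", paste(x$loci$genome, collapse = "+"), " locus, rule ",
               x$loci$rule[1], ")")
      } else paste0("- ", x$reason), "\n")
  invisible(x)
}

#' Classify allele origins at an assigned locus
#'
#' Labels every allele of a marker by subgenome origin given its locus
#' assignment: at an A-genome locus, rapa-only alleles are Ar-specific and
#' napus-only alleles An-specific; at a C-genome locus, carinata-only
#' alleles are Cc-specific and napus-only Cn-specific; B-locus alleles are
#' Bc-specific; alleles seen in two or more reference taxa (or unplaceable
#' under a split assignment) are shared; alleles absent from all reference
#' taxa but present in new-type samples are novel.
#'
#' @param assignment a [assign_locus_genome()] result.
#' @param pattern the matching [presence_pattern()].
#' @return data.frame: allele, locus, origin (factor over the origin
#'   levels), plus the flags.
#' @export
classify_allele_origin <- function(assignment, pattern) {
  assert_that(inherits(assignment, "locus_assignment"),
              "`assignment` must come from assign_locus_genome()")
  assert_that(inherits(pattern, "presence_pattern"),
              "`pattern` must be a presence_pattern")
  al <- pattern$alleles
  flags <- al[, c("in_rapa", "in_carinata", "in_napus", "in_newtype")]
  assert_that(all(rowSums(flags) >= 1), "allele observed nowhere")
  n_ref <- al$in_rapa + al$in_carinata + al$in_napus
  locus <- assignment$allele_locus[al$allele]
  genome <- assignment$loci$genome[match(locus, assignment$loci$locus)]
  origin <- character(nrow(al))
  for (i in seq_len(nrow(al))) {
    origin[i] <- if (n_ref[i] == 0L) {
      "novel"
    } else if (n_ref[i] >= 2L || is.na(genome[i])) {
      "shared"
    } else if (genome[i] == "B") {
      if (al$in_carinata[i]) "Bc_specific" else "shared"
    } else if (genome[i] == "A") {
      if (al$in_rapa[i]) "Ar_specific"
      else if (al$in_napus[i]) "An_specific"
      else "shared"
    } else {
      if (al$in_carinata[i]) "Cc_specific"
      else if (al$in_napus[i]) "Cn_specific"
      else "shared"
    }
  }
  data.frame(allele = al$allele, locus = unname(locus),
             origin = factor(origin, levels = ORIGIN_LEVELS),
             al[, c("in_rapa", "in_carinata", "in_napus", "in_newtype")],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build presence patterns and classify every marker of a genotype set
#'
#' Convenience pipeline wrapper: derives each marker's presence pattern from
#' reference panels within a genotype set, assigns loci from the alignment
#' hit table, and classifies allele origins.
#'
#' @param g a `genotypes` object containing reference and new-type samples.
#' @param hits data.frame with columns `marker`, `genome`, `chrom` (and
#'   optionally `pos`, `reference`).
#' @param panels named list with character vectors `B_rapa`, `B_carinata`,
#'   `T_napus`, `new_type` of sample ids.
#' @param min_count minimum number of panel samples carrying an allele for
#'   it to count as present in that taxon (default 1).
#' @return data.frame: marker, locus, genome, allele, origin, rule, status.
#' @export
classify_markers <- function(g, hits, panels, min_count = 1L) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  assert_that(all(c("B_rapa", "B_carinata", "T_napus", "new_type") %in%
                    names(panels)),
              "`panels` needs B_rapa, B_carinata, T_napus and new_type ids")
  assert_that(all(c("marker", "genome", "chrom") %in% names(hits)),
              "`hits` needs columns marker, genome, chrom")
  out <- list()
  for (m in unique(g$calls$marker)) {
    calls <- g$calls[g$calls$marker == m & !is.na(g$calls$allele1), ,
                     drop = FALSE]
    if (!nrow(calls)) next
    obs <- rbind(data.frame(sample = calls$sample, allele = calls$allele1),
                 data.frame(sample = calls$sample, allele = calls$allele2))
    count_in <- function(ids) {
      tab <- table(obs$allele[obs$sample %in% ids])
      names(tab)[tab >= min_count]
    }
    present <- lapply(panels, count_in)
    alleles_all <- sort(unique(obs$allele))
    al <- data.frame(allele = alleles_all,
                     in_rapa = alleles_all %in% present$B_rapa,
                     in_carinata = alleles_all %in% present$B_carinata,
                     in_napus = alleles_all %in% present$T_napus,
                     in_newtype = alleles_all %in% present$new_type,
                     stringsAsFactors = FALSE)
    al <- al[rowSums(al[, -1]) >= 1, , drop = FALSE]
    if (!nrow(al)) next
    mhits <- hits[hits$marker == m, , drop = FALSE]
    if (!nrow(mhits)) next
    pat <- presence_pattern(al, mhits)
    asg <- assign_locus_genome(pat)
    cls <- classify_allele_origin(asg, pat)
    cls$marker <- m
    cls$genome <- assignment_genome(asg, cls$locus)
    # locus ids are marker-scoped: "locus_A" of one assay is not "locus_A"
    # of another
    cls$locus <- ifelse(is.na(cls$locus), NA_character_,
                        paste(m, cls$locus, sep = ":"))
    cls$rule <- if (nrow(asg$loci)) asg$loci$rule[1] else NA_character_
    cls$status <- asg$status
    out[[length(out) + 1L]] <- cls
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("marker", "locus", "genome", "allele", "origin", "rule", "status",
          "in_rapa", "in_carinata", "in_napus", "in_newtype")]
}

assignment_genome <- function(asg, locus) {
  asg$loci$genome[match(locus, asg$loci$locus)]
}

#' Tally loci carrying specific introgressed alleles
#'
#' Counts, over the loci detected in a sample subset, how many carry at
#' least one allele specifically introgressed from the parental species
#' (Ar-, Cc- or Bc-specific), how many carry more than one, and the allele
#' tally per origin class.
#'
#' @param g a `genotypes` object.
#' @param classifications output of [classify_markers()] (or a data.frame
#'   with columns marker, locus, allele, origin).
#' @param samples optional sample subset defining the population (default
#'   all samples in `g`).
#' @return list: `n_loci_detected`, `n_specific_loci`,
#'   `n_multi_specific_loci`, `fraction_specific`, `alleles_by_origin`
#'   (table), `specific_loci` (character).
#' @export
summarize_introgressed_loci <- function(g, classifications, samples = NULL) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  assert_that(all(c("marker", "locus", "allele", "origin") %in%
                    names(classifications)),
              "`classifications` needs marker, locus, allele, origin")
  samples <- samples %||% g$samples$sample
  calls <- g$calls[g$calls$sample %in% samples & !is.na(g$calls$allele1), ,
                   drop = FALSE]
  detected <- unique(c(paste(calls$marker, calls$allele1),
                       paste(calls$marker, calls$allele2)))
  cl <- classifications
  cl$key <- paste(cl$marker, cl$allele)
  cl <- cl[cl$key %in% detected & !is.na(cl$locus), , drop = FALSE]
  missing_cls <- setdiff(detected,
                         paste(classifications$marker, classifications$allele))
  assert_that(length(missing_cls) == 0,
              "classifications do not cover every detected allele")
  loci <- unique(cl$locus)
  specific <- cl[cl$origin %in% c("Ar_specific", "Cc_specific", "Bc_specific"), ]
  per_locus <- table(specific$locus)
  list(n_loci_detected = length(loci),
       n_specific_loci = length(per_locus),
       n_multi_specific_loci = sum(per_locus > 1L),
       fraction_specific = if (length(loci)) length(per_locus) / length(loci)
                           else NA_real_,
       alleles_by_origin = table(cl$origin),
       specific_loci = names(per_locus))
}
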