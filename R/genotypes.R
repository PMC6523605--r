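# Long-format multi-allelic genotype container shared by the SSR-stage
# analyses. `calls` has one row per sample x assayed locus with an unordered
# pair of allele symbols (both NA when missing); `samples` carries the group
# (taxon / subpopulation) label used to build reference presence patterns.

new_genotypes <- function(calls, samples) {
  req <- c("sample", "marker", "locus", "allele1", "allele2")
  assert_that(is.data.frame(calls) && all(req %in% names(calls)),
              "genotype calls need columns sample, marker, locus, allele1, allele2")
  assert_that(is.data.frame(samples) &&
                all(c("sample", "taxon") %in% names(samples)),
              "sample table needs columns sample and taxon")
  assert_that(all(calls$sample %in% samples$sample),
              "calls reference samples absent from the sample table")
  half <- xor(is.na(calls$allele1), is.na(calls$allele2))
  assert_that(!any(half), "half-missing calls are not allowed")
  structure(list(calls = calls, samples = samples), class = "genotypes")
}

#' Combine genotype sets
#'
#' Row-binds the calls and sample tables of several `genotypes` objects,
#' e.g. founder reference panels and a simulated recurrent-selection panel.
#'
#' @param ... `genotypes` objects with disjoint sample ids.
#' @return a `genotypes` object.
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  assert_that(all(vapply(gs, inherits, TRUE, "genotypes")),
              "all arguments must be genotypes objects")
  samples <- do.call(rbind, lapply(gs, `[[`, "samples"))
  assert_that(!anyDuplicated(samples$sample),
              "sample ids must be disjoint across genotype sets")
  new_genotypes(do.call(rbind, lapply(gs, `[[`, "calls")), samples)
}

#' Subset a genotype set by sample
#'
#' @param g a `genotypes` object.
#' @param sample_ids sample ids to keep.
#' @return a `genotypes` object.
#' @export
subset_samples <- function(g, sample_ids) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  missing_ids <- setdiff(sample_ids, g$samples$sample)
  assert_that(length(missing_ids) == 0,
              paste("unknown samples:", paste(utils::head(missing_ids, 5),
                                              collapse = ", ")))
  new_genotypes(g$calls[g$calls$sample %in% sample_ids, , drop = FALSE],
                g$samples[g$samples$sample %in% sample_ids, , drop = FALSE])
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes:", nrow(x$samples), "samples x",
      length(unique(x$calls$locus)), "loci (",
      length(unique(x$calls$marker)), "assays );",
      sprintf("%.1f%% missing calls\n", 100 * mean(is.na(x$calls$allele1))))
  tab <- table(x$samples$taxon)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
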