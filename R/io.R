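# Readers and writers for the pipeline's plain-text formats: long genotype
# TSV, marker-matrix TSV, VCF (read), BED (write, 0-based half-open),
# newick, and a resolved run-configuration echo.

#' Read a long-format genotype table
#'
#' Expects a TSV with header columns sample, marker, locus, allele1,
#' allele2 and optionally taxon; missing calls are encoded as `NA`, `.` or
#' the empty string in both allele columns.
#'
#' @param path file path.
#' @return a `genotypes` object.
#' @export
read_genotype_table <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf("malformed row at line %d of %s (expected %d fields, got %d)",
                  bad, path, nf[1], nf[bad]))
  }
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("NA", ".", ""))
  req <- c("sample", "marker", "locus", "allele1", "allele2")
  miss <- setdiff(req, names(tab))
  assert_that(length(miss) == 0,
              paste("genotype table lacks columns:", paste(miss, collapse = ", ")))
  half <- which(xor(is.na(tab$allele1), is.na(tab$allele2)))
  if (length(half)) {
    abort(sprintf("half-missing call at line %d (one allele NA)", half[1] + 1L))
  }
  samples <- unique(tab[, intersect(c("sample", "taxon"), names(tab)),
                        drop = FALSE])
  if (!"taxon" %in% names(samples)) samples$taxon <- "unknown"
  samples <- samples[!duplicated(samples$sample), , drop = FALSE]
  message(sprintf("read %d calls for %d samples from %s", nrow(tab),
                  nrow(samples), path))
  new_genotypes(tab[, req], samples)
}

#' Write a long-format genotype table
#'
#' @param g a `genotypes` object.
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @return the path, invisibly.
#' @export
write_genotype_table <- function(g, path, overwrite = FALSE) {
  assert_that(inherits(g, "genotypes"), "`g` must be a genotypes object")
  check_collision(path, overwrite)
  out <- g$calls
  out$taxon <- g$samples$taxon[match(out$sample, g$samples$sample)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a marker matrix as TSV
#'
#' Columns: marker, source, genome, chrom, pos, then one genotype column per
#' sample with missing cells as ".".
#'
#' @param mm a [marker_matrix()].
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @return the path, invisibly.
#' @export
write_marker_matrix <- function(mm, path, overwrite = FALSE) {
  assert_that(inherits(mm, "marker_matrix"), "`mm` must be a marker_matrix")
  check_collision(path, overwrite)
  geno <- mm$geno
  geno[is.na(geno)] <- "."
  out <- cbind(mm$markers[, c("marker", "source", "genome", "chrom", "pos")],
               as.data.frame(geno, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker matrix from TSV
#'
#' @param path file written by [write_marker_matrix()] (or matching its
#'   layout); "." and "./." cells are missing.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  meta <- c("marker", "source", "genome", "chrom", "pos")
  miss <- setdiff(meta, names(tab))
  assert_that(length(miss) == 0,
              paste("marker matrix lacks columns:", paste(miss, collapse = ", ")))
  markers <- tab[, meta]
  markers$pos <- as.integer(markers$pos)
  samples <- setdiff(names(tab), meta)
  assert_that(length(samples) >= 1, "marker matrix has no sample columns")
  geno <- as.matrix(tab[, samples, drop = FALSE])
  geno[geno %in% c(".", "./.", "")] <- NA_character_
  rownames(geno) <- markers$marker
  marker_matrix(markers, geno)
}

#' Read a marker matrix from VCF
#'
#' Converts VCF genotypes (via vcfR) into a [marker_matrix()]. Contig names
#' may carry the source reference as a prefix separated by `|`
#' (e.g. `nigra_B|B04`); unprefixed contigs default to the primary
#' reference `napus_AC`. `./.` genotypes become missing; numeric genotype
#' indices are translated to REF/ALT allele strings.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [marker_matrix()].
#' @export
read_marker_matrix_vcf <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom_raw <- fix[, "CHROM"]
  has_src <- grepl("|", chrom_raw, fixed = TRUE)
  source <- ifelse(has_src, sub("\\|.*$", "", chrom_raw), "napus_AC")
  chrom <- ifelse(has_src, sub("^[^|]*\\|", "", chrom_raw), chrom_raw)
  genome <- substr(chrom, 1, 1)
  assert_that(all(genome %in% c("A", "B", "C")),
              "contig names must start with the genome letter (A/B/C)")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom[is.na(ids) | ids == "."], "_",
                                         fix[is.na(ids) | ids == ".", "POS"])
  markers <- data.frame(marker = ids, source = source, genome = genome,
                        chrom = chrom, pos = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- cbind(fix[, "REF"], matrix("", nrow(fix), 0))
  alt_split <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",")
  geno <- matrix(NA_character_, nrow(gt), ncol(gt),
                 dimnames = list(markers$marker, colnames(gt)))
  for (i in seq_len(nrow(gt))) {
    lut <- c(fix[i, "REF"], alt_split[[i]])
    for (j in seq_len(ncol(gt))) {
      gv <- gt[i, j]
      if (is.na(gv) || gv %in% c("./.", ".", ".|.")) next
      idx <- as.integer(strsplit(gv, "[/|]")[[1]]) + 1L
      if (anyNA(idx)) next
      geno[i, j] <- paste(sort(lut[idx]), collapse = "/")
    }
  }
  marker_matrix(markers, geno)
}

#' Write segments (or ancestry intervals) as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention: `start - 1`, `end`. An empty segment set yields a
#' file holding only the header comment.
#'
#' @param segments data.frame with columns chrom, start, end and optionally
#'   `sample` (name field) and `origin`/`n_markers` (score/extra field).
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @return the path, invisibly.
#' @export
write_bed <- function(segments, path, overwrite = FALSE) {
  assert_that(all(c("chrom", "start", "end") %in% names(segments)),
              "`segments` needs columns chrom, start, end")
  check_collision(path, overwrite)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED 0-based half-open; name=sample", con)
  if (nrow(segments)) {
    name <- segments$sample %||% segments$origin %||% "."
    extra <- segments$origin %||% segments$n_markers %||% "."
    lines <- paste(segments$chrom, format(segments$start - 1, scientific = FALSE,
                                          trim = TRUE),
                   format(segments$end, scientific = FALSE, trim = TRUE),
                   name, extra, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a tree in newick format
#'
#' @param tree an `nj_tree` from [build_nj_tree()] or an ape phylo object.
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path, overwrite = FALSE) {
  check_collision(path, overwrite)
  if (inherits(tree, "nj_tree")) {
    writeLines(tree$newick, path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' Write the resolved run configuration beside outputs
#'
#' Records parameter name/value pairs plus the package version and a
#' timestamp, so every run is reproducible from its output directory.
#'
#' @param params named list of resolved parameters (seeds included).
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @return the path, invisibly.
#' @export
write_run_config <- function(params, path, overwrite = FALSE) {
  assert_that(is.list(params) && !is.null(names(params)) &&
                all(nzchar(names(params))), "`params` must be a named list")
  check_collision(path, overwrite)
  vals <- vapply(params, function(v) paste(format(v), collapse = ","),
                 character(1))
  df <- data.frame(
    key = c("tool", "version", "timestamp", names(params)),
    value = c("rsgenepool",
              as.character(utils::packageVersion("rsgenepool")),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), vals),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_collision <- function(path, overwrite) {
  if (file.exists(path) && !overwrite) {
    abort(sprintf("output file exists (use overwrite = TRUE): %s", path))
  }
  invisible(TRUE)
}
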