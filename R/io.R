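#' Write a cohort to disk
#'
#' Writes the genotype matrix as VCF v4.2 (GT-only FORMAT, 1-based positions,
#' missing genotypes as \code{./.}) or as transposed PLINK-style text (one row
#' per variant of 0/1/2/NA dosages plus a variant map file), and always writes
#' the sample metadata as a tab-separated table with a header. The writer is
#' canonical: writing, reading back and writing again produces byte-identical
#' files.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param prefix output path prefix; files \code{<prefix>.vcf} or
#'   \code{<prefix>.tgeno} + \code{<prefix>.map}, and
#'   \code{<prefix>.samples.tsv} are created.
#' @param format \code{"vcf"} or \code{"plink-text"}.
#' @return invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, prefix, format = c("vcf", "plink-text")) {
  format <- match.arg(format)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  meta_path <- paste0(prefix, ".samples.tsv")
  utils::write.table(cohort$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(metadata = meta_path)
  vt <- cohort$variants
  g <- cohort$genotypes
  if (format == "vcf") {
    vcf_path <- paste0(prefix, ".vcf")
    gt <- matrix("./.", nrow(g), ncol(g))
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
    body <- paste(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt, ".", "PASS", ".",
                  "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", cohort$samples$sample_id),
                      collapse = "\t"))
    writeLines(c(header, body), vcf_path)
    paths <- c(paths, genotypes = vcf_path)
  } else {
    tg_path <- paste0(prefix, ".tgeno")
    map_path <- paste0(prefix, ".map")
    dos <- matrix(as.character(t(g)), ncol(g), nrow(g))
    dos[is.na(t(g))] <- "NA"
    lines <- paste(vt$id, apply(dos, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(paste(c("ID", cohort$samples$sample_id), collapse = "\t"),
                 lines), tg_path)
    utils::write.table(
      data.frame(chrom = vt$chrom, id = vt$id, pos = vt$pos, ref = vt$ref,
                 alt = vt$alt, stringsAsFactors = FALSE),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, genotypes = tg_path, map = map_path)
  }
  invisible(paths)
}

#' Read a cohort from disk
#'
#' Counterpart of \code{\link{write_cohort}}: reads VCF v4.2 (via vcfR;
#' genotype dosage is the count of non-reference alleles in GT, \code{./.}
#' read as missing, multiallelic records kept as one variant with
#' comma-separated alts) or the transposed PLINK-style text dialect, plus the
#' tab-separated sample metadata.
#'
#' @param prefix path prefix used by \code{\link{write_cohort}}.
#' @param format \code{"vcf"} or \code{"plink-text"}.
#' @return a \code{\link{cohort}} (without generator truth).
#' @export
read_cohort <- function(prefix, format = c("vcf", "plink-text")) {
  format <- match.arg(format)
  meta_path <- paste0(prefix, ".samples.tsv")
  if (!file.exists(meta_path)) stop_invalid("missing metadata file %s", meta_path)
  samples <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
  if ("age" %in% names(samples)) samples$age <- as.integer(samples$age)
  if (format == "vcf") {
    path <- paste0(prefix, ".vcf")
    validate_vcf_lines(path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    vt <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                        fix[, "REF"], fix[, "ALT"], id = fix[, "ID"])
    gt <- vcfR::extract.gt(v, element = "GT")
    g <- t(matrix(vapply(gt, gt_to_dosage, integer(1)), nrow(gt), ncol(gt)))
  } else {
    tg_path <- paste0(prefix, ".tgeno")
    map <- utils::read.table(paste0(prefix, ".map"), sep = "\t", header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    vt <- variant_table(map$chrom, as.integer(map$pos), map$ref, map$alt,
                        id = map$id)
    lines <- readLines(tg_path)
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    n_samp <- length(hdr) - 1L
    g <- matrix(NA_integer_, n_samp, length(lines) - 1L)
    for (i in seq_along(lines)[-1]) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(fields) != n_samp + 1L)
        stop_invalid("%s line %d: expected %d fields, found %d",
                     tg_path, i, n_samp + 1L, length(fields))
      dos <- suppressWarnings(as.integer(fields[-1]))
      bad <- !(fields[-1] %in% c("0", "1", "2", "NA"))
      if (any(bad))
        stop_invalid("%s line %d: dosage outside {0,1,2,NA}: %s",
                     tg_path, i, fields[-1][bad][1])
      g[, i - 1L] <- dos
    }
  }
  if (nrow(samples) != nrow(g))
    stop_invalid("metadata has %d samples but genotypes have %d",
                 nrow(samples), nrow(g))
  cohort(g, vt, samples)
}

# GT string -> non-reference allele count; "."-containing calls are missing.
gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles != "0")
}

# Cheap structural validation so malformed VCF records fail with a line number
# instead of an opaque parser error.
validate_vcf_lines <- function(path) {
  if (!file.exists(path)) stop_invalid("missing VCF file %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop_invalid("%s: no #CHROM header line", path)
  n_field <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  for (i in seq_along(lines)) {
    if (i <= hdr) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_field)
      stop_invalid("%s line %d: expected %d fields, found %d",
                   path, i, n_field, length(fields))
    if (is.na(suppressWarnings(as.integer(fields[2]))))
      stop_invalid("%s line %d: POS is not an integer: %s", path, i, fields[2])
  }
  invisible(TRUE)
}
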