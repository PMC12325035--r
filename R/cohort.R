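#' Construct a variant table
#'
#' A variant table holds per-variant identity: chromosome, 1-based position,
#' reference and alternate allele(s), and the substitution class. Multiple
#' alternate alleles are stored comma-separated in \code{alt}. The matching
#' key used throughout the package is (chrom, pos, sorted uppercased alleles),
#' so ref/alt orientation does not affect cross-platform matching.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param ref reference allele strings.
#' @param alt alternate allele strings; multiallelic sites comma-separated.
#' @param id optional variant identifiers; defaults to \code{chrom:pos}.
#' @return a \code{data.frame} of class \code{variant_table} with columns
#'   \code{chrom, pos, id, ref, alt, class, key}.
#' @export
variant_table <- function(chrom, pos, ref, alt, id = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  stopifnot(length(ref) == n, length(alt) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  vt <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    id = as.character(id), ref = ref, alt = alt,
    class = substitution_class(ref, alt),
    key = variant_key(chrom, pos, ref, alt),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(vt$key))
    stop_invalid("duplicate variant keys (chrom,pos,alleles): e.g. %s",
                 vt$key[duplicated(vt$key)][1])
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Substitution class of a ref/alt pair
#'
#' Transitions are A<->G and C<->T; every other single-base change is a
#' transversion. Multi-base, symbolic, or multiallelic records are classed
#' \code{"other"} at the record level (multiallelic sites are decomposed
#' per alternate allele by \code{\link{tstv_ratio}}).
#'
#' @param ref,alt allele strings (alt possibly comma-separated).
#' @return character vector: \code{"transition"}, \code{"transversion"} or
#'   \code{"other"}.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  out <- rep("other", length(ref))
  snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  pair <- paste0(ref, alt)
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  out[snv & ts] <- "transition"
  out[snv & !ts] <- "transversion"
  out
}

#' Variant matching key
#'
#' Key is chrom:pos:sorted(uppercased alleles); invariant to ref/alt swap so
#' that array and WGS call sets with opposite orientations still match.
#'
#' @inheritParams variant_table
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  multi <- grepl(",", alt, fixed = TRUE)
  alleles <- character(length(ref))
  alleles[!multi] <- paste(pmin(ref[!multi], alt[!multi]),
                           pmax(ref[!multi], alt[!multi]), sep = "/")
  if (any(multi)) {
    alleles[multi] <- mapply(function(r, a) {
      paste(sort(c(r, strsplit(a, ",", fixed = TRUE)[[1]])), collapse = "/")
    }, ref[multi], alt[multi], USE.NAMES = FALSE)
  }
  paste(chrom, pos, alleles, sep = ":")
}

#' Construct a cohort
#'
#' The container every pipeline stage consumes: an integer dosage matrix
#' (samples x variants, values 0/1/2 or NA for missing), a
#' \code{\link{variant_table}}, and a sample metadata table with at least
#' \code{sample_id} and \code{population} columns. Simulated cohorts carry a
#' \code{truth} list with per-sample realized admixture proportions and
#' per-variant artifact flags.
#'
#' @param genotypes integer matrix of alt-allele dosages, samples in rows.
#' @param variants a \code{variant_table} with one row per matrix column.
#' @param samples data.frame of sample metadata, one row per matrix row.
#' @param truth optional list of generator ground truth.
#' @return an object of class \code{cohort}.
#' @export
cohort <- function(genotypes, variants, samples, truth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(samples))
    stop_invalid("genotype rows (%d) != sample rows (%d)",
                 nrow(genotypes), nrow(samples))
  if (ncol(genotypes) != nrow(variants))
    stop_invalid("genotype columns (%d) != variant rows (%d)",
                 ncol(genotypes), nrow(variants))
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop_invalid("dosages must be 0, 1, 2 or NA; found %s",
                 paste(unique(genotypes[bad])[1:min(3, sum(bad))],
                       collapse = ", "))
  if (!"sample_id" %in% names(samples))
    samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- variants$id
  structure(list(genotypes = genotypes, variants = variants,
                 samples = samples, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d variants\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  if ("population" %in% names(x$samples)) {
    np <- length(unique(x$samples$population))
    cat(sprintf("  populations: %d\n", np))
  }
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.4f\n", miss))
  if (!is.null(x$truth)) cat("  generator truth attached\n")
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  tab <- table(object$samples$population)
  cat(sprintf("<cohort> %d samples, %d variants, %d populations\n",
              nrow(object$genotypes), ncol(object$genotypes), length(tab)))
  print(sort(tab, decreasing = TRUE))
  invisible(object)
}

#' Subset a cohort
#'
#' \code{x[i, j]} restricts to samples \code{i} and variants \code{j} (any
#' index type \code{[} accepts), carrying generator truth along.
#'
#' @param x a \code{\link{cohort}}.
#' @param i sample index.
#' @param j variant index.
#' @param ... unused.
#' @return a \code{cohort}.
#' @export
`[.cohort` <- function(x, i, j, ...) {
  si <- seq_len(nrow(x$genotypes)); names(si) <- rownames(x$genotypes)
  vi <- seq_len(ncol(x$genotypes)); names(vi) <- colnames(x$genotypes)
  if (!missing(i)) si <- si[i]
  if (!missing(j)) vi <- vi[j]
  subset_cohort(x, samples = unname(si), variants = unname(vi))
}

# Subset a cohort by sample and/or variant index, carrying truth along.
subset_cohort <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$genotypes)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$genotypes)) else variants
  truth <- x$truth
  if (!is.null(truth)) {
    if (!is.null(truth$admixture)) truth$admixture <- truth$admixture[si, , drop = FALSE]
    if (!is.null(truth$error_flag)) truth$error_flag <- truth$error_flag[vi]
    if (!is.null(truth$panel)) {
      truth$panel$p <- truth$panel$p[vi, , drop = FALSE]
      truth$panel$p0 <- truth$panel$p0[vi]
      pvt <- truth$panel$variants[vi, , drop = FALSE]
      class(pvt) <- c("variant_table", "data.frame")
      truth$panel$variants <- pvt
    }
  }
  vt <- x$variants[vi, , drop = FALSE]
  class(vt) <- c("variant_table", "data.frame")
  cohort(x$genotypes[si, vi, drop = FALSE], vt,
         x$samples[si, , drop = FALSE], truth)
}

# Alt-allele frequency per variant over non-missing genotypes (NA if all
# genotypes are missing).
alt_freq <- function(genotypes) {
  colMeans(genotypes, na.rm = TRUE) / 2
}

#' Minor allele frequency per variant of a cohort
#'
#' Computed on non-missing genotypes; NA for all-missing variants.
#'
#' @param x a \code{\link{cohort}}.
#' @return numeric vector of MAFs in [0, 0.5].
#' @export
cohort_maf <- function(x) {
  f <- alt_freq(x$genotypes)
  pmin(f, 1 - f)
}
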