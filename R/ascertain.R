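#' Array capture rate against a WGS variant set
#'
#' Fraction of WGS variant keys (chrom, pos, sorted alleles; IDs ignored)
#' present in the array variant table, overall and per chromosome (each
#' chromosome's rate uses that chromosome's WGS variants as denominator).
#'
#' @param wgs a \code{\link{variant_table}} of WGS-discovered variants.
#' @param array a \code{\link{variant_table}} of array content.
#' @return list: \code{overall} capture fraction, \code{by_chrom} data.frame
#'   (chrom, n_wgs, n_captured, rate).
#' @export
capture_rate <- function(wgs, array) {
  if (NROW(wgs) == 0) stop_invalid("WGS variant table is empty (undefined denominator)")
  hit <- wgs$key %in% array$key
  by <- stats::aggregate(hit, by = list(chrom = wgs$chrom),
                         FUN = function(z) c(sum(z), length(z)))
  by_chrom <- data.frame(chrom = by$chrom,
                         n_wgs = by$x[, 2], n_captured = by$x[, 1],
                         rate = by$x[, 1] / by$x[, 2],
                         stringsAsFactors = FALSE)
  list(overall = mean(hit), by_chrom = by_chrom[order(by_chrom$chrom), ])
}

#' MAF-spectrum distortion between platforms
#'
#' Bins each platform's polymorphic variants by minor allele frequency
#' (computed on that platform's own genotypes) and reports, per bin, the
#' fraction of each platform's variants and the distortion
#' (array fraction - WGS fraction) in percentage points. With the default
#' edges the first bin (MAF < 0.005) is the rare bin and the last
#' (MAF > 0.10) the common bin. Monomorphic variants are excluded from
#' binning and counted separately. Fractions are per-platform (each platform's
#' own variant list), the only convention under which percentage-point
#' differences between platforms are well defined.
#'
#' @param wgs_cohort,array_cohort \code{\link{cohort}} objects for the two
#'   platforms (samples need not overlap).
#' @param bins increasing MAF bin edges from 0 to 0.5.
#' @return object of class \code{spectrum_report}: \code{table} (per-bin
#'   fractions and distortion_pp), \code{capture} (overall + per-chromosome
#'   capture of WGS keys by the array table), and monomorphic counts.
#' @export
maf_spectrum_distortion <- function(wgs_cohort, array_cohort,
                                    bins = c(0, 0.005, 0.01, 0.05, 0.10, 0.5)) {
  bins <- sort(bins)
  if (abs(bins[1]) > 1e-12 || abs(bins[length(bins)] - 0.5) > 1e-9)
    stop_invalid("bin edges must cover (0, 0.5]: first edge 0, last edge 0.5")
  frac_of <- function(co) {
    maf <- cohort_maf(co)
    maf <- maf[!is.na(maf)]
    mono <- sum(maf == 0)
    maf <- maf[maf > 0]
    if (length(maf) == 0) stop_invalid("no polymorphic variants with computable MAF")
    cnt <- table(cut(maf, bins, include.lowest = FALSE, right = TRUE))
    list(frac = as.numeric(cnt) / length(maf), mono = mono)
  }
  w <- frac_of(wgs_cohort)
  a <- frac_of(array_cohort)
  lab <- levels(cut(0.1, bins))
  tab <- data.frame(
    bin = lab,
    lower = bins[-length(bins)], upper = bins[-1],
    wgs_fraction = w$frac, array_fraction = a$frac,
    distortion_pp = (a$frac - w$frac) * 100,
    stringsAsFactors = FALSE
  )
  cap <- capture_rate(wgs_cohort$variants, array_cohort$variants)
  structure(list(table = tab, capture = cap,
                 rare_pp = tab$distortion_pp[1],
                 common_pp = tab$distortion_pp[nrow(tab)],
                 n_monomorphic = c(wgs = w$mono, array = a$mono)),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<ascertainment spectrum> capture rate %.1f%%\n",
              100 * x$capture$overall))
  cat(sprintf("  rare bin (MAF < %.3g): %+.1f pp\n", x$table$upper[1],
              x$rare_pp))
  cat(sprintf("  common bin (MAF > %.2g): %+.1f pp\n",
              x$table$lower[nrow(x$table)], x$common_pp))
  print(x$table[, c("bin", "wgs_fraction", "array_fraction", "distortion_pp")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
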