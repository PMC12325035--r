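#' QC thresholds
#'
#' Defaults follow common human cohort practice: call rate >= 95 percent,
#' MAF >= 1 percent for common-variant analyses, HWE exact p >= 1e-6, and a
#' pi-hat relatedness bound of 0.185 (halfway between second- and third-degree
#' relatives) for IBD pruning.
#'
#' @param min_call_rate minimum per-variant (and per-sample) call rate.
#' @param min_maf minimum minor allele frequency.
#' @param min_hwe_p minimum Hardy-Weinberg exact p-value.
#' @param max_pihat maximum allowed pairwise pi-hat before pruning.
#' @return list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          min_hwe_p = 1e-6, max_pihat = 0.185) {
  vals <- c(min_call_rate, min_maf, min_hwe_p, max_pihat)
  if (any(vals < 0 | vals > 1))
    stop_invalid("all QC thresholds must lie in [0,1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, max_pihat = max_pihat),
            class = "qc_thresholds")
}

#' Per-variant quality control
#'
#' Computes per-variant call rate, minor allele frequency (on non-missing
#' genotypes), heterozygosity and the Levene-Haldane exact HWE p-value, and a
#' pass mask requiring call rate, MAF and HWE p all at or above their
#' thresholds. Variants with all genotypes missing get NA metrics and fail.
#' The per-sample call-rate pass fraction is attached as an attribute.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return data.frame with columns \code{id, call_rate, maf, het, hwe_p,
#'   pass}; attribute \code{sample_pass_fraction} gives the fraction of
#'   samples with call rate at or above \code{min_call_rate}.
#' @export
variant_qc <- function(cohort, thresholds = qc_thresholds()) {
  g <- cohort$genotypes
  if (length(g) == 0) stop_invalid("cohort is empty")
  n <- nrow(g)
  n_called <- n - colSums(is.na(g))
  call_rate <- n_called / n
  f <- alt_freq(g)
  maf <- pmin(f, 1 - f)
  het <- colSums(g == 1L, na.rm = TRUE) / pmax(n_called, 1L)
  n_hom_ref <- colSums(g == 0L, na.rm = TRUE)
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(g == 2L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    if (n_called[j] == 0) return(NA_real_)
    hwe_exact_pvalue(n_hom_ref[j], n_het[j], n_hom_alt[j])
  }, numeric(1))
  empty <- n_called == 0
  call_rate[empty] <- NA_real_; maf[empty] <- NA_real_; het[empty] <- NA_real_
  pass <- !empty & call_rate >= thresholds$min_call_rate &
    maf >= thresholds$min_maf & hwe_p >= thresholds$min_hwe_p
  pass[is.na(pass)] <- FALSE
  out <- data.frame(id = cohort$variants$id, call_rate = call_rate, maf = maf,
                    het = het, hwe_p = hwe_p, pass = pass,
                    stringsAsFactors = FALSE)
  sample_cr <- rowMeans(!is.na(g))
  attr(out, "sample_call_rate") <- sample_cr
  attr(out, "sample_pass_fraction") <-
    mean(sample_cr >= thresholds$min_call_rate)
  out
}

#' Exact Hardy-Weinberg test p-value
#'
#' Exact conditional test on the Levene-Haldane distribution of the
#' heterozygote count given the allele counts: the p-value is the sum of the
#' probabilities of all heterozygote counts whose probability does not exceed
#' the observed one (no mid-p correction). Monomorphic variants return 1 by
#' convention: with one allele absent no HWE deviation is possible.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts; the total
#'   must be at least 1.
#' @return the exact two-sided p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop_invalid("at least one genotype required")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  # Probabilities over all feasible het counts (same parity as n_rare) via the
  # stable ratio recurrence of the Levene-Haldane pmf
  #   P(h) proportional to 2^h * n! / (hom_rare! h! hom_com!)
  # so P(h+2)/P(h) = 4 * hom_rare(h) * hom_com(h) / ((h+1)(h+2)).
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_rare <- (n_rare - h) / 2
    hom_com <- n - h - hom_rare
    lp[i] <- lp[i - 1] + log(4) + log(hom_rare) + log(hom_com) -
      log(h + 1) - log(h + 2)
  }
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

#' Pairwise relatedness (pi-hat)
#'
#' Method-of-moments estimator of the IBD sharing coefficients from
#' identity-by-state counts, in the style of PLINK's \code{--genome}: expected
#' IBS probabilities conditional on sharing 0, 1 or 2 alleles IBD are computed
#' from cohort-estimated allele frequencies, the IBD state distribution is
#' solved by moment matching, constrained to [0,1], and
#' pi-hat = P(IBD=2) + P(IBD=1)/2. Monomorphic variants are excluded; per
#' pair, only variants called in both samples contribute.
#'
#' @param cohort a \code{\link{cohort}} (MAF-informative variants recommended).
#' @return data.frame with columns \code{id1, id2, pihat, n_variants};
#'   empty (zero rows) if fewer than two samples.
#' @export
kinship_pihat <- function(cohort) {
  g <- cohort$genotypes
  ids <- cohort$samples$sample_id
  n <- nrow(g)
  empty <- data.frame(id1 = character(), id2 = character(), pihat = numeric(),
                      n_variants = integer(), stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  p <- alt_freq(g)
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  q <- 1 - p
  # per-variant expected IBS-state probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2
  pairs <- utils::combn(n, 2)
  out <- data.frame(id1 = ids[pairs[1, ]], id2 = ids[pairs[2, ]],
                    pihat = NA_real_, n_variants = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    gi <- g[pairs[1, k], ]; gj <- g[pairs[2, k], ]
    ok <- !is.na(gi) & !is.na(gj)
    m_used <- sum(ok)
    if (m_used == 0) next
    d <- abs(gi[ok] - gj[ok])
    n_ibs <- c(sum(d == 2), sum(d == 1), sum(d == 0))
    E0 <- sum(e0_ibd0[ok]); E10 <- sum(e1_ibd0[ok]); E11 <- sum(e1_ibd1[ok])
    E20 <- sum(e2_ibd0[ok]); E21 <- sum(e2_ibd1[ok])
    z0 <- if (E0 > 0) n_ibs[1] / E0 else 0
    z1 <- if (E11 > 0) (n_ibs[2] - z0 * E10) / E11 else 0
    z2 <- (n_ibs[3] - z0 * E20 - z1 * E21) / m_used
    z <- pmax(c(z0, z1, z2), 0)
    if (sum(z) > 0) z <- z / sum(z)
    out$pihat[k] <- z[3] + z[2] / 2
    out$n_variants[k] <- m_used
  }
  out
}

#' Prune related samples
#'
#' Removes one member of each pair whose pi-hat exceeds the threshold,
#' keeping the member with the higher call rate (ties broken toward the
#' lexicographically smaller sample ID). Pruning is idempotent: applying it
#' twice removes nothing further.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param thresholds a \code{\link{qc_thresholds}} (uses \code{max_pihat}).
#' @param pihat optional precomputed \code{\link{kinship_pihat}} table.
#' @return the pruned \code{cohort}; removed IDs (with the partner that
#'   triggered removal) in \code{attr(, "removed")}.
#' @export
ibd_prune <- function(cohort, thresholds = qc_thresholds(), pihat = NULL) {
  if (is.null(pihat)) pihat <- kinship_pihat(cohort)
  cr <- rowMeans(!is.na(cohort$genotypes))
  names(cr) <- cohort$samples$sample_id
  flagged <- pihat[!is.na(pihat$pihat) & pihat$pihat > thresholds$max_pihat, ,
                   drop = FALSE]
  removed <- character(0)
  log <- data.frame(removed = character(), kept = character(),
                    pihat = numeric(), stringsAsFactors = FALSE)
  # process pairs from highest pi-hat down; skip pairs already broken
  flagged <- flagged[order(-flagged$pihat, flagged$id1, flagged$id2), ,
                     drop = FALSE]
  for (k in seq_len(nrow(flagged))) {
    a <- flagged$id1[k]; b <- flagged$id2[k]
    if (a %in% removed || b %in% removed) next
    drop <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b else max(a, b)
    keep <- setdiff(c(a, b), drop)
    removed <- c(removed, drop)
    log <- rbind(log, data.frame(removed = drop, kept = keep,
                                 pihat = flagged$pihat[k],
                                 stringsAsFactors = FALSE))
  }
  out <- subset_cohort(cohort,
                       samples = which(!cohort$samples$sample_id %in% removed))
  attr(out, "removed") <- log
  out
}

#' Audit population sample sizes
#'
#' Flags populations below the recommended minimum for stable allele-frequency
#' and PCA inference (default 30) and below a critical floor (default 10), and
#' reports the max:min size ratio. Percentages are rounded half-away-from-zero
#' to whole numbers.
#'
#' @param samples sample metadata with a \code{population} column.
#' @param min_n recommended minimum samples per population.
#' @param critical_n critical lower floor.
#' @return list of class \code{audit_report}: per-population counts, flag
#'   counts/percentages, flagged population names, and the size ratio.
#' @export
sample_size_audit <- function(samples, min_n = 30L, critical_n = 10L) {
  if (NROW(samples) == 0) stop_invalid("empty sample metadata")
  if (!"population" %in% names(samples))
    stop_invalid("metadata must contain a 'population' column")
  counts <- table(samples$population)
  n_pop <- length(counts)
  below_min <- counts < min_n
  below_crit <- counts < critical_n
  structure(list(
    counts = counts,
    n_populations = n_pop,
    n_below_min = sum(below_min),
    pct_below_min = round_half_away(100 * sum(below_min) / n_pop),
    n_below_critical = sum(below_crit),
    pct_below_critical = round_half_away(100 * sum(below_crit) / n_pop),
    below_min = names(counts)[below_min],
    below_critical = names(counts)[below_crit],
    size_ratio = as.numeric(max(counts) / min(counts)),
    min_n = min_n, critical_n = critical_n
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<sample-size audit> %d populations\n", x$n_populations))
  cat(sprintf("  below %d samples: %d (%d%%)\n", x$min_n, x$n_below_min,
              x$pct_below_min))
  cat(sprintf("  below %d samples: %d (%d%%)\n", x$critical_n,
              x$n_below_critical, x$pct_below_critical))
  cat(sprintf("  max:min size ratio %.1f:1\n", x$size_ratio))
  invisible(x)
}

#' Categorical cohort summary table
#'
#' Builds a participant-characteristics table: for each declared categorical
#' column, the count and percentage of each category, overall and stratified
#' by a grouping column (default \code{ancestry_group}). Percentages use the
#' column's non-missing total within each stratum and are rounded
#' half-away-from-zero to one decimal. Values outside the declared category
#' levels are counted under \code{"other"} with a warning.
#'
#' @param samples sample metadata.
#' @param columns character vector of categorical columns to summarize.
#' @param group_by stratifying column; set NULL for the overall column only.
#' @param levels optional named list of allowed category levels per column.
#' @return data.frame with columns \code{variable, category, group, n,
#'   percent}; \code{group} includes \code{"All"}.
#' @export
phenotype_summary <- function(samples, columns,
                              group_by = "ancestry_group", levels = NULL) {
  stopifnot(all(columns %in% names(samples)))
  groups <- list(All = rep(TRUE, nrow(samples)))
  if (!is.null(group_by)) {
    for (gv in sort(unique(samples[[group_by]])))
      groups[[gv]] <- samples[[group_by]] == gv
  }
  rows <- list()
  for (col in columns) {
    vals <- as.character(samples[[col]])
    allowed <- if (!is.null(levels) && col %in% names(levels))
      levels[[col]] else sort(unique(vals[!is.na(vals)]))
    unknown <- !is.na(vals) & !(vals %in% allowed)
    if (any(unknown)) {
      warning(sprintf("column %s: %d values outside declared categories counted as 'other'",
                      col, sum(unknown)), call. = FALSE)
      vals[unknown] <- "other"
      allowed <- c(allowed, "other")
    }
    for (gname in names(groups)) {
      v <- vals[groups[[gname]] & !is.na(vals)]
      total <- length(v)
      for (cat_i in allowed) {
        n_i <- sum(v == cat_i)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = col, category = cat_i, group = gname, n = n_i,
          percent = if (total > 0) round_half_away(100 * n_i / total, 1)
                    else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
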