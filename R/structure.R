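#' Sample-size-weighted principal component analysis
#'
#' PCA in which each sample carries weight inversely proportional to its
#' population's size (normalized to sum 1), so small populations are not
#' swamped by large ones. The weights enter both the allele-frequency
#' estimate and the covariance: genotypes are mean-imputed at the weighted
#' frequency, centered at 2p and scaled by sqrt(2p(1-p)) with p the weighted
#' frequency, and the weighted covariance is eigendecomposed through the
#' n x n inner-product trick. Component signs are fixed so each component's
#' largest-magnitude variant loading is positive, making runs comparable.
#'
#' @param cohort a \code{\link{cohort}} (post-QC recommended).
#' @param k number of components to return.
#' @param weight_mode \code{"inverse-group-size"} or \code{"uniform"}.
#' @return object of class \code{weighted_pca}: \code{coordinates} (n x k),
#'   \code{eigenvalues} (all non-trivial ones, non-increasing),
#'   \code{loadings}, \code{weights}, \code{total_variance}.
#' @export
weighted_pca <- function(cohort, k = 2L,
                         weight_mode = c("inverse-group-size", "uniform")) {
  weight_mode <- match.arg(weight_mode)
  g <- cohort$genotypes
  n <- nrow(g); m <- ncol(g)
  if (k < 1 || k > min(n, m))
    stop_invalid("k must lie in [1, min(samples, variants)] = [1, %d]",
                 min(n, m))
  pop <- cohort$samples$population
  if (weight_mode == "inverse-group-size") {
    tab <- table(pop)
    if (any(tab == 0))
      stop_invalid("population with zero samples: %s",
                   names(tab)[tab == 0][1])
    w <- 1 / as.numeric(tab[pop])
  } else {
    w <- rep(1, n)
  }
  w <- w / sum(w)
  # weighted allele frequency, accounting for missingness per variant
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  wsum <- crossprod(obs, w)                     # m x 1 total weight observed
  p_hat <- as.numeric(crossprod(g0, w) / (2 * wsum))
  keep <- is.finite(p_hat) & p_hat > 0 & p_hat < 1
  if (!any(keep)) stop_invalid("no polymorphic variants for PCA")
  x <- g0[, keep, drop = FALSE]
  p <- p_hat[keep]
  x <- sweep(x, 2, 2 * p)                       # center; missing -> 0 = mean
  x[!obs[, keep, drop = FALSE]] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  a <- sqrt(w) * x
  kmat <- tcrossprod(a)
  ev <- eigen(kmat, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  lambda <- ev$values[pos]
  u <- ev$vectors[, pos, drop = FALSE]
  k_use <- min(k, length(lambda))
  v <- crossprod(a, u[, seq_len(k_use), drop = FALSE]) %*%
    diag(1 / sqrt(lambda[seq_len(k_use)]), k_use)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k_use)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) v[, j] <- -v[, j]
  }
  scores <- x %*% v
  rownames(scores) <- cohort$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k_use))
  structure(list(coordinates = scores, eigenvalues = lambda, loadings = v,
                 weights = w, total_variance = sum(a^2),
                 weight_mode = weight_mode, kept_variants = which(keep)),
            class = "weighted_pca")
}

#' @export
print.weighted_pca <- function(x, ...) {
  cat(sprintf("<weighted PCA> %d samples, %d components (%s weights)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$weight_mode))
  pct <- 100 * x$eigenvalues[seq_len(ncol(x$coordinates))] /
    x$total_variance
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(pct), pct),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.weighted_pca <- function(x, color_by = NULL, ...) {
  col <- if (is.null(color_by)) 1 else as.integer(factor(color_by))
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2], col = col,
                 xlab = "PC1", ylab = "PC2", pch = 19, ...)
  invisible(x)
}

#' Stratified bootstrap stability of weighted PCA
#'
#' Resamples individuals with replacement within each population B times,
#' reruns the weighted PCA, and Procrustes-aligns (rotation, reflection,
#' scaling, translation) each replicate's coordinates of the resampled
#' samples onto the full-data solution. Reports the mean Procrustes RMSD,
#' per-sample coordinate standard deviation across replicates, and per
#' population the fraction of replicates in which its nearest-centroid
#' neighbor population is unchanged (cluster consistency). Populations of
#' size 1 are always resampled as themselves and flagged.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param k components to track.
#' @param B bootstrap replicates (>= 2).
#' @param weight_mode passed to \code{\link{weighted_pca}}.
#' @param seed integer RNG seed.
#' @return object of class \code{bootstrap_stability}: \code{mean_rmsd},
#'   \code{rmsd} (per replicate), \code{per_sample_sd},
#'   \code{cluster_consistency} (per population), \code{singleton_pops}.
#' @export
stratified_bootstrap_stability <- function(cohort, k = 2L, B = 100L,
                                           weight_mode = "inverse-group-size",
                                           seed = 1L) {
  if (B < 2) stop_invalid("B must be >= 2")
  full <- weighted_pca(cohort, k = k, weight_mode = weight_mode)
  coords <- full$coordinates
  pop <- cohort$samples$population
  pops <- sort(unique(pop))
  cent_full <- centroid_by(coords, pop)
  nn_full <- nearest_neighbor(cent_full)
  n <- nrow(coords)
  singleton <- names(table(pop))[table(pop) == 1]
  rmsd <- numeric(B)
  sd_sum <- matrix(0, n, ncol(coords))
  sd_sumsq <- matrix(0, n, ncol(coords))
  sd_cnt <- numeric(n)
  nn_same <- matrix(0, length(pops), B, dimnames = list(pops, NULL))
  with_seed(stage_seed(seed, "bootstrap_stability"), {
    for (b in seq_len(B)) {
      idx <- unlist(lapply(pops, function(pn) {
        i <- which(pop == pn)
        i[sample.int(length(i), length(i), replace = TRUE)]
      }), use.names = FALSE)
      rep_pca <- weighted_pca(subset_cohort(cohort, samples = idx),
                              k = k, weight_mode = weight_mode)
      shared <- !duplicated(idx)
      ref <- coords[idx[shared], , drop = FALSE]
      yc <- rep_pca$coordinates[shared, , drop = FALSE]
      pr <- vegan::procrustes(ref, yc, symmetric = FALSE)
      aligned <- pr$Yrot
      rmsd[b] <- sqrt(mean(rowSums((aligned - ref)^2)))
      si <- idx[shared]
      sd_sum[si, ] <- sd_sum[si, ] + aligned
      sd_sumsq[si, ] <- sd_sumsq[si, ] + aligned^2
      sd_cnt[si] <- sd_cnt[si] + 1
      cent_b <- centroid_by(aligned, pop[si])
      nn_b <- nearest_neighbor(cent_b)
      common <- intersect(names(nn_full), names(nn_b))
      nn_same[common, b] <- as.numeric(nn_b[common] == nn_full[common])
    }
  })
  cnt <- pmax(sd_cnt, 1)
  vars <- sd_sumsq / cnt - (sd_sum / cnt)^2
  per_sample_sd <- sqrt(pmax(rowMeans(vars), 0))
  names(per_sample_sd) <- cohort$samples$sample_id
  structure(list(mean_rmsd = mean(rmsd), rmsd = rmsd,
                 per_sample_sd = per_sample_sd,
                 cluster_consistency = rowMeans(nn_same),
                 singleton_pops = singleton, B = B, full = full),
            class = "bootstrap_stability")
}

centroid_by <- function(coords, groups) {
  cent <- rowsum(coords, groups) / as.numeric(table(groups)[sort(unique(groups))])
  cent
}

nearest_neighbor <- function(centroids) {
  if (nrow(centroids) < 2) return(setNames(character(0), character(0)))
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  setNames(rownames(centroids)[apply(d, 1, which.min)], rownames(centroids))
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat(sprintf("<bootstrap stability> B=%d replicates\n", x$B))
  cat(sprintf("  mean Procrustes RMSD: %.4f\n", x$mean_rmsd))
  cat(sprintf("  mean cluster consistency: %.3f\n",
              mean(x$cluster_consistency)))
  if (length(x$singleton_pops))
    cat(sprintf("  singleton populations (no within-group variance): %s\n",
                paste(x$singleton_pops, collapse = ", ")))
  invisible(x)
}

#' Hudson FST between two populations
#'
#' Per-variant Hudson estimator with sample-size correction:
#' numerator (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1) over denominator
#' p1(1-p2) + p2(1-p1), with n the allele counts. The mean is the
#' ratio-of-averages (sum of numerators over sum of denominators), the
#' standard recommendation for combining per-site estimates; negative
#' per-variant values are retained. Variants monomorphic for the same allele
#' in both populations are excluded from the mean and counted.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param pop_a,pop_b population labels present in the metadata.
#' @return list: \code{mean_fst}, \code{per_variant} (data.frame id/fst),
#'   \code{n_excluded_monomorphic}.
#' @export
hudson_fst <- function(cohort, pop_a, pop_b) {
  pop <- cohort$samples$population
  ia <- pop == pop_a; ib <- pop == pop_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop_invalid("both populations need >= 2 samples (%s: %d, %s: %d)",
                 pop_a, sum(ia), pop_b, sum(ib))
  ga <- cohort$genotypes[ia, , drop = FALSE]
  gb <- cohort$genotypes[ib, , drop = FALSE]
  n1 <- 2 * colSums(!is.na(ga)); n2 <- 2 * colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / n1
  p2 <- colSums(gb, na.rm = TRUE) / n2
  usable <- n1 >= 4 & n2 >= 4 & is.finite(p1) & is.finite(p2)
  mono_both <- usable & ((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  use <- usable & !mono_both
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  per_variant <- data.frame(id = cohort$variants$id[use],
                            fst = (num / den)[use],
                            stringsAsFactors = FALSE)
  list(mean_fst = sum(num[use]) / sum(den[use]),
       per_variant = per_variant,
       n_excluded_monomorphic = sum(mono_both),
       n_used = sum(use))
}

#' Pairwise FST matrix over all populations
#'
#' @param cohort a \code{\link{cohort}}.
#' @param min_n minimum samples per population to include it.
#' @return symmetric matrix of mean Hudson FST with zero diagonal.
#' @export
fst_matrix <- function(cohort, min_n = 2L) {
  tab <- table(cohort$samples$population)
  pops <- names(tab)[tab >= min_n]
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- hudson_fst(cohort, pops[i], pops[j])$mean_fst
    out[i, j] <- out[j, i] <- f
  }
  out
}

#' Unweighted polygenic risk score
#'
#' Per-sample count of risk alleles across a risk-variant table matched to
#' the cohort by (chrom, pos, alleles) key. Missing genotypes contribute the
#' sample's population expected dosage (2 x the population's risk-allele
#' frequency). Risk variants absent from the cohort are reported, not
#' silently dropped; zero overlap is an error. Population score distributions
#' are compared with a Kruskal-Wallis rank test.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param risk_variants data.frame with \code{chrom, pos, ref, alt} and a
#'   \code{risk_allele} column naming the counted allele.
#' @return list: \code{score} (per sample), \code{by_population}
#'   (mean/sd/n), \code{rank_test} (htest), \code{missing_variants}.
#' @export
unweighted_grs <- function(cohort, risk_variants) {
  rk <- variant_key(risk_variants$chrom, risk_variants$pos,
                    risk_variants$ref, risk_variants$alt)
  idx <- match(rk, cohort$variants$key)
  missing_rv <- risk_variants[is.na(idx), , drop = FALSE]
  hit <- which(!is.na(idx))
  if (length(hit) == 0) stop_invalid("no risk variants overlap the cohort")
  pop <- cohort$samples$population
  score <- numeric(nrow(cohort$genotypes))
  for (r in hit) {
    j <- idx[r]
    g <- cohort$genotypes[, j]
    risk <- toupper(risk_variants$risk_allele[r])
    dos <- if (risk == cohort$variants$alt[j]) g
           else if (risk == cohort$variants$ref[j]) 2L - g
           else stop_invalid("risk allele %s matches neither ref nor alt of %s",
                             risk, cohort$variants$id[j])
    if (anyNA(dos)) {
      pf <- tapply(dos, pop, mean, na.rm = TRUE) / 2
      pf[is.nan(pf)] <- mean(dos, na.rm = TRUE) / 2
      exp_dos <- 2 * pf[pop]
      dos <- ifelse(is.na(dos), exp_dos, dos)
    }
    score <- score + dos
  }
  names(score) <- cohort$samples$sample_id
  by_pop <- data.frame(
    population = sort(unique(pop)),
    n = as.integer(table(pop)[sort(unique(pop))]),
    mean = as.numeric(tapply(score, pop, mean)[sort(unique(pop))]),
    sd = as.numeric(tapply(score, pop, stats::sd)[sort(unique(pop))]),
    stringsAsFactors = FALSE)
  rank_test <- if (length(unique(pop)) > 1)
    stats::kruskal.test(score, factor(pop)) else NULL
  list(score = score, by_population = by_pop, rank_test = rank_test,
       missing_variants = missing_rv, n_used = length(hit))
}
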