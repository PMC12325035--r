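test_that("weighted PCA matches a dense eigen-oracle and standard PCA under uniform weights", {
  co <- two_pop_cohort(n_per_pop = 15, m = 300, F = 0.1, seed = 51)
  # dense oracle: build the weighted covariance over variants explicitly
  pca <- weighted_pca(co, k = 3)
  w <- pca$weights
  g <- co$genotypes[, pca$kept_variants]
  p <- as.numeric(crossprod(g, w)) / 2
  x <- sweep(sweep(g, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  cmat <- crossprod(sqrt(w) * x)
  ev <- eigen(cmat, symmetric = TRUE)
  oracle_scores <- x %*% ev$vectors[, 1:3]
  expect_equal(pca$eigenvalues[1:3], ev$values[1:3], tolerance = 1e-8)
  expect_equal(abs(unname(pca$coordinates)), abs(unname(oracle_scores)),
               tolerance = 1e-6)
  # uniform weights reproduce standard PCA coordinates up to sign
  pu <- weighted_pca(co, k = 3, weight_mode = "uniform")
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  expect_equal(abs(unname(pu$coordinates)),
               abs(unname(pc$x[, 1:3])), tolerance = 1e-6)
  # equal group sizes make inverse-size weights collapse to uniform
  pi2 <- weighted_pca(co, k = 3, weight_mode = "inverse-group-size")
  expect_equal(abs(unname(pi2$coordinates)), abs(unname(pu$coordinates)),
               tolerance = 1e-8)
  # variance conservation: total weighted variance equals the eigenvalue sum
  expect_equal(sum(pca$eigenvalues), pca$total_variance, tolerance = 1e-8)
  expect_error(weighted_pca(co, k = 1000), "k must lie")
})

test_that("weighted PC1 orders population centroids by Native admixture", {
  panel <- draw_ancestral_frequencies(20000, seed = 52)
  pops <- default_population_specs(scale = 0.5)
  co <- simulate_admixed_cohort(panel, pops, seed = 53)
  pca <- weighted_pca(co, k = 2)
  cent <- rowsum(pca$coordinates[, 1], co$samples$population) /
    as.numeric(table(co$samples$population))
  nat <- tapply(co$truth$admixture[, "NAT"], co$samples$population, mean)
  rho <- cor(cent[, 1], nat[rownames(cent)], method = "spearman")
  expect_gt(abs(rho), 0.9)
})

test_that("bootstrap stability is exact on degenerate resampling and stable for separated groups", {
  # singleton populations resample as themselves: RMSD exactly 0, flagged
  co1 <- two_pop_cohort(n_per_pop = 1, m = 400, F = 0.3, seed = 54)
  co1$samples$population <- c("A", "B")  # two singletons
  more <- two_pop_cohort(n_per_pop = 1, m = 400, F = 0.3, seed = 55)
  g <- rbind(co1$genotypes, more$genotypes)
  smp <- rbind(co1$samples, more$samples)
  smp$sample_id <- sprintf("S%d", 1:4)
  smp$population <- c("A", "B", "C", "D")
  co_singl <- cohort(g, co1$variants, smp)
  bs <- stratified_bootstrap_stability(co_singl, k = 2, B = 5, seed = 56)
  expect_equal(bs$mean_rmsd, 0, tolerance = 1e-10)
  expect_setequal(bs$singleton_pops, c("A", "B", "C", "D"))
  # three separated populations with distinct pairwise distances:
  # nearest-centroid neighbors never change across resamples
  panel <- draw_ancestral_frequencies(800, c("P1", "P2", "P3"),
                                      F_between = c(0.02, 0.10, 0.30),
                                      seed = 57)
  pops <- list(
    population_spec("P1", 50, c(P1 = 1, P2 = 0, P3 = 0)),
    population_spec("P2", 50, c(P1 = 0, P2 = 1, P3 = 0)),
    population_spec("P3", 20, c(P1 = 0, P2 = 0, P3 = 1)))
  co3 <- simulate_admixed_cohort(panel, pops, seed = 58)
  bs3 <- stratified_bootstrap_stability(co3, k = 2, B = 50, seed = 59)
  expect_true(all(bs3$cluster_consistency == 1))
  # replicate shapes stay close to the full solution, on the data's own scale
  rms_full <- sqrt(mean(rowSums(bs3$full$coordinates^2)))
  expect_lt(bs3$mean_rmsd, 0.5 * rms_full)
  # fixed seeds give identical summaries
  bs3b <- stratified_bootstrap_stability(co3, k = 2, B = 50, seed = 59)
  expect_identical(bs3$rmsd, bs3b$rmsd)
  expect_identical(bs3$cluster_consistency, bs3b$cluster_consistency)
  expect_error(stratified_bootstrap_stability(co3, B = 1), "B must be")
})

test_that("Procrustes RMSD is invariant to rigid motion of replicate coordinates", {
  set.seed(60)
  x <- matrix(rnorm(40), 20, 2)
  y <- x + matrix(rnorm(40, sd = 0.1), 20, 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  refl <- matrix(c(-1, 0, 0, 1), 2, 2)
  r0 <- vegan::procrustes(x, y, symmetric = FALSE)
  r1 <- vegan::procrustes(x, y %*% rot, symmetric = FALSE)
  r2 <- vegan::procrustes(x, 2.5 * y %*% rot %*% refl + 3, symmetric = FALSE)
  rmsd <- function(r) sqrt(mean(rowSums((r$Yrot - x)^2)))
  expect_equal(rmsd(r1), rmsd(r0), tolerance = 1e-10)
  expect_equal(rmsd(r2), rmsd(r0), tolerance = 1e-10)
})

test_that("bootstrap consistency does not degrade under the default 8:1 imbalance", {
  panel <- draw_ancestral_frequencies(800, c("P1", "P2", "P3"),
                                      F_between = c(0.02, 0.10, 0.30),
                                      seed = 61)
  mk <- function(sizes, seed) {
    pops <- list(
      population_spec("P1", sizes[1], c(P1 = 1, P2 = 0, P3 = 0)),
      population_spec("P2", sizes[2], c(P1 = 0, P2 = 1, P3 = 0)),
      population_spec("P3", sizes[3], c(P1 = 0, P2 = 0, P3 = 1)))
    simulate_admixed_cohort(panel, pops, seed = seed)
  }
  co_imb <- mk(c(80, 30, 10), 62)   # 8:1 imbalance
  co_bal <- mk(c(40, 40, 40), 63)   # same total n
  bs_imb <- stratified_bootstrap_stability(co_imb, k = 2, B = 30, seed = 64)
  bs_bal <- stratified_bootstrap_stability(co_bal, k = 2, B = 30, seed = 65)
  expect_gte(mean(bs_imb$cluster_consistency),
             mean(bs_bal$cluster_consistency) - 0.1)
})

test_that("Hudson FST hits its closed forms and recovers the drift parameter", {
  # identical allele frequencies: no differentiation
  set.seed(66)
  g <- matrix(rbinom(200 * 500, 2, rep(runif(500, 0.1, 0.9), each = 200)),
              200, 500)
  co0 <- toy_cohort(g)
  co0$samples$population <- rep(c("A", "B"), each = 100)
  expect_equal(hudson_fst(co0, "A", "B")$mean_fst, 0, tolerance = 0.01)
  # fixed difference: per-variant FST exactly 1
  gf <- cbind(rep(c(0L, 2L), each = 50))
  cof <- toy_cohort(gf)
  cof$samples$population <- rep(c("A", "B"), each = 50)
  expect_equal(hudson_fst(cof, "A", "B")$per_variant$fst, 1)
  # closed form at p = 0.2 vs 0.8: N/D -> 0.36/0.68
  gq <- cbind(c(rep(1L, 200), rep(0L, 300), rep(2L, 300), rep(1L, 200)))
  coq <- toy_cohort(gq)
  coq$samples$population <- rep(c("A", "B"), each = 500)
  expect_equal(hudson_fst(coq, "A", "B")$per_variant$fst, 0.36 / 0.68,
               tolerance = 0.002)
  # parameter recovery: two Balding-Nichols populations with drift F
  co <- two_pop_cohort(n_per_pop = 100, m = 10000, F = 0.1, seed = 67)
  est <- hudson_fst(co, "P1", "P2")$mean_fst
  expect_equal(est, 0.1, tolerance = 0.15)
  # monomorphic-in-both variants are excluded and counted
  gm <- cbind(rep(0L, 20), c(rep(0L, 10), rep(1L, 10)))
  com <- toy_cohort(gm)
  com$samples$population <- rep(c("A", "B"), each = 10)
  hf <- hudson_fst(com, "A", "B")
  expect_equal(hf$n_excluded_monomorphic, 1L)
  expect_equal(hf$n_used, 1L)
  # FST matrix is symmetric with zero diagonal
  fm <- fst_matrix(co)
  expect_equal(fm, t(fm))
  expect_equal(diag(fm), c(P1 = 0, P2 = 0))
})

test_that("unweighted GRS counts risk alleles and ranks the enriched population highest", {
  co <- two_pop_cohort(n_per_pop = 10, m = 50, F = 0.1, seed = 68)
  rv <- co$variants[1:10, c("chrom", "pos", "ref", "alt")]
  rv$risk_allele <- co$variants$alt[1:10]
  # homozygous carrier of every risk allele scores 2 * 10
  g <- co$genotypes
  g[1, 1:10] <- 2L
  co_max <- cohort(g, co$variants, co$samples)
  grs <- unweighted_grs(co_max, rv)
  expect_equal(unname(grs$score[1]), 20)
  # all-missing sample scores the sum of population expected dosages
  g2 <- co$genotypes
  g2[2, 1:10] <- NA
  co_miss <- cohort(g2, co$variants, co$samples)
  grs2 <- unweighted_grs(co_miss, rv)
  pop2 <- co$samples$population[2]
  in_pop <- co$samples$population == pop2
  exp_score <- sum(vapply(1:10, function(j)
    2 * mean(g2[in_pop, j], na.rm = TRUE) / 2, numeric(1)))
  expect_equal(unname(grs2$score[2]), exp_score)
  # unmatched risk variants are reported; zero overlap errors
  rv_miss <- rv
  rv_miss$pos <- rv_miss$pos + 100000L
  expect_error(unweighted_grs(co, rv_miss), "overlap")
  rv_half <- rbind(rv, rv_miss)
  expect_equal(nrow(unweighted_grs(co, rv_half)$missing_variants), 10L)
  # a population with elevated risk-allele frequencies ranks highest
  wins <- 0L
  for (r in 1:100) {
    pan <- draw_ancestral_frequencies(
      40, c("HI", "LO"), F_between = 0.05,
      base_spectrum = function(m) rep(0.35, m), seed = 700 + r)
    pan$p[, "HI"] <- pmin(pan$p[, "HI"] + 0.2, 0.99)
    sim <- simulate_admixed_cohort(pan, list(
      population_spec("HI", 25, c(HI = 1, LO = 0)),
      population_spec("LO", 25, c(HI = 0, LO = 1))), seed = 800 + r)
    rvs <- sim$variants[, c("chrom", "pos", "ref", "alt")]
    rvs$risk_allele <- sim$variants$alt
    gr <- unweighted_grs(sim, rvs)
    top <- gr$by_population$population[which.max(gr$by_population$mean)]
    wins <- wins + (top == "HI")
  }
  expect_gt(wins, 95)
})
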