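# Independent oracles and small fixture builders used across the suite.

# Full-enumeration Levene-Haldane exact HWE p-value, computed directly from
# log-factorials (independent of the package's ratio recurrence).
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) +
      lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp)
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Deterministic variant table with exact transition/transversion composition.
exact_class_table <- function(n_ts, n_tv) {
  m <- n_ts + n_tv
  ref <- c(rep("A", n_ts), rep("A", n_tv))
  alt <- c(rep("G", n_ts), rep("C", n_tv))
  variant_table(paste0("chr", rep(1:22, length.out = m)),
                seq_len(m), ref, alt)
}

# Cohort built from an explicit dosage matrix with one population.
toy_cohort <- function(g, population = "POP", ids = NULL) {
  g <- as.matrix(g)
  vt <- simulate_variant_table(ncol(g), seed = 99)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(g)))
  samples <- data.frame(sample_id = ids,
                        population = rep_len(population, nrow(g)),
                        ancestry_group = "native",
                        stringsAsFactors = FALSE)
  cohort(g, vt, samples)
}

# Cohort with prescribed per-variant MAFs, exact by construction: each variant
# gets round(2 * n * maf) heterozygous carriers.
maf_cohort <- function(mafs, n = 500L) {
  g <- sapply(mafs, function(f) {
    k <- round(2 * n * f)
    c(rep(1L, min(k, n)), rep(0L, n - min(k, n)))
  })
  toy_cohort(g)
}

subset_pop <- function(co, pop) co[co$samples$population == pop, ]
subset_one <- function(co) co[1, ]

# Two-population Balding-Nichols cohort for differentiation tests: each
# "ancestry" is one drifted population, individuals are unadmixed.
two_pop_cohort <- function(n_per_pop, m, F, seed) {
  panel <- draw_ancestral_frequencies(m, c("P1", "P2"), F_between = F,
                                      seed = seed)
  pops <- list(
    population_spec("P1", n_per_pop, c(P1 = 1, P2 = 0)),
    population_spec("P2", n_per_pop, c(P1 = 0, P2 = 1))
  )
  simulate_admixed_cohort(panel, pops, seed = seed + 1L)
}
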