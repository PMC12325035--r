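test_that("Balding-Nichols draws have the model's moments and the no-drift limit", {
  flat <- function(m) rep(0.3, m)
  # no-drift limit: population frequencies collapse onto the ancestral one
  p_tiny <- draw_ancestral_frequencies(2000, "A", F_between = 1e-9,
                                       base_spectrum = flat, seed = 4)$p[, 1]
  expect_true(all(abs(p_tiny - 0.3) < 1e-3))
  # closed-form variance F p (1-p) at p=0.3, F=0.1
  p <- draw_ancestral_frequencies(1e5, "A", F_between = 0.1,
                                  base_spectrum = flat, seed = 2)$p[, 1]
  expect_equal(mean(p), 0.3, tolerance = 0.02)
  expect_equal(var(p), 0.1 * 0.3 * 0.7, tolerance = 0.05)
  # determinism and parameter validation
  expect_identical(draw_ancestral_frequencies(100, seed = 9),
                   draw_ancestral_frequencies(100, seed = 9))
  expect_error(draw_ancestral_frequencies(0), "positive")
  expect_error(draw_ancestral_frequencies(10, F_between = 1.2), "\\(0,1\\)")
})

test_that("admixed cohort realizes its admixture proportions", {
  panel <- draw_ancestral_frequencies(500, seed = 1)
  # pure-ancestry population: realized fractions exactly (1,0,0)
  pure <- simulate_admixed_cohort(
    panel, list(population_spec("X", 5, c(NAT = 1, EUR = 0, AFR = 0))),
    seed = 2)
  expect_equal(unname(pure$truth$admixture[, "NAT"]), rep(1, 5))
  # mean dosage at a locus is 2 * sum_k q_k p_k
  pan1 <- draw_ancestral_frequencies(1, c("A", "B", "C"), 0.5, seed = 1)
  pan1$p <- matrix(c(0.5, 0.1, 0.9), 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  co <- simulate_admixed_cohort(
    pan1, list(population_spec("Y", 10000, c(A = 0.6, B = 0.3, C = 0.1))),
    seed = 4)
  expect_equal(mean(co$genotypes), 0.84, tolerance = 0.03)
  # realized ancestry fractions converge on q (>= 1e6 allele draws)
  pan2 <- draw_ancestral_frequencies(5000, seed = 3)
  co2 <- simulate_admixed_cohort(
    pan2, list(population_spec("Z", 120, c(NAT = 0.7, EUR = 0.2, AFR = 0.1))),
    seed = 5)
  expect_equal(unname(colMeans(co2$truth$admixture)), c(0.7, 0.2, 0.1),
               tolerance = 0.03)
  # unknown ancestry in q is a schema error
  expect_error(simulate_admixed_cohort(
    pan2, list(population_spec("W", 3, c(NAT = 0.5, XXX = 0.5)))), "absent")
})

test_that("cohort metadata reports the 8:1 size imbalance", {
  panel <- draw_ancestral_frequencies(50, seed = 1)
  co <- simulate_admixed_cohort(panel, list(
    population_spec("BIG", 80, c(NAT = 0.8, EUR = 0.15, AFR = 0.05)),
    population_spec("SMALL", 10, c(NAT = 0.9, EUR = 0.08, AFR = 0.02))
  ), seed = 7)
  audit <- sample_size_audit(co$samples)
  expect_equal(audit$size_ratio, 8)
  # the shipped default configuration spans 10-80 across 26 populations
  pops <- default_population_specs()
  sizes <- vapply(pops, `[[`, integer(1), "n")
  expect_equal(length(pops), 26L)
  expect_equal(max(sizes) / min(sizes), 8)
  expect_equal(sum(sizes < 30), 11L)
  q <- t(vapply(pops, `[[`, numeric(3), "q"))
  expect_true(all(q[, "NAT"] >= 0.60 & q[, "NAT"] <= 0.95))
  expect_true(all(q[, "EUR"] <= 0.35 & q[, "AFR"] <= 0.10))
})

test_that("array ascertainment keeps discovery-polymorphic variants and depletes target-specific ones", {
  panel <- draw_ancestral_frequencies(4000, seed = 6)
  # force a block of variants monomorphic in EUR but common in NAT
  forced <- 1:200
  panel$p[forced, "EUR"] <- 0
  panel$p[forced, "NAT"] <- 0.4
  co <- simulate_admixed_cohort(panel, list(
    population_spec("P", 60, c(NAT = 0.8, EUR = 0.15, AFR = 0.05))), seed = 8)
  arr0 <- ascertain_array_panel(co, array_design("EUR", 200, maf_cutoff = 0),
                                seed = 3)
  # EUR-monomorphic variants can never enter the panel
  expect_false(any(co$variants$key[forced] %in% arr0$variants$key))
  # cutoff 0 keeps strictly more content than the default cutoff
  arr5 <- ascertain_array_panel(co, array_design("EUR", 200, maf_cutoff = 0.05),
                                seed = 3)
  expect_gt(ncol(arr0$genotypes), ncol(arr5$genotypes))
  expect_true(all(arr5$variants$key %in% arr0$variants$key))
  # capture is lower for variants rare in the cohort than common ones
  maf <- cohort_maf(co)
  captured <- co$variants$key %in% arr5$variants$key
  rare <- maf > 0 & maf < 0.01
  common <- maf > 0.10
  expect_lt(mean(captured[rare]), mean(captured[common]))
  # empty panel errors loudly
  co_mono <- co
  co_mono$truth$panel$p[, "EUR"] <- 0
  expect_error(ascertain_array_panel(co_mono, array_design("EUR", 50)),
               "empty")
})

test_that("error and missingness injection matches its nominal rates", {
  panel <- draw_ancestral_frequencies(2000, seed = 11)
  co <- simulate_admixed_cohort(panel, list(
    population_spec("P", 50, c(NAT = 0.7, EUR = 0.2, AFR = 0.1))), seed = 12)
  # identity when both rates are zero
  expect_identical(inject_errors_and_missingness(co, 0, 0), co)
  # realized missingness within a binomial bound at >= 1e6 genotypes
  big <- simulate_admixed_cohort(
    draw_ancestral_frequencies(20000, seed = 13),
    list(population_spec("P", 60, c(NAT = 0.7, EUR = 0.2, AFR = 0.1))),
    seed = 14)
  big_m <- inject_errors_and_missingness(big, miss_rate = 0.02, err_rate = 0,
                                         seed = 15)
  expect_equal(mean(is.na(big_m$genotypes)), 0.02, tolerance = 0.002 / 0.02)
  # flagged artifact class has the requested Ts/Tv
  vt <- simulate_variant_table(1e6, p_transition = 2.1 / 3.1, seed = 16)
  co_v <- cohort(matrix(0L, 1, 1e6), vt,
                 data.frame(sample_id = "S1", population = "P"))
  co_e <- inject_errors_and_missingness(co_v, 0, err_rate = 0.0059,
                                        R_err = 0.4, seed = 17)
  flagged <- co_e$truth$error_flag
  expect_equal(sum(flagged) / 1e6, 0.0059, tolerance = 0.1)
  r_err <- tstv_ratio(co_e$variants[flagged, ])$ratio
  expect_equal(r_err, 0.4, tolerance = 0.05)
  # parameter validation
  expect_error(inject_errors_and_missingness(co, 0.1, 0.1, R_err = 0), "positive")
  # bit-reproducibility of the full generator chain
  again <- inject_errors_and_missingness(
    simulate_admixed_cohort(panel, list(
      population_spec("P", 50, c(NAT = 0.7, EUR = 0.2, AFR = 0.1))), seed = 12),
    0.01, 0.005, 0.4, seed = 18)
  once <- inject_errors_and_missingness(co, 0.01, 0.005, 0.4, seed = 18)
  expect_identical(once$genotypes, again$genotypes)
  expect_identical(once$variants, again$variants)
})
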