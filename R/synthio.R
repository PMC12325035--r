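#' Draw ancestral allele-frequency panel
#'
#' Draws a base site-frequency spectrum for \code{m} variants, then
#' per-ancestry frequencies under the Balding-Nichols model: given an
#' ancestral frequency p and drift parameter F, population frequencies are
#' Beta(p(1-F)/F, (1-p)(1-F)/F), with mean p and variance F p(1-p). The
#' default base spectrum is Beta(0.2, 0.2) truncated to [0.001, 0.999], which
#' gives the rare-variant excess needed to study array ascertainment without
#' coalescent machinery.
#'
#' @param m number of variants (>= 1).
#' @param ancestries character vector of ancestry labels, e.g.
#'   \code{c("NAT","EUR","AFR")}.
#' @param F_between per-ancestry drift parameter(s) in (0,1); recycled.
#' @param base_spectrum function(m) returning m base frequencies; default the
#'   truncated Beta(0.2, 0.2).
#' @param seed integer RNG seed; identical seeds give identical panels.
#' @return list of class \code{ancestral_panel}: \code{ancestries},
#'   \code{p} (m x K frequency matrix), \code{variants} (a
#'   \code{\link{variant_table}} of synthetic biallelic SNVs).
#' @export
draw_ancestral_frequencies <- function(m, ancestries = c("NAT", "EUR", "AFR"),
                                       F_between = 0.1,
                                       base_spectrum = NULL, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop_invalid("m must be a positive variant count, got %s", format(m))
  m <- as.integer(m)
  K <- length(ancestries)
  if (anyDuplicated(ancestries)) stop_invalid("ancestry labels must be unique")
  F_between <- rep_len(F_between, K)
  if (any(F_between <= 0 | F_between >= 1))
    stop_invalid("F_between must lie strictly in (0,1)")
  with_seed(seed, {
    p0 <- if (is.null(base_spectrum)) {
      pmin(pmax(stats::rbeta(m, 0.2, 0.2), 0.001), 0.999)
    } else {
      base_spectrum(m)
    }
    p <- matrix(NA_real_, m, K, dimnames = list(NULL, ancestries))
    for (k in seq_len(K)) {
      Fk <- F_between[k]
      p[, k] <- stats::rbeta(m, p0 * (1 - Fk) / Fk, (1 - p0) * (1 - Fk) / Fk)
    }
    # rbeta returns exact 0/1 for extreme shapes; keep frequencies proper
    p <- pmin(pmax(p, 0), 1)
    variants <- simulate_variant_table(m, seed = NULL)
    structure(list(ancestries = as.character(ancestries), p = p, p0 = p0,
                   F_between = F_between, variants = variants),
              class = "ancestral_panel")
  })
}

#' Simulate a table of synthetic biallelic SNVs
#'
#' Assigns each variant a transition or transversion ref/alt pair with the
#' given transition probability. Positions are consecutive along synthetic
#' chromosomes of 10,000 sites each (22 chromosome labels cycled), so keys are
#' unique by construction.
#'
#' @param m number of variants.
#' @param p_transition probability a variant is a transition; the genome-wide
#'   default 2/3 of substitution space is overridden by callers that model a
#'   specific Ts/Tv regime.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return a \code{\link{variant_table}} of m biallelic SNVs.
#' @export
simulate_variant_table <- function(m, p_transition = 2 / 3, seed = NULL) {
  draw <- function() {
    is_ts <- stats::runif(m) < p_transition
    ts_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"), ncol = 2,
                       byrow = TRUE)
    tv_pairs <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                         "C", "G", "G", "C", "G", "T", "T", "G"), ncol = 2,
                       byrow = TRUE)
    ref <- alt <- character(m)
    i_ts <- sample.int(4L, sum(is_ts), replace = TRUE)
    ref[is_ts] <- ts_pairs[i_ts, 1]; alt[is_ts] <- ts_pairs[i_ts, 2]
    i_tv <- sample.int(8L, sum(!is_ts), replace = TRUE)
    ref[!is_ts] <- tv_pairs[i_tv, 1]; alt[!is_ts] <- tv_pairs[i_tv, 2]
    chrom_len <- 10000L
    idx <- seq_len(m) - 1L
    chrom <- paste0("chr", (idx %/% chrom_len) %% 22L + 1L)
    pos <- idx %% chrom_len + 1L + (idx %/% (chrom_len * 22L)) * chrom_len
    variant_table(chrom, pos, ref, alt)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Specify a simulated population
#'
#' @param name population label.
#' @param n number of sampled individuals (>= 1).
#' @param q named admixture proportions over the panel's ancestries; must sum
#'   to 1 within 1e-9.
#' @param F within-population drift parameter in (0,1) (reserved; the default
#'   generator drifts at the ancestry level).
#' @param region geographic label.
#' @param altitude_band one of \code{"low"}, \code{"mid"}, \code{"high"}.
#' @param ancestry_group \code{"native"} or \code{"mestizo"}.
#' @return list of class \code{population_spec}.
#' @export
population_spec <- function(name, n, q, F = 0.05, region = "unknown",
                            altitude_band = c("low", "mid", "high"),
                            ancestry_group = c("native", "mestizo")) {
  altitude_band <- match.arg(altitude_band)
  ancestry_group <- match.arg(ancestry_group)
  if (n < 1) stop_invalid("population %s: n must be >= 1", name)
  if (abs(sum(q) - 1) > 1e-9)
    stop_invalid("population %s: admixture proportions sum to %.12f, not 1",
                 name, sum(q))
  if (any(F <= 0 | F >= 1)) stop_invalid("population %s: F outside (0,1)", name)
  structure(list(name = name, n = as.integer(n), q = q, F = F, region = region,
                 altitude_band = altitude_band,
                 ancestry_group = ancestry_group),
            class = "population_spec")
}

#' Default study-like population configuration
#'
#' Twenty-six populations with sample sizes spanning 10-80 (an 8:1 ratio,
#' 15 populations at or above 30 and 11 below), three-way admixture with the
#' Native American component between 0.60 and 0.95, European up to 0.35 and
#' African up to 0.10. Native communities sit at the high-NAT end of the
#' cline, mestizo groups at the low end.
#'
#' @param scale multiply all sample sizes by this factor (sizes are kept
#'   >= 2); useful for reduced-size runs.
#' @return list of \code{\link{population_spec}} objects.
#' @export
default_population_specs <- function(scale = 1) {
  sizes <- c(80, 75, 70, 65, 60, 55, 50, 45, 42, 40, 38, 35, 33, 31, 30,
             28, 25, 22, 20, 18, 16, 14, 12, 11, 10, 10)
  n_pop <- length(sizes)
  # NAT admixture declines along the list: native communities first
  nat <- seq(0.95, 0.60, length.out = n_pop)
  afr <- seq(0.005, 0.10, length.out = n_pop)
  eur <- 1 - nat - afr
  group <- rep(c("native", "mestizo"), c(14, 12))
  region <- rep(c("andes", "amazon", "coast"), length.out = n_pop)
  band <- ifelse(region == "andes", "high", ifelse(region == "amazon", "low", "low"))
  band[region == "coast"] <- "low"
  band[region == "amazon"] <- "mid"
  lapply(seq_len(n_pop), function(i) {
    population_spec(
      name = sprintf("POP%02d", i),
      n = max(2L, as.integer(round(sizes[i] * scale))),
      q = c(NAT = nat[i], EUR = eur[i], AFR = afr[i]),
      F = 0.05,
      region = region[i], altitude_band = band[i], ancestry_group = group[i]
    )
  })
}

#' Simulate an admixed cohort
#'
#' For every individual and locus, each of the two allele copies first picks
#' an ancestry from the population's admixture proportions q, then an allele
#' Bernoulli(p) from that ancestry's panel frequency. Realized per-sample
#' ancestry fractions (over 2m allele draws) are stored in
#' \code{truth$admixture}.
#'
#' @param panel an \code{\link{draw_ancestral_frequencies}} result.
#' @param pops list of \code{\link{population_spec}}.
#' @param seed integer RNG seed.
#' @return a \code{\link{cohort}} with generator truth attached.
#' @export
simulate_admixed_cohort <- function(panel, pops, seed = 1L) {
  stopifnot(inherits(panel, "ancestral_panel"))
  if (length(pops) == 0) stop_invalid("pops must be non-empty")
  if (inherits(pops, "population_spec")) pops <- list(pops)
  m <- nrow(panel$p); K <- length(panel$ancestries)
  for (sp in pops) {
    if (!all(names(sp$q) %in% panel$ancestries))
      stop_invalid("population %s references ancestry absent from panel: %s",
                   sp$name,
                   paste(setdiff(names(sp$q), panel$ancestries), collapse = ","))
  }
  with_seed(seed, {
    geno_list <- vector("list", length(pops))
    meta_list <- vector("list", length(pops))
    admix_list <- vector("list", length(pops))
    for (j in seq_along(pops)) {
      sp <- pops[[j]]
      n <- sp$n
      q <- sp$q[panel$ancestries]
      q[is.na(q)] <- 0
      g <- matrix(0L, n, m)
      frac <- matrix(0, n, K, dimnames = list(NULL, panel$ancestries))
      for (copy in 1:2) {
        anc <- matrix(sample.int(K, n * m, replace = TRUE, prob = q), n, m)
        pmat <- matrix(panel$p[cbind(rep(seq_len(m), each = n), as.vector(anc))],
                       n, m)
        g <- g + (matrix(stats::runif(n * m), n, m) < pmat)
        for (k in seq_len(K)) frac[, k] <- frac[, k] + rowSums(anc == k)
      }
      storage.mode(g) <- "integer"
      geno_list[[j]] <- g
      admix_list[[j]] <- frac / (2 * m)
      meta_list[[j]] <- data.frame(
        sample_id = sprintf("%s_%03d", sp$name, seq_len(n)),
        population = sp$name, ancestry_group = sp$ancestry_group,
        region = sp$region, altitude_band = sp$altitude_band,
        stringsAsFactors = FALSE
      )
    }
    samples <- do.call(rbind, meta_list)
    samples$sex <- sample(c("female", "male"), nrow(samples), replace = TRUE,
                          prob = c(0.333, 0.667))
    samples$age <- sample(18:79, nrow(samples), replace = TRUE)
    samples$bmi_class <- sample(c("normal", "overweight", "obese"),
                                nrow(samples), replace = TRUE,
                                prob = c(0.5, 0.35, 0.15))
    truth <- list(
      admixture = do.call(rbind, admix_list),
      q = do.call(rbind, lapply(pops, function(sp) sp$q[panel$ancestries])),
      panel = panel,
      error_flag = rep(FALSE, m)
    )
    rownames(truth$q) <- vapply(pops, `[[`, "", "name")
    cohort(do.call(rbind, geno_list), panel$variants, samples, truth)
  })
}

#' Design an ascertained SNP array panel
#'
#' @param discovery_ancestry ancestry label of the discovery panel.
#' @param discovery_n number of discovery haplotypes.
#' @param maf_cutoff minimum discovery-sample MAF for inclusion, in [0, 0.5].
#' @return list of class \code{array_design}.
#' @export
array_design <- function(discovery_ancestry = "EUR", discovery_n = 120L,
                         maf_cutoff = 0.05) {
  if (maf_cutoff < 0 || maf_cutoff > 0.5)
    stop_invalid("maf_cutoff must be in [0, 0.5]")
  if (discovery_n < 1) stop_invalid("discovery_n must be >= 1")
  structure(list(discovery_ancestry = discovery_ancestry,
                 discovery_n = as.integer(discovery_n),
                 maf_cutoff = maf_cutoff, panel = NULL),
            class = "array_design")
}

#' Ascertain an array sub-cohort from a simulated cohort
#'
#' Emulates array design against a single-ancestry discovery panel: draws
#' \code{discovery_n} haploid genomes from the discovery ancestry's panel
#' frequencies, keeps variants polymorphic in that sample with discovery MAF
#' at or above the cutoff, and returns the cohort restricted to the retained
#' panel. Variants rare or absent in the discovery ancestry are depleted,
#' reproducing European-array ascertainment against high-Native cohorts.
#'
#' @param cohort a simulated \code{\link{cohort}} (generator truth required).
#' @param design an \code{\link{array_design}}.
#' @param seed integer RNG seed for the discovery draw.
#' @return the array-typed sub-\code{cohort}; the retained panel is attached
#'   as \code{attr(, "design")$panel}.
#' @export
ascertain_array_panel <- function(cohort, design = array_design(), seed = 1L) {
  if (is.null(cohort$truth) || is.null(cohort$truth$panel))
    stop_invalid("ascertainment requires a simulated cohort with truth$panel")
  panel <- cohort$truth$panel
  if (!design$discovery_ancestry %in% panel$ancestries)
    stop_invalid("discovery ancestry %s not in panel (%s)",
                 design$discovery_ancestry,
                 paste(panel$ancestries, collapse = ","))
  p_disc <- panel$p[, design$discovery_ancestry]
  m <- length(p_disc)
  keep <- with_seed(stage_seed(seed, "ascertain_array_panel"), {
    # discovery_n haploid genomes from the discovery ancestry
    alt_count <- stats::rbinom(m, design$discovery_n, p_disc)
    f <- alt_count / design$discovery_n
    maf <- pmin(f, 1 - f)
    f > 0 & f < 1 & maf >= design$maf_cutoff
  })
  if (!any(keep))
    stop_invalid("ascertained panel is empty (discovery_n=%d, maf_cutoff=%g)",
                 design$discovery_n, design$maf_cutoff)
  out <- subset_cohort(cohort, variants = which(keep))
  design$panel <- out$variants
  attr(out, "design") <- design
  out
}

#' Inject genotype missingness and artifact variants
#'
#' Genotypes are set missing i.i.d. at \code{miss_rate}. A fraction
#' \code{err_rate} of variants is flagged as artifact sites and their ref/alt
#' substitution class redrawn so that the artifact class has expected Ts/Tv
#' ratio \code{R_err} (transition with probability R_err/(1+R_err)); artifact
#' call sets have a much lower Ts/Tv than true variation, which is what the
#' downstream mixture error bound exploits. Truth flags are stored in
#' \code{truth$error_flag}.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param miss_rate genotype missingness fraction in [0,1).
#' @param err_rate fraction of variants redrawn as artifacts, in [0,1).
#' @param R_err expected Ts/Tv of the artifact class (> 0).
#' @param seed integer RNG seed.
#' @return the modified \code{cohort}.
#' @export
inject_errors_and_missingness <- function(cohort, miss_rate = 0.01,
                                          err_rate = 0.0059, R_err = 0.4,
                                          seed = 1L) {
  if (miss_rate < 0 || miss_rate >= 1 || err_rate < 0 || err_rate >= 1)
    stop_invalid("miss_rate and err_rate must lie in [0,1)")
  if (R_err <= 0) stop_invalid("R_err must be positive")
  if (miss_rate == 0 && err_rate == 0) return(cohort)
  with_seed(stage_seed(seed, "inject_errors"), {
    g <- cohort$genotypes
    if (miss_rate > 0) {
      drop <- stats::runif(length(g)) < miss_rate
      g[drop] <- NA_integer_
    }
    vt <- cohort$variants
    m <- nrow(vt)
    flag <- stats::runif(m) < err_rate
    if (any(flag)) {
      n_err <- sum(flag)
      err_vt <- simulate_variant_table(n_err,
                                       p_transition = R_err / (1 + R_err))
      vt$ref[flag] <- err_vt$ref
      vt$alt[flag] <- err_vt$alt
      vt$class[flag] <- err_vt$class
      vt$key <- variant_key(vt$chrom, vt$pos, vt$ref, vt$alt)
    }
    truth <- cohort$truth
    if (is.null(truth)) truth <- list()
    truth$error_flag <- flag
    class(vt) <- c("variant_table", "data.frame")
    cohort(g, vt, cohort$samples, truth)
  })
}
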