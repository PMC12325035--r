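#' Default run configuration
#'
#' Parameters for the synthetic end-to-end audit. Every stochastic stage
#' derives its own seed deterministically from the global seed plus the stage
#' name, so stages can be re-run in isolation and still reproduce.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for stage reports.
#' @param m number of simulated variants.
#' @param pop_scale multiplier on the default population sizes.
#' @param stages character vector, an in-order prefix (or subset) of
#'   \code{c("simulate","qc","ascertain","validate","structure")}.
#' @param ... overrides for individual stage parameters (miss_rate, err_rate,
#'   R_err, discovery_n, maf_cutoff, k, B, thresholds).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = "admixaudit_run", m = 50000L,
                       pop_scale = 1,
                       stages = c("simulate", "qc", "ascertain", "validate",
                                  "structure"), ...) {
  known <- c("simulate", "qc", "ascertain", "validate", "structure")
  if (!all(stages %in% known))
    stop_invalid("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", "))
  dots <- list(...)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, m = as.integer(m),
              pop_scale = pop_scale, stages = stages,
              miss_rate = 0.01, err_rate = 0.0059, R_err = 0.4,
              discovery_ancestry = "EUR", discovery_n = 120L,
              maf_cutoff = 0.05, k = 2L, B = 100L,
              thresholds = qc_thresholds())
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file of \code{\link{run_config}} fields.
#' @return list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the synthetic cohort-audit pipeline
#'
#' Executes simulate, qc, ascertain, validate and structure (any subset of
#' that order) under one seeded configuration, writes each stage's report as
#' tab-separated text to the output directory (written atomically: to a
#' temporary file, then renamed), and logs per-stage record counts. The same
#' configuration and seed produce byte-identical reports. When the simulate
#' stage is not selected, a \code{cohort} must be supplied.
#'
#' @param config a \code{\link{run_config}}.
#' @param cohort optional input \code{\link{cohort}} for runs without the
#'   simulate stage.
#' @param quiet suppress log lines.
#' @return invisibly, a list with the final cohort and all stage results.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_stage <- function(stage, msg) {
    line <- sprintf("[%s] stage=%s %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  results <- list()

  if ("simulate" %in% config$stages) {
    pops <- default_population_specs(scale = config$pop_scale)
    panel <- draw_ancestral_frequencies(config$m,
                                        seed = stage_seed(config$seed, "panel"))
    cohort <- simulate_admixed_cohort(panel, pops,
                                      seed = stage_seed(config$seed, "cohort"))
    cohort <- inject_errors_and_missingness(cohort, config$miss_rate,
                                            config$err_rate, config$R_err,
                                            seed = config$seed)
    log_stage("simulate", sprintf("samples=%d variants=%d",
                                  nrow(cohort$genotypes),
                                  ncol(cohort$genotypes)))
    results$cohort_full <- cohort
  }
  if (is.null(cohort))
    stop_invalid("no cohort: include the simulate stage or pass one in")

  if ("qc" %in% config$stages) {
    qc <- variant_qc(cohort, config$thresholds)
    audit <- sample_size_audit(cohort$samples)
    write_tsv_atomic(qc, file.path(config$out_dir, "variant_qc.tsv"))
    write_tsv_atomic(audit_to_df(audit),
                     file.path(config$out_dir, "sample_size_audit.tsv"))
    cohort_qc <- subset_cohort(cohort, variants = which(qc$pass))
    log_stage("qc", sprintf("variants_in=%d variants_pass=%d sample_pass_frac=%.3f",
                            nrow(qc), sum(qc$pass),
                            attr(qc, "sample_pass_fraction")))
    results$qc <- qc
    results$audit <- audit
    cohort <- cohort_qc
  }

  if ("ascertain" %in% config$stages) {
    # compare against the full discovery variant set: the rare variants the
    # QC MAF filter drops are the ones array ascertainment depletes
    wgs_cohort <- if (!is.null(results$cohort_full)) results$cohort_full
                  else cohort
    design <- array_design(config$discovery_ancestry, config$discovery_n,
                           config$maf_cutoff)
    array_cohort <- ascertain_array_panel(wgs_cohort, design,
                                          seed = config$seed)
    spec_rep <- maf_spectrum_distortion(wgs_cohort, array_cohort)
    write_tsv_atomic(spec_rep$table,
                     file.path(config$out_dir, "maf_spectrum.tsv"))
    write_tsv_atomic(spec_rep$capture$by_chrom,
                     file.path(config$out_dir, "capture_by_chrom.tsv"))
    log_stage("ascertain",
              sprintf("wgs_variants=%d array_variants=%d capture=%.4f",
                      ncol(wgs_cohort$genotypes), ncol(array_cohort$genotypes),
                      spec_rep$capture$overall))
    results$array_cohort <- array_cohort
    results$spectrum <- spec_rep
  }

  if ("validate" %in% config$stages) {
    ts <- tstv_ratio(cohort$variants)
    bound <- if (!is.na(ts$ratio))
      error_upper_bound(tstv_model(ts$ratio, R_err = config$R_err)) else NULL
    burden <- burden_stats(cohort)
    vdf <- data.frame(metric = c("tstv", "n_transitions", "n_transversions",
                                 "in_pass_band", "artifact_pct",
                                 "high_confidence_pct", "multiallelic_rate"),
                      value = c(round(ts$ratio, 4), ts$n_transitions,
                                ts$n_transversions, as.integer(ts$in_pass_band),
                                if (is.null(bound)) NA else bound$e_pct,
                                if (is.null(bound)) NA else bound$high_confidence_pct,
                                round(burden$multiallelic_rate, 6)))
    write_tsv_atomic(vdf, file.path(config$out_dir, "validation.tsv"))
    log_stage("validate", sprintf("variants=%d tstv=%.3f",
                                  ncol(cohort$genotypes), ts$ratio))
    results$validation <- list(tstv = ts, error_bound = bound,
                               burden = burden)
  }

  if ("structure" %in% config$stages) {
    pca <- weighted_pca(cohort, k = config$k)
    boot <- stratified_bootstrap_stability(cohort, k = config$k, B = config$B,
                                           seed = config$seed)
    coords <- data.frame(sample_id = rownames(pca$coordinates),
                         population = cohort$samples$population,
                         round(pca$coordinates, 6),
                         stringsAsFactors = FALSE)
    write_tsv_atomic(coords, file.path(config$out_dir, "pca_coordinates.tsv"))
    stab <- data.frame(population = names(boot$cluster_consistency),
                       cluster_consistency = boot$cluster_consistency,
                       stringsAsFactors = FALSE)
    stab$mean_rmsd <- round(boot$mean_rmsd, 6)
    write_tsv_atomic(stab, file.path(config$out_dir, "bootstrap_stability.tsv"))
    log_stage("structure", sprintf("samples=%d components=%d rmsd=%.4f",
                                   nrow(coords), config$k, boot$mean_rmsd))
    results$pca <- pca
    results$bootstrap <- boot
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  results$cohort <- cohort
  invisible(results)
}

audit_to_df <- function(a) {
  data.frame(metric = c("n_populations", "n_below_min", "pct_below_min",
                        "n_below_critical", "pct_below_critical",
                        "size_ratio"),
             value = c(a$n_populations, a$n_below_min, a$pct_below_min,
                       a$n_below_critical, a$pct_below_critical,
                       round(a$size_ratio, 4)))
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
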