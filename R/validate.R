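#' Transition/transversion ratio
#'
#' Counts transitions (A<->G, C<->T) and transversions over SNV alleles.
#' Multiallelic records are decomposed so each alternate allele is classified
#' separately; non-SNV alleles are excluded from the ratio but counted under
#' \code{n_other}. A call set with zero transversions yields an undefined
#' ratio (NA) with the counts still reported.
#'
#' @param variants a \code{\link{variant_table}}.
#' @param pass_band numeric length-2 vector: the Ts/Tv range regarded as
#'   consistent with a high-quality human call set.
#' @return list: \code{ratio} (NA if undefined), \code{n_transitions},
#'   \code{n_transversions}, \code{n_other}, \code{in_pass_band}.
#' @export
tstv_ratio <- function(variants, pass_band = c(2.0, 2.2)) {
  multi <- grepl(",", variants$alt, fixed = TRUE)
  ref <- variants$ref[!multi]
  alt <- variants$alt[!multi]
  if (any(multi)) {
    alts <- strsplit(variants$alt[multi], ",", fixed = TRUE)
    ref <- c(ref, rep(variants$ref[multi], lengths(alts)))
    alt <- c(alt, unlist(alts, use.names = FALSE))
  }
  cls <- substitution_class(ref, alt)
  n_ts <- sum(cls == "transition")
  n_tv <- sum(cls == "transversion")
  if (n_ts + n_tv == 0) stop_invalid("no classified SNV alleles")
  ratio <- if (n_tv == 0) NA_real_ else n_ts / n_tv
  list(ratio = ratio, n_transitions = n_ts, n_transversions = n_tv,
       n_other = sum(cls == "other"),
       in_pass_band = !is.na(ratio) && ratio >= pass_band[1] &&
         ratio <= pass_band[2])
}

#' Ts/Tv mixture error model
#'
#' Treats an observed call set as a mixture of true variants with Ts/Tv ratio
#' \code{R_exp} and artifacts with ratio \code{R_err}; the artifact fraction
#' that reconciles the observed ratio is a conservative upper bound on the
#' call set's error rate. Two modes: \code{ratio-linear} interpolates on the
#' ratio scale, e = (R_exp - R_obs) / (R_exp - R_err); the
#' \code{proportion-mixture} mode mixes on the transition-proportion scale
#' p = R/(1+R), the scale on which site classes actually mix, and solves
#' p_obs = (1-e) p_exp + e p_err.
#'
#' @param R_obs observed Ts/Tv ratio.
#' @param R_exp assumed ratio of true variation (default 2.1, middle of the
#'   high-quality human band).
#' @param R_err assumed ratio of the artifact class (default 0.4; random
#'   sequence errors are transversion-heavy).
#' @param mode \code{"ratio-linear"} (default) or \code{"proportion-mixture"}.
#' @return list of class \code{tstv_model}.
#' @export
tstv_model <- function(R_obs, R_exp = 2.1, R_err = 0.4,
                       mode = c("ratio-linear", "proportion-mixture")) {
  mode <- match.arg(mode)
  if (R_err <= 0 || R_exp <= R_err)
    stop_invalid("require R_exp > R_err > 0 (got R_exp=%g, R_err=%g)",
                 R_exp, R_err)
  structure(list(R_obs = R_obs, R_exp = R_exp, R_err = R_err, mode = mode),
            class = "tstv_model")
}

#' Conservative artifact-fraction upper bound
#'
#' Evaluates the \code{\link{tstv_model}}: the estimated artifact fraction e
#' (clipped to [0,1]; R_obs outside (R_err, R_exp) clips to the boundary) and
#' the high-confidence fraction 1 - e, both also formatted as percentages at
#' two significant figures.
#'
#' @param model a \code{\link{tstv_model}}.
#' @return list: \code{e}, \code{high_confidence}, \code{e_pct},
#'   \code{high_confidence_pct}, \code{mode}.
#' @export
error_upper_bound <- function(model) {
  stopifnot(inherits(model, "tstv_model"))
  R_obs <- min(max(model$R_obs, model$R_err), model$R_exp)
  e <- if (model$mode == "ratio-linear") {
    (model$R_exp - R_obs) / (model$R_exp - model$R_err)
  } else {
    to_p <- function(r) r / (1 + r)
    (to_p(model$R_exp) - to_p(R_obs)) / (to_p(model$R_exp) - to_p(model$R_err))
  }
  e <- min(max(e, 0), 1)
  list(e = e, high_confidence = 1 - e,
       e_pct = pct2(e), high_confidence_pct = pct2(1 - e),
       mode = model$mode)
}

#' @export
print.tstv_model <- function(x, ...) {
  b <- error_upper_bound(x)
  cat(sprintf("<Ts/Tv mixture error model> mode=%s\n", x$mode))
  cat(sprintf("  R_obs=%.3g  R_exp=%.3g  R_err=%.3g\n", x$R_obs, x$R_exp,
              x$R_err))
  cat(sprintf("  artifact fraction <= %.3g%% (high-confidence %.4g%%)\n",
              b$e_pct, b$high_confidence_pct))
  invisible(x)
}

#' Variant and sample burden statistics
#'
#' Per-sample count of non-reference genotypes (dosage >= 1), the fraction of
#' variant records with more than one alternate allele, and totals.
#'
#' @param cohort a \code{\link{cohort}}.
#' @return list: \code{per_sample_burden} (named integer vector),
#'   \code{burden_quantiles}, \code{multiallelic_rate}, \code{n_variants},
#'   \code{n_samples}.
#' @export
burden_stats <- function(cohort) {
  g <- cohort$genotypes
  if (length(g) == 0) stop_invalid("cohort is empty")
  burden <- rowSums(g >= 1L, na.rm = TRUE)
  names(burden) <- cohort$samples$sample_id
  multi <- grepl(",", cohort$variants$alt, fixed = TRUE)
  list(per_sample_burden = burden,
       burden_quantiles = stats::quantile(burden, c(0, 0.25, 0.5, 0.75, 1)),
       multiallelic_rate = mean(multi),
       n_variants = ncol(g), n_samples = nrow(g))
}
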