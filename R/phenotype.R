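#' Length-normalized optical density
#'
#' `median.norm.EXT = median.EXT / median.TOF`: optical density integrated
#' over animal length, normalized by length, so the trait tracks body
#' thickness/complexity rather than size. Lengths must be positive.
#'
#' @param median_EXT optical density values.
#' @param median_TOF animal length values (> 0).
#' @return elementwise quotient.
#' @examples
#' derive_norm_ext(50, 200) # 0.25
#' @export
derive_norm_ext <- function(median_EXT, median_TOF) {
  if (any(!is.finite(median_TOF) | median_TOF <= 0, na.rm = FALSE))
    stopf("median_TOF must be positive and finite")
  median_EXT / median_TOF
}

#' Control-regressed residual trait
#'
#' Removes among-strain differences already present in the control condition
#' by fitting one ordinary-least-squares line of the drug-condition replicate
#' values on the per-strain mean control value
#' (`drug_phenotype ~ mean_control_phenotype`) and returning its residuals.
#' Only drug-specific variation remains: residuals sum to zero and are
#' uncorrelated with the control means. If all control means are equal the
#' regressor is degenerate and an intercept-only model is used (residuals
#' are deviations from the grand drug mean).
#'
#' @param drug_values drug-condition replicate values.
#' @param strain strain label per drug replicate.
#' @param control_means named vector of per-strain control-condition means;
#'   every strain in `strain` must be present.
#' @return numeric residuals, one per drug replicate.
#' @export
regress_control <- function(drug_values, strain, control_means) {
  strain <- as.character(strain)
  miss <- setdiff(unique(strain), names(control_means))
  if (length(miss))
    stopf("strain(s) missing control data: %s", paste(miss, collapse = ", "))
  x <- as.numeric(control_means[strain])
  if (stats::var(x) == 0) {
    drug_values - mean(drug_values)
  } else {
    stats::residuals(stats::lm(drug_values ~ x))
  }
}

#' Affine rescaling to the unit interval
#'
#' Maps the smallest residual value to 0 and the largest to 1, linearly in
#' between (the study's plotting normalization for residual traits).
#'
#' @param x numeric vector with at least two distinct values.
#' @return values in `[0, 1]`.
#' @examples
#' normalize_unit_interval(c(2, 5, 8)) # 0, 0.5, 1
#' @export
normalize_unit_interval <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(diff(r)) || diff(r) == 0)
    stopf("cannot normalize a constant vector to [0, 1]")
  (x - r[1]) / (r[2] - r[1])
}

#' Broad-sense heritability from replicated strain measurements
#'
#' Random-effects decomposition of the trait variance into among-strain
#' (genetic, for inbred strains) and residual components with the model
#' `phenotype ~ 1 + (1 | strain)`, fit by REML via [lme4::lmer()]. `H^2 =
#' var_strain / (var_strain + var_residual)`. For exactly balanced designs
#' `method = "anova"` gives the ANOVA method-of-moments estimator instead
#' (identical in expectation); its negative strain-variance estimates are
#' truncated at zero.
#'
#' @param values replicate trait values.
#' @param strain strain label per value (>= 2 strains).
#' @param method `"reml"` (default) or `"anova"`.
#' @return list with `H2`, `strain_variance`, `residual_variance`.
#' @export
broad_sense_heritability <- function(values, strain, method = c("reml", "anova")) {
  method <- match.arg(method)
  strain <- factor(as.character(strain))
  if (nlevels(strain) < 2) stopf("need >= 2 strains to estimate heritability")
  ok <- !is.na(values)
  values <- values[ok]; strain <- droplevels(strain[ok])
  if (method == "reml") {
    fit <- lme4::lmer(values ~ 1 + (1 | strain),
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vs <- vc$vcov[vc$grp == "strain"]
    ve <- vc$vcov[vc$grp == "Residual"]
  } else {
    # one-way ANOVA method of moments (balanced designs)
    ns <- table(strain)
    if (length(unique(ns)) != 1)
      stopf("method = 'anova' requires a balanced design")
    k <- as.integer(ns[1])
    an <- stats::anova(stats::lm(values ~ strain))
    ms_b <- an$`Mean Sq`[1]; ms_w <- an$`Mean Sq`[2]
    ve <- ms_w
    vs <- max((ms_b - ms_w) / k, 0)
  }
  vs <- max(vs, 0)
  H2 <- if (vs + ve == 0) 0 else vs / (vs + ve)
  list(H2 = min(max(H2, 0), 1), strain_variance = vs, residual_variance = ve)
}

#' Pairwise strain comparisons by Tukey's HSD
#'
#' Fits the one-way ANOVA `phenotype ~ strain` and returns the
#' studentized-range-adjusted p-value for every strain pair as a symmetric
#' matrix (diagonal 1).
#'
#' @param values trait values.
#' @param strain strain label per value (>= 2 strains, >= 2 replicates each
#'   recommended; zero residual variance is an error).
#' @return symmetric matrix of adjusted p-values with strain names on both
#'   dimensions; the raw [stats::TukeyHSD()] table in attribute `"tukey"`.
#' @export
pairwise_strain_comparison <- function(values, strain) {
  strain <- factor(as.character(strain))
  if (nlevels(strain) < 2) stopf("need >= 2 strains")
  fit <- stats::aov(values ~ strain)
  if (stats::deviance(fit) <= 0 || !is.finite(stats::deviance(fit)) ||
      stats::deviance(fit) < .Machine$double.eps * sum(values^2))
    stopf("zero residual variance: pairwise comparison is degenerate")
  tk <- stats::TukeyHSD(fit)$strain
  lev <- levels(strain)
  p <- matrix(1, nlevels(strain), nlevels(strain), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    p[a, b] <- p[b, a] <- tk[i, "p adj"]
  }
  attr(p, "tukey") <- tk
  p
}
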