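#' Causal mediation analysis for a single probe
#'
#' Linear structural-equation decomposition of a QTL's effect on a trait
#' into a component transmitted through a mediator (gene expression) and a
#' direct component, from three OLS fits:
#'
#' 1. mediator model `expression ~ genotype` (slope `a`),
#' 2. outcome model `phenotype ~ expression + genotype` (expression slope
#'    `b`, genotype slope `c'`),
#' 3. total model `phenotype ~ genotype` (slope `c`).
#'
#' The indirect (mediated) effect is `a * b`, the direct effect `c'`, the
#' total effect `c`, and `c = c' + a * b` holds exactly by OLS algebra. The
#' mediated proportion `a * b / c` is reported but is not interpretable
#' outside `[0, 1]` (inconsistent mediation), so it is never used for
#' ranking. Inference is by nonparametric bootstrap: lines are resampled
#' with replacement `n_boot` times, the indirect effect recomputed, and the
#' two-sided p-value is `2 * min(frac <= 0, frac >= 0)` with a half-count
#' correction for finite resamples.
#'
#' @param genotype 0/1 genotype vector at the QTL peak (both classes must be
#'   present).
#' @param mediator expression values of the candidate mediator probe.
#' @param phenotype trait values.
#' @param n_boot bootstrap resamples (default 1000; 0 skips inference).
#' @param seed RNG seed for the bootstrap.
#' @return a `mediation_fit` list: `total_effect`, `direct_effect`,
#'   `indirect_effect`, `mediated_proportion`, `a`, `b`, `p_value`,
#'   `ci_lower`, `ci_upper` (percentile 95% CI), `n_boot`, `n`, `seed`.
#' @export
mediate <- function(genotype, mediator, phenotype, n_boot = 1000, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", min = 0L)
  if (length(mediator) != length(genotype) ||
      length(phenotype) != length(genotype))
    stopf("genotype, mediator and phenotype must be aligned on the same lines")
  cc <- stats::complete.cases(genotype, mediator, phenotype)
  g <- as.numeric(genotype[cc]); m <- as.numeric(mediator[cc])
  y <- as.numeric(phenotype[cc])
  if (length(unique(g)) < 2) stopf("genotype has a single class: degenerate design")
  if (stats::var(m) == 0) stopf("mediator has zero variance: degenerate")
  est <- mediation_effects(g, m, y)
  boot <- numeric(0); p <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(check_count(seed, "seed", min = 0L))
    n <- length(g)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      gi <- g[idx]
      if (length(unique(gi)) < 2 || stats::var(m[idx]) == 0) return(NA_real_)
      mediation_effects(gi, m[idx], y[idx])["indirect"]
    }, numeric(1))
    boot <- boot[!is.na(boot)]
    B <- length(boot)
    p <- min(1, 2 * min((sum(boot <= 0) + 0.5) / (B + 1),
                        (sum(boot >= 0) + 0.5) / (B + 1)))
    ci <- as.numeric(stats::quantile(boot, c(0.025, 0.975), names = FALSE))
  }
  structure(list(
    total_effect = unname(est["total"]),
    direct_effect = unname(est["direct"]),
    indirect_effect = unname(est["indirect"]),
    mediated_proportion = unname(est["proportion"]),
    a = unname(est["a"]), b = unname(est["b"]),
    p_value = p, ci_lower = ci[1], ci_upper = ci[2],
    n_boot = n_boot, n = length(g), seed = seed,
    boot_indirect = boot
  ), class = "mediation_fit")
}

# Closed-form OLS slopes for the three mediation regressions.
mediation_effects <- function(g, m, y) {
  a <- stats::cov(g, m) / stats::var(g)
  cfit <- stats::lm.fit(cbind(1, m, g), y)$coefficients
  b <- cfit[2]; c_prime <- cfit[3]
  total <- stats::cov(g, y) / stats::var(g)
  c(a = a, b = unname(b), direct = unname(c_prime), indirect = a * unname(b),
    total = total,
    proportion = if (total != 0) a * unname(b) / total else NA_real_)
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Mediation fit (n = %d):\n",
           "  total effect     %8.4f\n  direct effect    %8.4f\n",
           "  indirect effect  %8.4f"),
    x$n, x$total_effect, x$direct_effect, x$indirect_effect))
  if (!is.na(x$p_value))
    cat(sprintf("  [95%% CI %.4f, %.4f], bootstrap p = %.4g (%d resamples)",
                x$ci_lower, x$ci_upper, x$p_value, x$n_boot))
  cat(sprintf("\n  mediated proportion %.3f%s\n", x$mediated_proportion,
              if (!is.na(x$mediated_proportion) &&
                  (x$mediated_proportion < 0 || x$mediated_proportion > 1))
                " (inconsistent mediation: not interpretable)" else ""))
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  data.frame(total_effect = object$total_effect,
             direct_effect = object$direct_effect,
             indirect_effect = object$indirect_effect,
             mediated_proportion = object$mediated_proportion,
             p_value = object$p_value, ci_lower = object$ci_lower,
             ci_upper = object$ci_upper, n = object$n, n_boot = object$n_boot)
}

#' Rank candidate mediator probes for one QTL and trait
#'
#' Runs [mediate()] for every candidate probe against the genotype at the
#' QTL peak marker, ranks probes by the absolute indirect effect, and flags
#' probes at or above the 90th percentile of that distribution as
#' prioritized candidates. The percentile of a probe is the fraction of
#' candidates with strictly smaller `|indirect|` (so with distinct scores at
#' most `ceiling(0.1 * n)` probes are flagged). Per-probe bootstrap seeds
#' are derived deterministically from `seed`, so results do not depend on
#' evaluation order.
#'
#' @param panel a `genotype_panel`.
#' @param qtl_marker marker id of the QTL peak.
#' @param expression lines x probes matrix restricted to (or containing) the
#'   candidate probes.
#' @param candidate_probes character vector of probe ids to test.
#' @param phenotype trait vector aligned to the panel.
#' @param n_boot bootstrap resamples per probe.
#' @param percentile_cut prioritization percentile (default 90).
#' @param seed master seed.
#' @return a `mediation_ranking` data frame sorted by decreasing
#'   `|indirect|`: probe_id, total/direct/indirect effects, mediated
#'   proportion, p_value, abs_indirect, percentile, prioritized.
#' @export
mediate_panel <- function(panel, qtl_marker, expression, candidate_probes,
                          phenotype, n_boot = 1000, percentile_cut = 90,
                          seed = 1L) {
  if (length(candidate_probes) == 0) stopf("empty candidate probe set")
  expression <- align_expression(panel, expression)
  miss <- setdiff(candidate_probes, colnames(expression))
  if (length(miss))
    stopf("candidate probe(s) absent from expression: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  g <- drop(genotype_at(panel, qtl_marker))
  y <- align_trait(panel, phenotype)
  fits <- lapply(seq_along(candidate_probes), function(i) {
    mediate(g, expression[, candidate_probes[i]], y, n_boot = n_boot,
            seed = derive_seed(seed, i))
  })
  out <- do.call(rbind, lapply(fits, summary))
  out <- data.frame(probe_id = candidate_probes, out, stringsAsFactors = FALSE)
  out$abs_indirect <- abs(out$indirect_effect)
  n <- nrow(out)
  out$percentile <- vapply(out$abs_indirect,
                           function(s) 100 * sum(out$abs_indirect < s) / n,
                           numeric(1))
  out$prioritized <- out$percentile >= percentile_cut
  out <- out[order(-out$abs_indirect), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mediation_ranking", "data.frame")
  out
}

#' @export
print.mediation_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Mediation ranking: %d candidate probes, %d prioritized (>= 90th pct)\n",
              nrow(x), sum(x$prioritized)))
  print.data.frame(utils::head(
    x[, c("probe_id", "indirect_effect", "direct_effect", "total_effect",
          "p_value", "percentile", "prioritized")], n),
    digits = 4, row.names = FALSE)
  invisible(x)
}
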