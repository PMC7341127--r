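#' Annotate a detected QTL
#'
#' Builds the QTL record for a peak marker on a completed scan: the 95%
#' confidence interval by a LOD drop from the peak (default 1.5), variance
#' explained from the closed form `1 - 10^(-2 * peak_LOD / n)`, and the
#' allelic effect as the difference of genotype-class phenotype means
#' (parent-B minus parent-A).
#'
#' The interval walks outward from the peak along its chromosome; each bound
#' is the first ("proximal") marker whose LOD falls strictly below
#' `peak_LOD - drop`, included as the bound, or the terminal marker if the
#' chromosome end is reached first.
#'
#' @param scan a `lod_scan`.
#' @param peak_marker marker id of the peak (must be on the scan).
#' @param panel the `genotype_panel` the scan was computed on (for allelic
#'   effects).
#' @param trait the trait vector the scan was computed on.
#' @param threshold significance threshold to record alongside the peak.
#' @param drop LOD drop defining the confidence interval (default 1.5).
#' @return one-row `qtl_table` data frame: trait, peak_marker, chromosome,
#'   genetic_pos, physical_pos, peak_lod, threshold, ci_left, ci_right,
#'   var_expl, allelic_effect, parent_of_high_trait.
#' @export
annotate_qtl <- function(scan, peak_marker, panel, trait, threshold = NA_real_,
                         drop = 1.5) {
  i <- match(peak_marker, scan$marker_id)
  if (is.na(i)) stopf("peak marker '%s' not on scan", peak_marker)
  chr <- scan$chromosome[i]
  on_chr <- which(scan$chromosome == chr)
  pos_in_chr <- match(i, on_chr)
  lods <- scan$lod[on_chr]
  cutoff <- scan$lod[i] - drop
  below <- !is.na(lods) & lods < cutoff
  left <- pos_in_chr; right <- pos_in_chr
  while (left > 1 && !below[left - 1]) left <- left - 1
  if (left > 1) left <- left - 1            # include first below-cutoff marker
  while (right < length(on_chr) && !below[right + 1]) right <- right + 1
  if (right < length(on_chr)) right <- right + 1
  trait_v <- align_trait(panel, trait)
  g <- drop(genotype_at(panel, peak_marker))
  effect <- mean(trait_v[g == 1L], na.rm = TRUE) - mean(trait_v[g == 0L], na.rm = TRUE)
  out <- data.frame(
    trait = attr(trait, "trait_name") %||% "trait",
    peak_marker = peak_marker,
    chromosome = as.character(chr),
    genetic_pos = scan$genetic_pos[i],
    physical_pos = scan$physical_pos[i],
    peak_lod = scan$lod[i],
    threshold = threshold,
    ci_left = scan$marker_id[on_chr[left]],
    ci_right = scan$marker_id[on_chr[right]],
    var_expl = variance_explained_from_lod(scan$lod[i], scan$n[i]),
    allelic_effect = effect,
    parent_of_high_trait = if (is.na(effect)) NA_character_ else if (effect >= 0) "B" else "A",
    stringsAsFactors = FALSE
  )
  class(out) <- c("qtl_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward-search QTL mapping with marker cofactors
#'
#' Iterative genome scan: the marker with the highest LOD above the
#' genome-wide permutation threshold is recorded as a QTL and absorbed as a
#' cofactor — the trait is residualized by OLS on the genotype columns of all
#' recorded peaks — and the residuals are rescanned. Iteration stops when no
#' marker exceeds the threshold or `max_qtl` QTL have been recorded. Each QTL
#' is annotated on the scan of the iteration that detected it.
#'
#' The threshold is computed once on the original trait and reused across
#' iterations (a single genome-wide error rate per trait); set
#' `recompute_threshold = TRUE` to re-permute the residualized trait at each
#' iteration instead.
#'
#' @param panel a `genotype_panel`.
#' @param trait numeric trait vector aligned to the panel.
#' @param n_perm,alpha,seed permutation-threshold parameters
#'   (see [permutation_threshold()]).
#' @param max_qtl maximum number of QTL to record.
#' @param drop LOD drop for confidence intervals.
#' @param recompute_threshold recompute the permutation threshold on each
#'   iteration's residualized trait.
#' @return a `qtl_table` (zero rows if nothing is significant) with the
#'   per-iteration scans in attribute `"scans"` and the threshold in
#'   attribute `"threshold"`.
#' @export
forward_search <- function(panel, trait, n_perm = 1000, alpha = 0.05,
                           max_qtl = 10, drop = 1.5, seed = 1L,
                           recompute_threshold = FALSE) {
  trait_name <- attr(trait, "trait_name") %||% "trait"
  y <- align_trait(panel, trait)
  max_qtl <- check_count(max_qtl, "max_qtl")
  thr <- permutation_threshold(panel, y, n_perm, alpha, seed = seed)
  peaks <- character(0)
  qtl <- list()
  scans <- list()
  current <- y
  for (iter in seq_len(max_qtl)) {
    scan <- lod_scan(panel, current)
    scans[[iter]] <- scan
    if (all(is.na(scan$lod))) break
    best <- which(scan$lod == max(scan$lod, na.rm = TRUE))
    best <- best[1] # ties: lowest genomic coordinate (scan is genome-ordered)
    use_thr <- if (recompute_threshold && iter > 1)
      permutation_threshold(panel, current, n_perm, alpha,
                            seed = derive_seed(seed, iter)) else thr
    if (scan$lod[best] <= use_thr) break
    pk <- scan$marker_id[best]
    ann <- annotate_qtl(scan, pk, panel, structure(current, trait_name = trait_name),
                        threshold = as.numeric(use_thr), drop = drop)
    qtl[[length(qtl) + 1L]] <- ann
    peaks <- c(peaks, pk)
    # residualize the ORIGINAL trait on all selected peaks (drop collinear)
    X <- genotype_at(panel, peaks)
    keep <- !duplicated(t(X))
    if (!all(keep)) warning("collinear cofactor marker(s) dropped")
    X1 <- cbind(1, X[, keep, drop = FALSE])
    cc <- stats::complete.cases(X1, y)
    res <- rep(NA_real_, length(y))
    res[cc] <- stats::lm.fit(X1[cc, , drop = FALSE], y[cc])$residuals
    current <- res
  }
  out <- if (length(qtl)) do.call(rbind, qtl) else
    annotate_empty_qtl_table(trait_name)
  class(out) <- c("qtl_table", "data.frame")
  attr(out, "scans") <- scans
  attr(out, "threshold") <- as.numeric(thr)
  out
}

annotate_empty_qtl_table <- function(trait_name) {
  data.frame(trait = character(0), peak_marker = character(0),
             chromosome = character(0), genetic_pos = numeric(0),
             physical_pos = numeric(0), peak_lod = numeric(0),
             threshold = numeric(0), ci_left = character(0),
             ci_right = character(0), var_expl = numeric(0),
             allelic_effect = numeric(0), parent_of_high_trait = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.qtl_table <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("No significant QTL.\n")
    return(invisible(x))
  }
  cat(sprintf("%d QTL (threshold %.2f):\n", nrow(x),
              attr(x, "threshold") %||% x$threshold[1]))
  print.data.frame(x[, c("trait", "peak_marker", "chromosome", "genetic_pos",
                         "peak_lod", "ci_left", "ci_right", "var_expl",
                         "allelic_effect")], digits = 4, row.names = FALSE)
  invisible(x)
}
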