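#' Genome-wide permutation significance threshold
#'
#' Trait values are permuted across lines `n_perm` times; each permutation is
#' rescanned and its genome-wide maximum LOD recorded. The threshold is the
#' empirical `1 - alpha` quantile of those maxima, i.e. the LOD exceeded by
#' chance in a fraction `alpha` of null genomes. With `n_perm = 1000` and
#' `alpha = 0.05` this is the conventional 5% genome-wide error rate.
#'
#' All permutations are scanned in one blocked correlation product, so the
#' cost is a single markers-by-permutations matrix multiply when the panel
#' has no missing genotypes.
#'
#' @param panel a `genotype_panel`.
#' @param trait numeric trait vector aligned to the panel.
#' @param n_perm number of permutations (warns below 100).
#' @param alpha genome-wide error rate.
#' @param seed RNG seed.
#' @return the threshold (single number), with the vector of per-permutation
#'   maxima in attribute `"max_lods"`.
#' @export
permutation_threshold <- function(panel, trait, n_perm = 1000, alpha = 0.05,
                                  seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100)
    warning("fewer than 100 permutations gives unstable quantiles")
  alpha <- check_fraction(alpha, "alpha")
  trait <- align_trait(panel, trait)
  set.seed(check_count(seed, "seed", min = 0L))
  ok <- !is.na(trait)
  G <- panel$genotypes
  # permute observed trait values across all lines (missing stay missing)
  P <- replicate(n_perm, { p <- trait; p[ok] <- sample(trait[ok]); p })
  blk <- lod_block(G, P)
  maxima <- apply(blk$lod, 2, max, na.rm = TRUE)
  # a 0% genome-wide error rate is unattainable from finite permutations
  thr <- if (alpha == 0) Inf
         else as.numeric(stats::quantile(maxima, 1 - alpha, names = FALSE))
  attr(thr, "max_lods") <- maxima
  thr
}
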