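#' Simulate RIAIL genotype mosaics
#'
#' Each line's chromosome is a two-parent mosaic built under the Haldane
#' (no-interference) model: the starting allele is Bernoulli(0.5), the
#' crossover count is Poisson with mean `map_expansion * chrom_length_cM /
#' 100`, breakpoint positions are uniform in genetic distance, and the allele
#' alternates at each breakpoint. `map_expansion > 1` emulates the denser
#' breakpoint structure of advanced-intercross panels relative to a single
#' meiosis. Alleles are coded 0 (parent A) and 1 (parent B).
#'
#' @param map a [marker_map()].
#' @param n_lines number of inbred lines (>= 2).
#' @param map_expansion crossover-intensity multiplier (>= 0; default 4,
#'   an advanced-intercross-like expansion).
#' @param seed RNG seed; identical seeds give bit-identical panels.
#' @return a `genotype_panel`: list with `genotypes` (lines x markers integer
#'   matrix in \{0, 1\}, `NA` allowed for missing) and `map`.
#' @examples
#' map <- generate_marker_map(2, 20, 50)
#' panel <- simulate_riail_genotypes(map, n_lines = 50, seed = 1)
#' dim(panel$genotypes)
#' @export
simulate_riail_genotypes <- function(map, n_lines, map_expansion = 4, seed = 1L) {
  if (!inherits(map, "marker_map")) stopf("`map` must be a marker_map")
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  if (!is.numeric(map_expansion) || length(map_expansion) != 1L || map_expansion < 0)
    stopf("`map_expansion` must be a single number >= 0")
  set.seed(check_count(seed, "seed", min = 0L))
  chroms <- levels(map$chromosome)
  geno <- matrix(NA_integer_, n_lines, nrow(map))
  colnames(geno) <- map$marker_id
  rownames(geno) <- sprintf("L%04d", seq_len(n_lines))
  for (chr in chroms) {
    idx <- which(map$chromosome == chr)
    pos <- map$genetic_pos[idx]
    len <- max(pos) - min(pos)
    lambda <- map_expansion * len / 100
    for (i in seq_len(n_lines)) {
      start <- stats::rbinom(1L, 1L, 0.5)
      k <- stats::rpois(1L, lambda)
      if (k == 0L) {
        geno[i, idx] <- start
      } else {
        bp <- sort(stats::runif(k, min(pos), max(pos)))
        # allele flips at each breakpoint: parity of breakpoints left of marker
        n_before <- findInterval(pos, bp)
        geno[i, idx] <- (start + n_before) %% 2L
      }
    }
  }
  structure(list(genotypes = geno, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  g <- x$genotypes
  af <- colMeans(g, na.rm = TRUE)
  cat(sprintf("RIAIL genotype panel: %d lines x %d markers, %d chromosome(s)\n",
              nrow(g), ncol(g), nlevels(x$map$chromosome)))
  cat(sprintf("  parent-B allele frequency: %.3f-%.3f (median %.3f)\n",
              min(af), max(af), stats::median(af)))
  if (anyNA(g))
    cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(g))))
  invisible(x)
}

# Genotype codes at a set of markers, lines x markers, by marker id.
genotype_at <- function(panel, marker_ids) {
  miss <- setdiff(marker_ids, colnames(panel$genotypes))
  if (length(miss))
    stopf("marker(s) not in panel: %s", paste(miss, collapse = ", "))
  panel$genotypes[, marker_ids, drop = FALSE]
}
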