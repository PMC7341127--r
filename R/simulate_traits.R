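#' Simulate a quantitative trait with planted QTL
#'
#' The genetic value of each line is the sum of additive allele effects at
#' the named markers (0/1 coding); Gaussian noise is added with a standard
#' deviation chosen so the genetic fraction of the trait variance matches
#' `heritability_target`:
#' `sigma_e^2 = var(g) * (1 - h2) / h2`, using the realized genetic variance
#' across the panel. With no QTL (or `h2 = 0`) the trait is standard-normal
#' noise; with `h2 = 1` it is the noise-free genetic value.
#'
#' @param panel a `genotype_panel`.
#' @param qtl_effects named numeric vector: names are marker ids, values the
#'   additive effect of the parent-B allele. May be empty.
#' @param heritability_target fraction of trait variance that is genetic.
#' @param seed RNG seed.
#' @return numeric trait vector, one value per line, named by line id.
#' @export
simulate_trait <- function(panel, qtl_effects = numeric(0),
                           heritability_target = 0.5, seed = 1L) {
  h2 <- check_fraction(heritability_target, "heritability_target")
  set.seed(check_count(seed, "seed", min = 0L))
  n <- nrow(panel$genotypes)
  if (length(qtl_effects) == 0 || h2 == 0) {
    y <- stats::rnorm(n)
  } else {
    g <- drop(genotype_at(panel, names(qtl_effects)) %*% qtl_effects)
    vg <- stats::var(g)
    if (vg == 0) stopf("planted QTL are monomorphic in this panel")
    y <- if (h2 == 1) g else g + stats::rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
  }
  names(y) <- rownames(panel$genotypes)
  y
}

#' Simulate an expression panel with local eQTL and a regulatory hotspot
#'
#' Probes fall in three classes. Local probes sit within 1 Mb of a randomly
#' chosen causal marker on the same chromosome and their expression is driven
#' by that marker. Hotspot probes are driven by a single shared regulatory
#' locus (`hotspot_locus`) but are placed far from it (different chromosome),
#' so their eQTL are distant and pile into the hotspot's bin. Remaining
#' probes are pure noise with random genomic positions. Expression noise is
#' standard normal, so `effect_size` is in within-genotype SD units.
#'
#' @param panel a `genotype_panel`.
#' @param n_probes total probes to simulate.
#' @param local_fraction fraction of probes with a local eQTL.
#' @param hotspot_locus marker id of the shared regulatory locus.
#' @param n_hotspot_genes number of probes driven by `hotspot_locus`
#'   (must be <= `n_probes` after local probes are allocated).
#' @param effect_size additive allele effect for causal probes, in noise-SD
#'   units; a single value or a function(n) drawing n effects.
#' @param seed RNG seed.
#' @return list with `expression` (lines x probes matrix),
#'   `probe_positions` (data frame: probe_id, chromosome, start_bp) and
#'   `truth` (probe_id, class, causal_marker, effect).
#' @export
simulate_expression_panel <- function(panel, n_probes = 500, local_fraction = 0.2,
                                      hotspot_locus = NULL, n_hotspot_genes = 0,
                                      effect_size = 0.8, seed = 1L) {
  n_probes <- check_count(n_probes, "n_probes")
  local_fraction <- check_fraction(local_fraction, "local_fraction")
  n_hotspot_genes <- check_count(n_hotspot_genes, "n_hotspot_genes", min = 0L)
  map <- panel$map
  n_local <- round(local_fraction * n_probes)
  if (n_hotspot_genes + n_local > n_probes)
    stopf("n_hotspot_genes + local probes exceed n_probes")
  if (n_hotspot_genes > 0) {
    if (is.null(hotspot_locus)) stopf("`hotspot_locus` required when n_hotspot_genes > 0")
    if (!hotspot_locus %in% map$marker_id)
      stopf("hotspot_locus '%s' not in marker map", hotspot_locus)
  }
  set.seed(check_count(seed, "seed", min = 0L))
  n_lines <- nrow(panel$genotypes)
  draw_effect <- if (is.function(effect_size)) effect_size
                 else function(n) rep(effect_size, n)

  classes <- rep(c("local", "hotspot", "null"),
                 c(n_local, n_hotspot_genes, n_probes - n_local - n_hotspot_genes))
  probe_id <- sprintf("P%05d", seq_len(n_probes))
  chrom <- character(n_probes); start <- numeric(n_probes)
  causal <- rep(NA_character_, n_probes); eff <- rep(0, n_probes)
  expr <- matrix(stats::rnorm(n_lines * n_probes), n_lines, n_probes,
                 dimnames = list(rownames(panel$genotypes), probe_id))

  chrom_max_bp <- tapply(map$physical_pos, map$chromosome, max)

  li <- which(classes == "local")
  if (length(li)) {
    cm <- sample(nrow(map), length(li), replace = TRUE)
    causal[li] <- map$marker_id[cm]
    chrom[li] <- as.character(map$chromosome[cm])
    # probe start within 1 Mb of its causal marker, clamped to the chromosome
    start[li] <- pmax(1, pmin(map$physical_pos[cm] +
                                round(stats::runif(length(li), -1e6, 1e6)),
                              chrom_max_bp[chrom[li]]))
    eff[li] <- draw_effect(length(li))
    expr[, li] <- expr[, li] + genotype_at(panel, causal[li]) *
      rep(eff[li], each = n_lines)
  }
  hi <- which(classes == "hotspot")
  if (length(hi)) {
    hchr <- as.character(map$chromosome[map$marker_id == hotspot_locus])
    other <- setdiff(levels(map$chromosome), hchr)
    if (length(other) == 0)
      stopf("hotspot probes need a chromosome other than the hotspot's")
    chrom[hi] <- sample(other, length(hi), replace = TRUE)
    start[hi] <- ceiling(stats::runif(length(hi)) * chrom_max_bp[chrom[hi]])
    causal[hi] <- hotspot_locus
    eff[hi] <- draw_effect(length(hi))
    expr[, hi] <- expr[, hi] + genotype_at(panel, rep(hotspot_locus, length(hi))) *
      rep(eff[hi], each = n_lines)
  }
  ni <- which(classes == "null")
  if (length(ni)) {
    chrom[ni] <- sample(levels(map$chromosome), length(ni), replace = TRUE)
    start[ni] <- ceiling(stats::runif(length(ni)) * chrom_max_bp[chrom[ni]])
  }

  list(
    expression = expr,
    probe_positions = data.frame(probe_id = probe_id, chromosome = chrom,
                                 start_bp = start, stringsAsFactors = FALSE),
    truth = data.frame(probe_id = probe_id, class = classes,
                       causal_marker = causal, effect = eff,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a drug trait mediated by gene expression
#'
#' Structural model: `mediator = a * genotype + e_m`,
#' `phenotype = b * mediator + c_prime * genotype + e_y`, with independent
#' Gaussian errors of standard deviation `noise_sd`. The ground-truth
#' indirect effect is `a * b` and the total effect `a * b + c_prime`. Pass a
#' pre-simulated `mediator_expression` vector to reuse an expression probe as
#' the mediator (its generating `a` is then implicit in the data).
#'
#' @param panel a `genotype_panel`.
#' @param qtl_marker marker id of the causal locus.
#' @param mediator_expression optional mediator vector aligned to panel
#'   lines; if `NULL` the mediator is simulated from `a`.
#' @param a genotype-to-mediator effect (used when simulating the mediator).
#' @param b mediator-to-phenotype effect.
#' @param c_prime direct genotype-to-phenotype effect.
#' @param noise_sd error SD for both equations.
#' @param seed RNG seed.
#' @return list with `phenotype` and `mediator` vectors (named by line) and
#'   `truth` (a, b, c_prime, indirect, total).
#' @export
simulate_mediated_trait <- function(panel, qtl_marker, mediator_expression = NULL,
                                    a = 0.8, b = 0.5, c_prime = 0.2,
                                    noise_sd = 0.5, seed = 1L) {
  set.seed(check_count(seed, "seed", min = 0L))
  g <- drop(genotype_at(panel, qtl_marker))
  n <- length(g)
  if (is.null(mediator_expression)) {
    m <- a * g + stats::rnorm(n, sd = noise_sd)
  } else {
    if (length(mediator_expression) != n)
      stopf("mediator_expression length %d != %d lines",
            length(mediator_expression), n)
    m <- as.numeric(mediator_expression)
  }
  y <- b * m + c_prime * g + stats::rnorm(n, sd = noise_sd)
  names(y) <- names(m) <- rownames(panel$genotypes)
  list(phenotype = y, mediator = m,
       truth = list(a = a, b = b, c_prime = c_prime,
                    indirect = a * b, total = a * b + c_prime))
}
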