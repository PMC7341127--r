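#' Default configuration for the end-to-end synthetic study replica
#'
#' Returns the full parameter list consumed by [run_pipeline()]. Defaults
#' describe a desk-scale replica of a RIAIL drug-response study: 300 lines
#' genotyped at 600 markers on 6 chromosomes, 500 expression probes with 20%
#' local eQTL and a 50-gene regulatory hotspot, and one drug trait whose QTL
#' effect is partly mediated by the expression of a hotspot gene.
#'
#' @param ... named overrides of any default element.
#' @return named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_chromosomes = 6, markers_per_chromosome = 100, chrom_length_cM = 50,
    bp_per_cM = 40000, n_lines = 300, map_expansion = 4,
    n_probes = 500, local_fraction = 0.2, n_hotspot_genes = 50,
    hotspot_marker = "MV_050", eqtl_effect_size = 0.8,
    mediation_a = 0.8, mediation_b = 0.5, mediation_c_prime = 0.2,
    mediation_noise_sd = 0.5,
    n_perm = 1000, alpha = 0.05, n_perm_fdr = 10, target_fdr = 0.05,
    bin_cM = 5, hotspot_percentile = 0.99, lod_floor = NULL,
    n_boot = 1000, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full synthetic study replica
#'
#' Orchestrates the analysis chain end to end on simulated data with known
#' ground truth: simulate a RIAIL panel, an expression panel with a planted
#' regulatory hotspot, and a mediated drug trait; map the drug trait by
#' forward search; map the expression panel with a permutation-FDR
#' threshold; detect eQTL hotspots; and run mediation across the hotspot's
#' candidate probes at the detected drug QTL. Per-stage seeds are derived
#' from the master seed with [derive_seed()], so the run is bit-reproducible
#' and adding stages never perturbs earlier streams.
#'
#' @param config list from [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's inputs and
#'   outputs are written as TSV plus a `manifest` TSV of row counts, seeds
#'   and parameters.
#' @param quiet suppress stage progress messages.
#' @return list with `panel`, `expression` (simulation output), `drug_trait`,
#'   `qtl` (qtl_table), `eqtl` (eqtl_table), `eqtl_threshold`, `hotspots`
#'   (hotspot_scan), `mediation` (mediation_ranking or NULL), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  validate_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  seeds <- derive_seed(config$seed, 1:8)

  say("stage 1/6: simulating marker map and %d RIAIL genotypes", config$n_lines)
  map <- generate_marker_map(config$n_chromosomes, config$markers_per_chromosome,
                             config$chrom_length_cM, config$bp_per_cM)
  panel <- simulate_riail_genotypes(map, config$n_lines, config$map_expansion,
                                    seed = seeds[1])

  say("stage 2/6: simulating %d-probe expression panel (hotspot at %s)",
      config$n_probes, config$hotspot_marker)
  expr <- simulate_expression_panel(panel, config$n_probes,
                                    config$local_fraction,
                                    config$hotspot_marker,
                                    config$n_hotspot_genes,
                                    config$eqtl_effect_size, seed = seeds[2])

  say("stage 3/6: simulating mediated drug trait")
  mediator_probe <- expr$truth$probe_id[expr$truth$class == "hotspot"][1]
  med <- simulate_mediated_trait(
    panel, config$hotspot_marker,
    mediator_expression = if (!is.na(mediator_probe))
      expr$expression[, mediator_probe] else NULL,
    a = config$mediation_a, b = config$mediation_b,
    c_prime = config$mediation_c_prime,
    noise_sd = config$mediation_noise_sd, seed = seeds[3])

  say("stage 4/6: forward-search linkage mapping (%d permutations)", config$n_perm)
  qtl <- forward_search(panel, med$phenotype, n_perm = config$n_perm,
                        alpha = config$alpha, seed = seeds[4])

  say("stage 5/6: eQTL mapping (FDR %g, %d permutations) and hotspot detection",
      config$target_fdr, config$n_perm_fdr)
  thr <- permutation_fdr_threshold(panel, expr$expression,
                                   n_perm = config$n_perm_fdr,
                                   target_fdr = config$target_fdr,
                                   seed = seeds[5])
  eqtl <- if (is.na(thr)) NULL else
    map_expression_panel(panel, expr$expression, expr$probe_positions, thr)
  hotspots <- if (!is.null(eqtl) && any(eqtl$classification == "distant"))
    detect_hotspots(eqtl[eqtl$classification == "distant", ], map,
                    bin_cM = config$bin_cM,
                    percentile = config$hotspot_percentile,
                    lod_floor = config$lod_floor) else NULL

  say("stage 6/6: mediation across hotspot candidate probes")
  mediation <- NULL
  if (nrow(qtl) > 0 && !is.null(eqtl)) {
    qtl_peak <- qtl$peak_marker[which.max(qtl$peak_lod)]
    hot_chr <- as.character(map$chromosome[map$marker_id == config$hotspot_marker])
    candidates <- eqtl$probe_id[eqtl$classification == "distant" &
                                  eqtl$peak_chromosome == hot_chr]
    if (length(candidates))
      mediation <- mediate_panel(panel, qtl_peak, expr$expression, candidates,
                                 med$phenotype, n_boot = config$n_boot,
                                 seed = seeds[6])
  }

  res <- list(panel = panel, expression = expr, drug_trait = med, qtl = qtl,
              eqtl = eqtl, eqtl_threshold = as.numeric(thr),
              hotspots = hotspots, mediation = mediation, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

validate_config <- function(config) {
  needed <- names(pipeline_config())
  miss <- setdiff(needed, names(config))
  if (length(miss))
    stopf("config missing field(s): %s", paste(miss, collapse = ", "))
  check_count(config$n_lines, "n_lines", min = 2L)
  check_count(config$n_probes, "n_probes")
  check_fraction(config$local_fraction, "local_fraction")
  check_fraction(config$alpha, "alpha")
  check_fraction(config$target_fdr, "target_fdr")
  check_positive(config$bin_cM, "bin_cM")
  check_count(config$n_perm, "n_perm")
  check_count(config$n_boot, "n_boot", min = 0L)
  check_count(config$seed, "seed", min = 0L)
  invisible(TRUE)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_genotypes(res$panel, p("genotypes.tsv"), p("marker_map.tsv"))
  write_traits(res$expression$expression, p("expression.tsv"))
  write_probe_positions(res$expression$probe_positions, p("probe_positions.tsv"))
  write_results(res$expression$truth, p("expression_truth.tsv"))
  write_traits(cbind(drug_trait = res$drug_trait$phenotype), p("drug_trait.tsv"))
  write_results(res$qtl, p("qtl.tsv"))
  if (!is.null(res$eqtl)) write_results(res$eqtl, p("eqtl.tsv"))
  if (!is.null(res$hotspots)) write_results(res$hotspots, p("hotspots.tsv"))
  if (!is.null(res$mediation)) write_results(res$mediation, p("mediation.tsv"))
  cfg <- res$config
  cfg$lod_floor <- cfg$lod_floor %||% NA
  manifest <- data.frame(
    key = c(names(cfg), "n_qtl", "n_eqtl", "n_hotspot_bins"),
    value = c(vapply(cfg, function(v) paste(format(v), collapse = ","), character(1)),
              nrow(res$qtl),
              if (is.null(res$eqtl)) 0L else nrow(res$eqtl),
              if (is.null(res$hotspots)) 0L else sum(res$hotspots$significant)))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_dir)
}
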