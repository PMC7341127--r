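# Panel-scale eQTL mapping, permutation FDR, local/distant classification,
# Poisson hotspot detection.

make_eqtl_panel <- function(n_lines = 200, n_probes = 100, frac_true = 0.2,
                            effect = 1.2, seed = 71) {
  panel <- simulate_riail_genotypes(generate_marker_map(3, 30, 50), n_lines,
                                    seed = seed)
  sim <- simulate_expression_panel(panel, n_probes, local_fraction = frac_true,
                                   hotspot_locus = NULL, n_hotspot_genes = 0,
                                   effect_size = effect, seed = seed + 1)
  list(panel = panel, sim = sim)
}

test_that("blocked expression scan equals the per-probe oracle to 1e-10", {
  x <- make_eqtl_panel(n_lines = 100, n_probes = 50)
  blocked <- map_expression_panel(x$panel, x$sim$expression,
                                  x$sim$probe_positions, threshold = 0)
  max_blocked <- attr(blocked, "max_lods")
  for (j in sample(ncol(x$sim$expression), 10)) {
    o <- oracle_lod_scan(x$panel, x$sim$expression[, j])
    expect_equal(unname(max_blocked[j]), max(o), tolerance = 1e-10)
  }
})

test_that("eQTL records classify local/distant by the 1 Mb same-chromosome rule", {
  expect_equal(classify_eqtl("II", 5e5, "II", 5e5 + 999999), "local")
  expect_equal(classify_eqtl("II", 5e5 + 999999, "II", 5e5), "local") # symmetric
  expect_equal(classify_eqtl("II", 5e5, "II", 5e5 + 1000001), "distant")
  expect_equal(classify_eqtl("II", 1, "III", 1), "distant")

  x <- make_eqtl_panel(n_lines = 200, n_probes = 60, frac_true = 0.5,
                       effect = 2, seed = 73)
  rec <- map_expression_panel(x$panel, x$sim$expression, x$sim$probe_positions,
                              threshold = 5)
  expect_identical(rec$classification,
                   classify_eqtl(rec$probe_chromosome, rec$probe_start,
                                 rec$peak_chromosome, rec$peak_physical_pos))
  # strong local probes are recovered with a local peak
  truth_local <- x$sim$truth$probe_id[x$sim$truth$class == "local"]
  found <- rec$probe_id[rec$classification == "local"]
  expect_gt(length(intersect(found, truth_local)) / length(truth_local), 0.9)
})

test_that("permutation FDR threshold behaves on null and mixed panels", {
  x <- make_eqtl_panel(n_lines = 150, n_probes = 80, frac_true = 0, seed = 75)
  thr_null <- suppressWarnings(
    permutation_fdr_threshold(x$panel, x$sim$expression, n_perm = 5, seed = 76))
  fdr_tab <- attr(thr_null, "fdr")
  # on a pure-null panel observed and permuted counts track each other
  low <- fdr_tab$threshold <= 3
  expect_gt(min(fdr_tab$fdr[low & fdr_tab$n_observed > 0]), 0.2)

  y <- make_eqtl_panel(n_lines = 200, n_probes = 80, frac_true = 0.25,
                       effect = 1.5, seed = 77)
  thr <- permutation_fdr_threshold(y$panel, y$sim$expression, n_perm = 5,
                                   seed = 78)
  expect_true(!is.na(thr) && thr >= 2 && thr <= 10)
  # determinism under a fixed seed
  thr2 <- permutation_fdr_threshold(y$panel, y$sim$expression, n_perm = 5,
                                    seed = 78)
  expect_identical(as.numeric(thr), as.numeric(thr2))
  # reported eQTL at the chosen threshold are mostly truly causal
  rec <- map_expression_panel(y$panel, y$sim$expression, y$sim$probe_positions, thr)
  is_null <- y$sim$truth$class[match(rec$probe_id, y$sim$truth$probe_id)] == "null"
  expect_lt(mean(is_null), 0.25)

  expect_error(permutation_fdr_threshold(y$panel, y$sim$expression,
                                         grid = numeric(0)), "grid")
})

test_that("Poisson critical count matches direct CDF summation", {
  # independent oracle: accumulate the CDF term by term
  oracle_critical <- function(lambda, n_bins, pct = 0.99) {
    target <- 1 - (1 - pct) / n_bins
    k <- 0; cdf <- exp(-lambda); term <- exp(-lambda)
    while (cdf < target) {
      k <- k + 1
      term <- term * lambda / k
      cdf <- cdf + term
    }
    k
  }
  expect_equal(riailmap:::poisson_critical_count(3.91, 60), oracle_critical(3.91, 60))
  expect_equal(oracle_critical(3.91, 60), 13)
  for (lam in c(0.5, 2, 3.91, 8)) {
    for (nb in c(10, 60, 120)) {
      expect_equal(riailmap:::poisson_critical_count(lam, nb),
                   oracle_critical(lam, nb))
      expect_gte(riailmap:::poisson_critical_count(lam, nb), lam)
    }
  }
})

test_that("hotspot detection conserves counts and responds to a LOD floor", {
  map <- generate_marker_map(6, 50, 50)
  set.seed(81)
  n <- 200
  idx <- sample(nrow(map), n, replace = TRUE)
  rec <- data.frame(peak_chromosome = as.character(map$chromosome[idx]),
                    peak_genetic_pos = map$genetic_pos[idx],
                    peak_lod = stats::runif(n, 2, 10))
  hs <- detect_hotspots(rec, map)
  expect_equal(sum(hs$count), n)
  expect_equal(attr(hs, "n_bins"), 60) # 6 chromosomes x 50 cM / 5 cM
  expect_equal(attr(hs, "lambda"), n / 60)
  # raising the floor never increases any bin count
  hs5 <- detect_hotspots(rec, map, lod_floor = 5)
  hs6 <- detect_hotspots(rec, map, lod_floor = 6)
  expect_true(all(hs5$count <= hs$count))
  expect_true(all(hs6$count <= hs5$count))
  expect_equal(sum(hs5$count), sum(rec$peak_lod >= 5))
  expect_error(detect_hotspots(rec, map, bin_cM = 0), "bin_cM")
})

test_that("a planted hotspot is flagged and uniform scatter is not", {
  map <- generate_marker_map(6, 50, 50)
  hot_marker <- which(map$marker_id == "MV_025")
  flagged_hot <- 0; flagged_other <- 0; flagged_null <- 0
  n_sim <- 100
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    idx_bg <- sample(nrow(map), 120, replace = TRUE)
    idx <- c(idx_bg, rep(hot_marker, 50))
    rec <- data.frame(peak_chromosome = as.character(map$chromosome[idx]),
                      peak_genetic_pos = map$genetic_pos[idx],
                      peak_lod = 6)
    hs <- detect_hotspots(rec, map)
    hot_bin <- hs$chromosome == "V" &
      map$genetic_pos[hot_marker] >= hs$start_cM &
      map$genetic_pos[hot_marker] < hs$end_cM
    flagged_hot <- flagged_hot + all(hs$significant[hot_bin])
    flagged_other <- flagged_other + any(hs$significant[!hot_bin])

    rec_null <- data.frame(peak_chromosome = as.character(map$chromosome[idx_bg]),
                           peak_genetic_pos = map$genetic_pos[idx_bg],
                           peak_lod = 6)
    flagged_null <- flagged_null + any(detect_hotspots(rec_null, map)$significant)
  }
  expect_gte(flagged_hot / n_sim, 0.95)
  expect_lte(flagged_other / n_sim, 0.05)
  expect_lte(flagged_null / n_sim, 0.05)
})

test_that("permuted datasets rarely contain spurious hotspots", {
  map <- generate_marker_map(6, 50, 50)
  set.seed(91)
  idx <- sample(nrow(map), 150, replace = TRUE)
  rec <- data.frame(peak_chromosome = as.character(map$chromosome[idx]),
                    peak_genetic_pos = map$genetic_pos[idx],
                    peak_lod = stats::runif(150, 4, 8))
  counts <- hotspot_permutation_check(rec, map, n_datasets = 50, seed = 92)
  expect_length(counts, 50)
  expect_lt(mean(counts), 1) # Bonferroni expectation
  expect_identical(counts,
                   hotspot_permutation_check(rec, map, n_datasets = 50, seed = 92))
  expect_identical(hotspot_permutation_check(rec, map, n_datasets = 0),
                   integer(0))
})
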