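# Linkage mapping: LOD scan, permutation threshold, forward search,
# QTL annotation.

test_that("closed-form LOD evaluates, zeroes and caps as specified", {
  expect_equal(lod_from_cor(0.5, 100), -100 * log(0.75) / (2 * log(10)))
  expect_equal(round(lod_from_cor(0.5, 100), 3), 6.247)
  expect_equal(lod_from_cor(0, 57), 0)
  # perfect correlation: floored at 1 - R^2 = 1e-16, never infinite
  expect_true(is.finite(lod_from_cor(1, 100)))
  expect_equal(lod_from_cor(1, 100), -100 * log(1e-16) / (2 * log(10)))
})

test_that("blocked scan equals the brute-force per-marker oracle to 1e-10", {
  panel <- tiny_panel(n_lines = 100, n_chrom = 2, n_markers = 25, seed = 51)
  y <- simulate_trait(panel, stats::setNames(0.8, colnames(panel$genotypes)[7]),
                      0.4, seed = 52)
  scan <- lod_scan(panel, y)
  expect_equal(scan$lod, oracle_lod_scan(panel, y), tolerance = 1e-10)

  # with missing genotypes, pairwise-complete n per marker
  panel$genotypes[sample(length(panel$genotypes), 200)] <- NA
  scan2 <- lod_scan(panel, y)
  expect_equal(scan2$lod, oracle_lod_scan(panel, y), tolerance = 1e-10)
  expect_true(any(scan2$n < 100))
})

test_that("LOD is invariant to affine recoding of trait and genotypes", {
  panel <- tiny_panel(n_lines = 80, seed = 53)
  y <- simulate_trait(panel, stats::setNames(1, colnames(panel$genotypes)[3]),
                      0.5, seed = 54)
  base <- lod_scan(panel, y)$lod
  expect_equal(lod_scan(panel, 10 - 3 * y)$lod, base, tolerance = 1e-10)
  flipped <- panel
  flipped$genotypes <- 1L - flipped$genotypes # swap parental coding
  expect_equal(lod_scan(flipped, y)$lod, base, tolerance = 1e-10)
})

test_that("permutation threshold is calibrated and respects quantile edges", {
  panel <- tiny_panel(n_lines = 100, seed = 55)
  y <- stats::rnorm(100)
  thr <- permutation_threshold(panel, y, n_perm = 500, seed = 56)
  maxima <- attr(thr, "max_lods")
  expect_length(maxima, 500)
  # threshold is the empirical 95th percentile of the null maxima
  expect_lt(mean(maxima > thr), 0.06)
  expect_gte(thr, stats::quantile(maxima, 0.90, names = FALSE))
  # alpha = 1 -> minimum of the maxima (degenerate but defined)
  thr1 <- permutation_threshold(panel, y, n_perm = 100, alpha = 1, seed = 57)
  expect_equal(as.numeric(thr1), min(attr(thr1, "max_lods")))
  # permutation distribution invariant to relabeling the trait values
  thr_a <- permutation_threshold(panel, y, n_perm = 300, seed = 58)
  thr_b <- permutation_threshold(panel, sample(y), n_perm = 300, seed = 58)
  expect_lt(abs(thr_a - thr_b), 0.75)
  expect_warning(permutation_threshold(panel, y, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("a strongly heritable QTL towers over its permutation threshold", {
  panel <- tiny_panel(n_lines = 300, seed = 59)
  y <- simulate_trait(panel, stats::setNames(1, colnames(panel$genotypes)[10]),
                      0.7, seed = 60)
  thr <- permutation_threshold(panel, y, n_perm = 300, seed = 61)
  expect_gt(max(lod_scan(panel, y)$lod), 3 * thr)
})

test_that("QTL annotation walks the 1.5-LOD-drop interval and round-trips R^2", {
  map <- generate_marker_map(1, 5, 40)
  panel <- simulate_riail_genotypes(map, 50, seed = 62)
  y <- simulate_trait(panel, stats::setNames(1, map$marker_id[3]), 0.6, seed = 63)
  scan <- lod_scan(panel, y)
  # hand profile 1,2,5,2,1: CI = the two markers flanking the peak
  scan$lod <- c(1, 2, 5, 2, 1)
  scan$n <- rep(50L, 5)
  ann <- annotate_qtl(scan, map$marker_id[3], panel, y)
  expect_equal(ann$ci_left, map$marker_id[2])
  expect_equal(ann$ci_right, map$marker_id[4])
  expect_equal(ann$var_expl, 1 - 10^(-2 * 5 / 50))

  # monotone profile peaking at the chromosome end: one-sided CI
  scan$lod <- c(1, 2, 3, 4, 5)
  ann2 <- annotate_qtl(scan, map$marker_id[5], panel, y)
  expect_equal(ann2$ci_right, map$marker_id[5])
  expect_equal(ann2$ci_left, map$marker_id[3]) # first marker below 5 - 1.5

  expect_error(annotate_qtl(scan, "nope", panel, y), "not on scan")
})

test_that("variance explained equals peak-marker R^2 to 1e-10", {
  panel <- tiny_panel(n_lines = 120, seed = 64)
  y <- simulate_trait(panel, stats::setNames(1, colnames(panel$genotypes)[8]),
                      0.5, seed = 65)
  scan <- lod_scan(panel, y)
  pk <- which.max(scan$lod)
  ann <- annotate_qtl(scan, scan$marker_id[pk], panel, y)
  expect_equal(ann$var_expl, scan$r[pk]^2, tolerance = 1e-10)
})

test_that("forward search finds planted QTL and returns nothing on null traits", {
  map <- generate_marker_map(4, 40, 50)
  panel <- simulate_riail_genotypes(map, 300, seed = 66)
  # two unlinked planted QTL on different chromosomes
  eff <- stats::setNames(c(1, 0.6), c(map$marker_id[20], map$marker_id[100]))
  y <- simulate_trait(panel, eff, 0.6, seed = 67)
  q <- forward_search(panel, y, n_perm = 300, seed = 68)
  expect_equal(nrow(q), 2)
  expect_equal(q$peak_lod, sort(q$peak_lod, decreasing = TRUE))
  expect_setequal(as.character(q$chromosome),
                  as.character(map$chromosome[c(20, 100)]))
  # peaks fall inside their own confidence intervals in genome order
  for (i in 1:2) {
    chr_markers <- map$marker_id[map$chromosome == q$chromosome[i]]
    expect_lte(match(q$ci_left[i], chr_markers),
               match(q$peak_marker[i], chr_markers))
    expect_gte(match(q$ci_right[i], chr_markers),
               match(q$peak_marker[i], chr_markers))
  }

  qn <- forward_search(panel, stats::rnorm(300), n_perm = 300, seed = 69)
  expect_equal(nrow(qn), 0)

  # alpha -> 0: threshold unattainable, empty set on any finite data
  q0 <- forward_search(panel, y, n_perm = 100, alpha = 0, seed = 70)
  expect_equal(nrow(q0), 0)
})
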