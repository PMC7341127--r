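# Shared fixtures: small panels built in code at test time.

tiny_map <- function(n_chrom = 2, n_markers = 25, len = 50)
  generate_marker_map(n_chrom, n_markers, len)

tiny_panel <- function(n_lines = 100, n_chrom = 2, n_markers = 25, seed = 11)
  simulate_riail_genotypes(tiny_map(n_chrom, n_markers), n_lines, 4, seed = seed)

# Independent brute-force oracle for the genome scan: per-marker loop with
# stats::cor, no shared code with the blocked implementation.
oracle_lod_scan <- function(panel, trait) {
  g <- panel$genotypes
  vapply(seq_len(ncol(g)), function(j) {
    ok <- !is.na(g[, j]) & !is.na(trait)
    n <- sum(ok)
    r <- suppressWarnings(stats::cor(g[ok, j], trait[ok]))
    -n * log(max(1 - r^2, 1e-16)) / (2 * log(10))
  }, numeric(1))
}
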