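#' Panel-scale expression QTL mapping
#'
#' Scans every probe against every marker in one blocked correlation
#' product, keeps each probe's genome-wide maximum LOD, and emits a record
#' for probes whose maximum meets `threshold`. Each record carries the
#' probe's genomic start, the peak marker, the variance explained, and the
#' local/distant classification (see [classify_eqtl()]).
#'
#' @param panel a `genotype_panel`.
#' @param expression lines x probes numeric matrix; rownames must match the
#'   panel's line ids (order free), colnames are probe ids.
#' @param probe_positions data frame with `probe_id`, `chromosome`,
#'   `start_bp` for every expression column.
#' @param threshold genome-wide LOD threshold (e.g. from
#'   [permutation_fdr_threshold()]).
#' @param local_window_bp distance defining a local eQTL (default 1e6).
#' @return `eqtl_table` data frame: probe_id, probe_chromosome, probe_start,
#'   peak_marker, peak_chromosome, peak_genetic_pos, peak_physical_pos, n,
#'   peak_lod, var_expl, classification.
#' @export
map_expression_panel <- function(panel, expression, probe_positions, threshold,
                                 local_window_bp = 1e6) {
  expression <- align_expression(panel, expression)
  pp <- probe_positions
  if (!all(colnames(expression) %in% pp$probe_id))
    stopf("probe_positions missing probes: %s",
          paste(setdiff(colnames(expression), pp$probe_id)[1:5], collapse = ", "))
  blk <- lod_block(panel$genotypes, expression)
  peak_i <- apply(blk$lod, 2, function(l)
    if (all(is.na(l))) NA_integer_ else which.max(l))
  peak_lod <- blk$lod[cbind(peak_i, seq_along(peak_i))]
  pass <- which(!is.na(peak_lod) & peak_lod >= threshold)
  map <- panel$map
  pos <- pp[match(colnames(expression)[pass], pp$probe_id), ]
  out <- data.frame(
    probe_id = colnames(expression)[pass],
    probe_chromosome = as.character(pos$chromosome),
    probe_start = pos$start_bp,
    peak_marker = map$marker_id[peak_i[pass]],
    peak_chromosome = as.character(map$chromosome[peak_i[pass]]),
    peak_genetic_pos = map$genetic_pos[peak_i[pass]],
    peak_physical_pos = map$physical_pos[peak_i[pass]],
    n = as.integer(blk$n[cbind(peak_i[pass], pass)]),
    peak_lod = peak_lod[pass],
    stringsAsFactors = FALSE
  )
  out$var_expl <- variance_explained_from_lod(out$peak_lod, out$n)
  out$classification <- ifelse(
    out$probe_chromosome == out$peak_chromosome &
      abs(out$peak_physical_pos - out$probe_start) <= local_window_bp,
    "local", "distant")
  attr(out, "max_lods") <- stats::setNames(peak_lod, colnames(expression))
  class(out) <- c("eqtl_table", "data.frame")
  out
}

align_expression <- function(panel, expression) {
  expression <- as.matrix(expression)
  lines <- rownames(panel$genotypes)
  if (is.null(rownames(expression))) {
    if (nrow(expression) != length(lines))
      stopf("expression has %d rows but panel has %d lines",
            nrow(expression), length(lines))
  } else {
    if (!setequal(rownames(expression), lines))
      stopf("expression line ids do not match the panel")
    expression <- expression[lines, , drop = FALSE]
  }
  expression
}

#' Classify an eQTL as local or distant
#'
#' Local means the peak marker lies on the probe's chromosome within
#' `window_bp` (default 1 Mb) of the probe's genomic start position;
#' anything else — including any cross-chromosome linkage — is distant
#' (trans).
#'
#' @param probe_chromosome,probe_start probe location (chromosome label, bp).
#' @param peak_chromosome,peak_physical_pos peak-marker location.
#' @param window_bp local window in bp.
#' @return character vector, `"local"` or `"distant"`.
#' @export
classify_eqtl <- function(probe_chromosome, probe_start,
                          peak_chromosome, peak_physical_pos,
                          window_bp = 1e6) {
  ifelse(as.character(probe_chromosome) == as.character(peak_chromosome) &
           abs(peak_physical_pos - probe_start) <= window_bp,
         "local", "distant")
}

#' Permutation-based FDR threshold for panel-scale eQTL mapping
#'
#' The line labels of the whole expression matrix are permuted jointly
#' `n_perm` times (preserving inter-probe correlation); each permuted panel
#' is rescanned and per-probe genome-maximum LODs recorded. For every
#' candidate threshold `t` on the grid,
#' `FDR(t) = mean over permutations of #\{probes with max LOD > t\} /
#' #\{observed probes with max LOD > t\}`; the returned threshold is the
#' smallest grid value with `FDR(t) < target_fdr` (the most permissive
#' threshold that controls the FDR). When the observed count at `t` is zero
#' the FDR is 0 if the permuted mean is also 0, otherwise infinite.
#'
#' @param panel a `genotype_panel`.
#' @param expression lines x probes matrix (see [map_expression_panel()]).
#' @param n_perm number of whole-matrix permutations (default 10).
#' @param grid candidate LOD thresholds (default `seq(2, 10, 0.01)`).
#' @param target_fdr FDR to control (default 0.05).
#' @param seed RNG seed.
#' @param per_probe permute each probe independently instead of jointly
#'   (breaks inter-probe correlation; default `FALSE`).
#' @return the selected threshold, or `NA` with a warning when no grid value
#'   attains the target; attributes `"fdr"` (grid data frame) and
#'   `"perm_max_lods"`.
#' @export
permutation_fdr_threshold <- function(panel, expression, n_perm = 10,
                                      grid = seq(2, 10, by = 0.01),
                                      target_fdr = 0.05, seed = 1L,
                                      per_probe = FALSE) {
  n_perm <- check_count(n_perm, "n_perm")
  if (length(grid) == 0) stopf("`grid` must be non-empty")
  grid <- sort(as.numeric(grid))
  target_fdr <- check_fraction(target_fdr, "target_fdr")
  expression <- align_expression(panel, expression)
  set.seed(check_count(seed, "seed", min = 0L))
  G <- panel$genotypes
  obs_max <- apply(lod_block(G, expression)$lod, 2, max, na.rm = TRUE)
  n_lines <- nrow(expression)
  perm_max <- matrix(NA_real_, n_perm, ncol(expression))
  for (p in seq_len(n_perm)) {
    E <- if (per_probe) apply(expression, 2, sample)
         else expression[sample(n_lines), , drop = FALSE]
    perm_max[p, ] <- apply(lod_block(G, E)$lod, 2, max, na.rm = TRUE)
  }
  n_obs <- vapply(grid, function(t) sum(obs_max > t), numeric(1))
  n_perm_mean <- vapply(grid, function(t) mean(rowSums(perm_max > t)), numeric(1))
  fdr <- ifelse(n_obs > 0, n_perm_mean / n_obs, ifelse(n_perm_mean == 0, 0, Inf))
  ok <- which(fdr < target_fdr)
  thr <- if (length(ok)) grid[ok[1]] else {
    warning("no grid threshold attains the target FDR; returning NA")
    NA_real_
  }
  attr(thr, "fdr") <- data.frame(threshold = grid, n_observed = n_obs,
                                 mean_permuted = n_perm_mean, fdr = fdr)
  attr(thr, "perm_max_lods") <- perm_max
  thr
}
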