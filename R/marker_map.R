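#' Construct and validate a marker map
#'
#' A marker map is a data frame with one row per marker and columns
#' `marker_id`, `chromosome`, `genetic_pos` (cM, >= 0) and `physical_pos`
#' (bp, 1-based, >= 1). Positions must be strictly increasing within each
#' chromosome and marker ids unique. The chromosome factor levels fix the
#' genome order used everywhere downstream.
#'
#' @param marker_id character vector of unique marker names.
#' @param chromosome chromosome label per marker; ordering of chromosomes is
#'   taken from `chrom_order` (default: order of first appearance).
#' @param genetic_pos genetic position in centimorgans.
#' @param physical_pos physical position in base pairs (1-based).
#' @param chrom_order optional character vector giving the genome-wide
#'   chromosome order.
#' @return a `marker_map` data frame.
#' @export
marker_map <- function(marker_id, chromosome, genetic_pos, physical_pos,
                       chrom_order = NULL) {
  n <- length(marker_id)
  if (length(chromosome) != n || length(genetic_pos) != n ||
      length(physical_pos) != n)
    stopf("marker_map fields must have equal length")
  if (anyDuplicated(marker_id))
    stopf("duplicate marker_id: %s",
          paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  if (any(genetic_pos < 0)) stopf("genetic_pos must be >= 0 cM")
  if (any(physical_pos < 1)) stopf("physical_pos must be >= 1 bp (1-based)")
  chromosome <- as.character(chromosome)
  if (is.null(chrom_order)) chrom_order <- unique(chromosome)
  if (!all(chromosome %in% chrom_order))
    stopf("chromosome labels not covered by chrom_order")
  map <- data.frame(marker_id = as.character(marker_id),
                    chromosome = factor(chromosome, levels = chrom_order),
                    genetic_pos = as.numeric(genetic_pos),
                    physical_pos = as.numeric(physical_pos),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$genetic_pos), , drop = FALSE]
  rownames(map) <- NULL
  for (chr in levels(map$chromosome)) {
    i <- map$chromosome == chr
    if (any(diff(map$genetic_pos[i]) <= 0))
      stopf("genetic_pos not strictly increasing on chromosome %s", chr)
    if (any(diff(map$physical_pos[i]) <= 0))
      stopf("physical_pos not strictly increasing on chromosome %s", chr)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Generate an evenly or uniformly spaced synthetic marker map
#'
#' Genetic positions span `[0, chrom_length_cM]` on each chromosome, either
#' on an even grid or uniformly at random (sorted). Physical positions are an
#' affine image of the genetic positions with a constant `bp_per_cM` factor
#' per chromosome and a 1-based origin, so a genetic window maps onto a
#' predictable physical window (1 Mb local-eQTL rules and 5 cM hotspot bins
#' are both exercisable on the same map).
#'
#' @param n_chromosomes number of chromosomes (default 6, nematode-like).
#' @param markers_per_chromosome markers on each chromosome.
#' @param chrom_length_cM genetic length of every chromosome, in cM.
#' @param bp_per_cM physical bp per genetic cM (default 40000).
#' @param spacing `"even"` for a regular grid, `"uniform"` for sorted
#'   uniform-random positions.
#' @param seed RNG seed, used only for `spacing = "uniform"`.
#' @return a [marker_map()].
#' @examples
#' map <- generate_marker_map(1, 11, 50)
#' map$genetic_pos # 0, 5, ..., 50
#' @export
generate_marker_map <- function(n_chromosomes = 6, markers_per_chromosome = 100,
                                chrom_length_cM = 50, bp_per_cM = 40000,
                                spacing = c("even", "uniform"), seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  markers_per_chromosome <- check_count(markers_per_chromosome, "markers_per_chromosome")
  chrom_length_cM <- check_positive(chrom_length_cM, "chrom_length_cM")
  bp_per_cM <- check_positive(bp_per_cM, "bp_per_cM")
  spacing <- match.arg(spacing)
  chroms <- default_chromosomes(n_chromosomes)
  if (spacing == "uniform") set.seed(check_count(seed, "seed", min = 0L))
  pos <- lapply(seq_len(n_chromosomes), function(i) {
    if (spacing == "even") {
      if (markers_per_chromosome == 1L) 0
      else seq(0, chrom_length_cM, length.out = markers_per_chromosome)
    } else {
      sort(stats::runif(markers_per_chromosome, 0, chrom_length_cM))
    }
  })
  gpos <- unlist(pos)
  chrom <- rep(chroms, each = markers_per_chromosome)
  marker_map(
    marker_id = sprintf("M%s_%03d", chrom, rep(seq_len(markers_per_chromosome), n_chromosomes)),
    chromosome = chrom,
    genetic_pos = gpos,
    physical_pos = round(gpos * bp_per_cM) + 1, # 1-based origin
    chrom_order = chroms
  )
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d markers on %d chromosome(s) (%s)\n",
              nrow(x), nlevels(x$chromosome),
              paste(levels(x$chromosome), collapse = ", ")))
  NextMethod()
}
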