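# TSV interchange: all pipeline tables are plain tab-separated files with
# header rows, so every simulated input and every stage output round-trips
# losslessly through read/write.

#' Read and write marker maps
#'
#' TSV schema: `marker_id`, `chromosome`, `genetic_pos_cM`, `physical_pos_bp`.
#' Validation on read enforces unique ids, 1-based physical coordinates and
#' strictly increasing positions per chromosome.
#'
#' @param path file path.
#' @param map a `marker_map`.
#' @return `read_marker_map`: a `marker_map`; `write_marker_map`: `path`,
#'   invisibly.
#' @export
read_marker_map <- function(path) {
  d <- read_tsv_checked(path, c("marker_id", "chromosome", "genetic_pos_cM",
                                "physical_pos_bp"))
  marker_map(d$marker_id, d$chromosome, as_numeric_checked(d$genetic_pos_cM, path, "genetic_pos_cM"),
             as_numeric_checked(d$physical_pos_bp, path, "physical_pos_bp"))
}

#' @rdname read_marker_map
#' @export
write_marker_map <- function(map, path) {
  d <- data.frame(marker_id = map$marker_id,
                  chromosome = as.character(map$chromosome),
                  genetic_pos_cM = map$genetic_pos,
                  physical_pos_bp = map$physical_pos)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype panels
#'
#' The genotype TSV has a `line_id` column followed by one column per
#' marker, values in \{0, 1\} or `NA`; the marker map travels in a separate
#' file (see [read_marker_map()]). Any other allele code is a parse error
#' naming the offending cell.
#'
#' @param geno_path genotype TSV path.
#' @param map_path marker-map TSV path.
#' @param panel a `genotype_panel`.
#' @return `read_genotypes`: a `genotype_panel`; `write_genotypes`:
#'   `geno_path`, invisibly.
#' @export
read_genotypes <- function(geno_path, map_path) {
  map <- read_marker_map(map_path)
  d <- utils::read.delim(geno_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "line_id") stopf("%s: first column must be line_id", geno_path)
  if (anyDuplicated(d$line_id)) stopf("%s: duplicate line ids", geno_path)
  g <- as.matrix(d[, -1, drop = FALSE])
  if (!setequal(colnames(g), map$marker_id))
    stopf("genotype columns do not match the marker map")
  g <- g[, map$marker_id, drop = FALSE]
  gv <- suppressWarnings(as.numeric(g))
  ok <- matrix(is.na(g) | (!is.na(gv) & (gv == 0 | gv == 1)),
               nrow(g), ncol(g))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stopf("%s: invalid allele code '%s' at line %s, marker %s",
          geno_path, g[bad[1, 1], bad[1, 2]], d$line_id[bad[1, 1]],
          colnames(g)[bad[1, 2]])
  }
  g <- matrix(as.integer(gv), nrow(g), ncol(g), dimnames = dimnames(g))
  rownames(g) <- d$line_id
  structure(list(genotypes = g, map = map), class = "genotype_panel")
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(panel, geno_path, map_path) {
  write_marker_map(panel$map, map_path)
  d <- data.frame(line_id = rownames(panel$genotypes), panel$genotypes,
                  check.names = FALSE)
  utils::write.table(d, geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(geno_path)
}

#' Read and write line-keyed trait tables
#'
#' TSV schema: `line_id` column then one numeric column per trait (or
#' probe). Non-numeric cells are parse errors naming row and column.
#'
#' @param path file path.
#' @param traits matrix or data frame of trait values with line ids as
#'   rownames.
#' @return `read_traits`: numeric matrix with line-id rownames;
#'   `write_traits`: `path`, invisibly.
#' @export
read_traits <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "line_id") stopf("%s: first column must be line_id", path)
  if (anyDuplicated(d$line_id)) stopf("%s: duplicate line ids", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) & !is.na(m[, j]) & m[, j] != "NA")
    if (length(bad))
      stopf("%s: non-numeric value '%s' at line %s, column %s",
            path, m[bad[1], j], d$line_id[bad[1]], colnames(m)[j])
  }
  storage.mode(m) <- "numeric"
  rownames(m) <- d$line_id
  m
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, path) {
  d <- data.frame(line_id = rownames(as.matrix(traits)), as.matrix(traits),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write probe genomic positions
#'
#' TSV schema: `probe_id`, `chromosome`, `start_bp` (1-based).
#'
#' @param path file path.
#' @param positions data frame with the three schema columns.
#' @return `read_probe_positions`: validated data frame;
#'   `write_probe_positions`: `path`, invisibly.
#' @export
read_probe_positions <- function(path) {
  d <- read_tsv_checked(path, c("probe_id", "chromosome", "start_bp"))
  d$start_bp <- as_numeric_checked(d$start_bp, path, "start_bp")
  if (any(d$start_bp < 1)) stopf("%s: start_bp must be >= 1 (1-based)", path)
  if (anyDuplicated(d$probe_id)) stopf("%s: duplicate probe ids", path)
  d
}

#' @rdname read_probe_positions
#' @export
write_probe_positions <- function(positions, path) {
  utils::write.table(positions[, c("probe_id", "chromosome", "start_bp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic result table as TSV
#'
#' @param x data frame (qtl_table, eqtl_table, hotspot_scan, ...).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(d))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  d
}

as_numeric_checked <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stopf("%s: non-numeric value '%s' in column %s, row %d",
          path, x[bad[1]], col, bad[1])
  v
}
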