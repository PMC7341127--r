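#' Closed-form LOD from a Pearson correlation
#'
#' `LOD = -n * ln(1 - R^2) / (2 * ln 10)`, where `R` is the Pearson
#' correlation between genotype codes and trait values over the `n` lines
#' with both observed. `1 - R^2` is floored at 1e-16, so a perfectly
#' correlated marker yields a large finite LOD rather than infinity.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @param n number(s) of complete genotype-trait pairs.
#' @return nonnegative LOD score(s); `NA` where `r` is `NA`.
#' @examples
#' lod_from_cor(0.5, 100) # 6.2469...
#' @export
lod_from_cor <- function(r, n) {
  -n * log(pmax(1 - r^2, 1e-16)) / (2 * log(10))
}

# Inverse relation used for variance explained: R^2 = 1 - 10^(-2 LOD / n).
variance_explained_from_lod <- function(lod, n) 1 - 10^(-2 * lod / n)

# Correlation of every column of G with every column of Y.
# Fast path (no missing data): crossprod of standardized matrices.
# Otherwise pairwise-complete via stats::cor. Returns list(r, n) where n is
# the per-pair complete count (markers x traits).
cor_block <- function(G, Y) {
  G <- as.matrix(G); Y <- as.matrix(Y)
  if (!anyNA(G) && !anyNA(Y)) {
    n <- nrow(G)
    Gs <- scale(G); Ys <- scale(Y)
    # zero-variance columns give NaN after scale(); keep as NA correlations
    r <- crossprod(Gs, Ys) / (n - 1)
    r[which(r > 1)] <- 1; r[which(r < -1)] <- -1
    list(r = r, n = matrix(n, ncol(G), ncol(Y)))
  } else {
    r <- suppressWarnings(stats::cor(G, Y, use = "pairwise.complete.obs"))
    okG <- !is.na(G); okY <- !is.na(Y)
    nmat <- crossprod(okG, okY)
    list(r = r, n = nmat)
  }
}

# LOD matrix (markers x traits) for a genotype matrix and trait matrix.
lod_block <- function(G, Y) {
  cb <- cor_block(G, Y)
  lod <- lod_from_cor(cb$r, cb$n)
  lod[cb$n < 3] <- NA_real_
  list(lod = lod, r = cb$r, n = cb$n)
}

#' Single-trait genome scan
#'
#' Marker regression via the Pearson correlation between each marker's
#' genotype codes and the trait, converted to a LOD score with
#' [lod_from_cor()]. Missing genotypes are handled pairwise-complete, so `n`
#' can differ between markers; markers with fewer than 3 complete pairs or
#' no genotype variation get `NA` LOD.
#'
#' @param panel a `genotype_panel`.
#' @param trait numeric trait vector aligned to the panel's lines (names, if
#'   present, must match the panel line ids).
#' @return a `lod_scan` data frame: marker_id, chromosome, genetic_pos,
#'   physical_pos, n, r, lod.
#' @examples
#' map <- generate_marker_map(1, 20, 50)
#' panel <- simulate_riail_genotypes(map, 100, seed = 2)
#' y <- simulate_trait(panel, c(MI_010 = 1), 0.5, seed = 3)
#' scan <- lod_scan(panel, y)
#' scan[which.max(scan$lod), ]
#' @export
lod_scan <- function(panel, trait) {
  trait <- align_trait(panel, trait)
  if (all(is.na(trait))) stopf("trait is entirely missing")
  blk <- lod_block(panel$genotypes, matrix(trait, ncol = 1))
  out <- data.frame(panel$map,
                    n = as.integer(blk$n[, 1]),
                    r = as.numeric(blk$r[, 1]),
                    lod = as.numeric(blk$lod[, 1]),
                    stringsAsFactors = FALSE)
  class(out) <- c("lod_scan", "data.frame")
  out
}

align_trait <- function(panel, trait) {
  lines <- rownames(panel$genotypes)
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), lines))
      stopf("trait names do not match panel line ids")
    trait <- trait[lines]
  } else if (length(trait) != length(lines)) {
    stopf("trait length %d != %d panel lines", length(trait), length(lines))
  }
  as.numeric(trait)
}

#' @export
print.lod_scan <- function(x, ...) {
  pk <- x[which.max(x$lod), ]
  cat(sprintf("LOD scan over %d markers; peak %.2f at %s (%s: %.1f cM)\n",
              nrow(x), pk$lod, pk$marker_id, pk$chromosome, pk$genetic_pos))
  invisible(x)
}

#' @export
summary.lod_scan <- function(object, threshold = NULL, ...) {
  by_chr <- do.call(rbind, lapply(split(object, object$chromosome), function(d) {
    pk <- d[which.max(d$lod), c("marker_id", "chromosome", "genetic_pos", "lod")]
    pk
  }))
  rownames(by_chr) <- NULL
  if (!is.null(threshold)) by_chr$significant <- by_chr$lod >= threshold
  by_chr
}

#' Plot a genome scan
#'
#' LOD profile against cumulative genetic position, panelled by chromosome
#' boundaries; an optional horizontal line marks the significance threshold.
#'
#' @param x a `lod_scan`.
#' @param threshold optional LOD threshold to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lod_scan <- function(x, threshold = NULL, ...) {
  offs <- c(0, cumsum(tapply(x$genetic_pos, x$chromosome, max)))
  names(offs) <- c(levels(x$chromosome), "end")
  gx <- x$genetic_pos + offs[as.character(x$chromosome)]
  graphics::plot(gx, x$lod, type = "l", xlab = "genome position (cM)",
                 ylab = "LOD", ...)
  graphics::abline(v = offs[-1], col = "grey80", lty = 3)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}
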