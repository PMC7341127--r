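#' @keywords internal
"_PACKAGE"

# Parameter checking helpers shared across the package. All user-facing
# errors name the offending argument.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("`%s` must be a single positive number", name)
  as.numeric(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1]", name)
  as.numeric(x)
}

#' Derive a stream of per-stage seeds from a master seed
#'
#' Counter-based scheme: stage `k` always receives the same seed for a given
#' master seed, so adding a later stage never perturbs earlier stages'
#' random streams. Seeds stay below 2^31.
#'
#' @param seed master seed (single integer).
#' @param k stage counter (single non-negative integer) or vector of counters.
#' @return integer vector of derived seeds, same length as `k`.
#' @export
derive_seed <- function(seed, k) {
  seed <- check_count(seed, "seed", min = 0L)
  m <- 2147483629 # largest prime < 2^31
  as.integer((as.numeric(seed) %% m + 1000003 * (as.numeric(k) + 1)) %% m)
}

# Roman chromosome labels used by default (C. elegans convention).
default_chromosomes <- function(n) {
  labels <- c("I", "II", "III", "IV", "V", "X")
  if (n <= length(labels)) labels[seq_len(n)] else c(labels, paste0("chr", seq_len(n - length(labels)) + 6L))[seq_len(n)]
}
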