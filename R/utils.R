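# Internal helpers: structured error conditions and marker-name handling.

stop_rg <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Normalize a marker name for matching
#'
#' Marker matching throughout the package is case-insensitive and ignores
#' hyphens, spaces and dots, so vendor spellings such as "HLA-DR" and "HLADR"
#' refer to the same antigen.
#'
#' @param x character vector of marker names.
#' @return normalized character vector (upper case, alphanumeric only).
#' @export
#' @examples
#' normalize_marker(c("HLA-DR", "hladr", "cy MPO"))
normalize_marker <- function(x) {
  toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
}

# TRUE where `a` matches `b` under marker normalization
marker_eq <- function(a, b) normalize_marker(a) == normalize_marker(b)

# Derive a stream seed < 2^31 from a master seed and an integer offset.
# Simple LCG-style mix; stable across platforms (pure integer arithmetic on
# doubles well below 2^53).
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((s * 48271 + as.numeric(k) * 69621 + 1) %% 2147483647)
}

# largest-remainder allocation of n among fractions p (sums to n exactly)
allocate_counts <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
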