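#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random fixed-length DNA strings
#'
#' @param n number of strings
#' @param len string length in bases
#' @return character vector of length `n`
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Split equal-length strings into a character matrix (one row per string)
#' @keywords internal
char_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1)
  if (length(x) == 0) return(matrix(character(0), nrow = 0))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

#' Hamming distance between two equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Vectorized mismatch count of each string against one reference string
#'
#' All strings in `x` must have the same length as `ref`.
#' @keywords internal
mismatches_to <- function(x, ref) {
  if (length(x) == 0) return(integer(0))
  cm <- char_matrix(x)
  rv <- strsplit(ref, "", fixed = TRUE)[[1]]
  rowSums(cm != matrix(rv, nrow = nrow(cm), ncol = length(rv), byrow = TRUE))
}

#' All Hamming-distance-1 variants of each string
#'
#' Returns a data.frame with columns `idx` (index into `x`) and `variant`.
#' Includes only variants differing from the original (3 * len per string).
#' @keywords internal
hamming1_variants <- function(x) {
  len <- unique(nchar(x))
  stopifnot(length(len) == 1)
  n <- length(x)
  out_var <- vector("list", len * 3L)
  out_idx <- vector("list", len * 3L)
  slot <- 1L
  pre <- lapply(seq_len(len), function(p) substr(x, 1L, p - 1L))
  post <- lapply(seq_len(len), function(p) substr(x, p + 1L, len))
  orig <- lapply(seq_len(len), function(p) substr(x, p, p))
  for (p in seq_len(len)) {
    for (b in DNA_BASES) {
      keep <- orig[[p]] != b
      if (!any(keep)) { slot <- slot + 1L; next }
      out_var[[slot]] <- paste0(pre[[p]][keep], b, post[[p]][keep])
      out_idx[[slot]] <- which(keep)
      slot <- slot + 1L
    }
  }
  data.frame(idx = unlist(out_idx), variant = unlist(out_var),
             stringsAsFactors = FALSE)
}

#' Largest-remainder apportionment of `total` units proportional to weights
#'
#' Deterministic: ties in remainders broken by index order.
#' @keywords internal
apportion <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Trapezoidal integration on a uniform or non-uniform grid
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Strip a trailing droplet-suffix ("-1", "-2", ...) from cell barcodes
#'
#' Cell identifiers from expression pipelines often carry a numeric GEM-well
#' suffix that tag-read data lacks; stripping it lets the two streams join.
#' @param x character vector of cell barcodes
#' @return character vector with any "-<digits>" suffix removed
#' @export
strip_cell_suffix <- function(x) {
  sub("-[0-9]+$", "", x)
}
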