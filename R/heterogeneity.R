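#' Per-cell intra-tumoral heterogeneity (ITH) scores
#'
#' The ITH score of a cell is its average Euclidean distance to every other
#' cell of the same sample, in the selected principal components:
#' `score_i = (1/(n-1)) * sum_{j != i} ||x_i - x_j||`. The self distance is
#' excluded; including it would deflate every score by a factor
#' `(n-1)/n` (set `include_self = TRUE` for that convention).
#'
#' @param embedding an `embedding` or a cells x dims coordinate matrix
#' @param sample_label label attached to the returned distribution
#' @param include_self divide the distance sum by `n` instead of `n - 1`
#' @return list of class `ith_distribution`: `sample`, `scores` (named
#'   numeric), `n_cells`
#' @export
ith_scores <- function(embedding, sample_label = "sample",
                       include_self = FALSE) {
  coords <- embedding_coords(embedding)
  n <- nrow(coords)
  if (n < 2) stop("at least 2 cells are required")
  d <- as.matrix(stats::dist(coords))
  denom <- if (include_self) n else n - 1L
  scores <- rowSums(d) / denom
  names(scores) <- rownames(coords)
  structure(list(sample = sample_label, scores = scores, n_cells = n),
            class = "ith_distribution")
}

#' @export
print.ith_distribution <- function(x, ...) {
  cat(sprintf("ith_distribution '%s': %d cells, mean score %.3f\n",
              x$sample, x$n_cells, mean(x$scores)))
  invisible(x)
}

#' Subsample each sample to an equal number of cells
#'
#' Seeded uniform subsampling applied before scoring, so distributions from
#' samples of different sizes are comparable.
#'
#' @param samples named list of coordinate matrices (cells x dims) or
#'   data.frames
#' @param n_per_sample cells retained per sample
#' @param seed RNG seed
#' @return list of the same shape with `n_per_sample` rows each
#' @export
subsample_equal <- function(samples, n_per_sample, seed = 0L) {
  set.seed(seed)
  lapply(samples, function(m) {
    n <- nrow(m)
    if (n < n_per_sample)
      stop(sprintf("sample has %d cells, fewer than n_per_sample = %d",
                   n, n_per_sample))
    if (n == n_per_sample) return(m)
    m[sort(sample.int(n, n_per_sample)), , drop = FALSE]
  })
}

#' Percentage overlap of two score distributions
#'
#' Gaussian kernel density estimates (Silverman's rule-of-thumb bandwidth)
#' of each sample are evaluated on a common grid spanning the pooled range
#' padded by three bandwidths; the overlap is 100 times the trapezoidal
#' integral of the pointwise minimum of the two densities (the overlapping
#' index). If either sample is a point mass the densities are replaced by
#' normalized histograms on shared bins.
#'
#' @param scores_a,scores_b numeric score vectors (or `ith_distribution`s)
#' @param grid_points evaluation grid size
#' @return overlap percentage in [0, 100]
#' @export
distribution_overlap <- function(scores_a, scores_b, grid_points = 1024L) {
  if (inherits(scores_a, "ith_distribution")) scores_a <- scores_a$scores
  if (inherits(scores_b, "ith_distribution")) scores_b <- scores_b$scores
  if (length(scores_a) == 0 || length(scores_b) == 0)
    stop("empty score vector")
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    breaks <- seq(min(scores_a, scores_b) - 0.5,
                  max(scores_a, scores_b) + 0.5, length.out = 52L)
    pa <- graphics::hist(scores_a, breaks = breaks, plot = FALSE)$counts
    pb <- graphics::hist(scores_b, breaks = breaks, plot = FALSE)$counts
    return(100 * sum(pmin(pa / sum(pa), pb / sum(pb))))
  }
  ha <- stats::bw.nrd0(scores_a)
  hb <- stats::bw.nrd0(scores_b)
  lo <- min(scores_a, scores_b) - 3 * max(ha, hb)
  hi <- max(scores_a, scores_b) + 3 * max(ha, hb)
  fa <- stats::density(scores_a, bw = ha, from = lo, to = hi,
                       n = grid_points)
  fb <- stats::density(scores_b, bw = hb, from = lo, to = hi,
                       n = grid_points)
  100 * trapz(fa$x, pmin(fa$y, fb$y))
}

#' Compare ITH distributions across samples
#'
#' One-way ANOVA of the per-cell scores on the sample factor, followed by
#' all pairwise two-sided t tests using the pooled within-group variance
#' (the ANOVA mean square error) and Sidak adjustment
#' `p' = 1 - (1 - p)^m` over the `m` pairs.
#'
#' @param distributions list of `ith_distribution`s (or named list of
#'   numeric vectors)
#' @return list with `anova` (data.frame: F, df1, df2, p) and `pairwise`
#'   (data.frame: group1, group2, diff, t, p, p_sidak)
#' @export
compare_ith <- function(distributions) {
  if (length(distributions) < 2) stop("at least 2 groups are required")
  scores <- lapply(distributions, function(d)
    if (inherits(d, "ith_distribution")) d$scores else as.numeric(d))
  labs <- names(scores)
  if (is.null(labs))
    labs <- vapply(distributions, function(d)
      if (inherits(d, "ith_distribution")) d$sample else NA_character_,
      character(1))
  if (anyNA(labs)) labs <- paste0("group", seq_along(scores))
  ns <- lengths(scores)
  if (any(ns < 2)) stop("every group needs at least 2 values")
  zero_var <- vapply(scores, function(s) stats::var(s) == 0, logical(1))
  if (any(zero_var & ns == 2))
    warning("group with zero variance and n = 2: ",
            paste(labs[zero_var & ns == 2], collapse = ", "))
  y <- unlist(scores, use.names = FALSE)
  g <- factor(rep(labs, ns), levels = labs)
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df2 <- an["Residuals", "Df"]
  pairs <- utils::combn(labs, 2)
  m <- ncol(pairs)
  means <- vapply(scores, mean, numeric(1))
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   stringsAsFactors = FALSE)
  pw$diff <- means[pw$group1] - means[pw$group2]
  se <- sqrt(mse * (1 / ns[pw$group1] + 1 / ns[pw$group2]))
  pw$t <- pw$diff / se
  pw$p <- 2 * stats::pt(-abs(pw$t), df = df2)
  pw$p_sidak <- pmin(1, 1 - (1 - pw$p)^m)
  rownames(pw) <- NULL
  list(anova = data.frame(F = an["g", "F value"], df1 = an["g", "Df"],
                          df2 = df2, p = an["g", "Pr(>F)"]),
       pairwise = pw)
}
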