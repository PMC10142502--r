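#' Quality-control filtering of a count matrix
#'
#' Applies, in fixed order: (1) drop cells with fewer than `min_genes`
#' detected genes; (2) drop outlier cells whose total count or detected-gene
#' count exceeds median + `count_mad_k` * MAD (a doublet proxy) or whose
#' mitochondrial count fraction exceeds median + `mito_mad_k` * MAD (a
#' damaged-cell proxy); (3) drop genes expressed in fewer than `min_cells`
#' of the retained cells. The pass sequence is repeated until nothing
#' changes, so the filter is idempotent: gene removal can push a cell's
#' detected-gene count below threshold, and outlier thresholds shift as
#' outliers leave, so a single pass is not a fixed point in general.
#'
#' Set `count_mad_k` or `mito_mad_k` to `Inf` to disable the corresponding
#' outlier rule.
#'
#' @param counts genes x cells matrix (dense or `Matrix`) with dimnames
#' @param min_genes minimum detected genes per cell
#' @param min_cells minimum cells per gene
#' @param mito_mad_k MAD multiplier for the mitochondrial-fraction rule
#' @param count_mad_k MAD multiplier for the count/gene outlier rules
#' @param mito_prefix gene-symbol prefix flagging mitochondrial genes
#' @return list with `counts` (filtered), `cells_dropped` / `genes_dropped`
#'   (character vectors), and `report` (per-pass drop counts by reason)
#' @export
qc_filter <- function(counts, min_genes = 800L, min_cells = 5L,
                      mito_mad_k = 3, count_mad_k = 3,
                      mito_prefix = "MT-") {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and cell identifiers")
  dropped_cells <- character(0)
  dropped_genes <- character(0)
  report <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    n0 <- dim(counts)
    detected <- Matrix::colSums(counts > 0)
    keep_cells <- detected >= min_genes
    n_lowgene <- sum(!keep_cells)
    counts2 <- counts[, keep_cells, drop = FALSE]
    if (ncol(counts2) == 0) stop("all cells removed by QC")

    detected <- Matrix::colSums(counts2 > 0)
    totals <- Matrix::colSums(counts2)
    mito <- is_mito(rownames(counts2), mito_prefix)
    mito_frac <- if (any(mito)) {
      Matrix::colSums(counts2[mito, , drop = FALSE]) / pmax(totals, 1)
    } else {
      rep(0, ncol(counts2))
    }
    hi <- function(x, k) {
      if (!is.finite(k)) return(rep(FALSE, length(x)))
      x > stats::median(x) + k * stats::mad(x)
    }
    out_count <- hi(totals, count_mad_k) | hi(detected, count_mad_k)
    out_mito <- hi(mito_frac, mito_mad_k)
    keep2 <- !(out_count | out_mito)
    counts3 <- counts2[, keep2, drop = FALSE]
    if (ncol(counts3) == 0) stop("all cells removed by QC")

    prevalence <- Matrix::rowSums(counts3 > 0)
    keep_genes <- prevalence >= min_cells
    counts4 <- counts3[keep_genes, , drop = FALSE]

    dropped_cells <- c(dropped_cells,
                       colnames(counts)[!keep_cells],
                       colnames(counts2)[!keep2])
    dropped_genes <- c(dropped_genes, rownames(counts3)[!keep_genes])
    report[[pass]] <- c(low_genes = n_lowgene,
                        outlier_count_or_genes = sum(out_count),
                        outlier_mito = sum(out_mito & !out_count),
                        genes_low_prevalence = sum(!keep_genes))
    changed <- !identical(dim(counts4), n0)
    counts <- counts4
    if (!changed) break
  }
  list(counts = counts, cells_dropped = dropped_cells,
       genes_dropped = dropped_genes, report = report)
}

#' Log-normalize counts to a fixed scale factor
#'
#' `value = log(1 + count * scale_factor / cell_total)` (natural log), the
#' standard global-scaling normalization for droplet UMI counts.
#'
#' @param counts genes x cells matrix
#' @param scale_factor target per-cell total after scaling
#' @return dense genes x cells matrix of normalized values
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cell with zero total count")
  m <- as.matrix(counts)
  log1p(sweep(m, 2, scale_factor / totals, "*"))
}

#' Merge count matrices from several samples by naive concatenation
#'
#' Columns are concatenated over the union of genes (genes absent from a
#' sample are zero-filled); cell identifiers are prefixed by the sample
#' label.
#'
#' @param matrices list of genes x cells matrices with dimnames
#' @param labels sample labels, one per matrix
#' @param sep separator between label and cell id
#' @return merged genes x cells sparse matrix; sample of each cell is
#'   recoverable from the identifier prefix
#' @export
merge_samples <- function(matrices, labels = names(matrices), sep = "_") {
  stopifnot(length(matrices) >= 1, length(labels) == length(matrices))
  genes <- Reduce(union, lapply(matrices, rownames))
  blocks <- mapply(function(m, lab) {
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    full <- Matrix::Matrix(0, nrow = length(genes), ncol = ncol(m),
                           dimnames = list(genes, paste0(lab, sep, colnames(m))),
                           sparse = TRUE)
    full[rownames(m), ] <- m
    full
  }, matrices, labels, SIMPLIFY = FALSE)
  out <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(out))) stop("duplicate cell ids after prefixing")
  out
}

#' Split a merged matrix back into per-sample matrices
#'
#' Inverse of [merge_samples()]: strips the label prefix from cell ids.
#'
#' @param merged matrix from [merge_samples()]
#' @param labels the sample labels used at merge time
#' @param sep separator used at merge time
#' @return named list of matrices
#' @export
split_samples <- function(merged, labels, sep = "_") {
  out <- lapply(labels, function(lab) {
    pre <- paste0(lab, sep)
    cols <- startsWith(colnames(merged), pre)
    m <- merged[, cols, drop = FALSE]
    colnames(m) <- substring(colnames(m), nchar(pre) + 1L)
    m
  })
  names(out) <- labels
  out
}

#' Expression-program module score
#'
#' Mean expression of the gene set minus the mean of expression-matched
#' control genes, per cell. Genes are binned into `n_bins` equal-frequency
#' bins of average expression; for each set gene, `n_ctrl` control genes
#' are sampled from its bin (with replacement when the bin is smaller than
#' `n_ctrl`), under the given seed.
#'
#' @param normed genes x cells normalized matrix
#' @param gene_set character vector of gene symbols
#' @param n_bins number of expression bins
#' @param n_ctrl control genes per set gene
#' @param seed RNG seed for control sampling
#' @return named numeric vector, one score per cell
#' @export
score_gene_module <- function(normed, gene_set, n_bins = 24L, n_ctrl = 100L,
                              seed = 0L) {
  genes <- rownames(normed)
  set_genes <- sort(intersect(gene_set, genes))  # canonical order: the
  # score is invariant to the order genes are supplied in
  if (length(set_genes) == 0)
    stop("gene set has no genes in the matrix")
  avg <- rowMeans(normed)
  n_bins_eff <- min(n_bins, length(genes))
  # equal-frequency binning on the rank of average expression
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins_eff / length(genes))
  by_bin <- split(seq_along(genes), bin)
  set.seed(seed)
  ctrl_idx <- unlist(lapply(set_genes, function(g) {
    pool <- by_bin[[as.character(bin[match(g, genes)])]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }), use.names = FALSE)
  set_mean <- colMeans(normed[set_genes, , drop = FALSE])
  ctrl_mean <- colMeans(normed[ctrl_idx, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Cell-cycle phase scores and calls
#'
#' S and G2M scores are module scores over the respective gene lists; a cell
#' is called G1 when both scores are negative (or when the scores tie),
#' otherwise the phase of the larger score.
#'
#' @param normed genes x cells normalized matrix
#' @param s_genes,g2m_genes phase gene lists
#' @param n_bins,n_ctrl,seed passed to [score_gene_module()] (the G2M score
#'   uses `seed + 1` so the two control draws are independent)
#' @return data.frame with columns `cell`, `s_score`, `g2m_score`, `phase`
#' @export
cell_cycle_scores <- function(normed, s_genes, g2m_genes, n_bins = 24L,
                              n_ctrl = 100L, seed = 0L) {
  s <- score_gene_module(normed, s_genes, n_bins, n_ctrl, seed = seed)
  g2m <- score_gene_module(normed, g2m_genes, n_bins, n_ctrl, seed = seed + 1L)
  phase <- ifelse(s < 0 & g2m < 0, "G1",
                  ifelse(s > g2m, "S", ifelse(g2m > s, "G2M", "G1")))
  data.frame(cell = colnames(normed), s_score = s, g2m_score = g2m,
             phase = phase, row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress out per-cell covariates and scale genes
#'
#' Per gene: ordinary least squares of normalized expression on the
#' covariates (with intercept), residuals centered and scaled to unit
#' variance, then clipped at `clip` in absolute value. Constant genes map
#' to all-zero rows. Constant covariate columns are dropped (the intercept
#' absorbs them); remaining rank deficiency is an error.
#'
#' @param normed genes x cells normalized matrix
#' @param covariates cells x p numeric matrix/data.frame (e.g. cell-cycle
#'   scores), or NULL for plain z-scoring
#' @param clip clip value for scaled residuals
#' @return genes x cells scaled residual matrix
#' @export
scale_and_regress <- function(normed, covariates = NULL, clip = 10) {
  n_cells <- ncol(normed)
  X <- matrix(1, nrow = n_cells, ncol = 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n_cells) stop("covariates must have one row per cell")
    keep <- apply(cv, 2, function(x) stats::sd(x) > 0)
    cv <- cv[, keep, drop = FALSE]
    X <- cbind(X, cv)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient")
  resid <- t(qr.resid(qx, t(normed)))
  sds <- apply(resid, 1, stats::sd)
  in_sds <- apply(normed, 1, stats::sd)
  # a gene is degenerate when it was constant or is fully explained by the
  # covariates (residuals at numerical noise level)
  const <- !is.finite(sds) | sds <= 1e-10 * pmax(in_sds, 1)
  sds[const] <- 1
  out <- resid / sds
  out[const, ] <- 0
  pmin(pmax(out, -clip), clip)
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing ranking: a local regression (loess, default span
#' 0.3) of log10 variance on log10 mean of the raw counts predicts each
#' gene's expected standard deviation; counts are standardized by that SD,
#' clipped at sqrt(n_cells), and genes are ranked by the variance of the
#' standardized values. Ties break by gene identifier.
#'
#' @param counts genes x cells raw count matrix
#' @param n number of genes to return
#' @param loess_span span of the mean-variance trend fit
#' @return character vector of the top `n` gene identifiers, in rank order
#' @export
select_hvgs <- function(counts, n = 2000L, loess_span = 0.3) {
  if (n > nrow(counts)) stop("n exceeds the gene count")
  m <- as.matrix(counts)
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  fitted_var <- rep(0, nrow(m))
  usable <- v > 0 & mu > 0
  fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                      span = loess_span, degree = 2)
  fitted_var[usable] <- 10^stats::predict(fit)
  clip_max <- sqrt(ncol(m))
  score <- rep(0, nrow(m))
  for (i in which(usable)) {
    z <- (m[i, ] - mu[i]) / sqrt(fitted_var[i])
    z <- pmin(pmax(z, -clip_max), clip_max)
    score[i] <- stats::var(z)
  }
  ord <- order(-score, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Principal component analysis of the scaled matrix
#'
#' Exact PCA with cells as observations, restricted to the given genes.
#' Deterministic sign convention: the largest-magnitude loading of each
#' component is positive. Variance-explained fractions are relative to the
#' total variance of the input (restricted) matrix.
#'
#' @param scaled genes x cells scaled matrix
#' @param genes genes to use (default: all rows)
#' @param n_pcs number of components
#' @return list of class `embedding` with `coords` (cells x n_pcs),
#'   `loadings` (genes x n_pcs), `variance_explained`
#' @export
run_pca <- function(scaled, genes = NULL, n_pcs = 20L) {
  if (is.null(genes)) genes <- rownames(scaled)
  X <- t(as.matrix(scaled[genes, , drop = FALSE]))  # cells x genes
  if (n_pcs > min(dim(X)) - 1L)
    stop("n_pcs must be at most min(genes, cells) - 1")
  total_var <- sum(apply(X, 2, stats::var))
  if (total_var == 0) stop("input matrix has zero variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  coords <- pc$x
  load <- pc$rotation
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- colnames(load) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coords = coords, loadings = load,
                 variance_explained = pc$sdev[seq_len(ncol(coords))]^2 / total_var),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells x %d PCs (%.1f%% variance explained)\n",
              nrow(x$coords), ncol(x$coords),
              100 * sum(x$variance_explained)))
  invisible(x)
}

embedding_coords <- function(embedding) {
  if (inherits(embedding, "embedding")) embedding$coords else as.matrix(embedding)
}

#' Build a shared-nearest-neighbor graph in PC space
#'
#' k-nearest-neighbor sets by Euclidean distance (self excluded; distance
#' ties break by cell index order); edge weight is the Jaccard overlap of
#' the two neighbor sets; weights below `prune` are removed. The graph is
#' symmetric by construction.
#'
#' @param embedding an `embedding` or a cells x dims coordinate matrix
#' @param k neighbors per cell (must be < number of cells)
#' @param prune Jaccard pruning threshold
#' @return symmetric sparse weight matrix (`dgCMatrix`) of class, with cell
#'   identifiers as dimnames
#' @export
build_snn <- function(embedding, k = 20L, prune = 1 / 15) {
  coords <- embedding_coords(embedding)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  nb <- matrix(0L, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # ties by index order
    nb[i, ] <- (seq_len(n)[-i])[ord[seq_len(k)]]
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nb)), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared / (2 * k - shared)
  jac <- as.matrix(jac)
  diag(jac) <- 0
  jac[jac < prune] <- 0
  out <- methods::as(methods::as(Matrix::Matrix(jac, sparse = TRUE),
                                 "CsparseMatrix"), "generalMatrix")
  dimnames(out) <- list(rownames(coords), rownames(coords))
  out
}

#' Cluster cells on the SNN graph with silhouette-based model selection
#'
#' Modularity-based (multilevel) community detection is run across a
#' resolution grid under a fixed seed; for each distinct cluster number `k`
#' within `k_range` the maximum-modularity partition is kept, its mean
#' silhouette width (Euclidean distance in the clustering PC space) is
#' computed, and the partition with the best mean silhouette wins. Ties go
#' to the smaller `k`, then to the lower resolution. Labels are contiguous
#' integers `0..k-1`, ordered by decreasing cluster size.
#'
#' @param graph SNN weight matrix from [build_snn()]
#' @param embedding the `embedding` (or coordinate matrix) used to build it
#' @param k_range admissible cluster-number range, c(lo, hi)
#' @param resolution_grid modularity resolutions to scan
#' @param seed RNG seed fixed before each detection run
#' @return list of class `cluster_assignment`: `labels` (named integer
#'   vector), `k`, `mean_silhouette`, `resolution`, `modularity`,
#'   `candidates` (per-k summary table)
#' @export
cluster_cells <- function(graph, embedding, k_range = c(2L, 10L),
                          resolution_grid = seq(0.1, 2, by = 0.1),
                          seed = 0L) {
  coords <- embedding_coords(embedding)
  g <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_by_k <- list()
  for (res in resolution_grid) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = res)
    memb <- igraph::membership(cl)
    k <- length(unique(memb))
    if (k < k_range[1] || k > k_range[2]) next
    mod <- igraph::modularity(g, memb,
                              weights = igraph::E(g)$weight,
                              resolution = res)
    key <- as.character(k)
    if (is.null(best_by_k[[key]]) || mod > best_by_k[[key]]$modularity) {
      best_by_k[[key]] <- list(membership = memb, modularity = mod,
                               resolution = res, k = k)
    }
  }
  if (length(best_by_k) == 0)
    stop("no partition with a cluster number inside k_range")
  d <- stats::dist(coords)
  for (key in names(best_by_k)) {
    sil <- cluster::silhouette(as.integer(best_by_k[[key]]$membership), d)
    best_by_k[[key]]$mean_silhouette <- mean(sil[, "sil_width"])
  }
  cand <- do.call(rbind, lapply(best_by_k, function(b)
    data.frame(k = b$k, resolution = b$resolution, modularity = b$modularity,
               mean_silhouette = b$mean_silhouette)))
  cand <- cand[order(cand$k), , drop = FALSE]
  rownames(cand) <- NULL
  ord <- order(-cand$mean_silhouette, cand$k, cand$resolution)
  winner <- best_by_k[[as.character(cand$k[ord[1]])]]
  memb <- winner$membership
  sizes <- table(memb)
  rank_map <- stats::setNames(seq_along(sizes) - 1L,
                              names(sizes)[order(-as.vector(sizes),
                                                 as.integer(names(sizes)))])
  labels <- as.integer(rank_map[as.character(memb)])
  names(labels) <- rownames(coords)
  structure(list(labels = labels, k = winner$k,
                 mean_silhouette = winner$mean_silhouette,
                 resolution = winner$resolution,
                 modularity = winner$modularity,
                 candidates = cand),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: k = %d (mean silhouette %.3f, resolution %.2f)\n",
              x$k, x$mean_silhouette, x$resolution))
  print(table(x$labels))
  invisible(x)
}
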