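#' Library-size size factors normalized to median one
#'
#' @param counts genes x cells matrix
#' @return numeric vector, one positive factor per cell
#' @export
size_factors <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cell with zero total count")
  totals / stats::median(totals)
}

#' Negative-binomial Wald test between two cell groups
#'
#' Self-contained two-group differential expression for UMI counts. Per
#' gene: size-factor-normalized group means; a common dispersion estimated
#' by the method of moments on the pooled normalized counts
#' (`Var = mu + alpha * mu^2`, `alpha` floored at 1e-8); a Wald statistic
#' on the log fold change with a delta-method standard error; two-sided
#' normal p values; Benjamini-Hochberg adjustment across the tested genes.
#' Genes with zero counts in both groups are skipped (NA). A group with a
#' zero mean enters the ratio and the variance at a pseudo-mean of half a
#' normalized count over the group, `max(eps, 0.5/n)`, so its fold change
#' is finite and its evidence scales with the other group's depth; such
#' genes are flagged in `zero_group`.
#'
#' @param counts genes x cells matrix
#' @param cells_group1,cells_group2 cell identifiers (or indices) of the
#'   two groups, each of size >= 3
#' @param sf size factors per cell of `counts`; computed when NULL
#' @param eps lower bound of the zero-group pseudo-mean
#' @return data.frame of class `de_result`: gene, mean1, mean2, log2fc,
#'   se, stat, p, padj, zero_group, direction
#' @export
nb_wald_test <- function(counts, cells_group1, cells_group2, sf = NULL,
                         eps = 1e-9) {
  m <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(m)
  idx <- function(cells) {
    if (is.character(cells)) match(cells, colnames(m)) else as.integer(cells)
  }
  i1 <- idx(cells_group1)
  i2 <- idx(cells_group2)
  if (anyNA(i1) || anyNA(i2)) stop("unknown cell identifiers")
  if (length(i1) < 3 || length(i2) < 3)
    stop("both groups need at least 3 cells")
  if (any(sf <= 0)) stop("size factors must be positive")
  y1 <- sweep(m[, i1, drop = FALSE], 2, sf[i1], "/")
  y2 <- sweep(m[, i2, drop = FALSE], 2, sf[i2], "/")
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(y1)
  m2 <- rowMeans(y2)
  pooled_mean <- (n1 * m1 + n2 * m2) / (n1 + n2)
  pooled_var <- (rowSums((y1 - m1)^2) + rowSums((y2 - m2)^2)) / (n1 + n2 - 2)
  alpha <- pmax((pooled_var - pooled_mean) / pooled_mean^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  tested <- m1 + m2 > 0
  zero_group <- tested & (m1 == 0 | m2 == 0)
  # zero-mean groups enter ratio and variance at a pseudo-mean of half a
  # normalized count over the group, keeping fold change and Wald
  # statistic finite and mutually consistent
  b1 <- pmax(m1, pmax(eps, 0.5 / n1))
  b2 <- pmax(m2, pmax(eps, 0.5 / n2))
  log2fc <- log2(b1 / b2)
  s1 <- sum(1 / sf[i1])
  s2 <- sum(1 / sf[i2])
  # Var(log mean) by the delta method under Var(count) = mu + alpha mu^2
  v1 <- (b1 * s1 / n1^2 + alpha * b1^2 / n1) / b1^2
  v2 <- (b2 * s2 / n2^2 + alpha * b2^2 / n2) / b2^2
  se_log2 <- sqrt(v1 + v2) / log(2)
  stat <- log2fc / se_log2
  p <- 2 * stats::pnorm(-abs(stat))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(
    gene = rownames(m), mean1 = m1, mean2 = m2,
    log2fc = ifelse(tested, log2fc, NA_real_),
    se = ifelse(tested, se_log2, NA_real_),
    stat = ifelse(tested, stat, NA_real_),
    p = p, padj = padj, zero_group = zero_group,
    direction = ifelse(!tested, NA_character_,
                       ifelse(log2fc > 0, "up",
                              ifelse(log2fc < 0, "down", "none"))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}

#' Positive marker genes per cluster
#'
#' For each cluster, runs [nb_wald_test()] of its cells against all other
#' cells and keeps genes with `log2fc >= min_log2fc` and `padj < alpha`
#' (positive markers only).
#'
#' @param counts genes x cells matrix
#' @param clusters cluster label per cell (named vectors are matched on
#'   cell ids)
#' @param min_log2fc minimum log2 fold change
#' @param alpha adjusted-p cutoff
#' @return named list of `de_result` data.frames (markers only), one per
#'   cluster
#' @export
find_cluster_markers <- function(counts, clusters, min_log2fc = 0.25,
                                 alpha = 0.05) {
  if (!is.null(names(clusters))) clusters <- clusters[colnames(counts)]
  stopifnot(length(clusters) == ncol(counts))
  levs <- sort(unique(clusters))
  if (length(levs) < 2) stop("at least 2 clusters are required")
  sf <- size_factors(counts)
  out <- lapply(levs, function(cl) {
    in_cl <- which(clusters == cl)
    if (length(in_cl) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      return(NULL)
    }
    de <- nb_wald_test(counts, in_cl, which(clusters != cl), sf = sf)
    keep <- !is.na(de$padj) & de$padj < alpha & de$log2fc >= min_log2fc
    de[keep, , drop = FALSE]
  })
  names(out) <- as.character(levs)
  out
}

#' Pseudo-bulk condition contrast
#'
#' Cells take their sample identity; all cells of condition A samples are
#' contrasted against all cells of condition B samples with
#' [nb_wald_test()], returning both up- and downregulated genes.
#'
#' @param counts genes x cells matrix
#' @param samples sample identity per cell
#' @param condition_map named vector mapping sample -> condition
#' @param condition_a,condition_b the two conditions to contrast (group 1
#'   = A)
#' @return a `de_result` data.frame
#' @export
pseudo_bulk_contrast <- function(counts, samples, condition_map,
                                 condition_a, condition_b) {
  stopifnot(length(samples) == ncol(counts))
  cond <- condition_map[samples]
  i_a <- which(cond == condition_a)
  i_b <- which(cond == condition_b)
  if (length(i_a) == 0 || length(i_b) == 0)
    stop("condition with zero cells")
  nb_wald_test(counts, i_a, i_b)
}

#' Genes shared across models
#'
#' Given per-model gene lists of one direction (e.g. genes upregulated on
#' colonization in each model), returns genes present in at least
#' `min_models` lists, plus the counts of every region of the Venn
#' partition (keyed by membership pattern, e.g. `"1011"`).
#'
#' @param gene_lists named list of character vectors
#' @param min_models minimum number of lists a shared gene must appear in
#' @return list: `shared` (character), `venn_counts` (named integer vector
#'   over membership bitmasks), `n_models`
#' @export
shared_signature <- function(gene_lists, min_models = 3L) {
  if (length(gene_lists) < min_models)
    stop("fewer lists than min_models")
  all_genes <- unique(unlist(gene_lists, use.names = FALSE))
  memb <- vapply(gene_lists, function(l) all_genes %in% l,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1)
  n_in <- rowSums(memb)
  pattern <- apply(memb, 1, function(z) paste(as.integer(z), collapse = ""))
  venn <- table(pattern)
  list(shared = sort(all_genes[n_in >= min_models]),
       venn_counts = stats::setNames(as.integer(venn), names(venn)),
       n_models = length(gene_lists))
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set (intersected with the universe and size-filtered), the
#' upper-tail hypergeometric probability `P(X >= overlap)` of drawing at
#' least the observed overlap when `|query|` genes are drawn from the
#' universe; BH adjustment across tested sets.
#'
#' @param query character vector of hit genes (intersected with universe)
#' @param universe background gene list (e.g. all genes expressed after QC)
#' @param collection named list of gene sets (see [read_gmt()])
#' @param min_set,max_set set-size bounds (after universe intersection)
#' @return data.frame of class `enrichment_result`: set, overlap, set_size,
#'   query_size, universe_size, p, padj, genes (semicolon-joined overlap)
#' @export
hypergeom_enrich <- function(query, universe, collection,
                             min_set = 10L, max_set = 500L) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("empty query after universe intersection")
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  keep <- lengths(sets) >= min_set & lengths(sets) <= max_set
  sets <- sets[keep]
  N <- length(universe)
  n_draw <- length(query)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    ov <- intersect(query, sets[[nm]])
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K,
               query_size = n_draw, universe_size = N, p = p,
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), c("set", "overlap", "set_size",
                                      "query_size", "universe_size", "p",
                                      "padj", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper: `q_i = min_{j >= i} (p_(j) * m / j)` capped at 1, in
#' the original order.
#'
#' @param p numeric vector of p values in [0, 1]
#' @return adjusted p values
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Transcriptional signature of expanded clones
#'
#' Contrasts the cells of the given (top expanded) clones against the
#' remaining assigned cells of the same sample with [nb_wald_test()], then
#' runs [hypergeom_enrich()] on the significantly upregulated genes. The
#' downregulated significant gene list is also returned.
#'
#' @param counts genes x cells matrix
#' @param assignment a `clone_assignment` covering the sample's cells
#' @param top_clones tag ids of the expanded clones
#' @param collection gene-set collection for enrichment (NULL to skip)
#' @param alpha adjusted-p cutoff for the signature genes
#' @param min_log2fc minimum |log2fc| for the signature genes
#' @param ... passed to [hypergeom_enrich()]
#' @return list: `de` (`de_result`), `up_genes`, `down_genes`,
#'   `enrichment` (on up genes, or NULL)
#' @export
enriched_clone_signature <- function(counts, assignment, top_clones,
                                     collection = NULL, alpha = 0.05,
                                     min_log2fc = 0.25, ...) {
  assigned <- assignment[!is.na(assignment$tag_id), , drop = FALSE]
  assigned <- assigned[assigned$cell %in% colnames(counts), , drop = FALSE]
  in_top <- assigned$tag_id %in% top_clones
  cells_top <- assigned$cell[in_top]
  cells_rest <- assigned$cell[!in_top]
  if (length(cells_top) < 3 || length(cells_rest) < 3)
    stop("both groups need at least 3 cells")
  de <- nb_wald_test(counts, cells_top, cells_rest)
  sig <- !is.na(de$padj) & de$padj < alpha & abs(de$log2fc) >= min_log2fc
  up <- de$gene[sig & de$log2fc > 0]
  down <- de$gene[sig & de$log2fc < 0]
  enr <- NULL
  if (!is.null(collection) && length(up) > 0) {
    enr <- hypergeom_enrich(up, rownames(counts), collection, ...)
  }
  list(de = de, up_genes = up, down_genes = down, enrichment = enr)
}
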