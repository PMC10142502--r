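#' Clone-size distribution per condition
#'
#' Counts assigned cells per lineage tag within each condition. Unassigned
#' cells are excluded from the table and reported separately.
#'
#' @param assignment a `clone_assignment` (columns `cell`, `tag_id`)
#' @param conditions condition label per row of `assignment`
#' @return list with `table` (data.frame: condition, tag_id, n_cells, rank
#'   -- rank 1 = largest within its condition, ties by tag id) and
#'   `unassigned` (named vector of unassigned-cell counts per condition)
#' @export
clone_size_distribution <- function(assignment, conditions) {
  stopifnot(nrow(assignment) == length(conditions))
  assigned <- !is.na(assignment$tag_id)
  unassigned <- tapply(!assigned, conditions, sum)
  if (!any(assigned)) {
    return(list(table = data.frame(condition = character(0),
                                   tag_id = character(0),
                                   n_cells = integer(0), rank = integer(0),
                                   stringsAsFactors = FALSE),
                unassigned = unassigned))
  }
  df <- data.frame(condition = conditions[assigned],
                   tag_id = assignment$tag_id[assigned],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n_cells = rep(1L, nrow(df))) ~ condition + tag_id,
                          data = df, FUN = sum)
  agg <- agg[order(agg$condition, -agg$n_cells, agg$tag_id), , drop = FALSE]
  agg$rank <- stats::ave(seq_len(nrow(agg)), agg$condition,
                         FUN = seq_along)
  rownames(agg) <- NULL
  list(table = agg[, c("condition", "tag_id", "n_cells", "rank")],
       unassigned = unassigned)
}

#' Unique-clone fraction of a condition
#'
#' Percentage of assigned cells whose lineage tag occurs in exactly one
#' cell of that condition. High under neutral growth, low after selective
#' clonal expansion.
#'
#' @param assignment a `clone_assignment`
#' @param conditions condition label per row; NULL treats all rows as one
#'   condition
#' @param condition the condition to evaluate (default: all rows)
#' @return percentage in [0, 100]
#' @export
unique_clone_fraction <- function(assignment, conditions = NULL,
                                  condition = NULL) {
  tags <- assignment$tag_id
  if (!is.null(conditions) && !is.null(condition)) {
    tags <- tags[conditions == condition]
  }
  tags <- tags[!is.na(tags)]
  if (length(tags) == 0) stop("no assigned cells in the condition")
  sizes <- table(tags)
  100 * sum(sizes == 1) / length(tags)
}

#' Top expanded clones by cell count
#'
#' Ranks clones by descending cell count with ties broken by tag id, and
#' returns the top `n` with their member cells. If no clone has more than
#' one cell the result is flagged `no_expansion`.
#'
#' @param assignment a `clone_assignment`
#' @param n clones to return
#' @param warn_small warn when fewer than `n` clones have >= 2 cells
#' @return list: `tag_ids` (ordered character), `sizes`, `members` (named
#'   list of cell vectors), `no_expansion` flag
#' @export
top_enriched_clones <- function(assignment, n = 10L, warn_small = TRUE) {
  assigned <- assignment[!is.na(assignment$tag_id), , drop = FALSE]
  if (nrow(assigned) == 0) stop("no assigned cells")
  sizes <- table(assigned$tag_id)
  ord <- order(-as.vector(sizes), names(sizes))
  top <- names(sizes)[ord][seq_len(min(n, length(sizes)))]
  if (warn_small && sum(sizes >= 2) < n)
    warning(sprintf("only %d clones have >= 2 cells (requested top %d)",
                    sum(sizes >= 2), n))
  members <- split(assigned$cell, assigned$tag_id)[top]
  list(tag_ids = top,
       sizes = as.integer(sizes[top]),
       members = members,
       no_expansion = all(sizes == 1))
}

#' Cluster occupancy by condition with enrichment tests
#'
#' For each cluster, the percentage of each condition's cells falling in
#' that cluster, a two-sided two-proportion z test (pooled) comparing the
#' two conditions, and Benjamini-Hochberg adjustment across clusters.
#' Exact percentages sum to 100 per condition before any formatting.
#'
#' @param clusters cluster label per cell
#' @param conditions condition label per cell (exactly 2 distinct values)
#' @param alpha significance level for the `enriched` flag
#' @param fisher use Fisher's exact test instead of the z test (small
#'   counts)
#' @return data.frame: cluster, pct_<condA>, pct_<condB>, n_<condA>,
#'   n_<condB>, p, padj, enriched
#' @export
cluster_condition_distribution <- function(clusters, conditions,
                                           alpha = 0.05, fisher = FALSE) {
  stopifnot(length(clusters) == length(conditions))
  conds <- sort(unique(conditions))
  if (length(conds) != 2) stop("exactly 2 conditions are required")
  n_a <- sum(conditions == conds[1])
  n_b <- sum(conditions == conds[2])
  if (n_a == 0 || n_b == 0) stop("condition with 0 cells")
  tab <- table(factor(clusters), factor(conditions, levels = conds))
  ka <- as.vector(tab[, 1])
  kb <- as.vector(tab[, 2])
  p_vals <- vapply(seq_len(nrow(tab)), function(i) {
    if (fisher) {
      m <- matrix(c(ka[i], n_a - ka[i], kb[i], n_b - kb[i]), nrow = 2)
      stats::fisher.test(m)$p.value
    } else {
      p_pool <- (ka[i] + kb[i]) / (n_a + n_b)
      se <- sqrt(p_pool * (1 - p_pool) * (1 / n_a + 1 / n_b))
      if (se == 0) return(1)
      z <- (ka[i] / n_a - kb[i] / n_b) / se
      2 * stats::pnorm(-abs(z))
    }
  }, numeric(1))
  padj <- stats::p.adjust(p_vals, method = "BH")
  out <- data.frame(cluster = rownames(tab),
                    pct_a = 100 * ka / n_a,
                    pct_b = 100 * kb / n_b,
                    n_a = ka, n_b = kb,
                    p = p_vals, padj = padj,
                    enriched = padj < alpha,
                    stringsAsFactors = FALSE)
  colnames(out)[2:5] <- c(paste0("pct_", conds), paste0("n_", conds))
  rownames(out) <- NULL
  out
}

#' Clone-by-cluster contingency table for enriched clones
#'
#' Rows are the given (enriched) clones, columns are clusters, entries are
#' cell counts; row and column margins are attached.
#'
#' @param assignment a `clone_assignment`
#' @param clusters named vector of cluster labels (names = cell ids), or a
#'   vector aligned with `assignment`
#' @param clone_set tag ids forming the rows
#' @return list: `table` (matrix clones x clusters), `row_margins`,
#'   `col_margins`
#' @export
clone_cluster_contingency <- function(assignment, clusters, clone_set) {
  if (!is.null(names(clusters))) {
    cl <- clusters[assignment$cell]
  } else {
    stopifnot(length(clusters) == nrow(assignment))
    cl <- clusters
  }
  keep <- !is.na(assignment$tag_id) & assignment$tag_id %in% clone_set
  tab <- table(factor(assignment$tag_id[keep], levels = clone_set),
               factor(cl[keep]))
  m <- methods::as(unclass(tab), "matrix")
  list(table = m,
       row_margins = rowSums(m),
       col_margins = colSums(m))
}
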