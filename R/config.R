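#' Pipeline run configuration
#'
#' Bundles the tunable thresholds of the workflow in one validated object.
#' Defaults follow the published analysis this package reproduces: cells with
#' fewer than 800 expressed genes are discarded, genes must be seen in at
#' least 5 cells, the top 2000 highly variable genes feed a 20-component PCA,
#' clustering runs on a 20-nearest-neighbor SNN graph pruned at Jaccard
#' 1/15, the cluster number is chosen between 2 and 10 by mean silhouette,
#' and lineage tags are 38 bp corrected within Hamming distance 1.
#'
#' @param min_genes_per_cell minimum detected genes for a cell to be kept
#' @param min_cells_per_gene minimum cells expressing a gene for it to be kept
#' @param n_hvgs number of highly variable genes
#' @param n_pcs number of principal components retained
#' @param k_neighbors neighbors for the SNN graph
#' @param snn_prune Jaccard weight below which SNN edges are dropped, in [0,1)
#' @param k_range integer vector of length 2, inclusive range of admissible
#'   cluster numbers; lower bound must be >= 2
#' @param tag_length lineage-tag length in bp
#' @param max_tag_hamming maximum Hamming distance for tag correction (0 or 1)
#' @param cid_len cell-barcode length in bp for tag reads
#' @param umi_len UMI length in bp for tag reads
#' @param rng_seed integer seed used by all stochastic stages
#' @return a list of class `run_config`
#' @export
run_config <- function(min_genes_per_cell = 800L,
                       min_cells_per_gene = 5L,
                       n_hvgs = 2000L,
                       n_pcs = 20L,
                       k_neighbors = 20L,
                       snn_prune = 1 / 15,
                       k_range = c(2L, 10L),
                       tag_length = 38L,
                       max_tag_hamming = 1L,
                       cid_len = 16L,
                       umi_len = 12L,
                       rng_seed = 0L) {
  cfg <- list(
    min_genes_per_cell = as.integer(min_genes_per_cell),
    min_cells_per_gene = as.integer(min_cells_per_gene),
    n_hvgs = as.integer(n_hvgs),
    n_pcs = as.integer(n_pcs),
    k_neighbors = as.integer(k_neighbors),
    snn_prune = as.numeric(snn_prune),
    k_range = as.integer(k_range),
    tag_length = as.integer(tag_length),
    max_tag_hamming = as.integer(max_tag_hamming),
    cid_len = as.integer(cid_len),
    umi_len = as.integer(umi_len),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("min_genes_per_cell", "min_cells_per_gene", "n_hvgs", "n_pcs",
              "k_neighbors", "tag_length", "cid_len", "umi_len")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop(sprintf("'%s' must be a single strictly positive integer", f))
  }
  if (cfg$max_tag_hamming < 0L)
    stop("'max_tag_hamming' must be non-negative")
  if (cfg$snn_prune < 0 || cfg$snn_prune >= 1)
    stop("'snn_prune' must lie in [0, 1)")
  if (length(cfg$k_range) != 2L || cfg$k_range[1] < 2L ||
      cfg$k_range[2] < cfg$k_range[1])
    stop("'k_range' must be c(lo, hi) with 2 <= lo <= hi")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys are the arguments of [run_config()]; missing keys take defaults,
#' unknown keys are an error.
#'
#' @param path YAML file path
#' @return a `run_config` object
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (f in names(x)) {
    cat(sprintf("  %-20s %s\n", f, paste(x[[f]], collapse = ", ")))
  }
  invisible(x)
}
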