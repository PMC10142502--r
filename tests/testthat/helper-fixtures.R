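# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A moderate clone-structured dataset with counts, used by clustering,
# module-score and clonal tests.
default_sim <- function() {
  fixture("default_sim", function() {
    truth <- simulate_clonal_population(1200, 1100, seed = 101)
    sim <- simulate_counts(truth, n_genes = 2000, seed = 102)
    qc <- qc_filter(sim$counts)
    normed <- normalize_counts(qc$counts)
    meta <- sim$cell_meta[match(colnames(qc$counts), sim$cell_meta$cell), ]
    list(truth = truth, sim = sim, qc = qc, normed = normed, meta = meta)
  })
}

# The same dataset carried through scaling, HVG selection and PCA.
default_embedding <- function() {
  fixture("default_embedding", function() {
    fx <- default_sim()
    cc <- cell_cycle_scores(fx$normed, fx$sim$s_genes, fx$sim$g2m_genes,
                            seed = 103)
    scaled <- scale_and_regress(fx$normed, cc[, c("s_score", "g2m_score")])
    hvgs <- select_hvgs(fx$qc$counts, n = 800)
    emb <- run_pca(scaled, hvgs, n_pcs = 20)
    c(fx, list(cc = cc, scaled = scaled, hvgs = hvgs, emb = emb))
  })
}

# Two well-separated Gaussian blobs in 2-D.
two_blob_coords <- function(n_per = 100, sep = 20, sd = 1, seed = 7) {
  set.seed(seed)
  coords <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd)))
  rownames(coords) <- sprintf("cell%03d", seq_len(2 * n_per))
  coords
}

# Counts matrix with a prescribed number of detected genes per cell.
counts_with_detected <- function(detected, n_genes = max(detected) + 10) {
  n <- length(detected)
  m <- matrix(0L, nrow = n_genes, ncol = n,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n))))
  for (j in seq_len(n)) m[seq_len(detected[j]), j] <- 1L
  m
}

# Small deterministic barcode library for tag tests.
toy_library <- function(n_tags = 50, tag_length = 12, seed = 42) {
  make_barcode_library(n_tags, tag_length = tag_length, seed = seed)
}

# Hand-rolled Hamming distance used as an oracle (independent of the
# package's vectorized implementations).
oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}
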