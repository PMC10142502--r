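test_that("QC thresholds are strict and hand-checkable", {
  m <- counts_with_detected(c(900, 799, 1200, 800), n_genes = 1300)
  out <- qc_filter(m, min_genes = 800, min_cells = 1,
                   mito_mad_k = Inf, count_mad_k = Inf)
  expect_equal(colnames(out$counts), c("c01", "c03", "c04"))

  # gene expressed in fewer than min_cells cells is removed
  m2 <- matrix(1L, nrow = 3, ncol = 5,
               dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
  m2[3, 1] <- 0L  # gene 3 seen in 4 of 5 cells
  out2 <- qc_filter(m2, min_genes = 1, min_cells = 5,
                    mito_mad_k = Inf, count_mad_k = Inf)
  expect_equal(rownames(out2$counts), c("g1", "g2"))
})

test_that("QC removes planted doublets and high-mito cells", {
  set.seed(5)
  n <- 300
  n_genes <- 500
  base <- matrix(rpois(n_genes * n, 4), nrow = n_genes,
                 dimnames = list(c(sprintf("MT-%02d", 1:10),
                                   sprintf("g%03d", 1:(n_genes - 10))),
                                 sprintf("c%03d", 1:n)))
  dbl <- 1:30
  base[, dbl] <- base[, dbl] + matrix(rpois(n_genes * 30, 4), nrow = n_genes)
  dmg <- 31:45
  base[1:10, dmg] <- base[1:10, dmg] * 8L
  out <- qc_filter(base, min_genes = 50, min_cells = 1)
  expect_gte(mean(sprintf("c%03d", dbl) %in% out$cells_dropped), 0.9)
  expect_gte(mean(sprintf("c%03d", dmg) %in% out$cells_dropped), 0.9)
})

test_that("QC filtering is idempotent", {
  fx <- default_sim()
  once <- qc_filter(fx$sim$counts)
  twice <- qc_filter(once$counts)
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
  expect_length(twice$cells_dropped, 0)
  expect_length(twice$genes_dropped, 0)
})

test_that("log-normalization has the stated closed form", {
  m <- matrix(c(1L, 99L, 0L, 50L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- normalize_counts(m, scale_factor = 1e4)
  expect_equal(norm["g1", "c1"], log(1 + 1 * 1e4 / 100))
  expect_equal(norm["g1", "c2"], 0)
  # algebraic identity: column sums of exp(value) - 1 equal the scale factor
  expect_equal(unname(colSums(exp(norm) - 1)), c(1e4, 1e4))
  m[, 1] <- 0L
  expect_error(normalize_counts(m), "zero total")
})

test_that("normalization commutes with cell subsetting after QC", {
  fx <- default_sim()
  sub <- colnames(fx$qc$counts)[seq(1, ncol(fx$qc$counts), by = 7)]
  a <- normalize_counts(fx$qc$counts)[, sub]
  b <- normalize_counts(fx$qc$counts[, sub])
  expect_equal(a, b)
})

test_that("module scores are centered, seeded, and track true program weights", {
  m <- matrix(3, nrow = 40, ncol = 10,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:10)))
  s <- score_gene_module(m, paste0("g", 1:5), seed = 1)
  expect_equal(unname(s), rep(0, 10))

  fx <- default_sim()
  prog1 <- fx$sim$gene_meta$gene[!is.na(fx$sim$gene_meta$program) &
                                   fx$sim$gene_meta$program == 1]
  prog1 <- intersect(prog1, rownames(fx$normed))
  sc1 <- score_gene_module(fx$normed, prog1, seed = 2)
  sc2 <- score_gene_module(fx$normed, rev(prog1), seed = 2)
  expect_equal(sc1, sc2)  # gene-order invariance with a fixed seed

  w1 <- fx$truth$weights[colnames(fx$normed), 1]
  expect_gt(cor(sc1, w1, method = "spearman"), 0.8)

  expect_error(score_gene_module(fx$normed, c("absent1", "absent2")),
               "no genes")
})

test_that("cell-cycle calls follow the sign rule and recover true phases", {
  m <- matrix(2, nrow = 30, ncol = 6,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:6)))
  cc0 <- cell_cycle_scores(m, paste0("g", 1:5), paste0("g", 6:10), seed = 1)
  expect_true(all(cc0$phase == "G1"))
  expect_equal(cc0$s_score, rep(0, 6))

  fx <- default_sim()
  cc <- cell_cycle_scores(fx$normed, fx$sim$s_genes, fx$sim$g2m_genes,
                          seed = 3)
  expect_gt(mean(cc$phase == fx$meta$phase), 0.9)
  # the larger positive score names the phase
  pos <- cc$s_score > 0 & cc$s_score > cc$g2m_score
  expect_true(all(cc$phase[pos] == "S"))
})

test_that("covariate regression yields orthogonal, scaled, clipped residuals", {
  set.seed(9)
  n <- 80
  covar <- cbind(score = rnorm(n))
  y <- rbind(2 * covar[, 1] + rnorm(n, sd = 0.5),
             rnorm(n),
             rep(1, n))
  dimnames(y) <- list(c("driven", "noise", "flat"), paste0("c", 1:n))
  out <- scale_and_regress(y, covar)
  expect_lt(abs(cor(out["driven", ], covar[, 1])), 1e-10)
  expect_lt(abs(cor(out["noise", ], covar[, 1])), 1e-10)
  expect_equal(unname(out["flat", ]), rep(0, n))
  expect_equal(sd(out["noise", ]), 1, tolerance = 1e-8)

  # closed-form OLS oracle: residual variance of the driven gene matches
  fit <- lm(y["driven", ] ~ covar[, 1])
  expect_gt(summary(fit)$r.squared, 0.8)
  raw_resid <- t(resid(fit))
  expect_equal(unname(out["driven", ]),
               unname(as.vector(raw_resid / sd(raw_resid))))

  # no covariates -> plain z-scoring
  z <- scale_and_regress(y)
  expect_equal(unname(z["noise", ]),
               unname(as.vector(scale(y["noise", ]))), tolerance = 1e-10)
  expect_equal(max(abs(scale_and_regress(y, covar, clip = 1))), 1)
})

test_that("HVG selection ranks by standardized variance with stated ties", {
  fx <- default_sim()
  hv <- select_hvgs(fx$qc$counts, n = 600)
  prog <- fx$sim$gene_meta$gene[!is.na(fx$sim$gene_meta$program)]
  prog <- intersect(prog, rownames(fx$qc$counts))
  expect_gte(mean(prog %in% hv), 0.8)

  # identical count vectors tie; order falls back to gene id
  m <- fx$qc$counts[1:50, 1:100]
  m <- rbind(m, zzz_dup = m[1, ], aaa_dup = m[1, ])
  hv2 <- select_hvgs(m, n = nrow(m))
  expect_lt(match("aaa_dup", hv2), match("zzz_dup", hv2))

  # a zero-variance gene is never selected over varying genes
  m2 <- rbind(m, const = rep(3L, ncol(m)))
  hv3 <- select_hvgs(m2, n = nrow(m2) - 1)
  expect_false("const" %in% hv3)

  expect_error(select_hvgs(m, n = 1e5), "exceeds")
})

test_that("PCA is exact, sign-fixed, and variance-ordered", {
  # data on a line in gene space: PC1 carries ~all variance
  set.seed(4)
  t_par <- rnorm(50)
  line <- rbind(g1 = 2 * t_par, g2 = -t_par, g3 = 0.5 * t_par)
  colnames(line) <- paste0("c", 1:50)
  emb1 <- run_pca(line, n_pcs = 2)
  expect_gt(emb1$variance_explained[1], 0.999)

  fx <- default_embedding()
  ve <- fx$emb$variance_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1)
  expect_true(all(ve >= 0 & ve <= 1))

  # eigendecomposition oracle on a random matrix
  set.seed(11)
  x <- matrix(rnorm(50 * 30), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:50)))
  emb <- run_pca(x, n_pcs = 10)
  xc <- scale(t(x), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  oracle <- xc %*% eig$vectors[, 1:10]
  expect_lt(max(abs(abs(emb$coords) - abs(oracle))), 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:10) {
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
  }
})

test_that("the SNN graph has hand-checkable Jaccard weights", {
  pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, 1))
  g <- build_snn(pts, k = 2, prune = 0)
  off <- as.matrix(g)[upper.tri(matrix(0, 3, 3))]
  expect_equal(off, rep(1 / 3, 3))

  # duplicate points: deterministic tie-break by cell index
  dup <- rbind(a = c(0, 0), b = c(0, 0), c = c(0, 0), d = c(5, 5))
  g1 <- build_snn(dup, k = 2, prune = 0)
  g2 <- build_snn(dup, k = 2, prune = 0)
  expect_identical(as.matrix(g1), as.matrix(g2))

  # two-blob data: pruning separates the graph into 2 components,
  # matching a brute-force kNN oracle
  coords <- two_blob_coords(100)
  g3 <- build_snn(coords, k = 20, prune = 1 / 15)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    g3, mode = "undirected", weighted = TRUE))
  expect_equal(comp$no, 2)
  d <- as.matrix(dist(coords))
  oracle_nb <- lapply(1:200, function(i) {
    ord <- order(d[i, -i], seq_len(200)[-i])
    (seq_len(200)[-i])[ord[1:20]]
  })
  cross <- outer(1:200, 1:200, Vectorize(function(i, j) {
    s <- length(intersect(oracle_nb[[i]], oracle_nb[[j]]))
    s / (40 - s)
  }))
  diag(cross) <- 0
  cross[cross < 1 / 15] <- 0
  expect_equal(unname(as.matrix(g3)), cross, tolerance = 1e-12)

  expect_error(build_snn(pts, k = 3), "smaller")
})

test_that("silhouette model selection recovers separated structure", {
  coords <- two_blob_coords(80)
  g <- build_snn(coords, k = 15, prune = 1 / 15)
  cl <- cluster_cells(g, coords, seed = 0)
  expect_equal(cl$k, 2)
  expect_gt(cl$mean_silhouette, 0.7)
  expect_equal(sort(unique(cl$labels)), c(0L, 1L))

  # constrained selection returns the best partition for that k
  cl2 <- cluster_cells(g, coords, k_range = c(2, 2), seed = 0)
  expect_equal(cl2$k, 2)

  # permuting the cells yields the identical partition up to labels
  perm <- sample(seq_len(nrow(coords)))
  gp <- build_snn(coords[perm, ], k = 15, prune = 1 / 15)
  clp <- cluster_cells(gp, coords[perm, ], seed = 0)
  expect_equal(mclust::adjustedRandIndex(
    cl$labels[rownames(coords)[perm]], clp$labels), 1)
})

test_that("sample merging concatenates over the gene union and round-trips", {
  a <- matrix(1:6, nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  b <- matrix(7:12, nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  m <- merge_samples(list(A = a, B = b))
  expect_equal(dim(m), c(3, 4))
  expect_equal(colnames(m), c("A_c1", "A_c2", "B_c1", "B_c2"))

  # disjoint gene sets zero-fill
  c1 <- matrix(1:2, nrow = 2, dimnames = list(c("x1", "x2"), "c1"))
  c2 <- matrix(3:5, nrow = 3, dimnames = list(c("y1", "y2", "y3"), "c1"))
  mm <- merge_samples(list(S1 = c1, S2 = c2))
  expect_equal(dim(mm), c(5, 2))
  expect_equal(as.numeric(mm["y1", ]), c(0, 3))

  # merge then split reproduces the inputs
  back <- split_samples(m, c("A", "B"))
  expect_equal(as.matrix(back$A), a)
  expect_equal(as.matrix(back$B), b)

  expect_error(merge_samples(list(A = a, A = a)), "duplicate")
})

test_that("clustering the default clone-structured data recovers programs", {
  fx <- default_embedding()
  g <- build_snn(fx$emb)
  cl <- cluster_cells(g, fx$emb, seed = 0)
  dom <- fx$truth$clones$dominant_program[
    match(fx$meta$clone, fx$truth$clones$clone)]
  expect_gt(mclust::adjustedRandIndex(cl$labels, dom), 0.7)
})
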