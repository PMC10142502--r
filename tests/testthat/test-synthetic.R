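test_that("barcode library is unique, deterministic, and distance-audited", {
  lib <- make_barcode_library(4, tag_length = 1, seed = 3)
  expect_setequal(lib$tags, c("A", "C", "G", "T"))

  lib1 <- make_barcode_library(200, tag_length = 10, seed = 5)
  lib2 <- make_barcode_library(200, tag_length = 10, seed = 5)
  expect_identical(lib1, lib2)
  expect_false(anyDuplicated(lib1$tags) > 0)

  # reported min pairwise Hamming matches a brute-force all-pairs oracle
  lib3 <- make_barcode_library(150, tag_length = 8, seed = 9)
  brute <- min(combn(lib3$tags, 2,
                     function(p) oracle_hamming(p[1], p[2])))
  expect_equal(lib3$min_hamming, brute)

  expect_error(make_barcode_library(5, tag_length = 1), "exceeds")
})

test_that("clonal population has controllable near-uniform clone sizes", {
  # pigeonhole: as many clones as cells -> all singletons
  tr <- simulate_clonal_population(10, 10, seed = 1)
  expect_true(all(tr$clones$size == 1))
  expect_equal(truth_unique_fraction(tr), 100)

  # heritability: sigma = 0 makes clonemates identical
  tr0 <- simulate_clonal_population(60, 20, sigma = 0, seed = 2)
  by_clone <- split(seq_len(60), tr0$cells$clone)
  for (idx in by_clone) {
    if (length(idx) > 1) {
      expect_equal(max(apply(tr0$weights[idx, , drop = FALSE], 2, var)), 0)
    }
  }

  # realized singleton fraction vs a Monte-Carlo resampling oracle
  tr7 <- simulate_clonal_population(2000, 1800, seed = 7)
  oracle <- replicate(3000, {
    extra <- tabulate(sample.int(1800, 200, replace = TRUE), nbins = 1800)
    sz <- 1L + extra
    100 * sum(sz == 1) / 2000
  })
  expect_lt(abs(truth_unique_fraction(tr7) - mean(oracle)), 3)

  expect_error(simulate_clonal_population(10, 10, sigma = -1), "sigma")
  expect_error(simulate_clonal_population(10, 11), "n_clones")
})

test_that("identity bottleneck preserves clone sizes and shifts programs", {
  tr <- simulate_clonal_population(300, 200, seed = 4)
  shifted <- apply_bottleneck(tr, survival_prob = 1, skew = 0,
                              expansion_mean = 1,
                              cond_effect = c(1, 0, 0, 0),
                              condition = "tibia", seed = 5)
  expect_equal(shifted$clones$size[order(shifted$clones$clone)],
               tr$clones$size[order(tr$clones$clone)])
  expect_equal(sum(shifted$clones$size), 300)
  # condition effect appears as a mean shift on the targeted program
  expect_equal(mean(shifted$weights[, 1]) - mean(tr$weights[, 1]), 1,
               tolerance = 0.1)
})

test_that("selective bottleneck reduces clonal diversity as replicates predict", {
  # the realized diversity gap of one run lies inside the replicate
  # distribution of the generator itself (mean +/- 2 SD)
  gap_for_seed <- function(s) {
    tr <- simulate_clonal_population(500, 460, seed = s)
    bt <- apply_bottleneck(tr, survival_prob = 0.2, skew = 2,
                           expansion_mean = 8, seed = s + 1000)
    truth_unique_fraction(tr) - truth_unique_fraction(bt)
  }
  observed <- gap_for_seed(3)
  reps <- vapply(1:200, gap_for_seed, numeric(1))
  expect_gt(observed, mean(reps) - 2 * sd(reps))
  expect_lt(observed, mean(reps) + 2 * sd(reps))
  expect_gt(observed, 0)

  expect_error(apply_bottleneck(simulate_clonal_population(10, 5),
                                survival_prob = 0), "survival_prob")
})

test_that("generator is deterministic and conserves cells across conditions", {
  a <- simulate_clonal_population(200, 150, seed = 11)
  b <- simulate_clonal_population(200, 150, seed = 11)
  expect_identical(a, b)
  bt_a <- apply_bottleneck(a, seed = 12)
  bt_b <- apply_bottleneck(b, seed = 12)
  expect_identical(bt_a, bt_b)
  expect_equal(sum(bt_a$clones$size), 200)
  expect_equal(nrow(bt_a$cells), 200)
})

test_that("bottlenecked condition loses diversity in nearly all seeds", {
  res <- vapply(1:100, function(s) {
    tr <- simulate_clonal_population(400, 370, seed = s)
    bt <- apply_bottleneck(tr, seed = s + 500)
    truth_unique_fraction(bt) <= truth_unique_fraction(tr)
  }, logical(1))
  expect_gte(mean(res), 0.95)
})

test_that("count simulation matches its negative-binomial model", {
  tr <- simulate_clonal_population(150, 100, seed = 21)

  # Poisson limit: huge theta and a mean fixed across cells -> per-gene
  # variance ~ mean
  sim_p <- simulate_counts(tr, n_genes = 400, theta = 1e8,
                           beta = matrix(0, 4, 400), cc_effect = 0,
                           libsize_sdlog = 0, doublet_rate = 0,
                           damaged_frac = 0, seed = 22)
  m <- sim_p$counts
  mu_hat <- rowMeans(m)
  v_hat <- apply(m, 1, var)
  well_expr <- mu_hat > 5
  # variance within a few MC standard errors of the mean, gene-averaged
  expect_equal(mean(v_hat[well_expr] / mu_hat[well_expr]), 1, tolerance = 0.35)

  # with dispersion theta = 2 the variance is far above the mean
  sim_nb <- simulate_counts(tr, n_genes = 400, theta = 2,
                            beta = matrix(0, 4, 400), cc_effect = 0,
                            libsize_sdlog = 0, doublet_rate = 0,
                            damaged_frac = 0, seed = 23)
  v_nb <- apply(sim_nb$counts, 1, var)
  mu_nb <- rowMeans(sim_nb$counts)
  expect_gt(mean((v_nb / mu_nb)[mu_nb > 5]), 2)

  # replicate oracle: per-gene empirical means agree across generations
  reps <- sapply(1:10, function(s)
    rowMeans(simulate_counts(tr, n_genes = 200, doublet_rate = 0,
                             seed = 30 + s)$counts))
  mu_bar <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(10)
  one <- rowMeans(simulate_counts(tr, n_genes = 200, doublet_rate = 0,
                                  seed = 41)$counts)
  expect_gt(mean(abs(one - mu_bar) <= 4 * pmax(se, 1e-6) * sqrt(10)), 0.95)

  expect_error(simulate_counts(tr, n_genes = 400,
                               beta = matrix(0, 2, 400)), "row count")
  expect_error(simulate_counts(tr, doublet_rate = 0.5), "doublet_rate")
})

test_that("null program effects produce no clone separability", {
  tr <- simulate_clonal_population(120, 12, sigma = 0, seed = 31)
  beta0 <- matrix(0, nrow = 4, ncol = 300)
  sim <- simulate_counts(tr, n_genes = 300, beta = beta0,
                         libsize_sdlog = 0, doublet_rate = 0,
                         damaged_frac = 0, seed = 32)
  normed <- normalize_counts(sim$counts)
  scaled <- scale_and_regress(normed)
  emb <- run_pca(scaled, n_pcs = 10)
  sil <- cluster::silhouette(as.integer(factor(tr$cells$clone)),
                             dist(emb$coords))
  expect_lt(abs(mean(sil[, "sil_width"])), 0.1)
})

test_that("tag reads carry the expected error structure", {
  tr <- simulate_clonal_population(200, 150, seed = 51)
  lib <- toy_library(200, tag_length = 38)

  # error-free, chimera-free: every read's tag region equals the true tag
  tg0 <- simulate_tag_reads(tr, lib, lambda = 5, epsilon = 0,
                            chimera_rate = 0, seed = 52)
  l5 <- nchar(lib$flank5)
  tags_in_reads <- substr(tg0$reads$read2, l5 + 1, l5 + 38)
  true_tag <- tg0$clone_tags$tag[match(
    tr$cells$clone[tg0$truth_reads$cell_idx], tg0$clone_tags$clone)]
  expect_equal(tags_in_reads, true_tag)

  # lambda = 0: no reads, downstream assignment has zero cells
  tg_none <- simulate_tag_reads(tr, lib, lambda = 0, seed = 53)
  expect_equal(nrow(tg_none$reads), 0)
  res <- process_tag_reads(tg_none$reads, lib, tg_none$whitelist)
  expect_equal(nrow(res$assignment), 0)

  # closed-form binomial oracle for the >= 2-substitution tag fraction
  tg <- simulate_tag_reads(tr, lib, lambda = 40, epsilon = 0.01,
                           chimera_rate = 0, seed = 54)
  tags_err <- substr(tg$reads$read2, l5 + 1, l5 + 38)
  true_tag <- tg$clone_tags$tag[match(
    tr$cells$clone[tg$truth_reads$cell_idx], tg$clone_tags$clone)]
  nmm <- mapply(oracle_hamming, tags_err, true_tag)
  frac2 <- mean(nmm >= 2)
  p2 <- 1 - (1 - 0.01)^38 - 38 * 0.01 * (1 - 0.01)^37
  ci <- qbinom(c(0.0005, 0.9995), length(nmm), p2) / length(nmm)
  expect_gte(frac2, ci[1])
  expect_lte(frac2, ci[2])

  small_lib <- toy_library(20, tag_length = 38)
  expect_error(simulate_tag_reads(tr, small_lib), "more clones")
})
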