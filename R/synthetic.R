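#' Generate a random lineage-tag barcode library
#'
#' Emulates a high-diversity semi-random oligonucleotide library: `n_tags`
#' unique uniform-random DNA tags of fixed length between two known flanking
#' sequences. Tags containing either flank as a substring are resampled so
#' flank anchoring stays unambiguous. For libraries of at most
#' `max_pairs_n` tags the exact minimum pairwise Hamming distance is
#' computed (blockwise one-hot inner products); above that it is reported
#' as `NA`.
#'
#' @param n_tags number of tags
#' @param tag_length tag length in bp (38 by default)
#' @param flank5,flank3 constant flanking sequences surrounding the tag
#' @param seed RNG seed
#' @param max_pairs_n largest library size for which the exact minimum
#'   pairwise distance is computed
#' @return list of class `barcode_library` with elements `tags`,
#'   `tag_length`, `flank5`, `flank3`, `min_hamming`
#' @export
make_barcode_library <- function(n_tags, tag_length = 38L,
                                 flank5 = "ACCGGTCGTA",
                                 flank3 = "TGCATAGCGG",
                                 seed = 0L,
                                 max_pairs_n = 20000L) {
  if (n_tags < 1) stop("n_tags must be positive")
  if (!nzchar(flank5) || !nzchar(flank3)) stop("flanks must be non-empty")
  if (log(n_tags) > tag_length * log(4))
    stop("n_tags exceeds the 4^tag_length sequence space")
  set.seed(seed)
  tags <- character(0)
  while (length(tags) < n_tags) {
    cand <- random_dna(n_tags - length(tags), tag_length)
    cand <- cand[!grepl(flank5, cand, fixed = TRUE) &
                   !grepl(flank3, cand, fixed = TRUE)]
    tags <- unique(c(tags, cand))
  }
  min_h <- if (n_tags >= 2 && n_tags <= max_pairs_n) {
    min_pairwise_hamming(tags)
  } else {
    NA_integer_
  }
  structure(list(tags = tags, tag_length = as.integer(tag_length),
                 flank5 = flank5, flank3 = flank3,
                 min_hamming = min_h),
            class = "barcode_library")
}

#' Exact minimum pairwise Hamming distance of equal-length DNA strings
#'
#' One-hot encodes sequences and computes match counts by blockwise matrix
#' products, so the full all-pairs scan stays tractable for libraries of
#' tens of thousands of tags.
#'
#' @param tags character vector of equal-length strings
#' @param block rows per block in the crossproduct
#' @return integer minimum Hamming distance
#' @export
min_pairwise_hamming <- function(tags, block = 500L) {
  n <- length(tags)
  stopifnot(n >= 2)
  len <- nchar(tags[1])
  cm <- char_matrix(tags)
  onehot <- matrix(0, nrow = n, ncol = 4L * len)
  for (b in seq_along(DNA_BASES)) {
    onehot[, ((b - 1L) * len + 1L):(b * len)] <- (cm == DNA_BASES[b])
  }
  best <- 0L  # max matches off-diagonal
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, n)
    mm <- tcrossprod(onehot[rows, , drop = FALSE], onehot)
    for (i in seq_along(rows)) mm[i, rows[i]] <- -1
    best <- max(best, max(mm))
  }
  as.integer(len - best)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode_library: %d tags of %d bp (flanks %s / %s), min pairwise Hamming %s\n",
              length(x$tags), x$tag_length, x$flank5, x$flank3,
              ifelse(is.na(x$min_hamming), "not computed", x$min_hamming)))
  invisible(x)
}

#' Simulate a tagged clonal population under neutral culture growth
#'
#' Every clone is founded by one cell; the remaining `n_cells - n_clones`
#' cells are assigned uniformly at random among clones, giving a
#' near-uniform multinomial clone-size distribution whose expected singleton
#' fraction is controlled by the `n_clones / n_cells` ratio. Each clone
#' carries a founding program-weight vector: an i.i.d. standard-normal draw
#' per program plus a `program_boost` increment on its largest-weight
#' (dominant) program, so discrete program-dominant transcriptional subsets
#' exist alongside continuous variation. Cells inherit the clone vector plus
#' independent normal jitter of SD `sigma` (heritability: `sigma = 0` makes
#' clonemates identical).
#'
#' Cell identifiers are unique random DNA barcodes of length `cid_len`, as
#' produced by droplet chemistry, so expression and tag-read data share keys.
#'
#' @param n_cells number of cells sampled
#' @param n_clones number of founding clones (<= n_cells)
#' @param n_programs number of latent expression programs
#' @param sigma within-clone program-weight jitter SD (>= 0)
#' @param program_boost increment added to each clone's dominant program
#' @param cid_len cell-barcode length
#' @param seed RNG seed
#' @return list of class `clone_truth` with `cells` (data.frame: cell,
#'   clone, condition), `weights` (cells x programs matrix), `clones`
#'   (data.frame: clone, dominant_program, size), `founding` (clones x
#'   programs matrix), and `params`
#' @export
simulate_clonal_population <- function(n_cells = 2000L, n_clones = 1850L,
                                       n_programs = 4L, sigma = 0.1,
                                       program_boost = 2,
                                       cid_len = 16L, seed = 0L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_clones > n_cells) stop("n_clones must not exceed n_cells")
  if (n_clones < 1) stop("n_clones must be positive")
  set.seed(seed)
  clone_of <- c(seq_len(n_clones),
                sample.int(n_clones, n_cells - n_clones, replace = TRUE))
  clone_of <- clone_of[sample.int(n_cells)]  # shuffle cell order
  founding <- matrix(stats::rnorm(n_clones * n_programs),
                     nrow = n_clones, ncol = n_programs)
  dominant <- max.col(founding, ties.method = "first")
  founding[cbind(seq_len(n_clones), dominant)] <-
    founding[cbind(seq_len(n_clones), dominant)] + program_boost
  weights <- founding[clone_of, , drop = FALSE] +
    matrix(stats::rnorm(n_cells * n_programs, sd = sigma),
           nrow = n_cells, ncol = n_programs)
  cells <- make_unique_cids(n_cells, cid_len)
  rownames(weights) <- cells
  colnames(weights) <- paste0("P", seq_len(n_programs))
  colnames(founding) <- colnames(weights)
  sz <- tabulate(clone_of, nbins = n_clones)
  structure(list(
    cells = data.frame(cell = cells,
                       clone = paste0("clone", clone_of),
                       condition = "culture",
                       stringsAsFactors = FALSE),
    weights = weights,
    clones = data.frame(clone = paste0("clone", seq_len(n_clones)),
                        dominant_program = dominant,
                        size = sz,
                        stringsAsFactors = FALSE),
    founding = founding,
    params = list(n_cells = as.integer(n_cells),
                  n_clones = as.integer(n_clones),
                  n_programs = as.integer(n_programs),
                  sigma = sigma, program_boost = program_boost,
                  cid_len = as.integer(cid_len), seed = as.integer(seed))
  ), class = "clone_truth")
}

make_unique_cids <- function(n, cid_len) {
  cids <- unique(random_dna(n, cid_len))
  while (length(cids) < n) {
    cids <- unique(c(cids, random_dna(n - length(cids), cid_len)))
  }
  cids
}

#' Pass a clonal population through a colonization bottleneck
#'
#' Each clone survives independently with probability
#' `min(1, survival_prob * s^skew)` where `s ~ Uniform(0,1)` is a latent
#' clone fitness; `skew = 0` makes survival fitness-blind, larger `skew`
#' concentrates survival on the fittest clones. Surviving clones expand by a
#' geometric factor with mean `expansion_mean` (shifted geometric, support
#' >= 1). A new sample of `n_cells` cells is drawn by deterministic
#' largest-remainder apportionment proportional to expanded clone mass, so
#' clone sizes sum exactly to `n_cells` and the identity bottleneck
#' (`survival_prob = 1, skew = 0, expansion_mean = 1`) reproduces the input
#' clone sizes exactly. Progeny inherit the clone's founding weights plus
#' fresh jitter, and `cond_effect` (a per-program shift vector) is added to
#' every cell, modeling the condition-wide transcriptional response.
#'
#' If no clone survives, survival is redrawn (with a warning) up to 100
#' times.
#'
#' @param truth a `clone_truth` from [simulate_clonal_population()]
#' @param survival_prob baseline clone survival probability in (0, 1]
#' @param skew fitness exponent (>= 0)
#' @param expansion_mean mean geometric expansion factor (>= 1)
#' @param cond_effect numeric vector of per-program shifts (recycled to the
#'   program count)
#' @param condition label for the new condition
#' @param n_cells cells sampled from the colonized population (default: as
#'   the input)
#' @param sigma progeny jitter SD (default: as the input)
#' @param seed RNG seed
#' @return a new `clone_truth` for the colonized condition; `clones` keeps
#'   all founding clones with their new sizes (0 = extinct/unsampled)
#' @export
apply_bottleneck <- function(truth, survival_prob = 1, skew = 0.4,
                             expansion_mean = 3,
                             cond_effect = 0,
                             condition = "lung",
                             n_cells = NULL, sigma = NULL, seed = 1L) {
  stopifnot(inherits(truth, "clone_truth"))
  if (survival_prob <= 0 || survival_prob > 1)
    stop("survival_prob must be in (0, 1]")
  if (skew < 0) stop("skew must be non-negative")
  if (expansion_mean < 1) stop("expansion_mean must be >= 1")
  if (is.null(n_cells)) n_cells <- truth$params$n_cells
  if (is.null(sigma)) sigma <- truth$params$sigma
  n_clones <- nrow(truth$clones)
  n_programs <- truth$params$n_programs
  cond_effect <- rep_len(cond_effect, n_programs)
  set.seed(seed)
  fitness <- stats::runif(n_clones)
  p_surv <- pmin(1, survival_prob * fitness^skew)
  present <- truth$clones$size > 0
  survives <- logical(n_clones)
  for (attempt in seq_len(100L)) {
    survives <- present & (stats::runif(n_clones) < p_surv)
    if (any(survives)) break
    warning("no clone survived the bottleneck; resampling survival")
  }
  if (!any(survives)) stop("no clone survived after 100 attempts")
  expansion <- ifelse(survives,
                      1 + stats::rgeom(n_clones, prob = 1 / expansion_mean),
                      0)
  mass <- truth$clones$size * expansion
  new_sizes <- integer(n_clones)
  new_sizes[survives] <- apportion(mass[survives], n_cells)
  clone_idx <- rep(seq_len(n_clones), new_sizes)
  weights <- truth$founding[clone_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_cells * n_programs, sd = sigma),
           nrow = n_cells, ncol = n_programs)
  weights <- sweep(weights, 2, cond_effect, "+")
  cells <- make_unique_cids(n_cells, truth$params$cid_len)
  rownames(weights) <- cells
  colnames(weights) <- colnames(truth$founding)
  clones <- truth$clones
  clones$size <- new_sizes
  clones$fitness <- fitness
  clones$survived <- survives
  clones$expansion <- expansion
  structure(list(
    cells = data.frame(cell = cells,
                       clone = clones$clone[clone_idx],
                       condition = condition,
                       stringsAsFactors = FALSE),
    weights = weights,
    clones = clones,
    founding = truth$founding,
    params = utils::modifyList(truth$params, list(
      n_cells = as.integer(n_cells), sigma = sigma,
      survival_prob = survival_prob, skew = skew,
      expansion_mean = expansion_mean, cond_effect = cond_effect,
      condition = condition, bottleneck_seed = as.integer(seed)))
  ), class = "clone_truth")
}

#' Unique-clone fraction implied by ground-truth labels
#'
#' Percentage of cells whose clone contains exactly one cell, computed from
#' the generator's own labels (the quantity the assignment pipeline
#' estimates).
#'
#' @param truth a `clone_truth`
#' @return percentage in [0, 100]
#' @export
truth_unique_fraction <- function(truth) {
  sz <- table(truth$cells$clone)
  100 * sum(sz == 1) / nrow(truth$cells)
}

#' Build a default program-effect matrix
#'
#' Assigns each program a disjoint block of `genes_per_program` target genes
#' with log-scale effect `effect`; all other entries are zero.
#'
#' @param n_programs,n_genes dimensions
#' @param genes_per_program block size
#' @param effect log-scale effect of one program-weight unit
#' @param gene_names optional gene names for columns
#' @return `n_programs` x `n_genes` matrix
#' @export
default_program_matrix <- function(n_programs, n_genes,
                                   genes_per_program = 60L, effect = 1,
                                   gene_names = NULL) {
  if (n_programs * genes_per_program > n_genes)
    stop("program blocks exceed gene count")
  beta <- matrix(0, nrow = n_programs, ncol = n_genes)
  for (m in seq_len(n_programs)) {
    cols <- ((m - 1L) * genes_per_program + 1L):(m * genes_per_program)
    beta[m, cols] <- effect
  }
  if (!is.null(gene_names)) colnames(beta) <- gene_names
  beta
}

#' Simulate a clone-structured count matrix
#'
#' Counts follow a negative binomial with mean
#' `mu_cg = l_c * exp(b_g + sum_m w_cm beta_mg + phase_cg)` and dispersion
#' `theta` (variance `mu + mu^2/theta`). The model includes gene-specific
#' log baselines, per-cell library-size factors (log-normal), latent
#' cell-cycle phases driving two dedicated gene blocks (S-like and
#' G2M-like), mitochondrially encoded genes (`MT-` prefix) whose share is
#' inflated in a flagged "damaged" cell subset, and doublets formed by
#' summing the counts of two cells.
#'
#' @param truth a `clone_truth`
#' @param n_genes number of genes
#' @param beta optional programs x genes effect matrix; defaults to
#'   [default_program_matrix()] over the non-mitochondrial,
#'   non-cell-cycle genes
#' @param theta NB dispersion (> 0); larger is closer to Poisson
#' @param base_meanlog,base_sdlog log-normal parameters of gene baseline
#'   means
#' @param libsize_sdlog log-normal SD of cell library-size factors
#' @param n_cc_genes genes per cell-cycle block
#' @param cc_effect log-scale phase effect on the matching block
#' @param phase_probs probabilities of G1 / S / G2M
#' @param n_mito_genes number of `MT-` genes
#' @param mito_frac expected mitochondrial count share in healthy cells
#' @param damaged_frac fraction of cells flagged damaged
#' @param mito_boost multiplicative mitochondrial inflation in damaged cells
#' @param doublet_rate fraction of cells replaced by doublets, in [0, 0.2]
#' @param seed RNG seed
#' @return list of class `sim_counts`: `counts` (genes x cells integer
#'   matrix), `cell_meta` (cell, clone, condition, phase, doublet, damaged,
#'   libsize_factor), `gene_meta` (gene, program, cc_block, mito), `beta`,
#'   `s_genes`, `g2m_genes`, `params`
#' @export
simulate_counts <- function(truth, n_genes = 2500L, beta = NULL,
                            theta = 2,
                            base_meanlog = 0.7, base_sdlog = 1.2,
                            libsize_sdlog = 0.25,
                            n_cc_genes = 40L, cc_effect = 1.2,
                            phase_probs = c(G1 = 0.6, S = 0.2, G2M = 0.2),
                            n_mito_genes = 25L, mito_frac = 0.05,
                            damaged_frac = 0.05, mito_boost = 4,
                            doublet_rate = 0.03,
                            seed = 0L) {
  stopifnot(inherits(truth, "clone_truth"))
  if (theta <= 0) stop("theta must be positive")
  if (doublet_rate < 0 || doublet_rate > 0.2)
    stop("doublet_rate must lie in [0, 0.2]")
  n_cells <- nrow(truth$cells)
  n_programs <- truth$params$n_programs
  set.seed(seed)

  # gene layout: programs | cell-cycle blocks | filler | mito at the end
  n_mt <- n_mito_genes
  n_nuc <- n_genes - n_mt
  genes <- c(sprintf("G%04d", seq_len(n_nuc)), sprintf("MT-%02d", seq_len(n_mt)))
  if (is.null(beta)) {
    gpp <- min(60L, floor((n_nuc - 2L * n_cc_genes) / n_programs))
    beta <- default_program_matrix(n_programs, n_genes,
                                   genes_per_program = gpp,
                                   gene_names = genes)
  }
  if (nrow(beta) != n_programs)
    stop("beta row count must equal the program count")
  if (ncol(beta) != n_genes) stop("beta column count must equal n_genes")
  program_of <- apply(beta != 0, 2, function(z) if (any(z)) which(z)[1] else NA_integer_)
  prog_cols <- which(!is.na(program_of))
  cc_pool <- setdiff(seq_len(n_nuc), prog_cols)
  s_idx <- cc_pool[seq_len(n_cc_genes)]
  g2m_idx <- cc_pool[(n_cc_genes + 1L):(2L * n_cc_genes)]
  mito_idx <- (n_nuc + 1L):n_genes

  b <- stats::rnorm(n_genes, mean = base_meanlog, sd = base_sdlog)
  # pin mitochondrial baseline mass to the target healthy-cell share
  nuc_mass <- sum(exp(b[-mito_idx]))
  b[mito_idx] <- b[mito_idx] - log(sum(exp(b[mito_idx]))) +
    log(nuc_mass * mito_frac / (1 - mito_frac))

  l <- stats::rlnorm(n_cells, meanlog = 0, sdlog = libsize_sdlog)
  phase <- sample(names(phase_probs), n_cells, replace = TRUE,
                  prob = phase_probs)
  damaged <- stats::runif(n_cells) < damaged_frac

  logmu <- truth$weights %*% beta  # cells x genes
  logmu <- sweep(logmu, 2, b, "+")
  logmu[phase == "S", s_idx] <- logmu[phase == "S", s_idx] + cc_effect
  logmu[phase == "G2M", g2m_idx] <- logmu[phase == "G2M", g2m_idx] + cc_effect
  logmu[damaged, mito_idx] <- logmu[damaged, mito_idx] + log(mito_boost)
  mu <- exp(logmu) * l

  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = theta),
                   nrow = n_cells, ncol = n_genes)

  doublet <- logical(n_cells)
  n_dbl <- floor(doublet_rate * n_cells)
  if (n_dbl > 0) {
    hosts <- sample.int(n_cells, n_dbl)
    partners <- vapply(hosts, function(h) {
      p <- sample.int(n_cells, 1L)
      while (p == h) p <- sample.int(n_cells, 1L)
      p
    }, integer(1))
    counts[hosts, ] <- counts[hosts, , drop = FALSE] +
      counts[partners, , drop = FALSE]
    doublet[hosts] <- TRUE
  }

  counts <- t(counts)  # genes x cells
  dimnames(counts) <- list(genes, truth$cells$cell)
  storage.mode(counts) <- "integer"

  cc_block <- rep(NA_character_, n_genes)
  cc_block[s_idx] <- "S"
  cc_block[g2m_idx] <- "G2M"
  list(
    counts = counts,
    cell_meta = data.frame(
      cell = truth$cells$cell, clone = truth$cells$clone,
      condition = truth$cells$condition, phase = phase,
      doublet = doublet, damaged = damaged, libsize_factor = l,
      stringsAsFactors = FALSE),
    gene_meta = data.frame(
      gene = genes, program = program_of, cc_block = cc_block,
      mito = is_mito(genes), stringsAsFactors = FALSE),
    beta = beta,
    s_genes = genes[s_idx],
    g2m_genes = genes[g2m_idx],
    params = list(n_genes = as.integer(n_genes), theta = theta,
                  base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                  libsize_sdlog = libsize_sdlog, n_cc_genes = as.integer(n_cc_genes),
                  cc_effect = cc_effect, n_mito_genes = as.integer(n_mito_genes),
                  mito_frac = mito_frac, damaged_frac = damaged_frac,
                  mito_boost = mito_boost, doublet_rate = doublet_rate,
                  seed = as.integer(seed))
  )
}

#' Simulate lineage-tag sequencing reads for a tagged population
#'
#' Each clone is mapped injectively to one library tag (tag `i` for clone
#' `i`). Every cell emits `Poisson(lambda)` reads; read 2 is
#' `flank5 + tag + flank3` with i.i.d. per-base substitution errors at rate
#' `epsilon` applied over the whole read, read 1 carries the cell barcode
#' and a uniform-random UMI. A `chimera_rate` fraction of reads carries a
#' random wrong library tag, exercising downstream purity filtering.
#'
#' @param truth a `clone_truth`
#' @param library a `barcode_library` with at least as many tags as clones
#' @param lambda mean reads per cell
#' @param epsilon per-base substitution rate in [0, 0.5)
#' @param chimera_rate fraction of reads with a random wrong tag
#' @param umi_len UMI length in bp
#' @param seed RNG seed
#' @return list: `reads` (data.frame cid/umi/read2), `whitelist` (cell
#'   barcodes), `clone_tags` (data.frame clone, tag_id, tag), `truth_reads`
#'   (per-read true cell index and chimera flag)
#' @export
simulate_tag_reads <- function(truth, library, lambda = 20, epsilon = 0.01,
                               chimera_rate = 0.02, umi_len = 12L,
                               seed = 0L) {
  stopifnot(inherits(truth, "clone_truth"), inherits(library, "barcode_library"))
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  n_clones <- nrow(truth$clones)
  if (n_clones > length(library$tags))
    stop("more clones than library tags")
  set.seed(seed)
  clone_tags <- data.frame(
    clone = truth$clones$clone,
    tag_id = sprintf("LT%06d", seq_len(n_clones)),
    tag = library$tags[seq_len(n_clones)],
    stringsAsFactors = FALSE)
  n_cells <- nrow(truth$cells)
  n_reads_per_cell <- stats::rpois(n_cells, lambda)
  cell_idx <- rep(seq_len(n_cells), n_reads_per_cell)
  n_reads <- length(cell_idx)
  clone_idx <- match(truth$cells$clone[cell_idx], clone_tags$clone)
  tag_seq <- clone_tags$tag[clone_idx]
  chimera <- stats::runif(n_reads) < chimera_rate
  if (any(chimera)) {
    tag_seq[chimera] <- library$tags[sample.int(length(library$tags),
                                                sum(chimera), replace = TRUE)]
  }
  if (n_reads == 0) {
    reads <- data.frame(cid = character(0), umi = character(0),
                        read2 = character(0), stringsAsFactors = FALSE)
  } else {
    read2 <- paste0(library$flank5, tag_seq, library$flank3)
    if (epsilon > 0) read2 <- inject_substitutions(read2, epsilon)
    reads <- data.frame(
      cid = truth$cells$cell[cell_idx],
      umi = random_dna(n_reads, umi_len),
      read2 = read2,
      stringsAsFactors = FALSE)
  }
  list(reads = reads,
       whitelist = truth$cells$cell,
       clone_tags = clone_tags,
       truth_reads = data.frame(cell_idx = cell_idx, chimera = chimera))
}

#' Apply i.i.d. per-base substitution errors to equal-length reads
#' @keywords internal
inject_substitutions <- function(reads, epsilon) {
  cm <- char_matrix(reads)
  hit <- which(stats::runif(length(cm)) < epsilon)
  if (length(hit) > 0) {
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(cm[hit], DNA_BASES)
    cm[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, as.data.frame(cm, stringsAsFactors = FALSE))
}

#' Simulate the full three-condition lineage-tracing experiment
#'
#' Convenience wrapper reproducing the study design: a tagged culture
#' population, a permissive-colonization condition ("tibia": every clone
#' survives, mild fitness-blind drift in clone sizes), and a bottlenecked
#' condition ("lung": fitness-skewed survival with strong geometric
#' expansion, producing dominant clones). Counts and tag reads are generated
#' per condition.
#'
#' Default bottleneck settings emulate the clonal-diversity profile the
#' assay is designed to detect: culture retains ~85% unique clones, the
#' permissive condition slightly fewer, and the bottlenecked condition far
#' fewer.
#'
#' @param n_cells cells per condition
#' @param n_clones founding clones in culture
#' @param library optional `barcode_library`; generated when `NULL`
#' @param tibia,lung named lists overriding [apply_bottleneck()] arguments
#'   per condition
#' @param counts_args named list of overrides for [simulate_counts()]
#' @param reads_args named list of overrides for [simulate_tag_reads()]
#' @param seed master RNG seed; per-stage seeds are derived from it
#' @return list with per-condition elements `truth`, `sim` (counts), and
#'   `tags` (reads), plus the `library`
#' @export
simulate_experiment <- function(n_cells = 2000L, n_clones = 1850L,
                                library = NULL,
                                tibia = list(), lung = list(),
                                counts_args = list(),
                                reads_args = list(),
                                seed = 0L) {
  seed <- as.integer(seed) %% 100000L
  if (is.null(library)) {
    library <- make_barcode_library(max(4L * n_clones, 5000L),
                                    seed = seed + 11L,
                                    max_pairs_n = 0L)
  }
  culture <- simulate_clonal_population(n_cells, n_clones, seed = seed)
  tibia_args <- utils::modifyList(
    list(truth = culture, survival_prob = 1, skew = 0, expansion_mean = 1.4,
         cond_effect = c(0.6, 0, 0, 0), condition = "tibia",
         seed = seed + 1L),
    tibia)
  lung_args <- utils::modifyList(
    list(truth = culture, survival_prob = 1, skew = 0.4,
         expansion_mean = 3, cond_effect = c(0, 0.9, 0, -0.4),
         condition = "lung", seed = seed + 2L),
    lung)
  truths <- list(culture = culture,
                 tibia = do.call(apply_bottleneck, tibia_args),
                 lung = do.call(apply_bottleneck, lung_args))
  out <- list(library = library)
  for (cond in names(truths)) {
    tr <- truths[[cond]]
    sim <- do.call(simulate_counts,
                   utils::modifyList(list(truth = tr,
                                          seed = seed + 20L + match(cond, names(truths))),
                                     counts_args))
    tg <- do.call(simulate_tag_reads,
                  utils::modifyList(list(truth = tr, library = library,
                                         seed = seed + 30L + match(cond, names(truths))),
                                    reads_args))
    out[[cond]] <- list(truth = tr, sim = sim, tags = tg)
  }
  out
}
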