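#' Read a gene x cell count matrix
#'
#' Supports MatrixMarket triplet format with `features.tsv` / `barcodes.tsv`
#' sidecars (gene and cell identifiers, one per line, first column used) and
#' dense TSV with gene identifiers in the first column and cell identifiers
#' as the header. Cell identifiers are stripped of any droplet suffix
#' ("-1") so they join with tag-read data.
#'
#' @param path matrix file (`.mtx` or `.tsv`); gzip accepted
#' @param format `"mtx"` or `"tsv"`; guessed from the extension by default
#' @param features,barcodes sidecar paths for mtx input; default to
#'   `features.tsv` / `barcodes.tsv` next to the matrix file
#' @return a `dgCMatrix` (genes x cells) of integer counts with unique
#'   dimnames
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"),
                        features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(features)) features <- file.path(dir, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    if (!file.exists(features)) stop("features sidecar not found: ", features)
    if (!file.exists(barcodes)) stop("barcodes sidecar not found: ", barcodes)
    m <- Matrix::readMM(path)
    feat <- utils::read.table(features, sep = "\t", header = FALSE,
                              colClasses = "character")[[1]]
    bc <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                            colClasses = "character")[[1]]
    if (length(feat) != nrow(m))
      stop(sprintf("dimension mismatch: %d features listed, matrix has %d rows",
                   length(feat), nrow(m)))
    if (length(bc) != ncol(m))
      stop(sprintf("dimension mismatch: %d barcodes listed, matrix has %d columns",
                   length(bc), ncol(m)))
    vals <- m@x
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE)
    feat <- rownames(tab)
    bc <- colnames(tab)
    m <- as.matrix(tab)
    vals <- m
  }
  if (any(vals != round(vals)) || any(vals < 0))
    stop("count matrix must contain non-negative integers")
  if (anyDuplicated(feat)) stop("duplicate gene identifiers")
  bc <- strip_cell_suffix(bc)
  if (anyDuplicated(bc)) stop("duplicate cell identifiers")
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(feat, bc)
  m
}

#' Write a count matrix as MatrixMarket triplet plus sidecars
#'
#' @param counts genes x cells matrix with dimnames
#' @param dir output directory (created if missing); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`
#' @return `dir`, invisibly
#' @export
write_counts <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and cell identifiers")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Flag mitochondrial genes by symbol prefix
#'
#' @param genes character vector of gene symbols
#' @param prefix symbol prefix marking mitochondrially encoded genes
#' @return logical vector
#' @export
is_mito <- function(genes, prefix = "MT-") {
  startsWith(genes, prefix)
}

#' Read a GMT gene-set collection
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are collapsed; duplicate set names and lines
#' with fewer than three fields are errors.
#'
#' @param path GMT file
#' @return named list of unique gene character vectors
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed GMT line (fewer than 3 fields): line ",
         which(nf < 3)[1])
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Read paired lineage-tag FASTQ files
#'
#' R1 carries the cell barcode (first `cid_len` bases) followed by the UMI
#' (next `umi_len` bases); R2 carries the transcript fragment containing the
#' lineage tag. Gzip input is accepted.
#'
#' @param r1_path,r2_path FASTQ files
#' @param cid_len,umi_len barcode segment lengths in bp
#' @return data.frame with columns `cid`, `umi`, `read2`
#' @export
read_tag_reads <- function(r1_path, r2_path, cid_len = 16L, umi_len = 12L) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2))
    stop(sprintf("paired FASTQ record counts differ: %d vs %d",
                 length(r1), length(r2)))
  r1 <- unname(as.character(r1))
  if (any(nchar(r1) < cid_len + umi_len))
    stop("truncated record: R1 shorter than cid_len + umi_len")
  data.frame(
    cid = substr(r1, 1L, cid_len),
    umi = substr(r1, cid_len + 1L, cid_len + umi_len),
    read2 = unname(as.character(r2)),
    stringsAsFactors = FALSE
  )
}

#' Write a result table as TSV with a fixed schema
#'
#' Columns are emitted in schema order; numeric columns are printed at fixed
#' precision so outputs are byte-stable.
#'
#' @param rows data.frame
#' @param path output file
#' @param schema character vector of required column names, in output order
#' @param digits decimal places for numeric columns
#' @return `path`, invisibly
#' @export
write_table <- function(rows, path, schema = colnames(rows), digits = 6L) {
  missing <- setdiff(schema, colnames(rows))
  if (length(missing) > 0)
    stop("rows missing schema column(s): ", paste(missing, collapse = ", "))
  out <- rows[, schema, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], format = "f", digits = digits)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write paired tag reads as FASTQ files
#'
#' R1 is the concatenation of cell barcode and UMI; R2 is the tag-bearing
#' read. Constant maximal base qualities are written. Paths ending in `.gz`
#' are gzip-compressed.
#'
#' @param reads data.frame with columns `cid`, `umi`, `read2`
#' @param r1_path,r2_path output FASTQ paths
#' @return invisibly, c(r1_path, r2_path)
#' @export
write_tag_fastq <- function(reads, r1_path, r2_path) {
  r1_seq <- paste0(reads$cid, reads$umi)
  ids <- sprintf("@read%06d", seq_len(nrow(reads)))
  write_one <- function(seqs, path) {
    qual <- strrep("I", nchar(seqs))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(as.vector(rbind(ids, seqs, "+", qual)), con)
  }
  write_one(r1_seq, r1_path)
  write_one(reads$read2, r2_path)
  invisible(c(r1_path, r2_path))
}
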