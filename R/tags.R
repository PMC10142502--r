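#' Extract lineage tags and cell/UMI barcodes from tag reads
#'
#' Locates the 5' and 3' flanks at their expected offsets in read 2 (flank5
#' at the read start, flank3 immediately after the tag), allowing up to
#' `max_flank_mismatch` substitutions in each flank, and emits the
#' intervening `tag_length` bases. Reads failing either flank or too short
#' to contain the full cassette are dropped and counted per reason.
#'
#' @param reads data.frame with columns `cid`, `umi`, `read2` (from
#'   [read_tag_reads()] or [simulate_tag_reads()])
#' @param flank5,flank3 flanking sequences
#' @param tag_length expected tag length in bp
#' @param max_flank_mismatch maximum substitutions tolerated per flank
#' @return list with `triples` (data.frame `cid`, `umi`, `tag`) and `drops`
#'   (named integer vector of per-reason drop counts)
#' @export
extract_tags <- function(reads, flank5, flank3, tag_length = 38L,
                         max_flank_mismatch = 2L) {
  if (tag_length <= 0) stop("tag_length must be positive")
  if (!nzchar(flank5) || !nzchar(flank3)) stop("flanks must be non-empty")
  l5 <- nchar(flank5)
  l3 <- nchar(flank3)
  need <- l5 + tag_length + l3
  r2 <- reads$read2
  long_enough <- nchar(r2) >= need
  drops <- c(too_short = sum(!long_enough))
  keep <- which(long_enough)
  mm5 <- mismatches_to(substr(r2[keep], 1L, l5), flank5)
  ok5 <- mm5 <= max_flank_mismatch
  drops["flank5_not_found"] <- sum(!ok5)
  keep <- keep[ok5]
  mm3 <- mismatches_to(substr(r2[keep], l5 + tag_length + 1L,
                              l5 + tag_length + l3), flank3)
  ok3 <- mm3 <= max_flank_mismatch
  drops["flank3_not_found"] <- sum(!ok3)
  keep <- keep[ok3]
  list(
    triples = data.frame(cid = reads$cid[keep],
                         umi = reads$umi[keep],
                         tag = substr(reads$read2[keep], l5 + 1L,
                                      l5 + tag_length),
                         read_idx = keep,  # provenance for truth comparisons
                         stringsAsFactors = FALSE),
    drops = drops
  )
}

#' Keep triples whose cell barcode matches the expression whitelist
#'
#' With `max_cid_hamming = 0` (default, the conservative reading of
#' "high-confidence" assignment) only exact matches are kept. With
#' `max_cid_hamming = 1` a non-matching barcode is corrected iff exactly one
#' whitelist entry lies within Hamming distance 1; ambiguous corrections are
#' dropped. Whitelist entries are stripped of droplet suffixes before
#' matching.
#'
#' @param triples data.frame with columns `cid`, `umi`, `tag`
#' @param whitelist character vector of retained cell barcodes
#' @param max_cid_hamming 0 or 1
#' @return filtered (and possibly corrected) triples
#' @export
filter_cid <- function(triples, whitelist, max_cid_hamming = 0L) {
  if (length(whitelist) == 0) stop("whitelist is empty")
  if (!max_cid_hamming %in% c(0L, 1L))
    stop("max_cid_hamming must be 0 or 1")
  whitelist <- unique(strip_cell_suffix(whitelist))
  hit <- match(triples$cid, whitelist)
  out <- triples[!is.na(hit), , drop = FALSE]
  if (max_cid_hamming == 1L && any(is.na(hit))) {
    cand <- triples[is.na(hit), , drop = FALSE]
    corrected <- correct_hamming1(cand$cid, whitelist)
    ok <- !is.na(corrected)
    if (any(ok)) {
      cand <- cand[ok, , drop = FALSE]
      cand$cid <- corrected[ok]
      out <- rbind(out, cand)
    }
  }
  rownames(out) <- NULL
  out
}

#' Correct strings to a unique reference within Hamming distance 1
#'
#' Returns the unique reference at distance exactly 1, or NA when none or
#' several exist. Queries already present in `ref` map to themselves.
#' @keywords internal
correct_hamming1 <- function(x, ref) {
  out <- ref[match(x, ref)]
  todo <- which(is.na(out))
  if (length(todo) == 0) return(out)
  uq <- unique(x[todo])
  vars <- hamming1_variants(uq)
  m <- match(vars$variant, ref)
  found <- !is.na(m)
  hits_per <- tapply(m[found], vars$idx[found], function(v) unique(v))
  resolved <- rep(NA_character_, length(uq))
  if (length(hits_per) > 0) {
    idx <- as.integer(names(hits_per))
    one <- lengths(hits_per) == 1L
    resolved[idx[one]] <- ref[unlist(hits_per[one], use.names = FALSE)]
  }
  out[todo] <- resolved[match(x[todo], uq)]
  out
}

#' Collapse redundant reads to unique (cid, umi, tag) triples
#'
#' One record per distinct triple; read multiplicity is kept as `reads`.
#'
#' @param triples data.frame with columns `cid`, `umi`, `tag`
#' @return data.frame `cid`, `umi`, `tag`, `reads`
#' @export
deduplicate <- function(triples) {
  if (nrow(triples) == 0) {
    return(cbind(triples, reads = integer(0)))
  }
  key <- paste(triples$cid, triples$umi, triples$tag, sep = "\r")
  first <- !duplicated(key)
  ukey <- key[first]
  out <- triples[first, , drop = FALSE]
  out$reads <- as.integer(tabulate(match(key, ukey), nbins = length(ukey)))
  rownames(out) <- NULL
  out
}

#' Match extracted tags against the known barcode library
#'
#' Exact matches are accepted; a non-matching tag is corrected iff exactly
#' one library tag lies within `max_tag_hamming` (0 or 1 supported);
#' otherwise the triple is eliminated. Matched tags are reported by library
#' identifier (`LT` + index).
#'
#' @param triples data.frame with columns `cid`, `umi`, `tag` (and
#'   optionally `reads`)
#' @param library a `barcode_library` or character vector of tags
#' @param max_tag_hamming 0 or 1
#' @return list with `triples` (matched, `tag` replaced by the corrected
#'   sequence plus a `tag_id` column) and `stats` (input, matched_exact,
#'   corrected, eliminated, fraction_matched)
#' @export
match_library <- function(triples, library, max_tag_hamming = 1L) {
  tags <- if (inherits(library, "barcode_library")) library$tags else library
  if (length(tags) == 0) stop("library is empty")
  if (!max_tag_hamming %in% c(0L, 1L))
    stop("max_tag_hamming must be 0 or 1")
  n_in <- nrow(triples)
  hit <- match(triples$tag, tags)
  n_exact <- sum(!is.na(hit))
  corrected <- 0L
  if (max_tag_hamming == 1L && any(is.na(hit))) {
    idx <- which(is.na(hit))
    fixed <- correct_hamming1(triples$tag[idx], tags)
    ok <- !is.na(fixed)
    corrected <- sum(ok)
    triples$tag[idx[ok]] <- fixed[ok]
    hit[idx[ok]] <- match(fixed[ok], tags)
  }
  keep <- !is.na(hit)
  out <- triples[keep, , drop = FALSE]
  out$tag_id <- sprintf("LT%06d", hit[keep])
  rownames(out) <- NULL
  list(triples = out,
       stats = c(input = n_in, matched_exact = n_exact,
                 corrected = corrected, eliminated = n_in - sum(keep),
                 fraction_matched = if (n_in > 0) sum(keep) / n_in else NA_real_))
}

#' Assign each cell to a clone from its matched, deduplicated triples
#'
#' UMIs supporting each (cell, tag) pair are counted (one per distinct
#' triple). A cell is assigned its plurality tag iff that tag's UMI count is
#' at least `min_umis` and its purity (supporting / total UMIs) is at least
#' `min_purity`; plurality ties yield UNASSIGNED. With
#' `policy = "strict-single"` any cell showing more than one tag is
#' UNASSIGNED.
#'
#' @param triples deduplicated, library-matched triples (with `tag_id`)
#' @param min_umis minimum supporting UMI count
#' @param min_purity minimum purity fraction
#' @param policy `"plurality"` (default) or `"strict-single"`
#' @return data.frame of class `clone_assignment` with columns `cell`,
#'   `tag_id` (NA when unassigned), `umis_support`, `umis_total`, `purity`
#' @export
assign_clones <- function(triples, min_umis = 2L, min_purity = 0.6,
                          policy = c("plurality", "strict-single")) {
  policy <- match.arg(policy)
  if (nrow(triples) == 0) {
    out <- data.frame(cell = character(0), tag_id = character(0),
                      umis_support = integer(0), umis_total = integer(0),
                      purity = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("clone_assignment", class(out))
    return(out)
  }
  tab <- table(triples$cid, triples$tag_id)
  cells <- rownames(tab)
  totals <- rowSums(tab)
  top <- apply(tab, 1, max)
  n_tags_seen <- rowSums(tab > 0)
  top_id <- colnames(tab)[apply(tab, 1, which.max)]
  tied <- apply(tab, 1, function(r) sum(r == max(r)) > 1L)
  purity <- top / totals
  assigned <- !tied & top >= min_umis & purity >= min_purity
  if (policy == "strict-single") assigned <- assigned & n_tags_seen == 1L
  out <- data.frame(
    cell = cells,
    tag_id = ifelse(assigned, top_id, NA_character_),
    umis_support = as.integer(top),
    umis_total = as.integer(totals),
    purity = purity,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("clone_assignment", class(out))
  out
}

#' Run the full tag-processing chain on raw reads
#'
#' extract -> whitelist filter -> deduplicate -> library match -> assign.
#'
#' @param reads data.frame `cid`, `umi`, `read2`
#' @param library a `barcode_library`
#' @param whitelist retained cell barcodes
#' @param tag_length tag length in bp
#' @param max_flank_mismatch substitutions tolerated per flank
#' @param max_cid_hamming whitelist matching radius (0 or 1)
#' @param max_tag_hamming library matching radius (0 or 1)
#' @param min_umis,min_purity,policy assignment rule, see [assign_clones()]
#' @return list with `assignment`, `triples` (final), and `qc` (per-stage
#'   record counts)
#' @export
process_tag_reads <- function(reads, library, whitelist,
                              tag_length = 38L, max_flank_mismatch = 2L,
                              max_cid_hamming = 0L, max_tag_hamming = 1L,
                              min_umis = 2L, min_purity = 0.6,
                              policy = "plurality") {
  ex <- extract_tags(reads, library$flank5, library$flank3,
                     tag_length = tag_length,
                     max_flank_mismatch = max_flank_mismatch)
  filt <- filter_cid(ex$triples, whitelist, max_cid_hamming = max_cid_hamming)
  dedup <- deduplicate(filt)
  matched <- match_library(dedup, library, max_tag_hamming = max_tag_hamming)
  assignment <- assign_clones(matched$triples, min_umis = min_umis,
                              min_purity = min_purity, policy = policy)
  list(assignment = assignment,
       triples = matched$triples,
       qc = list(reads_in = nrow(reads), extract_drops = ex$drops,
                 extracted = nrow(ex$triples), whitelisted = nrow(filt),
                 deduplicated = nrow(dedup), match_stats = matched$stats))
}
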