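# Instrument selection: genome-wide significance filter + greedy LD clumping.

#' Construct an LD matrix object
#'
#' Squared-correlation matrix over a set of SNPs, with positions (and
#' chromosome labels) aligned to the identifier order.  Symmetry, a unit
#' diagonal and entries in \[0, 1\] are enforced.
#'
#' @param r2 Square numeric matrix of squared correlations.
#' @param snp_ids Character vector of identifiers, one per row/column.
#' @param pos Base-pair positions (1-based) aligned to `snp_ids`.
#' @param chrom Chromosome labels aligned to `snp_ids`; a scalar is recycled.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids, pos, chrom = "1") {
  r2 <- as.matrix(r2)
  n <- length(snp_ids)
  stopifnot(nrow(r2) == n, ncol(r2) == n, length(pos) == n)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n)
  if (!isTRUE(all.equal(r2, t(r2), tolerance = 1e-10))) {
    stop("LD matrix must be symmetric")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop("LD r2 entries must lie in [0, 1]")
  r2 <- pmin(pmax(r2, 0), 1)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 pos = as.numeric(pos), chrom = as.character(chrom)),
            class = "ld_matrix")
}

#' Read an LD matrix from a square tab-separated table
#'
#' The table must carry snp_ids as both header row and first column.
#' Positions/chromosomes are supplied separately (they are not part of the
#' square table format).
#'
#' @param path Path to the square TSV.
#' @param pos,chrom Positions and chromosome labels aligned to the table order.
#' @export
read_ld_matrix <- function(path, pos, chrom = "1") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(tab), rownames(tab), pos, chrom)
}

#' Filter SNP records by P-value threshold
#'
#' Retains exactly the records with `pval` strictly below `p_threshold`
#' (strict inequality: boundary SNPs are excluded), preserving input order.
#' The default reproduces the instrument-relevance filter P < 5e-6.
#'
#' @param stats A [sumstats()] object.
#' @param p_threshold Upper bound (exclusive) on the P value.
#' @return data.frame of the retained SNP records.
#' @export
filter_by_pvalue <- function(stats, p_threshold = 5e-6) {
  stopifnot(inherits(stats, "sumstats"))
  if (nrow(stats$records) == 0) stop("stats contains no records")
  keep <- stats$records$pval < p_threshold
  out <- stats$records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Standard index-SNP clumping: candidates are sorted by ascending P value
#' (ties broken by lexicographic `snp_id` for reproducibility); the best
#' remaining SNP is taken as an index and every remaining candidate on the
#' same chromosome within `clump_kb` kilobases whose squared correlation with
#' the index is `>= clump_r2` is removed.  Index SNPs form the instrument set.
#' Candidates absent from the LD matrix are dropped with a warning rather than
#' assumed independent.
#'
#' @param candidates data.frame of SNP records (as from [filter_by_pvalue()]).
#' @param ld An [ld_matrix()] covering the candidates.
#' @param clump_r2 Squared-correlation threshold, default 0.001.
#' @param clump_kb Window half-width in kilobases, default 10000.
#' @param exposure_name Label stored on the result.
#' @param p_threshold The filter that produced `candidates` (metadata only).
#' @return An object of class `instrument_set` with fields `exposure_name`,
#'   `snp_ids`, `p_threshold`, `clump_r2`, `clump_kb`, `n_dropped_no_ld`.
#' @export
ld_clump <- function(candidates, ld, clump_r2 = 0.001, clump_kb = 10000,
                     exposure_name = "exposure", p_threshold = NA_real_) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (nrow(candidates) == 0) {
    return(structure(list(exposure_name = exposure_name, snp_ids = character(0),
                          p_threshold = p_threshold, clump_r2 = clump_r2,
                          clump_kb = clump_kb, n_dropped_no_ld = 0L),
                     class = "instrument_set"))
  }
  in_ld <- candidates$snp_id %in% ld$snp_ids
  if (any(!in_ld)) {
    warning(sum(!in_ld), " candidate(s) absent from the LD matrix were dropped")
  }
  cand <- candidates[in_ld, , drop = FALSE]
  # Deterministic order: ascending P, then lexicographic id.
  cand <- cand[order(cand$pval, cand$snp_id, method = "radix"), , drop = FALSE]
  idx_of <- match(cand$snp_id, ld$snp_ids)
  pos <- ld$pos[idx_of]
  chrom <- ld$chrom[idx_of]
  alive <- rep(TRUE, nrow(cand))
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept <- c(kept, cand$snp_id[i])
    later <- which(alive)
    later <- later[later > i]
    if (length(later) == 0) next
    same_chr <- chrom[later] == chrom[i]
    near <- abs(pos[later] - pos[i]) <= clump_kb * 1000
    r2 <- ld$r2[idx_of[i], idx_of[later]]
    alive[later[same_chr & near & r2 >= clump_r2]] <- FALSE
  }
  structure(list(exposure_name = exposure_name, snp_ids = kept,
                 p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, n_dropped_no_ld = sum(!in_ld)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %s, %d SNPs (P < %g, r2 < %g, %g kb)\n",
              x$exposure_name, length(x$snp_ids), x$p_threshold,
              x$clump_r2, x$clump_kb))
  invisible(x)
}

#' Select instruments for an exposure: P filter followed by LD clumping
#'
#' Convenience wrapper chaining [filter_by_pvalue()] and [ld_clump()].
#'
#' @inheritParams filter_by_pvalue
#' @inheritParams ld_clump
#' @export
select_instruments <- function(stats, ld, p_threshold = 5e-6,
                               clump_r2 = 0.001, clump_kb = 10000) {
  cand <- filter_by_pvalue(stats, p_threshold)
  ld_clump(cand, ld, clump_r2 = clump_r2, clump_kb = clump_kb,
           exposure_name = stats$trait_name, p_threshold = p_threshold)
}
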