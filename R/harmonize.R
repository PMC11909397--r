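# Allele harmonization: place exposure and outcome effects on a common
# effect-allele frame.  Four rules, applied per SNP in a fixed order:
#   1) palindromic (A/T, C/G) exposure pairs are removed outright — their
#      strand state is undecidable, so correction cannot be trusted;
#   2) exact or swapped allele matches are kept (swap flips the outcome sign);
#   3) complement-strand matches are corrected (optionally with a flip);
#   4) anything else is incompatible and removed.

HARMONIZE_ACTIONS <- c("kept", "sign_flipped", "strand_corrected",
                       "strand_corrected_and_flipped", "dropped_palindromic",
                       "dropped_incompatible", "missing_in_outcome")

wc_complement <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

is_palindromic_pair <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Classify the alignment between exposure and outcome allele pairs
#'
#' Decision procedure, applied in order: palindromic exposure pair ->
#' `dropped_palindromic`; exact match -> `kept`; swapped -> `sign_flipped`;
#' complement-strand match -> `strand_corrected`; complement-strand swapped ->
#' `strand_corrected_and_flipped`; otherwise `dropped_incompatible`.
#'
#' @param ea_x,oa_x Exposure effect and other allele (single characters,
#'   A/C/G/T).
#' @param ea_y,oa_y Outcome effect and other allele.
#' @return One of the action strings; vectorized over its arguments.
#' @export
classify_alignment <- function(ea_x, oa_x, ea_y, oa_y) {
  alleles <- c(ea_x, oa_x, ea_y, oa_y)
  if (!all(alleles %in% VALID_ALLELES)) {
    stop("alleles must be single characters among A, C, G, T")
  }
  n <- max(length(ea_x), length(oa_x), length(ea_y), length(oa_y))
  ea_x <- rep_len(ea_x, n); oa_x <- rep_len(oa_x, n)
  ea_y <- rep_len(ea_y, n); oa_y <- rep_len(oa_y, n)
  if (any(ea_x == oa_x) || any(ea_y == oa_y)) {
    stop("effect and other allele must differ within each trait")
  }
  out <- rep("dropped_incompatible", n)
  cy_e <- unname(wc_complement(ea_y))
  cy_o <- unname(wc_complement(oa_y))
  out[cy_e == ea_x & cy_o == oa_x] <- "strand_corrected"
  out[cy_e == oa_x & cy_o == ea_x] <- "strand_corrected_and_flipped"
  out[ea_y == oa_x & oa_y == ea_x] <- "sign_flipped"
  out[ea_y == ea_x & oa_y == oa_x] <- "kept"
  out[is_palindromic_pair(ea_x, oa_x)] <- "dropped_palindromic"
  out
}

#' Harmonize exposure instruments against an outcome GWAS
#'
#' For every exposure instrument: if the SNP is absent from the outcome it is
#' logged `missing_in_outcome`; otherwise [classify_alignment()] decides its
#' disposition.  `sign_flipped` and `strand_corrected_and_flipped` negate the
#' outcome effect and replace the outcome frequency by 1 - eaf; `kept` and
#' `strand_corrected` leave the outcome effect unchanged.  Exposure effects
#' are never modified.  Dropped SNPs are excluded from the pair table but
#' always appear in the disposition log.
#'
#' Duplicate `snp_id` rows in the outcome are resolved by first occurrence,
#' with a warning.
#'
#' @param exposure A [sumstats()] object (typically already restricted to the
#'   selected instruments, or restricted here via `snp_ids`).
#' @param outcome A [sumstats()] object indexed by `snp_id`.
#' @param snp_ids Optional instrument identifiers to restrict `exposure` to;
#'   an `instrument_set` is also accepted.
#' @return An object of class `harmonized_set` with fields `exposure_name`,
#'   `outcome_name`, `pairs` (data.frame: snp_id, beta_x, se_x, beta_y, se_y,
#'   eaf_x, eaf_y, pval_x, pval_y) and `dispositions` (snp_id, action).
#' @export
harmonize <- function(exposure, outcome, snp_ids = NULL) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  if (inherits(snp_ids, "instrument_set")) snp_ids <- snp_ids$snp_ids
  if (!is.null(snp_ids)) {
    ex <- ex[ex$snp_id %in% snp_ids, , drop = FALSE]
  }
  out <- outcome$records
  if (anyDuplicated(out$snp_id)) {
    warning("duplicate snp_id rows in outcome; keeping first occurrence")
    out <- out[!duplicated(out$snp_id), , drop = FALSE]
  }
  m <- match(ex$snp_id, out$snp_id)
  present <- !is.na(m)
  action <- rep("missing_in_outcome", nrow(ex))
  if (any(present)) {
    action[present] <- classify_alignment(
      ex$effect_allele[present], ex$other_allele[present],
      out$effect_allele[m[present]], out$other_allele[m[present]]
    )
  }
  flip <- action %in% c("sign_flipped", "strand_corrected_and_flipped")
  keep <- action %in% c("kept", "sign_flipped", "strand_corrected",
                        "strand_corrected_and_flipped")
  beta_y <- ifelse(flip, -out$beta[m], out$beta[m])
  eaf_y <- ifelse(flip, 1 - out$eaf[m], out$eaf[m])
  pairs <- data.frame(
    snp_id = ex$snp_id[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = beta_y[keep], se_y = out$se[m[keep]],
    eaf_x = ex$eaf[keep], eaf_y = eaf_y[keep],
    pval_x = ex$pval[keep], pval_y = out$pval[m[keep]],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  structure(
    list(exposure_name = exposure$trait_name, outcome_name = outcome$trait_name,
         pairs = pairs,
         dispositions = data.frame(snp_id = ex$snp_id, action = action,
                                   stringsAsFactors = FALSE)),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %s -> %s, %d pairs\n",
              x$exposure_name, x$outcome_name, nrow(x$pairs)))
  tab <- table(x$dispositions$action)
  for (a in names(tab)) cat(sprintf("  %s: %d\n", a, tab[[a]]))
  invisible(x)
}

#' Write the per-SNP harmonization disposition log as a TSV audit table
#' @param hset A `harmonized_set`.
#' @param path Output path.
#' @export
write_dispositions <- function(hset, path) {
  stopifnot(inherits(hset, "harmonized_set"))
  utils::write.table(hset$dispositions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
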