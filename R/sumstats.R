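# Canonical column order used by write_sumstats() and expected back by
# read_sumstats() on round-trip.
SUMSTATS_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n_cases", "n_controls")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics object
#'
#' A `sumstats` object holds one trait's per-SNP association records: one row
#' per SNP with identifier, alleles, effect size on the log-odds
#' (case-control) or SD (quantitative) scale, its standard error and two-sided
#' P value.  The trait type is carried explicitly because it selects the
#' effect-scale prior in colocalization.
#'
#' @param records data.frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optionally `chrom`, `pos`, `eaf`,
#'   `n_cases`, `n_controls`.
#' @param trait_name Character scalar naming the trait.
#' @param trait_type `"case_control"` or `"quantitative"`.
#' @param provenance Free-text source tag.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(records, trait_name, trait_type = c("case_control", "quantitative"),
                     provenance = "") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  for (col in c("chrom", "pos", "eaf", "n_cases", "n_controls")) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  needed <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("records is missing required columns: ", paste(missing, collapse = ", "))
  }
  records <- records[, SUMSTATS_COLUMNS]
  if (anyDuplicated(records$snp_id)) {
    stop("snp_id must be unique within a sumstats object")
  }
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         records = records, provenance = provenance),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: %s (%s), %d SNPs [%s]\n",
              x$trait_name, x$trait_type, nrow(x$records), x$provenance))
  invisible(x)
}

#' Number of SNP records in a sumstats object
#' @param x A `sumstats` object.
#' @export
n_snps <- function(x) nrow(x$records)

#' Reconstruct effect size and standard error from an odds ratio and P value
#'
#' Many public GWAS release only the odds ratio and P value per SNP.  The
#' additive effect and its standard error are recovered as
#' beta = ln(OR), Z = Phi^-1(1 - P/2), SE = |beta| / Z.
#'
#' P values of exactly 0 (underflow in the source file) are floored at
#' `p_floor` before the quantile is taken; the formula is undefined at P = 0.
#'
#' @param or_value Odds ratio, > 0 and != 1.
#' @param p_value Two-sided P value in (0, 1).
#' @param p_floor Minimum P substituted for underflowed zeros.
#' @return List with elements `beta` and `se`.
#' @examples
#' reconstruct_beta_se(1.5, 0.05)
#' @export
reconstruct_beta_se <- function(or_value, p_value, p_floor = 1e-300) {
  if (any(!is.finite(or_value)) || any(or_value <= 0)) {
    stop("or_value must be finite and > 0")
  }
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value >= 1)) {
    stop("p_value must lie in (0, 1)")
  }
  p_value <- pmax(p_value, p_floor)
  beta <- log(or_value)
  if (any(beta == 0)) {
    stop("or_value = 1 gives beta = 0; the standard error is not recoverable")
  }
  # Upper-tail form of qnorm(1 - P/2): numerically exact down to the floor,
  # where the complement would round to 1 for P below ~4e-16.
  z <- stats::qnorm(p_value / 2, lower.tail = FALSE)
  if (any(z <= 0)) {
    stop("degenerate input: the implied Z statistic is not positive")
  }
  list(beta = beta, se = abs(beta) / z)
}

# Validate and coerce raw rows; returns list(records, tally) where tally
# counts dropped rows by reason.  Reconstruction of beta/se from (or, pval)
# or (beta, pval) happens here, row-wise by availability.
validate_snp_rows <- function(raw, p_floor = 1e-300, z_p_tol = 0.05) {
  tally <- c(invalid_allele = 0L, invalid_se = 0L, invalid_pval = 0L,
             invalid_eaf = 0L, unrecoverable_beta_se = 0L, duplicate_snp_id = 0L)
  n <- nrow(raw)
  for (col in c("eaf", "beta", "se", "pval", "or")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  for (col in c("n_cases", "n_controls")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_integer_
    raw[[col]] <- suppressWarnings(as.integer(raw[[col]]))
  }
  if (!"chrom" %in% names(raw)) raw$chrom <- NA_character_
  if (!"pos" %in% names(raw)) raw$pos <- NA_real_
  raw$pos <- suppressWarnings(as.numeric(raw$pos))

  raw$effect_allele <- toupper(trimws(as.character(raw$effect_allele)))
  raw$other_allele <- toupper(trimws(as.character(raw$other_allele)))
  raw$snp_id <- as.character(raw$snp_id)
  raw$chrom <- as.character(raw$chrom)

  ok_allele <- raw$effect_allele %in% VALID_ALLELES &
    raw$other_allele %in% VALID_ALLELES &
    raw$effect_allele != raw$other_allele
  tally["invalid_allele"] <- sum(!ok_allele)
  raw <- raw[ok_allele, , drop = FALSE]

  # Fill beta/se per row from what is available.
  have_beta_se <- !is.na(raw$beta) & !is.na(raw$se)
  have_or_p <- is.na(raw$beta) & !is.na(raw$or) & !is.na(raw$pval)
  have_beta_p <- !is.na(raw$beta) & is.na(raw$se) & !is.na(raw$pval)
  for (i in which(have_or_p)) {
    rec <- tryCatch(reconstruct_beta_se(raw$or[i], raw$pval[i], p_floor),
                    error = function(e) NULL)
    if (is.null(rec)) next
    raw$beta[i] <- rec$beta
    raw$se[i] <- rec$se
  }
  for (i in which(have_beta_p)) {
    if (raw$beta[i] == 0 || raw$pval[i] <= 0 || raw$pval[i] >= 1) next
    z <- stats::qnorm(max(raw$pval[i], p_floor) / 2, lower.tail = FALSE)
    if (z > 0) raw$se[i] <- abs(raw$beta[i]) / z
  }
  recoverable <- !is.na(raw$beta) & !is.na(raw$se)
  tally["unrecoverable_beta_se"] <- sum(!recoverable)
  raw <- raw[recoverable, , drop = FALSE]

  ok_se <- is.finite(raw$se) & raw$se > 0
  tally["invalid_se"] <- sum(!ok_se)
  raw <- raw[ok_se, , drop = FALSE]

  # Fill missing P from the Wald Z; then range-check.
  miss_p <- is.na(raw$pval)
  raw$pval[miss_p] <- 2 * stats::pnorm(-abs(raw$beta[miss_p] / raw$se[miss_p]))
  ok_p <- is.finite(raw$pval) & raw$pval > 0 & raw$pval <= 1
  tally["invalid_pval"] <- sum(!ok_p)
  raw <- raw[ok_p, , drop = FALSE]

  ok_eaf <- is.na(raw$eaf) | (raw$eaf >= 0 & raw$eaf <= 1)
  tally["invalid_eaf"] <- sum(!ok_eaf)
  raw <- raw[ok_eaf, , drop = FALSE]

  dup <- duplicated(raw$snp_id)
  tally["duplicate_snp_id"] <- sum(dup)
  raw <- raw[!dup, , drop = FALSE]

  # Warn-level Z/P consistency check.
  implied <- 2 * stats::pnorm(-abs(raw$beta / raw$se))
  inconsistent <- abs(implied - raw$pval) > z_p_tol * pmax(implied, raw$pval) &
    raw$pval > 1e-280
  if (any(inconsistent, na.rm = TRUE)) {
    warning(sum(inconsistent, na.rm = TRUE),
            " record(s) have P values inconsistent with beta/se beyond tolerance")
  }

  rownames(raw) <- NULL
  list(records = raw[, SUMSTATS_COLUMNS, drop = FALSE], tally = tally)
}

#' Read GWAS summary statistics from a delimited text table
#'
#' Reads a tab-separated (optionally gzip-compressed) table with a header row,
#' maps its columns onto the canonical roles via `column_map`, validates each
#' row, and reconstructs `beta`/`se` where only `(or, pval)` or `(beta, pval)`
#' are available.  Rows failing validation are dropped and counted in the
#' `drop_tally` attribute of the result.
#'
#' @param path Path to the table (plain or `.gz`).
#' @param column_map Named character vector mapping role -> column name in the
#'   file, e.g. `c(snp_id = "SNP", effect_allele = "A1", ...)`.  Must cover
#'   `snp_id`, `effect_allele`, `other_allele` and one of the pairs
#'   `(beta, se)`, `(beta, pval)`, `(or, pval)`.
#' @param trait_name,trait_type,provenance Trait metadata (see [sumstats()]).
#' @param sep Field separator, default tab.
#' @param p_floor Floor for underflowed P values.
#' @return A [sumstats()] object with attribute `drop_tally`.
#' @export
read_sumstats <- function(path, column_map,
                          trait_name, trait_type = c("case_control", "quantitative"),
                          provenance = path, sep = "\t", p_floor = 1e-300) {
  trait_type <- match.arg(trait_type)
  mandatory <- c("snp_id", "effect_allele", "other_allele")
  if (!all(mandatory %in% names(column_map))) {
    stop("column_map must assign snp_id, effect_allele and other_allele")
  }
  has <- function(...) all(c(...) %in% names(column_map))
  if (!(has("beta", "se") || has("beta", "pval") || has("or", "pval"))) {
    stop("column_map must assign (beta, se), (beta, pval) or (or, pval)")
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      comment.char = "", check.names = FALSE),
    error = function(e) stop("failed to read summary statistics from '", path,
                             "': ", conditionMessage(e))
  )
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("columns mapped but absent from '", path, "': ",
         paste(missing_cols, collapse = ", "))
  }
  mapped <- raw[, unname(column_map), drop = FALSE]
  names(mapped) <- names(column_map)
  out <- validate_snp_rows(mapped, p_floor = p_floor)
  if (nrow(out$records) == 0) {
    stop("no valid summary-statistic rows in '", path, "'")
  }
  ss <- sumstats(out$records, trait_name, trait_type, provenance)
  attr(ss, "drop_tally") <- out$tally
  ss
}

#' Write summary statistics as a tab-separated table
#'
#' Columns are written in the fixed order `snp_id, chrom, pos, effect_allele,
#' other_allele, eaf, beta, se, pval, n_cases, n_controls`; numerics use 17
#' significant digits so `read_sumstats(write_sumstats(s))` reproduces every
#' field exactly.
#'
#' @param stats A non-empty [sumstats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  if (nrow(stats$records) == 0) stop("refusing to write an empty sumstats object")
  rec <- stats$records
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    snp_id = rec$snp_id, chrom = as.character(rec$chrom),
    pos = ifelse(is.na(rec$pos), "NA", sprintf("%.0f", rec$pos)),
    effect_allele = rec$effect_allele, other_allele = rec$other_allele,
    eaf = fmt(rec$eaf), beta = fmt(rec$beta), se = fmt(rec$se),
    pval = fmt(rec$pval),
    n_cases = ifelse(is.na(rec$n_cases), "NA", as.character(rec$n_cases)),
    n_controls = ifelse(is.na(rec$n_controls), "NA", as.character(rec$n_controls)),
    stringsAsFactors = FALSE
  )
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("failed to write '", path, "': ", conditionMessage(e))
  )
  invisible(path)
}

# Default column map matching write_sumstats output.
#' Canonical column map for tables produced by [write_sumstats()]
#' @export
canonical_column_map <- function() {
  stats::setNames(SUMSTATS_COLUMNS, SUMSTATS_COLUMNS)
}
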