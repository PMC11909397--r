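# Bayesian colocalization of two traits in a genomic window via Wakefield
# approximate Bayes factors and the five-hypothesis posterior:
#   H0 neither trait associated, H1/H2 one trait only, H3 two distinct
#   causal variants, H4 one shared causal variant.
# All evidence sums run in log space so |Z| up to 100 cannot overflow.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Wakefield log approximate Bayes factor for one SNP
#'
#' With `V = se^2`, `W = prior_sd^2`, `Z = beta/se`:
#' `log ABF = 0.5 log(V/(V+W)) + 0.5 Z^2 W/(V+W)`.
#'
#' @param beta,se Marginal effect and standard error (`se > 0`).
#' @param prior_sd Effect-scale prior standard deviation (`> 0`): 0.15 is
#'   conventional for case-control (log-odds) traits, 0.2 for quantitative
#'   traits in SD units.
#' @return Log ABF; vectorized.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + w)) + 0.5 * z2 * w / (v + w)
}

default_prior_sd <- function(trait_type) {
  if (identical(trait_type, "quantitative")) 0.2 else 0.15
}

#' Extract the colocalization test region around the lead exposure-outcome SNP
#'
#' The lead SNP is the shared SNP minimizing the product of the two traits'
#' P values (ties: smaller minimum P, then lexicographic id).  The region is
#' every shared SNP on the lead's chromosome within `half_window` base pairs
#' of it (inclusive), both traits restricted and aligned to the same SNP
#' order.
#'
#' @param trait1,trait2 [sumstats()] objects with position information.
#' @param half_window Half window in base pairs, default 500000 (± 500 kb).
#' @return Object of class `coloc_region`: `lead_snp`, `half_window`,
#'   `trait1`, `trait2` (aligned record data.frames), `trait_type1`,
#'   `trait_type2`, `n_snps`.
#' @export
extract_region <- function(trait1, trait2, half_window = 500000) {
  stopifnot(inherits(trait1, "sumstats"), inherits(trait2, "sumstats"))
  shared <- intersect(trait1$records$snp_id, trait2$records$snp_id)
  if (length(shared) == 0) stop("traits share no SNPs: empty intersection")
  r1 <- trait1$records[match(shared, trait1$records$snp_id), , drop = FALSE]
  r2 <- trait2$records[match(shared, trait2$records$snp_id), , drop = FALSE]
  if (all(is.na(r1$pos))) stop("trait1 lacks position information")
  lp <- log(r1$pval) + log(r2$pval)
  minp <- pmin(r1$pval, r2$pval)
  ord <- order(lp, minp, shared, method = "radix")
  lead <- ord[1]
  in_win <- !is.na(r1$pos) &
    r1$chrom == r1$chrom[lead] &
    abs(r1$pos - r1$pos[lead]) <= half_window
  r1 <- r1[in_win, , drop = FALSE]
  r2 <- r2[in_win, , drop = FALSE]
  o <- order(r1$pos, r1$snp_id, method = "radix")
  structure(list(
    lead_snp = shared[lead], half_window = half_window,
    trait1 = r1[o, , drop = FALSE], trait2 = r2[o, , drop = FALSE],
    trait_type1 = trait1$trait_type, trait_type2 = trait2$trait_type,
    n_snps = sum(in_win)
  ), class = "coloc_region")
}

#' Five-hypothesis colocalization posterior from per-SNP Bayes factors
#'
#' Assuming at most one causal variant per trait in the region, with per-SNP
#' log-ABFs `l1`, `l2` and prior probabilities `p1` (trait 1 causal), `p2`
#' (trait 2 causal), `p12` (shared causal), the unnormalized hypothesis
#' weights are `w0 = 1`, `w1 = p1 S1`, `w2 = p2 S2`,
#' `w3 = p1 p2 (S1 S2 - S12)`, `w4 = p12 S12` where `S1 = sum exp l1`,
#' `S2 = sum exp l2`, `S12 = sum exp(l1 + l2)`.  Posteriors are the
#' normalized weights, computed with log-sum-exp throughout.  `pp_h4 >= 0.8`
#' is the colocalization verdict.
#'
#' @param region A `coloc_region` (or a list with `trait1`/`trait2` record
#'   data.frames carrying `beta` and `se`).
#' @param p1,p2,p12 Priors, defaults 1e-4, 1e-4, 1e-5.
#' @param prior_sd1,prior_sd2 Effect-scale prior SDs; defaults chosen by each
#'   trait's type (0.15 case-control, 0.2 quantitative).
#' @return Object of class `coloc_result`: `n_snps`, priors, prior SDs,
#'   `log_abf1`, `log_abf2`, `pp` (named vector h0..h4), `colocalized`.
#' @export
coloc_posteriors <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (is.null(prior_sd1)) {
    prior_sd1 <- default_prior_sd(if (is.null(region$trait_type1)) "case_control"
                                  else region$trait_type1)
  }
  if (is.null(prior_sd2)) {
    prior_sd2 <- default_prior_sd(if (is.null(region$trait_type2)) "case_control"
                                  else region$trait_type2)
  }
  r1 <- region$trait1
  r2 <- region$trait2
  if (nrow(r1) == 0) stop("empty region")
  stopifnot(nrow(r1) == nrow(r2))
  l1 <- log_abf(r1$beta, r1$se, prior_sd1)
  l2 <- log_abf(r2$beta, r2$se, prior_sd2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lw <- c(
    h0 = 0,
    h1 = log(p1) + ls1,
    h2 = log(p2) + ls2,
    h3 = NA_real_,
    h4 = log(p12) + ls12
  )
  # log(S1*S2 - S12) via log1p; S12 <= S1*S2 always (Cauchy-ish bound), with
  # equality only at n = 1, where two distinct causal variants are impossible.
  d <- ls12 - ls1 - ls2
  if (d >= -1e-12) {
    lw["h3"] <- -Inf
    note <- "single-SNP region: H3 impossible, weight set to 0"
  } else {
    lw["h3"] <- log(p1) + log(p2) + ls1 + ls2 + log1p(-exp(d))
    note <- NA_character_
  }
  denom <- logsumexp(lw)
  pp <- exp(lw - denom)
  names(pp) <- c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4")
  structure(list(
    n_snps = nrow(r1), p1 = p1, p2 = p2, p12 = p12,
    prior_sd1 = prior_sd1, prior_sd2 = prior_sd2,
    log_abf1 = l1, log_abf2 = l2,
    pp = pp, colocalized = unname(pp["pp_h4"] >= 0.8),
    lead_snp = region$lead_snp, note = note
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc: %d SNPs, PP(H0..H4) = %s, %s\n", x$n_snps,
              paste(sprintf("%.3f", x$pp), collapse = " "),
              if (x$colocalized) "COLOCALIZED (H4 >= 0.8)" else "not colocalized"))
  invisible(x)
}

#' Run colocalization end-to-end on two traits
#'
#' [extract_region()] followed by [coloc_posteriors()].
#' @inheritParams extract_region
#' @inheritParams coloc_posteriors
#' @export
colocalize <- function(trait1, trait2, half_window = 500000,
                       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd1 = NULL, prior_sd2 = NULL) {
  region <- extract_region(trait1, trait2, half_window)
  coloc_posteriors(region, p1, p2, p12, prior_sd1, prior_sd2)
}

#' Write a one-row colocalization summary (plus optional per-SNP ABF table)
#' @param res A `coloc_result`.
#' @param path Output TSV path.
#' @param abf_path Optional path for the per-SNP log-ABF table.
#' @param region The `coloc_region` (needed for `abf_path` snp ids).
#' @export
write_coloc <- function(res, path, abf_path = NULL, region = NULL) {
  row <- data.frame(lead_snp = res$lead_snp, n_snps = res$n_snps,
                    t(res$pp),
                    verdict = if (res$colocalized) "colocalized" else "not_colocalized")
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(abf_path) && !is.null(region)) {
    abf <- data.frame(snp_id = region$trait1$snp_id,
                      log_abf1 = res$log_abf1, log_abf2 = res$log_abf2,
                      neglog10_p1 = -log10(region$trait1$pval),
                      neglog10_p2 = -log10(region$trait2$pval))
    utils::write.table(abf, abf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
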