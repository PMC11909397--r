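# Small in-code fixtures shared across test files.

make_records <- function(n, seed = 1, chrom = "1", pos_step = 1e5) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom, pos = seq_len(n) * pos_step,
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C"), length.out = n),
    eaf = runif(n, 0.05, 0.95),
    beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    n_cases = NA_integer_, n_controls = NA_integer_,
    stringsAsFactors = FALSE
  )
}

make_sumstats <- function(n, seed = 1, trait_name = "trait",
                          trait_type = "case_control", ...) {
  sumstats(make_records(n, seed, ...), trait_name, trait_type, "fixture")
}

make_pairs <- function(beta_x, beta_y, se_y, se_x = 0.01) {
  data.frame(snp_id = sprintf("rs%03d", seq_along(beta_x)),
             beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
             eaf_x = NA_real_, eaf_y = NA_real_,
             pval_x = NA_real_, pval_y = NA_real_)
}

# Independently coded truth table for allele alignment: tries each candidate
# transformation of the outcome pair explicitly, in the documented priority
# order, instead of the implementation's vectorized masking.
oracle_alignment <- function(ea_x, oa_x, ea_y, oa_y) {
  comp <- function(a) c(A = "T", T = "A", C = "G", G = "C")[[a]]
  pal <- function(e, o) (e == comp(o))
  if (pal(ea_x, oa_x)) return("dropped_palindromic")
  if (ea_y == ea_x && oa_y == oa_x) return("kept")
  if (ea_y == oa_x && oa_y == ea_x) return("sign_flipped")
  if (comp(ea_y) == ea_x && comp(oa_y) == oa_x) return("strand_corrected")
  if (comp(ea_y) == oa_x && comp(oa_y) == ea_x) return("strand_corrected_and_flipped")
  "dropped_incompatible"
}

all_allele_pairs <- function() {
  g <- expand.grid(ea = c("A", "C", "G", "T"), oa = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g[g$ea != g$oa, ]
}

# A small hand-built fixture grid over a shared pool of independent SNPs:
# exposure i owns 5 instrument SNPs (strong signal, null elsewhere); every
# outcome carries mild effects at all SNPs; the last outcome is missing the
# last exposure's instrument SNPs, so exactly that cell goes gray.
make_grid_fixture <- function(n_exposures = 9, n_outcomes = 5, seed = 801) {
  set.seed(seed)
  n <- max(60, 5 * n_exposures + 10)
  ids <- sprintf("rsP%03d", seq_len(n))
  base <- data.frame(
    snp_id = ids, chrom = "1", pos = seq_len(n) * 2.1e7,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    n_cases = NA_integer_, n_controls = NA_integer_,
    stringsAsFactors = FALSE
  )
  mk <- function(beta, se, name) {
    rec <- base
    rec$beta <- beta
    rec$se <- se
    rec$pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
    rec <- rec[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n_cases", "n_controls")]
    sumstats(rec, name, "case_control", "fixture")
  }
  exposures <- list()
  for (i in seq_len(n_exposures)) {
    beta <- rep(0, n)
    beta[(i - 1) * 5 + 1:5] <- 0.1 + 0.01 * seq_len(5)
    exposures[[paste0("exp", i)]] <- mk(beta, rep(0.01, n), paste0("exp", i))
  }
  outcomes <- list()
  for (j in seq_len(n_outcomes)) {
    outcomes[[paste0("out", j)]] <-
      mk(rnorm(n, 0.015, 0.01), rep(0.012, n), paste0("out", j))
  }
  # The last exposure's instruments are removed from the last outcome.
  inst_last <- ids[(n_exposures - 1) * 5 + 1:5]
  last <- paste0("out", n_outcomes)
  keep <- !(outcomes[[last]]$records$snp_id %in% inst_last)
  outcomes[[last]]$records <- outcomes[[last]]$records[keep, , drop = FALSE]
  ld <- ld_matrix(diag(n), ids, base$pos, base$chrom)
  list(exposures = exposures, outcomes = outcomes, ld = ld)
}
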