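# Synthetic GWAS summary-statistic generator with known ground truth.
#
# Summary statistics are simulated directly (no individual-level genotypes):
# a SNP's standard error follows the standard 1/sqrt(2 n maf (1-maf))
# scaling, the observed effect is the true effect plus N(0, se^2) noise, and
# the P value is the two-sided normal tail of beta/se — so every generated
# record satisfies the Z/P/SE coherence invariant by construction.  Exposure
# and outcome panels draw from independent noise streams (two-sample design,
# no sample overlap).  Effect alleles of instruments are coded as the
# exposure-increasing allele (true effects >= 0), the usual orientation
# convention for summary-level instruments.

#' Simulation configuration
#'
#' @param n_snps_total Total SNPs simulated (instruments + null SNPs).
#' @param n_instruments SNPs given a true effect on the exposure.
#' @param theta Causal effect of exposure on outcome, log-odds per exposure
#'   unit.
#' @param instrument_effect_sd Spread of instrument effect magnitudes around
#'   the design floor (`sigma_gamma`).
#' @param pleiotropy_mean,pleiotropy_sd Mean/SD of per-instrument direct
#'   (pleiotropic) effects on the outcome; 0/0 disables pleiotropy, a nonzero
#'   mean makes it directional.  Drawn independently of instrument strength,
#'   so the InSIDE assumption holds by construction.
#' @param exposure_n,outcome_n Effective sample sizes driving the SEs.
#' @param ld_block_size,within_block_r2 Null SNPs are arranged in LD blocks of
#'   this size with this squared correlation inside a block; instruments are
#'   mutually independent (r2 = 0).
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G allele
#'   pairs.
#' @param design_z Minimum true |Z| of an instrument; the default 6 places
#'   expected P values comfortably below the 5e-6 selection threshold.
#' @param seed Mandatory integer seed; identical seed + config give
#'   byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps_total = 1000, n_instruments = 17, theta = 0.25,
                       instrument_effect_sd = 0.1,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       exposure_n = 176219, outcome_n = 500000,
                       ld_block_size = 10, within_block_r2 = 0.5,
                       maf_range = c(0.05, 0.5),
                       palindromic_fraction = 0, design_z = 6, seed) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  stopifnot(n_instruments <= n_snps_total, n_instruments >= 0,
            instrument_effect_sd >= 0, pleiotropy_sd >= 0,
            exposure_n > 0, outcome_n > 0,
            within_block_r2 >= 0, within_block_r2 <= 1,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

draw_alleles <- function(n, palindromic_fraction) {
  pal <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)
  npal <- matrix(c("A", "C", "C", "A", "A", "G", "G", "A",
                   "C", "T", "T", "C", "G", "T", "T", "G"), ncol = 2, byrow = TRUE)
  is_pal <- stats::runif(n) < palindromic_fraction
  pick_pal <- sample.int(4, n, replace = TRUE)
  pick_npal <- sample.int(8, n, replace = TRUE)
  ea <- ifelse(is_pal, pal[pick_pal, 1], npal[pick_npal, 1])
  oa <- ifelse(is_pal, pal[pick_pal, 2], npal[pick_npal, 2])
  list(ea = ea, oa = oa)
}

se_from_maf <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

#' Simulate an exposure GWAS with planted instruments
#'
#' The first `n_instruments` SNPs receive true effects
#' `gamma_j = design_z * se_j + |N(0, sigma_gamma^2)|` (nonnegative: the
#' effect allele is the exposure-increasing allele), so every instrument's
#' expected P value clears the 5e-6 selection threshold while
#' `instrument_effect_sd` controls the spread; the rest are null
#' (`gamma = 0`).  Instruments are placed far apart and mutually uncorrelated
#' so LD clumping is the identity on them; null SNPs form LD blocks per the
#' config.
#'
#' @param config A [sim_config()].
#' @return List with `stats` (a [sumstats()]), `truth` (data.frame `snp_id`,
#'   `gamma`, `maf`, `is_instrument` plus attributes), and `ld` (an
#'   [ld_matrix()] covering all SNPs).
#' @export
simulate_exposure <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps_total
  ni <- config$n_instruments
  snp_id <- sprintf("rs%06d", seq_len(n))
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  se_x <- se_from_maf(config$exposure_n, maf)
  gamma <- numeric(n)
  if (ni > 0) {
    gamma[seq_len(ni)] <- config$design_z * se_x[seq_len(ni)] +
      abs(stats::rnorm(ni, 0, config$instrument_effect_sd))
  }
  al <- draw_alleles(n, config$palindromic_fraction)
  beta <- gamma + stats::rnorm(n, 0, se_x)
  pval <- 2 * stats::pnorm(-abs(beta / se_x))
  pval <- pmax(pval, 1e-300)
  # Instruments 10 Mb apart on chromosome 1..; null SNPs tiled after them.
  pos <- (seq_len(n)) * 20000 + 1e6
  pos[seq_len(ni)] <- seq_len(ni) * 2.1e7
  chrom <- rep("1", n)
  rec <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                    effect_allele = al$ea, other_allele = al$oa,
                    eaf = maf, beta = beta, se = se_x, pval = pval,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    stringsAsFactors = FALSE)
  stats <- sumstats(rec, "synthetic_exposure", "case_control", "simulated")
  # LD: identity for instruments; compound blocks among null SNPs.
  r2 <- diag(n)
  if (n > ni && config$ld_block_size > 1 && config$within_block_r2 > 0) {
    null_idx <- (ni + 1):n
    block <- (seq_along(null_idx) - 1) %/% config$ld_block_size
    for (b in unique(block)) {
      members <- null_idx[block == b]
      r2[members, members] <- config$within_block_r2
    }
    diag(r2) <- 1
  }
  ld <- ld_matrix(r2, snp_id, pos, chrom)
  truth <- data.frame(snp_id = snp_id, gamma = gamma, maf = maf,
                      is_instrument = seq_len(n) <= ni,
                      stringsAsFactors = FALSE)
  attr(truth, "theta") <- config$theta
  attr(truth, "config") <- config
  attr(truth, "alleles") <- al
  list(stats = stats, truth = truth, ld = ld)
}

#' Simulate the matched outcome GWAS given exposure ground truth
#'
#' Outcome effects are `theta * gamma_j + alpha_j + N(0, se_y^2)`, where the
#' pleiotropic effects `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` apply
#' to instruments only (balanced when the mean is 0, directional otherwise;
#' InSIDE holds because alpha is drawn independently of gamma).  The noise
#' stream derives from `config$seed + 1` so the two panels are independent
#' samples yet jointly reproducible.
#'
#' @param truth The `truth` element returned by [simulate_exposure()].
#' @param config The same [sim_config()].
#' @return A [sumstats()] for the outcome on the same SNPs and allele frame.
#' @export
simulate_outcome <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  maf <- truth$maf
  se_y <- se_from_maf(config$outcome_n, maf)
  alpha <- numeric(n)
  ni <- sum(truth$is_instrument)
  if (ni > 0 && (config$pleiotropy_sd > 0 || config$pleiotropy_mean != 0)) {
    alpha[truth$is_instrument] <-
      stats::rnorm(ni, config$pleiotropy_mean, config$pleiotropy_sd)
  }
  true_by <- config$theta * truth$gamma + alpha
  beta <- true_by + stats::rnorm(n, 0, se_y)
  pval <- pmax(2 * stats::pnorm(-abs(beta / se_y)), 1e-300)
  al <- attr(truth, "alleles")
  cfg_exp <- attr(truth, "config")
  rec <- data.frame(snp_id = truth$snp_id, chrom = "1",
                    pos = cfg_exp_pos(cfg_exp, n),
                    effect_allele = al$ea, other_allele = al$oa,
                    eaf = maf, beta = beta, se = se_y, pval = pval,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    stringsAsFactors = FALSE)
  sumstats(rec, "synthetic_outcome", "case_control", "simulated")
}

cfg_exp_pos <- function(config, n) {
  pos <- (seq_len(n)) * 20000 + 1e6
  ni <- config$n_instruments
  if (ni > 0) pos[seq_len(ni)] <- seq_len(ni) * 2.1e7
  pos
}

#' Simulate a three-trait mediation system with known path effects
#'
#' Three disjoint instrument sets drive the system: set A (exposure
#' instruments, effects `gamma`) acts on the mediator via `theta_em` and on
#' the outcome via `theta_direct + theta_em * theta_mo`; set B (mediator
#' instruments, effects `delta`) acts on the outcome via `theta_mo` only; set
#' C (outcome instruments) has no effect on exposure or mediator, so the
#' reverse outcome -> exposure path is absent by construction.  The true
#' proportion mediated is `theta_em*theta_mo / (theta_direct +
#' theta_em*theta_mo)`.
#'
#' @param config A [sim_config()]; `n_instruments` sizes each of the three
#'   sets.
#' @param theta_em,theta_mo,theta_direct Path effects.
#' @param mediator_n Sample size for the (quantitative) mediator GWAS.
#' @return List with `exposure`, `mediator`, `outcome` ([sumstats()]),
#'   `truth` (instrument sets and path effects, incl. `proportion_true`).
#' @export
simulate_mediation_triple <- function(config, theta_em = 0.21, theta_mo = 0.23,
                                      theta_direct = 0.21,
                                      mediator_n = 173480) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ni <- config$n_instruments
  n_null <- max(config$n_snps_total - 3 * ni, 0)
  n <- 3 * ni + n_null
  snp_id <- sprintf("rs%06d", seq_len(n))
  set_a <- seq_len(ni)
  set_b <- ni + seq_len(ni)
  set_c <- 2 * ni + seq_len(ni)
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  se_x <- se_from_maf(config$exposure_n, maf)
  se_m <- se_from_maf(mediator_n, maf)
  se_y <- se_from_maf(config$outcome_n, maf)
  draw_eff <- function(se) config$design_z * se +
    abs(stats::rnorm(length(se), 0, config$instrument_effect_sd))
  gamma <- numeric(n); gamma[set_a] <- draw_eff(se_x[set_a])
  delta <- numeric(n); delta[set_b] <- draw_eff(se_m[set_b])
  zeta <- numeric(n);  zeta[set_c] <- draw_eff(se_y[set_c])
  theta_total <- theta_direct + theta_em * theta_mo
  true_x <- gamma
  true_m <- theta_em * gamma + delta
  true_y <- theta_total * gamma + theta_mo * delta + zeta
  al <- draw_alleles(n, config$palindromic_fraction)
  pos <- seq_len(n) * 2.1e7
  mk <- function(true_beta, se, name, type) {
    beta <- true_beta + stats::rnorm(n, 0, se)
    pval <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
    rec <- data.frame(snp_id = snp_id, chrom = "1", pos = pos,
                      effect_allele = al$ea, other_allele = al$oa,
                      eaf = maf, beta = beta, se = se, pval = pval,
                      n_cases = NA_integer_, n_controls = NA_integer_,
                      stringsAsFactors = FALSE)
    sumstats(rec, name, type, "simulated")
  }
  exposure <- mk(true_x, se_x, "synthetic_exposure", "case_control")
  mediator <- mk(true_m, se_m, "synthetic_mediator", "quantitative")
  outcome <- mk(true_y, se_y, "synthetic_outcome", "case_control")
  truth <- list(
    instruments_exposure = snp_id[set_a],
    instruments_mediator = snp_id[set_b],
    instruments_outcome = snp_id[set_c],
    gamma = gamma[set_a], delta = delta[set_b], zeta = zeta[set_c],
    theta_em = theta_em, theta_mo = theta_mo, theta_direct = theta_direct,
    theta_total = theta_total,
    proportion_true = theta_em * theta_mo / theta_total
  )
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a colocalization region with a shared or distinct causal variant
#'
#' One 1 Mb window of `region_n_snps` SNPs.  LD decays as
#' `r_ij = ld_rho^|i-j|` within a block; with `shared = FALSE` the window
#' splits into two uncorrelated sub-blocks, trait 1's causal variant in the
#' first and trait 2's in the second.  True marginal effects are the
#' LD-weighted causal effect (`beta_i = r_ic * beta_c`) with the causal Z
#' fixed at `z_lead`; observed effects add noise that is multivariate normal
#' with the LD correlation — the correct sampling model for marginal
#' statistics computed on one cohort.
#'
#' @param shared TRUE for one shared causal variant, FALSE for two distinct
#'   ones.
#' @param config A [sim_config()]; `exposure_n`/`outcome_n` size the traits.
#' @param region_n_snps SNPs in the window, default 200.
#' @param ld_rho Adjacent-SNP correlation, default 0.9.
#' @param z_lead True Z at the causal variant, default 10.
#' @return List with `trait1`, `trait2` ([sumstats()]) and `truth`
#'   (causal indices/ids).
#' @export
simulate_coloc_region <- function(shared, config, region_n_snps = 200,
                                  ld_rho = 0.9, z_lead = 10) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- region_n_snps
  snp_id <- sprintf("rs%06d", seq_len(n))
  pos <- 1e6 + seq_len(n) * round(1e6 / n)
  maf <- rep(0.3, n)
  se1 <- rep(se_from_maf(config$exposure_n, maf[1]), n)
  se2 <- rep(se_from_maf(config$outcome_n, maf[1]), n)
  r <- ld_rho^abs(outer(seq_len(n), seq_len(n), "-"))
  if (shared) {
    c1 <- c2 <- n %/% 2
  } else {
    half <- n %/% 2
    r[seq_len(half), (half + 1):n] <- 0
    r[(half + 1):n, seq_len(half)] <- 0
    c1 <- half %/% 2
    c2 <- half + (n - half) %/% 2
  }
  true_z1 <- z_lead * r[, c1]
  true_z2 <- z_lead * r[, c2]
  noise1 <- MASS::mvrnorm(1, mu = rep(0, n), Sigma = r)
  noise2 <- MASS::mvrnorm(1, mu = rep(0, n), Sigma = r)
  z1 <- true_z1 + noise1
  z2 <- true_z2 + noise2
  al <- draw_alleles(n, 0)
  mk <- function(z, se, name) {
    beta <- z * se
    pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
    rec <- data.frame(snp_id = snp_id, chrom = "5", pos = pos,
                      effect_allele = al$ea, other_allele = al$oa,
                      eaf = maf, beta = beta, se = se, pval = pval,
                      n_cases = NA_integer_, n_controls = NA_integer_,
                      stringsAsFactors = FALSE)
    sumstats(rec, name, "case_control", "simulated")
  }
  list(trait1 = mk(z1, se1, "synthetic_trait1"),
       trait2 = mk(z2, se2, "synthetic_trait2"),
       truth = list(shared = shared, causal1 = snp_id[c1], causal2 = snp_id[c2],
                    z_lead = z_lead))
}
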