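# Monte-Carlo calibration harnesses: repeated synthetic-data runs of the
# full chain (simulate -> harmonize -> estimate) that score estimator
# recovery, interval coverage and test calibration against the generator's
# ground truth.  Used by the test suite, the acceptance script and the
# analysis drivers alike.

#' Replicate the MR chain on synthetic data and collect per-replicate results
#'
#' Each replicate simulates an exposure and its matched outcome at the given
#' conditions, harmonizes the planted instruments, and fits random-effects
#' IVW plus the sensitivity tests.  Replicate seeds are `seed0 + 2*i`, so the
#' exposure (seed) and outcome (seed + 1) streams never collide across
#' replicates.
#'
#' @param n_reps Number of replicates.
#' @param theta True causal effect.
#' @param n_instruments Planted instruments per replicate.
#' @param pleiotropy_mean,pleiotropy_sd Directional pleiotropy parameters.
#' @param seed0 Base seed.
#' @param ... Further arguments to [sim_config()].
#' @return data.frame with one row per replicate: `beta_hat`, `se_hat`,
#'   `pval`, `covered` (95% CI covers theta), `q_pval`, `egger_intercept`,
#'   `egger_intercept_pval`.
#' @export
mr_replicates <- function(n_reps, theta, n_instruments = 17,
                          pleiotropy_mean = 0, pleiotropy_sd = 0,
                          seed0 = 1, ...) {
  z95 <- stats::qnorm(0.975)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(n_snps_total = n_instruments,
                      n_instruments = n_instruments, theta = theta,
                      pleiotropy_mean = pleiotropy_mean,
                      pleiotropy_sd = pleiotropy_sd,
                      seed = seed0 + 2L * i, ...)
    sim <- simulate_exposure(cfg)
    outcome <- simulate_outcome(sim$truth, cfg)
    h <- harmonize(sim$stats, outcome)
    fit <- mr_ivw(h)
    sens <- mr_sensitivity(h, fit)
    out[[i]] <- data.frame(
      beta_hat = fit$beta_hat, se_hat = fit$se_hat, pval = fit$pval,
      covered = abs(fit$beta_hat - theta) <= z95 * fit$se_hat,
      q_pval = sens$q_pval,
      egger_intercept = sens$egger_intercept,
      egger_intercept_pval = sens$egger_intercept_pval
    )
  }
  do.call(rbind, out)
}

#' Replicate colocalization on simulated regions
#'
#' Each replicate simulates a region with a shared or distinct causal
#' variant, runs [extract_region()] + [coloc_posteriors()], and records the
#' posterior vector.
#'
#' @param n_reps Number of replicates.
#' @param shared TRUE for shared-causal regions, FALSE for distinct.
#' @param seed0 Base seed.
#' @param region_n_snps,ld_rho,z_lead Passed to [simulate_coloc_region()].
#' @param ... Further arguments to [sim_config()].
#' @return data.frame with columns `pp_h0` .. `pp_h4` per replicate.
#' @export
coloc_replicates <- function(n_reps, shared, seed0 = 1, region_n_snps = 200,
                             ld_rho = 0.9, z_lead = 10, ...) {
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(seed = seed0 + i, ...)
    reg <- simulate_coloc_region(shared, cfg, region_n_snps = region_n_snps,
                                 ld_rho = ld_rho, z_lead = z_lead)
    res <- colocalize(reg$trait1, reg$trait2)
    out[[i]] <- as.data.frame(as.list(res$pp))
  }
  do.call(rbind, out)
}
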