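# Independent enumeration oracle for the five-hypothesis posterior on a tiny
# region: loops explicitly over every causal configuration (which SNP is
# causal for which trait) instead of the implementation's log-sum-exp sums.
oracle_coloc <- function(beta1, se1, beta2, se2, sd1, sd2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf <- function(b, s, w) {
    v <- s^2
    sqrt(v / (v + w^2)) * exp(0.5 * (b / s)^2 * w^2 / (v + w^2))
  }
  n <- length(beta1)
  bf1 <- vapply(seq_len(n), function(i) abf(beta1[i], se1[i], sd1), 0)
  bf2 <- vapply(seq_len(n), function(i) abf(beta2[i], se2[i], sd2), 0)
  w0 <- 1
  w1 <- p1 * sum(bf1)
  w2 <- p2 * sum(bf2)
  w3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
  }
  w4 <- p12 * sum(bf1 * bf2)
  w <- c(w0, w1, w2, w3, w4)
  w / sum(w)
}

region_from <- function(beta1, se1, beta2, se2,
                        type1 = "case_control", type2 = "case_control") {
  n <- length(beta1)
  mk <- function(beta, se) data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)), chrom = "1", pos = seq_len(n) * 1e4,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)),
    n_cases = NA_integer_, n_controls = NA_integer_
  )
  list(trait1 = mk(beta1, se1), trait2 = mk(beta2, se2),
       trait_type1 = type1, trait_type2 = type2, lead_snp = "rs001")
}

test_that("log ABF matches the closed form and is monotone in |beta|", {
  v <- 0.02^2; w <- 0.15^2
  expect_equal(log_abf(0.1, 0.02, 0.15),
               0.5 * log(v / (v + w)) + 0.5 * (0.1 / 0.02)^2 * w / (v + w),
               tolerance = 1e-12)
  expect_lt(log_abf(0, 0.02, 0.15), 0)        # null: evidence against
  b <- seq(0, 0.5, by = 0.01)
  la <- log_abf(b, 0.02, 0.15)
  expect_true(all(diff(la) > 0))
  expect_error(log_abf(0.1, 0, 0.15), "se")
  expect_error(log_abf(0.1, 0.02, -1), "prior_sd")
})

test_that("no overflow up to |Z| = 100: the log-space contract holds", {
  la <- log_abf(100 * 0.02, 0.02, 0.15)
  expect_true(is.finite(la))
  reg <- region_from(c(100, 99, 0) * 0.02, rep(0.02, 3),
                     c(100, 98, 0) * 0.02, rep(0.02, 3))
  res <- coloc_posteriors(reg)
  expect_true(all(is.finite(res$pp)))
  expect_equal(sum(res$pp), 1, tolerance = 1e-10)
})

test_that("3-SNP posterior equals the exhaustive enumeration oracle", {
  cases <- list(
    list(b1 = c(0.10, 0.02, 0.00), b2 = c(0.09, 0.01, 0.00)),   # shared-looking
    list(b1 = c(0.10, 0.00, 0.00), b2 = c(0.00, 0.00, 0.11)),   # distinct
    list(b1 = c(0.01, 0.00, 0.01), b2 = c(0.00, 0.01, 0.00)),   # null-ish
    list(b1 = c(0.15, -0.12, 0.03), b2 = c(-0.02, 0.13, 0.05))  # mixed signs
  )
  for (cs in cases) {
    se1 <- c(0.02, 0.025, 0.03); se2 <- c(0.03, 0.02, 0.025)
    reg <- region_from(cs$b1, se1, cs$b2, se2)
    res <- coloc_posteriors(reg)
    want <- oracle_coloc(cs$b1, se1, cs$b2, se2, 0.15, 0.15)
    expect_equal(unname(res$pp), want, tolerance = 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-10)
  }
})

test_that("prior effect scale defaults follow the trait type", {
  reg <- region_from(c(0.1, 0.02), c(0.02, 0.02), c(0.1, 0.02), c(0.02, 0.02),
                     type1 = "case_control", type2 = "quantitative")
  res <- coloc_posteriors(reg)
  expect_equal(res$prior_sd1, 0.15)
  expect_equal(res$prior_sd2, 0.2)
  want <- oracle_coloc(c(0.1, 0.02), c(0.02, 0.02), c(0.1, 0.02), c(0.02, 0.02),
                       0.15, 0.2)
  expect_equal(unname(res$pp), want, tolerance = 1e-10)
})

test_that("swapping the traits swaps H1 and H2 and fixes H0, H3, H4", {
  b1 <- c(0.12, 0.01, -0.04); b2 <- c(0.00, 0.08, 0.02)
  se <- rep(0.02, 3)
  r12 <- coloc_posteriors(region_from(b1, se, b2, se), p1 = 2e-4, p2 = 1e-4)
  r21 <- coloc_posteriors(region_from(b2, se, b1, se), p1 = 1e-4, p2 = 2e-4)
  expect_equal(unname(r12$pp[c("pp_h0", "pp_h3", "pp_h4")]),
               unname(r21$pp[c("pp_h0", "pp_h3", "pp_h4")]), tolerance = 1e-12)
  expect_equal(unname(r12$pp["pp_h1"]), unname(r21$pp["pp_h2"]), tolerance = 1e-12)
  expect_equal(unname(r12$pp["pp_h2"]), unname(r21$pp["pp_h1"]), tolerance = 1e-12)
})

test_that("a single-SNP region forces H3 to zero, H4 dominating when both associate", {
  reg <- region_from(0.2, 0.02, 0.25, 0.02)
  res <- coloc_posteriors(reg)
  expect_equal(unname(res$pp["pp_h3"]), 0)
  expect_gt(res$pp["pp_h4"], res$pp["pp_h3"])
  expect_true(res$colocalized)
  expect_match(res$note, "single-SNP|H3")
})

test_that("the region extractor picks the min-P-product lead and an inclusive window", {
  rec <- make_records(3, pos_step = 1)
  rec$pos <- c(1e6, 1499999, 1500001)
  rec$pval <- c(1e-10, 1e-3, 1e-3)
  t1 <- sumstats(rec, "t1", "case_control")
  rec2 <- rec
  rec2$pval <- c(1e-8, 1e-3, 1e-3)
  t2 <- sumstats(rec2, "t2", "case_control")
  reg <- extract_region(t1, t2, half_window = 500000)
  expect_equal(reg$lead_snp, rec$snp_id[1])
  # 1,499,999 is inside the inclusive +-500 kb boundary; 1,500,001 is not.
  expect_setequal(reg$trait1$snp_id, rec$snp_id[1:2])
  expect_equal(reg$n_snps, 2)

  only_shared <- sumstats(rec[2, ], "t3", "case_control")
  reg1 <- extract_region(t1, only_shared)
  expect_equal(reg1$n_snps, 1)
  disjoint <- sumstats(transform(rec, snp_id = paste0(snp_id, "x")),
                       "t4", "case_control")
  expect_error(extract_region(t1, disjoint), "intersection")
})

test_that("a synthetic region with a planted center lead keeps its full size", {
  cfg <- sim_config(seed = 501)
  sim <- simulate_coloc_region(TRUE, cfg, region_n_snps = 200)
  reg <- extract_region(sim$trait1, sim$trait2)
  expect_equal(reg$n_snps, 200)   # 1 Mb span fits inside +-500 kb of center
  expect_equal(reg$lead_snp, sim$truth$causal1)
})

test_that("posterior normalization holds across random inputs", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    reg <- region_from(rnorm(n, 0, 0.05), runif(n, 0.01, 0.05),
                       rnorm(n, 0, 0.05), runif(n, 0.01, 0.05))
    res <- coloc_posteriors(reg)
    expect_equal(sum(res$pp), 1, tolerance = 1e-10)
    expect_true(all(res$pp >= 0))
    expect_equal(res$colocalized, unname(res$pp["pp_h4"] >= 0.8))
  }
})

test_that("coloc summary exports with per-SNP ABF table", {
  cfg <- sim_config(seed = 502)
  sim <- simulate_coloc_region(TRUE, cfg, region_n_snps = 50)
  reg <- extract_region(sim$trait1, sim$trait2)
  res <- coloc_posteriors(reg)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_coloc(res, p1, abf_path = p2, region = reg)
  summ <- read.delim(p1)
  expect_equal(summ$n_snps, 50)
  abf <- read.delim(p2)
  expect_equal(nrow(abf), 50)
})
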