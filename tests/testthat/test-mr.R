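test_that("Wald ratio arithmetic, degenerate input and sign symmetry", {
  p <- make_pairs(0.2, 0.05, 0.02)
  fit <- wald_ratio(p[1, ])
  expect_equal(fit$beta_hat, 0.25)
  expect_equal(fit$se_hat, 0.1)
  expect_equal(fit$or_hat, exp(0.25))
  expect_error(wald_ratio(make_pairs(0, 0.05, 0.02)[1, ]), "beta_x = 0")
  flipped <- wald_ratio(make_pairs(-0.2, -0.05, 0.02)[1, ])
  expect_equal(flipped$beta_hat, fit$beta_hat)
  expect_equal(flipped$se_hat, fit$se_hat)
})

test_that("IVW reduces to the Wald ratio for a single pair", {
  p <- make_pairs(0.15, 0.03, 0.02)
  expect_equal(mr_ivw(p)$beta_hat, wald_ratio(p[1, ])$beta_hat)
  expect_equal(mr_ivw(p)$method, "wald_ratio")
  expect_error(mr_ivw(p[0, ]), "insufficient")
})

test_that("with equal outcome SEs the IVW estimate is the beta_x^2-weighted mean of Wald ratios", {
  set.seed(31)
  bx <- runif(6, 0.05, 0.3)
  by <- runif(6, -0.1, 0.1)
  p <- make_pairs(bx, by, rep(0.04, 6))
  # Independent algebraic oracle.
  ratios <- by / bx
  oracle <- sum(bx^2 * ratios) / sum(bx^2)
  expect_equal(mr_ivw(p)$beta_hat, oracle, tolerance = 1e-12)
})

test_that("IVW agrees with a weighted origin regression fit by lm", {
  set.seed(32)
  p <- make_pairs(runif(10, 0.05, 0.3), rnorm(10, 0.02, 0.03),
                  runif(10, 0.02, 0.06))
  fit <- mr_ivw(p)
  ref <- summary(lm(beta_y ~ beta_x - 1, data = p, weights = 1 / p$se_y^2))
  expect_equal(fit$beta_hat, unname(ref$coefficients[1, 1]), tolerance = 1e-10)
  expect_equal(fit$se_hat,
               unname(ref$coefficients[1, 2]) / min(ref$sigma, 1),
               tolerance = 1e-10)
})

test_that("IVW is invariant under joint sign flips of any pair", {
  set.seed(33)
  p <- make_pairs(runif(8, 0.05, 0.3), rnorm(8, 0.02, 0.03),
                  runif(8, 0.02, 0.06))
  base <- mr_ivw(p)
  for (i in c(1, 4, 8)) {
    q <- p
    q$beta_x[i] <- -q$beta_x[i]
    q$beta_y[i] <- -q$beta_y[i]
    flipped <- mr_ivw(q)
    expect_equal(flipped$beta_hat, base$beta_hat)
    expect_equal(flipped$se_hat, base$se_hat)
  }
})

test_that("random-effects SE never shrinks below the fixed-effects SE", {
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    p <- make_pairs(runif(n, 0.05, 0.3), rnorm(n, 0, 0.05),
                    runif(n, 0.02, 0.08))
    fit <- mr_ivw(p)
    se_fixed <- 1 / sqrt(sum(p$beta_x^2 / p$se_y^2))
    expect_gte(fit$se_hat, se_fixed - 1e-12)
    q <- cochran_q(p, fit$beta_hat)
    if (q$q_stat <= n - 1) expect_equal(fit$se_hat, se_fixed)
  }
})

test_that("Cochran's Q matches an independently coded sum and degenerates to 0", {
  # Arithmetic oracle on three hand-built pairs.
  p <- make_pairs(c(0.1, 0.2, 0.3), c(0.03, 0.02, 0.09), c(0.02, 0.03, 0.04))
  fit <- mr_ivw(p)
  q <- cochran_q(p, fit$beta_hat)
  r <- p$beta_y / p$beta_x
  w <- (p$beta_x / p$se_y)^2
  expect_equal(q$q_stat, sum(w * (r - fit$beta_hat)^2), tolerance = 1e-12)
  expect_equal(q$q_df, 2L)
  expect_equal(q$q_pval, pchisq(q$q_stat, 2, lower.tail = FALSE))

  # All ratios identical -> exact homogeneity.
  hom <- make_pairs(c(0.1, 0.2, 0.4), 0.5 * c(0.1, 0.2, 0.4), c(0.02, 0.02, 0.02))
  qh <- cochran_q(hom, 0.5)
  expect_equal(qh$q_stat, 0)
  expect_equal(qh$q_pval, 1)
  expect_error(cochran_q(hom[1, ]), "at least 2")
})

test_that("Egger regression matches weighted lm and uses t-based P values", {
  set.seed(35)
  p <- make_pairs(runif(9, 0.05, 0.3), rnorm(9, 0.05, 0.04),
                  runif(9, 0.02, 0.06))
  eg <- mr_egger(p)
  ref <- summary(lm(beta_y ~ beta_x, data = p, weights = 1 / p$se_y^2))
  expect_equal(eg$egger_intercept, unname(ref$coefficients[1, 1]),
               tolerance = 1e-10)
  expect_equal(eg$egger_intercept_se,
               unname(ref$coefficients[1, 2]) / min(ref$sigma, 1),
               tolerance = 1e-10)
  expect_equal(eg$egger_slope$beta_hat, unname(ref$coefficients[2, 1]),
               tolerance = 1e-10)
  tval <- eg$egger_intercept / eg$egger_intercept_se
  expect_equal(eg$egger_intercept_pval, 2 * pt(-abs(tval), df = 7))
  expect_error(mr_egger(p[1:2, ]), "at least 3")
})

test_that("Egger orientation leaves stored pairs untouched and handles collinearity", {
  set.seed(36)
  p <- make_pairs(c(-0.2, 0.1, 0.3, -0.15), rnorm(4, 0, 0.05),
                  runif(4, 0.02, 0.06))
  before <- p
  eg1 <- mr_egger(p)
  expect_identical(p, before)
  # Orientation is equivalent to pre-negating the negative-beta_x pairs.
  q <- p
  neg <- q$beta_x < 0
  q$beta_x[neg] <- -q$beta_x[neg]
  q$beta_y[neg] <- -q$beta_y[neg]
  eg2 <- mr_egger(q)
  expect_equal(eg1$egger_intercept, eg2$egger_intercept)
  expect_equal(eg1$egger_slope$beta_hat, eg2$egger_slope$beta_hat)

  collinear <- make_pairs(rep(0.2, 4), rep(0.1, 4), rep(0.03, 4))
  expect_error(mr_egger(collinear), "collinear|degenerate")
})

test_that("strength tiers honor the inclusive boundaries", {
  expect_equal(classify_strength(0.021), "moderate")
  expect_equal(classify_strength(0.005), "strong")
  expect_equal(classify_strength(0.06), "weak")
  expect_equal(classify_strength(0.01), "strong")
  expect_equal(classify_strength(0.05), "moderate")
  expect_equal(classify_strength(0.1), "weak")
  expect_equal(classify_strength(0.5), "none")
  expect_error(classify_strength(1.5), "\\[0, 1\\]")
  expect_equal(strength_stars(c("strong", "moderate", "weak", "none")),
               c("***", "**", "*", ""))
})

test_that("mr_result enforces its invariants", {
  fit <- mr_result("ivw_random_effects", 0.2, 0.1, 0.045, 5)
  expect_equal(fit$or_hat, exp(0.2))
  expect_lt(fit$ci_low, fit$or_hat)
  expect_gt(fit$ci_high, fit$or_hat)
  expect_equal(fit$strength, "moderate")
  expect_error(mr_result("wald_ratio", 0.2, 0.1, 0.5, 0), "n_snps")
})
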