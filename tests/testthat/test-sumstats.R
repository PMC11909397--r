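test_that("beta/SE reconstruction matches the closed form and round-trips", {
  # Oracle: ln(1.5) and the 97.5% normal quantile computed independently.
  r <- reconstruct_beta_se(1.5, 0.05)
  expect_equal(r$beta, 0.405465, tolerance = 1e-5)
  expect_equal(r$se, 0.405465108 / 1.959964, tolerance = 1e-5)

  expect_error(reconstruct_beta_se(1.0, 0.05), "beta = 0")
  expect_error(reconstruct_beta_se(-2, 0.05), "> 0")
  expect_error(reconstruct_beta_se(1.5, 1), "p_value")
  expect_error(reconstruct_beta_se(1.5, -0.1), "p_value")

  # Inverse-function identity: beta/se -> two-sided P -> reconstruct.
  set.seed(11)
  for (i in 1:50) {
    beta <- rnorm(1, 0, 0.5)
    if (abs(beta) < 1e-3) next
    se <- runif(1, 0.01, 0.3)
    p <- 2 * pnorm(-abs(beta / se))
    if (p < 1e-300) next   # underflowed beyond the documented floor
    r <- reconstruct_beta_se(exp(beta), p)
    expect_equal(r$beta, beta, tolerance = 1e-6)
    expect_equal(r$se, se, tolerance = 1e-6)
  }
})

test_that("underflowed P values are floored before quantile evaluation", {
  r <- reconstruct_beta_se(1.5, 1e-320)
  expect_true(is.finite(r$se) && r$se > 0)
})

test_that("read_sumstats validates rows, tallies drops and reconstructs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(SNP = c("rs1", "rs2", "rs3"), A1 = c("A", "C", "G"),
                    A2 = c("G", "T", "A"), BETA = c(0.1, -0.2, 0.05),
                    SE = c(0.02, 0.05, 0.01))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- c(snp_id = "SNP", effect_allele = "A1", other_allele = "A2",
          beta = "BETA", se = "SE")
  ss <- read_sumstats(path, cm, "t", "case_control")
  expect_s3_class(ss, "sumstats")
  expect_equal(n_snps(ss), 3)
  expect_equal(sum(attr(ss, "drop_tally")), 0)
  # P filled from the Wald Z when absent.
  expect_equal(ss$records$pval, 2 * pnorm(-abs(tab$BETA / tab$SE)))

  # se = 0 row dropped and tallied.
  tab$SE[2] <- 0
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss2 <- read_sumstats(path, cm, "t", "case_control")
  expect_equal(n_snps(ss2), 2)
  expect_equal(unname(attr(ss2, "drop_tally")["invalid_se"]), 1L)

  # OR + P rows reconstructed through the same formula as reconstruct_beta_se.
  tab2 <- data.frame(SNP = c("rs1", "rs2"), A1 = c("A", "C"), A2 = c("G", "T"),
                     OR = c(1.5, 0.8), P = c(0.05, 1e-4))
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss3 <- read_sumstats(path, c(snp_id = "SNP", effect_allele = "A1",
                               other_allele = "A2", or = "OR", pval = "P"),
                       "t", "case_control")
  r1 <- reconstruct_beta_se(1.5, 0.05)
  expect_equal(ss3$records$beta[1], r1$beta)
  expect_equal(ss3$records$se[1], r1$se)
  expect_equal(ss3$records$beta[2], log(0.8))

  # Missing mandatory mapping / absent column / empty result are errors.
  expect_error(read_sumstats(path, c(snp_id = "SNP"), "t"), "column_map")
  expect_error(read_sumstats(path, c(snp_id = "NOPE", effect_allele = "A1",
                                     other_allele = "A2", or = "OR", pval = "P"),
                             "t"), "absent")
  tab2$A1 <- c("I", "D")   # indel alleles rejected -> zero valid rows
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path, c(snp_id = "SNP", effect_allele = "A1",
                                     other_allele = "A2", or = "OR", pval = "P"),
                             "t"), "no valid")
})

test_that("alleles are uppercased on read and indels rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(SNP = c("rs1", "rs2"), A1 = c("a", "AT"), A2 = c("g", "A"),
                    BETA = c(0.1, 0.1), SE = c(0.02, 0.02))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_sumstats(path, c(snp_id = "SNP", effect_allele = "A1",
                              other_allele = "A2", beta = "BETA", se = "SE"), "t")
  expect_equal(ss$records$effect_allele, "A")
  expect_equal(unname(attr(ss, "drop_tally")["invalid_allele"]), 1L)
})

test_that("write/read round-trip is the identity on valid tables", {
  ss <- make_sumstats(10, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path, canonical_column_map(), ss$trait_name,
                        ss$trait_type)
  expect_equal(back$records, ss$records)

  empty <- ss
  empty$records <- ss$records[0, ]
  expect_error(write_sumstats(empty, path), "empty")
})

test_that("Windows line endings are read identically", {
  ss <- make_sumstats(5, seed = 4)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, p1)
  writeLines(sub("\n$", "", gsub("\n", "\r\n", paste0(
    paste(readLines(p1), collapse = "\n"), "\n"))), p2, sep = "")
  back <- read_sumstats(p2, canonical_column_map(), ss$trait_name, ss$trait_type)
  expect_equal(back$records, ss$records)
})

test_that("gzip-compressed input is accepted", {
  ss <- make_sumstats(6, seed = 5)
  plain <- withr::local_tempfile(fileext = ".tsv")
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_sumstats(ss, plain)
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  back <- read_sumstats(gz, canonical_column_map(), ss$trait_name, ss$trait_type)
  expect_equal(back$records, ss$records)
})

test_that("duplicate snp_id rows are dropped deterministically and tallied", {
  rec <- make_records(4)
  rec$snp_id[2] <- rec$snp_id[1]
  out <- strokemr:::validate_snp_rows(rec)
  expect_equal(nrow(out$records), 3)
  expect_equal(unname(out$tally["duplicate_snp_id"]), 1L)
  expect_error(sumstats(rec, "t", "case_control"), "unique")
})
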