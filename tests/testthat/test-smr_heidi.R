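test_that("smr_test matches the closed-form statistic and its limits", {
  # z_gwas = 4, z_eqtl = 6: T = 576/52, 1-df chi-square tail
  r <- smr_test(b_gwas = 4, se_gwas = 1, b_eqtl = 6, se_eqtl = 1)
  expect_equal(r$t_smr, 576 / 52, tolerance = 1e-12)
  expect_equal(r$p_smr, 8.74087211298e-4, tolerance = 1e-9)
  expect_equal(r$b_xy, 4 / 6)
  # symmetric in the two z-scores at the statistic level
  r2 <- smr_test(6, 1, 4, 1)
  expect_equal(r2$t_smr, r$t_smr)
  # equal z -> T = z^2/2; huge eQTL z -> T -> z_gwas^2
  expect_equal(smr_test(3, 1, 3, 1)$t_smr, 4.5)
  expect_equal(smr_test(4, 1, 1e6, 1)$t_smr, 16, tolerance = 1e-9)
  expect_error(smr_test(1, 1, 0, 1), "undefined")
})

test_that("T_SMR never exceeds the weaker squared z-score", {
  set.seed(41)
  zg <- rnorm(200, 0, 3); ze <- rnorm(200, 0, 3)
  ze[ze == 0] <- 1
  t <- smr_test(zg, 1, ze, 1)$t_smr
  expect_true(all(t <= pmin(zg^2, ze^2) + 1e-12))
})

test_that("HEIDI is ~1 when all instruments agree in perfect LD", {
  p <- 6
  ids <- paste0("v", seq_len(p))
  R <- matrix(1, p, p)
  ld <- ld_from_matrix(R, ids)
  gwas <- data.table::data.table(SNP = ids, CHR = "1", BP = seq_len(p),
                                 A1 = "A", A2 = "G", BETA = 0.02,
                                 SE = 0.002, Z = 10,
                                 P = 2 * pnorm(-10), N = 1e5)
  eqtl <- data.table::data.table(gene_id = "g", tissue = "t",
                                 variant_id = ids, b_eqtl = 0.2,
                                 se_eqtl = 0.02)
  h <- heidi_test("g", gwas, eqtl, ld, r2_prune = 1)
  expect_equal(h$p_heidi, 1)
  expect_equal(h$n_heidi_snps, p - 1L)
})

test_that("HEIDI returns untested with fewer than three eligible instruments", {
  med <- make_mediation_genes(n_genes = 2, class_mix = c(mediated = 1,
                                                         linkage = 0,
                                                         null = 0),
                              p_cis = 4, seed = 42)
  g <- med$truth$gene_id[1]
  h <- heidi_test(g, med$gwas, med$eqtl, med$ld, max_snps = 2)
  expect_true(is.na(h$p_heidi))
})

test_that("HEIDI separates linkage from mediation at realistic instrument strength", {
  med <- make_mediation_genes(n_genes = 500,
                              class_mix = c(mediated = 1, linkage = 0,
                                            null = 0), seed = 43)
  res <- smr_scan(med$gwas, med$eqtl, med$ld)
  tested <- res[!is.na(p_heidi)]
  expect_gt(nrow(tested), 400)
  # false-exclusion envelope under single-causal mediation: close to
  # the nominal 0.01, bounded by the Wald-ratio tail inflation that
  # finite eQTL panels impose
  rate <- mean(tested$p_heidi < 0.01)
  expect_gte(rate, 0.003)
  expect_lte(rate, 0.06)

  lnk <- make_mediation_genes(n_genes = 500,
                              class_mix = c(mediated = 0, linkage = 1,
                                            null = 0), seed = 44)
  resl <- smr_scan(lnk$gwas, lnk$eqtl, lnk$ld)
  testedl <- resl[!is.na(p_heidi)]
  power <- mean(testedl$p_heidi < 0.01)
  # power targets one half at this linkage strength; allow the
  # binomial Monte-Carlo error of a 500-gene experiment (3 SE)
  expect_gte(power, 0.5 - 3 * sqrt(0.25 / 500))
  # linkage genes reject far more often than mediated genes
  expect_gt(power, 5 * rate)
})

test_that("SMR recovers the planted expression-to-trait slope", {
  med <- make_mediation_genes(n_genes = 200,
                              class_mix = c(mediated = 1, linkage = 0,
                                            null = 0), seed = 45)
  res <- smr_scan(med$gwas, med$eqtl, med$ld)
  truth <- med$truth[match(res$gene_id, gene_id)]
  est <- res$b_xy * sign(truth$b_xy_true)
  expect_lt(abs(median(est) - 0.1) / 0.1, 0.10)
})

test_that("heidi_filter excludes p < 0.01 and passes untested with caveat", {
  res <- data.table::data.table(
    gene_id = paste0("g", 1:10), tissue = "t",
    p_heidi = c(0.005, 0.5, 0.002, NA, 0.2, 0.009, 0.8, 0.3, 0.05, 0.011))
  hf <- suppressMessages(heidi_filter(res))
  expect_equal(length(hf$excluded), 3L)
  expect_equal(length(hf$pass), 7L)
  expect_equal(hf$status[gene_id == "g4"]$heidi_status, "untested")
  expect_equal(hf$status[gene_id == "g10"]$heidi_status, "pass")
})
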