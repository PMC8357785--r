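mk_assocs <- function(z, bp = seq_along(z), chr = "1") {
  data.table::data.table(SNP = paste0("v", seq_along(z)), CHR = chr,
                         BP = as.integer(bp), A1 = "A", A2 = "G",
                         BETA = z, SE = 1, Z = z,
                         P = 2 * pnorm(-abs(z)), N = 1000L)
}

test_that("gene test reduces to the variant test for k = 1 and perfect LD", {
  g <- list(gene_id = "g", chrom = "1", start = 1, end = 1)
  a <- mk_assocs(2.5)
  ld <- ld_from_matrix(diag(1), "v1")
  expect_equal(gene_test(g, a, ld)$p, 2 * pnorm(-2.5), tolerance = 1e-12)
  # ten copies of one variant: effective df collapses to 1
  z <- rep(2.5, 10)
  ldp <- ld_from_matrix(matrix(1, 10, 10), paste0("v", 1:10))
  gp <- gene_test(list(gene_id = "g", chrom = "1", start = 1, end = 10),
                  mk_assocs(z), ldp)
  expect_equal(gp$p, 2 * pnorm(-2.5), tolerance = 1e-10)
  expect_message(
    gene_test(list(gene_id = "none", chrom = "9", start = 1, end = 2),
              a, ld), "skipped")
})

test_that("gene test is calibrated under the null with LD", {
  set.seed(51)
  k <- 10
  R <- 0.5^abs(outer(1:k, 1:k, "-"))
  L <- t(chol(R))
  ld <- ld_from_matrix(R, paste0("v", 1:k))
  g <- list(gene_id = "g", chrom = "1", start = 1, end = k)
  p <- replicate(2000, {
    z <- as.vector(L %*% rnorm(k))
    gene_test(g, mk_assocs(z), ld)$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("gene test agrees with a brute-force Monte-Carlo null in the tail", {
  set.seed(52)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    R <- sample(c(0.3, 0.6, 0.8), 1)^abs(outer(1:k, 1:k, "-"))
    L <- t(chol(R))
    # modest planted signal keeps p in the decision-relevant tail
    z <- as.vector(L %*% rnorm(k)) + 1.5
    ld <- ld_from_matrix(R, paste0("v", 1:k))
    g <- list(gene_id = "g", chrom = "1", start = 1, end = k)
    p_brown <- gene_test(g, mk_assocs(z), ld)$p
    stat <- mean(z^2)
    null <- colMeans(matrix(as.vector(L %*% matrix(rnorm(k * 20000), k))^2,
                            k))
    p_mc <- mean(null >= stat)
    expect_lt(abs(p_brown - p_mc), 0.02)
  }
})

test_that("load_stream applies the stream's stated correction", {
  tab <- data.frame(gene = paste0("g", 1:10),
                    p = c(0.0004, 0.004, 0.011, 0.03, 0.04,
                          0.2, 0.4, 0.6, 0.8, 0.9),
                    direction = c(1, -1, 1, 1, -1, 1, -1, 1, 1, -1),
                    tissue = "cortex")
  bon <- load_stream(tab, "twas_brain")      # Bonferroni: p < 0.005
  expect_equal(bon$genes, c("g1", "g2"))
  fdr <- load_stream(tab, "eqtl_map")        # BH is never less powerful
  expect_true(all(bon$genes %in% fdr$genes))
  expect_equal(bon$directions$sign[1:2], c(1L, -1L))
  # hand-run BH fixture: 3 of 8 significant at FDR 0.05
  tab8 <- data.frame(gene = paste0("h", 1:8),
                     p = c(0.001, 0.004, 0.012, 0.20, 0.35, 0.5, 0.7, 0.9))
  expect_equal(load_stream(tab8, "eqtl_map")$genes, c("h1", "h2", "h3"))
  expect_error(load_stream(tab, "not_a_stream"), "unknown stream")
  # pathway stream flags members of sets passing the set-level test
  pw <- data.frame(set = rep(c("s1", "s2"), each = 3),
                   gene = paste0("g", 1:6),
                   set_p = rep(c(1e-6, 0.2), each = 3))
  expect_equal(load_stream(pw, "pathway_member")$genes,
               c("g1", "g2", "g3"))
})

test_that("build_evidence groups streams into approaches for the method count", {
  streams <- list(twas_brain = c("gA", "gB"),
                  smr = "gA",
                  eqtl_map = c("gB", "gC"),
                  sqtl = "gC", rqtl = "gC")
  ev <- build_evidence(streams)
  expect_equal(ev[gene_id == "gA"]$method_count, 2L)  # TWAS + SMR
  expect_equal(ev[gene_id == "gB"]$method_count, 2L)  # TWAS + QTL-map
  expect_equal(ev[gene_id == "gC"]$method_count, 1L)  # 3 streams, 1 approach
  expect_equal(nrow(ev), 3L)
  expect_true(all(ev$heidi_status == "untested"))
  # union bookkeeping and monotonicity: adding a flag never lowers counts
  streams2 <- streams; streams2$gene_test <- "gC"
  ev2 <- build_evidence(streams2)
  expect_true(all(ev2$method_count >=
                    ev$method_count[match(ev2$gene_id, ev$gene_id)]))
  # directions alone are not evidence but keep the gene in the table
  dirs <- data.table::data.table(gene_id = "gZ", source = "eqtl",
                                 tissue = "t", sign = 1L)
  ev3 <- build_evidence(streams, directions = dirs)
  expect_equal(ev3[gene_id == "gZ"]$method_count, 0L)
  expect_equal(build_evidence(list())[, .N], 0L)
})
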