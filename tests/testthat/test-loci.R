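test_that("clump groups significant variants around smallest-p leads", {
  ss <- function(snp, bp, p) data.table::data.table(
    SNP = snp, CHR = "1", BP = bp, A1 = "A", A2 = "G",
    BETA = 1, SE = 1, Z = qnorm(p / 2, lower.tail = FALSE), P = p,
    N = 1000L)
  # one significant variant -> one single-member locus at its position
  one <- clump(ss("rs1", 500L, 1e-9), toy_ld())
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(500L, 500L))
  # three variants in tight LD (r^2 ~ 0.90) -> one locus led by 1e-9
  a <- ss(c("rs1", "rs2", "rs3"), c(1000L, 2000L, 3000L),
          c(1e-9, 1e-8, 2e-8))
  cl <- clump(a, toy_ld())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$lead_snp, "rs1")
  expect_equal(cl$n_members, 3L)
  expect_equal(c(cl$start, cl$end), c(1000L, 3000L))
  # r^2 = 0.1 pair 10 kb apart -> two loci before merging
  ld_lo <- ld_ref(data.frame(variant_a = "rs1", variant_b = "rs2",
                             r = sqrt(0.1)))
  two <- clump(ss(c("rs1", "rs2"), c(1000L, 11000L), c(1e-9, 1e-8)),
               ld_lo)
  expect_equal(nrow(two), 2L)
  # every significant variant lands in exactly one locus
  expect_equal(sort(unlist(cl$members)), c("rs1", "rs2", "rs3"))
  # variants absent from the reference are r2 = 0, with a warning
  expect_warning(
    clump(ss(c("rs1", "zz9"), c(1000L, 2000L), c(1e-9, 1e-8)), toy_ld()),
    "absent from LD reference")
})

test_that("merge_loci merges within 250 kb, transitively, conserving members", {
  a <- mk_locus(1, 1000L, 2000L, "a", 1e-9)
  b <- mk_locus(1, 200000L, 210000L, "b", 1e-10)
  c_ <- mk_locus(1, 400000L, 410000L, "c", 1e-8)
  near <- merge_loci(rbind(a, b))        # gap 198,000 <= 250 kb
  expect_equal(nrow(near), 1L)
  expect_equal(c(near$start, near$end), c(1000L, 210000L))
  expect_equal(near$lead_snp, "b")       # smallest-p constituent leads
  far <- merge_loci(rbind(a, c_))        # gap 398,000 > 250 kb
  expect_equal(nrow(far), 2L)
  # chain A-B 200 kb, B-C 200 kb, A-C 420 kb: transitive single locus
  chain <- rbind(mk_locus(1, 1L, 1000L, "a"),
                 mk_locus(1, 201000L, 202000L, "b"),
                 mk_locus(1, 402000L, 421000L, "c"))
  merged <- merge_loci(chain)
  expect_equal(nrow(merged), 1L)
  expect_equal(sum(merged$n_members), sum(chain$n_members))
  # idempotent and order-invariant
  expect_equal(merge_loci(merged), merged)
  perm <- merge_loci(chain[c(3, 1, 2)])
  expect_equal(perm[, c("CHR", "start", "end")],
               merged[, c("CHR", "start", "end")])
  expect_equal(merge_loci(mk_locus(1, 1, 2)[0]),
               mk_locus(1, 1, 2)[0])
})

test_that("merge_loci matches the brute-force interval-graph oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- 50
    starts <- sample.int(5e6, n)
    loci <- data.table::rbindlist(lapply(seq_len(n), function(j)
      mk_locus(sample(1:3, 1), starts[j],
               starts[j] + sample.int(50000, 1), paste0("v", j))))
    got <- merge_loci(loci)
    exp <- oracle_merge(loci)
    expect_equal(as.data.frame(got[order(CHR, start),
                                   c("CHR", "start", "end")]),
                 exp, ignore_attr = TRUE)
    # post-condition: separations all exceed the merge gap
    bychr <- split(got, got$CHR)
    for (g in bychr) if (nrow(g) > 1) {
      g <- g[order(g$start)]
      expect_true(all(g$start[-1] - g$end[-nrow(g)] > 250000))
    }
  }
})

test_that("classify_loci labels shared/gained/lost with 250 kb padding", {
  meta <- rbind(mk_locus(1, 1000L, 2000L, "m1"),
                mk_locus(2, 5000000L, 5100000L, "m2"),
                mk_locus(3, 900000L, 950000L, "m3"))
  s1 <- rbind(mk_locus(1, 1500L, 2500L, "a1"),
              mk_locus(1, 150000L, 160000L, "a2"))  # within padding of m1
  s2 <- mk_locus(2, 5050000L, 5060000L, "b1")
  cl <- classify_loci(meta, s1, s2)
  expect_equal(sum(cl$category == "shared"), 2L)
  expect_equal(sum(cl$category == "gained"), 1L)
  expect_equal(cl[cl$lead_snp == "m3"]$category, "gained")
  expect_equal(sum(grepl("lost", cl$category)), 0L)
  # an input locus overlapping no combined locus is lost
  s1_far <- rbind(s1, mk_locus(7, 1L, 1000L, "a3"))
  cl2 <- classify_loci(meta, s1_far, s2)
  expect_equal(cl2[cl2$lead_snp == "a3"]$category, "lost_from_s1")
})

test_that("loci round-trip through the BED-like on-disk format", {
  loci <- rbind(mk_locus(1, 1000L, 2000L, "a", 1e-9,
                         members = list(c("a", "x"))),
                mk_locus(2, 5L, 10L, "b", 1e-12))
  path <- withr::local_tempfile(fileext = ".bed")
  write_loci(loci, path)
  disk <- read.delim(path)
  expect_equal(disk$start, loci$start - 1L)  # 0-based half-open on disk
  back <- read_loci(path)
  expect_equal(back$start, loci$start)
  expect_equal(back$members, loci$members)
})
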