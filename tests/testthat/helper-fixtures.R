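# toy summary-statistics tables used across tests

toy_sumstats <- function() {
  data.frame(
    SNP = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    CHR = "1", BP = 1:6 * 1000L,
    A1 = c("A", "C", "A", "G", "C", "A"),
    A2 = c("G", "T", "T", "C", "A", "C"),
    BETA = c(0.10, -0.05, 0.02, 0.08, -0.12, 0.03),
    SE = 0.05, N = 1000L)
}

# study 2: rs1 allele-swapped, rs3/rs4 strand-ambiguous, rs6 absent
toy_sumstats_b <- function() {
  b <- toy_sumstats()[1:5, ]
  b$A1[1] <- "G"; b$A2[1] <- "A"
  b$BETA <- c(0.20, -0.04, 0.01, 0.07, -0.10)
  b
}

# small dense-LD toy reference
toy_ld <- function() {
  ld_ref(data.frame(
    variant_a = c("rs1", "rs1", "rs2"),
    variant_b = c("rs2", "rs3", "rs3"),
    r = c(0.95, 0.95, 0.95)))
}

# a loci table from scratch
mk_locus <- function(chr, start, end, lead = paste0("v", start),
                     p = 1e-9, members = list(lead)) {
  data.table::data.table(CHR = as.character(chr), start = start,
                         end = end, lead_snp = lead, lead_p = p,
                         n_members = lengths(members),
                         members = members)
}

# brute-force interval merging oracle: connected components of the
# "gap <= threshold" interval graph, via exhaustive pairwise adjacency
oracle_merge <- function(loci, gap = 250000) {
  loci <- data.table::as.data.table(loci)
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- loci$CHR[i] == loci$CHR[j] &&
      loci$start[j] - loci$end[i] <= gap &&
      loci$start[i] - loci$end[j] <= gap
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  out <- lapply(split(seq_len(n), comp), function(ix)
    c(chr = loci$CHR[ix][1], start = min(loci$start[ix]),
      end = max(loci$end[ix])))
  out <- do.call(rbind, out)
  out <- data.frame(CHR = out[, "chr"],
                    start = as.integer(out[, "start"]),
                    end = as.integer(out[, "end"]))
  out[order(out$CHR, out$start), , drop = FALSE]
}
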