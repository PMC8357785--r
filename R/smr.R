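#' Summary-data Mendelian randomization test at a single instrument
#'
#' Uses a cis-eQTL as an instrument to test whether gene expression
#' mediates the GWAS signal.  The expression-to-trait effect is the
#' Wald ratio `b_xy = b_gwas / b_eqtl`; its test statistic combines
#' the two z-scores as
#' \deqn{T_{SMR} = z_g^2 z_e^2 / (z_g^2 + z_e^2),}
#' referred to a 1-df chi-square.  `T_SMR` never exceeds the smaller
#' of the two squared z-scores, so mediation evidence is capped by the
#' weaker of the GWAS and eQTL associations.
#'
#' @param b_gwas,se_gwas variant effect and standard error on the
#'   trait (vectors allowed).
#' @param b_eqtl,se_eqtl variant effect and standard error on
#'   expression.
#' @return list with `b_xy`, `t_smr`, `p_smr` (vectors matching the
#'   input length).
#' @export
smr_test <- function(b_gwas, se_gwas, b_eqtl, se_eqtl) {
  if (any(b_eqtl == 0)) stop("smr_test: b_eqtl = 0 gives an undefined ratio")
  zg2 <- (b_gwas / se_gwas)^2
  ze2 <- (b_eqtl / se_eqtl)^2
  t_smr <- zg2 * ze2 / (zg2 + ze2)
  list(b_xy = b_gwas / b_eqtl, t_smr = t_smr,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

# Delta-method covariance of Wald ratios b_xy at two variants whose
# GWAS errors (and, independently, eQTL errors) are correlated r
# through LD.  i and j index aligned vectors.
.bxy_cov <- function(bg_i, se_g_i, be_i, se_e_i,
                     bg_j, se_g_j, be_j, se_e_j, r) {
  r * se_g_i * se_g_j / (be_i * be_j) +
    r * bg_i * bg_j * se_e_i * se_e_j / (be_i^2 * be_j^2)
}

#' HEIDI heterogeneity test at one gene
#'
#' Distinguishes a single causal variant shared by expression and
#' trait (pleiotropy/mediation) from distinct causal variants in LD
#' (linkage).  For every selected cis variant *i* beyond the top
#' instrument, the deviation `d_i = b_xy(i) - b_xy(top)` is
#' standardized by its delta-method variance (GWAS and eQTL standard
#' errors plus the LD r with the top variant); the joint null
#' `all d_i = 0` is tested by summing the squared standardized
#' deviations and referring the sum of dependent 1-df chi-squares to a
#' Satterthwaite-scaled chi-square.
#'
#' Instrument selection follows the published SMR tool conventions:
#' the top cis-eQTL must pass `p_instrument`; test variants must pass
#' `p_snp` on the eQTL side, have `r2` with the top in
#' `[r2_min, r2_prune]`, survive pairwise pruning at `r2_prune`, and
#' are capped at `max_snps` (most significant eQTLs kept).
#'
#' @param gene gene id.
#' @param gwas canonical summary-statistics table (alleles already
#'   harmonized to the eQTL table).
#' @param eqtl long eQTL table with columns `gene_id, tissue,
#'   variant_id, b_eqtl, se_eqtl` (a single tissue at a time).
#' @param ld an `ld_ref` with signed r between the cis variants.
#' @param p_instrument instrument threshold for the top eQTL
#'   (default 5e-8).
#' @param p_snp eQTL threshold for HEIDI test variants
#'   (default 1.57e-3, i.e. chi-square > 10).
#' @param r2_min,r2_prune LD window with the top variant and pairwise
#'   pruning threshold (defaults 0.05 and 0.9).
#' @param max_snps maximum number of test variants (default 20).
#' @param min_snps minimum test variants required; below this the
#'   gene's HEIDI status is "untested" (default 3).
#' @return list with `p_heidi` (NA when untested) and `n_heidi_snps`.
#' @export
heidi_test <- function(gene, gwas, eqtl, ld, p_instrument = 5e-8,
                       p_snp = 1.57e-3, r2_min = 0.05, r2_prune = 0.9,
                       max_snps = 20, min_snps = 3) {
  eq <- data.table::as.data.table(eqtl)[gene_id == gene]
  gw <- data.table::as.data.table(gwas)
  eq <- eq[variant_id %in% gw$SNP]
  if (nrow(eq) == 0L) return(list(p_heidi = NA_real_, n_heidi_snps = 0L))
  gi <- gw[match(eq$variant_id, SNP)]
  ze <- eq$b_eqtl / eq$se_eqtl
  pe <- 2 * stats::pnorm(-abs(ze))
  top <- which.min(pe)
  if (pe[top] >= p_instrument)
    return(list(p_heidi = NA_real_, n_heidi_snps = 0L))

  cand <- which(pe < p_snp)
  cand <- setdiff(cand, top)
  r_top <- ld_r(ld, eq$variant_id[cand], eq$variant_id[top])
  cand <- cand[r_top^2 >= r2_min & r_top^2 <= r2_prune]
  # pairwise pruning at r2_prune, keeping the more significant eQTL
  cand <- cand[order(pe[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) &&
        any(ld_r(ld, eq$variant_id[i], eq$variant_id[kept])^2 > r2_prune))
      next
    kept <- c(kept, i)
    if (length(kept) >= max_snps) break
  }
  if (length(kept) < min_snps)
    return(list(p_heidi = NA_real_, n_heidi_snps = length(kept)))

  idx <- c(top, kept)
  bg <- gi$BETA[idx]; sg <- gi$SE[idx]
  be <- eq$b_eqtl[idx]; se <- eq$se_eqtl[idx]
  bxy <- bg / be
  R <- ld_matrix(ld, eq$variant_id[idx])
  k <- length(kept)
  covb <- matrix(0, k + 1, k + 1)
  for (i in seq_len(k + 1)) for (j in seq_len(k + 1))
    covb[i, j] <- .bxy_cov(bg[i], sg[i], be[i], se[i],
                           bg[j], sg[j], be[j], se[j], R[i, j])
  d <- bxy[-1] - bxy[1]
  Vd <- covb[-1, -1, drop = FALSE] -
    matrix(covb[-1, 1], k, k) - matrix(covb[1, -1], k, k, byrow = TRUE) +
    covb[1, 1]
  vdiag <- pmax(diag(Vd), 0)
  sd_d <- sqrt(vdiag)
  live <- sd_d > 1e-12
  if (!any(live)) return(list(p_heidi = 1, n_heidi_snps = k))
  zd <- d[live] / sd_d[live]
  Cd <- Vd[live, live, drop = FALSE] /
    tcrossprod(sd_d[live])
  tstat <- sum(zd^2)
  mu <- sum(live)
  v <- 2 * sum(Cd^2)
  cc <- v / (2 * mu)
  f <- 2 * mu^2 / v
  list(p_heidi = stats::pchisq(tstat / cc, df = f, lower.tail = FALSE),
       n_heidi_snps = k)
}

#' SMR + HEIDI scan over all genes and tissues
#'
#' For each `gene_id` x `tissue` combination with a top cis-eQTL
#' passing the instrument threshold, runs [smr_test()] at the top
#' variant and [heidi_test()] over the cis region, then annotates two
#' significance tiers across all tested combinations: Bonferroni
#' (`smr_significant`) and nominal p < 0.05 (`smr_nominal`).
#'
#' @inheritParams heidi_test
#' @param eqtl long eQTL table, possibly spanning several tissues.
#' @param ... further arguments passed to [heidi_test()].
#' @return A `data.table` with one row per tested gene x tissue:
#'   `gene_id tissue top_variant b_xy p_smr p_heidi n_heidi_snps
#'   smr_significant smr_nominal`.
#' @export
smr_scan <- function(gwas, eqtl, ld, p_instrument = 5e-8, ...) {
  eq <- data.table::as.data.table(eqtl)
  gw <- data.table::as.data.table(gwas)
  if (!"tissue" %in% names(eq)) eq[, tissue := "tissue1"]
  combos <- unique(eq[, list(gene_id, tissue)])
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    g <- combos$gene_id[i]; tis <- combos$tissue[i]
    sub <- eq[gene_id == g & tissue == tis & variant_id %in% gw$SNP]
    if (nrow(sub) == 0L) next
    ze <- sub$b_eqtl / sub$se_eqtl
    pe <- 2 * stats::pnorm(-abs(ze))
    top <- which.min(pe)
    if (pe[top] >= p_instrument) next
    gi <- gw[match(sub$variant_id[top], SNP)]
    sm <- smr_test(gi$BETA, gi$SE, sub$b_eqtl[top], sub$se_eqtl[top])
    hd <- heidi_test(g, gw, sub, ld, p_instrument = p_instrument, ...)
    rows[[i]] <- data.table::data.table(
      gene_id = g, tissue = tis, top_variant = sub$variant_id[top],
      b_xy = sm$b_xy, p_smr = sm$p_smr,
      p_heidi = hd$p_heidi, n_heidi_snps = hd$n_heidi_snps)
  }
  res <- data.table::rbindlist(rows)
  if (nrow(res) == 0L) return(res)
  n_genes <- length(unique(res$gene_id))
  res[, `:=`(smr_significant = p_smr < 0.05 / n_genes,
             smr_nominal = p_smr < 0.05)]
  res[]
}

#' Exclude genes whose mediation signal reflects linkage
#'
#' Genes with `p_heidi < alpha` are flagged as likely linkage
#' artifacts and excluded from downstream druggability analysis; genes
#' without a HEIDI result ("untested") pass with a logged caveat.
#'
#' @param results an SMR results table ([smr_scan()]); multiple
#'   tissues per gene are excluded if any tissue fails HEIDI.
#' @param alpha HEIDI exclusion threshold (default 0.01).
#' @return list with `pass` and `excluded` gene-id vectors and
#'   `status`, a data.table of per-gene `heidi_status` in
#'   `pass`/`excluded`/`untested`.
#' @export
heidi_filter <- function(results, alpha = 0.01) {
  res <- data.table::as.data.table(results)
  st <- res[, list(
    heidi_status = if (any(!is.na(p_heidi) & p_heidi < alpha)) "excluded"
                   else if (all(is.na(p_heidi))) "untested" else "pass"),
    by = gene_id]
  n_untested <- sum(st$heidi_status == "untested")
  if (n_untested > 0)
    message("heidi_filter: ", n_untested,
            " gene(s) without a HEIDI result pass with caveat")
  list(pass = st$gene_id[st$heidi_status != "excluded"],
       excluded = st$gene_id[st$heidi_status == "excluded"],
       status = st[])
}
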