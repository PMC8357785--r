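#' Generate LD-blocked genotypes and their realized LD table
#'
#' Haplotypes within a block follow a first-order Markov copying
#' process: each site copies the previous site's allele with
#' probability `rho` and otherwise draws a fresh allele at the block's
#' frequency, giving an expected AR(1) correlation `rho^|j-k|` between
#' dosages.  Blocks are independent and share a single allele
#' frequency drawn from `maf_range`.  Dosages are the sum of two
#' independent haplotypes.
#'
#' @param n individuals.
#' @param blocks data.frame with columns `size` and `rho`
#'   (`0 <= rho < 1`), one row per block.
#' @param maf_range allele-frequency range (default `c(0.05, 0.5)`).
#' @param seed optional RNG seed (fixed seed = byte-identical output).
#' @return list with `G` (n x m integer dosage matrix, columns named
#'   by variant id), `variants` (data.table `variant_id, CHR, BP`),
#'   `ld` (an `ld_ref` of realized within-block correlations), and
#'   `maf` (per-variant frequency).
#' @export
make_ld_genotypes <- function(n, blocks, maf_range = c(0.05, 0.5),
                              seed = NULL) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "rho") %in% names(blocks)))
  if (any(blocks$rho < 0 | blocks$rho >= 1))
    stop("block rho must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- sum(blocks$size)
  G <- matrix(0L, n, m)
  maf <- numeric(m)
  col <- 0L
  hap_block <- function(k, p, rho) {
    H <- matrix(0L, n, k)
    H[, 1] <- stats::rbinom(n, 1L, p)
    if (k > 1) for (j in 2:k) {
      copy <- stats::rbinom(n, 1L, rho)
      H[, j] <- copy * H[, j - 1] + (1L - copy) * stats::rbinom(n, 1L, p)
    }
    H
  }
  for (b in seq_len(nrow(blocks))) {
    k <- blocks$size[b]
    p <- stats::runif(1, maf_range[1], maf_range[2])
    G[, col + seq_len(k)] <- hap_block(k, p, blocks$rho[b]) +
      hap_block(k, p, blocks$rho[b])
    maf[col + seq_len(k)] <- p
    col <- col + k
  }
  ids <- paste0("snp", seq_len(m))
  colnames(G) <- ids
  variants <- data.table::data.table(
    variant_id = ids, CHR = "1", BP = as.integer(seq_len(m) * 1000L))
  # realized within-block LD
  pair_rows <- vector("list", nrow(blocks))
  col <- 0L
  for (b in seq_len(nrow(blocks))) {
    k <- blocks$size[b]
    if (k > 1) {
      R <- stats::cor(G[, col + seq_len(k), drop = FALSE])
      idx <- which(upper.tri(R), arr.ind = TRUE)
      pair_rows[[b]] <- data.table::data.table(
        variant_a = ids[col + idx[, 1]],
        variant_b = ids[col + idx[, 2]], r = R[idx])
    }
    col <- col + k
  }
  ld <- ld_ref(data.table::rbindlist(pair_rows))
  list(G = G, variants = variants, ld = ld, maf = maf,
       blocks = blocks)
}

# per-variant association of dosage columns with y on a subset of
# individuals; returns per-allele BETA/SE on the standardized-trait
# scale plus Z
.marginal_gwas <- function(G, y, idx = NULL) {
  if (!is.null(idx)) { G <- G[idx, , drop = FALSE]; y <- y[idx] }
  n <- length(y)
  Gd <- matrix(as.double(G), n, ncol(G))
  sx <- colMeans(Gd)
  vx <- colMeans(Gd^2) - sx^2
  vy <- mean(y^2) - mean(y)^2
  r <- (colMeans(Gd * y) - sx * mean(y)) / sqrt(vx * vy)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- r * sqrt(n - 2) / sqrt(1 - r^2)
  beta <- r * sqrt(vy / vx)
  list(beta = beta, se = beta / z, z = z, n = n)
}

#' Generate an overlapping same-trait GWAS pair on LD-blocked
#' genotypes
#'
#' Plants `n_causal` standardized effects totalling heritability `h2`
#' on the supplied genotypes, builds the phenotype, draws two
#' equal-size subsamples with the requested overlap fraction, and
#' returns each subsample's per-variant association results as a
#' canonical summary-statistics table (alleles A/G, effect allele =
#' dosage allele).
#'
#' @param geno output of [make_ld_genotypes()].
#' @param h2 heritability (default 0.3).
#' @param n_causal causal variants (default 20).
#' @param overlap shared fraction of each subsample (default 0.8).
#' @param subsample_fraction subsample size as a fraction of n
#'   (default `1 / (2 - overlap)`, so the union tiles the cohort).
#' @param seed optional RNG seed.
#' @return list with `study1`, `study2` (canonical tables), `full`
#'   (full-cohort table), and `truth` (causal variant ids, effects,
#'   subsample indices).
#' @export
make_gwas_pair <- function(geno, h2 = 0.3, n_causal = 20,
                           overlap = 0.8, subsample_fraction = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- geno$G
  n <- nrow(G); m <- ncol(G)
  causal <- sort(sample.int(m, n_causal))
  b <- stats::rnorm(n_causal, 0, sqrt(h2 / n_causal))
  sds <- sqrt(2 * geno$maf[causal] * (1 - geno$maf[causal]))
  Xs <- sweep(sweep(matrix(as.double(G[, causal]), n), 2,
                    2 * geno$maf[causal]), 2, sds, "/")
  gv <- as.vector(Xs %*% b)
  gv <- gv * sqrt(h2) / stats::sd(gv)
  y <- as.vector(scale(gv + stats::rnorm(n, 0, sqrt(1 - h2))))

  sfrac <- subsample_fraction %||% (1 / (2 - overlap))
  n_sub <- round(sfrac * n)
  n_o <- round(overlap * n_sub)
  if (2 * n_sub - n_o > n) stop("infeasible overlap configuration")
  ids <- sample.int(n, 2 * n_sub - n_o)
  s1 <- ids[seq_len(n_sub)]
  s2 <- c(ids[seq_len(n_o)], ids[seq_len(n_sub - n_o) + n_sub])

  as_tbl <- function(fit) data.table::data.table(
    SNP = geno$variants$variant_id, CHR = geno$variants$CHR,
    BP = geno$variants$BP, A1 = "A", A2 = "G",
    BETA = fit$beta, SE = fit$se, Z = fit$z,
    P = 2 * stats::pnorm(-abs(fit$z)), N = fit$n)
  list(study1 = as_tbl(.marginal_gwas(G, y, s1)),
       study2 = as_tbl(.marginal_gwas(G, y, s2)),
       full = as_tbl(.marginal_gwas(G, y)),
       truth = list(causal = geno$variants$variant_id[causal],
                    beta = b, s1 = s1, s2 = s2, h2 = h2, y = y))
}

.ar1_matrix <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), "-"))

#' Generate cis-gene summary statistics with planted mediation classes
#'
#' Emulates, at the summary-statistic level, the joint sampling
#' distribution of eQTL and GWAS effects in a cis window of `p_cis`
#' variants with AR(1) LD: `mediated` genes share one causal variant
#' between expression and trait (expression-to-trait slope
#' `b_xy_true`, random sign); `linkage` genes place the expression and
#' trait causal variants on adjacent positions (LD `rho`); `null`
#' genes have an eQTL only.  eQTL and GWAS noise are independent
#' draws from `N(0, R)` (distinct cohorts), so every downstream
#' mediation statistic has its theoretical null/alternative behavior.
#'
#' @param n_genes number of genes (default 300).
#' @param class_mix named proportions for `mediated`, `linkage`,
#'   `null` (summing to 1).
#' @param b_xy_true expression-to-trait slope magnitude for mediated
#'   genes (default 0.1).
#' @param b_eqtl_true causal cis-eQTL effect magnitude on the
#'   standardized-expression scale (default 0.35).
#' @param n_eqtl,n_gwas eQTL- and GWAS-cohort sizes (defaults 1,500
#'   and 370,000).
#' @param p_cis cis variants per gene (default 25).
#' @param rho AR(1) LD parameter (default 0.7; also the LD between
#'   the two causal variants of a linkage gene).
#' @param seed optional RNG seed.
#' @return list with `eqtl` (long table `gene_id tissue variant_id
#'   b_eqtl se_eqtl`), `gwas` (canonical table over all cis variants),
#'   `ld` (exact AR(1) `ld_ref` across all genes), and `truth`
#'   (data.table `gene_id class causal_expr causal_trait b_xy_true
#'   direction`).
#' @export
make_mediation_genes <- function(n_genes = 300,
                                 class_mix = c(mediated = 1/3,
                                               linkage = 1/3,
                                               null = 1/3),
                                 b_xy_true = 0.1, b_eqtl_true = 0.35,
                                 n_eqtl = 1500, n_gwas = 370000,
                                 p_cis = 25, rho = 0.7, seed = NULL) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  cnt <- diff(c(0, round(cumsum(class_mix) * n_genes)))
  classes <- sample(rep(names(class_mix), times = cnt))
  R <- .ar1_matrix(p_cis, rho)
  L <- t(chol(R))
  eqtl_rows <- vector("list", n_genes)
  gwas_rows <- vector("list", n_genes)
  ld_rows <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  idxR <- which(upper.tri(R), arr.ind = TRUE)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", g)
    ids <- sprintf("%s_snp%02d", gid, seq_len(p_cis))
    cls <- classes[g]
    ce <- sample(2:(p_cis - 1), 1)           # expression causal variant
    dir_e <- sample(c(-1, 1), 1)
    be <- dir_e * b_eqtl_true
    mu_e <- sqrt(n_eqtl) * R[, ce] * be
    z_e <- mu_e + as.vector(L %*% stats::rnorm(p_cis))
    if (cls == "mediated") {
      dir_xy <- sample(c(-1, 1), 1)
      bxy <- dir_xy * b_xy_true
      ct <- ce
      mu_g <- sqrt(n_gwas) * R[, ce] * (bxy * be)
    } else if (cls == "linkage") {
      dir_xy <- 0
      bxy <- 0
      ct <- ce + 1L                           # adjacent, LD = rho
      bt <- sample(c(-1, 1), 1) * 0.01
      mu_g <- sqrt(n_gwas) * R[, ct] * bt
    } else {
      dir_xy <- 0; bxy <- 0; ct <- NA_integer_
      mu_g <- rep(0, p_cis)
    }
    z_g <- mu_g + as.vector(L %*% stats::rnorm(p_cis))
    eqtl_rows[[g]] <- data.table::data.table(
      gene_id = gid, tissue = "brain", variant_id = ids,
      b_eqtl = z_e / sqrt(n_eqtl), se_eqtl = 1 / sqrt(n_eqtl))
    gwas_rows[[g]] <- data.table::data.table(
      SNP = ids, CHR = "1", BP = as.integer((g - 1) * 10000L +
                                              seq_len(p_cis) * 100L),
      A1 = "A", A2 = "G",
      BETA = z_g / sqrt(n_gwas), SE = 1 / sqrt(n_gwas), Z = z_g,
      P = 2 * stats::pnorm(-abs(z_g)), N = n_gwas)
    ld_rows[[g]] <- data.table::data.table(
      variant_a = ids[idxR[, 1]], variant_b = ids[idxR[, 2]],
      r = R[idxR])
    truth[[g]] <- data.table::data.table(
      gene_id = gid, class = cls,
      causal_expr = ids[ce],
      causal_trait = if (is.na(ct)) NA_character_ else ids[ct],
      b_xy_true = bxy, direction = dir_xy)
  }
  list(eqtl = data.table::rbindlist(eqtl_rows),
       gwas = data.table::rbindlist(gwas_rows),
       ld = ld_ref(data.table::rbindlist(ld_rows)),
       truth = data.table::rbindlist(truth))
}

#' Generate a druggability fixture with planted priority targets
#'
#' Builds the gene universe, evidence streams, HEIDI statuses, eQTL
#' directions, druggable-gene list, and drug-annotation table for the
#' prioritization cascade, with planted ground truth: every planted
#' priority gene is druggable, HEIDI-clean, flagged by two
#' identification approaches, has a consistent direction vote, and
#' carries at least one non-oncology drug whose mechanism-of-action
#' term agrees with its planted direction.  Decoy genes each fail
#' exactly one requirement (not druggable, HEIDI-excluded, a single
#' identification approach, oncology-only indications, tied direction
#' votes, or an opposing MOA term).
#'
#' @param n_genes gene-universe size (default 60).
#' @param n_priority planted priority targets (default 5).
#' @param druggable_fraction fraction of the non-planted universe
#'   included in the druggable set (default 0.6).
#' @param oncology_fraction fraction of decoy drug records given an
#'   oncology indication (default 0.3; the oncology-only decoy class
#'   always has 1).
#' @param moa_vocabulary character vector containing both
#'   agonist-class and antagonist-class terms (default: the names of
#'   [default_moa_synonyms()]).
#' @param seed optional RNG seed.
#' @return list with `streams` (named list of flagged gene-id sets),
#'   `heidi` (data.table `gene_id heidi_status`), `directions`
#'   (data.table `gene_id source tissue sign`), `druggable`
#'   (character), `drugs` (data.table `gene drug moa indication`),
#'   and `truth` (list with `priority` gene ids and the decoy
#'   classes).
#' @export
make_drug_fixture <- function(n_genes = 60, n_priority = 5,
                              druggable_fraction = 0.6,
                              oncology_fraction = 0.3,
                              moa_vocabulary = names(default_moa_synonyms()),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  syn <- default_moa_synonyms()[moa_vocabulary]
  ago_terms <- names(syn)[syn == "agonist"]
  ant_terms <- names(syn)[syn == "antagonist"]
  if (!length(ago_terms) || !length(ant_terms))
    stop("moa_vocabulary must include agonist- and antagonist-class terms")
  genes <- sprintf("gene%02d", seq_len(n_genes))
  priority <- genes[seq_len(n_priority)]
  decoy_classes <- c("undruggable", "heidi_excluded", "one_method",
                     "oncology_only", "ambiguous", "wrong_moa")
  decoys <- genes[n_priority + seq_along(decoy_classes)]
  rest <- setdiff(genes, c(priority, decoys))

  term_for <- function(dir, agree = TRUE) {
    pool <- if (xor(dir > 0, !agree)) ago_terms else ant_terms
    pool[sample.int(length(pool), 1)]
  }
  dir_p <- sample(c(-1L, 1L), n_priority, replace = TRUE)

  # evidence streams: planted genes hit TWAS-brain and SMR (two
  # approaches); decoys/rest per class
  twas_brain <- c(priority, decoys[decoy_classes != "one_method"])
  smr <- c(priority, decoys)
  streams <- list(twas_brain = twas_brain, smr = smr)

  heidi <- data.table::data.table(
    gene_id = genes,
    heidi_status = ifelse(genes == decoys[2], "excluded", "pass"))

  mk_dirs <- function(g, signs) data.table::data.table(
    gene_id = g, source = "eqtl",
    tissue = paste0("tissue", seq_along(signs)),
    sign = as.integer(signs))
  dirs <- data.table::rbindlist(c(
    lapply(seq_len(n_priority), function(i)
      mk_dirs(priority[i], rep(dir_p[i], 3))),
    list(mk_dirs(decoys[5], c(1, -1))),          # ambiguous: tie
    lapply(decoys[decoy_classes %in% c("undruggable", "heidi_excluded",
                                       "one_method", "oncology_only",
                                       "wrong_moa")],
           function(g) mk_dirs(g, c(1, 1)))))

  druggable <- c(priority, decoys[decoy_classes != "undruggable"],
                 rest[seq_len(ceiling(druggable_fraction * length(rest)))])

  benign <- c("Epilepsy", "Hypertension", "Depression", "Migraine")
  mk_drug <- function(g, term, onc) data.table::data.table(
    gene = g, drug = paste0("drug_", g),
    moa = paste("Target", term),
    indication = if (onc) "Oncology" else sample(benign, 1))
  drugs <- data.table::rbindlist(c(
    lapply(seq_len(n_priority), function(i)
      mk_drug(priority[i], term_for(dir_p[i]), FALSE)),
    list(mk_drug(decoys[4], term_for(1), onc = TRUE),      # oncology only
         mk_drug(decoys[6], term_for(1, agree = FALSE), FALSE)),
    lapply(decoys[c(1, 2, 3, 5)], function(g)
      mk_drug(g, term_for(1), stats::runif(1) < oncology_fraction))))

  list(streams = streams, heidi = heidi, directions = dirs,
       druggable = druggable, drugs = drugs,
       truth = list(priority = priority, priority_direction = dir_p,
                    decoys = stats::setNames(decoys, decoy_classes)))
}

#' Write a complete fixture bundle to disk
#'
#' Emits every pipeline input generated by the synthetic module in
#' the formats the corresponding readers consume: canonical
#' summary-statistics tables, the long LD format, the long eQTL
#' format, per-stream gene tables, the druggable-gene list and the
#' drug-annotation table.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed fanned out to per-component substreams.
#' @param n,blocks genotype dimensions for the GWAS-pair component.
#' @param n_genes mediation genes.
#' @return invisibly, the list of generated objects.
#' @export
make_fixture_set <- function(dir, seed = 1, n = 2000,
                             blocks = data.frame(size = 10, rho = 0.8)[
                               rep(1, 50), ],
                             n_genes = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- seed + 1:4
  geno <- make_ld_genotypes(n, blocks, seed = seeds[1])
  pair <- make_gwas_pair(geno, seed = seeds[2])
  med <- make_mediation_genes(n_genes = n_genes, seed = seeds[3])
  drug <- make_drug_fixture(seed = seeds[4])
  write_sumstats(pair$study1, file.path(dir, "study1.sumstats.tsv"))
  write_sumstats(pair$study2, file.path(dir, "study2.sumstats.tsv"))
  write_ld(geno$ld, file.path(dir, "genotypes.ld.tsv"))
  write_ld(med$ld, file.path(dir, "cis.ld.tsv"))
  data.table::fwrite(med$eqtl, file.path(dir, "eqtl.tsv"), sep = "\t")
  write_sumstats(med$gwas, file.path(dir, "cis.sumstats.tsv"))
  data.table::fwrite(med$truth, file.path(dir, "mediation_truth.tsv"),
                     sep = "\t")
  writeLines(drug$druggable, file.path(dir, "druggable_genes.txt"))
  data.table::fwrite(drug$drugs, file.path(dir, "drugs.tsv"), sep = "\t")
  invisible(list(geno = geno, pair = pair, mediation = med,
                 drugs = drug))
}
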