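# correlation of a standard bivariate normal with correlation rho
# after truncating both coordinates to [-c, c] (midpoint quadrature)
.trunc_corr <- function(rho, c, n_grid = 200) {
  if (abs(rho) < 1e-12) return(0)
  x <- seq(-c, c, length.out = n_grid + 1)
  x <- (x[-1] + x[-length(x)]) / 2
  q <- 1 - rho^2
  f <- exp(-(outer(x^2, x^2, "+") - 2 * rho * outer(x, x)) / (2 * q))
  m00 <- sum(f)
  m11 <- sum(outer(x, x) * f)
  m20 <- sum(outer(x^2, rep(1, length(x))) * f)
  (m11 / m00) / (m20 / m00)
}

# invert the truncation attenuation: find rho whose truncated
# correlation matches the observed null-window correlation
.detruncate_corr <- function(r_obs, c) {
  if (abs(r_obs) < 1e-8) return(r_obs)
  hi <- 0.9999
  if (abs(r_obs) >= .trunc_corr(sign(r_obs) * hi, c) * sign(r_obs))
    return(r_obs)  # beyond the invertible range: essentially +/-1
  stats::uniroot(function(rho) .trunc_corr(rho, c) - r_obs,
                 interval = sort(c(0, sign(r_obs) * hi)),
                 tol = 1e-6)$root
}

#' Estimate the cross-study error correlation of two overlapping GWAS
#'
#' Sample overlap between two GWAS of the same trait induces a
#' correlation between the sampling errors of their z-scores.  Among
#' effectively null variants the z-scores are almost pure sampling
#' error, so their correlation across variants estimates that error
#' correlation (the same quantity the bivariate LD-score intercept
#' targets; for two equal-size cohorts sharing `N_o` of `N`
#' individuals under the null it equals `N_o / sqrt(N1 N2)`).  Null
#' variants are defined by `|z| < z_cut` in both studies; because that
#' double truncation attenuates the Pearson correlation, the raw
#' null-window correlation is mapped back through the
#' truncated-bivariate-normal moment relation before being reported.
#'
#' @param pair a `harmonized_pair` from [harmonize()].
#' @param z_cut |z| cutoff defining the null window (default 1.96).
#' @return An object of class `overlap_model`: list with `r_err`
#'   (truncation-corrected), `r_null` (raw null-window Pearson
#'   correlation), `n_null` (variants used), `n1`, `n2` (median
#'   sample sizes) and `z_cut`.
#' @export
estimate_error_correlation <- function(pair, z_cut = 1.96) {
  stopifnot(inherits(pair, "harmonized_pair"))
  p <- pair$pairs
  nul <- abs(p$Z1) < z_cut & abs(p$Z2) < z_cut
  m <- sum(nul)
  if (m < 1000)
    stop("too few null variants to estimate error correlation: ", m,
         " (need >= 1000)")
  r_null <- stats::cor(p$Z1[nul], p$Z2[nul])
  r_err <- min(max(.detruncate_corr(r_null, z_cut), -1), 1)
  structure(list(r_err = r_err, r_null = r_null, n_null = m,
                 n1 = stats::median(p$N1), n2 = stats::median(p$N2),
                 z_cut = z_cut),
            class = "overlap_model")
}

#' @export
print.overlap_model <- function(x, ...) {
  cat(sprintf("Overlap model: r_err = %.4f (from %d null variants, |z| < %g)\n",
              x$r_err, x$n_null, x$z_cut))
  invisible(x)
}

#' Overlap-aware fixed-effect combination of two z-scores
#'
#' The constrained single-trait combination used when two GWAS index
#' the same phenotype with equal heritability and genetic correlation
#' 1: a weighted z-score sum whose denominator accounts for the
#' error correlation `r_err` induced by sample overlap,
#' \deqn{z = (w_1 z_1 + w_2 z_2) / \sqrt{w_1^2 + w_2^2 + 2 r w_1 w_2}.}
#' At `r_err = 0` this is the classical fixed-effect (weighted
#' z-score) meta-analysis; at `r_err = 1` with equal weights the two
#' studies are fully redundant and the combined z equals the input z.
#'
#' @param z1,z2 numeric vectors of aligned z-scores.
#' @param w1,w2 per-study weights (scalars or vectors; conventionally
#'   `sqrt(N)`).
#' @param r_err cross-study error correlation in `[-1, 1]`.
#' @return numeric vector of combined z-scores.
#' @export
combine_z <- function(z1, z2, w1, w2, r_err) {
  if (abs(r_err) > 1) stop("r_err must lie in [-1, 1]")
  (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2 + 2 * r_err * w1 * w2)
}

#' Combine two overlapping same-trait GWAS into one set of summary
#' statistics
#'
#' Applies [combine_z()] per variant with the supplied overlap model,
#' recomputes two-sided p-values, and reports the power accounting:
#' per-study and combined mean chi-square and the projected
#' GWAS-equivalent sample size (see [effective_n()]).
#'
#' @param pair a `harmonized_pair`.
#' @param om an `overlap_model` (or a number interpreted as `r_err`).
#' @param weights `"sqrt-n"` (default; `w = sqrt(N)` per study),
#'   `"equal"`, or a numeric length-2 vector `c(w1, w2)`.
#' @return An object of class `meta_result`: list with
#'   * `sumstats`: canonical table (`BETA`/`SE` rescaled so
#'     `Z = BETA/SE`, `N` set to the rounded effective N);
#'   * `r_err`, `mean_chisq_1`, `mean_chisq_2`, `mean_chisq_meta`,
#'     `n_effective` (NA when any mean chi-square is <= 1).
#' @export
meta_combine <- function(pair, om, weights = "sqrt-n") {
  stopifnot(inherits(pair, "harmonized_pair"))
  r_err <- if (inherits(om, "overlap_model")) om$r_err else as.numeric(om)
  p <- pair$pairs
  distinct <- !isTRUE(all.equal(p$Z1, p$Z2))
  if (r_err >= 1 && distinct)
    stop("degenerate overlap model: r_err >= 1 for distinct studies")
  if (is.numeric(weights)) {
    stopifnot(length(weights) == 2)
    w1 <- weights[1]; w2 <- weights[2]
  } else if (identical(weights, "sqrt-n")) {
    w1 <- sqrt(p$N1); w2 <- sqrt(p$N2)
  } else if (identical(weights, "equal")) {
    w1 <- 1; w2 <- 1
  } else stop("weights must be 'sqrt-n', 'equal', or a numeric pair")

  z <- combine_z(p$Z1, p$Z2, w1, w2, r_err)
  mc1 <- mean(p$Z1^2); mc2 <- mean(p$Z2^2); mcm <- mean(z^2)
  n1 <- stats::median(p$N1); n2 <- stats::median(p$N2)
  neff <- if (mcm > 1 && mc1 > 1 && mc2 > 1)
    effective_n(mcm, c(mc1, mc2), c(n1, n2)) else NA_real_

  nn <- if (is.na(neff)) round((n1 + n2) / 2) else round(neff)
  se <- 1 / sqrt(nn)
  ss <- data.table::data.table(
    SNP = p$SNP, CHR = p$CHR, BP = p$BP, A1 = p$A1, A2 = p$A2,
    BETA = z * se, SE = se, Z = z, P = 2 * stats::pnorm(-abs(z)),
    N = nn)
  structure(list(sumstats = ss, r_err = r_err,
                 mean_chisq_1 = mc1, mean_chisq_2 = mc2,
                 mean_chisq_meta = mcm, n_effective = neff),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Combined GWAS: %d variants, r_err = %.4f\n  mean chi2: %.3f / %.3f -> %.3f;  effective N = %s\n",
    nrow(x$sumstats), x$r_err, x$mean_chisq_1, x$mean_chisq_2,
    x$mean_chisq_meta,
    ifelse(is.na(x$n_effective), "NA", format(round(x$n_effective), big.mark = ","))))
  invisible(x)
}

#' Projected GWAS-equivalent sample size of a combined analysis
#'
#' Reconstructs the "GWAS-equivalent N" from mean chi-square
#' accounting: under a polygenic trait the expected mean chi-square is
#' approximately `1 + N h2 l / m`, so `(mean chi2 - 1)` scales linearly
#' with sample size and the combined analysis corresponds, relative to
#' input study *j*, to `N_j (chi2_meta - 1) / (chi2_j - 1)` samples.
#' The projections from the input studies are averaged.
#'
#' @param mean_chisq_meta mean chi-square of the combined statistics.
#' @param mean_chisq_inputs numeric vector of input-study mean
#'   chi-squares.
#' @param n_inputs input-study sample sizes (same length).
#' @return the projected equivalent sample size (positive real).
#' @export
effective_n <- function(mean_chisq_meta, mean_chisq_inputs, n_inputs) {
  stopifnot(length(mean_chisq_inputs) == length(n_inputs))
  if (mean_chisq_meta <= 1 || any(mean_chisq_inputs <= 1))
    stop("effective N undefined: all mean chi-squares must exceed 1")
  mean((mean_chisq_meta - 1) / (mean_chisq_inputs - 1) * n_inputs)
}

#' Winner's-curse adjustment by FDR inverse quantile transformation
#'
#' Shrinks a vector of z-scores toward the null by (i) converting to
#' two-sided p-values, (ii) Benjamini-Hochberg adjusting across all
#' `length(z)` tests, and (iii) mapping the adjusted p back through the
#' normal quantile with the original sign.  The adjustment is
#' sign-preserving, magnitude-non-increasing, and rank-preserving
#' within each sign; with a single test it is the identity.
#'
#' @param z numeric vector of finite z-scores.
#' @return numeric vector of adjusted z-scores, input order preserved.
#' @export
fiqt_adjust <- function(z) {
  if (length(z) == 0) return(z)
  if (any(!is.finite(z))) stop("fiqt_adjust: non-finite z input")
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = "BH")
  p_adj <- pmax(p_adj, 1e-300)  # floor before quantile inversion
  sign(z) * stats::qnorm(p_adj / 2, lower.tail = FALSE)
}

#' Flag loci lost from a combined analysis as likely winner's curse
#'
#' For lead variants of loci that were significant in an input study
#' but not in the combined analysis, applies the FDR inverse quantile
#' transformation *as embedded in the full m-variant experiment*: each
#' lead's BH-adjusted p is `p * m / rank`, with ranks taken among the
#' supplied leads (the experiment's top order statistics) and the
#' step-up cumulative minimum enforced.  A locus is flagged as a
#' likely winner's-curse false positive when its adjusted two-sided p
#' exceeds `threshold`.
#'
#' @param z lead-variant z-scores from the originating study
#'   (non-finite or missing values are a lookup error).
#' @param m total number of variants tested in the experiment.
#' @param threshold genome-wide significance threshold on the adjusted
#'   p (default 5e-8).
#' @return logical vector, `TRUE` = likely false positive.
#' @export
winners_curse_flag <- function(z, m, threshold = 5e-8) {
  if (length(z) == 0) return(logical(0))
  if (any(!is.finite(z))) stop("lead variant z missing or non-finite")
  p <- 2 * stats::pnorm(-abs(z))
  o <- order(p)
  k <- length(p)
  adj <- pmin(1, p[o] * m / seq_len(k))
  adj <- rev(cummin(rev(adj)))  # BH step-up enforcement
  out <- numeric(k)
  out[o] <- adj
  out > threshold
}
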