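#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited file with a header row into the
#' canonical column layout `SNP CHR BP A1 A2 BETA SE Z P N` (`A1` is
#' the effect allele).  Input dialects are absorbed through
#' `column_map`; a small set of common aliases (`RSID`, `POS`, `EA`,
#' `NEA`, ...) is recognized automatically.  `Z` is recomputed as
#' `BETA/SE` when absent, and `P` as the two-sided normal tail of `Z`
#' when absent.  Rows violating the record invariants (alleles outside
#' ACGT or equal, `SE <= 0`, `P` outside `(0, 1]`, inconsistent
#' `Z`/`BETA/SE`) are dropped, as are duplicate `SNP` ids (the record
#' with the smallest `P` is kept).  Drop counts are attached as the
#' `"drop_log"` attribute.
#'
#' @param path file path (gzip transparently supported) or a
#'   data.frame already in memory.
#' @param column_map named character vector mapping canonical names to
#'   the file's column names, e.g. `c(SNP = "MarkerName", P = "Pval")`.
#' @return A `data.table` in canonical layout with attribute
#'   `drop_log` (named integer vector of dropped-row counts).
#' @export
read_sumstats <- function(path, column_map = NULL) {
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop("empty summary-statistics input: no rows")

  aliases <- list(
    SNP = c("SNP", "RSID", "VARIANT_ID", "MARKERNAME", "ID"),
    CHR = c("CHR", "CHROM", "CHROMOSOME"),
    BP  = c("BP", "POS", "POSITION", "BASE_PAIR"),
    A1  = c("A1", "EA", "EFFECT_ALLELE", "ALLELE1"),
    A2  = c("A2", "NEA", "OTHER_ALLELE", "ALLELE2", "OA"),
    BETA = c("BETA", "B", "EFFECT"),
    SE  = c("SE", "STDERR"),
    Z   = c("Z", "ZSCORE", "Z_STAT"),
    P   = c("P", "PVAL", "PVALUE", "P_VALUE"),
    N   = c("N", "NMISS", "SAMPLE_SIZE"))
  upper <- toupper(names(dt))
  pick <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      j <- match(toupper(column_map[[canon]]), upper)
      if (is.na(j)) stop("configured column '", column_map[[canon]],
                         "' for ", canon, " not found in input")
      return(j)
    }
    j <- match(aliases[[canon]], upper)
    j <- j[!is.na(j)]
    if (length(j)) j[1] else NA_integer_
  }
  idx <- vapply(names(aliases), pick, integer(1))
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "N")
  miss <- mandatory[is.na(idx[mandatory])]
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))

  out <- data.table::data.table(
    SNP = as.character(dt[[idx["SNP"]]]),
    CHR = as.character(dt[[idx["CHR"]]]),
    BP  = as.integer(dt[[idx["BP"]]]),
    A1  = toupper(as.character(dt[[idx["A1"]]])),
    A2  = toupper(as.character(dt[[idx["A2"]]])),
    BETA = as.numeric(dt[[idx["BETA"]]]),
    SE  = as.numeric(dt[[idx["SE"]]]),
    Z   = if (!is.na(idx["Z"])) as.numeric(dt[[idx["Z"]]]) else NA_real_,
    P   = if (!is.na(idx["P"])) as.numeric(dt[[idx["P"]]]) else NA_real_,
    N   = as.numeric(dt[[idx["N"]]]))

  log <- c(bad_values = 0L, invariant = 0L, duplicate = 0L)

  ok <- !is.na(out$SNP) & !is.na(out$BP) & !is.na(out$BETA) &
    !is.na(out$SE) & out$SE > 0 & !is.na(out$N) & out$N > 0 &
    out$A1 %in% c("A", "C", "G", "T") & out$A2 %in% c("A", "C", "G", "T") &
    out$A1 != out$A2
  log["bad_values"] <- sum(!ok)
  out <- out[ok]

  # fill Z and P where absent, then enforce consistency
  out[is.na(Z), Z := BETA / SE]
  out[is.na(P), P := 2 * stats::pnorm(-abs(Z))]
  rel <- function(x, y) abs(x - y) / pmax(abs(y), 1e-12)
  ok <- rel(out$Z, out$BETA / out$SE) <= 1e-6 &
    is.finite(out$P) & out$P > 0 & out$P <= 1
  log["invariant"] <- sum(!ok)
  out <- out[ok]
  if (nrow(out) == 0L) stop("no valid rows after validation")

  data.table::setorder(out, P)
  dup <- duplicated(out$SNP)
  log["duplicate"] <- sum(dup)
  out <- out[!dup]
  data.table::setorder(out, CHR, BP)
  if (any(log > 0))
    message("read_sumstats: dropped ", sum(log), " row(s) [",
            paste(names(log), log, sep = "=", collapse = ", "), "]")
  data.table::setattr(out, "drop_log", log)
  out[]
}

#' Write summary statistics in the canonical dialect
#'
#' @param x a summary-statistics table from [read_sumstats()] (or any
#'   data.frame with the canonical columns).
#' @param path output path; a `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  cols <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "P", "N")
  stopifnot(all(cols %in% names(x)))
  data.table::fwrite(data.table::as.data.table(x)[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_ambiguous <- function(a1, a2) .complement[a1] == a2

#' Harmonize two summary-statistics tables to shared variants
#'
#' Intersects the two studies on `SNP` id, drops strand-ambiguous
#' (A/T, C/G) variants, aligns study 2 to study 1's effect allele
#' (negating `BETA`/`Z` when the allele labels are swapped), and drops
#' variants whose allele sets disagree.  No strand flipping is
#' attempted: conservative and testable without allele frequencies.
#'
#' @param a,b canonical summary-statistics tables ([read_sumstats()]).
#' @return An object of class `harmonized_pair`: a list with
#'   * `pairs`: data.table with shared `SNP CHR BP A1 A2` and
#'     per-study `BETA1 SE1 Z1 P1 N1 BETA2 SE2 Z2 P2 N2`;
#'   * `dropped`: named counts `missing`, `allele_mismatch`,
#'     `strand_ambiguous`.
#' @export
harmonize <- function(a, b) {
  a <- data.table::as.data.table(a)
  b <- data.table::as.data.table(b)
  shared <- intersect(a$SNP, b$SNP)
  dropped <- c(missing = (nrow(a) - length(shared)) +
                 (nrow(b) - length(shared)),
               allele_mismatch = 0L, strand_ambiguous = 0L)
  if (length(shared) == 0L) stop("zero shared variants between studies")
  ai <- a[match(shared, SNP)]
  bi <- b[match(shared, SNP)]

  amb <- .is_ambiguous(ai$A1, ai$A2) | .is_ambiguous(bi$A1, bi$A2)
  same <- ai$A1 == bi$A1 & ai$A2 == bi$A2
  swap <- ai$A1 == bi$A2 & ai$A2 == bi$A1
  mism <- !amb & !same & !swap
  dropped["strand_ambiguous"] <- sum(amb)
  dropped["allele_mismatch"] <- sum(mism)

  keep <- !amb & (same | swap)
  if (!any(keep)) stop("zero shared variants after allele harmonization")
  ai <- ai[keep]; bi <- bi[keep]
  sgn <- ifelse(swap[keep], -1, 1)
  pairs <- data.table::data.table(
    SNP = ai$SNP, CHR = ai$CHR, BP = ai$BP, A1 = ai$A1, A2 = ai$A2,
    BETA1 = ai$BETA, SE1 = ai$SE, Z1 = ai$Z, P1 = ai$P, N1 = ai$N,
    BETA2 = sgn * bi$BETA, SE2 = bi$SE, Z2 = sgn * bi$Z, P2 = bi$P,
    N2 = bi$N)
  data.table::setorder(pairs, CHR, BP)
  structure(list(pairs = pairs, dropped = dropped),
            class = "harmonized_pair")
}

#' Extract one study from a harmonized pair as a canonical table
#'
#' @param hp a `harmonized_pair`.
#' @param study 1 or 2.
#' @return a canonical summary-statistics `data.table`.
#' @export
pair_study <- function(hp, study) {
  stopifnot(inherits(hp, "harmonized_pair"), study %in% 1:2)
  p <- hp$pairs
  s <- as.character(study)
  data.table::data.table(
    SNP = p$SNP, CHR = p$CHR, BP = p$BP, A1 = p$A1, A2 = p$A2,
    BETA = p[[paste0("BETA", s)]], SE = p[[paste0("SE", s)]],
    Z = p[[paste0("Z", s)]], P = p[[paste0("P", s)]],
    N = p[[paste0("N", s)]])
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("Harmonized GWAS pair:", nrow(x$pairs), "shared variants\n")
  cat("  dropped:", paste(names(x$dropped), x$dropped, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}
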