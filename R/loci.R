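#' Greedy LD clumping of genome-wide significant variants into loci
#'
#' Repeatedly takes the unassigned significant variant with the
#' smallest p-value as a lead (ties broken by chromosome then
#' position), assigns to it every unassigned significant variant on
#' the same chromosome within `window` base pairs whose squared LD
#' with the lead exceeds `r2_thresh`, and spans the locus interval
#' over its members.  Variant pairs beyond `window` or absent from the
#' LD reference are treated as `r2 = 0`; absences are collected into a
#' single warning.
#'
#' @param assocs canonical summary-statistics table.
#' @param ld an `ld_ref`.
#' @param p_thresh genome-wide significance threshold (default 5e-8).
#' @param r2_thresh squared-correlation threshold for clump membership
#'   (default 0.6).
#' @param window maximum lead-member distance in bp (default 1 Mb).
#' @return A `data.table` of loci: `CHR start end lead_snp lead_p
#'   n_members members` (`members` is a list column of variant ids),
#'   1-based inclusive coordinates, sorted by `(CHR, start)`.
#' @export
clump <- function(assocs, ld, p_thresh = 5e-8, r2_thresh = 0.6,
                  window = 1e6) {
  a <- data.table::as.data.table(assocs)
  sig <- a[P < p_thresh]
  if (nrow(sig) == 0L) return(.empty_loci())
  data.table::setorder(sig, P, CHR, BP)
  assigned <- rep(FALSE, nrow(sig))
  missing_ld <- character(0)
  out <- vector("list", 0L)
  for (i in seq_len(nrow(sig))) {
    if (assigned[i]) next
    lead <- sig[i]
    cand <- which(!assigned & sig$CHR == lead$CHR &
                    abs(sig$BP - lead$BP) <= window)
    r <- ld_r(ld, sig$SNP[cand], lead$SNP)
    missing_ld <- c(missing_ld,
                    setdiff(sig$SNP[cand], ld$variants))
    memb <- cand[r^2 > r2_thresh | sig$SNP[cand] == lead$SNP]
    assigned[memb] <- TRUE
    out[[length(out) + 1L]] <- data.table::data.table(
      CHR = lead$CHR, start = min(sig$BP[memb]), end = max(sig$BP[memb]),
      lead_snp = lead$SNP, lead_p = lead$P,
      n_members = length(memb), members = list(sig$SNP[memb]))
  }
  if (length(missing_ld))
    warning("clump: ", length(unique(missing_ld)),
            " variant(s) absent from LD reference treated as r2 = 0")
  loci <- data.table::rbindlist(out)
  data.table::setorder(loci, CHR, start)
  loci[]
}

.empty_loci <- function() {
  data.table::data.table(CHR = character(), start = integer(),
                         end = integer(), lead_snp = character(),
                         lead_p = numeric(), n_members = integer(),
                         members = list())
}

#' Merge nearby loci on each chromosome
#'
#' Transitively merges same-chromosome loci whose interval gap is at
#' most `gap` base pairs (250 kb by default).  The merged locus spans
#' the union of its constituents; its lead is the smallest-p lead
#' among them; member lists are concatenated.  The operation is
#' idempotent and order-invariant, and conserves total member count.
#'
#' @param loci a loci table as returned by [clump()].
#' @param gap maximum separation (bp) for merging (default 250,000).
#' @return a merged loci table; after merging, any two loci on one
#'   chromosome are separated by more than `gap` bp.
#' @export
merge_loci <- function(loci, gap = 250000) {
  loci <- data.table::as.data.table(loci)
  if (nrow(loci) == 0L) return(loci)
  data.table::setorder(loci, CHR, start, end)
  grp <- integer(nrow(loci))
  g <- 0L
  cur_chr <- ""; cur_end <- -Inf
  for (i in seq_len(nrow(loci))) {
    if (loci$CHR[i] != cur_chr || loci$start[i] - cur_end > gap) {
      g <- g + 1L
      cur_chr <- loci$CHR[i]; cur_end <- loci$end[i]
    } else cur_end <- max(cur_end, loci$end[i])
    grp[i] <- g
  }
  loci[, {
    j <- which.min(lead_p)
    list(CHR = CHR[1], start = min(start), end = max(end),
         lead_snp = lead_snp[j], lead_p = lead_p[j],
         n_members = sum(n_members),
         members = list(unlist(members)))
  }, by = list(grp = grp)][, grp := NULL][]
}

#' Classify combined-analysis loci against the input studies
#'
#' Two loci overlap when their intervals intersect after symmetric
#' padding by `pad` bp (the same 250 kb distance used for merging).
#' Combined-analysis loci overlapping at least one input locus are
#' `shared`; those overlapping neither input list are `gained`; input
#' loci overlapping no combined locus are `lost_from_s1` /
#' `lost_from_s2`.
#'
#' @param meta_loci,s1_loci,s2_loci loci tables on one coordinate
#'   system.
#' @param pad symmetric padding in bp (default 250,000).
#' @return one `data.table` of loci with columns `source`
#'   (`meta`/`study1`/`study2`) and `category` (`shared`, `gained`,
#'   `lost_from_s1`, `lost_from_s2`); input loci that are shared are
#'   not repeated.
#' @export
classify_loci <- function(meta_loci, s1_loci, s2_loci, pad = 250000) {
  ov <- function(x, y) {
    # for each row of x: does any row of y overlap after padding?
    if (nrow(x) == 0L) return(logical(0))
    if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
    vapply(seq_len(nrow(x)), function(i) {
      any(y$CHR == x$CHR[i] &
            y$start - pad <= x$end[i] + pad &
            y$end + pad >= x$start[i] - pad)
    }, logical(1))
  }
  meta_loci <- data.table::as.data.table(meta_loci)
  s1_loci <- data.table::as.data.table(s1_loci)
  s2_loci <- data.table::as.data.table(s2_loci)
  m <- data.table::copy(meta_loci)
  hit <- ov(m, s1_loci) | ov(m, s2_loci)
  m[, `:=`(source = "meta", category = ifelse(hit, "shared", "gained"))]
  l1 <- data.table::copy(s1_loci)[!ov(s1_loci, meta_loci)]
  if (nrow(l1)) l1[, `:=`(source = "study1", category = "lost_from_s1")]
  l2 <- data.table::copy(s2_loci)[!ov(s2_loci, meta_loci)]
  if (nrow(l2)) l2[, `:=`(source = "study2", category = "lost_from_s2")]
  data.table::rbindlist(list(m, l1, l2), fill = TRUE)[]
}

#' Read / write loci as BED-like tab-delimited text
#'
#' On disk the format is 0-based half-open (`chrom start end
#' lead_variant lead_p n_members [category]`); in memory coordinates
#' are 1-based inclusive.  The `members` list column is serialized as
#' a comma-separated field.
#'
#' @param loci a loci table.
#' @param path file path.
#' @return `read_loci()` returns a loci `data.table`; `write_loci()`
#'   returns `path` invisibly.
#' @export
write_loci <- function(loci, path) {
  dt <- data.table::as.data.table(loci)
  out <- data.table::data.table(
    chrom = dt$CHR, start = dt$start - 1L, end = dt$end,
    lead_variant = dt$lead_snp, lead_p = dt$lead_p,
    n_members = dt$n_members,
    members = vapply(dt$members, paste, character(1), collapse = ","))
  if ("category" %in% names(dt)) out[, category := dt$category]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_loci
#' @export
read_loci <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  out <- data.table::data.table(
    CHR = as.character(dt$chrom), start = dt$start + 1L, end = dt$end,
    lead_snp = dt$lead_variant, lead_p = dt$lead_p,
    n_members = dt$n_members,
    members = strsplit(dt$members, ",", fixed = TRUE))
  if ("category" %in% names(dt)) out[, category := dt$category]
  out[]
}
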