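# Brown's-method p-value for the mean-chi-square gene statistic:
# sum of member chi-squares referred to a scaled chi-square whose
# first two moments come from the LD matrix.
.brown_p <- function(z, R) {
  k <- length(z)
  stat <- sum(z^2)
  v <- 2 * sum(R^2)          # Var(sum chi2) = 2 * sum r_ij^2
  cc <- v / (2 * k)
  f <- 2 * k^2 / v
  stats::pchisq(stat / cc, df = f, lower.tail = FALSE)
}

#' Gene-based association test from summary statistics
#'
#' Tests a gene by averaging the chi-squares of the variants in its
#' window and referring the sum to a scaled chi-square whose mean and
#' variance are computed from the LD matrix (Brown's method: mean `k`,
#' variance `2 sum r_ij^2`).  A single-variant gene reduces exactly to
#' the variant's two-sided test; perfectly correlated variants
#' collapse to one effective degree of freedom.
#'
#' @param gene a list or single-row data.frame with `gene_id`,
#'   `chrom`, `start`, `end` (1-based, inclusive).
#' @param assocs canonical summary-statistics table.
#' @param ld an `ld_ref` covering the gene's variants.
#' @param window symmetric window extension in bp (default 0).
#' @return list with `gene_id`, `p`, `n_variants`; `p` is `NA` (with a
#'   message) when no variant falls in the window.
#' @export
gene_test <- function(gene, assocs, ld, window = 0) {
  a <- data.table::as.data.table(assocs)
  memb <- a[CHR == as.character(gene$chrom) &
              BP >= gene$start - window & BP <= gene$end + window]
  if (nrow(memb) == 0L) {
    message("gene_test: no variants in window for ", gene$gene_id,
            "; skipped")
    return(list(gene_id = gene$gene_id, p = NA_real_, n_variants = 0L))
  }
  R <- ld_matrix(ld, memb$SNP)
  list(gene_id = gene$gene_id, p = .brown_p(memb$Z, R),
       n_variants = nrow(memb))
}

.stream_correction <- c(
  twas_tissue = "bonferroni", twas_brain = "bonferroni",
  smr = "bonferroni", gene_test = "bonferroni",
  eqtl_map = "fdr", rqtl = "fdr", evqtl = "fdr", sqtl = "fdr",
  pathway_member = "set")

#' Load one gene-evidence stream and apply its significance rule
#'
#' Reads a tab-delimited per-gene table (`gene, p[, direction,
#' tissue]`) for a named identification stream and returns the genes
#' passing the stream's stated multiple-testing correction: Bonferroni
#' for the TWAS, SMR and gene-based-test streams; Benjamini-Hochberg
#' FDR for the QTL-mapping streams.  The `pathway_member` stream
#' instead expects `(set, gene, set_p)` and flags genes belonging to
#' any set passing a Bonferroni-corrected set-level threshold.
#'
#' @param path file path or data.frame.
#' @param stream one of `twas_tissue`, `twas_brain`, `smr`,
#'   `eqtl_map`, `rqtl`, `evqtl`, `sqtl`, `gene_test`,
#'   `pathway_member`.
#' @param alpha family-wise / FDR level (default 0.05).
#' @param correction override the stream's default rule
#'   (`"bonferroni"`, `"fdr"`, or `"none"`).
#' @return list with `genes` (character vector of flagged gene ids)
#'   and `directions` (data.table `gene_id, source, tissue, sign`,
#'   empty when the table has no direction column).
#' @export
load_stream <- function(path, stream, alpha = 0.05, correction = NULL) {
  if (!stream %in% names(.stream_correction))
    stop("unknown stream name: ", stream)
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, header = TRUE)
  rule <- correction %||% .stream_correction[[stream]]

  if (identical(rule, "set") && is.null(correction)) {
    stopifnot(all(c("set", "gene", "set_p") %in% names(dt)))
    set_p <- dt[, list(p = set_p[1]), by = set]
    sig_sets <- set_p$set[set_p$p < alpha / nrow(set_p)]
    genes <- unique(dt$gene[dt$set %in% sig_sets])
    return(list(genes = genes,
                directions = .empty_directions()))
  }
  stopifnot(all(c("gene", "p") %in% names(dt)))
  flag <- switch(rule,
    bonferroni = dt$p < alpha / nrow(dt),
    fdr = stats::p.adjust(dt$p, "BH") < alpha,
    none = dt$p < alpha,
    stop("unknown correction rule: ", rule))
  dirs <- .empty_directions()
  if ("direction" %in% names(dt)) {
    dirs <- data.table::data.table(
      gene_id = as.character(dt$gene), source = stream,
      tissue = if ("tissue" %in% names(dt)) as.character(dt$tissue)
               else "all",
      sign = as.integer(sign(dt$direction)))
    dirs <- dirs[sign != 0]
  }
  list(genes = unique(dt$gene[flag]), directions = dirs)
}

.empty_directions <- function() {
  data.table::data.table(gene_id = character(), source = character(),
                         tissue = character(), sign = integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default grouping of evidence streams into identification approaches
#'
#' Five approaches: TWAS (tissue-wide + brain), SMR, QTL mapping
#' (eQTL/rQTL/evQTL/sQTL), the gene-based association test, and
#' pathway membership.
#' @return named list mapping approach name to stream names.
#' @export
default_approach_groups <- function() {
  list(twas = c("twas_tissue", "twas_brain"),
       smr = "smr",
       qtl_map = c("eqtl_map", "rqtl", "evqtl", "sqtl"),
       gene_test = "gene_test",
       pathway = "pathway_member")
}

#' Assemble the per-gene evidence matrix across identification streams
#'
#' Unions the flagged genes of every stream into one table with a
#' logical column per stream, a `method_count` equal to the number of
#' distinct identification *approaches* (stream groups) with at least
#' one flag, and the per-gene HEIDI status.  Directions are carried as
#' the `"directions"` attribute; a gene with directions but no flags
#' is retained with its method count computed normally (directions
#' alone are not evidence).
#'
#' @param streams named list; each element either a character vector
#'   of flagged gene ids or a [load_stream()] result.
#' @param directions optional data.table `gene_id, source, tissue,
#'   sign` of signed eQTL directions (rbind-ed with any directions
#'   carried by the streams).
#' @param heidi optional per-gene status: the `status` element of
#'   [heidi_filter()] (columns `gene_id, heidi_status`).  Genes absent
#'   from it are `untested`.
#' @param approach_groups stream-to-approach mapping; defaults to
#'   [default_approach_groups()].
#' @return A `data.table` with `gene_id`, one logical column per
#'   stream, `method_count`, `heidi_status`; attribute `directions`.
#' @export
build_evidence <- function(streams, directions = NULL, heidi = NULL,
                           approach_groups = default_approach_groups()) {
  stream_genes <- lapply(streams, function(s)
    if (is.list(s) && !is.null(s$genes)) as.character(s$genes)
    else as.character(s))
  dir_list <- lapply(streams, function(s)
    if (is.list(s) && !is.null(s$directions)) s$directions else NULL)
  dirs <- data.table::rbindlist(
    c(dir_list, list(directions)), use.names = TRUE, fill = TRUE)
  if (nrow(dirs) == 0L) dirs <- .empty_directions()

  all_genes <- sort(unique(c(unlist(stream_genes), dirs$gene_id)))
  ev <- data.table::data.table(gene_id = all_genes)
  for (nm in names(stream_genes))
    ev[, (nm) := gene_id %in% stream_genes[[nm]]]

  flag_mat <- as.matrix(ev[, names(stream_genes), with = FALSE])
  counts <- integer(nrow(ev))
  for (grp in approach_groups) {
    grp <- intersect(grp, colnames(flag_mat))
    if (length(grp))
      counts <- counts +
        (rowSums(flag_mat[, grp, drop = FALSE]) > 0)
  }
  ev[, method_count := counts]

  status <- rep("untested", nrow(ev))
  if (!is.null(heidi)) {
    heidi <- data.table::as.data.table(heidi)
    j <- match(ev$gene_id, heidi$gene_id)
    status[!is.na(j)] <- heidi$heidi_status[j[!is.na(j)]]
  }
  ev[, heidi_status := status]
  data.table::setattr(ev, "directions", dirs)
  ev[]
}
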