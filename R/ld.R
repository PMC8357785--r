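#' Build an LD reference from a long pair table
#'
#' An LD reference holds signed pairwise correlations \eqn{r} between
#' variants, as produced by an external reference panel or by
#' [make_ld_genotypes()].  Lookups are symmetric; pairs absent from the
#' table are taken to have \eqn{r = 0} (the caller decides whether that
#' warrants a warning, see [clump()]).
#'
#' @param pairs data.frame with columns `variant_a`, `variant_b`, `r`
#'   (signed correlation in `[-1, 1]`).  One row per unordered pair;
#'   duplicate orderings are collapsed (last wins).
#' @return An object of class `ld_ref`.
#' @export
ld_ref <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("variant_a", "variant_b", "r")
  if (!all(need %in% names(pairs)))
    stop("LD pair table needs columns: ", paste(need, collapse = ", "))
  if (nrow(pairs) && any(abs(pairs$r) > 1 + 1e-8))
    stop("LD r values must lie in [-1, 1]")
  a <- as.character(pairs$variant_a)
  b <- as.character(pairs$variant_b)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  r <- as.numeric(pairs$r)
  keep <- !duplicated(key, fromLast = TRUE)
  structure(
    list(r = stats::setNames(r[keep], key[keep]),
         variants = unique(c(a, b))),
    class = "ld_ref")
}

#' Build an LD reference from a correlation matrix
#'
#' @param R square correlation matrix (signed r).
#' @param ids variant ids for the rows/columns; defaults to the
#'   dimnames of `R`.
#' @return An `ld_ref` object.
#' @export
ld_from_matrix <- function(R, ids = rownames(R)) {
  R <- as.matrix(R)
  if (is.null(ids)) stop("variant ids required (dimnames or `ids`)")
  p <- nrow(R)
  if (p != ncol(R) || p != length(ids)) stop("R must be square, matching ids")
  if (p < 2) return(ld_ref(data.frame(variant_a = character(),
                                      variant_b = character(),
                                      r = numeric())))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  ld_ref(data.frame(variant_a = ids[idx[, 1]],
                    variant_b = ids[idx[, 2]],
                    r = R[idx]))
}

#' Look up pairwise LD r
#'
#' Vectorized over pairs; identical ids return 1, unknown pairs return
#' `default` (0 by default).
#'
#' @param ld an `ld_ref` object.
#' @param a,b character vectors of variant ids (recycled to common
#'   length).
#' @param default value returned for pairs absent from the reference.
#' @return numeric vector of signed correlations.
#' @export
ld_r <- function(ld, a, b, default = 0) {
  stopifnot(inherits(ld, "ld_ref"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- unname(ld$r[key])
  out[is.na(out)] <- default
  out[a == b] <- 1
  out
}

#' Dense LD matrix for a set of variants
#'
#' @param ld an `ld_ref` object.
#' @param ids variant ids.
#' @param default fill value for pairs absent from the reference.
#' @return a `length(ids)` square signed-correlation matrix with unit
#'   diagonal.
#' @export
ld_matrix <- function(ld, ids, default = 0) {
  ids <- as.character(ids)
  p <- length(ids)
  R <- diag(1, p)
  dimnames(R) <- list(ids, ids)
  if (p > 1) {
    idx <- which(upper.tri(R), arr.ind = TRUE)
    r <- ld_r(ld, ids[idx[, 1]], ids[idx[, 2]], default = default)
    R[idx] <- r
    R[cbind(idx[, 2], idx[, 1])] <- r
  }
  R
}

#' Read / write the long three-column LD format
#'
#' Tab-delimited with header `variant_a variant_b r`.
#'
#' @param path file path (gzip handled transparently).
#' @return `read_ld()` returns an `ld_ref`; `write_ld()` returns `path`
#'   invisibly.
#' @export
read_ld <- function(path) {
  ld_ref(data.table::fread(path, header = TRUE, data.table = FALSE))
}

#' @rdname read_ld
#' @param ld an `ld_ref` to serialize.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_ref"))
  key <- names(ld$r)
  ab <- data.table::tstrsplit(key, "\r", fixed = TRUE)
  dt <- data.table::data.table(variant_a = ab[[1]], variant_b = ab[[2]],
                               r = unname(ld$r))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
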