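#' Preliminary druggability filter on the evidence matrix
#'
#' Retains genes satisfying all three requirements: membership in the
#' consolidated druggable-gene set, HEIDI status not `excluded` (a
#' mediation signal not attributable to linkage), and identification
#' by two or more distinct gene-identification approaches
#' (`method_count >= 2`).
#'
#' @param evidence evidence matrix from [build_evidence()].
#' @param druggable character vector of druggable gene ids (the union
#'   across drug databases).
#' @param min_methods minimum number of identification approaches
#'   (default 2).
#' @return character vector of retained gene ids.
#' @export
preliminary_filter <- function(evidence, druggable, min_methods = 2) {
  if (length(druggable) == 0) stop("empty druggable gene set")
  ev <- data.table::as.data.table(evidence)
  ev$gene_id[ev$gene_id %in% druggable &
               ev$heidi_status != "excluded" &
               ev$method_count >= min_methods]
}

#' Drop genes whose only known drugs carry excluded indications
#'
#' A gene is removed only when *all* of its drug records carry an
#' excluded indication term (case-insensitive substring match, default
#' `"oncology"`); one surviving indication keeps the gene.  Genes with
#' no drug records at all are retained (the indication filter only
#' acts on annotated indications).  Set `drop_records = TRUE` to
#' additionally strip the excluded records from the returned
#' annotation.
#'
#' @param genes character vector of candidate gene ids.
#' @param drugs drug-annotation table with columns `gene, drug, moa,
#'   indication`.
#' @param excluded_terms character vector of indication substrings to
#'   exclude (default `"oncology"`); empty vector is the identity.
#' @param drop_records also remove excluded records from the
#'   `"drugs"` attribute of the result (default `FALSE`).
#' @return character vector of surviving gene ids; attribute
#'   `"drugs"` holds the (possibly filtered) records for those genes.
#' @export
indication_filter <- function(genes, drugs, excluded_terms = "oncology",
                              drop_records = FALSE) {
  drugs <- data.table::as.data.table(drugs)
  if (length(excluded_terms) == 0) {
    out <- genes
    attr(out, "drugs") <- drugs[drugs$gene %in% genes]
    return(out)
  }
  excl <- rep(FALSE, nrow(drugs))
  for (term in excluded_terms)
    excl <- excl | grepl(term, drugs$indication, ignore.case = TRUE,
                         fixed = FALSE)
  all_excluded <- vapply(genes, function(g) {
    rec <- which(drugs$gene == g)
    length(rec) > 0 && all(excl[rec])
  }, logical(1))
  out <- genes[!all_excluded]
  keep <- drugs$gene %in% out & (!drop_records | !excl)
  attr(out, "drugs") <- drugs[keep]
  out
}

#' Predict required mechanism of action by eQTL direction voting
#'
#' One vote per `(source, tissue)` pair (duplicates within a pair are
#' collapsed by majority); higher cognitive ability associated with
#' up-regulation across more votes than down-regulation predicts an
#' agonist, the reverse an antagonist, and a tie is ambiguous (no
#' prediction, target eliminated downstream).
#'
#' @param directions data.table `source, tissue, sign` for one gene
#'   (signs in `{-1, +1}`).
#' @return list with `n_up`, `n_down`, `net_direction`
#'   (`up`/`down`/`ambiguous`) and `predicted_moa`
#'   (`agonist`/`antagonist`/`none`).
#' @export
direction_vote <- function(directions) {
  d <- data.table::as.data.table(directions)
  if (nrow(d) == 0L) {
    message("direction_vote: empty direction list")
    return(list(n_up = 0L, n_down = 0L, net_direction = "ambiguous",
                predicted_moa = "none"))
  }
  stopifnot(all(d$sign %in% c(-1L, 1L)))
  votes <- d[, list(v = sign(sum(sign))), by = list(source, tissue)]
  votes <- votes[v != 0]
  n_up <- sum(votes$v > 0)
  n_down <- sum(votes$v < 0)
  net <- if (n_up > n_down) "up" else if (n_down > n_up) "down"
         else "ambiguous"
  list(n_up = n_up, n_down = n_down, net_direction = net,
       predicted_moa = switch(net, up = "agonist", down = "antagonist",
                              ambiguous = "none"))
}

#' Default MOA-term synonym map
#'
#' Maps free-text mechanism-of-action vocabulary to the two predicted
#' classes: activation-like terms to `agonist`, inhibition-like terms
#' to `antagonist`.
#' @return named character vector (term -> class).
#' @export
default_moa_synonyms <- function() {
  c(agonist = "agonist", activator = "agonist",
    "positive allosteric modulator" = "agonist", opener = "agonist",
    antagonist = "antagonist", inhibitor = "antagonist",
    blocker = "antagonist",
    "negative allosteric modulator" = "antagonist")
}

.norm_text <- function(x) {
  x <- tolower(x)
  gsub("[[:punct:]]+", " ", x)
}

#' Match predicted mechanisms of action against drug annotations
#'
#' A drug record matches a gene when any synonym-mapped term in its
#' (lowercased, punctuation-stripped) MOA string agrees with the
#' gene's predicted MOA.  Matches are `direct` when the MOA string
#' also names the gene's own target class (per-gene keyword list),
#' otherwise `indirect`.  Genes with `predicted_moa = "none"` are not
#' matched.
#'
#' @param targets data.table with `gene_id` and `predicted_moa`
#'   (see [prioritize_targets()]).
#' @param drugs drug-annotation table `gene, drug, moa, indication`.
#' @param synonym_map term-to-class map; defaults to
#'   [default_moa_synonyms()].
#' @param direct_keywords optional named list: gene id -> character
#'   vector of target-class keywords whose presence in the MOA marks a
#'   direct match.
#' @return A `data.table` of matched records: `gene_id predicted_moa
#'   drug moa indication match_quality`.
#' @export
match_moa <- function(targets, drugs, synonym_map = default_moa_synonyms(),
                      direct_keywords = NULL) {
  targets <- data.table::as.data.table(targets)
  drugs <- data.table::as.data.table(drugs)
  out <- vector("list", 0L)
  terms <- .norm_text(names(synonym_map))
  # word-boundary patterns so e.g. "agonist" does not hit "antagonist"
  term_pat <- paste0("\\b", gsub("([^[:alnum:] ])", "\\\\\\1", terms),
                     "\\b")
  for (i in seq_len(nrow(targets))) {
    g <- targets$gene_id[i]
    pred <- targets$predicted_moa[i]
    if (pred == "none") next
    rec <- drugs[drugs$gene == g]
    if (nrow(rec) == 0L) next
    moa_txt <- .norm_text(rec$moa)
    hit <- vapply(moa_txt, function(m) {
      present <- vapply(term_pat, grepl, logical(1), x = m)
      any(synonym_map[present] == pred)
    }, logical(1), USE.NAMES = FALSE)
    if (!any(hit)) next
    rec <- rec[hit]
    moa_txt <- moa_txt[hit]
    quality <- rep("indirect", nrow(rec))
    kw <- direct_keywords[[g]]
    if (!is.null(kw)) {
      kw <- .norm_text(kw)
      direct <- vapply(moa_txt, function(m)
        any(vapply(kw, grepl, logical(1), x = m, fixed = TRUE)),
        logical(1), USE.NAMES = FALSE)
      quality[direct] <- "direct"
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      gene_id = g, predicted_moa = pred, drug = rec$drug,
      moa = rec$moa, indication = rec$indication,
      match_quality = quality)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table::data.table(
      gene_id = character(), predicted_moa = character(),
      drug = character(), moa = character(), indication = character(),
      match_quality = character())
  res[]
}

#' Full target-prioritization cascade
#'
#' Runs [preliminary_filter()], [indication_filter()],
#' [direction_vote()] per gene, and [match_moa()], producing the
#' ranked human-review table of candidate nootropic targets.
#' Ambiguous-direction genes (tied up/down votes) are eliminated.
#'
#' @param evidence evidence matrix from [build_evidence()] (its
#'   `"directions"` attribute supplies the votes unless `directions`
#'   is given).
#' @param druggable character vector of druggable gene ids.
#' @param drugs drug-annotation table `gene, drug, moa, indication`.
#' @param directions optional data.table `gene_id, source, tissue,
#'   sign`.
#' @param excluded_terms indication substrings to exclude (default
#'   `"oncology"`).
#' @param direct_keywords per-gene direct-match keyword list (see
#'   [match_moa()]).
#' @return list with
#'   * `targets`: per-gene table `gene_id n_up n_down net_direction
#'     predicted_moa n_matched` for all genes surviving the two
#'     filters (ambiguous genes included, marked, with 0 matches);
#'   * `matches`: the [match_moa()] record table;
#'   * `filtered`: gene ids after each stage (`preliminary`,
#'     `indication`, `unambiguous`).
#' @export
prioritize_targets <- function(evidence, druggable, drugs,
                               directions = NULL,
                               excluded_terms = "oncology",
                               direct_keywords = NULL) {
  drugs <- data.table::as.data.table(drugs)
  dirs <- directions %||% attr(evidence, "directions")
  dirs <- if (is.null(dirs)) .empty_directions()
          else data.table::as.data.table(dirs)

  prelim <- preliminary_filter(evidence, druggable)
  survivors <- as.character(indication_filter(prelim, drugs,
                                              excluded_terms))
  rows <- lapply(survivors, function(g) {
    v <- direction_vote(dirs[dirs$gene_id == g])
    data.table::data.table(gene_id = g, n_up = v$n_up,
                           n_down = v$n_down,
                           net_direction = v$net_direction,
                           predicted_moa = v$predicted_moa)
  })
  targets <- data.table::rbindlist(rows)
  if (nrow(targets) == 0L)
    targets <- data.table::data.table(
      gene_id = character(), n_up = integer(), n_down = integer(),
      net_direction = character(), predicted_moa = character())
  matches <- match_moa(targets, drugs, direct_keywords = direct_keywords)
  nm <- table(matches$gene_id)
  targets[, n_matched := as.integer(nm[gene_id])]
  targets[is.na(n_matched), n_matched := 0L]
  data.table::setorder(targets, -n_matched, gene_id)
  list(targets = targets[], matches = matches,
       filtered = list(preliminary = prelim, indication = survivors,
                       unambiguous = targets$gene_id[
                         targets$net_direction != "ambiguous"]))
}
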