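mk_evidence <- function(genes, heidi, counts) {
  data.table::data.table(gene_id = genes, method_count = counts,
                         heidi_status = heidi)
}

test_that("preliminary filter enforces all three requirements", {
  ev <- mk_evidence(c("a", "b", "c", "d"),
                    heidi = c("pass", "excluded", "pass", "untested"),
                    counts = c(3L, 2L, 1L, 2L))
  druggable <- c("a", "b", "c", "d")
  kept <- preliminary_filter(ev, druggable)
  expect_equal(kept, c("a", "d"))             # b HEIDI-excluded, c 1 method
  expect_equal(preliminary_filter(ev, c("d")), "d")
  expect_error(preliminary_filter(ev, character(0)), "empty druggable")
})

test_that("a 20-gene fixture with exactly 7 triple-qualified genes filters to 7", {
  set.seed(61)
  genes <- sprintf("g%02d", 1:20)
  druggable <- genes[1:12]                    # g13..g20 fail druggability
  heidi <- rep("pass", 20); heidi[c(2, 5)] <- "excluded"
  counts <- rep(3L, 20); counts[c(8, 9, 10)] <- 1L
  # qualifying: druggable(1:12) minus heidi-excluded {2,5} minus low-count
  # {8,9,10} -> {1,3,4,6,7,11,12} = 7 genes
  ev <- mk_evidence(genes, heidi = heidi, counts = counts)
  kept <- preliminary_filter(ev, druggable)
  expect_equal(kept, genes[c(1, 3, 4, 6, 7, 11, 12)])
})

test_that("indication filter drops only genes whose every drug is excluded", {
  drugs <- data.table::data.table(
    gene = c("a", "a", "b", "c"),
    drug = c("d1", "d2", "d3", "d4"),
    moa = "x inhibitor",
    indication = c("Oncology", "Epilepsy", "oncology; solid tumors",
                   "Hypertension"))
  out <- indication_filter(c("a", "b", "c"), drugs)
  expect_equal(as.character(out), c("a", "c"))  # a saved by Epilepsy record
  expect_equal(as.character(indication_filter(c("a", "b", "c"), drugs,
                                              excluded_terms = character(0))),
               c("a", "b", "c"))
  # genes without records pass through the indication stage
  expect_true("z" %in% indication_filter(c("z", "b"), drugs))
})

test_that("direction voting predicts MOA, is order-invariant, flips with signs", {
  d <- data.table::data.table(source = "eqtl",
                              tissue = c("t1", "t2", "t3", "t4"),
                              sign = c(1L, 1L, 1L, -1L))
  v <- direction_vote(d)
  expect_equal(v[c("n_up", "n_down")], list(n_up = 3L, n_down = 1L))
  expect_equal(v$net_direction, "up")
  expect_equal(v$predicted_moa, "agonist")
  expect_equal(direction_vote(d[sample(4)]), v)
  flipped <- data.table::copy(d)[, sign := -sign]
  expect_equal(direction_vote(flipped)$predicted_moa, "antagonist")
  tie <- direction_vote(d[tissue %in% c("t1", "t4")])
  expect_equal(tie$net_direction, "ambiguous")
  expect_equal(tie$predicted_moa, "none")
  empty <- suppressMessages(direction_vote(d[0]))
  expect_equal(empty$predicted_moa, "none")
  # duplicate (source, tissue) rows collapse to one majority vote
  dup <- data.table::data.table(source = "eqtl", tissue = "t1",
                                sign = c(1L, 1L, -1L))
  expect_equal(direction_vote(dup)$n_up, 1L)
})

test_that("MOA matching agrees with predicted direction, with direct/indirect quality", {
  targets <- data.table::data.table(
    gene_id = c("CA1", "CLCN2", "X1"),
    predicted_moa = c("antagonist", "agonist", "agonist"))
  drugs <- data.table::data.table(
    gene = c("CA1", "CLCN2", "X1", "CA1"),
    drug = c("Acetazolamide", "Lubiprostone", "DrugX", "OtherDrug"),
    moa = c("Carbonic anhydrase inhibitor", "Chloride channel activator",
            "Histamine receptor antagonist", "Glutamate receptor agonist"),
    indication = c("Glaucoma", "Constipation", "Allergy", "Epilepsy"))
  m <- match_moa(targets, drugs,
                 direct_keywords = list(CA1 = "carbonic anhydrase",
                                        CLCN2 = "chloride channel"))
  ca1 <- m[m$gene_id == "CA1"]
  expect_equal(ca1$drug, "Acetazolamide")     # agonist record disagrees
  expect_equal(ca1$match_quality, "direct")
  clcn2 <- m[m$gene_id == "CLCN2"]
  expect_equal(clcn2$match_quality, "direct")
  # predicted agonist vs "receptor antagonist": no match ("agonist"
  # inside "antagonist" must not count)
  expect_false("X1" %in% m$gene_id)
  # no matching attempted without a prediction
  none <- match_moa(data.table::data.table(gene_id = "CA1",
                                           predicted_moa = "none"), drugs)
  expect_equal(nrow(none), 0L)
})

test_that("the cascade is monotone and recovers planted targets end to end", {
  fx <- make_drug_fixture(seed = 62)
  ev <- build_evidence(fx$streams, directions = fx$directions,
                       heidi = fx$heidi)
  pri <- prioritize_targets(ev, fx$druggable, fx$drugs)
  # monotone shrinkage across filter stages
  expect_true(all(pri$filtered$indication %in% pri$filtered$preliminary))
  expect_true(all(pri$filtered$unambiguous %in% pri$filtered$indication))
  expect_true(all(pri$filtered$preliminary %in%
                    intersect(fx$druggable, ev$gene_id)))
  hits <- pri$targets[predicted_moa != "none" & n_matched > 0]$gene_id
  expect_setequal(hits, fx$truth$priority)
})
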