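taxonomy3 <- data.frame(taxon_id = c("tA", "tB", "tC"),
                        species = c("tA", "tB", "tC"),
                        genus = c("gAB", "gAB", "gC"))

test_that("precision and recall follow the read-level definitions", {
  # 4 reads: 3 mapped, 2 correctly -> precision 2/3, recall 1/2
  truth <- data.frame(read_id = paste0("r", 1:4), source_taxon = "tA")
  al <- alignment_table(read_id = c("r1", "r2", "r3"),
                        marker_id = c("tA|m1", "tA|m2", "tB|m1"),
                        taxon_id = c("tA", "tA", "tB"))
  ev <- score_mappings(al, truth, taxonomy3, rank = "species")
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 1 / 2)
  expect_equal(ev$n_mapped, 3L)
  # everything correct -> both 1
  al2 <- alignment_table(paste0("r", 1:4), "tA|m1", "tA")
  ev2 <- score_mappings(al2, truth, taxonomy3)
  expect_equal(c(ev2$precision, ev2$recall), c(1, 1))
  # nothing mapped -> recall 0, precision flagged undefined
  ev3 <- score_mappings(al2[0L, ], truth, taxonomy3)
  expect_equal(ev3$recall, 0)
  expect_true(is.na(ev3$precision))
  expect_false(ev3$precision_defined)
  # genus rank rescues a same-genus mismatch
  ev4 <- score_mappings(al, truth, taxonomy3, rank = "genus")
  expect_equal(ev4$precision, 1)
  expect_error(score_mappings(al, data.frame(read_id = "x",
                                             source_taxon = "tZ"),
                              taxonomy3), "tZ")
})

test_that("best-identity match with favorable ties; per-taxon table aggregates", {
  truth <- data.frame(read_id = c("r1", "r2"), source_taxon = c("tA", "tC"))
  # r1 ties between tA (correct) and tB at identity 0.99 -> correct
  # r2 best hit is tA (wrong) despite a lower tC alignment
  al <- alignment_table(
    read_id = c("r1", "r1", "r2", "r2"),
    marker_id = c("tA|m1", "tB|m1", "tA|m1", "tC|m1"),
    taxon_id = c("tA", "tB", "tA", "tC"),
    identity = c(0.99, 0.99, 0.98, 0.90))
  ev <- score_mappings(al, truth, taxonomy3)
  expect_equal(ev$n_correct, 1L)
  pt <- ev$per_taxon
  expect_equal(sum(pt$n_reads), ev$n_reads)
  expect_equal(sum(pt$n_mapped), ev$n_mapped)
  expect_equal(sum(pt$n_correct), ev$n_correct)
  expect_equal(pt$recall[pt$source_taxon == "tA"], 1)
  expect_equal(pt$recall[pt$source_taxon == "tC"], 0)
})

test_that("MAPQ filtering is a boundary-inclusive subset; recall non-increasing", {
  al <- alignment_table(read_id = paste0("r", 1:3),
                        marker_id = paste0("tA|m", 1:3), taxon_id = "tA",
                        mapq = c(29L, 30L, 42L))
  kept <- apply_mapq_filter(al, 30L)
  expect_equal(kept$mapq, c(30L, 42L))
  expect_equal(nrow(apply_mapq_filter(al, 0L)), 3L)
  al_na <- alignment_table("r1", "tA|m1", "tA", mapq = NA_integer_)
  expect_error(apply_mapq_filter(al_na), "MAPQ")
  # recall monotonicity across a MAPQ sweep on a mixed fixture
  truth <- data.frame(read_id = paste0("r", 1:3), source_taxon = "tA")
  recalls <- vapply(c(0L, 30L, 40L, 50L), function(mq)
    score_mappings(apply_mapq_filter(al, mq), truth, taxonomy3)$recall,
    numeric(1L))
  expect_true(all(diff(recalls) <= 0))
  # all-high-MAPQ fixture: the filter changes nothing
  hi <- alignment_table(paste0("r", 1:3), paste0("tA|m", 1:3), "tA",
                        mapq = 42L)
  expect_equal(as.data.frame(apply_mapq_filter(hi, 30L)), as.data.frame(hi))
})

test_that("pair outcomes are classified exhaustively", {
  mk <- function(labels, members = labels) data.table::data.table(
    label = labels, call_type = "unambiguous", member_taxa = members,
    n_reads = 2L, n_markers = 2L, identity_average = 1)
  expect_equal(classify_pair_outcome(mk(c("A", "B")), "A", "B")$category,
               "both_only")
  expect_equal(classify_pair_outcome(mk(c("A", "B", "C")), "A", "B")$category,
               "extra_taxa")
  expect_equal(classify_pair_outcome(mk(character(0)), "A", "B")$category,
               "none")
  expect_equal(classify_pair_outcome(mk("A"), "A", "B")$category, "A_only")
  expect_equal(classify_pair_outcome(mk("B"), "A", "B")$category, "B_only")
  # "?"-joined members count as detections of their member taxa
  amb <- mk("?A,B", members = "A,B")
  expect_equal(classify_pair_outcome(amb, "A", "B")$category, "both_only")
})

test_that("read flow tabulates best matches with fractional ties", {
  truth <- data.frame(read_id = c("r1", "r2", "r3"),
                      source_taxon = c("tA", "tA", "tB"))
  al <- alignment_table(
    read_id = c("r1", "r2", "r2"),
    marker_id = c("tA|m1", "tA|m1", "tB|m1"),
    taxon_id = c("tA", "tA", "tB"),
    identity = c(1, 0.99, 0.99))
  fl <- read_flow_table(al, truth)
  expect_equal(fl$n_reads[fl$source_taxon == "tA" & fl$match_taxon == "tA"],
               1.5)
  expect_equal(fl$n_reads[fl$source_taxon == "tA" & fl$match_taxon == "tB"],
               0.5)
  expect_equal(fl$n_reads[fl$source_taxon == "tB" & is.na(fl$match_taxon)], 1)
  expect_equal(sum(fl$n_reads), nrow(truth))
})
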