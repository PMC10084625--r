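# deduplicated alignment tables built directly; marker ids are globally
# unique ("tax|m") as produced by the reader

al_floor <- function(identity = 1) {
  alignment_table(read_id = c("r1", "r2"),
                  marker_id = c("tA|m1", "tA|m2"),
                  taxon_id = "tA", identity = identity)
}

test_that("length filter keeps alignments at the 60 nt boundary", {
  al <- alignment_table(read_id = c("r1", "r2", "r3"),
                        marker_id = c("tA|m1", "tA|m2", "tA|m3"),
                        taxon_id = "tA", aln_length = c(59L, 60L, 61L))
  kept <- filter_by_length(al, 60L)
  expect_equal(kept$aln_length, c(60L, 61L))
  expect_equal(nrow(filter_by_length(al[0L, ], 60L)), 0L)
  expect_equal(as.data.frame(filter_by_length(kept, 60L)), as.data.frame(kept))
})

test_that("marker graph counts distinct shared reads", {
  al <- alignment_table(
    read_id  = c("r1", "r1", "r2", "r2", "r3"),
    marker_id = c("tA|m1", "tB|m1", "tA|m1", "tB|m1", "tA|m2"),
    taxon_id = c("tA", "tB", "tA", "tB", "tA"))
  g <- build_marker_graph(al)
  expect_setequal(g$nodes, c("tA|m1", "tA|m2", "tB|m1"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 2)
  # one read on three markers -> unit triangle
  al3 <- alignment_table(read_id = "r1",
                         marker_id = c("tA|m1", "tA|m2", "tA|m3"),
                         taxon_id = "tA")
  g3 <- build_marker_graph(al3)
  expect_equal(nrow(g3$edges), 3L)
  expect_true(all(g3$edges$weight == 1))
  # no sharing -> edgeless
  expect_equal(nrow(build_marker_graph(al_floor())$edges), 0L)
})

test_that("inferior-marker rejection is strict on 'lower' and inclusive at 50%", {
  # one cluster of 4 markers of taxon tA with identities .99 .99 .95 .95:
  # cluster average .97; exactly 2 of 4 markers inferior -> rejected
  al <- alignment_table(
    read_id = paste0("r", 1:4), taxon_id = "tA",
    marker_id = paste0("tA|m", 1:4),
    identity = c(0.99, 0.99, 0.95, 0.95))
  clus <- structure(list(paste0("tA|m", 1:4)), class = "euk_clustering")
  st <- marker_stats(al, clus)
  expect_equal(unique(st$cluster_average), 0.97)
  expect_equal(reject_inferior_taxa(st, 0.5), character())
  # 1 of 4 inferior (0.25 < 0.5) -> survives
  al2 <- alignment_table(
    read_id = paste0("r", 1:4), taxon_id = "tA",
    marker_id = paste0("tA|m", 1:4),
    identity = c(0.99, 0.99, 0.99, 0.90))
  st2 <- marker_stats(al2, clus)
  expect_equal(reject_inferior_taxa(st2, 0.5), "tA")
  # singleton cluster: marker equals its own average, never inferior
  al3 <- alignment_table("r1", "tB|m1", "tB", identity = 0.5)
  st3 <- marker_stats(al3, structure(list("tB|m1"),
                                     class = "euk_clustering"))
  expect_equal(reject_inferior_taxa(st3, 0.5), "tB")
})

test_that("taxon graph counts multiply aligned reads between surviving taxa", {
  al <- alignment_table(
    read_id  = c("r1", "r1", paste0("s", 1:5), paste0("s", 1:5),
                 paste0("s", 1:5)),
    marker_id = c("tA|m1", "tB|m1", rep("tC|m1", 5), rep("tD|m1", 5),
                  rep("tE|m1", 5)),
    taxon_id = c("tA", "tB", rep("tC", 5), rep("tD", 5), rep("tE", 5)))
  g <- build_taxon_graph(al, c("tA", "tB", "tC", "tD", "tE"))
  ab <- g$edges[g$edges$from == "tA" & g$edges$to == "tB", ]
  expect_equal(ab$weight, 1)
  tri <- g$edges[g$edges$from %in% c("tC", "tD") & g$edges$to %in% c("tD", "tE"), ]
  expect_equal(nrow(tri), 3L)
  expect_true(all(tri$weight == 5))
  # restriction to surviving taxa drops other nodes
  g2 <- build_taxon_graph(al, c("tA", "tB"))
  expect_setequal(g2$nodes, c("tA", "tB"))
  # uniquely aligned reads -> edgeless graph
  expect_equal(nrow(build_taxon_graph(al_floor(), "tA")$edges), 0L)
})

single_cluster <- function(taxa) structure(list(taxa), class = "euk_clustering")

test_that("calling applies the unambiguous and strong-ambiguous rules", {
  th <- default_thresholds()
  # floor case: 2 reads / 2 markers / identity 0.98
  calls <- call_taxa(single_cluster("tA"), al_floor(0.98), th)
  expect_equal(calls$call_type, "unambiguous")
  expect_equal(calls$label, "tA")
  # below the floor: 1 read on 1 marker at identity 1
  one <- alignment_table("r1", "tA|m1", "tA")
  expect_equal(nrow(call_taxa(single_cluster("tA"), one, th)), 0L)
  # identity below 97%: not unambiguous even with plenty of evidence
  low <- alignment_table(paste0("r", 1:3), paste0("tA|m", 1:3), "tA",
                         identity = 0.9699)
  expect_equal(nrow(call_taxa(single_cluster("tA"), low, th)), 0L)
  expect_equal(call_taxa(single_cluster("tA"),
                         alignment_table(paste0("r", 1:3), paste0("tA|m", 1:3),
                                         "tA", identity = 0.97),
                         th)$call_type, "unambiguous")
})

ambiguous_cluster_al <- function(n_markers, n_reads, identity = 0.93) {
  # reads spread across two taxa; each read hits one marker of each taxon
  markers_a <- sprintf("t1|m%d", seq_len(ceiling(n_markers / 2)))
  markers_b <- sprintf("t2|m%d", seq_len(floor(n_markers / 2)))
  reads <- sprintf("r%d", seq_len(n_reads))
  alignment_table(
    read_id = c(reads, reads),
    marker_id = c(rep_len(markers_a, n_reads), rep_len(markers_b, n_reads)),
    taxon_id = rep(c("t1", "t2"), each = n_reads),
    identity = identity)
}

test_that("clusters without unambiguous members pool evidence into '?' calls", {
  th <- default_thresholds()
  cl <- single_cluster(c("t1", "t2"))
  # 5 markers / 10 reads, identity 0.93 -> one "?t1,t2" call
  ok <- call_taxa(cl, ambiguous_cluster_al(5L, 10L), th)
  expect_equal(ok$label, "?t1,t2")
  expect_equal(ok$call_type, "strong_ambiguous")
  expect_equal(ok$n_markers, 5L)
  expect_equal(ok$n_reads, 10L)
  # 3 markers / 20 reads -> marker floor unmet, dropped
  expect_equal(nrow(call_taxa(cl, ambiguous_cluster_al(3L, 20L), th)), 0L)
  # exactly at the floor: 4 markers / 8 reads -> reported
  expect_equal(nrow(call_taxa(cl, ambiguous_cluster_al(4L, 8L), th)), 1L)
  # one below on reads -> dropped
  expect_equal(nrow(call_taxa(cl, ambiguous_cluster_al(4L, 7L), th)), 0L)
})

test_that("unambiguous members suppress the rest of their cluster", {
  al <- data.table::rbindlist(list(
    alignment_table(c("r1", "r2"), c("tA|m1", "tA|m2"), "tA", identity = 1),
    alignment_table(paste0("q", 1:8),
                    rep(paste0("tB|m", 1:4), 2), "tB", identity = 0.9)))
  al <- alignment_table(al$read_id, al$marker_id, al$taxon_id,
                        identity = al$identity)
  calls <- call_taxa(single_cluster(c("tA", "tB")), al)
  expect_equal(calls$label, "tA")
  expect_equal(calls$call_type, "unambiguous")
})

test_that("member taxa across calls are disjoint and thresholds are monotone", {
  fx <- generate_fixture(scenario_confusable_pair(cross_fraction = 0.5),
                         seed = 9)
  al <- read_alignments(fx$sam)
  base <- detect_taxa(al)
  members <- unlist(strsplit(base$member_taxa, ","))
  expect_equal(anyDuplicated(members), 0L)
  # raising thresholds never increases the number of calls
  for (th in list(default_thresholds(unambiguous_min_reads = 10L),
                  default_thresholds(unambiguous_min_identity = 0.999,
                                     strong_ambiguous_min_reads = 50L),
                  default_thresholds(min_aln_length = 150L))) {
    expect_lte(nrow(detect_taxa(al, th)), nrow(base))
  }
})

test_that("uniquely aligned reads reduce calling to per-taxon thresholding", {
  al <- alignment_table(
    read_id = c("a1", "a2", "b1"),
    marker_id = c("tA|m1", "tA|m2", "tB|m1"),
    taxon_id = c("tA", "tA", "tB"))
  calls <- detect_taxa(al)
  stages <- attr(calls, "stages")
  expect_length(stages$taxon_clustering, 2L)  # every taxon its own cluster
  expect_equal(calls$label, "tA")             # tB below the 2-read floor
})
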