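# The seven-step decision procedure: length filter, marker clustering,
# inferior-marker rejection, taxon clustering, ambiguity-aware calling.

#' Default detection thresholds
#'
#' All thresholds are overridable; the defaults are the published ones:
#' alignments must be at least 60 nt long; an unambiguous hit needs average
#' identity >= 97% with >= 2 distinct reads on >= 2 distinct markers; a
#' cluster without an unambiguous member is reported as one strong
#' ambiguous hit when its pooled evidence spans >= 4 markers and >= 8
#' reads; a taxon is rejected when >= 50% of its aligned markers are
#' inferior to their cluster's identity average.
#'
#' @param min_aln_length Minimum alignment length in nucleotides.
#' @param unambiguous_min_identity Identity floor for unambiguous hits.
#' @param unambiguous_min_reads,unambiguous_min_markers Evidence floors for
#'   unambiguous hits.
#' @param strong_ambiguous_min_markers,strong_ambiguous_min_reads Evidence
#'   floors for strong ambiguous cluster hits.
#' @param inferior_marker_fraction Rejection fraction (inclusive boundary).
#' @return A named list of class `euk_thresholds`.
#' @export
default_thresholds <- function(min_aln_length = 60L,
                               unambiguous_min_identity = 0.97,
                               unambiguous_min_reads = 2L,
                               unambiguous_min_markers = 2L,
                               strong_ambiguous_min_markers = 4L,
                               strong_ambiguous_min_reads = 8L,
                               inferior_marker_fraction = 0.5) {
  th <- list(min_aln_length = as.integer(min_aln_length),
             unambiguous_min_identity = unambiguous_min_identity,
             unambiguous_min_reads = as.integer(unambiguous_min_reads),
             unambiguous_min_markers = as.integer(unambiguous_min_markers),
             strong_ambiguous_min_markers = as.integer(strong_ambiguous_min_markers),
             strong_ambiguous_min_reads = as.integer(strong_ambiguous_min_reads),
             inferior_marker_fraction = inferior_marker_fraction)
  ok <- vapply(th, function(x) is.finite(x) && x > 0, logical(1L))
  if (!all(ok)) stop("all thresholds must be positive finite numbers")
  if (th$unambiguous_min_identity > 1 || th$inferior_marker_fraction > 1) {
    stop("fractional thresholds must lie in (0, 1]")
  }
  structure(th, class = c("euk_thresholds", "list"))
}

#' Filter alignments by aligned query length
#'
#' Step 1: keep alignments at least `min_aln_length` nucleotides long
#' (boundary inclusive), preserving order.
#'
#' @param alignments A `euk_alignments` table.
#' @param min_aln_length Length cut in nucleotides (default 60).
#' @return The filtered table (attributes preserved).
#' @export
filter_by_length <- function(alignments, min_aln_length = 60L) {
  out <- alignments[alignments$aln_length >= min_aln_length, ]
  .copy_aln_attrs(out, alignments)
}

.copy_aln_attrs <- function(out, src) {
  data.table::setattr(out, "total_reads", attr(src, "total_reads"))
  if (!inherits(out, "euk_alignments")) {
    data.table::setattr(out, "class", c("euk_alignments", class(out)))
  }
  out
}

# count of distinct reads shared by each pair of groups (markers or taxa)
.shared_read_edges <- function(read_id, group) {
  dt <- unique(data.table::data.table(read_id = read_id, group = group))
  dt <- dt[, if (.N > 1L) {
    g <- sort(group)
    p <- utils::combn(g, 2L)
    list(from = p[1L, ], to = p[2L, ])
  }, by = read_id]
  if (nrow(dt) == 0L) {
    return(data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  e <- dt[, list(weight = as.numeric(.N)), by = c("from", "to")]
  as.data.frame(e)
}

#' Build the shared-alignment marker graph
#'
#' Step 2 input: marker genes are nodes; the weight of edge (m1, m2) is the
#' number of distinct reads aligned to both markers.
#'
#' @param alignments A deduplicated `euk_alignments` table.
#' @return A [weighted_graph()] over all markers with at least one alignment.
#' @export
build_marker_graph <- function(alignments) {
  weighted_graph(unique(alignments$marker_id),
                 .shared_read_edges(alignments$read_id, alignments$marker_id))
}

#' Per-marker identity summaries
#'
#' Step 3: aggregate alignment identities by marker. When a marker
#' clustering is supplied the cluster id and the cluster's identity average
#' (unweighted mean over member markers' averages) are attached.
#'
#' @param alignments A `euk_alignments` table.
#' @param marker_clustering Optional `euk_clustering` of the markers.
#' @param weighted If `TRUE` the cluster average weights markers by their
#'   alignment counts instead of the default unweighted marker mean.
#' @return `data.table` with columns `marker_id`, `taxon_id`,
#'   `identity_average`, `n_reads` (+ `cluster_id`, `cluster_average`).
#' @export
marker_stats <- function(alignments, marker_clustering = NULL,
                         weighted = FALSE) {
  identity <- read_id <- NULL
  st <- alignments[, list(identity_average = mean(identity),
                          n_reads = length(unique(read_id))),
                   by = c("marker_id", "taxon_id")]
  data.table::setorder(st, marker_id)
  if (!is.null(marker_clustering)) {
    mem <- cluster_membership(marker_clustering)
    st$cluster_id <- as.integer(mem[st$marker_id])
    if (anyNA(st$cluster_id)) stop("marker clustering does not cover all markers")
    identity_average <- n_reads <- NULL
    ca <- if (weighted) {
      st[, list(cluster_average = stats::weighted.mean(identity_average, n_reads)),
         by = "cluster_id"]
    } else {
      st[, list(cluster_average = mean(identity_average)), by = "cluster_id"]
    }
    st <- merge(st, ca, by = "cluster_id", sort = FALSE)
    data.table::setcolorder(st, c("marker_id", "taxon_id", "identity_average",
                                  "n_reads", "cluster_id", "cluster_average"))
  }
  st[]
}

#' Reject taxa dominated by inferior markers
#'
#' Steps 3-4: a marker is *inferior* when its identity average is strictly
#' lower than its marker cluster's average (the unweighted mean of member
#' markers' averages, so a singleton cluster is never inferior). A taxon is
#' rejected when the fraction of its aligned markers that are inferior
#' reaches `inferior_marker_fraction` (boundary inclusive: exactly 50%
#' rejects at the default). The denominator is the taxon's markers with at
#' least one surviving alignment, not its full reference complement.
#'
#' @param stats Output of [marker_stats()] including `cluster_average`.
#' @param inferior_marker_fraction Rejection boundary (default 0.5).
#' @return Character vector of surviving taxon ids (sorted).
#' @export
reject_inferior_taxa <- function(stats, inferior_marker_fraction = 0.5) {
  if (!"cluster_average" %in% names(stats)) {
    stop("stats must carry cluster averages; call marker_stats() with a clustering")
  }
  inferior <- stats$identity_average < stats$cluster_average
  tab <- data.table::data.table(taxon_id = stats$taxon_id, inferior = inferior)
  agg <- tab[, list(frac = mean(inferior)), by = "taxon_id"]
  sort(agg$taxon_id[agg$frac < inferior_marker_fraction])
}

#' Build the multiply-aligned-read taxon graph
#'
#' Step 5 input: surviving taxa are nodes; the weight of edge (tA, tB) is
#' the number of distinct reads having at least one alignment to a marker
#' of each.
#'
#' @param alignments A `euk_alignments` table.
#' @param surviving_taxa Character vector of taxa to keep.
#' @return A [weighted_graph()] over the surviving taxa.
#' @export
build_taxon_graph <- function(alignments, surviving_taxa) {
  al <- alignments[alignments$taxon_id %in% surviving_taxa, ]
  weighted_graph(surviving_taxa,
                 .shared_read_edges(al$read_id, al$taxon_id))
}

#' Call taxa from taxon clusters
#'
#' Steps 6-7. Within each taxon cluster: taxa meeting the unambiguous
#' criteria (identity average >= 97%, >= 2 distinct reads, >= 2 distinct
#' markers, by default) are each reported as an unambiguous hit and the
#' cluster's other members are rejected. A cluster with no unambiguous
#' member is reported as a single strong ambiguous hit when the union of
#' its evidence spans at least 4 distinct markers and 8 distinct reads,
#' labelled with the member taxa sorted lexicographically, comma-joined
#' and prefixed with `"?"`; otherwise the cluster is dropped.
#'
#' @param taxon_clustering A `euk_clustering` partitioning the surviving taxa.
#' @param alignments Alignments restricted to the surviving taxa.
#' @param thresholds A [default_thresholds()] list.
#' @return `data.table` of class `euk_calls` with columns `label`,
#'   `call_type`, `member_taxa` (comma-joined), `n_reads`, `n_markers`,
#'   `identity_average`, and the hidden evidence column `evidence_markers`
#'   used by quantification.
#' @export
call_taxa <- function(taxon_clustering, alignments,
                      thresholds = default_thresholds()) {
  al <- alignments[alignments$taxon_id %in% unlist(taxon_clustering), ]
  calls <- list()
  for (cluster in taxon_clustering) {
    cal <- al[al$taxon_id %in% cluster, ]
    if (nrow(cal) == 0L) next
    identity <- read_id <- marker_id <- NULL
    ts <- cal[, list(identity_average = mean(identity),
                     n_reads = length(unique(read_id)),
                     n_markers = length(unique(marker_id)),
                     evidence_markers = paste(sort(unique(marker_id)),
                                              collapse = ",")),
              by = "taxon_id"]
    unamb <- ts$identity_average >= thresholds$unambiguous_min_identity &
      ts$n_reads >= thresholds$unambiguous_min_reads &
      ts$n_markers >= thresholds$unambiguous_min_markers
    if (any(unamb)) {
      u <- ts[unamb, ]
      calls[[length(calls) + 1L]] <- data.table::data.table(
        label = u$taxon_id,
        call_type = "unambiguous",
        member_taxa = u$taxon_id,
        n_reads = u$n_reads,
        n_markers = u$n_markers,
        identity_average = u$identity_average,
        evidence_markers = u$evidence_markers)
    } else {
      n_markers <- length(unique(cal$marker_id))
      n_reads <- length(unique(cal$read_id))
      if (n_markers >= thresholds$strong_ambiguous_min_markers &&
          n_reads >= thresholds$strong_ambiguous_min_reads) {
        members <- sort(unique(cal$taxon_id))
        calls[[length(calls) + 1L]] <- data.table::data.table(
          label = paste0("?", paste(members, collapse = ",")),
          call_type = "strong_ambiguous",
          member_taxa = paste(members, collapse = ","),
          n_reads = n_reads,
          n_markers = n_markers,
          identity_average = mean(cal$identity),
          evidence_markers = paste(sort(unique(cal$marker_id)), collapse = ","))
      }
    }
  }
  out <- if (length(calls)) data.table::rbindlist(calls) else
    data.table::data.table(label = character(), call_type = character(),
                           member_taxa = character(), n_reads = integer(),
                           n_markers = integer(), identity_average = numeric(),
                           evidence_markers = character())
  data.table::setorder(out, label)
  data.table::setattr(out, "class", c("euk_calls", class(out)))
  out
}

#' Run the full detection procedure
#'
#' Executes the seven steps end to end: length filtering, marker-graph
#' Markov clustering, inferior-marker taxon rejection, taxon-graph Markov
#' clustering, and ambiguity-aware calling.
#'
#' @param alignments A `euk_alignments` table (from [read_alignments()]).
#' @param thresholds A [default_thresholds()] list.
#' @param inflation,max_iterations MCL parameters shared by both
#'   clustering passes.
#' @param verbose Log per-stage record counts via `message()`.
#' @return A `euk_calls` table; intermediate products (marker clustering,
#'   surviving taxa, taxon clustering, stage counts) are attached as the
#'   attribute `stages`.
#' @export
detect_taxa <- function(alignments, thresholds = default_thresholds(),
                        inflation = 2, max_iterations = 100L,
                        verbose = FALSE) {
  log <- function(...) if (verbose) message(...)
  log("alignments in: ", nrow(alignments))
  al <- filter_by_length(alignments, thresholds$min_aln_length)
  log("after length filter (>= ", thresholds$min_aln_length, " nt): ", nrow(al))
  if (nrow(al) == 0L) {
    out <- call_taxa(structure(list(), class = "euk_clustering"), al, thresholds)
    data.table::setattr(out, "stages", list(n_alignments = 0L))
    return(out)
  }
  mg <- build_marker_graph(al)
  mcl_markers <- mcl(mg, inflation = inflation, max_iterations = max_iterations)
  st <- marker_stats(al, mcl_markers)
  surviving <- reject_inferior_taxa(st, thresholds$inferior_marker_fraction)
  log("taxa surviving inferior-marker rejection: ", length(surviving),
      " of ", length(unique(al$taxon_id)))
  al_surv <- .copy_aln_attrs(al[al$taxon_id %in% surviving, ], al)
  tg <- build_taxon_graph(al_surv, surviving)
  mcl_taxa <- mcl(tg, inflation = inflation, max_iterations = max_iterations)
  out <- call_taxa(mcl_taxa, al_surv, thresholds)
  log("calls: ", nrow(out))
  data.table::setattr(out, "stages", list(
    n_alignments = nrow(al),
    marker_clustering = mcl_markers,
    marker_stats = st,
    surviving_taxa = surviving,
    taxon_clustering = mcl_taxa))
  out
}
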