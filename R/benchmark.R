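# Precision/recall scoring of read mappings against truth, MAPQ-filter
# evaluation and pair-outcome classification.

#' Score read mappings against a truth table
#'
#' OPAL-style read-level metrics: a read's *match* is the taxon of its
#' best-identity alignment (ties resolved favourably: the read counts as
#' correct when any tied match is correct). A mapping is correct when the
#' source and match taxa share the lineage entry at `rank` (species for
#' same-reference evaluations, genus for holdout evaluations). Precision is
#' the fraction of correctly mapped reads among mapped reads; recall is the
#' fraction of correctly mapped reads among all reads.
#'
#' @param alignments A `euk_alignments` table.
#' @param truth `data.frame(read_id, source_taxon)` covering every
#'   simulated read.
#' @param taxonomy `data.frame` with column `taxon_id` plus one column per
#'   rank (e.g. `species`, `genus`).
#' @param rank Rank at which source and match must agree.
#' @return A list of class `euk_eval`: `n_reads`, `n_mapped`, `n_correct`,
#'   `precision` (NA with `precision_defined = FALSE` when nothing
#'   mapped), `recall`, and `per_taxon`, the same metrics grouped by
#'   source taxon.
#' @export
score_mappings <- function(alignments, truth, taxonomy, rank = "species") {
  stopifnot(all(c("read_id", "source_taxon") %in% names(truth)),
            "taxon_id" %in% names(taxonomy), rank %in% names(taxonomy))
  lineage <- stats::setNames(as.character(taxonomy[[rank]]), taxonomy$taxon_id)
  missing_src <- setdiff(unique(truth$source_taxon), names(lineage))
  if (length(missing_src)) {
    stop("truth taxa absent from taxonomy: ",
         paste(missing_src, collapse = ", "))
  }
  missing_match <- setdiff(unique(alignments$taxon_id), names(lineage))
  if (length(missing_match)) {
    stop("matched taxa absent from taxonomy: ",
         paste(missing_match, collapse = ", "))
  }

  al <- data.table::as.data.table(alignments)
  identity <- read_id <- taxon_id <- NULL
  best <- if (nrow(al) > 0L) {
    al[, list(taxon_id = taxon_id[identity == max(identity)]), by = "read_id"]
  } else {
    data.table::data.table(read_id = character(), taxon_id = character())
  }

  truth <- data.table::as.data.table(truth)[, c("read_id", "source_taxon"),
                                            with = FALSE]
  m <- merge(truth, best, by = "read_id", all.x = TRUE,
             allow.cartesian = TRUE)
  source_taxon <- NULL
  per_read <- m[, list(
    source_taxon = source_taxon[1L],
    mapped = !all(is.na(taxon_id)),
    correct = any(!is.na(taxon_id) &
                    lineage[taxon_id] == lineage[source_taxon[1L]])),
    by = "read_id"]

  summarize <- function(d) {
    n_reads <- nrow(d)
    n_mapped <- sum(d$mapped)
    n_correct <- sum(d$correct)
    list(n_reads = n_reads, n_mapped = n_mapped, n_correct = n_correct,
         precision = if (n_mapped > 0) n_correct / n_mapped else NA_real_,
         precision_defined = n_mapped > 0,
         recall = if (n_reads > 0) n_correct / n_reads else NA_real_)
  }
  mapped <- correct <- NULL
  per_taxon <- per_read[, {
    s <- summarize(.SD)
    data.table::as.data.table(s)
  }, by = "source_taxon"]
  data.table::setorder(per_taxon, source_taxon)
  out <- summarize(per_read)
  out$per_taxon <- per_taxon
  structure(out, class = "euk_eval")
}

#' @export
print.euk_eval <- function(x, ...) {
  cat(sprintf("euk_eval: %d reads, %d mapped, %d correct; precision %s, recall %.4g\n",
              x$n_reads, x$n_mapped, x$n_correct,
              if (x$precision_defined) sprintf("%.4g", x$precision) else "undefined",
              x$recall))
  invisible(x)
}

#' Filter alignments by mapping quality
#'
#' Keeps exactly the records with `mapq >= min_mapq`. The published
#' baseline filter uses MAPQ >= 30.
#'
#' @param alignments A `euk_alignments` table carrying MAPQ.
#' @param min_mapq Threshold (default 30).
#' @return The filtered table.
#' @export
apply_mapq_filter <- function(alignments, min_mapq = 30L) {
  if (anyNA(alignments$mapq)) {
    stop("alignments lack MAPQ values; cannot apply MAPQ filter")
  }
  out <- alignments[alignments$mapq >= min_mapq, ]
  .copy_aln_attrs(out, alignments)
}

#' Classify the outcome of a two-taxon detection experiment
#'
#' Given the calls produced on a simulated sample containing the taxon
#' pair (A, B): `both_only` when exactly {A, B} were detected, `A_only` /
#' `B_only` for a single correct detection with nothing else, `extra_taxa`
#' when any taxon outside the pair was reported, `none` when nothing was.
#'
#' @param calls A `euk_calls` table.
#' @param taxon_a,taxon_b The pair.
#' @return List of class `euk_pair_outcome`: `category` and `detected`
#'   (the set of reported member taxa).
#' @export
classify_pair_outcome <- function(calls, taxon_a, taxon_b) {
  detected <- sort(unique(unlist(
    strsplit(calls$member_taxa, ",", fixed = TRUE))))
  category <- if (length(detected) == 0L) {
    "none"
  } else if (length(setdiff(detected, c(taxon_a, taxon_b))) > 0L) {
    "extra_taxa"
  } else if (setequal(detected, c(taxon_a, taxon_b))) {
    "both_only"
  } else if (identical(detected, taxon_a)) {
    "A_only"
  } else {
    "B_only"
  }
  structure(list(category = category, detected = detected),
            class = "euk_pair_outcome")
}

#' Tabulate read flow from an evaluation
#'
#' Collapses best-identity matches into a (source, match) read-count table
#' consumed by the confusability analysis. Ties contribute fractionally
#' (a read tied between k matches adds 1/k to each).
#'
#' @param alignments A `euk_alignments` table.
#' @param truth `data.frame(read_id, source_taxon)`.
#' @return `data.table(source_taxon, match_taxon, n_reads)` including
#'   unmapped reads as `match_taxon = NA`.
#' @export
read_flow_table <- function(alignments, truth) {
  al <- data.table::as.data.table(alignments)
  identity <- taxon_id <- NULL
  best <- if (nrow(al) > 0L) {
    al[, list(match_taxon = unique(taxon_id[identity == max(identity)])),
       by = "read_id"]
  } else {
    data.table::data.table(read_id = character(), match_taxon = character())
  }
  best[, "w" := 1 / .N, by = "read_id"]
  truth <- data.table::as.data.table(truth)[, c("read_id", "source_taxon"),
                                            with = FALSE]
  m <- merge(truth, best, by = "read_id", all.x = TRUE)
  m$w[is.na(m$w)] <- 1
  w <- NULL
  out <- m[, list(n_reads = sum(w)), by = c("source_taxon", "match_taxon")]
  data.table::setorder(out, source_taxon, match_taxon, na.last = TRUE)
  out[]
}
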