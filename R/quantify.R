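# Copies-per-million quantification and report I/O.

#' Copies per million for one call
#'
#' CPM follows the reads-per-kilobase-over-depth convention used by
#' integrated metagenomic profilers:
#' `CPM = (R / (L / 1000)) / (D / 1e6)`, where `R` is the number of
#' distinct reads assigned to the call, `L` the summed length in
#' nucleotides of the call's evidence markers (the union across member
#' taxa for ambiguous calls), and `D` the sequencing depth in reads.
#'
#' @param n_reads Distinct reads assigned to the call.
#' @param marker_length_total Summed evidence-marker length, nt.
#' @param total_reads Sequencing depth `D` (> 0).
#' @return CPM, a non-negative number.
#' @export
compute_cpm <- function(n_reads, marker_length_total, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads (sequencing depth) must be > 0")
  if (any(marker_length_total <= 0)) stop("summed marker length must be > 0")
  (n_reads / (marker_length_total / 1000)) / (total_reads / 1e6)
}

#' Attach CPM values to a call table
#'
#' @param calls A `euk_calls` table from [call_taxa()] / [detect_taxa()].
#' @param reference A [marker_reference()] providing marker lengths.
#' @param total_reads Sequencing depth; defaults to the `total_reads`
#'   attribute carried by the alignment table through the pipeline (pass
#'   explicitly when the SAM lacked unmapped reads).
#' @param mode `"depth"` (default, absolute depth normalization) or
#'   `"sum-normalized"` (reads-per-kilobase rescaled to sum to 1e6 across
#'   calls, a community-relative dialect).
#' @return The call table with a `cpm` column, ordered by descending CPM
#'   then label.
#' @export
quantify_calls <- function(calls, reference, total_reads,
                           mode = c("depth", "sum-normalized")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "marker_reference"))
  if (nrow(calls) == 0L) {
    out <- data.table::copy(calls)
    out$cpm <- numeric(0)
    return(.as_calls(out))
  }
  lens <- stats::setNames(reference$marker_length, reference$marker_id)
  L <- vapply(strsplit(calls$evidence_markers, ",", fixed = TRUE),
              function(m) {
                if (anyNA(lens[m])) {
                  stop("marker length unknown for evidence marker(s): ",
                       paste(m[is.na(lens[m])], collapse = ", "))
                }
                sum(lens[m])
              }, numeric(1L))
  out <- data.table::copy(calls)
  if (mode == "depth") {
    if (missing(total_reads) || is.null(total_reads)) {
      stop("total_reads is required in depth mode")
    }
    out$cpm <- compute_cpm(out$n_reads, L, total_reads)
  } else {
    rpk <- out$n_reads / (L / 1000)
    out$cpm <- rpk / sum(rpk) * 1e6
  }
  data.table::setorder(out, -cpm, label)
  .as_calls(out)
}

.as_calls <- function(x) {
  if (!inherits(x, "euk_calls")) {
    data.table::setattr(x, "class", c("euk_calls", class(x)))
  }
  x
}

#' Write the taxon-call report
#'
#' TSV with columns `label`, `call_type`, `member_taxa`, `n_reads`,
#' `n_markers`, `identity_average`, `cpm`; one row per call, ordered by
#' descending CPM with lexicographic label tie-break.
#'
#' @param calls A quantified `euk_calls` table (a missing `cpm` column is
#'   written as `NA`).
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_report <- function(calls, destination) {
  cols <- c("label", "call_type", "member_taxa", "n_reads", "n_markers",
            "identity_average", "cpm")
  out <- data.table::as.data.table(calls)
  if (!"cpm" %in% names(out)) out$cpm <- NA_real_
  out <- out[, cols, with = FALSE]
  data.table::setorder(out, -cpm, label, na.last = FALSE)
  ok <- tryCatch({
    data.table::fwrite(out, destination, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write report to '", destination,
                              "': ", conditionMessage(e)))
  invisible(destination)
}

#' Read a taxon-call report back
#'
#' @param path A TSV written by [write_report()].
#' @return A `euk_calls` data.table.
#' @export
read_report <- function(path) {
  out <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("label", "call_type", "member_taxa"),
    integer = c("n_reads", "n_markers"),
    numeric = c("identity_average", "cpm")))
  .as_calls(out)
}
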