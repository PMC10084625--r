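# Ingestion of SAM/BAM marker alignments and reference metadata.

#' Marker-name parsing configuration
#'
#' Reference sequence names encode the source taxon and the marker gene,
#' e.g. `"Candida_albicans|BUSCO123"`. A configuration is either a single
#' delimiter character (the name is split at its *first* occurrence: taxon
#' before, marker label after) or a regular expression with exactly two
#' capture groups `(taxon, marker)`.
#'
#' @param delimiter Single character used to split names (default `"|"`).
#' @param pattern Optional regular expression with two capture groups;
#'   overrides `delimiter` when supplied.
#' @return An object of class `marker_parse_config`.
#' @export
marker_parse_config <- function(delimiter = "|", pattern = NULL) {
  if (is.null(pattern)) {
    stopifnot(is.character(delimiter), length(delimiter) == 1L, nchar(delimiter) == 1L)
  } else {
    stopifnot(is.character(pattern), length(pattern) == 1L)
  }
  structure(list(delimiter = delimiter, pattern = pattern),
            class = "marker_parse_config")
}

#' Split reference sequence names into taxon and marker label
#'
#' Deterministic split at the first delimiter: `"taxA|m1|extra"` yields
#' taxon `"taxA"` and marker label `"m1|extra"`. With a `pattern`
#' configuration the two capture groups are used instead.
#'
#' @param sequence_name Character vector of reference sequence names.
#' @param config A [marker_parse_config()].
#' @return A `data.frame` with columns `taxon_id` and `marker_id` (the
#'   within-taxon marker label). Note that the pipeline itself keys markers
#'   by the full sequence name, which is globally unique; the label
#'   returned here may recur across taxa.
#' @export
parse_marker_taxon <- function(sequence_name, config = marker_parse_config()) {
  stopifnot(inherits(config, "marker_parse_config"))
  if (length(sequence_name) == 0L) {
    return(data.frame(taxon_id = character(), marker_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(config$pattern)) {
    pos <- regexpr(config$delimiter, sequence_name, fixed = TRUE)
    bad <- pos < 0L
    if (any(bad)) {
      stop("cannot parse marker name(s): ",
           paste(utils::head(sequence_name[bad], 5L), collapse = ", "),
           " (no '", config$delimiter, "' delimiter)")
    }
    taxon <- substr(sequence_name, 1L, pos - 1L)
    marker <- substr(sequence_name, pos + 1L, nchar(sequence_name))
  } else {
    m <- regexec(config$pattern, sequence_name)
    parts <- regmatches(sequence_name, m)
    bad <- vapply(parts, length, 1L) != 3L
    if (any(bad)) {
      stop("cannot parse marker name(s): ",
           paste(utils::head(sequence_name[bad], 5L), collapse = ", "),
           " (pattern did not match with two capture groups)")
    }
    taxon <- vapply(parts, `[`, "", 2L)
    marker <- vapply(parts, `[`, "", 3L)
  }
  if (any(taxon == "") || any(marker == "")) {
    bad <- sequence_name[taxon == "" | marker == ""]
    stop("cannot parse marker name(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         " (empty taxon or marker part)")
  }
  data.frame(taxon_id = taxon, marker_id = marker, stringsAsFactors = FALSE)
}

#' Build a marker reference table
#'
#' Maps each reference sequence (one marker gene) to its taxon and length.
#' The table is built either from a marker FASTA or from the `@SQ` header
#' lines of a SAM/BAM file.
#'
#' @param source Path to a FASTA (`.fa`, `.fasta`) or SAM/BAM file, or a
#'   named integer vector of sequence lengths.
#' @param config A [marker_parse_config()].
#' @return A `data.frame` of class `marker_reference` with columns
#'   `marker_id` (full sequence name, unique), `taxon_id`, `marker_label`
#'   and `marker_length`.
#' @export
marker_reference <- function(source, config = marker_parse_config()) {
  if (is.numeric(source)) {
    lens <- as.integer(source)
    names(lens) <- names(source)
  } else {
    stopifnot(is.character(source), length(source) == 1L, file.exists(source))
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("fa", "fasta", "fna")) {
      seqs <- Biostrings::readDNAStringSet(source)
      lens <- stats::setNames(Biostrings::width(seqs),
                              sub("\\s.*$", "", names(seqs)))
    } else {
      bam <- .as_bam(source)
      targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
      lens <- targets
    }
  }
  if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
    stop("reference sequences must be named")
  }
  if (anyDuplicated(names(lens))) {
    stop("duplicate marker sequence names in reference")
  }
  if (any(lens < 1L)) stop("marker lengths must be >= 1")
  parsed <- parse_marker_taxon(names(lens), config)
  out <- data.frame(marker_id = names(lens),
                    taxon_id = parsed$taxon_id,
                    marker_label = parsed$marker_id,
                    marker_length = as.integer(lens),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_reference", "data.frame")
  out
}

# SAM input goes through samtools (Rsamtools) conversion; BAM passes through.
.as_bam <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Read marker alignments from SAM/BAM into the canonical alignment table
#'
#' Produces one row per (read, marker) pair. All alignments are retained
#' (including secondary/supplementary, i.e. the aligner is expected to have
#' run in all-alignments mode); when the same read aligns more than once to
#' the same marker only the highest-identity alignment is kept. Unmapped
#' records are skipped but counted towards the sequencing depth attribute.
#'
#' Identity is computed from the standard edit-distance tag as
#' `(aln_length - NM) / aln_length` where `aln_length` is the aligned
#' portion of the query (CIGAR operations that consume the query, soft
#' clips excluded). `coverage_fraction` is the reference span of the
#' alignment divided by the marker length. Paired-end mates are distinct
#' reads: `read_id` is the query name suffixed with `/1` or `/2`.
#'
#' @param sam_source Path to a SAM or BAM file with `@SQ` headers carrying
#'   lengths for every aligned marker.
#' @param reference Optional [marker_reference()]; built from the file's
#'   own `@SQ` headers when omitted.
#' @param config A [marker_parse_config()] used when `reference` is built
#'   from the headers.
#' @return A `data.table` of class `euk_alignments` with columns `read_id`,
#'   `marker_id`, `taxon_id`, `aln_length`, `identity`,
#'   `coverage_fraction`, `mapq`; attribute `total_reads` holds the number
#'   of distinct reads seen in the file (mapped + unmapped).
#' @export
read_alignments <- function(sam_source, reference = NULL,
                            config = marker_parse_config()) {
  stopifnot(file.exists(sam_source))
  bam <- .as_bam(sam_source)
  if (is.null(reference)) reference <- marker_reference(bam, config)
  stopifnot(inherits(reference, "marker_reference"))

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]

  flag <- res$flag
  paired <- bitwAnd(flag, 0x1L) > 0L
  first <- bitwAnd(flag, 0x40L) > 0L
  mate <- ifelse(paired, ifelse(first, "/1", "/2"), "")
  read_id_all <- paste0(res$qname, mate)

  unmapped <- bitwAnd(flag, 0x4L) > 0L
  total_reads <- length(unique(read_id_all))

  keep <- !unmapped
  if (!any(keep)) {
    out <- data.table::data.table(
      read_id = character(), marker_id = character(), taxon_id = character(),
      aln_length = integer(), identity = numeric(),
      coverage_fraction = numeric(), mapq = integer())
    data.table::setattr(out, "total_reads", total_reads)
    data.table::setattr(out, "class", c("euk_alignments", class(out)))
    return(out)
  }

  cigar <- res$cigar[keep]
  nm <- res$tag$NM[keep]
  marker <- as.character(res$rname[keep])
  read_id <- read_id_all[keep]

  if (is.null(nm) || anyNA(nm)) {
    bad <- if (is.null(nm)) read_id else read_id[is.na(nm)]
    stop("missing NM (edit distance) tag for read(s): ",
         paste(utils::head(unique(bad), 5L), collapse = ", "))
  }

  aln_len <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE)
  ref_span <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)

  idx <- match(marker, reference$marker_id)
  if (anyNA(idx)) {
    stop("no @SQ length / reference entry for marker(s): ",
         paste(utils::head(unique(marker[is.na(idx)]), 5L), collapse = ", "))
  }

  al <- data.table::data.table(
    read_id = read_id,
    marker_id = marker,
    taxon_id = reference$taxon_id[idx],
    aln_length = as.integer(aln_len),
    identity = (aln_len - nm) / aln_len,
    coverage_fraction = ref_span / reference$marker_length[idx],
    mapq = as.integer(res$mapq[keep]))

  # dedup per (read, marker): keep the best identity, stable on ties
  data.table::setorder(al, read_id, marker_id, -identity)
  al <- unique(al, by = c("read_id", "marker_id"))
  data.table::setattr(al, "total_reads", total_reads)
  data.table::setattr(al, "class", c("euk_alignments", class(al)))
  al
}

#' Construct an alignment table directly (in-memory fixture path)
#'
#' Convenience constructor used by tests and simulations to bypass SAM
#' round-trips. Applies the same (read, marker) deduplication rule as
#' [read_alignments()].
#'
#' @param read_id,marker_id,taxon_id Character vectors.
#' @param aln_length Integer aligned query lengths.
#' @param identity Numeric identities in `[0, 1]`.
#' @param coverage_fraction Numeric in `(0, 1]`; defaults to 0.1.
#' @param mapq Integer MAPQ values; default 42.
#' @param total_reads Sequencing depth attribute; defaults to the number of
#'   distinct `read_id`s.
#' @return A `euk_alignments` data.table.
#' @export
alignment_table <- function(read_id, marker_id, taxon_id,
                            aln_length = 100L, identity = 1,
                            coverage_fraction = 0.1, mapq = 42L,
                            total_reads = NULL) {
  al <- data.table::data.table(
    read_id = as.character(read_id),
    marker_id = as.character(marker_id),
    taxon_id = as.character(taxon_id),
    aln_length = as.integer(aln_length),
    identity = as.numeric(identity),
    coverage_fraction = as.numeric(coverage_fraction),
    mapq = as.integer(mapq))
  stopifnot(all(al$identity >= 0 & al$identity <= 1),
            all(al$aln_length >= 1L),
            all(al$coverage_fraction > 0 & al$coverage_fraction <= 1))
  data.table::setorder(al, read_id, marker_id, -identity)
  al <- unique(al, by = c("read_id", "marker_id"))
  if (is.null(total_reads)) total_reads <- length(unique(al$read_id))
  data.table::setattr(al, "total_reads", as.integer(total_reads))
  data.table::setattr(al, "class", c("euk_alignments", class(al)))
  al
}
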