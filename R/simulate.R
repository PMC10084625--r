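# Truth-labelled read simulation from marker references and synthetic
# fixture generation (marker FASTA, taxonomy TSV, truth table, SAM).
#
# The simulator emulates a wgsim-style protocol: 100 bp reads sampled
# uniformly with base error rate 0, optionally mutated afterwards to mimic
# strain divergence from the reference.

#' Reads needed to reach a target fold-coverage
#'
#' Lander-Waterman: `N = round(coverage * marker_length / read_length)`,
#' rounding half away from zero. Markers shorter than the read length are
#' skipped (0 reads), mirroring simulators that refuse to source reads
#' from fragments shorter than the read.
#'
#' @param marker_length Marker length, nt.
#' @param coverage Target fold-coverage (e.g. 0.1).
#' @param read_length Read length, nt (default 100).
#' @return Integer read count (vectorized over `marker_length`).
#' @export
reads_for_coverage <- function(marker_length, coverage, read_length = 100L) {
  stopifnot(all(marker_length > 0), coverage > 0, read_length > 0)
  n <- floor(coverage * marker_length / read_length + 0.5)
  n[marker_length < read_length] <- 0
  as.integer(n)
}

#' Sample error-free reads from a marker reference
#'
#' Each marker contributes [reads_for_coverage()] reads with uniform random
#' start positions; reads are exact substrings of their source marker
#' (base error rate 0). Read names encode provenance as
#' `taxon:markerLabel:start:index` (start 0-based).
#'
#' @param reference_fasta Path to a marker FASTA, or a named
#'   `DNAStringSet` / named character vector of sequences.
#' @param coverage Target fold-coverage per marker.
#' @param read_length Read length, nt.
#' @param seed Integer RNG seed (required; the simulation is fully
#'   reproducible from it).
#' @param config [marker_parse_config()] for sequence names.
#' @return `data.table` with columns `read_id`, `source_taxon`,
#'   `source_marker` (full sequence name), `start` (0-based), `sequence`,
#'   `mutation_rate` (0 here); markers skipped as too short are listed in
#'   the `skipped_markers` attribute.
#' @export
sample_reads <- function(reference_fasta, coverage, read_length = 100L,
                         seed, config = marker_parse_config()) {
  stopifnot(!missing(seed))
  seqs <- .as_sequences(reference_fasta)
  if (length(seqs) == 0L) stop("empty reference: no marker sequences")
  parsed <- parse_marker_taxon(names(seqs), config)
  set.seed(as.integer(seed))
  lens <- nchar(seqs)
  counts <- reads_for_coverage(lens, coverage, read_length)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    n <- counts[i]
    if (n == 0L) next
    starts <- sample.int(lens[i] - read_length + 1L, n, replace = TRUE) - 1L
    rows[[i]] <- data.table::data.table(
      read_id = sprintf("%s:%s:%d:%d", parsed$taxon_id[i],
                        parsed$marker_id[i], starts, seq_len(n)),
      source_taxon = parsed$taxon_id[i],
      source_marker = names(seqs)[i],
      start = starts,
      sequence = substring(seqs[i], starts + 1L, starts + read_length),
      mutation_rate = 0)
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(read_id = character(),
                                  source_taxon = character(),
                                  source_marker = character(),
                                  start = integer(), sequence = character(),
                                  mutation_rate = numeric())
  }
  data.table::setattr(out, "skipped_markers",
                      names(seqs)[lens < read_length])
  out
}

.as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    .as_sequences(Biostrings::readDNAStringSet(x))
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else {
    stop("reference must be a FASTA path or a named sequence set")
  }
}

#' Mutate reads by independent base substitution
#'
#' Every base is substituted with probability `mutation_rate`, drawing
#' uniformly among the three other bases (no indels). Used to emulate a
#' novel strain diverging from the reference.
#'
#' @param reads A read table from [sample_reads()].
#' @param mutation_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return The read table with mutated `sequence` and updated
#'   `mutation_rate`.
#' @export
mutate_reads <- function(reads, mutation_rate, seed) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, !missing(seed))
  out <- data.table::copy(reads)
  if (mutation_rate == 0 || nrow(out) == 0L) return(out)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  out$sequence <- vapply(out$sequence, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(v)) < mutation_rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L), "")
    }
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
  out$mutation_rate <- mutation_rate
  out
}

#' Write reads as FASTQ
#'
#' Constant maximum base quality ("I"), consistent with an error-free
#' simulation.
#'
#' @param reads A read table from [sample_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

# ---- synthetic fixtures ----------------------------------------------------

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Describe a synthetic fixture scenario
#'
#' A scenario states the world a fixture emulates: which taxa exist, how
#' many markers each has and how long they are, how many reads each taxon
#' contributes and at what identity/MAPQ, which taxon pairs cross-map and
#' at what fraction, and which truth taxa are absent from the reference
#' (holdout). [generate_fixture()] turns it into files.
#'
#' @param taxa Character vector of taxon ids present in the reference.
#' @param markers_per_taxon Markers per taxon (scalar or named vector).
#' @param marker_length Marker length, nt (scalar or named by taxon).
#' @param read_length Read length, nt.
#' @param reads_per_taxon Reads sourced per reference taxon (scalar or
#'   named), distributed round-robin over the taxon's markers.
#' @param identity Alignment identity of a read to its own taxon's markers.
#' @param mapq MAPQ reported for unique alignments.
#' @param cross_map Optional `data.frame(from, to, fraction, identity,
#'   mapq)`: that fraction of `from`'s reads additionally aligns to the
#'   corresponding marker of `to` (secondary alignment at the given
#'   identity; `mapq` of the *primary* alignment of such multi-mapping
#'   reads drops to the given value, default 3, as aligners do).
#' @param holdout Optional `data.frame(taxon, maps_to, identity,
#'   reads)`: truth taxa absent from the reference whose reads align to
#'   `maps_to`'s markers at the given identity.
#' @param genus Optional named vector mapping taxon id to genus; default
#'   is the part of the taxon id before the first underscore.
#' @return A list of class `euk_scenario`.
#' @export
fixture_scenario <- function(taxa, markers_per_taxon = 4L,
                             marker_length = 1000L, read_length = 100L,
                             reads_per_taxon = 10L, identity = 1,
                             mapq = 42L, cross_map = NULL, holdout = NULL,
                             genus = NULL) {
  expand <- function(x, names) {
    if (is.null(names(x))) stats::setNames(rep(x, length.out = length(names)), names)
    else x[names]
  }
  sc <- list(taxa = taxa,
             markers_per_taxon = expand(as.integer(markers_per_taxon), taxa),
             marker_length = expand(as.integer(marker_length), taxa),
             read_length = as.integer(read_length),
             reads_per_taxon = expand(as.integer(reads_per_taxon), taxa),
             identity = identity, mapq = as.integer(mapq),
             cross_map = cross_map, holdout = holdout, genus = genus)
  if (any(sc$marker_length < sc$read_length)) {
    stop("inconsistent scenario: alignment/read longer than marker")
  }
  structure(sc, class = c("euk_scenario", "list"))
}

#' Generate a self-consistent synthetic fixture
#'
#' Writes a marker FASTA, a taxonomy lineage TSV (`taxon_id`, `species`,
#' `genus`), a truth table TSV (`read_id`, `source_taxon`) and a SAM file
#' whose `@SQ` lengths match the FASTA and whose alignment identities
#' (via the NM tag), lengths and MAPQ values follow the scenario. Every
#' read in the SAM is covered by the truth table.
#'
#' @param scenario A [fixture_scenario()].
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @return List with paths `fasta`, `taxonomy`, `truth`, `sam` and the
#'   in-memory `truth` table and `reference`.
#' @export
generate_fixture <- function(scenario, seed, dir = tempfile("fixture")) {
  stopifnot(inherits(scenario, "euk_scenario"), !missing(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  rl <- scenario$read_length

  # reference sequences
  marker_names <- unlist(lapply(scenario$taxa, function(t)
    sprintf("%s|m%d", t, seq_len(scenario$markers_per_taxon[[t]]))))
  seqs <- stats::setNames(
    vapply(marker_names, function(m) {
      t <- sub("\\|.*$", "", m)
      .random_dna(scenario$marker_length[[t]])
    }, ""), marker_names)

  # reads per reference taxon, round-robin over its markers
  plan <- list()
  for (t in scenario$taxa) {
    n <- scenario$reads_per_taxon[[t]]
    if (n == 0L) next
    markers <- sprintf("%s|m%d", t, seq_len(scenario$markers_per_taxon[[t]]))
    tgt <- markers[(seq_len(n) - 1L) %% length(markers) + 1L]
    starts <- vapply(tgt, function(m)
      sample.int(nchar(seqs[[m]]) - rl + 1L, 1L) - 1L, 1L)
    plan[[t]] <- data.table::data.table(
      read_id = sprintf("%s:r%d", t, seq_len(n)),
      source_taxon = t, marker_id = tgt, start = starts,
      identity = scenario$identity, mapq = scenario$mapq,
      primary = TRUE)
  }
  plan <- data.table::rbindlist(plan)

  # cross-mapping: a fraction of `from` reads also aligns to `to`
  if (!is.null(scenario$cross_map) && nrow(plan) > 0L) {
    cm <- scenario$cross_map
    extra <- list()
    for (k in seq_len(nrow(cm))) {
      from <- cm$from[k]; to <- cm$to[k]
      idn <- if ("identity" %in% names(cm)) cm$identity[k] else 0.95
      mq <- if ("mapq" %in% names(cm)) cm$mapq[k] else 3L
      fr <- plan[plan$source_taxon == from & plan$primary, ]
      n_cross <- floor(nrow(fr) * cm$fraction[k] + 0.5)
      if (n_cross == 0L) next
      sel <- fr[seq_len(n_cross), ]
      to_markers <- sprintf("%s|m%d", to,
                            seq_len(scenario$markers_per_taxon[[to]]))
      tgt <- to_markers[(seq_len(n_cross) - 1L) %% length(to_markers) + 1L]
      extra[[k]] <- data.table::data.table(
        read_id = sel$read_id, source_taxon = from, marker_id = tgt,
        start = vapply(tgt, function(m)
          sample.int(nchar(seqs[[m]]) - rl + 1L, 1L) - 1L, 1L),
        identity = idn, mapq = 0L, primary = FALSE)
      plan[plan$read_id %in% sel$read_id & plan$primary,
           "mapq" := as.integer(mq)]
    }
    plan <- data.table::rbindlist(c(list(plan), extra))
  }

  # holdout taxa: in the truth but not the reference; reads align elsewhere
  if (!is.null(scenario$holdout)) {
    ho <- scenario$holdout
    rows <- list()
    for (k in seq_len(nrow(ho))) {
      n <- if ("reads" %in% names(ho)) ho$reads[k] else 10L
      idn <- if ("identity" %in% names(ho)) ho$identity[k] else 0.9
      to <- ho$maps_to[k]
      to_markers <- sprintf("%s|m%d", to,
                            seq_len(scenario$markers_per_taxon[[to]]))
      tgt <- to_markers[(seq_len(n) - 1L) %% length(to_markers) + 1L]
      rows[[k]] <- data.table::data.table(
        read_id = sprintf("%s:r%d", ho$taxon[k], seq_len(n)),
        source_taxon = ho$taxon[k], marker_id = tgt,
        start = vapply(tgt, function(m)
          sample.int(nchar(seqs[[m]]) - rl + 1L, 1L) - 1L, 1L),
        identity = idn, mapq = scenario$mapq, primary = TRUE)
    }
    plan <- data.table::rbindlist(c(list(plan), rows))
  }

  paths <- list(fasta = file.path(dir, "markers.fasta"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                truth = file.path(dir, "truth.tsv"),
                sam = file.path(dir, "alignments.sam"))

  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
             paths$fasta)

  all_taxa <- unique(c(scenario$taxa,
                       if (!is.null(scenario$holdout)) scenario$holdout$taxon))
  genus <- scenario$genus
  if (is.null(genus)) genus <- stats::setNames(sub("_.*$", "", all_taxa), all_taxa)
  taxonomy <- data.table::data.table(taxon_id = all_taxa, species = all_taxa,
                                     genus = genus[all_taxa])
  data.table::fwrite(taxonomy, paths$taxonomy, sep = "\t")

  truth <- unique(plan[, c("read_id", "source_taxon")])
  data.table::fwrite(truth, paths$truth, sep = "\t")

  .write_sam(plan, seqs, rl, paths$sam)

  list(fasta = paths$fasta, taxonomy = paths$taxonomy, truth = paths$truth,
       sam = paths$sam, truth_table = truth,
       reference = marker_reference(paths$fasta))
}

# Assemble SAM text. Rsamtools offers no record-level writer and the
# fixtures need exact control of NM/MAPQ/CIGAR; records are plain
# tab-separated text validated by re-reading through Rsamtools.
.write_sam <- function(plan, seqs, read_length, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  if (nrow(plan) > 0L) {
    if (any(plan$start + read_length > nchar(seqs[plan$marker_id]))) {
      stop("inconsistent scenario: alignment extends past the marker end")
    }
    nm <- as.integer(round((1 - plan$identity) * read_length))
    flag <- ifelse(plan$primary, 0L, 256L)
    seq_field <- ifelse(plan$primary,
                        substring(seqs[plan$marker_id], plan$start + 1L,
                                  plan$start + read_length),
                        "*")
    qual <- ifelse(plan$primary, strrep("I", read_length), "*")
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                    plan$read_id, flag, plan$marker_id, plan$start + 1L,
                    plan$mapq, read_length, seq_field, qual, nm)
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Canned scenario: detection floor
#'
#' Exactly two perfect reads on two distinct markers of one taxon — the
#' designed lower limit of detection.
#' @param taxon Taxon id.
#' @return A [fixture_scenario()].
#' @export
scenario_detection_floor <- function(taxon = "Taxon_floor") {
  fixture_scenario(taxa = taxon, markers_per_taxon = 2L,
                   reads_per_taxon = 2L, identity = 1)
}

#' Canned scenario: confusable pair
#'
#' Two taxa where a fraction of each taxon's reads cross-maps to the other
#' (secondary alignments at slightly lower identity).
#' @param cross_fraction Fraction of reads carrying alignments to both taxa.
#' @param reads_per_taxon Reads per taxon.
#' @return A [fixture_scenario()].
#' @export
scenario_confusable_pair <- function(cross_fraction = 0.3,
                                     reads_per_taxon = 20L) {
  fixture_scenario(
    taxa = c("Taxon_A", "Taxon_B"),
    reads_per_taxon = reads_per_taxon,
    cross_map = data.frame(from = c("Taxon_A", "Taxon_B"),
                           to = c("Taxon_B", "Taxon_A"),
                           fraction = cross_fraction,
                           identity = 0.96))
}

#' Canned scenario: unrepresented (holdout) species
#'
#' A truth taxon absent from the reference whose reads align to a
#' same-genus relative — scored at genus rank downstream.
#' @return A [fixture_scenario()].
#' @export
scenario_unrepresented <- function() {
  fixture_scenario(
    taxa = c("GenusX_present", "GenusY_other"),
    reads_per_taxon = c(GenusX_present = 10L, GenusY_other = 10L),
    holdout = data.frame(taxon = "GenusX_novel", maps_to = "GenusX_present",
                         identity = 0.9, reads = 10L))
}
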