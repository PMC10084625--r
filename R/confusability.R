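# Pairwise taxon confusability: emit/accept rates, PCA embedding, greedy
# geospatial subsampling.

#' Emit/accept rates for one taxon pair
#'
#' Eight rates summarizing how a pair (A, B) exchanges simulated reads.
#' For member X with partner Y:
#' * `emit_to_partner(X)` — reads sourced from X matching Y / reads from X;
#' * `emit_outside(X)` — reads from X matching taxa outside the pair /
#'   reads from X;
#' * `accept_from_partner(X)` — reads from Y matching X / reads from Y;
#' * `accept_from_outside(X)` — reads from outside taxa matching X /
#'   reads from outside taxa (0 when the table has no outside reads).
#'
#' @param flow `data.frame(source_taxon, match_taxon, n_reads)` from a
#'   simulation (see [read_flow_table()]); `match_taxon` may be NA for
#'   unmapped reads.
#' @param taxon_a,taxon_b The pair.
#' @return Named numeric vector of the 8 rates
#'   (`emit_to_partner_a`, `emit_outside_a`, `accept_from_partner_a`,
#'   `accept_from_outside_a`, and the `_b` counterparts).
#' @export
pair_rates <- function(flow, taxon_a, taxon_b) {
  stopifnot(all(c("source_taxon", "match_taxon", "n_reads") %in% names(flow)))
  f <- data.table::as.data.table(flow)
  src_tot <- function(t) sum(f$n_reads[f$source_taxon == t])
  n_a <- src_tot(taxon_a)
  n_b <- src_tot(taxon_b)
  if (n_a == 0) stop("no reads sourced from taxon: ", taxon_a)
  if (n_b == 0) stop("no reads sourced from taxon: ", taxon_b)
  pair <- c(taxon_a, taxon_b)
  outside_src <- !(f$source_taxon %in% pair)
  n_out <- sum(f$n_reads[outside_src])
  cnt <- function(src_in, match_in) {
    sum(f$n_reads[f$source_taxon %in% src_in &
                    !is.na(f$match_taxon) & f$match_taxon %in% match_in])
  }
  outside_taxa <- setdiff(unique(c(f$source_taxon, f$match_taxon)), pair)
  outside_taxa <- outside_taxa[!is.na(outside_taxa)]
  rates_for <- function(x, y) {
    n_x <- if (x == taxon_a) n_a else n_b
    n_y <- if (y == taxon_a) n_a else n_b
    c(emit_to_partner = cnt(x, y) / n_x,
      emit_outside = cnt(x, outside_taxa) / n_x,
      accept_from_partner = cnt(y, x) / n_y,
      accept_from_outside = if (n_out > 0) cnt(outside_taxa, x) / n_out else 0)
  }
  out <- c(stats::setNames(rates_for(taxon_a, taxon_b),
                           c("emit_to_partner_a", "emit_outside_a",
                             "accept_from_partner_a", "accept_from_outside_a")),
           stats::setNames(rates_for(taxon_b, taxon_a),
                           c("emit_to_partner_b", "emit_outside_b",
                             "accept_from_partner_b", "accept_from_outside_b")))
  stopifnot(all(out >= 0 & out <= 1))
  out
}

#' Confusability feature table over many pairs
#'
#' @param flow A read-flow table (see [pair_rates()]).
#' @param pairs Optional `data.frame(taxon_a, taxon_b)`; defaults to all
#'   unordered pairs of source taxa in the table.
#' @return `data.table` with `taxon_a`, `taxon_b` and the 8 rate columns.
#' @export
confusability_features <- function(flow, pairs = NULL) {
  if (is.null(pairs)) {
    taxa <- sort(unique(flow$source_taxon))
    if (length(taxa) < 2L) stop("need at least two source taxa")
    cmb <- utils::combn(taxa, 2L)
    pairs <- data.frame(taxon_a = cmb[1L, ], taxon_b = cmb[2L, ],
                        stringsAsFactors = FALSE)
  }
  feats <- t(mapply(function(a, b) pair_rates(flow, a, b),
                    pairs$taxon_a, pairs$taxon_b))
  out <- data.table::data.table(taxon_a = pairs$taxon_a,
                                taxon_b = pairs$taxon_b)
  cbind(out, data.table::as.data.table(feats))
}

#' PCA embedding of a confusability feature table
#'
#' Mean-centered (unscaled — the features are already rates on `[0, 1]`)
#' PCA via singular value decomposition. The sign of each component is
#' fixed so that its loadings sum positive, matching the convention that
#' the first component is an overall-confusability axis with positive
#' coefficients for every feature.
#'
#' @param features Output of [confusability_features()] (or any
#'   `data.frame` whose numeric columns are the features).
#' @param scale. Standardize features to unit variance first (default
#'   `FALSE`).
#' @return List of class `euk_pca`: `coords` (data.table with pair labels
#'   and `PC1`, `PC2`, ...), `rotation`, `explained_variance_pct`.
#' @export
pca_embed <- function(features, scale. = FALSE) {
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1L))
  X <- as.matrix(features[, num, drop = FALSE])
  if (nrow(X) < 2L) stop("need at least two rows for PCA")
  if (all(apply(X, 2L, stats::var) < .Machine$double.eps)) {
    stop("constant feature table: zero variance")
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  flip <- ifelse(colSums(p$rotation) < 0, -1, 1)
  p$rotation <- sweep(p$rotation, 2L, flip, "*")
  p$x <- sweep(p$x, 2L, flip, "*")
  ev <- p$sdev^2
  labels <- features[, !num, drop = FALSE]
  coords <- cbind(data.table::as.data.table(labels),
                  data.table::as.data.table(p$x))
  structure(list(coords = coords, rotation = p$rotation,
                 explained_variance_pct = 100 * ev / sum(ev)),
            class = "euk_pca")
}

#' @export
print.euk_pca <- function(x, ...) {
  cat("euk_pca:", nrow(x$coords), "points;",
      "PC1", sprintf("%.1f%%", x$explained_variance_pct[1L]),
      if (length(x$explained_variance_pct) > 1L)
        sprintf("PC2 %.1f%%", x$explained_variance_pct[2L]), "\n")
  invisible(x)
}

#' Greedy geospatial subsampling of 2-D points
#'
#' The seed point is kept first; the remaining points are visited in
#' ascending Euclidean distance from the seed (ties broken by label) and
#' kept iff at least `min_distance` away from every point already kept.
#' The kept set is therefore pairwise separated by `min_distance` and
#' always contains the seed.
#'
#' @param points `data.frame` with a `label` column and two numeric
#'   coordinate columns (default `PC1`, `PC2`).
#' @param min_distance Separation distance (the published analysis used
#'   0.005 for a focused subset and 0.05 for a broad one).
#' @param seed_label Label of the seed point (must be present).
#' @param coord_cols Names of the two coordinate columns.
#' @return The kept subset of `points`, seed first, in visit order.
#' @export
greedy_subsample <- function(points, min_distance, seed_label,
                             coord_cols = c("PC1", "PC2")) {
  stopifnot("label" %in% names(points), all(coord_cols %in% names(points)))
  lab <- as.character(points$label)
  i_seed <- which(lab == seed_label)
  if (length(i_seed) != 1L) {
    stop("seed point not found (or not unique): ", seed_label)
  }
  X <- as.matrix(points[, coord_cols, drop = FALSE])
  d_seed <- sqrt(rowSums((X - matrix(X[i_seed, ], nrow(X), 2L,
                                     byrow = TRUE))^2))
  ord <- order(d_seed, lab)
  ord <- c(i_seed, setdiff(ord, i_seed))
  kept <- i_seed
  for (i in ord[-1L]) {
    d <- sqrt(rowSums((X[kept, , drop = FALSE] -
                         matrix(X[i, ], length(kept), 2L, byrow = TRUE))^2))
    if (all(d >= min_distance)) kept <- c(kept, i)
  }
  points[kept, , drop = FALSE]
}
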