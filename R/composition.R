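# ASV-table handling, quality filters, relative abundance, and diversity.
#
# An ASV table is a wide tibble: one row per sample with metadata columns
# `sample_id` (character, unique), `blank` (logical) and `stage`
# (character: "inoculum", "community" or "extinction"), followed by one
# numeric count column per taxon.  This matches the on-disk TSV dialect
# (samples as rows, first column the sample id, a blank flag column).

.meta_cols <- c("sample_id", "blank", "stage")

#' Extract the numeric count matrix from an ASV table
#'
#' @param table An ASV table (see [filter_min_depth()] for the layout).
#' @return A numeric matrix, samples x taxa, with dimnames.
#' @export
asv_counts <- function(table) {
  check_columns(table, "sample_id", "table")
  taxa <- setdiff(names(table), .meta_cols)
  m <- as.matrix(table[, taxa, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

#' Drop samples with insufficient sequencing depth
#'
#' Samples whose total read count is strictly below `min_reads` are
#' removed (the default 2000-read rule; a sample at exactly `min_reads`
#' is retained).  Idempotent.
#'
#' @param table An ASV table.
#' @param min_reads Minimum total reads per sample (default 2000).
#' @return The filtered ASV table.
#' @export
filter_min_depth <- function(table, min_reads = 2000) {
  if (nrow(table) == 0L) return(table)
  totals <- rowSums(asv_counts(table))
  dropped <- sum(totals < min_reads)
  if (dropped > 0) {
    inform(sprintf("filter_min_depth: dropped %d of %d samples below %s reads.",
                   dropped, nrow(table), format(min_reads)))
  }
  table[totals >= min_reads, , drop = FALSE]
}

#' Remove contaminant ASVs identified from blank samples
#'
#' An ASV is called a contaminant when its relative abundance exceeds
#' `blank_fraction` (strictly) in a fraction of the blank samples that
#' strictly exceeds `blank_prevalence`.  Contaminant reads are removed
#' (zeroed) from every biological sample; blank rows keep their counts -
#' they are QC evidence, not analysis samples - which makes the filter
#' idempotent.  Columns left with no reads anywhere are dropped.  The
#' removed taxon ids are attached as the `"removed_taxa"` attribute.
#'
#' @param table An ASV table containing at least one row with
#'   `blank == TRUE`.
#' @param blank_fraction Relative-abundance threshold within a blank
#'   (default 0.02).
#' @param blank_prevalence Fraction-of-blanks threshold (default 0.20).
#' @return The ASV table without contaminant columns; attribute
#'   `removed_taxa` lists what was removed.
#' @export
remove_contaminants <- function(table, blank_fraction = 0.02, blank_prevalence = 0.20) {
  check_columns(table, c("sample_id", "blank"), "table")
  blanks <- table[table$blank, , drop = FALSE]
  if (nrow(blanks) == 0L) {
    abort("no blank samples in `table`; cannot screen contaminants.",
          class = "relfun_no_blank")
  }
  m <- asv_counts(blanks)
  totals <- rowSums(m)
  frac <- sweep(m, 1, pmax(totals, 1), "/")
  prev <- colMeans(frac > blank_fraction)
  removed <- colnames(m)[prev > blank_prevalence]
  out <- table
  newly <- character(0)
  if (length(removed)) {
    zeroed <- as.matrix(out[!out$blank, removed, drop = FALSE])
    newly <- removed[colSums(zeroed) > 0]
    out[!out$blank, removed] <- 0
  }
  if (length(newly)) {
    inform(sprintf("remove_contaminants: removed %d contaminant ASV(s).",
                   length(newly)))
  }
  empty <- setdiff(names(out), .meta_cols)
  empty <- empty[colSums(as.matrix(out[, empty, drop = FALSE])) == 0]
  out <- out[, !(names(out) %in% empty), drop = FALSE]
  attr(out, "removed_taxa") <- removed
  out
}

#' Per-sample relative abundances
#'
#' @param table An ASV table.
#' @param keep_zero Keep taxa with zero reads in the output (default
#'   `FALSE`: only taxa present in a sample appear in its rows).
#' @return A long tibble `sample_id`, `taxon_id`, `reads`, `rel_abund`;
#'   fractions sum to 1 within each sample.
#' @export
relative_abundance <- function(table, keep_zero = FALSE) {
  m <- asv_counts(table)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("sample(s) with zero total reads: %s.",
                  paste(rownames(m)[totals <= 0], collapse = ", ")),
          class = "relfun_degenerate_sample")
  }
  out <- tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    taxon_id = rep(colnames(m), each = nrow(m)),
    reads = as.vector(m),
    rel_abund = as.vector(m / totals)
  )
  if (!keep_zero) out <- out[out$reads > 0, , drop = FALSE]
  dplyr::arrange(out, .data$sample_id, .data$taxon_id)
}

#' Observed and rarefied taxonomic richness
#'
#' Observed richness is the number of taxa with a positive count.
#' Rarefied richness is the exact hypergeometric expectation of the
#' number of taxa seen in a random subsample of `depth` reads
#' (computed via [vegan::rarefy()]).
#'
#' @param table An ASV table.
#' @return `observed_richness()`: tibble `sample_id`, `richness`.
#' @export
observed_richness <- function(table) {
  m <- asv_counts(table)
  tibble::tibble(sample_id = rownames(m), richness = as.integer(rowSums(m > 0)))
}

#' @rdname observed_richness
#' @param depth Rarefaction depth; must not exceed any sample's total.
#' @return `rarefied_richness()`: tibble `sample_id`, `richness_rarefied`.
#' @export
rarefied_richness <- function(table, depth) {
  m <- asv_counts(table)
  check_count(depth, "depth")
  totals <- rowSums(m)
  if (any(depth > totals)) {
    abort("`depth` exceeds the total reads of at least one sample.",
          class = "relfun_invalid_argument")
  }
  # vegan warns when no sample has singletons (a heuristic aimed at
  # non-count data); integer ASV counts can legitimately lack them
  r <- withCallingHandlers(
    vegan::rarefy(round(m), sample = depth),
    warning = function(w) {
      if (grepl("observed count data have counts 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble::tibble(sample_id = rownames(m), richness_rarefied = as.numeric(r))
}

#' Patristic distances among taxa from a phylogeny
#'
#' Sums branch lengths along tree paths.  Every requested taxon must be a
#' tip of the tree; extra tips are ignored.
#'
#' @param tree An [ape::phylo] tree (e.g. read with [ape::read.tree()]).
#' @param taxa Character vector of taxon ids to keep; default all tips.
#' @return A square symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape `phylo` object.", class = "relfun_invalid_argument")
  }
  taxa <- taxa %||% tree$tip.label
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    abort(sprintf("tree lacks tip(s): %s.", paste(missing, collapse = ", ")),
          class = "relfun_invalid_argument")
  }
  d <- ape::cophenetic.phylo(tree)
  d[taxa, taxa, drop = FALSE]
}

.check_dist <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
      any(diag(d) != 0) || any(d < 0)) {
    abort("`distances` must be square, symmetric, non-negative with zero diagonal.",
          class = "relfun_invalid_argument")
  }
  d
}

.abund_matrix <- function(abundances) {
  if (is.data.frame(abundances)) {
    check_columns(abundances, c("sample_id", "taxon_id", "rel_abund"), "abundances")
    wide <- tidyr::pivot_wider(
      abundances[, c("sample_id", "taxon_id", "rel_abund")],
      names_from = "taxon_id", values_from = "rel_abund", values_fill = 0)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$sample_id
    m
  } else if (is.numeric(abundances)) {
    if (is.null(names(abundances))) {
      abort("a bare abundance vector must be named by taxon id.",
            class = "relfun_invalid_argument")
    }
    matrix(abundances, nrow = 1, dimnames = list("community", names(abundances)))
  } else {
    abort("`abundances` must be a long tibble or a named numeric vector.",
          class = "relfun_invalid_argument")
  }
}

.weighted_phylo_metric <- function(abundances, distances, fun, metric) {
  d <- .check_dist(distances)
  m <- .abund_matrix(abundances)
  missing <- setdiff(colnames(m), rownames(d))
  if (length(missing)) {
    abort(sprintf("`distances` lacks taxa: %s.", paste(missing, collapse = ", ")),
          class = "relfun_invalid_argument")
  }
  if (any(rowSums(m > 0) < 2)) {
    abort("each community needs >= 2 taxa with positive abundance.",
          class = "relfun_undefined_metric")
  }
  vals <- fun(m, d[colnames(m), colnames(m)], abundance.weighted = TRUE)
  tibble::tibble(sample_id = rownames(m), !!metric := as.numeric(vals))
}

# MPD with the i != j pairs both in numerator and normaliser (so that a
# two-taxon community returns the pair's distance regardless of
# abundance); picante's abundance-weighted mpd keeps the i = j mass in
# the denominator and differs by the factor 1 - sum(f^2)
.mpd_pairs <- function(m, d, abundance.weighted = TRUE) {
  vapply(seq_len(nrow(m)), function(i) {
    f <- m[i, ]
    f <- f / sum(f)
    w <- outer(f, f)
    diag(w) <- 0
    sum(w * d) / sum(w)
  }, numeric(1))
}

#' Abundance-weighted phylogenetic diversity of communities
#'
#' `weighted_mpd()` is the abundance-weighted mean pairwise distance:
#' \eqn{\sum_{i \ne j} f_i f_j d_{ij} / \sum_{i \ne j} f_i f_j}.
#' `weighted_mntd()` is the abundance-weighted mean nearest-taxon
#' distance, \eqn{\sum_i f_i \min_{j \ne i} d_{ij}}, with abundances
#' renormalised over the taxa present.  MNTD follows the standard
#' picante `abundance.weighted` definition (computation delegates to
#' [picante::mntd()]); MPD restricts both numerator and normaliser to
#' distinct pairs, so a two-taxon community always returns the pair's
#' distance.
#'
#' @param abundances Either a long tibble `sample_id`, `taxon_id`,
#'   `rel_abund` (as from [relative_abundance()]) or a named numeric
#'   vector for a single community.
#' @param distances A square symmetric distance matrix over taxon ids
#'   (e.g. from [patristic_distances()]); may contain extra taxa.
#' @return A tibble `sample_id` plus `mpd` or `mntd`.
#' @export
weighted_mpd <- function(abundances, distances) {
  .weighted_phylo_metric(abundances, distances, .mpd_pairs, "mpd")
}

#' @rdname weighted_mpd
#' @export
weighted_mntd <- function(abundances, distances) {
  .weighted_phylo_metric(abundances, distances, picante::mntd, "mntd")
}

#' Read / write the ASV-table TSV dialect
#'
#' Samples as rows; columns `sample_id`, `blank`, `stage`, then one
#' column per taxon.
#'
#' @param path File path.
#' @return `read_asv_table()` returns the ASV table tibble.
#' @export
read_asv_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, .meta_cols, "ASV table file")
  out$blank <- as.logical(out$blank)
  out
}

#' @rdname read_asv_table
#' @param table ASV table to write.
#' @export
write_asv_table <- function(table, path) {
  check_columns(table, .meta_cols, "table")
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a square distance matrix TSV (taxon ids as header row and first
#' column)
#'
#' @param path File path.
#' @return A numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  .check_dist(m)
}
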