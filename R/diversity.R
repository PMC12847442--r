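# Alpha diversity, rarefaction, taxonomic aggregation and Bray-Curtis
# distances. Feature tables are tibbles with `taxon_id`, optional `lineage`
# (rank-delimited, e.g. "k__...;p__...;..."), and one count column per sample.

#' Alpha diversity per sample
#'
#' Computes, per sample column of a feature table: observed richness,
#' singleton and doubleton counts, the bias-corrected Chao1 estimator
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` (defined even when no doubletons are
#' seen; the classical `S_obs + f1^2 / (2 f2)` is available), Shannon entropy
#' `-sum p_i log(p_i)` and the Gini-Simpson index `1 - sum p_i^2`.
#'
#' Shannon defaults to base 2 (bits); natural log by `shannon_base = "e"`.
#'
#' @param table Feature tibble (see [simulate_community()]) or a single
#'   non-negative integer count vector.
#' @param shannon_base `"2"` (default) or `"e"`.
#' @param chao1_variant `"bias_corrected"` (default) or `"classical"`.
#' @return A tibble with one row per sample: `sample_id`, `s_obs`, `f1`,
#'   `f2`, `chao1`, `shannon`, `simpson`.
#' @examples
#' alpha_diversity(c(a = 4, b = 4, c = 4, d = 4))
#' @export
alpha_diversity <- function(table, shannon_base = c("2", "e"),
                            chao1_variant = c("bias_corrected", "classical")) {
  shannon_base <- match.arg(as.character(shannon_base), c("2", "e"))
  chao1_variant <- match.arg(chao1_variant)
  base <- if (shannon_base == "2") 2 else exp(1)
  counts <- if (is.data.frame(table)) feature_counts(table) else
    matrix(table, ncol = 1, dimnames = list(names(table), "sample"))
  purrr::map_dfr(colnames(counts), function(s) {
    x <- counts[, s]
    if (all(x == 0)) abort(paste0("Sample '", s, "' has no positive counts."))
    x <- x[x > 0]
    p <- x / sum(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (chao1_variant == "bias_corrected") {
      length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
    } else {
      if (f2 == 0 && f1 > 0) {
        warn("Classical Chao1 undefined with no doubletons; reporting NA.")
        NA_real_
      } else if (f1 == 0) length(x) else length(x) + f1^2 / (2 * f2)
    }
    tibble::tibble(sample_id = s, s_obs = length(x), f1 = f1, f2 = f2,
                   chao1 = chao1,
                   shannon = -sum(p * log(p, base = base)),
                   simpson = 1 - sum(p^2))
  })
}

#' Rarefaction curve of expected richness
#'
#' Expected number of taxa observed in subsamples of increasing depth drawn
#' without replacement. `mode = "analytic"` uses the exact hypergeometric
#' expectation `E[S_d] = sum_i (1 - choose(N - n_i, d) / choose(N, d))`
#' (computed via [vegan::rarefy()]); `mode = "montecarlo"` averages observed
#' richness over `reps` random subsamples.
#'
#' @param counts Non-negative integer count vector for one sample.
#' @param depths Increasing subsample sizes, each at most `sum(counts)`.
#' @param mode `"analytic"` (default) or `"montecarlo"`.
#' @param reps Number of Monte-Carlo subsamples.
#' @param seed Optional integer seed for Monte-Carlo mode.
#' @return A tibble with `depth`, `expected_richness` and, in Monte-Carlo
#'   mode, `se` (standard error of the mean over replicates).
#' @export
rarefaction_curve <- function(counts, depths, mode = c("analytic", "montecarlo"),
                              reps = 100, seed = NULL) {
  mode <- match.arg(mode)
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (any(depths > total)) abort("Rarefaction depth exceeds the sample total.")
  if (any(depths < 1) || any(diff(depths) <= 0)) {
    abort("depths must be increasing positive integers.")
  }
  if (mode == "analytic") {
    er <- vapply(depths, function(d) {
      suppressWarnings(
        unname(drop(vegan::rarefy(matrix(counts, nrow = 1), sample = d))))
    }, numeric(1))
    tibble::tibble(depth = as.integer(depths), expected_richness = er)
  } else {
    if (!is.null(seed)) set.seed(seed)
    pool <- rep.int(seq_along(counts), counts)
    res <- purrr::map_dfr(depths, function(d) {
      s <- vapply(seq_len(reps), function(i) {
        length(unique(sample(pool, d, replace = FALSE)))
      }, numeric(1))
      tibble::tibble(depth = as.integer(d), expected_richness = mean(s),
                     se = sd(s) / sqrt(reps))
    })
    res
  }
}

#' Aggregate a feature table to relative abundance at a taxonomy rank
#'
#' Parses rank-delimited lineage strings (`;`-separated, optional `x__`
#' prefixes), sums counts per taxon group at the requested rank and converts
#' to per-sample proportions (each sample sums to 1). Taxa whose lineage has
#' no usable label at the rank are pooled as `"Unclassified"`.
#'
#' @param table Feature tibble with a `lineage` column.
#' @param rank 1-based rank position (e.g. 2 for phylum in a
#'   kingdom-first lineage) or a rank prefix letter such as `"p"`.
#' @return A tibble with `taxon` and one proportion column per sample.
#' @export
aggregate_relative_abundance <- function(table, rank = 2) {
  if (!"lineage" %in% names(table)) abort("Feature table has no lineage column.")
  parts <- strsplit(table$lineage, ";", fixed = TRUE)
  label_at <- function(p) {
    p <- trimws(p)
    if (is.character(rank) && nchar(rank) == 1) {
      hit <- grep(paste0("^", rank, "__"), p, value = TRUE)
      lab <- if (length(hit) > 0) sub("^[a-z]__", "", hit[1]) else ""
    } else {
      lab <- if (length(p) >= rank) sub("^[a-z]__", "", p[[rank]]) else ""
    }
    if (is.na(lab) || lab == "") "Unclassified" else lab
  }
  groups <- vapply(parts, label_at, character(1))
  if (all(groups == "Unclassified")) {
    abort("Requested rank absent from every lineage.")
  }
  counts <- feature_counts(table)
  totals <- colSums(counts)
  if (any(totals == 0)) abort("Sample(s) with zero total counts.")
  agg <- rowsum(counts, group = groups)
  prop <- sweep(agg, 2, totals, "/")
  tibble::as_tibble(prop, rownames = "taxon")
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = 1 - 2 sum_i min(a_i, b_i) / (sum a_i + sum b_i)`: 0 for
#' identical samples, 1 for samples sharing no taxa. Symmetric and bounded in
#' `[0, 1]` but not a metric (the triangle inequality can fail).
#'
#' @param table Feature tibble or a taxa-by-samples count matrix with at
#'   least two sample columns.
#' @return A symmetric base-R distance matrix with zero diagonal and sample
#'   names on both margins.
#' @export
bray_curtis <- function(table) {
  counts <- if (is.data.frame(table)) feature_counts(table) else table
  if (ncol(counts) < 2) abort("Bray-Curtis needs at least two samples.")
  if (any(colSums(counts) == 0)) abort("Sample(s) with zero total counts.")
  d <- vegan::vegdist(t(counts), method = "bray")
  as.matrix(d)
}
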