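# Synthetic study generator: study-shaped enzyme/soil tables drawn around
# published (or user) group means/SDs, and taxa count tables with planted
# signed correlation blocks, so every downstream stage can be validated
# against known ground truth.

#' Define a treatment-by-depth-by-replicate study design
#'
#' The default reproduces the field layout the package emulates: a mulching
#' chronosequence (0, 5, 10, 15 years) at two depth layers with three
#' replicates per cell, i.e. 24 samples.
#'
#' @param treatments Mulching years (subset of 0/5/10/15).
#' @param depths Depth layers (subset of `"0-20"`, `"20-40"`).
#' @param n_replicates Replicates per cell (>= 2 for any variance-based test).
#' @return A list of class `"study_design"`.
#' @export
study_design <- function(treatments = c(0, 5, 10, 15),
                         depths = c("0-20", "20-40"),
                         n_replicates = 3) {
  treatment_label(treatments)
  if (!all(depths %in% .depth_levels)) {
    abort(paste0("depths must be among: ", paste(.depth_levels, collapse = ", ")))
  }
  if (n_replicates < 2) abort("n_replicates must be >= 2.")
  structure(list(treatments = treatments, depths = depths,
                 n_replicates = as.integer(n_replicates)),
            class = "study_design")
}

#' Simulate a study around fixture (or user) group means and SDs
#'
#' Draws per-replicate values independently as Normal(mean, SD) truncated at
#' zero by resampling (not clipping, so no point mass at zero; with the
#' small SD/mean ratios of the packaged tables the truncation is almost
#' never triggered and cell means are preserved). `sd_scale = 0` returns the
#' cell means exactly, so zero-noise simulation composed with
#' [group_summary()] is the identity on the means table.
#'
#' @param design A [study_design()].
#' @param means A long means table as returned by [load_fixture()] (columns
#'   `depth`, `treatment`, `variable`, `mean`, `sd`), covering every design
#'   cell; or a fixture name string.
#' @param seed Integer seed; fully determines the output.
#' @param sd_scale Multiplier on the table SDs (0 = noise-free).
#' @return A list with `values` (long tibble: `sample_id`, `variable`,
#'   `value`) and `metadata` (tibble: `sample_id`, `mulch_years`, `depth`,
#'   `replicate`).
#' @examples
#' sim <- simulate_study(study_design(), "table2_enzymes", seed = 1)
#' head(sim$values)
#' @export
simulate_study <- function(design, means, seed, sd_scale = 1) {
  stopifnot(inherits(design, "study_design"))
  if (is.character(means)) means <- load_fixture(means)
  means <- dplyr::mutate(means, treatment = as.character(.data$treatment))
  labels <- as.character(treatment_label(design$treatments))
  cells <- tidyr::expand_grid(depth = design$depths, treatment = labels)
  covered <- dplyr::semi_join(cells, means, by = c("depth", "treatment"))
  if (nrow(covered) < nrow(cells)) {
    miss <- dplyr::anti_join(cells, means, by = c("depth", "treatment"))
    abort(paste0("Design cell(s) missing from the means table: ",
                 paste(paste(miss$depth, miss$treatment), collapse = "; ")))
  }
  set.seed(seed)
  metadata <- tidyr::expand_grid(depth = design$depths, treatment = labels,
                                 replicate = seq_len(design$n_replicates)) |>
    dplyr::mutate(
      mulch_years = mulch_years(.data$treatment),
      sample_id = sprintf("%s_%s_r%d", .data$treatment,
                          gsub("-", "_", .data$depth), .data$replicate)) |>
    dplyr::select("sample_id", "mulch_years", "depth", "replicate")
  grid <- dplyr::inner_join(
    tidyr::expand_grid(cells, replicate = seq_len(design$n_replicates)),
    means, by = c("depth", "treatment"),
    relationship = "many-to-many")
  vals <- rtruncnorm_pos(nrow(grid), grid$mean, grid$sd * sd_scale)
  values <- grid |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_r%d", .data$treatment,
                          gsub("-", "_", .data$depth), .data$replicate),
      value = vals) |>
    dplyr::select("sample_id", "variable", "value")
  list(values = values, metadata = metadata)
}

# Normal(mean, sd) truncated at 0 via resampling; exact means when sd = 0.
rtruncnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0]
    guard <- guard + 1
  }
  if (length(bad) > 0) out[bad] <- 0
  out
}

#' Long simulated values to a wide per-sample table
#'
#' @param values Long tibble from [simulate_study()].
#' @return Wide tibble: `sample_id` plus one column per variable.
#' @export
pivot_samples <- function(values) {
  tidyr::pivot_wider(values, names_from = "variable", values_from = "value")
}

#' Simulate a taxa count table with planted correlation blocks
#'
#' Latent per-sample Gaussian vectors with block-structured covariance are
#' exponentiated to relative abundances and converted to counts by
#' multinomial sampling at a per-sample depth drawn log-normally (emulating
#' uneven library sizes). Within a block, every taxon pair has latent
#' correlation `rho` (signed); a block whose implied covariance is not
#' positive definite (e.g. an equicorrelated negative block of size > 2 at
#' `rho <= -0.5`) errors before sampling, so strong negative associations
#' are planted as size-2 blocks.
#'
#' The planted truth records every within-block pair with `|latent
#' correlation| >= 0.8` as an edge with its sign.
#'
#' @param n_taxa Total number of taxa.
#' @param n_samples Number of samples.
#' @param blocks List of `list(size =, rho =)` entries; sizes must sum to at
#'   most `n_taxa`, `|rho| < 1`. Taxa outside blocks are independent.
#' @param depth_mean_log Mean of log library size (default `log(1e4)`).
#' @param depth_sd_log SD of log library size (default 0.25).
#' @param base_mean_log,base_sd_log Mean/SD of per-taxon baseline log
#'   abundance.
#' @param seed Integer seed; fully determines the output.
#' @return A list with `table` (feature tibble: `taxon_id`, `lineage`, one
#'   column per sample) and `truth` (list: `edges` tibble with `taxon_a`,
#'   `taxon_b`, `sign`; `membership` integer block ids, 0 = no block).
#' @export
simulate_community <- function(n_taxa, n_samples, blocks = list(),
                               depth_mean_log = log(1e4), depth_sd_log = 0.25,
                               base_mean_log = 0, base_sd_log = 1,
                               seed) {
  sizes <- vapply(blocks, `[[`, numeric(1), "size")
  rhos <- vapply(blocks, `[[`, numeric(1), "rho")
  if (sum(sizes) > n_taxa) abort("Block sizes exceed n_taxa.")
  if (any(abs(rhos) >= 1)) abort("Block |rho| must be < 1.")
  set.seed(seed)
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  membership <- integer(n_taxa)
  sigma <- diag(n_taxa)
  at <- 0
  for (b in seq_along(blocks)) {
    idx <- at + seq_len(sizes[b])
    membership[idx] <- b
    sigma[idx, idx] <- rhos[b]
    diag(sigma)[idx] <- 1
    at <- at + sizes[b]
  }
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("Implied latent covariance is not positive definite.")
  })
  z <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa) %*% ch
  mu <- rnorm(n_taxa, base_mean_log, base_sd_log)
  abund <- exp(sweep(z, 2, mu, "+"))
  depths <- round(exp(rnorm(n_samples, depth_mean_log, depth_sd_log)))
  counts <- vapply(seq_len(n_samples), function(j) {
    stats::rmultinom(1, size = depths[j], prob = abund[j, ])[, 1]
  }, numeric(n_taxa))
  colnames(counts) <- sprintf("s%03d", seq_len(n_samples))
  # planted edges: within-block pairs with |latent correlation| >= 0.8
  edges <- NULL
  for (b in seq_along(blocks)) {
    if (abs(rhos[b]) >= 0.8 && sizes[b] >= 2) {
      idx <- which(membership == b)
      pr <- t(combn(idx, 2))
      edges <- rbind(edges, data.frame(
        taxon_a = taxa[pr[, 1]], taxon_b = taxa[pr[, 2]],
        sign = if (rhos[b] > 0) "positive" else "negative"))
    }
  }
  edges <- if (is.null(edges)) {
    tibble::tibble(taxon_a = character(), taxon_b = character(),
                   sign = character())
  } else tibble::as_tibble(edges)
  phyla <- paste0("Phylum", ifelse(membership == 0, "X", membership))
  table <- tibble::tibble(taxon_id = taxa,
                          lineage = paste0("k__Bacteria;p__", phyla),
                          tibble::as_tibble(counts))
  list(table = table,
       truth = list(edges = edges, membership = membership))
}

#' Precision and recall of an inferred edge set against planted truth
#'
#' Edges are unordered taxon pairs. Precision is the fraction of inferred
#' edges that are planted; recall the fraction of planted edges recovered.
#' Both are defined as 1 when their denominator set is empty and the other
#' set is empty too (and 1 for precision / 0 for recall when only one is).
#'
#' @param truth Truth list from [simulate_community()] (or a tibble of
#'   planted edges with `taxon_a`, `taxon_b`).
#' @param inferred Edge tibble from [build_network()].
#' @return A one-row tibble: `n_planted`, `n_inferred`, `n_correct`,
#'   `precision`, `recall`.
#' @export
recovery_metrics <- function(truth, inferred) {
  planted <- if (is.data.frame(truth)) truth else truth$edges
  key <- function(e) {
    if (nrow(e) == 0) return(character())
    paste(pmin(e$taxon_a, e$taxon_b), pmax(e$taxon_a, e$taxon_b), sep = "|")
  }
  kp <- key(planted)
  ki <- key(inferred)
  hit <- length(intersect(kp, ki))
  tibble::tibble(
    n_planted = length(kp), n_inferred = length(ki), n_correct = hit,
    precision = if (length(ki) == 0) as.numeric(length(kp) == 0) else hit / length(ki),
    recall = if (length(kp) == 0) 1 else hit / length(kp))
}
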