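# Shared fixtures built in code.

# The eight published treatment-by-depth enzyme mean profiles.
table2_cells <- function() fixture_means("table2_enzymes")

# A small wide enzyme table with ids.
toy_enzymes <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2"),
    BG = c(100, 50), CBH = c(10, 5), NAG = c(20, 10),
    LAP = c(30, 15), ALP = c(60, 30))
}

# Random strictly positive enzyme profiles.
random_profiles <- function(n, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    BG = runif(n, 10, 300), CBH = runif(n, 1, 40), NAG = runif(n, 1, 40),
    LAP = runif(n, 10, 150), ALP = runif(n, 50, 400))
}

# Small feature tibble from a counts matrix.
feature_tibble <- function(m, lineage = NULL) {
  taxa <- rownames(m) %||% sprintf("t%02d", seq_len(nrow(m)))
  tb <- tibble::tibble(taxon_id = taxa)
  if (!is.null(lineage)) tb$lineage <- lineage
  cols <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  for (j in seq_along(cols)) tb[[cols[j]]] <- m[, j]
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_temp_table <- function(df, delim = "\t") {
  path <- tempfile(fileext = if (delim == "\t") ".tsv" else ".csv")
  readr::write_delim(df, path, delim = delim)
  path
}
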