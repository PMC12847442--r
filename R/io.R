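# Table readers/writers and the packaged published group-mean tables.

.schema_columns <- list(
  enzymes  = c("sample_id", "BG", "CBH", "NAG", "LAP", "ALP"),
  soil     = c("sample_id"),
  features = c("taxon_id"),
  metadata = c("sample_id", "mulch_years", "depth", "replicate")
)

#' Read a study table from TSV or CSV
#'
#' Reads one of the four table kinds the pipeline consumes and validates it
#' against its schema. The delimiter (tab or comma) is sniffed from the
#' header line; decimal separator is always `"."` and encoding UTF-8.
#'
#' Schemas:
#' \describe{
#'   \item{`enzymes`}{`sample_id` plus the five activities `BG`, `CBH`,
#'     `NAG`, `LAP`, `ALP` (non-negative; consistent but arbitrary units).}
#'   \item{`soil`}{`sample_id` plus numeric physicochemical columns
#'     (all concentrations must be non-negative).}
#'   \item{`features`}{`taxon_id`, optional `lineage`, and one non-negative
#'     integer count column per sample.}
#'   \item{`metadata`}{`sample_id`, `mulch_years` (0/5/10/15), `depth`
#'     (`"0-20"` or `"20-40"`), `replicate` (positive integer).}
#' }
#'
#' Empty cells are read as `NA` (missing); rows violating an invariant are
#' reported with their row numbers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"enzymes"`, `"soil"`, `"features"`, `"metadata"`.
#' @return A validated tibble.
#' @export
read_study_table <- function(path, schema = c("enzymes", "soil", "features", "metadata")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA"))
  validate_study_table(tab, schema)
}

validate_study_table <- function(tab, schema) {
  required <- .schema_columns[[schema]]
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema '", schema, "' requires missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (schema %in% c("enzymes", "soil", "metadata")) {
    dup <- tab$sample_id[duplicated(tab$sample_id)]
    if (length(dup) > 0) {
      abort(paste0("Duplicate sample_id: ", paste(unique(dup), collapse = ", ")))
    }
  }
  if (schema == "enzymes") {
    for (enz in .enzyme_names) {
      bad <- which(!is.na(tab[[enz]]) & tab[[enz]] < 0)
      if (length(bad) > 0) {
        abort(paste0("Negative ", enz, " activity in row(s): ",
                     paste(bad, collapse = ", ")))
      }
    }
    incomplete <- which(!stats::complete.cases(tab[.enzyme_names]))
    if (length(incomplete) > 0) {
      warn(paste0("Row(s) ", paste(incomplete, collapse = ", "),
                  " have missing enzyme activities and will be excluded ",
                  "from vector statistics."))
    }
  }
  if (schema == "soil") {
    num <- names(tab)[vapply(tab, is.numeric, logical(1))]
    for (v in num) {
      bad <- which(!is.na(tab[[v]]) & tab[[v]] < 0)
      if (length(bad) > 0) {
        abort(paste0("Negative ", v, " in row(s): ", paste(bad, collapse = ", ")))
      }
    }
  }
  if (schema == "features") {
    dup <- tab$taxon_id[duplicated(tab$taxon_id)]
    if (length(dup) > 0) {
      abort(paste0("Duplicate taxon_id: ", paste(unique(dup), collapse = ", ")))
    }
    counts <- feature_counts(tab)
    if (any(counts < 0, na.rm = TRUE)) abort("Negative counts in feature table.")
    if (any(abs(counts - round(counts)) > 1e-8, na.rm = TRUE)) {
      abort("Feature counts must be integers.")
    }
  }
  if (schema == "metadata") {
    treatment_label(tab$mulch_years) # validates values
    bad <- setdiff(unique(tab$depth), .depth_levels)
    if (length(bad) > 0) {
      abort(paste0("depth must be one of ", paste(.depth_levels, collapse = ", "),
                   "; got: ", paste(bad, collapse = ", ")))
    }
    if (any(tab$replicate < 1 | tab$replicate != round(tab$replicate))) {
      abort("replicate must be a positive integer.")
    }
  }
  tibble::as_tibble(tab)
}

# numeric count matrix (taxa x samples) from a feature tibble
feature_counts <- function(tab) {
  samp <- setdiff(names(tab), c("taxon_id", "lineage"))
  m <- as.matrix(tab[samp])
  rownames(m) <- tab$taxon_id
  m
}

#' Load a packaged group-mean fixture table
#'
#' The package ships the published treatment-by-depth group means and SDs for
#' soil physicochemical properties, enzyme activities (plus their C:N:P
#' stoichiometric ratios), and bacterial/fungal alpha diversity, transcribed
#' cell-for-cell at printed precision (n = 3 replicates per cell). Rows with
#' `treatment == "Overall"` carry the printed per-depth overall means.
#'
#' @param name One of `"table1_soil"`, `"table2_enzymes"`, `"table3_diversity"`.
#' @param overall If `FALSE` (default), drop the `"Overall"` rows and return
#'   the 8 treatment-by-depth cells per variable; if `TRUE`, return only the
#'   printed overall rows.
#' @return A tibble with columns `depth`, `treatment`, `variable`, `mean`,
#'   `sd`, `n`.
#' @examples
#' load_fixture("table2_enzymes") |> head()
#' @export
load_fixture <- function(name, overall = FALSE) {
  available <- c("table1_soil", "table2_enzymes", "table3_diversity")
  if (length(name) != 1 || !name %in% available) {
    abort(paste0("Unknown fixture '", paste(name, collapse = ","),
                 "'. Available: ", paste(available, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "stoichnet",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$n <- 3L
  tab <- tibble::as_tibble(tab)
  if (overall) {
    dplyr::filter(tab, .data$treatment == "Overall")
  } else {
    out <- dplyr::filter(tab, .data$treatment != "Overall")
    out$treatment <- factor(out$treatment, levels = .treatment_levels)
    out
  }
}

#' Fixture group means in wide per-variable form
#'
#' Convenience pivot of [load_fixture()]: one row per treatment-by-depth cell,
#' one column per variable, means only.
#'
#' @inheritParams load_fixture
#' @return A tibble with columns `depth`, `treatment`, then one per variable.
#' @export
fixture_means <- function(name) {
  load_fixture(name) |>
    dplyr::select("depth", "treatment", "variable", "mean") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "mean")
}

#' Write and re-read result tables
#'
#' `write_results()` serialises any result tibble (or list record, for JSON)
#' to TSV or JSON; `read_results()` reads it back so that a write/read
#' round-trip reproduces the record.
#'
#' @param result A data frame, or (for JSON) any list-like record.
#' @param path Output file path; the parent directory must exist.
#' @param format `"tsv"` or `"json"`.
#' @return `write_results()` returns `path` invisibly.
#' @export
write_results <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    abort(paste0("Directory does not exist: ", dirname(path)))
  }
  if (format == "tsv") {
    if (!is.data.frame(result)) abort("TSV output requires a data frame.")
    readr::write_tsv(result, path, progress = FALSE)
  } else {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
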