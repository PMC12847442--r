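# Ecoenzymatic stoichiometry: C:N:P ratios, vector length/angle, limitation
# classes, group summaries and percent-change contrasts.
#
# The five hydrolases split into acquisition groups:
#   C: BG + CBH,  N: NAG + LAP,  P: ALP
# and the vector statistics are computed on relative activities
#   x = C / (C + P),  y = C / (C + N)
# length = sqrt(x^2 + y^2) indexes relative microbial C limitation;
# angle = atan(y/x) in degrees indexes the N (<45 deg) vs P (>45 deg) side.

#' Enzyme stoichiometry vector statistics
#'
#' Computes, for each row of an enzyme activity table, the relative activity
#' coordinates `x` (C vs P acquisition) and `y` (C vs N acquisition), the
#' vector length `sqrt(x^2 + y^2)` (larger = stronger relative carbon
#' limitation) and the vector angle in degrees (angle of the point `(x, y)`
#' from the origin, i.e. `atan(y/x)`), and classifies nutrient limitation by
#' the 45-degree rule: angles above 45 degrees indicate relative phosphorus
#' limitation, below 45 degrees relative nitrogen limitation.
#'
#' Both statistics are scale-invariant: multiplying all five activities by a
#' common positive factor leaves them unchanged, so activity units only need
#' to be consistent within a table.
#'
#' Rows with a missing activity, or with a zero acquisition-group sum, are
#' dropped with a warning naming them (the vector is undefined there).
#'
#' @param data A data frame with numeric columns `BG`, `CBH`, `NAG`, `LAP`,
#'   `ALP`; any other columns (sample ids, grouping factors) are carried
#'   through.
#' @return The input columns minus the five activities, plus `x`, `y`,
#'   `vector_length`, `vector_angle` (degrees) and `limitation`
#'   (`"P_limited"`, `"N_limited"` or `"balanced_45"`).
#' @examples
#' fixture_means("table2_enzymes") |> enzyme_vectors()
#' @export
enzyme_vectors <- function(data) {
  check_enzyme_columns(data)
  c_acq <- data$BG + data$CBH
  n_acq <- data$NAG + data$LAP
  p_acq <- data$ALP
  usable <- !is.na(c_acq) & !is.na(n_acq) & !is.na(p_acq)
  if (!all(usable)) {
    warn(paste0("Dropping row(s) with missing enzyme activities: ",
                paste(which(!usable), collapse = ", ")))
  }
  zero <- usable & (c_acq <= 0 | n_acq <= 0 | p_acq <= 0)
  if (any(zero)) {
    grp <- dplyr::case_when(c_acq[zero] <= 0 ~ "C (BG+CBH)",
                            n_acq[zero] <= 0 ~ "N (NAG+LAP)",
                            TRUE ~ "P (ALP)")
    abort(paste0("Vector undefined: zero ", paste(unique(grp), collapse = " and "),
                 " acquisition activity in row(s) ",
                 paste(which(zero), collapse = ", ")))
  }
  out <- data[usable, setdiff(names(data), .enzyme_names), drop = FALSE]
  x <- (c_acq / (c_acq + p_acq))[usable]
  y <- (c_acq / (c_acq + n_acq))[usable]
  angle <- atan2(y, x) * 180 / pi
  tibble::as_tibble(out) |>
    dplyr::mutate(
      x = x, y = y,
      vector_length = sqrt(x^2 + y^2),
      vector_angle = angle,
      limitation = dplyr::case_when(
        angle > 45 ~ "P_limited",
        angle < 45 ~ "N_limited",
        TRUE ~ "balanced_45"
      )
    )
}

#' Enzyme C:N:P acquisition ratios
#'
#' The three activity ratios `(BG+CBH)/(NAG+LAP)`, `(BG+CBH)/ALP` and
#' `(NAG+LAP)/ALP`, with the identity `c_to_p = c_to_n * n_to_p`.
#'
#' @inheritParams enzyme_vectors
#' @return The non-enzyme input columns plus `c_to_n`, `c_to_p`, `n_to_p`.
#' @export
enzyme_ratios <- function(data) {
  check_enzyme_columns(data)
  c_acq <- data$BG + data$CBH
  n_acq <- data$NAG + data$LAP
  p_acq <- data$ALP
  if (any(n_acq <= 0 | p_acq <= 0, na.rm = TRUE)) {
    abort("Ratio undefined: zero NAG+LAP or ALP activity.")
  }
  tibble::as_tibble(data[setdiff(names(data), .enzyme_names)]) |>
    dplyr::mutate(c_to_n = c_acq / n_acq,
                  c_to_p = c_acq / p_acq,
                  n_to_p = n_acq / p_acq)
}

check_enzyme_columns <- function(data) {
  missing_cols <- setdiff(.enzyme_names, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Enzyme column(s) missing: ", paste(missing_cols, collapse = ", ")))
  }
  invisible(data)
}

#' Group means and SDs with per-depth overall means
#'
#' Summarises a long value table by treatment-by-depth group: per-group mean,
#' sample SD (n - 1 denominator) and n, plus, for each depth layer, an
#' "overall" row whose mean is the unweighted arithmetic mean of that depth's
#' treatment means (and whose SD is the SD of the pooled per-sample values).
#' Groups of size 1 get `sd = NA` with a warning.
#'
#' @param values Long tibble with columns `sample_id`, `variable`, `value`.
#' @param metadata Metadata tibble with `sample_id`, `mulch_years`, `depth`;
#'   every sample in `values` must appear exactly once.
#' @return A tibble with `depth`, `treatment` (factor, plus `"Overall"` rows),
#'   `variable`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(values, metadata) {
  need <- setdiff(c("sample_id", "variable", "value"), names(values))
  if (length(need) > 0) {
    abort(paste0("values must have column(s): ", paste(need, collapse = ", ")))
  }
  unmatched <- setdiff(unique(values$sample_id), metadata$sample_id)
  if (length(unmatched) > 0) {
    abort(paste0("Sample(s) without metadata: ", paste(unmatched, collapse = ", ")))
  }
  joined <- dplyr::inner_join(values, metadata, by = "sample_id") |>
    dplyr::mutate(treatment = treatment_label(.data$mulch_years))
  per_group <- joined |>
    dplyr::group_by(.data$depth, .data$treatment, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (any(per_group$n == 1)) {
    warn("Group(s) with a single replicate: SD reported as missing.")
  }
  overall <- per_group |>
    dplyr::group_by(.data$depth, .data$variable) |>
    dplyr::summarise(o_mean = mean(.data$mean), .groups = "drop")
  overall_sd <- joined |>
    dplyr::group_by(.data$depth, .data$variable) |>
    dplyr::summarise(o_sd = sd(.data$value), o_n = dplyr::n(), .groups = "drop")
  overall <- dplyr::inner_join(overall, overall_sd, by = c("depth", "variable")) |>
    dplyr::transmute(.data$depth, treatment = "Overall", .data$variable,
                     mean = .data$o_mean, sd = .data$o_sd, n = .data$o_n)
  per_group$treatment <- as.character(per_group$treatment)
  dplyr::bind_rows(per_group, overall) |>
    dplyr::arrange(.data$depth, .data$variable)
}

#' Signed percent change relative to a baseline
#'
#' `100 * (value - baseline) / baseline`, vectorised; used throughout for
#' depth and mulching contrasts (e.g. deep-layer overall water content 18.5
#' vs surface 16.6 gives +11.45 percent).
#'
#' @param value,baseline Numeric vectors (recycled); `baseline` must be
#'   non-zero.
#' @return Numeric vector of signed percent changes.
#' @examples
#' percent_change(18.5, 16.6)
#' @export
percent_change <- function(value, baseline) {
  if (any(baseline == 0, na.rm = TRUE)) abort("Baseline of 0: percent change undefined.")
  100 * (value - baseline) / baseline
}
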