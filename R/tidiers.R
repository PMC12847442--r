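# broom-style tidiers for fitted objects.

#' Turn a stoichnet result object into a tidy tibble
#'
#' @param x A `"mantel_test"`, `"anova2"` or `"duncan_letters"` object.
#' @param ... Unused.
#' @return A tibble with one row per statistic/term/group.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a stoichnet result object
#'
#' @inheritParams tidy
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(statistic = x$r_m, p_value = x$p,
                 n_perm = x$n_perm, alternative = x$alternative)
}

#' @rdname glance
#' @export
glance.mantel_test <- function(x, ...) {
  tibble::tibble(r_m = x$r_m, p_value = x$p, n = x$n, n_perm = x$n_perm)
}

#' @rdname tidy
#' @export
tidy.anova2 <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname glance
#' @export
glance.anova2 <- function(x, ...) {
  ss <- x$sum_sq
  tibble::tibble(ss_total = sum(ss),
                 r_squared = sum(ss[1:3]) / sum(ss),
                 df_error = x$df[x$term == "Residuals"],
                 ms_error = x$mean_sq[x$term == "Residuals"])
}

#' @rdname tidy
#' @export
tidy.duncan_letters <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "alpha") <- NULL
  attr(out, "mse") <- NULL
  attr(out, "df_error") <- NULL
  out
}

#' @rdname glance
#' @export
glance.duncan_letters <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x), alpha = attr(x, "alpha"),
                 mse = attr(x, "mse"), df_error = attr(x, "df_error"),
                 all_distinct = !anyDuplicated(x$letters) &&
                   all(nchar(x$letters) == 1))
}
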