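# Inference: permutation Mantel test, balanced two-way ANOVA (raw or
# summary-statistics input), Duncan's multiple range letters, and pairwise
# correlation screens.

#' Permutation Mantel test
#'
#' Correlation between two distance matrices: `r_m` is the Pearson
#' correlation of the upper-triangle entries, and significance comes from
#' jointly permuting the rows and columns of `dist_b`. The default
#' alternative is one-sided "greater" (the usual ecological convention);
#' `p = (1 + #{permuted r >= observed}) / (n_perm + 1)`. With
#' `exhaustive = TRUE` all `n!` relabelings are enumerated and
#' `p = #{r_perm >= r_obs} / n!` (the identity included), which is exact for
#' small matrices.
#'
#' @param dist_a,dist_b Symmetric zero-diagonal distance matrices (or
#'   `dist` objects) of the same size, at least 4 x 4.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exhaustive Enumerate all permutations instead of sampling
#'   (feasible up to ~8 samples).
#' @return An object of class `"mantel_test"`: list with `r_m`, `p`,
#'   `n_perm`, `n`, `alternative`, `seed`. Has [tidy()] and [glance()]
#'   methods.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  if (!isTRUE(all.equal(dim(a), dim(b)))) abort("Distance matrices differ in size.")
  n <- nrow(a)
  if (n < 4) abort("Mantel test needs matrices of size >= 4.")
  if (max(abs(a - t(a))) > 1e-8 || max(abs(b - t(b))) > 1e-8) {
    abort("Distance matrices must be symmetric.")
  }
  ut <- upper.tri(a)
  va <- a[ut]
  if (sd(va) == 0 || sd(b[ut]) == 0) {
    abort("Constant upper triangle: Mantel correlation undefined.")
  }
  r_obs <- cor(va, b[ut])
  stat <- function(perm) cor(va, b[perm, perm][ut])
  if (exhaustive) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, stat, numeric(1))
    n_perm <- length(perms)
    p <- if (alternative == "greater") {
      mean(r_perm >= r_obs - 1e-12)
    } else {
      mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) stat(sample.int(n)), numeric(1))
    p <- if (alternative == "greater") {
      (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1)
    } else {
      (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(r_m = r_obs, p = p, n_perm = n_perm, n = n,
                 alternative = alternative, seed = seed),
            class = "mantel_test")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel permutation test\n")
  cat(sprintf("  r_m = %.4f, p = %.4g (%s, %d permutations, n = %d)\n",
              x$r_m, x$p, x$alternative, x$n_perm, x$n))
  invisible(x)
}

#' Balanced two-way ANOVA with interaction
#'
#' Fixed-effects two-way ANOVA (factor A x factor B, interaction included)
#' for a balanced design, in two modes:
#' \describe{
#'   \item{raw}{`data` holds one row per observation; fitted via
#'     [stats::aov()] (type-I = type-II for balanced data).}
#'   \item{summary}{`data` holds one row per cell with columns `mean`, `sd`,
#'     `n`; sums of squares are reconstructed from the cell statistics
#'     (`SS_error = sum (n - 1) sd^2`, factor SS from the cell means), which
#'     is exact for balanced designs. This is the mode used with published
#'     mean +/- SD tables.}
#' }
#'
#' @param data Tibble; raw mode needs `response`, summary mode needs
#'   `mean`, `sd`, `n`.
#' @param factor_a,factor_b Column names (strings) of the two factors, e.g.
#'   depth layer and mulching years.
#' @param response Response column name (raw mode only).
#' @return An object of class `"anova2"`: tibble with one row per term
#'   (`factor_a`, `factor_b`, interaction, Residuals) and columns `term`,
#'   `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`.
#' @export
anova_two_way <- function(data, factor_a, factor_b, response = NULL) {
  have_summary <- all(c("mean", "sd", "n") %in% names(data))
  if (is.null(response) && !have_summary) {
    abort("Provide `response` (raw mode) or mean/sd/n columns (summary mode).")
  }
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (is.null(response)) {
    cells <- data
    if (nrow(cells) != nlevels(fa) * nlevels(fb)) {
      abort("Summary mode needs exactly one row per factor-level cell.")
    }
    if (length(unique(cells$n)) != 1) abort("Summary mode requires a balanced design.")
    n <- cells$n[1]
    if (n < 2) abort("No error term: cell n must be >= 2.")
    a_lev <- nlevels(fa); b_lev <- nlevels(fb)
    grand <- mean(cells$mean)
    mean_a <- tapply(cells$mean, fa, mean)
    mean_b <- tapply(cells$mean, fb, mean)
    ss_a <- b_lev * n * sum((mean_a - grand)^2)
    ss_b <- a_lev * n * sum((mean_b - grand)^2)
    ss_cells <- n * sum((cells$mean - grand)^2)
    ss_ab <- ss_cells - ss_a - ss_b
    ss_e <- sum((cells$n - 1) * cells$sd^2)
    df <- c(a_lev - 1, b_lev - 1, (a_lev - 1) * (b_lev - 1),
            a_lev * b_lev * (n - 1))
    ss <- c(ss_a, ss_b, ss_ab, ss_e)
  } else {
    y <- data[[response]]
    tabn <- table(fa, fb)
    if (length(unique(c(tabn))) != 1) abort("Raw mode requires a balanced design.")
    if (any(tabn < 2)) abort("No error term: at least 2 replicates per cell.")
    fit <- aov(y ~ fa * fb)
    at <- summary(fit)[[1]]
    df <- at[["Df"]]
    ss <- at[["Sum Sq"]]
  }
  ms <- ss / df
  # a factor with (numerically) zero SS has F = 0 even if the error MS is 0
  zero <- ss[1:3] <= .Machine$double.eps^0.5 * max(sum(ss), 1)
  f <- c(ifelse(zero, 0, ms[1:3] / ms[4]), NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  out <- tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals"),
    df = df, sum_sq = ss, mean_sq = ms, statistic = f, p_value = p)
  class(out) <- c("anova2", class(out))
  out
}

#' Duncan's multiple range test letters
#'
#' Step-down multiple comparison of group means after an ANOVA. Means are
#' sorted in descending order; the critical range for comparing the extremes
#' of a span of `p` ordered means is
#' `R_p = q(1 - alpha_p, p, df_error) * sqrt(MSE / n_h)` with the protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)` (studentized-range quantile via
#' [stats::qtukey()]) and `n_h` the harmonic mean of the group sizes.
#' Letters come from the standard insert-and-absorb display: every maximal
#' run of ordered means whose extremes differ by less than its critical
#' range shares a letter, so groups sharing any letter are not significantly
#' different at `alpha`. Ties in means are broken by group label for
#' deterministic output.
#'
#' @param data Tibble with the response and grouping columns.
#' @param response,group Column names (strings).
#' @param alpha Significance level (default 0.05).
#' @param mse,df_error Error mean square and degrees of freedom. If omitted,
#'   both come from the one-way ANOVA of `response` on `group`.
#' @return An object of class `"duncan_letters"`: tibble with `group`,
#'   `mean`, `n`, `letters`, ordered by descending mean, with `alpha`,
#'   `mse`, `df_error` as attributes.
#' @export
duncan_letters <- function(data, response, group, alpha = 0.05,
                           mse = NULL, df_error = NULL) {
  y <- data[[response]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("Duncan's test needs at least 2 groups.")
  if (is.null(mse) || is.null(df_error)) {
    fit <- aov(y ~ g)
    at <- summary(fit)[[1]]
    mse <- at[["Mean Sq"]][2]
    df_error <- at[["Df"]][2]
  }
  if (df_error <= 0) abort("Non-positive error degrees of freedom.")
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ord <- order(-means, names(means))
  means <- means[ord]
  ns <- ns[ord]
  k <- length(means)
  n_h <- k / sum(1 / ns)
  crit <- vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - alpha_p, p, df_error) * sqrt(mse / n_h)
  }, numeric(1))
  # maximal non-significant runs of the ordered means: a whole range is
  # declared non-significant when its extremes differ by less than the
  # critical range for its span
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    for (u in k:i) {
      if (u == i || (means[i] - means[u]) < crit[u - i]) {
        j <- u
        break
      }
    }
    runs[[i]] <- c(i, j)
  }
  maximal <- Filter(function(r) {
    !any(vapply(runs, function(s) {
      (s[1] < r[1] && s[2] >= r[2]) || (s[1] <= r[1] && s[2] > r[2])
    }, logical(1)))
  }, runs)
  maximal <- unique(maximal)
  letters_vec <- character(k)
  for (m in seq_along(maximal)) {
    r <- maximal[[m]]
    for (i in r[1]:r[2]) {
      letters_vec[i] <- paste0(letters_vec[i], letters[m])
    }
  }
  out <- tibble::tibble(group = names(means), mean = unname(means),
                        n = as.integer(ns), letters = letters_vec)
  attr(out, "alpha") <- alpha
  attr(out, "mse") <- mse
  attr(out, "df_error") <- df_error
  class(out) <- c("duncan_letters", class(out))
  out
}

#' Pairwise correlation screen between two variable sets
#'
#' Pearson (default) or Spearman correlation of every variable in `table_a`
#' against every variable in `table_b` over paired samples, with two-sided
#' p-values from [stats::cor.test()] and significance stars (`*` p < 0.05,
#' `**` p < 0.01). Zero-variance variables are flagged with `NA`.
#'
#' @param table_a,table_b Data frames of numeric columns with matching rows
#'   (>= 4 samples). `table_b` defaults to `table_a`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble with `var_a`, `var_b`, `r`, `p`, `stars`.
#' @export
correlation_screen <- function(table_a, table_b = table_a,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- dplyr::select(tibble::as_tibble(table_a), dplyr::where(is.numeric))
  b <- dplyr::select(tibble::as_tibble(table_b), dplyr::where(is.numeric))
  if (nrow(a) != nrow(b)) abort("Tables must have paired rows.")
  if (nrow(a) < 4) abort("At least 4 paired samples required.")
  grid <- tidyr::expand_grid(var_a = names(a), var_b = names(b))
  res <- purrr::pmap_dfr(grid, function(var_a, var_b) {
    x <- a[[var_a]]; y <- b[[var_b]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(var_a = var_a, var_b = var_b,
                            r = NA_real_, p = NA_real_, stars = ""))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    tibble::tibble(var_a = var_a, var_b = var_b,
                   r = unname(ct$estimate), p = ct$p.value,
                   stars = if (ct$p.value < 0.01) "**"
                           else if (ct$p.value < 0.05) "*" else "")
  })
  res
}
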