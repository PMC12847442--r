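test_that("Mantel of a matrix with itself is maximal with the smallest p", {
  set.seed(2)
  d <- as.matrix(dist(matrix(runif(12), 6)))
  mt <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(mt$r_m, 1)
  expect_equal(mt$p, 1 / 100)
  expect_s3_class(tidy(mt), "tbl_df")
  expect_equal(glance(mt)$n, 6)
})

test_that("exhaustive Mantel p equals full-enumeration on size-4 matrices", {
  set.seed(9)
  a <- as.matrix(dist(matrix(runif(8), 4)))
  b <- as.matrix(dist(matrix(runif(8), 4)))
  mt <- mantel_test(a, b, exhaustive = TRUE)
  expect_equal(mt$n_perm, 24)

  # independent oracle: iterate the 24 permutations from scratch
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  r_all <- apply(perms, 1, function(p) cor(a[ut], b[p, p][ut]))
  expect_equal(mt$r_m, r_obs)
  expect_equal(mt$p, mean(r_all >= r_obs - 1e-12))
})

test_that("Mantel p is invariant to joint relabeling and matches vegan", {
  set.seed(14)
  a <- as.matrix(dist(matrix(runif(16), 8)))
  b <- as.matrix(dist(matrix(runif(16), 8)))
  m1 <- mantel_test(a, b, exhaustive = TRUE)
  perm <- sample(8)
  m2 <- mantel_test(a[perm, perm], b[perm, perm], exhaustive = TRUE)
  expect_equal(m1$p, m2$p, tolerance = 1e-12)
  expect_equal(m1$r_m, m2$r_m, tolerance = 1e-12)

  vg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(m1$r_m, unname(vg$statistic), tolerance = 1e-12)

  expect_error(mantel_test(a[1:3, 1:3], b[1:3, 1:3]), "size >= 4")
  cst <- matrix(1, 8, 8); diag(cst) <- 0
  expect_error(mantel_test(a, cst), "Constant")
})

test_that("two-way ANOVA matches a hand-worked 2x2 example and aov", {
  # hand example: depth x treatment, n = 2 per cell
  dat <- tibble::tibble(
    depth = rep(c("top", "deep"), each = 4),
    trt = rep(rep(c("ck", "m"), each = 2), 2),
    value = c(10, 12, 20, 22, 14, 16, 30, 34))
  res <- anova_two_way(dat, "depth", "trt", response = "value")
  # oracle: direct sums of squares
  grand <- mean(dat$value)
  ss_a <- 4 * sum((tapply(dat$value, dat$depth, mean) - grand)^2)
  ss_b <- 4 * sum((tapply(dat$value, dat$trt, mean) - grand)^2)
  cellm <- tapply(dat$value, interaction(dat$depth, dat$trt), mean)
  ss_cells <- 2 * sum((cellm - grand)^2)
  ss_e <- sum((dat$value - rep(cellm[interaction(dat$depth, dat$trt)], 1))^2)
  expect_equal(res$sum_sq[1], ss_a, tolerance = 1e-9)
  expect_equal(res$sum_sq[2], ss_b, tolerance = 1e-9)
  expect_equal(res$sum_sq[3], ss_cells - ss_a - ss_b, tolerance = 1e-9)
  expect_equal(res$sum_sq[4], ss_e, tolerance = 1e-9)
  expect_equal(res$statistic[1:3],
               (res$sum_sq[1:3] / res$df[1:3]) / (ss_e / 4), tolerance = 1e-9)

  # constant response: all F are zero
  cdat <- dplyr::mutate(dat, value = 5)
  cres <- anova_two_way(cdat, "depth", "trt", response = "value")
  expect_equal(cres$statistic[1:3], c(0, 0, 0))
})

test_that("summary-mode ANOVA agrees with raw mode and decomposes exactly", {
  set.seed(27)
  raw <- tidyr::expand_grid(depth = c("0-20", "20-40"),
                            years = c(0, 5, 10, 15),
                            rep = 1:3) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 10 + 2 * (depth == "0-20") +
                                  0.1 * years, 1))
  res_raw <- anova_two_way(raw, "depth", "years", response = "value")
  summ <- raw |>
    dplyr::group_by(depth, years) |>
    dplyr::summarise(mean = mean(value), sd = sd(value), n = dplyr::n(),
                     .groups = "drop")
  res_sum <- anova_two_way(summ, "depth", "years")
  expect_equal(res_sum$sum_sq, res_raw$sum_sq, tolerance = 1e-9)
  expect_equal(res_sum$statistic[1:3], res_raw$statistic[1:3], tolerance = 1e-9)
  expect_equal(res_sum$p_value[1:3], res_raw$p_value[1:3], tolerance = 1e-9)

  # SS decomposition: parts sum to the total corrected SS
  ss_total <- sum((raw$value - mean(raw$value))^2)
  expect_equal(sum(res_raw$sum_sq), ss_total, tolerance = 1e-9 * ss_total)

  expect_error(anova_two_way(raw[-1, ], "depth", "years", response = "value"),
               "balanced")
  expect_error(anova_two_way(dplyr::mutate(summ, n = 1), "depth", "years"),
               "error term")
})

test_that("Duncan letters separate clear groups and keep identical ones together", {
  same <- tibble::tibble(g = rep(c("A", "B"), each = 3),
                         y = c(5.0, 5.1, 4.9, 5.0, 5.1, 4.9))
  ls <- duncan_letters(same, "y", "g")
  expect_equal(ls$letters, c("a", "a"))

  far <- tibble::tibble(g = rep(c("A", "B"), each = 3),
                        y = c(100, 101, 99, 5, 6, 4))
  lf <- duncan_letters(far, "y", "g")
  expect_equal(lf$group, c("A", "B"))
  expect_equal(lf$letters, c("a", "b"))
  expect_true(glance(lf)$all_distinct)
})

test_that("Duncan letters agree with the brute-force pairwise range oracle", {
  toy <- tibble::tibble(
    g = rep(c("w", "x", "y", "z"), each = 3),
    y = c(28.1, 27.6, 28.4, 27.8, 27.3, 28.0, 24.9, 25.3, 24.6,
          24.6, 25.1, 24.8))
  dl <- duncan_letters(toy, "y", "g", alpha = 0.05)

  # oracle: protected pairwise decisions composed by hand
  means <- sort(tapply(toy$y, toy$g, mean), decreasing = TRUE)
  fit <- summary(aov(y ~ g, data = toy))[[1]]
  mse <- fit[["Mean Sq"]][2]
  dfe <- fit[["Df"]][2]
  k <- length(means)
  crit <- function(p) {
    # protected level: quantile at (1 - alpha)^(p - 1)
    qtukey((1 - 0.05)^(p - 1), p, dfe) * sqrt(mse / 3)
  }
  # pair (i, j) is non-significant iff some enclosing run of ordered means
  # has extreme difference below its critical range
  nonsig <- function(i, j) {
    any(vapply(seq_len(k), function(l) {
      any(vapply(l:k, function(u) {
        l <= i && j <= u && (means[l] - means[u]) < crit(u - l + 1)
      }, logical(1)))
    }, logical(1)))
  }
  share <- function(i, j) {
    any(strsplit(dl$letters[i], "")[[1]] %in% strsplit(dl$letters[j], "")[[1]])
  }
  expect_equal(dl$group, names(means))
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      expect_equal(share(i, j), nonsig(i, j),
                   info = paste("pair", i, j))
    }
  }
})

test_that("Duncan letters collapse to one group as alpha shrinks", {
  set.seed(33)
  dat <- tibble::tibble(g = rep(letters[1:4], each = 3),
                        y = rnorm(12, rep(c(10, 11, 12, 13), each = 3), 1))
  tiny <- duncan_letters(dat, "y", "g", alpha = 1e-9)
  expect_true(all(tiny$letters == "a"))
  expect_error(duncan_letters(dat[1:3, ], "y", "g"), "2 groups")
})

test_that("correlation screens match per-pair tests and flag degenerate input", {
  set.seed(4)
  a <- tibble::tibble(u = runif(10), v = runif(10))
  self <- correlation_screen(a["u"], a["u"])
  expect_equal(self$r, 1)

  anti <- correlation_screen(a["u"], tibble::tibble(w = -a$u))
  expect_equal(anti$r, -1)

  b <- tibble::tibble(p = rnorm(10), q = rnorm(10), s = rnorm(10),
                      t2 = rnorm(10), z = rnorm(10))
  sc <- correlation_screen(b, b)
  expect_equal(nrow(sc), 25)
  for (i in c(1, 7, 13, 24)) {
    ct <- cor.test(b[[sc$var_a[i]]], b[[sc$var_b[i]]])
    expect_equal(sc$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sc$p[i], ct$p.value, tolerance = 1e-12)
  }
  const <- correlation_screen(a, tibble::tibble(c = rep(1, 10)))
  expect_true(all(is.na(const$r)))
  expect_error(correlation_screen(a[1:3, ], a[1:3, ]), "4 paired")
})
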