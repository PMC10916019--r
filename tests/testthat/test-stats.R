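# Independent oracle: Kruskal-Wallis H from first principles on midranks
# with tie correction.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  tab <- table(x)
  h / (1 - sum(tab^3 - tab) / (n^3 - n))
}

# Independent oracle: two-group rank-sum z with tie-corrected variance.
ranksum_z_oracle <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  n2 <- length(b)
  n <- n1 + n2
  r1 <- sum(rank(x)[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  tab <- table(x)
  v <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  (r1 - mu) / sqrt(v)
}

test_that("Kruskal-Wallis matches a hand-computed rank statistic", {
  groups <- list(a = c(1, 2, 3), b = c(101, 102, 103))
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, kw_oracle(groups), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # with ties
  tied <- list(a = c(1, 1, 2, 5), b = c(2, 2, 3), c = c(5, 5, 6, 7, 7))
  res2 <- kruskal_wallis(tied)
  expect_equal(res2$statistic, kw_oracle(tied), tolerance = 1e-12)
  expect_equal(res2$p_value,
               stats::pchisq(res2$statistic, 2, lower.tail = FALSE))
})

test_that("fully tied data give H = 0 and p = 1", {
  res <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  d <- dunn_posthoc(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(d$p_adjusted, 1)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(42)
  groups <- list(a = rlnorm(12), b = rlnorm(9, 0.5), c = rlnorm(7, -0.3))
  h0 <- kruskal_wallis(groups)$statistic
  for (f in list(log, exp, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(kruskal_wallis(lapply(groups, f))$statistic, h0,
                 tolerance = 1e-12)
  }
})

test_that("Dunn on two groups reduces to the rank-sum normal approximation", {
  set.seed(3)
  a <- rlnorm(14)
  b <- rlnorm(11, 0.4)
  d <- dunn_posthoc(list(a = a, b = b), adjust = "none")
  z_oracle <- ranksum_z_oracle(a, b)
  expect_equal(abs(d$z), abs(z_oracle), tolerance = 1e-9)
  expect_equal(d$p_value, 2 * stats::pnorm(-abs(z_oracle)), tolerance = 1e-9)
  # and with heavy ties
  a2 <- c(1, 1, 2, 2, 3)
  b2 <- c(2, 3, 3, 4)
  d2 <- dunn_posthoc(list(a = a2, b = b2), adjust = "none")
  expect_equal(abs(d2$z), abs(ranksum_z_oracle(a2, b2)), tolerance = 1e-9)
})

test_that("Dunn separates a strongly shifted group and respects Bonferroni", {
  set.seed(4)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, 50))
  d <- dunn_posthoc(g, adjust = "bonferroni")
  far <- d$p_adjusted[(d$group_a == "a" & d$group_b == "c") |
                      (d$group_a == "b" & d$group_b == "c")]
  near <- d$p_adjusted[d$group_a == "a" & d$group_b == "b"]
  expect_true(all(far < 0.001))
  expect_gt(near, 0.05)
  none <- dunn_posthoc(g, adjust = "none")
  expect_true(all(d$p_adjusted >= none$p_adjusted))
})

test_that("degenerate group layouts error instead of crashing", {
  expect_error(kruskal_wallis(list(a = 1, b = 2)), "three")
  expect_error(kruskal_wallis(list(a = c(1, 2, 3))), "two groups")
  expect_error(kruskal_wallis(list(a = numeric(0), b = c(1, 2, 3))))
})

test_that("box summaries follow the inclusive quartile convention", {
  s <- summarize_box(c(1, 2, 3, 4, 5))
  expect_equal(unlist(s[c("mean", "median", "q1", "q3", "min", "max")]),
               c(mean = 3, median = 3, q1 = 2, q3 = 4, min = 1, max = 5))
  one <- summarize_box(0.6)
  expect_true(all(unlist(one[c("mean", "median", "q1", "q3", "min", "max")])
                  == 0.6))
  expect_error(summarize_box(numeric(0)))
})

test_that("compare_bands annotates stars at the conventional thresholds", {
  set.seed(9)
  n <- 30
  tbl <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:n),
    phenotype = rep(c("linear", "circular"), each = n / 2),
    trap_region = "tail",
    sample_group = "prog80_20",
    band_0_2_nN = c(rlnorm(n / 2, log(0.6), 0.3), rlnorm(n / 2, log(0.1), 0.3)),
    band_3_5_nN = rlnorm(n, log(0.3), 0.3)
  )
  cmp <- compare_bands(tbl, group_by = "phenotype")
  td <- tidy(cmp)
  expect_equal(nrow(td), 2L) # 2 bands x 1 pair
  expect_equal(td$stars[td$band == "0-2 Hz"], "***")
  expect_equal(td$stars[td$band == "3-5 Hz"], "ns")
  gl <- glance(cmp)
  expect_equal(gl$n_cells, 30)
  expect_equal(gl$n_groups, 2L)
  # summaries agree with summarize_box on the raw columns
  s <- cmp$summaries
  lin02 <- s[s$band == "0-2 Hz" & s$group == "linear", ]
  expect_equal(lin02$median,
               median(tbl$band_0_2_nN[tbl$phenotype == "linear"]))
})

test_that("compare_bands rejects empty groups and missing columns", {
  tbl <- tibble::tibble(
    cell_id = c("a", "b", "c", "d"),
    phenotype = factor(c("linear", "linear", "linear", "linear"),
                       levels = c("linear", "circular")),
    band_0_2_nN = c(1, 2, 3, 4)
  )
  expect_error(compare_bands(tbl, "phenotype"), "circular")
  expect_error(compare_bands(dplyr::select(tbl, -band_0_2_nN), "phenotype"),
               "band_")
  expect_error(compare_bands(tbl, "nonexistent"), "not found")
})

test_that("null p-values are uniform under label permutation", {
  set.seed(101)
  n_sim <- 2000
  p <- replicate(n_sim, {
    x <- rlnorm(43, log(0.6), 0.33)
    g <- rep(c("a", "b"), c(26, 17))
    kruskal_wallis(x, g)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
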