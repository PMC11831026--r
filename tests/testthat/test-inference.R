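test_that("one-sample t tests per cell match the textbook formula", {
  d <- tibble::tibble(cell = "H/H", W = c(0.8, 1.0, 1.2, 1.0))
  out <- test_vs_zero(d, "W")
  expect_equal(out$statistic, 12.24745, tolerance = 1e-5)
  expect_equal(out$df, 3)
  expect_equal(out$p_raw, 2 * stats::pt(-12.24745, 3), tolerance = 1e-5)
  expect_true(out$significant)

  sym <- tibble::tibble(cell = "H/H", W = c(-1, 1, -1, 1))
  out2 <- test_vs_zero(sym, "W")
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_raw, 1)
  expect_false(out2$significant)
})

test_that("zero-variance groups are degenerate, with sign-exact calls", {
  d <- tibble::tibble(cell = rep(c("H/H", "H/L"), each = 3),
                      W = rep(c(2, 0), each = 3))
  out <- test_vs_zero(d, "W")
  expect_true(all(out$degenerate))
  expect_true(all(is.na(out$p_raw)))
  expect_true(out$significant[out$cell == "H/H"])
  expect_false(out$significant[out$cell == "H/L"])
})

test_that("Holm adjustment matches the worked family and the oracle", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.20, 0.30)),
               c(0.04, 0.06, 0.40, 0.40))
  set.seed(41)
  for (m in 1:6) {
    for (k in 1:20) {
      p <- round(runif(m), 3)  # rounding forces occasional ties
      expect_equal(holm_adjust(p), holm_oracle(p))
      expect_true(all(holm_adjust(p) >= p))
    }
  }
})

test_that("Holm is applied over the declared family of history cells", {
  set.seed(42)
  d <- tibble::tibble(cell = rep(cell_levels_fixture(), each = 4),
                      W = rnorm(16, mean = rep(c(2, 0, 0, 0), each = 4)))
  out <- test_vs_zero(d, "W")
  expect_equal(out$p_adjusted, holm_oracle(out$p_raw))
})

test_that("two-cell Tukey reduces to the pooled-variance two-sample t", {
  set.seed(43)
  d <- tibble::tibble(cell = rep(c("H/H", "L/L"), each = 4),
                      W = c(rnorm(4, 1), rnorm(4, 0.2)))
  tk <- compare_histories(d, "W", mode = "all-pairs")
  tt <- stats::t.test(W ~ cell, data = d, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$estimate, -diff(rev(tt$estimate)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a cell shifted by 10 sigma separates in both contrast modes", {
  set.seed(44)
  d <- tibble::tibble(cell = rep(cell_levels_fixture(), each = 4),
                      W = rnorm(16, sd = 0.2) +
                        rep(c(0, 0, 2, 0), each = 4))
  tk <- compare_histories(d, "W", mode = "all-pairs")
  hit <- grepl("L/H", tk$contrast)
  expect_true(all(tk$significant[hit]))
  expect_false(any(tk$significant[!hit]))

  dn <- compare_histories(d, "W", mode = "vs-reference")
  expect_equal(nrow(dn), 3)
  expect_true(dn$significant[dn$cell == "L/H"])
  expect_false(any(dn$significant[dn$cell != "L/H"]))
})

test_that("a missing reference cell is an error in vs-reference mode", {
  d <- tibble::tibble(cell = rep(c("H/L", "L/L"), each = 3), W = rnorm(6))
  expect_error(compare_histories(d, "W", mode = "vs-reference"),
               class = "myxofit_domain_error")
})

test_that("noise-free data yield degenerate but sign-exact contrasts", {
  d <- tibble::tibble(cell = rep(cell_levels_fixture(), each = 4),
                      W = rep(c(1.5, 1.5, 0.8, -2), each = 4))
  dn <- compare_histories(d, "W", mode = "vs-reference")
  expect_true(all(dn$degenerate))
  expect_true(all(is.na(dn$p_adjusted)))
  expect_true(dn$significant[dn$cell == "L/H"])
  expect_lt(dn$estimate[dn$cell == "L/H"], 0)
  expect_false(dn$significant[dn$cell == "H/L"])
})

test_that("contrast p-values are reproducible and leave the RNG untouched", {
  set.seed(45)
  d <- tibble::tibble(cell = rep(cell_levels_fixture(), each = 4),
                      W = rnorm(16, rep(c(1, 0.5, 0, 0), each = 4), 0.3))
  before <- .Random.seed
  p1 <- compare_histories(d, "W", mode = "vs-reference")$p_adjusted
  expect_identical(.Random.seed, before)
  p2 <- compare_histories(d, "W", mode = "vs-reference")$p_adjusted
  expect_identical(p1, p2)
})

test_that("the factorial ANOVA is order-invariant on balanced designs", {
  skip_if_not_installed("car")
  set.seed(46)
  d <- tidyr::expand_grid(genotype = c("Ch1", "Ch2"), nf = c("H", "L"),
                          np = c("H", "L"), replicate = 1:4)
  d$W <- rnorm(nrow(d)) + (d$np == "L") * -1
  tab <- factorial_anova(d, "W", c("genotype", "nf", "np"))
  expect_equal(nrow(tab), 7)
  expect_true(all(tab$df == 1))
  expect_equal(attr(tab, "df_residual"), 24)

  # Type III needs sum-to-zero contrasts to be meaningful.
  d2 <- dplyr::mutate(d, dplyr::across(c("genotype", "nf", "np"),
                                       ~ factor(.x)))
  fit <- stats::lm(W ~ genotype * nf * np, data = d2,
                   contrasts = list(genotype = "contr.sum", nf = "contr.sum",
                                    np = "contr.sum"))
  t3 <- car::Anova(fit, type = 3)
  for (term in c("genotype", "nf", "np")) {
    expect_equal(tab$statistic[tab$term == term],
                 t3[term, "F value"], tolerance = 1e-9)
  }
})

test_that("the factorial ANOVA refuses empty cells, naming them", {
  d <- tidyr::expand_grid(nf = c("H", "L"), np = c("H", "L"),
                          replicate = 1:3)
  d$W <- rnorm(nrow(d))
  d <- d[!(d$nf == "L" & d$np == "L"), ]
  expect_error(factorial_anova(d, "W", c("nf", "np")), regexp = "L:L",
               class = "myxofit_domain_error")
})

test_that("ANOVA p-values are uniform under the null and detect real shifts", {
  set.seed(47)
  null_p <- replicate(120, {
    d <- tidyr::expand_grid(nf = c("H", "L"), np = c("H", "L"),
                            replicate = 1:4)
    d$W <- rnorm(nrow(d), sd = 0.2)
    tab <- factorial_anova(d, "W", c("nf", "np"))
    tab$p[tab$term == "np"]
  })
  ks <- stats::ks.test(null_p, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lt(mean(null_p < 0.05), 0.12)

  power_hits <- replicate(40, {
    d <- tidyr::expand_grid(nf = c("H", "L"), np = c("H", "L"),
                            replicate = 1:4)
    d$W <- rnorm(nrow(d), sd = 0.2) + (d$np == "L") * 1.0
    tab <- factorial_anova(d, "W", c("nf", "np"))
    tab$p[tab$term == "np"] < 0.05
  })
  expect_gt(mean(power_hits), 0.8)
})

test_that("outcome classification applies the sign-and-significance rules", {
  zt <- tibble::tibble(
    cell = cell_levels_fixture(),
    mean = c(1.2, 1.1, 0.9, -1.5),
    p_adjusted = c(0.001, 0.004, 0.01, 0.002),
    significant = TRUE, degenerate = FALSE)
  # No reference contrasts: every significantly positive cell is "+".
  oc <- classify_outcomes(zt)
  expect_equal(oc$verdict, c("+", "+", "+", "antagonized"))

  # A significant decrease versus H/H downgrades to reduced-but-present.
  dn <- tibble::tibble(cell = c("H/L", "L/H", "L/L"),
                       estimate = c(-0.1, -0.7, -2.7),
                       p_adjusted = c(0.6, 0.01, 0.001),
                       significant = c(FALSE, TRUE, TRUE),
                       degenerate = FALSE)
  oc2 <- classify_outcomes(zt, dn)
  expect_equal(oc2$verdict,
               c("+", "+", "reduced-but-present", "antagonized"))

  # Non-significant cells are "-" regardless of sign.
  zt$significant <- FALSE
  oc3 <- classify_outcomes(zt, dn)
  expect_true(all(oc3$verdict == "-"))

  # Pure function: identical inputs give identical verdicts.
  expect_identical(classify_outcomes(zt, dn), classify_outcomes(zt, dn))
})
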