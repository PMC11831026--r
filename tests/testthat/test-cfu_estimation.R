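test_that("pooling reduces to the single-plate estimate and pools counts", {
  one <- read_counts(make_plate(colonies = 50, dilution = 1e-4))$observations
  est <- pool_dilutions(one)
  expect_equal(est$spores_total, 50 / 1e-5)
  expect_false(est$lod_imputed)

  two <- read_counts(dplyr::bind_rows(
    make_plate(colonies = 50, dilution = 1e-4),
    make_plate(colonies = 5, dilution = 1e-5)))$observations
  est2 <- pool_dilutions(two)
  expect_equal(est2$spores_total, 55 / 1.1e-5)
  expect_equal(est2$detection_floor, 1e5)
})

test_that("pooling is invariant to splitting a plate into two half-plates", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(0:300, 1)
    f <- 10^stats::runif(1, -7, -2)
    whole <- tibble::tibble(colonies = n, countable = TRUE,
                            plated_fraction = f)
    split2 <- tibble::tibble(colonies = c(floor(n / 2), ceiling(n / 2)),
                             countable = TRUE, plated_fraction = f / 2)
    expect_equal(pool_dilutions(split2)$spores_total,
                 pool_dilutions(whole)$spores_total)
  }
})

test_that("all-zero plates are imputed at the limit of detection", {
  zeros <- read_counts(dplyr::bind_rows(
    make_plate(colonies = 0, dilution = 1e-2),
    make_plate(colonies = 0, dilution = 1e-3),
    make_plate(colonies = NA, countable = FALSE, dilution = 1e-1)))
  est <- pool_dilutions(zeros$observations)
  expect_identical(est$spores_total, 0.9)
  expect_true(est$lod_imputed)
  # Floor reflects the most concentrated *countable* plate.
  expect_equal(est$detection_floor, 1 / 1e-3)
})

test_that("a sample with no countable plates is an estimation error", {
  lawn <- read_counts(make_plate(colonies = NA, countable = FALSE))
  expect_error(pool_dilutions(lawn$observations),
               class = "myxofit_estimation_error")
})

test_that("the pooled estimator is unbiased in a Poisson simulation", {
  set.seed(301)
  n_true <- 5e6
  fractions <- c(1e-5, 4e-6)
  draws <- 2000
  counts <- matrix(stats::rpois(draws * 2, rep(n_true * fractions, draws)),
                   ncol = 2, byrow = TRUE)
  estimates <- rowSums(counts) / sum(fractions)
  expect_lt(abs(mean(estimates) / n_true - 1), 0.01)
})

test_that("marker deconvolution subtracts, clamps and passes through", {
  design <- toy_design()
  total <- tibble::tibble(spores_total = 1e6, lod_imputed = FALSE,
                          detection_floor = 100)
  marked <- list(A = tibble::tibble(spores_total = 1e5, lod_imputed = FALSE,
                                    detection_floor = 100))
  out <- deconvolve_mix(total, marked, design, "A:B")
  expect_equal(out$spores_total[out$strain == "A"], 1e5)
  expect_equal(out$spores_total[out$strain == "B"], 9e5)
  expect_equal(out$method[out$strain == "B"], "subtraction")
  # Conservation when nothing clamps.
  expect_equal(sum(out$spores_total), total$spores_total)

  # Marked exceeding the total clamps the subtraction strain to the floor.
  over <- list(A = tibble::tibble(spores_total = 1.2e6, lod_imputed = FALSE,
                                  detection_floor = 100))
  clamped <- deconvolve_mix(total, over, design, "A:B")
  expect_identical(clamped$spores_total[clamped$strain == "B"], 0.9)
  expect_true(clamped$lod_imputed[clamped$strain == "B"])
  expect_error(deconvolve_mix(total, over, design, "A:B", strict = TRUE),
               class = "myxofit_estimation_error")

  # Pure culture (no markers) carries the total unchanged.
  pure <- deconvolve_mix(total, list(), design, "A:B")
  expect_equal(nrow(pure), 1)
  expect_equal(pure$spores_total, 1e6)

  # A marker absent from the design is a configuration error.
  bad <- list(Z = marked$A)
  expect_error(deconvolve_mix(total, bad, design, "A:B"),
               class = "myxofit_config_error")
})

test_that("initial-cell bookkeeping follows density, volume and ratio", {
  d11 <- toy_design()
  expect_equal(initial_cells(d11, "A"), 5e8)              # pure culture
  expect_equal(initial_cells(d11, "A", "A:B"), 2.5e8)     # 1:1 mix
  d19 <- toy_design(ratio_a = 1L, ratio_b = 9L)
  expect_equal(initial_cells(d19, "A", "A:B"), 5e7)
  expect_equal(initial_cells(d19, "B", "A:B"), 4.5e8)
  expect_error(initial_cells(d11, "Z", "A:B"),
               class = "myxofit_config_error")
})

test_that("estimate_samples deconvolves a mixed spot end to end", {
  design <- toy_design()
  counts <- dplyr::bind_rows(
    make_plate(pair_id = "A:B", focal_strain = "A", partner_strain = "B",
               history_partner = "H", selection = "none",
               dilution = 1e-4, colonies = 100),
    make_plate(pair_id = "A:B", focal_strain = "A", partner_strain = "B",
               history_partner = "H", selection = "kanamycin",
               dilution = 1e-4, colonies = 40))
  est <- estimate_samples(read_counts(counts), design)
  expect_equal(est$spores_total[est$strain == "A"], 40 / 1e-5)
  expect_equal(est$spores_total[est$strain == "B"], 60 / 1e-5)
})
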