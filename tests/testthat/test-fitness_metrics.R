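test_that("sporulation efficiency is the spore:cell ratio", {
  expect_equal(sporulation_efficiency(5e6, 5e8), 0.01)
  expect_equal(sporulation_efficiency(5e8, 5e8), 1.0)
  expect_equal(sporulation_efficiency(0.9, 2.5e8), 3.6e-9)
  expect_error(sporulation_efficiency(0, 5e8),
               class = "myxofit_domain_error")
  expect_error(sporulation_efficiency(10, -1),
               class = "myxofit_domain_error")
})

test_that("relative fitness matches hand computation and is antisymmetric", {
  expect_equal(relative_fitness(1e6, 5e7, 9e7, 4.5e8), -1.0,
               tolerance = 1e-12)
  expect_equal(relative_fitness(9e7, 4.5e8, 1e6, 5e7), +1.0,
               tolerance = 1e-12)
  expect_equal(relative_fitness(3, 10, 6, 20), 0)

  set.seed(21)
  for (k in 1:50) {
    si <- 10^runif(1, 0, 9); sj <- 10^runif(1, 0, 9)
    ii <- 10^runif(1, 6, 9); ij <- 10^runif(1, 6, 9)
    expect_identical(relative_fitness(si, ii, sj, ij),
                     -relative_fitness(sj, ij, si, ii))
  }
})

test_that("mixing effect matches hand computation", {
  expect_equal(mixing_effect(0.04, 0.01), log10(4), tolerance = 1e-12)
  expect_equal(mixing_effect(0.001, 0.01), -1.0, tolerance = 1e-12)
  expect_equal(mixing_effect(0.02, 0.02), 0)
  # The base is a knob; the sign never depends on it.
  expect_equal(sign(mixing_effect(0.04, 0.01, base = exp(1))),
               sign(mixing_effect(0.04, 0.01)))
})

test_that("W and C are invariant to common rescaling of their inputs", {
  set.seed(22)
  for (s in 10^runif(5, -3, 3)) {
    expect_equal(relative_fitness(2e6 * s, 5e7, 3e6 * s, 4.5e8),
                 relative_fitness(2e6, 5e7, 3e6, 4.5e8))
    expect_equal(mixing_effect(0.03 * s, 0.007 * s), mixing_effect(0.03, 0.007))
  }
})

test_that("W decomposes into mixing effects plus pure-culture offsets", {
  # W_ij = C_i(j) - C_j(i) + log10(D_i_pure) - log10(D_j_pure) on shared
  # inputs.
  set.seed(23)
  for (k in 1:20) {
    init_i <- 2.5e8; init_j <- 2.5e8
    spores_i <- 10^runif(1, 2, 8); spores_j <- 10^runif(1, 2, 8)
    d_pure_i <- 10^runif(1, -4, -1); d_pure_j <- 10^runif(1, -4, -1)
    w <- relative_fitness(spores_i, init_i, spores_j, init_j)
    ci <- mixing_effect(spores_i / init_i, d_pure_i)
    cj <- mixing_effect(spores_j / init_j, d_pure_j)
    expect_equal(w, ci - cj + log10(d_pure_i) - log10(d_pure_j),
                 tolerance = 1e-12)
  }
})

test_that("W is monotone in each strain's spore count", {
  w0 <- relative_fitness(1e6, 5e7, 1e6, 5e7)
  expect_gt(relative_fitness(2e6, 5e7, 1e6, 5e7), w0)
  expect_lt(relative_fitness(1e6, 5e7, 2e6, 5e7), w0)
})

fitness_fixture_estimates <- function() {
  # One pair, one H/H cell, 4 replicates, plus pure cultures of both
  # strains; simple round numbers.
  mix <- tidyr::expand_grid(replicate = 1:4, strain = c("A", "B")) |>
    dplyr::mutate(pair_id = "A:B", focal_strain = "A", partner_strain = "B",
                  history_focal = "H", history_partner = "H",
                  spores_total = ifelse(strain == "A", 2e6, 4e6),
                  lod_imputed = FALSE, detection_floor = 100,
                  method = "marker")
  pure <- tidyr::expand_grid(replicate = 1:4, strain = c("A", "B")) |>
    dplyr::mutate(pair_id = "pure", focal_strain = strain,
                  partner_strain = NA_character_, history_focal = "H",
                  history_partner = NA_character_,
                  spores_total = ifelse(strain == "A", 5e6, 1e7),
                  lod_imputed = FALSE, detection_floor = 100,
                  method = "total")
  dplyr::bind_rows(mix, pure)
}

test_that("the fitness table pairs mixes with same-replicate pure cultures", {
  est <- fitness_fixture_estimates()
  tab <- build_fitness_table(est, toy_design())
  expect_equal(nrow(tab), 8)  # 4 replicates x 2 orientations
  a <- tab[tab$strain_i == "A", ]
  expect_equal(unique(a$pure_ref), "replicate")
  # D_A_mix = 2e6 / 2.5e8; D_A_pure = 5e6 / 5e8.
  expect_equal(unique(a$D_i_mix), 2e6 / 2.5e8)
  expect_equal(unique(a$D_i_pure), 0.01)
  expect_equal(unique(a$C_i_of_j), log10((2e6 / 2.5e8) / 0.01))
  expect_equal(unique(a$W_ij),
               relative_fitness(2e6, 2.5e8, 4e6, 2.5e8))
})

test_that("a missing pure replicate falls back to the flagged mean", {
  est <- fitness_fixture_estimates()
  est <- est[!(est$pair_id == "pure" & est$focal_strain == "A" &
                 est$replicate == 3), ]
  tab <- build_fitness_table(est, toy_design())
  a3 <- tab[tab$strain_i == "A" & tab$replicate == 3, ]
  expect_equal(a3$pure_ref, "mean")
  expect_equal(a3$D_i_pure, 0.01)  # geometric mean of identical values
  a_other <- tab[tab$strain_i == "A" & tab$replicate != 3, ]
  expect_true(all(a_other$pure_ref == "replicate"))
})

test_that("a strain with no matching-history pure culture gets C = NA", {
  est <- fitness_fixture_estimates()
  est <- est[!(est$pair_id == "pure" & est$focal_strain == "A"), ]
  tab <- build_fitness_table(est, toy_design())
  a <- tab[tab$strain_i == "A", ]
  expect_true(all(is.na(a$C_i_of_j)))
  expect_equal(unique(a$pure_ref), "missing")
  expect_true(all(is.finite(a$W_ij)))  # W does not need the pure culture
})
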