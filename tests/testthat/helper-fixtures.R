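# Programmatic fixtures shared across the suite.

# One plate row in the canonical counts schema, with overridable fields.
make_plate <- function(pair_id = "pure", focal_strain = "WT",
                       partner_strain = NA_character_,
                       history_focal = "H",
                       history_partner = NA_character_,
                       replicate = 1L, selection = "none",
                       dilution = 1e-5, volume_ml = 0.1,
                       harvest_volume_ml = 1, colonies = 50,
                       countable = TRUE) {
  tibble::tibble(pair_id, focal_strain, partner_strain, history_focal,
                 history_partner, replicate, selection, dilution,
                 volume_ml, harvest_volume_ml, colonies, countable)
}

# Minimal two-strain design: A marked, B counted by subtraction, 1:1.
toy_design <- function(analysis = "W", ratio_a = 1L, ratio_b = 1L) {
  mix_design(
    strains = tibble::tibble(strain = c("A", "B"), role = "isolate",
                             marker = c("kanamycin", NA)),
    pairs = tibble::tibble(pair_id = "A:B", strain_a = "A", strain_b = "B",
                           ratio_a = ratio_a, ratio_b = ratio_b,
                           subtraction_strain = "B", analysis = analysis))
}

# Matching synthetic configuration with no interaction effects (true W = 0).
null_config <- function(sigma_rep = 0.2, dilutions = c(1e-3, 1e-4, 1e-5),
                        noise_mode = "full", seed = NULL) {
  synthetic_config(
    strains = tibble::tibble(strain = c("A", "B"), role = "isolate",
                             marker = c("kanamycin", NA)),
    pairs = tibble::tibble(pair_id = "A:B", strain_a = "A", strain_b = "B",
                           ratio_a = 1L, ratio_b = 1L,
                           subtraction_strain = "B", analysis = "W"),
    base_log10_D = c(A = -2, B = -2), sigma_rep = sigma_rep,
    dilutions = dilutions, noise_mode = noise_mode, seed = seed)
}

cell_levels_fixture <- function() c("H/H", "H/L", "L/H", "L/L")

# Independent Holm oracle: explicit step-down enumeration over the sorted
# family, kept separate from stats::p.adjust.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# Complete factorial counts fixture for one toy pair, built from the
# generator in expectation mode (fast, no randomness).
toy_expectation_counts <- function() {
  generate_experiment(null_config(noise_mode = "expectation"))
}
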