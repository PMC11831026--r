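# Synthetic developmental experiments with closed-form ground truth.
#
# Generative model, per treatment x replicate and per strain:
#   latent log10 sporulation efficiency
#     = base(strain, own history)
#       + interaction delta (mixed spots only; 0 in pure culture)
#       + Normal(0, sigma_rep)                    [replicate noise]
#   spores = initial cells x 10^latent
#   plate colonies ~ Poisson(spores x plated_fraction) per dilution.
# Because the interaction deltas act additively on log10 efficiency, the
# true statistics are linear in the parameters:
#   true W_ab = latent_a - latent_b   (noise-free),
#   true C_i(j) = delta_i.

#' Configure a synthetic developmental experiment
#'
#' @param strains Data frame with `strain`, `role`, `marker` (as in
#'   [mix_design()]).
#' @param pairs Data frame of pairs (as in [mix_design()]).
#' @param base_log10_D Either a named numeric vector (per strain,
#'   history-independent — pure-culture sporulation unaffected by nutrient
#'   history, the empirical baseline) or a data frame with columns `strain`,
#'   `history`, `base`.
#' @param interaction_delta Optional data frame with columns `pair_id`,
#'   `focal`, `history_focal`, `history_partner`, `delta`: additive shift on
#'   the focal strain's log10 efficiency in that mix cell. Unlisted
#'   combinations are 0.
#' @param sigma_rep Replicate-level SD on log10 efficiency (default 0.2).
#' @param n_replicates Temporally separate replicates (default 4).
#' @param dilutions Dilution series plated per sample (fractions).
#' @param plates_per_dilution Replicate plates poured per dilution
#'   (default 2, standard duplicate plating).
#' @param volume_ml Volume plated per plate (default 0.1 ml).
#' @param harvest_volume_ml Volume into which each spot is harvested
#'   (default 1 ml).
#' @param density_cells_per_ml,spot_volume_ml Initial-cell bookkeeping
#'   (defaults 5e9 and 0.1).
#' @param countable_cap Colony count above which a plate is an uncountable
#'   lawn (default 1000; colonies embedded in a poured plate stay countable
#'   at higher densities than surface-spread ones).
#' @param seed Integer seed for full-noise generation, or `NULL` to draw
#'   from the ambient RNG stream.
#' @param noise_mode `"full"` (replicate noise + Poisson plating) or
#'   `"expectation"` (exact real-valued expected counts; sigma and Poisson
#'   disabled, so the pipeline should recover ground truth exactly).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(strains, pairs, base_log10_D,
                             interaction_delta = NULL,
                             sigma_rep = 0.2, n_replicates = 4L,
                             dilutions = 10^-(1:5),
                             plates_per_dilution = 2L,
                             volume_ml = 0.1, harvest_volume_ml = 1,
                             density_cells_per_ml = 5e9,
                             spot_volume_ml = 0.1,
                             countable_cap = 1000,
                             seed = NULL,
                             noise_mode = c("full", "expectation")) {
  noise_mode <- match.arg(noise_mode)
  design <- mix_design(strains, pairs,
                       density_cells_per_ml = density_cells_per_ml,
                       spot_volume_ml = spot_volume_ml)
  if (is.numeric(base_log10_D) && !is.null(names(base_log10_D))) {
    base_log10_D <- tidyr::expand_grid(strain = names(base_log10_D),
                                       history = c("H", "L")) |>
      dplyr::mutate(base = base_log10_D[.data$strain])
  }
  base_log10_D <- tibble::as_tibble(base_log10_D)
  stopifnot(all(c("strain", "history", "base") %in% names(base_log10_D)))
  need <- tidyr::expand_grid(strain = design$strains$strain,
                             history = c("H", "L"))
  got <- dplyr::semi_join(need, base_log10_D, by = c("strain", "history"))
  if (nrow(got) < nrow(need)) {
    rlang::abort("base_log10_D must cover every strain under both histories",
                 class = "myxofit_config_error")
  }
  if (is.null(interaction_delta)) {
    interaction_delta <- tibble::tibble(pair_id = character(),
                                        focal = character(),
                                        history_focal = character(),
                                        history_partner = character(),
                                        delta = numeric())
  }
  interaction_delta <- tibble::as_tibble(interaction_delta)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
  }
  if (!is_scalar_number(sigma_rep) || sigma_rep < 0) {
    rlang::abort("sigma_rep must be a non-negative scalar",
                 class = "myxofit_config_error")
  }
  cfg <- structure(list(
    strains = design$strains, pairs = design$pairs,
    base_log10_D = base_log10_D, interaction_delta = interaction_delta,
    sigma_rep = sigma_rep, n_replicates = as.integer(n_replicates),
    dilutions = sort(dilutions, decreasing = TRUE),
    plates_per_dilution = as.integer(plates_per_dilution),
    volume_ml = volume_ml, harvest_volume_ml = harvest_volume_ml,
    density_cells_per_ml = density_cells_per_ml,
    spot_volume_ml = spot_volume_ml, countable_cap = countable_cap,
    seed = seed, noise_mode = noise_mode), class = "synthetic_config")
  pf <- volume_ml * dilutions / harvest_volume_ml
  if (any(pf > 1)) {
    rlang::abort("dilution scheme implies plated fractions above 1",
                 class = "myxofit_config_error")
  }
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", nrow(x$pairs), " pairs, ", x$n_replicates,
      " replicates, sigma_rep = ", x$sigma_rep, ", mode = ", x$noise_mode,
      "\n", sep = "")
  invisible(x)
}

# Design object implied by a synthetic configuration.
design_from_config <- function(config) {
  mix_design(config$strains, config$pairs,
             density_cells_per_ml = config$density_cells_per_ml,
             spot_volume_ml = config$spot_volume_ml)
}

base_of <- function(config, strain, history) {
  b <- config$base_log10_D
  b$base[b$strain == strain & b$history == history][1]
}

delta_of <- function(config, pair_id, focal, history_focal, history_partner) {
  d <- config$interaction_delta
  hit <- d$pair_id == pair_id & d$focal == focal &
    d$history_focal == history_focal & d$history_partner == history_partner
  if (any(hit)) d$delta[hit][1] else 0
}

# Noise-free latent log10 efficiencies for every (pair, cell, strain), plus
# derived true statistics.
#' Closed-form ground truth of a synthetic configuration
#'
#' Computes, without any sampling, the true per-strain spore totals, true
#' relative fitness `W` (strain_a over strain_b) and true mixing effects
#' `C_a`/`C_b` for every pair and nutrient-history cell implied by a
#' [synthetic_config()].
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per (pair, cell).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- design_from_config(config)
  grid <- tidyr::expand_grid(pair_id = config$pairs$pair_id,
                             history_a = c("H", "L"),
                             history_b = c("H", "L"))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    p <- config$pairs[config$pairs$pair_id == g$pair_id, ]
    da <- delta_of(config, g$pair_id, p$strain_a, g$history_a, g$history_b)
    db <- delta_of(config, g$pair_id, p$strain_b, g$history_b, g$history_a)
    la <- base_of(config, p$strain_a, g$history_a) + da
    lb <- base_of(config, p$strain_b, g$history_b) + db
    tibble::tibble(
      pair_id = g$pair_id, strain_a = p$strain_a, strain_b = p$strain_b,
      cell = cell_label(g$history_a, g$history_b),
      spores_a = initial_cells(design, p$strain_a, g$pair_id) * 10^la,
      spores_b = initial_cells(design, p$strain_b, g$pair_id) * 10^lb,
      W = la - lb, C_a = da, C_b = db)
  })
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic experiment
#'
#' Simulates the full assay — pure cultures of every strain under both
#' nutrient histories and every pairwise mix in all four history cells,
#' each with `n_replicates` temporally separate replicates — and emits
#' plate counts in the exact input schema of [read_counts()], together with
#' the closed-form [ground_truth()]. Selective plates are produced for each
#' marked strain of a pair, non-selective plates for the total; plates whose
#' colony count exceeds `countable_cap` are recorded as uncountable lawns.
#'
#' In `"full"` mode generation is byte-identical across runs for a fixed
#' seed; in `"expectation"` mode no randomness is used at all and colony
#' values are exact real-valued expectations.
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed`; `NULL` uses the ambient RNG stream.
#' @return A list of class `myxo_experiment`: `counts` (`myxo_counts`),
#'   `truth`, `design`, `config`.
#' @export
generate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- design_from_config(config)
  full <- config$noise_mode == "full"
  if (full && !is.null(seed)) set.seed(seed)

  pure <- tidyr::expand_grid(
    pair_id = "pure", focal_strain = config$strains$strain,
    history_focal = c("H", "L"), replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(partner_strain = NA_character_,
                  history_partner = NA_character_)
  mixes <- tidyr::expand_grid(
    pair_id = config$pairs$pair_id, history_focal = c("H", "L"),
    history_partner = c("H", "L"),
    replicate = seq_len(config$n_replicates)) |>
    dplyr::left_join(dplyr::select(config$pairs, "pair_id",
                                   focal_strain = "strain_a",
                                   partner_strain = "strain_b"),
                     by = "pair_id")
  spots <- dplyr::bind_rows(pure, mixes)[
    , c(spot_keys)]
  spots <- dplyr::arrange(spots, .data$pair_id, .data$focal_strain,
                          .data$history_focal, .data$history_partner,
                          .data$replicate)

  # One latent efficiency per (spot, strain), in a fixed row order so the
  # random stream is reproducible.
  per_strain <- dplyr::bind_rows(
    dplyr::mutate(spots,
                  strain = .data$focal_strain, history = .data$history_focal,
                  partner_history = .data$history_partner),
    dplyr::mutate(spots[spots$pair_id != "pure", ],
                  strain = .data$partner_strain,
                  history = .data$history_partner,
                  partner_history = .data$history_focal))
  base_tbl <- dplyr::rename(config$base_log10_D, base_val = "base")
  delta_tbl <- dplyr::rename(config$interaction_delta, delta_val = "delta")
  per_strain <- per_strain |>
    dplyr::left_join(base_tbl, by = c("strain", "history")) |>
    dplyr::left_join(delta_tbl,
                     by = c("pair_id", strain = "focal",
                            history = "history_focal",
                            partner_history = "history_partner"))
  per_strain$delta_val[is.na(per_strain$delta_val) |
                         per_strain$pair_id == "pure"] <- 0
  mu <- per_strain$base_val + per_strain$delta_val
  eps <- if (full && config$sigma_rep > 0) {
    stats::rnorm(nrow(per_strain), 0, config$sigma_rep)
  } else 0
  total_cells <- config$density_cells_per_ml * config$spot_volume_ml
  pidx <- match(per_strain$pair_id, config$pairs$pair_id)
  share <- ifelse(
    is.na(pidx), 1,
    ifelse(per_strain$strain == config$pairs$strain_a[pidx],
           config$pairs$ratio_a[pidx],
           config$pairs$ratio_b[pidx]) /
      (config$pairs$ratio_a[pidx] + config$pairs$ratio_b[pidx]))
  per_strain$init <- total_cells * share
  per_strain$spores <- per_strain$init * 10^(mu + eps)

  marker_of <- stats::setNames(design$strains$marker, design$strains$strain)

  # One sample per (spot, selection): non-selective plates see every
  # strain's spores, marker plates only the marked strain's.
  totals <- per_strain |>
    dplyr::group_by(dplyr::across(dplyr::all_of(spot_keys))) |>
    dplyr::summarise(spores = sum(.data$spores), .groups = "drop") |>
    dplyr::mutate(selection = "none")
  marked <- per_strain |>
    dplyr::filter(.data$pair_id != "pure",
                  !is.na(marker_of[.data$strain])) |>
    dplyr::mutate(selection = unname(marker_of[.data$strain]))
  samples <- dplyr::bind_rows(totals,
                              marked[c(spot_keys, "selection", "spores")])
  plate_rows <- tidyr::expand_grid(
    samples, dilution = config$dilutions,
    plate = seq_len(config$plates_per_dilution)) |>
    dplyr::mutate(expected = .data$spores *
                    config$volume_ml * .data$dilution /
                    config$harvest_volume_ml) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(
      c(spot_keys, "selection", "dilution", "plate"))))

  colonies <- if (full) stats::rpois(nrow(plate_rows), plate_rows$expected)
  else plate_rows$expected
  countable <- colonies <= config$countable_cap
  colonies[!countable] <- NA
  counts_tbl <- plate_rows |>
    dplyr::mutate(volume_ml = config$volume_ml,
                  harvest_volume_ml = config$harvest_volume_ml,
                  colonies = colonies, countable = countable) |>
    dplyr::select(dplyr::all_of(counts_schema))

  structure(list(counts = read_counts(counts_tbl),
                 truth = ground_truth(config),
                 design = design, config = config),
            class = "myxo_experiment")
}

#' @export
print.myxo_experiment <- function(x, ...) {
  cat("<myxo_experiment> ", nrow(x$counts$observations), " plates (",
      x$config$noise_mode, " mode)\n", sep = "")
  invisible(x)
}
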