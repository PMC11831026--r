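# Log-ratio social-fitness statistics.

#' Sporulation efficiency
#'
#' Fraction of initially deposited cells that survive development as viable
#' spores: `spores / initial`. The same formula gives the pure-culture
#' efficiency D_i (initial = whole-spot cell number) and the in-mix
#' efficiency D_i(j) (initial = the strain's share of the spot).
#'
#' @param spores Viable spores recovered (positive).
#' @param initial Viable cells deposited (positive).
#' @return Efficiency (dimensionless), vectorised.
#' @export
sporulation_efficiency <- function(spores, initial) {
  if (any(!is.finite(spores)) || any(!is.finite(initial)) ||
      any(spores <= 0) || any(initial <= 0)) {
    rlang::abort("spores and initial cells must be positive and finite",
                 class = "myxofit_domain_error")
  }
  spores / initial
}

#' Relative fitness W of strain i over strain j
#'
#' Difference of log10 per-capita spore yields of two co-developing strains:
#' `W = log10(spores_i / init_i) - log10(spores_j / init_j)`. W > 0 means
#' strain i converted its cells into spores proportionally better than
#' strain j in the same spot; a defector with significantly positive W over
#' a cooperator is cheating. Antisymmetric by construction:
#' `W(i,j) = -W(j,i)` exactly on the same inputs.
#'
#' @param spores_i,init_i Spores recovered and cells deposited for strain i.
#' @param spores_j,init_j Same for strain j.
#' @return W (log10 units), vectorised.
#' @export
relative_fitness <- function(spores_i, init_i, spores_j, init_j) {
  log10(sporulation_efficiency(spores_i, init_i)) -
    log10(sporulation_efficiency(spores_j, init_j))
}

#' Mixing effect C of partner j on focal strain i
#'
#' Log difference between a strain's sporulation efficiency in a mix and in
#' pure culture under the same nutrient history:
#' `C = log(D_mix) - log(D_pure)`. A significantly positive C means the
#' focal strain produces proportionally more spores in the mix than alone —
#' social exploitation of the partner; a significantly negative C means the
#' focal strain is antagonized by the mix.
#'
#' Base 10 by default, matching the explicit base of W; the sign-based
#' interpretation is invariant to the base.
#'
#' @param d_mix In-mix sporulation efficiency D_i(j) (positive).
#' @param d_pure Matching-history pure-culture efficiency D_i (positive).
#' @param base Logarithm base (default 10).
#' @return C (log units), vectorised.
#' @export
mixing_effect <- function(d_mix, d_pure, base = 10) {
  if (any(!is.finite(d_mix)) || any(!is.finite(d_pure)) ||
      any(d_mix <= 0) || any(d_pure <= 0)) {
    rlang::abort("efficiencies must be positive and finite",
                 class = "myxofit_domain_error")
  }
  log(d_mix, base = base) - log(d_pure, base = base)
}

#' Build the per-replicate fitness table
#'
#' Joins mixed-culture spore estimates with initial-cell bookkeeping and
#' pure-culture references to produce one record per (pair, nutrient-history
#' cell, replicate, focal strain): both orientations of each mix are
#' emitted, so each spot yields a row with focal = strain_a and a row with
#' focal = strain_b, carrying D_i (pure), D_i(j) (mix), W_ij and C_i(j).
#'
#' The pure-culture reference D_i is taken from the same replicate when that
#' pure culture exists; otherwise the cross-replicate geometric mean is used
#' and the row is flagged (`pure_ref = "mean"`). A focal strain with no pure
#' culture at all under the matching history gets `C_i_of_j = NA` with
#' `pure_ref = "missing"`; W is unaffected. Limit-of-detection involvement
#' of any component is propagated as flags, never censored.
#'
#' @param estimates Output of [estimate_samples()].
#' @param design A [mix_design()].
#' @param log_base Base for the mixing effect (default 10).
#' @return Tibble with columns `pair_id`, `replicate`, `strain_i`,
#'   `strain_j`, `history_i`, `history_j`, `cell`, `D_i_pure`, `D_i_mix`,
#'   `W_ij`, `C_i_of_j`, `lod_i`, `lod_j`, `lod_pure_i`, `pure_ref`.
#' @export
build_fitness_table <- function(estimates, design, log_base = 10) {
  stopifnot(inherits(design, "mix_design"))
  est <- tibble::as_tibble(estimates)

  pure <- est[est$pair_id == "pure", , drop = FALSE]
  pure$initial <- design$density_cells_per_ml * design$spot_volume_ml
  pure$D <- pure$spores_total / pure$initial

  pure_lookup <- function(strain, history, replicate) {
    rows <- pure[pure$strain == strain & pure$history_focal == history, ]
    if (!nrow(rows)) {
      return(list(D = NA_real_, lod = NA, ref = "missing"))
    }
    hit <- rows[rows$replicate == replicate, ]
    if (nrow(hit) >= 1) {
      list(D = hit$D[1], lod = hit$lod_imputed[1], ref = "replicate")
    } else {
      list(D = geom_mean(rows$D), lod = any(rows$lod_imputed), ref = "mean")
    }
  }

  mixes <- est[est$pair_id != "pure", , drop = FALSE]
  if (!nrow(mixes)) {
    rlang::abort("no mixed-culture estimates to build a fitness table from",
                 class = "myxofit_domain_error")
  }

  spots <- split(mixes, interaction(mixes$pair_id, mixes$history_focal,
                                    mixes$history_partner, mixes$replicate,
                                    drop = TRUE))
  out <- lapply(spots, function(sp) {
    key <- sp[1, ]
    members <- tibble::tibble(
      strain = c(key$focal_strain, key$partner_strain),
      history = c(key$history_focal, key$history_partner))
    rows <- lapply(1:2, function(k) {
      i <- members$strain[k]; j <- members$strain[3 - k]
      hi <- members$history[k]; hj <- members$history[3 - k]
      ei <- sp[sp$strain == i, ]; ej <- sp[sp$strain == j, ]
      if (nrow(ei) != 1 || nrow(ej) != 1) {
        rlang::warn(sprintf(
          "pair '%s' replicate %d: missing per-strain estimate; record skipped",
          key$pair_id, key$replicate))
        return(NULL)
      }
      init_i <- initial_cells(design, i, key$pair_id)
      init_j <- initial_cells(design, j, key$pair_id)
      d_mix <- ei$spores_total / init_i
      ref <- pure_lookup(i, hi, key$replicate)
      tibble::tibble(
        pair_id = key$pair_id, replicate = key$replicate,
        strain_i = i, strain_j = j, history_i = hi, history_j = hj,
        cell = cell_label(hi, hj),
        D_i_pure = ref$D, D_i_mix = d_mix,
        W_ij = relative_fitness(ei$spores_total, init_i,
                                ej$spores_total, init_j),
        C_i_of_j = if (is.na(ref$D)) NA_real_ else
          mixing_effect(d_mix, ref$D, base = log_base),
        lod_i = ei$lod_imputed, lod_j = ej$lod_imputed,
        lod_pure_i = ref$lod, pure_ref = ref$ref)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$pair_id, .data$strain_i,
                 .data$cell, .data$replicate)
}
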