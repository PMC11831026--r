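# From plate counts to per-spot viable-spore estimates.

#' Pool a dilution series into one spore estimate
#'
#' Combines all countable plates from one harvested spot and one selection
#' into the pooled Poisson maximum-likelihood estimate of total viable
#' spores, `N = sum(colonies) / sum(plated_fraction)`. With a single plate
#' this reduces to colonies / plated_fraction.
#'
#' When every countable plate shows zero colonies the sample is at the lower
#' limit of detection and the estimate is imputed as 0.9 spores
#' (`lod_imputed = TRUE`). The `detection_floor` reported alongside is the
#' spore count corresponding to one colony on the most concentrated countable
#' plate, `1 / max(plated_fraction)`.
#'
#' @param plates Data frame of plates sharing one spot and selection, with
#'   columns `colonies`, `countable` and `plated_fraction` (as produced by
#'   [read_counts()]).
#' @param lod_spores Spore value imputed at the limit of detection
#'   (default 0.9).
#' @return A one-row tibble with `spores_total`, `lod_imputed`,
#'   `detection_floor` and `n_plates` (countable plates pooled).
#' @export
pool_dilutions <- function(plates, lod_spores = 0.9) {
  plates <- tibble::as_tibble(plates)
  ok <- plates$countable %in% TRUE
  if (!any(ok)) {
    stage_abort("cfu_estimation",
                "no countable plates for this sample; cannot estimate spores",
                class = "myxofit_estimation_error")
  }
  counts <- plates$colonies[ok]
  fractions <- plates$plated_fraction[ok]
  total <- sum(counts)
  if (total == 0) {
    spores <- lod_spores
    lod <- TRUE
  } else {
    spores <- total / sum(fractions)
    lod <- FALSE
  }
  tibble::tibble(spores_total = spores, lod_imputed = lod,
                 detection_floor = 1 / max(fractions),
                 n_plates = sum(ok))
}

#' Deconvolve a mixed-culture spore sample by selective marker
#'
#' Directly marked strains take their marker-plate estimates unchanged; the
#' (at most one) strain counted by subtraction receives the non-selective
#' total minus the sum of the marked estimates. A subtraction result at or
#' below zero (marked counts exceeding the total, possible under plating
#' noise) is clamped to the limit-of-detection floor and flagged. When the
#' mix has no marked strains (a pure culture passed through), the single
#' strain carries the total unchanged.
#'
#' @param total One-row estimate from non-selective agar ([pool_dilutions()]
#'   output).
#' @param marked Named list of one-row estimates from selective agar; names
#'   are strain labels.
#' @param design A [mix_design()].
#' @param pair_id Pair whose counting scheme applies.
#' @param lod_spores Clamp floor (default 0.9 spores).
#' @param strict If `TRUE`, clamping is an error rather than a flag.
#' @return Tibble with one row per strain: `strain`, `spores_total`,
#'   `lod_imputed`, `detection_floor`, `method` (`"marker"`,
#'   `"subtraction"` or `"total"`).
#' @export
deconvolve_mix <- function(total, marked, design, pair_id,
                           lod_spores = 0.9, strict = FALSE) {
  stopifnot(inherits(design, "mix_design"))
  p <- design$pairs[design$pairs$pair_id == pair_id, ]
  if (nrow(p) != 1) {
    stage_abort("cfu_estimation", sprintf("unknown pair '%s'", pair_id),
                class = "myxofit_config_error")
  }
  members <- c(p$strain_a, p$strain_b)
  if (length(marked) && !all(names(marked) %in% members)) {
    stage_abort("cfu_estimation",
                sprintf("marked strain(s) %s not members of pair '%s'",
                        paste(setdiff(names(marked), members), collapse = ", "),
                        pair_id),
                class = "myxofit_config_error")
  }
  if (!length(marked)) {
    return(tibble::tibble(strain = members[1], spores_total = total$spores_total,
                          lod_imputed = total$lod_imputed,
                          detection_floor = total$detection_floor,
                          method = "total"))
  }
  out <- dplyr::bind_rows(lapply(names(marked), function(s) {
    m <- marked[[s]]
    tibble::tibble(strain = s, spores_total = m$spores_total,
                   lod_imputed = m$lod_imputed,
                   detection_floor = m$detection_floor, method = "marker")
  }))
  sub <- p$subtraction_strain
  if (!is.na(sub) && !sub %in% names(marked)) {
    resid <- total$spores_total - sum(out$spores_total)
    clamped <- resid <= 0
    if (clamped && strict) {
      stage_abort("cfu_estimation",
                  sprintf("pair '%s': marked counts exceed the non-selective total",
                          pair_id),
                  class = "myxofit_estimation_error")
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      strain = sub,
      spores_total = if (clamped) lod_spores else resid,
      lod_imputed = clamped || total$lod_imputed,
      detection_floor = total$detection_floor,
      method = "subtraction"))
  }
  out
}

#' Estimate per-strain spore totals for every developmental spot
#'
#' The workhorse of the estimation stage: groups validated plate
#' observations by harvested spot and selection, pools each dilution series
#' with [pool_dilutions()], and deconvolves mixed spots into per-strain
#' estimates with [deconvolve_mix()] according to the design's counting
#' scheme. Pure-culture spots are estimated from their non-selective plates.
#'
#' @param counts A `myxo_counts` object, counts data frame, or CSV path.
#' @param design A [mix_design()].
#' @param lod_spores Limit-of-detection imputation value (default 0.9).
#' @param strict Passed to [deconvolve_mix()].
#' @return Tibble with one row per (spot, strain): the spot key columns plus
#'   `strain`, `spores_total`, `lod_imputed`, `detection_floor`, `method`.
#' @export
estimate_samples <- function(counts, design, lod_spores = 0.9,
                             strict = FALSE) {
  if (!inherits(counts, "myxo_counts")) counts <- read_counts(counts)
  obs <- counts$observations
  stopifnot(inherits(design, "mix_design"))

  # Vectorised pooled Poisson MLE per (spot, selection); identical to
  # pool_dilutions() applied group-wise.
  pooled <- obs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(spot_keys, "selection")))) |>
    dplyr::summarise(
      n_plates = sum(.data$countable %in% TRUE),
      colonies_sum = sum(.data$colonies[.data$countable %in% TRUE]),
      pf_sum = sum(.data$plated_fraction[.data$countable %in% TRUE]),
      max_pf = suppressWarnings(
        max(.data$plated_fraction[.data$countable %in% TRUE])),
      .groups = "drop")
  if (any(pooled$n_plates == 0)) {
    bad <- pooled[pooled$n_plates == 0, ][1, ]
    stage_abort("cfu_estimation",
                sprintf("sample %s / %s selection '%s' replicate %d has no countable plates",
                        bad$pair_id, bad$focal_strain, bad$selection,
                        bad$replicate),
                class = "myxofit_estimation_error")
  }
  pooled <- pooled |>
    dplyr::mutate(
      lod_imputed = .data$colonies_sum == 0,
      spores_total = ifelse(.data$lod_imputed, lod_spores,
                            .data$colonies_sum / .data$pf_sum),
      detection_floor = 1 / .data$max_pf) |>
    dplyr::select(-"colonies_sum", -"pf_sum", -"max_pf")

  marker_of <- stats::setNames(design$strains$marker, design$strains$strain)

  one_spot <- function(rows) {
    key <- rows[1, spot_keys]
    ests <- split(rows, rows$selection)
    if (key$pair_id == "pure") {
      src <- ests[["none"]] %||% stage_abort(
        "cfu_estimation",
        sprintf("pure culture %s (%s, replicate %d) has no non-selective plates",
                key$focal_strain, key$history_focal, key$replicate),
        class = "myxofit_estimation_error")
      per_strain <- tibble::tibble(
        strain = key$focal_strain, spores_total = src$spores_total,
        lod_imputed = src$lod_imputed,
        detection_floor = src$detection_floor, method = "total")
    } else {
      members <- c(key$focal_strain, key$partner_strain)
      marked <- list()
      for (s in members) {
        mk <- marker_of[[s]]
        if (!is.na(mk) && !is.null(ests[[mk]])) marked[[s]] <- ests[[mk]]
      }
      markers_seen <- setdiff(names(ests), "none")
      unknown <- setdiff(markers_seen, stats::na.omit(marker_of[members]))
      if (length(unknown)) {
        stage_abort("cfu_estimation",
                    sprintf("pair '%s': selection '%s' matches no marker in the design",
                            key$pair_id, paste(unknown, collapse = ", ")),
                    class = "myxofit_config_error")
      }
      total <- ests[["none"]]
      needs_sub <- {
        p <- design$pairs[design$pairs$pair_id == key$pair_id, ]
        !is.na(p$subtraction_strain) && !p$subtraction_strain %in% names(marked)
      }
      if (is.null(total) && needs_sub) {
        stage_abort("cfu_estimation",
                    sprintf("mix '%s' replicate %d: no non-selective plates for the subtraction estimate",
                            key$pair_id, key$replicate),
                    class = "myxofit_estimation_error")
      }
      if (is.null(total)) {
        total <- tibble::tibble(spores_total = sum(
          vapply(marked, function(m) m$spores_total, numeric(1))),
          lod_imputed = FALSE,
          detection_floor = max(vapply(marked, function(m) m$detection_floor,
                                       numeric(1))),
          n_plates = NA_integer_)
      }
      per_strain <- deconvolve_mix(total, marked, design, key$pair_id,
                                   lod_spores = lod_spores, strict = strict)
    }
    dplyr::bind_cols(key[rep(1, nrow(per_strain)), ], per_strain)
  }

  pooled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(spot_keys))) |>
    dplyr::group_map(~ one_spot(dplyr::bind_cols(.y, .x))) |>
    dplyr::bind_rows()
}
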