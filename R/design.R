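#' Construct an experimental mix design
#'
#' A mix design describes the strains, the pairwise mixes, their initial
#' mixing ratios, the selective markers used to count each strain, and the
#' plating bookkeeping constants. It is the configuration object consumed by
#' [estimate_samples()], [initial_cells()] and [build_fitness_table()].
#'
#' Counting scheme: within a mixed culture, every strain is counted either
#' directly on its selective marker, or indirectly by subtracting all
#' marker-plate counts from the non-selective total. At most one strain per
#' pair may be counted by subtraction (the `subtraction_strain`).
#'
#' @param strains A data frame with columns `strain`, `role` (one of
#'   `"cooperator"`, `"defector"`, `"isolate"`) and `marker` (selective-agar
#'   marker name, or `NA` for unmarked strains).
#' @param pairs A data frame with columns `pair_id`, `strain_a`, `strain_b`,
#'   `ratio_a`, `ratio_b` (positive integers; initial mixing ratio a:b),
#'   `subtraction_strain` (strain counted by subtraction, or `NA` when both
#'   strains carry markers) and `analysis` (`"W"` for defector-vs-cooperator
#'   relative fitness, `"C"` for mixing effects of both partners).
#' @param density_cells_per_ml Cell density of the resuspended cultures
#'   spotted for development. Default `5e9` cells/ml.
#' @param spot_volume_ml Volume spotted per developmental spot. Default
#'   `0.1` ml, so a pure-culture spot starts from `5e8` cells.
#' @return An object of class `mix_design`.
#' @seealso [default_design()], [read_design()], [initial_cells()]
#' @export
mix_design <- function(strains, pairs,
                       density_cells_per_ml = 5e9,
                       spot_volume_ml = 0.1) {
  strains <- tibble::as_tibble(strains)
  pairs <- tibble::as_tibble(pairs)
  need_s <- c("strain", "role", "marker")
  need_p <- c("pair_id", "strain_a", "strain_b", "ratio_a", "ratio_b",
              "subtraction_strain", "analysis")
  if (!all(need_s %in% names(strains))) {
    rlang::abort(paste0("`strains` must have columns: ",
                        paste(need_s, collapse = ", ")),
                 class = "myxofit_config_error")
  }
  if (!all(need_p %in% names(pairs))) {
    rlang::abort(paste0("`pairs` must have columns: ",
                        paste(need_p, collapse = ", ")),
                 class = "myxofit_config_error")
  }
  if (anyDuplicated(strains$strain)) {
    rlang::abort("duplicate strain labels in `strains`",
                 class = "myxofit_config_error")
  }
  if (!is_scalar_number(density_cells_per_ml) || density_cells_per_ml <= 0 ||
      !is_scalar_number(spot_volume_ml) || spot_volume_ml <= 0) {
    rlang::abort("density and spot volume must be positive scalars",
                 class = "myxofit_config_error")
  }
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    members <- c(p$strain_a, p$strain_b)
    if (!all(members %in% strains$strain)) {
      rlang::abort(sprintf("pair '%s' references unknown strains", p$pair_id),
                   class = "myxofit_config_error")
    }
    if (p$ratio_a <= 0 || p$ratio_b <= 0) {
      rlang::abort(sprintf("pair '%s': mixing ratios must be positive",
                           p$pair_id),
                   class = "myxofit_config_error")
    }
    markers <- strains$marker[match(members, strains$strain)]
    unmarked <- members[is.na(markers)]
    if (!is.na(p$subtraction_strain) && !p$subtraction_strain %in% members) {
      rlang::abort(sprintf(
        "pair '%s': subtraction_strain '%s' is not a member of the pair",
        p$pair_id, p$subtraction_strain), class = "myxofit_config_error")
    }
    if (length(unmarked) > 1) {
      rlang::abort(sprintf(
        "pair '%s': only one strain per pair may lack a marker (counted by subtraction)",
        p$pair_id), class = "myxofit_config_error")
    }
    if (length(unmarked) == 1 &&
        (is.na(p$subtraction_strain) || p$subtraction_strain != unmarked)) {
      rlang::abort(sprintf(
        "pair '%s': unmarked strain '%s' must be the subtraction_strain",
        p$pair_id, unmarked), class = "myxofit_config_error")
    }
    if (!p$analysis %in% c("W", "C")) {
      rlang::abort(sprintf("pair '%s': analysis must be \"W\" or \"C\"",
                           p$pair_id), class = "myxofit_config_error")
    }
  }
  structure(
    list(strains = strains, pairs = pairs,
         density_cells_per_ml = density_cells_per_ml,
         spot_volume_ml = spot_volume_ml),
    class = "mix_design")
}

#' Default developmental-competition design
#'
#' The stock configuration shipped with the package: a sporulation-proficient
#' wild-type cooperator (`WT`, counted by subtraction) mixed 1:9 with each of
#' two rifampicin-marked obligate defectors (`Ch1`, `Ch2`), analysed through
#' relative fitness W; and three natural isolates (`D`, kanamycin; `G`,
#' novobiocin; `I`, unmarked) mixed pairwise 1:1 and analysed through the
#' mixing effect C. Initial density 5e9 cells/ml, 0.1 ml per spot.
#'
#' @return A [mix_design()] object.
#' @export
default_design <- function() {
  strains <- tibble::tibble(
    strain = c("Ch1", "Ch2", "WT", "D", "G", "I"),
    role   = c("defector", "defector", "cooperator",
               "isolate", "isolate", "isolate"),
    marker = c("rifampicin", "rifampicin", NA, "kanamycin", "novobiocin", NA))
  pairs <- tibble::tibble(
    pair_id = c("Ch1:WT", "Ch2:WT", "D:G", "D:I", "I:G"),
    strain_a = c("Ch1", "Ch2", "D", "D", "I"),
    strain_b = c("WT", "WT", "G", "I", "G"),
    ratio_a = c(1L, 1L, 1L, 1L, 1L),
    ratio_b = c(9L, 9L, 1L, 1L, 1L),
    subtraction_strain = c("WT", "WT", NA, "I", "I"),
    analysis = c("W", "W", "C", "C", "C"))
  mix_design(strains, pairs)
}

#' Read a mix design from a YAML or JSON file
#'
#' The file must contain `strains` and `pairs` tables (lists of records with
#' the columns documented in [mix_design()]) and may override
#' `density_cells_per_ml` and `spot_volume_ml`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` design file.
#' @return A [mix_design()] object.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("design file not found: %s", path),
                 class = "myxofit_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    rlang::abort("design file must be .yaml, .yml or .json",
                 class = "myxofit_config_error")
  }
  to_tbl <- function(x) {
    x <- tibble::as_tibble(if (is.data.frame(x)) x else dplyr::bind_rows(x))
    x[x == ""] <- NA
    x
  }
  strains <- to_tbl(raw$strains)
  pairs <- to_tbl(raw$pairs)
  if (!"marker" %in% names(strains)) strains$marker <- NA_character_
  if (!"subtraction_strain" %in% names(pairs)) {
    pairs$subtraction_strain <- NA_character_
  }
  mix_design(strains, pairs,
             density_cells_per_ml = raw$density_cells_per_ml %||% 5e9,
             spot_volume_ml = raw$spot_volume_ml %||% 0.1)
}

#' Initial viable cells of a strain in a developmental spot
#'
#' Pure-culture spots start from `density * spot_volume` cells (by default
#' 5e9 cells/ml x 0.1 ml = 5e8). In a mix, that total is split by the pair's
#' initial ratio: 1:1 gives 2.5e8 per strain, 1:9 gives 5e7 for the minority
#' partner and 4.5e8 for the majority partner.
#'
#' @param design A [mix_design()].
#' @param strain Strain label.
#' @param pair_id Pair identifier for mixed spots, or `NULL`/`"pure"` for a
#'   pure-culture spot.
#' @return Number of cells (scalar).
#' @export
initial_cells <- function(design, strain, pair_id = NULL) {
  stopifnot(inherits(design, "mix_design"))
  total <- design$density_cells_per_ml * design$spot_volume_ml
  if (is.null(pair_id) || identical(pair_id, "pure") || is.na(pair_id)) {
    if (!strain %in% design$strains$strain) {
      rlang::abort(sprintf("unknown strain '%s'", strain),
                   class = "myxofit_config_error")
    }
    return(total)
  }
  p <- design$pairs[design$pairs$pair_id == pair_id, ]
  if (nrow(p) != 1) {
    rlang::abort(sprintf("unknown pair '%s'", pair_id),
                 class = "myxofit_config_error")
  }
  denom <- p$ratio_a + p$ratio_b
  if (strain == p$strain_a) {
    total * p$ratio_a / denom
  } else if (strain == p$strain_b) {
    total * p$ratio_b / denom
  } else {
    rlang::abort(sprintf("strain '%s' is not a member of pair '%s'",
                         strain, pair_id),
                 class = "myxofit_config_error")
  }
}

#' @export
print.mix_design <- function(x, ...) {
  cat("<mix_design> ", nrow(x$strains), " strains, ", nrow(x$pairs),
      " pairs; ", format(x$density_cells_per_ml, big.mark = ","),
      " cells/ml x ", x$spot_volume_ml, " ml per spot\n", sep = "")
  invisible(x)
}
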