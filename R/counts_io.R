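# Tabular data model for dilution-series plate counts.
#
# One row = one agar plate poured from a dilution of one harvested
# developmental spot. The canonical CSV schema is fixed:
#   pair_id, focal_strain, partner_strain, history_focal, history_partner,
#   replicate, selection, dilution, volume_ml, harvest_volume_ml,
#   colonies, countable
# Pure-culture spots use pair_id = "pure" with partner columns empty.
# `dilution` is a fraction (1e-5), not a fold; `colonies` may be NA only on
# uncountable (lawn) plates, which are retained but excluded from pooling.

counts_schema <- c("pair_id", "focal_strain", "partner_strain",
                   "history_focal", "history_partner", "replicate",
                   "selection", "dilution", "volume_ml",
                   "harvest_volume_ml", "colonies", "countable")

spot_keys <- c("pair_id", "focal_strain", "partner_strain",
               "history_focal", "history_partner", "replicate")

#' Read and validate a plate-count table
#'
#' Parses the canonical plate-count CSV (or an equivalent data frame),
#' validates every row, and computes each plate's `plated_fraction` — the
#' fraction of the harvested spore sample represented on the plate,
#' `volume_ml * dilution / harvest_volume_ml`.
#'
#' Rows that violate the data model (negative colony counts, dilutions
#' outside (0, 1], non-positive volumes, malformed history codes, a missing
#' colony count on a countable plate, or a plated fraction above 1) are
#' dropped and reported in the `diagnostics` table with their row number;
#' valid rows are kept. A missing required column is a schema error and
#' aborts. Duplicate (treatment, selection, dilution) rows are legitimate
#' replicate plates and are retained.
#'
#' @param source Path to a CSV file, or a data frame already in the schema.
#' @return An object of class `myxo_counts`: a list with `observations`
#'   (validated tibble with `plated_fraction` added) and `diagnostics`
#'   (tibble with columns `row`, `field`, `problem`).
#' @seealso [write_counts()], [validate_design()]
#' @export
read_counts <- function(source) {
  df <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    if (!file.exists(source)) {
      stage_abort("counts_io", sprintf("counts file not found: %s", source),
                  class = "myxofit_schema_error")
    }
    readr::read_csv(source, col_types = readr::cols(
      pair_id = readr::col_character(),
      focal_strain = readr::col_character(),
      partner_strain = readr::col_character(),
      history_focal = readr::col_character(),
      history_partner = readr::col_character(),
      replicate = readr::col_integer(),
      selection = readr::col_character(),
      dilution = readr::col_double(),
      volume_ml = readr::col_double(),
      harvest_volume_ml = readr::col_double(),
      colonies = readr::col_double(),
      countable = readr::col_logical()), progress = FALSE)
  }
  missing_cols <- setdiff(counts_schema, names(df))
  if (length(missing_cols)) {
    stage_abort("counts_io",
                paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")),
                class = "myxofit_schema_error")
  }
  df <- df[counts_schema]
  df$replicate <- as.integer(df$replicate)
  df$countable <- as.logical(df$countable)

  diag <- list()
  flag <- function(bad, field, problem) {
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      diag[[length(diag) + 1L]] <<- tibble::tibble(
        row = which(bad), field = field, problem = problem)
    }
    bad
  }
  pure <- is.na(df$partner_strain)
  bad <- flag(is.na(df$pair_id) | is.na(df$focal_strain),
              "pair_id/focal_strain", "missing identifier")
  bad <- bad | flag(!(pure == is.na(df$history_partner)),
                    "history_partner",
                    "partner history must be absent iff partner strain is absent")
  bad <- bad | flag(!df$history_focal %in% c("H", "L"),
                    "history_focal", "must be 'H' or 'L'")
  bad <- bad | flag(!(is.na(df$history_partner) |
                        df$history_partner %in% c("H", "L")),
                    "history_partner", "must be 'H' or 'L'")
  bad <- bad | flag(df$replicate < 1L, "replicate", "must be >= 1")
  bad <- bad | flag(is.na(df$selection) | df$selection == "",
                    "selection", "missing (use 'none' for non-selective agar)")
  bad <- bad | flag(df$dilution <= 0 | df$dilution > 1,
                    "dilution", "must be a fraction in (0, 1]")
  bad <- bad | flag(df$volume_ml <= 0, "volume_ml", "must be positive")
  bad <- bad | flag(df$harvest_volume_ml <= 0, "harvest_volume_ml",
                    "must be positive")
  countable <- df$countable %in% TRUE
  bad <- bad | flag(countable & (is.na(df$colonies) | df$colonies < 0),
                    "colonies",
                    "countable plates need a non-negative colony count")
  pf <- df$volume_ml * df$dilution / df$harvest_volume_ml
  bad <- bad | flag(!bad & pf > 1, "plated_fraction",
                    "volume x dilution exceeds harvest volume")

  obs <- df[!bad, , drop = FALSE]
  obs$plated_fraction <- pf[!bad]
  diagnostics <- if (length(diag)) {
    dplyr::arrange(dplyr::bind_rows(diag), .data$row)
  } else {
    tibble::tibble(row = integer(), field = character(),
                   problem = character())
  }
  structure(list(observations = obs, diagnostics = diagnostics),
            class = "myxo_counts")
}

#' Write a plate-count table in the canonical CSV schema
#'
#' Inverse of [read_counts()]: writes the twelve schema columns (derived
#' columns such as `plated_fraction` are dropped, never stored).
#'
#' @param counts A `myxo_counts` object or an observations data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  obs <- if (inherits(counts, "myxo_counts")) counts$observations else counts
  readr::write_csv(obs[counts_schema], path, progress = FALSE)
  invisible(path)
}

#' @export
print.myxo_counts <- function(x, ...) {
  cat("<myxo_counts> ", nrow(x$observations), " plates, ",
      nrow(x$diagnostics), " diagnostics\n", sep = "")
  invisible(x)
}

#' Check a plate-count table against the expected factorial design
#'
#' Reports, for every pair in the design, which of the four nutrient-history
#' cells (H/H, H/L, L/H, L/L) are present and with how many replicates;
#' which (strain, history) pure-culture controls exist; and for which focal
#' strains the mixing effect C is uncomputable because the matching-history
#' pure culture is missing entirely. Reporting only: nothing is rejected
#' here, but [build_fitness_table()] refuses to compute C for the flagged
#' strains.
#'
#' @param counts A `myxo_counts` object or observations data frame.
#' @param design A [mix_design()].
#' @param n_replicates Expected replicates per cell (default 4).
#' @return A list of class `myxo_design_report` with elements `cells`,
#'   `missing_cells`, `pure_coverage`, `c_uncomputable` and `complete`.
#' @export
validate_design <- function(counts, design, n_replicates = 4L) {
  obs <- if (inherits(counts, "myxo_counts")) counts$observations else
    tibble::as_tibble(counts)
  stopifnot(inherits(design, "mix_design"))

  mixes <- obs[obs$pair_id != "pure", , drop = FALSE]
  expected <- tidyr::expand_grid(pair_id = design$pairs$pair_id,
                                 history_focal = c("H", "L"),
                                 history_partner = c("H", "L"))
  seen <- dplyr::distinct(mixes, .data$pair_id, .data$history_focal,
                          .data$history_partner, .data$replicate)
  cells <- dplyr::count(seen, .data$pair_id, .data$history_focal,
                        .data$history_partner, name = "n_replicates")
  cells <- dplyr::left_join(expected, cells,
                            by = c("pair_id", "history_focal",
                                   "history_partner"))
  cells$n_replicates[is.na(cells$n_replicates)] <- 0L
  cells$cell <- cell_label(cells$history_focal, cells$history_partner)
  cells$complete <- cells$n_replicates >= n_replicates
  missing_cells <- cells[cells$n_replicates == 0L,
                         c("pair_id", "cell"), drop = FALSE]

  pures <- obs[obs$pair_id == "pure", , drop = FALSE]
  pure_seen <- dplyr::distinct(pures, strain = .data$focal_strain,
                               history = .data$history_focal,
                               .data$replicate)
  pure_coverage <- dplyr::count(pure_seen, .data$strain, .data$history,
                                name = "n_replicates")
  pure_expected <- tidyr::expand_grid(strain = design$strains$strain,
                                      history = c("H", "L"))
  pure_coverage <- dplyr::left_join(pure_expected, pure_coverage,
                                    by = c("strain", "history"))
  pure_coverage$n_replicates[is.na(pure_coverage$n_replicates)] <- 0L

  # C_i(j) needs a pure culture of the focal strain grown under the focal
  # strain's own nutrient history; list every (pair, focal, cell) without one.
  need <- dplyr::bind_rows(
    dplyr::transmute(cells, pair_id = .data$pair_id,
                     focal = design$pairs$strain_a[match(.data$pair_id, design$pairs$pair_id)],
                     history = .data$history_focal, cell = .data$cell,
                     present = .data$n_replicates > 0L),
    dplyr::transmute(cells, pair_id = .data$pair_id,
                     focal = design$pairs$strain_b[match(.data$pair_id, design$pairs$pair_id)],
                     history = .data$history_partner, cell = .data$cell,
                     present = .data$n_replicates > 0L))
  need <- dplyr::left_join(
    need[need$present, setdiff(names(need), "present")],
    dplyr::transmute(pure_coverage, strain = .data$strain,
                     history = .data$history,
                     pure_ok = .data$n_replicates > 0L),
    by = c(focal = "strain", "history"))
  c_uncomputable <- need[!need$pure_ok,
                         c("pair_id", "focal", "cell"), drop = FALSE]

  structure(list(
    cells = cells[c("pair_id", "cell", "n_replicates", "complete")],
    missing_cells = missing_cells,
    pure_coverage = pure_coverage,
    c_uncomputable = c_uncomputable,
    complete = nrow(missing_cells) == 0L && all(cells$complete) &&
      all(pure_coverage$n_replicates > 0L)),
    class = "myxo_design_report")
}

#' @export
print.myxo_design_report <- function(x, ...) {
  cat("<design report> ", if (x$complete) "complete" else "incomplete", "\n",
      sep = "")
  if (nrow(x$missing_cells)) {
    cat("missing cells:\n")
    print(x$missing_cells)
  }
  if (nrow(x$c_uncomputable)) {
    cat("mixing effect uncomputable (no matching-history pure culture):\n")
    print(x$c_uncomputable)
  }
  invisible(x)
}
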