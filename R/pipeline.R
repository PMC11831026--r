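# End-to-end orchestration: counts -> estimates -> fitness -> inference ->
# outcome calls, with CSV/JSON artifact emission.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "myxofit_error") && !is.null(e$stage)) stop(e)
    stage_abort(stage, paste0("[", stage, "] ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a plate-count table: schema validation and
#' design completeness reporting, per-spot spore estimation, the fitness
#' table, the factorial ANOVA, the two-question testing protocol
#' (zero-tests with Holm; Tukey HSD and Dunnett-vs-H/H contrasts), and
#' qualitative outcome classification.
#'
#' For each pair the statistic follows the design's `analysis` column:
#' `"W"` pairs are tested on the first-listed (defector) strain's relative
#' fitness; `"C"` pairs are tested on the mixing effect of each partner.
#' The ANOVA is the three-factor genotype x focal-nutrients x
#' partner-nutrients model on W across all `"W"` pairs (two-factor when only
#' one such pair is present), plus a two-factor nutrients model on C per
#' (`"C"` pair, focal strain).
#'
#' When `out_dir` is given, writes `estimates.csv`, `fitness.csv`,
#' `anova.csv`, `tests.csv`, `outcomes.csv` and `summary.json` (the full
#' run configuration plus a content hash, for provenance). Re-running with
#' identical inputs and configuration rewrites identical artifacts.
#'
#' @param counts A `myxo_counts` object, counts data frame, or CSV path.
#' @param design A [mix_design()] (default [default_design()]).
#' @param alpha Significance level (default 0.05).
#' @param log_base Base of the mixing-effect logarithm (default 10).
#' @param out_dir Optional output directory for the artifact bundle.
#' @param n_replicates Expected replicates per cell for the design report.
#' @return A list of class `myxo_run` with elements `design_report`,
#'   `estimates`, `fitness`, `anova`, `tests`, `contrasts`, `outcomes` and
#'   `config`.
#' @export
run_pipeline <- function(counts, design = default_design(), alpha = 0.05,
                         log_base = 10, out_dir = NULL,
                         n_replicates = 4L) {
  counts_src <- if (is.character(counts)) counts else "<in-memory>"
  counts <- run_stage("counts_io", {
    if (inherits(counts, "myxo_counts")) counts else read_counts(counts)
  })
  report <- run_stage("counts_io", validate_design(counts, design,
                                                   n_replicates))
  estimates <- run_stage("cfu_estimation", estimate_samples(counts, design))
  fitness <- run_stage("fitness_metrics",
                       build_fitness_table(estimates, design,
                                           log_base = log_base))

  uncomputable <- report$c_uncomputable

  tests <- list(); contrasts <- list(); outcomes <- list(); anovas <- list()
  run_stage("inference", {
    for (k in seq_len(nrow(design$pairs))) {
      p <- design$pairs[k, ]
      focals <- if (p$analysis == "W") p$strain_a else
        c(p$strain_a, p$strain_b)
      for (focal in focals) {
        value <- if (p$analysis == "W") "W_ij" else "C_i_of_j"
        fam <- fitness[fitness$pair_id == p$pair_id &
                         fitness$strain_i == focal, ]
        if (!nrow(fam)) next
        blocked <- uncomputable[uncomputable$pair_id == p$pair_id &
                                  uncomputable$focal == focal, ]
        if (p$analysis == "C" && nrow(blocked)) {
          rlang::warn(sprintf(
            "pair '%s', focal '%s': mixing effect not analysed (missing matching-history pure culture)",
            p$pair_id, focal))
          next
        }
        zt <- test_vs_zero(fam, value = value, alpha = alpha)
        dn <- tryCatch(
          compare_histories(fam, value = value, mode = "vs-reference",
                            reference = "H/H", alpha = alpha),
          error = function(e) NULL)
        tk <- tryCatch(
          compare_histories(fam, value = value, mode = "all-pairs",
                            alpha = alpha),
          error = function(e) NULL)
        oc <- classify_outcomes(zt, dn)
        id <- tibble::tibble(pair_id = p$pair_id, response = p$analysis,
                             focal_strain = focal)
        tests[[length(tests) + 1L]] <- dplyr::bind_cols(
          id[rep(1, nrow(zt)), ], zt)
        if (!is.null(dn)) {
          contrasts[[length(contrasts) + 1L]] <- dplyr::bind_cols(
            id[rep(1, nrow(dn)), ], dn)
        }
        if (!is.null(tk)) {
          contrasts[[length(contrasts) + 1L]] <- dplyr::bind_cols(
            id[rep(1, nrow(tk)), ], tk)
        }
        # Display cells in the pair's canonical orientation (first-listed
        # strain's history first).
        oc$cell_pair <- if (focal == p$strain_a) oc$cell else
          flip_cell(oc$cell)
        outcomes[[length(outcomes) + 1L]] <- dplyr::bind_cols(
          id[rep(1, nrow(oc)), ], oc)
      }
    }

    w_pairs <- design$pairs[design$pairs$analysis == "W", ]
    if (nrow(w_pairs)) {
      wdat <- fitness[fitness$pair_id %in% w_pairs$pair_id &
                        fitness$strain_i %in% w_pairs$strain_a, ]
      factors <- if (length(unique(wdat$strain_i)) > 1) {
        c("strain_i", "history_i", "history_j")
      } else {
        c("history_i", "history_j")
      }
      tab <- tryCatch(factorial_anova(wdat, "W_ij", factors),
                      error = function(e) NULL)
      if (!is.null(tab)) {
        tab$term <- rename_anova_terms(tab$term)
        anovas[[length(anovas) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(scope = "defector pairs", response = "W")[
            rep(1, nrow(tab)), ],
          tab, tibble::tibble(df_residual = attr(tab, "df_residual")))
      }
    }
    for (k in which(design$pairs$analysis == "C")) {
      p <- design$pairs[k, ]
      for (focal in c(p$strain_a, p$strain_b)) {
        cdat <- fitness[fitness$pair_id == p$pair_id &
                          fitness$strain_i == focal, ]
        tab <- tryCatch(
          factorial_anova(cdat, "C_i_of_j", c("history_i", "history_j")),
          error = function(e) NULL)
        if (is.null(tab)) next
        tab$term <- rename_anova_terms(tab$term)
        anovas[[length(anovas) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(scope = paste0(p$pair_id, " focal ", focal),
                         response = "C")[rep(1, nrow(tab)), ],
          tab, tibble::tibble(df_residual = attr(tab, "df_residual")))
      }
    }
  })

  tests <- dplyr::bind_rows(tests)
  contrasts <- dplyr::bind_rows(contrasts)
  outcomes <- dplyr::bind_rows(outcomes)
  anova_tbl <- dplyr::bind_rows(anovas)
  config <- list(counts_source = counts_src, alpha = alpha,
                 log_base = log_base, n_replicates = n_replicates,
                 holm_family = "the 4 history cells of one (pair, statistic)",
                 design = list(strains = as.data.frame(design$strains),
                               pairs = as.data.frame(design$pairs),
                               density_cells_per_ml = design$density_cells_per_ml,
                               spot_volume_ml = design$spot_volume_ml))

  result <- structure(list(design_report = report, estimates = estimates,
                           fitness = fitness, anova = anova_tbl,
                           tests = tests, contrasts = contrasts,
                           outcomes = outcomes, config = config),
                      class = "myxo_run")
  if (!is.null(out_dir)) {
    run_stage("cli_report", write_run_bundle(result, out_dir))
  }
  result
}

# Human-readable names for the factorial terms.
rename_anova_terms <- function(terms) {
  terms <- gsub("strain_i", "genotype", terms, fixed = TRUE)
  terms <- gsub("history_i", "nutrients[focal]", terms, fixed = TRUE)
  terms <- gsub("history_j", "nutrients[partner]", terms, fixed = TRUE)
  gsub(":", " x ", terms, fixed = TRUE)
}

write_run_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$estimates, file.path(out_dir, "estimates.csv"),
                   progress = FALSE)
  readr::write_csv(result$fitness, file.path(out_dir, "fitness.csv"),
                   progress = FALSE)
  readr::write_csv(result$anova, file.path(out_dir, "anova.csv"),
                   progress = FALSE)
  readr::write_csv(result$tests, file.path(out_dir, "tests.csv"),
                   progress = FALSE)
  readr::write_csv(result$outcomes, file.path(out_dir, "outcomes.csv"),
                   progress = FALSE)
  summary <- list(config = result$config,
                  config_hash = rlang::hash(result$config),
                  n_estimates = nrow(result$estimates),
                  n_fitness_records = nrow(result$fitness),
                  design_complete = result$design_report$complete,
                  outcome_grid = as.data.frame(
                    result$outcomes[c("pair_id", "response", "focal_strain",
                                      "cell_pair", "verdict")]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render the qualitative outcome grid
#'
#' Formats the outcome calls as a markdown table of pairs (rows) by
#' nutrient-history cells (columns), mirroring the occurrence-grid style of
#' presentation: `+` exploitation/cheating, `(+)` occurrence with strength
#' significantly reduced versus H/H, `-` no significant positive effect,
#' `x` significantly negative (antagonized). Cell columns follow the
#' pair's orientation (first letter = history of the first-listed strain).
#'
#' @param outcomes The `outcomes` tibble of a [run_pipeline()] result (or a
#'   `myxo_run` object).
#' @return Character vector of markdown lines, class `myxo_grid` (printed
#'   with a legend).
#' @export
render_outcome_grid <- function(outcomes) {
  if (inherits(outcomes, "myxo_run")) outcomes <- outcomes$outcomes
  outcomes <- tibble::as_tibble(outcomes)
  if (!nrow(outcomes)) {
    rlang::warn("no outcomes to render; returning an empty grid")
    return(structure(character(), class = "myxo_grid"))
  }
  sym <- c("+" = "+", "reduced-but-present" = "(+)", "-" = "-",
           "antagonized" = "x")
  cellcol <- if ("cell_pair" %in% names(outcomes)) "cell_pair" else "cell"
  wide <- outcomes |>
    dplyr::mutate(rowlab = paste0(.data$pair_id, " [", .data$response,
                                  ", focal ", .data$focal_strain, "]"),
                  symbol = sym[.data$verdict]) |>
    dplyr::select("rowlab", cell = dplyr::all_of(cellcol), "symbol") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "symbol")
  cells <- intersect(cell_levels, names(wide))
  header <- paste0("| pair | ", paste(cells, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---|", length(cells) + 1), collapse = ""))
  body <- vapply(seq_len(nrow(wide)), function(r) {
    vals <- vapply(cells, function(cc) {
      v <- wide[[cc]][r]
      if (is.na(v)) "." else v
    }, character(1))
    paste0("| ", wide$rowlab[r], " | ", paste(vals, collapse = " | "), " |")
  }, character(1))
  legend <- "Legend: + exploitation/cheating; (+) occurs but reduced vs H/H; - none; x antagonized; . not tested"
  structure(c(header, sep, body, "", legend), class = "myxo_grid")
}

#' @export
print.myxo_grid <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.myxo_run <- function(x, ...) {
  cat("<myxo_run> ", nrow(x$fitness), " fitness records, ",
      nrow(x$outcomes), " outcome calls\n", sep = "")
  print(render_outcome_grid(x$outcomes))
  invisible(x)
}
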