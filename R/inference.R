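# Two-question testing protocol and factorial ANOVA.
#
# Question (a): did exploitation/cheating occur — is the statistic different
# from zero in each nutrient-history cell (one-sample t, Bonferroni-Holm
# over the cells of one pair x statistic family)?
# Question (b): does nutrient history affect the interaction — comparing the
# cells against each other (Tukey HSD) or against the H/H standard-condition
# reference (Dunnett).

#' Holm step-down adjustment
#'
#' Thin, explicit wrapper around `stats::p.adjust(method = "holm")`; rows
#' are processed in a stable order so ties are handled deterministically.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  stats::p.adjust(p, method = "holm")
}

#' One-sample t tests of a statistic against zero, per history cell
#'
#' Runs a two-sided one-sample t test in every group (by default the four
#' nutrient-history cells of one pair-statistic family) and applies the
#' Bonferroni-Holm correction across the family. Groups are ordered by
#' label before adjustment so output is deterministic.
#'
#' A zero-variance group is degenerate: no t distribution applies, so
#' `p_raw`/`p_adjusted` are `NA` and `degenerate = TRUE`. Such a group is
#' still marked `significant` when its constant value differs from `mu`
#' (zero sampling variance; this is what noise-free expectation-mode data
#' produce), and not significant when it equals `mu`.
#'
#' @param data Data frame of per-replicate values.
#' @param value Name of the value column (e.g. `"W_ij"`).
#' @param group Name of the grouping column (default `"cell"`).
#' @param mu Null value (default 0).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble with one row per group: group label, `n`, `mean`, `sd`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted`, `method`, `significant`,
#'   `direction`, `degenerate`.
#' @export
test_vs_zero <- function(data, value, group = "cell", mu = 0, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  vals <- data[[value]]
  grps <- data[[group]]
  keep <- is.finite(vals)
  vals <- vals[keep]; grps <- grps[keep]
  labels <- sort(unique(grps))
  rows <- lapply(labels, function(g) {
    x <- vals[grps == g]
    if (length(x) < 2) {
      rlang::abort(sprintf("group '%s' has fewer than 2 finite values", g),
                   class = "myxofit_domain_error")
    }
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) {
      tibble::tibble(group = g, n = length(x), mean = m, sd = s,
                     statistic = NA_real_, df = length(x) - 1,
                     p_raw = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(x, mu = mu)
      tibble::tibble(group = g, n = length(x), mean = m, sd = s,
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_raw = tt$p.value,
                     degenerate = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- NA_real_
  testable <- !out$degenerate
  out$p_adjusted[testable] <- holm_adjust(out$p_raw[testable])
  out$method <- ifelse(out$degenerate, "one-sample t (degenerate)",
                       "one-sample t + Holm")
  out$significant <- ifelse(out$degenerate, out$mean != mu,
                            out$p_adjusted < alpha)
  out$direction <- sign(out$mean - mu)
  names(out)[names(out) == "group"] <- group
  out[c(group, "n", "mean", "sd", "statistic", "df", "p_raw", "p_adjusted",
        "method", "significant", "direction", "degenerate")]
}

#' Compare a statistic between nutrient-history cells
#'
#' `mode = "all-pairs"` runs Tukey's HSD over all cells;
#' `mode = "vs-reference"` runs Dunnett contrasts of every cell against the
#' H/H standard-condition reference. Both assume equal variances across
#' cells (the standard implementations, on the pooled one-way ANOVA fit).
#'
#' If the one-way fit has (numerically) zero residual variance — noise-free
#' expectation-mode data — contrasts are reported with `p_adjusted = NA`,
#' `degenerate = TRUE`, and significance determined by whether the exact
#' contrast estimate is nonzero.
#'
#' @param data Data frame of per-replicate values.
#' @param value Name of the value column.
#' @param group Name of the grouping column (default `"cell"`).
#' @param mode `"all-pairs"` (Tukey HSD) or `"vs-reference"` (Dunnett).
#' @param reference Reference group for Dunnett mode (default `"H/H"`).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per contrast: `contrast`, `cell` (the
#'   non-reference cell, Dunnett mode), `estimate`, `se`, `df`,
#'   `p_adjusted`, `method`, `significant`, `degenerate`.
#' @export
compare_histories <- function(data, value, group = "cell",
                              mode = c("all-pairs", "vs-reference"),
                              reference = "H/H", alpha = 0.05) {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  d <- tibble::tibble(y = data[[value]], g = as.character(data[[group]]))
  d <- d[is.finite(d$y), ]
  tab <- table(d$g)
  if (length(tab) < 2 || any(tab < 2)) {
    rlang::abort("need >= 2 groups with >= 2 values each",
                 class = "myxofit_domain_error")
  }
  if (mode == "vs-reference" && !reference %in% names(tab)) {
    rlang::abort(sprintf("reference cell '%s' absent from the data", reference),
                 class = "myxofit_domain_error")
  }
  lev <- if (mode == "vs-reference") {
    c(reference, sort(setdiff(names(tab), reference)))
  } else {
    sort(names(tab))
  }
  d$g <- factor(d$g, levels = lev)
  fit <- stats::aov(y ~ g, data = d)
  sigma2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  scale <- stats::var(d$y)
  degenerate <- !is.finite(sigma2) || scale == 0 ||
    sigma2 <= scale * .Machine$double.eps * 1e3

  means <- tapply(d$y, d$g, mean)
  if (mode == "all-pairs") {
    combos <- utils::combn(lev, 2)
    est <- means[combos[2, ]] - means[combos[1, ]]
    contrast <- paste(combos[2, ], combos[1, ], sep = " - ")
    cellcol <- rep(NA_character_, length(est))
    method <- "Tukey HSD"
  } else {
    others <- lev[-1]
    est <- means[others] - means[[reference]]
    contrast <- paste(others, reference, sep = " - ")
    cellcol <- others
    method <- "Dunnett"
  }

  if (degenerate) {
    return(tibble::tibble(
      contrast = contrast, cell = cellcol, estimate = unname(est),
      se = 0, df = stats::df.residual(fit), p_adjusted = NA_real_,
      method = paste(method, "(degenerate)"),
      significant = abs(unname(est)) > 0, degenerate = TRUE))
  }

  if (mode == "all-pairs") {
    tk <- stats::TukeyHSD(fit)$g
    # TukeyHSD labels contrasts "b-a" with later level first; align to ours.
    key <- paste(combos[2, ], combos[1, ], sep = "-")
    idx <- match(key, rownames(tk))
    p_adj <- tk[idx, "p adj"]
    se <- sqrt(sigma2) *
      as.numeric(sqrt(1 / tab[combos[1, ]] + 1 / tab[combos[2, ]]))
  } else {
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- with_fixed_rng(summary(glht_fit))
    p_adj <- as.numeric(sm$test$pvalues)
    se <- as.numeric(sm$test$sigma)
  }
  tibble::tibble(
    contrast = contrast, cell = cellcol, estimate = unname(est),
    se = unname(se), df = stats::df.residual(fit),
    p_adjusted = unname(p_adj), method = method,
    significant = unname(p_adj) < alpha, degenerate = FALSE)
}

#' Full-factorial ANOVA for strain-by-nutrient-history effects
#'
#' Fits a Gaussian linear model with all main effects and interactions of
#' the supplied factors (for defector-cooperator data: cheater genotype x
#' focal-strain nutrients x partner nutrients on W) and returns the ANOVA
#' table. On the balanced factorial design the sequential (Type I) sums of
#' squares equal Type III, so term order is immaterial.
#'
#' @param data Data frame of per-replicate records.
#' @param response Name of the response column (e.g. `"W_ij"`,
#'   `"C_i_of_j"`, or a log10 spore total).
#' @param factors Character vector of factor column names (crossed in
#'   full).
#' @return Tibble with one row per model term: `term`, `df`, `sumsq`,
#'   `statistic` (F), `p`; residual df and sum of squares are attached as
#'   attributes `df_residual` and `sumsq_residual`.
#' @export
factorial_anova <- function(data, response, factors) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss)) {
    rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                 class = "myxofit_domain_error")
  }
  d <- data[c(response, factors)]
  d <- d[is.finite(d[[response]]), ]
  cells <- table(d[factors])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE, useNames = TRUE)
    lab <- apply(empty, 1, function(idx) {
      paste(mapply(function(f, i) dimnames(cells)[[f]][i],
                   seq_along(factors), idx),
            collapse = ":")
    })
    rlang::abort(paste0("cannot fit the full factorial: empty cell(s) ",
                        paste(lab, collapse = ", ")),
                 class = "myxofit_domain_error")
  }
  for (f in factors) d[[f]] <- factor(d[[f]])
  fml <- stats::reformulate(paste(factors, collapse = " * "),
                            response = response)
  fit <- stats::lm(fml, data = d)
  if (stats::df.residual(fit) < 1) {
    rlang::abort("no residual degrees of freedom (need >= 2 replicates per cell)",
                 class = "myxofit_domain_error")
  }
  tab <- stats::anova(fit)
  terms <- rownames(tab)
  resid_row <- terms == "Residuals"
  out <- tibble::tibble(
    term = terms[!resid_row], df = tab$Df[!resid_row],
    sumsq = tab$`Sum Sq`[!resid_row],
    statistic = tab$`F value`[!resid_row], p = tab$`Pr(>F)`[!resid_row])
  attr(out, "df_residual") <- tab$Df[resid_row]
  attr(out, "sumsq_residual") <- tab$`Sum Sq`[resid_row]
  out
}

#' Turn test results into qualitative outcome calls
#'
#' Applies the sign-and-significance rules used for the occurrence grids:
#' per cell, `"+"` when the mean is positive and the zero-test significant;
#' `"antagonized"` when the mean is negative and significant; `"-"`
#' otherwise. A `"+"` cell whose Dunnett contrast against the H/H reference
#' shows a significant decrease is downgraded to `"reduced-but-present"`
#' (exploitation/cheating still occurs, at significantly lower strength
#' than under the standard condition).
#'
#' Pure function of its inputs: the full supporting test rows are carried
#' along as provenance columns.
#'
#' @param zero_tests Output of [test_vs_zero()] for one family.
#' @param reference_contrasts Optional output of
#'   [compare_histories()] in `"vs-reference"` mode.
#' @param group Grouping column name (default `"cell"`).
#' @return Tibble with one row per cell: the cell, `verdict`, `mean`,
#'   `p_zero` (Holm-adjusted), `p_vs_reference` and `degenerate`.
#' @export
classify_outcomes <- function(zero_tests, reference_contrasts = NULL,
                              group = "cell") {
  zt <- tibble::as_tibble(zero_tests)
  verdict <- rep("-", nrow(zt))
  verdict[zt$significant & zt$mean > 0] <- "+"
  verdict[zt$significant & zt$mean < 0] <- "antagonized"
  p_ref <- rep(NA_real_, nrow(zt))
  if (!is.null(reference_contrasts)) {
    rc <- tibble::as_tibble(reference_contrasts)
    idx <- match(zt[[group]], rc$cell)
    hit <- !is.na(idx)
    p_ref[hit] <- rc$p_adjusted[idx[hit]]
    reduced <- hit & verdict == "+" &
      rc$significant[idx] %in% TRUE & rc$estimate[idx] < 0
    verdict[reduced] <- "reduced-but-present"
  }
  out <- tibble::tibble(cell = zt[[group]], verdict = verdict,
                        mean = zt$mean, p_zero = zt$p_adjusted,
                        p_vs_reference = p_ref, degenerate = zt$degenerate)
  names(out)[1] <- group
  out
}
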