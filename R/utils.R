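# Internal helpers shared across the pipeline.

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical ordering of the four nutrient-history cells (focal/partner).
cell_levels <- c("H/H", "H/L", "L/H", "L/L")

cell_label <- function(history_focal, history_partner) {
  paste(history_focal, history_partner, sep = "/")
}

# Stop with a stage-tagged condition so run_pipeline() can name the stage
# where a failure originated.
stage_abort <- function(stage, message, class = "myxofit_error", ...) {
  rlang::abort(message, class = c(class, "myxofit_error"), stage = stage, ...)
}

# Evaluate `expr` under a fixed RNG state and restore the caller's state
# afterwards. Used for multcomp's quasi-Monte-Carlo multivariate-t
# integration so adjusted p-values are reproducible without consuming the
# user's random stream.
with_fixed_rng <- function(expr, seed = 20240101L) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Geometric mean on the log10 scale; efficiencies and spore totals are
# summarised multiplicatively throughout.
geom_mean <- function(x) 10^mean(log10(x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
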