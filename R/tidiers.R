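#' Tidy a cost-utility result into a category cost table
#'
#' One row per arm and cost category (discounted lifetime Euros), mirroring
#' the structure of a published cost-benefit table: acute phase, pacemaker,
#' rehospitalization, reintervention and the three alive health states,
#' plus the (zero) death category.
#'
#' @param x A `cea_result` from [run_base_case()] or [run_scenario()].
#' @param ... Unused.
#' @return A tibble with columns `arm`, `category`, `discounted`,
#'   `undiscounted`, `year1`.
#' @export
tidy.cea_result <- function(x, ...) {
  bind_rows(
    mutate(x$tavi$categories, arm = "tavi"),
    mutate(x$savr$categories, arm = "savr")
  ) |>
    select("arm", "category", "discounted", "undiscounted", "year1")
}

#' One-row summary of a cost-utility result
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A one-row tibble: per-arm totals, QALYs, life years, median
#'   survival, and the incremental statistics at the result's threshold.
#' @export
glance.cea_result <- function(x, ...) {
  inc <- x$incremental
  tibble(
    tavi_cost = x$tavi$total_cost, savr_cost = x$savr$total_cost,
    tavi_qalys = x$tavi$qalys, savr_qalys = x$savr$qalys,
    tavi_life_years = x$tavi$life_years, savr_life_years = x$savr$life_years,
    tavi_median_survival = as.numeric(x$tavi$median_survival),
    savr_median_survival = as.numeric(x$savr$median_survival),
    delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
    icer = inc$icer, inmb = inc$inmb, inhb = inc$inhb,
    dominance = inc$dominance, lambda = inc$lambda
  )
}

#' Tidy PSA draws
#'
#' @param x A `cea_psa` tibble.
#' @param ... Unused.
#' @return The per-draw tibble (draw, per-arm cost/QALYs, increments).
#' @export
tidy.cea_psa <- function(x, ...) as_tibble(x)

#' One-row PSA summary
#'
#' @param x A `cea_psa` tibble.
#' @param lambda Threshold for the cost-effectiveness probability (default:
#'   the threshold the PSA was run with).
#' @param ... Unused.
#' @return A one-row tibble with draw count, mean increments, probability
#'   cost-effective at `lambda` and at 20,000 Euros/QALY, and probability
#'   dominant.
#' @export
glance.cea_psa <- function(x, lambda = attr(x, "lambda"), ...) {
  tibble(
    n = nrow(x),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qaly = mean(x$delta_qaly),
    prob_ce = mean(lambda * x$delta_qaly - x$delta_cost > 0),
    prob_ce_20k = mean(20000 * x$delta_qaly - x$delta_cost > 0),
    prob_dominant = mean(x$delta_cost < 0 & x$delta_qaly > 0),
    lambda = lambda
  )
}
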