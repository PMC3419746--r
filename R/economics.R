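#' Gross benefit of retained catch
#'
#' Values retained catch at per-group prices: `GB = sum price * quantity`
#' per fleet and year. Non-retained (discarded) records contribute nothing.
#'
#' @param catch Catch tibble with columns `year`, `fleet`, `group`,
#'   `quantity_t`, `retained`.
#' @param prices Named vector, USD per tonne. Every retained group must be
#'   priced.
#' @return Tibble with columns `fleet`, `year`, `gb` (USD).
#' @export
gross_benefit <- function(catch, prices) {
  kept <- dplyr::filter(catch, .data$retained)
  missing <- setdiff(unique(kept$group), names(prices))
  if (length(missing) > 0) {
    abort(paste("no price for retained group(s):",
                paste(missing, collapse = ", ")),
          class = "vaquitamse_config_error")
  }
  kept |>
    dplyr::mutate(value = .data$quantity_t * prices[.data$group]) |>
    dplyr::group_by(.data$fleet, .data$year) |>
    dplyr::summarise(gb = sum(.data$value), .groups = "drop")
}

#' Net benefit from gross benefit and a cost rate
#'
#' `NB = GB * (1 - C)` with cost rate `C` in `[0, 1]` (0.32 for artisanal
#' fleets, 0.96 for industrial fleets).
#'
#' @param gb Gross benefit (USD), vectorized.
#' @param cost_rate Cost rate(s) in `[0, 1]`.
#' @return Net benefit (USD).
#' @examples
#' net_benefit(100, 0.32)
#' @export
net_benefit <- function(gb, cost_rate) {
  if (any(cost_rate < 0 | cost_rate > 1)) {
    abort("cost rate must lie in [0, 1]", class = "vaquitamse_domain_error")
  }
  gb * (1 - cost_rate)
}

#' Discount factor
#'
#' `d_t = (1 + delta)^(-t)`; the first projection year is `t = 0` (`d = 1`).
#'
#' @param t Years from the start, >= 0 (vectorized).
#' @param delta Annual discount rate (default 0.036).
#' @return Discount factor(s).
#' @examples
#' discount_factor(30, 0.036)
#' @export
discount_factor <- function(t, delta = 0.036) {
  stopifnot(all(t >= 0), delta >= 0)
  (1 + delta)^(-t)
}

#' Net present value of a net-benefit stream
#'
#' `NPV = sum_t NB_t * (1 + delta)^(-t)`, additive over fleets. Years are
#' indexed from the series' first year, which is discounted with `d = 1` by
#' default (`t0 = 0`).
#'
#' @param series Tibble with columns `fleet`, `year`, `nb` (or a plain
#'   numeric vector of annual net benefits, treated as a single fleet).
#' @param delta Annual discount rate.
#' @param t0 Index assigned to the first year of the series (0 by default;
#'   use 1 to discount the first year once).
#' @return A list of class `npv_result`: `npv` (total USD), `by_fleet`
#'   (tibble), `delta`, `discount` (tibble year, d).
#' @examples
#' npv(rep(1, 30), delta = 0.036, t0 = 1)$npv  # 30-year annuity, 18.16
#' @export
npv <- function(series, delta = 0.036, t0 = 0) {
  if (is.numeric(series)) {
    series <- tibble::tibble(fleet = "all",
                             year = seq_along(series) - 1 + 0,
                             nb = as.numeric(series))
  }
  stopifnot(all(c("fleet", "year", "nb") %in% names(series)))
  y0 <- min(series$year)
  series <- dplyr::mutate(series,
                          t = .data$year - y0 + t0,
                          d = discount_factor(.data$t, delta))
  by_fleet <- series |>
    dplyr::group_by(.data$fleet) |>
    dplyr::summarise(npv = sum(.data$nb * .data$d), .groups = "drop")
  structure(list(
    npv = sum(by_fleet$npv),
    by_fleet = by_fleet,
    delta = delta,
    discount = dplyr::distinct(series[, c("year", "t", "d")])
  ), class = "npv_result")
}

#' Mean and standard error over the final five years
#'
#' End-of-simulation summaries are reported as the mean of the last five
#' annual values with its standard error (`sd / sqrt(5)`).
#'
#' @param x Numeric vector of annual values in year order (length >= 5).
#' @return Named vector `c(mean, se)`.
#' @examples
#' last5_summary(1:5)
#' @export
last5_summary <- function(x) {
  if (length(x) < 5) {
    abort("need at least five annual values", class = "vaquitamse_domain_error")
  }
  tail5 <- utils::tail(x, 5)
  c(mean = mean(tail5), se = stats::sd(tail5) / sqrt(5))
}

#' Per-fleet annual gross and net benefit of a run
#'
#' Values each fleet's retained catch at the model's prices and applies the
#' fleet's cost rate. Years with no retained catch appear with zero benefit.
#'
#' @param run A `gulf_run`.
#' @param model The `gulf_model` that produced it (prices, cost rates).
#' @return Tibble with columns `fleet`, `year`, `gb`, `nb`.
#' @export
fleet_economics <- function(run, model) {
  horizon <- run$scenario$horizon_years
  frame <- tidyr::expand_grid(fleet = run$fleets$id, year = seq_len(horizon))
  gb <- gross_benefit(run$catch, model$economics$prices)
  cost <- setNames(run$fleets$cost_rate, run$fleets$id)
  frame |>
    dplyr::left_join(gb, by = c("fleet", "year")) |>
    dplyr::mutate(gb = dplyr::coalesce(.data$gb, 0),
                  nb = net_benefit(.data$gb, cost[.data$fleet]))
}
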