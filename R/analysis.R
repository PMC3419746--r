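#' Mature vaquita abundance of a state
#'
#' Sum of abundance over the mature age classes (lower age bound at or above
#' the maturity age, 10 y: classes 6--10) across all polygons.
#'
#' @param state A `gulf_state`.
#' @param model The `gulf_model` (age-structure metadata).
#' @param group Group id (default `"vaquita"`).
#' @return Individuals.
#' @export
mature_abundance <- function(state, model, group = "vaquita") {
  g <- match(group, model$foodweb$groups$id)
  if (is.na(g) || model$foodweb$groups$kind[g] != "age_structured") {
    abort("group must be an age-structured member of the food web",
          class = "vaquitamse_config_error")
  }
  cls <- mature_classes(model$foodweb$groups$n_classes[g],
                        model$foodweb$groups$years_per_class[g],
                        model$foodweb$groups$maturity_age[g])
  sum(state$n[[group]][cls, , drop = FALSE])
}

#' Percent change between two years of a trajectory
#'
#' `100 * (N_final - N_ref) / N_ref`, by convention between simulation year 1
#' (the first projected year, "2009") and year 30.
#'
#' @param trajectory Tibble with columns `year` and the value column.
#' @param value Column to compare (default `mature_abundance`).
#' @param ref_year,final_year Years compared (defaults 1 and 30).
#' @return Percent change.
#' @export
percent_change <- function(trajectory, value = "mature_abundance",
                           ref_year = 1, final_year = 30) {
  v_ref <- trajectory[[value]][trajectory$year == ref_year]
  v_fin <- trajectory[[value]][trajectory$year == final_year]
  if (length(v_ref) != 1 || length(v_fin) != 1) {
    abort("trajectory must contain exactly one row for each compared year",
          class = "vaquitamse_domain_error")
  }
  if (v_ref == 0) {
    abort("reference-year value is zero; percent change undefined",
          class = "vaquitamse_domain_error")
  }
  100 * (v_fin - v_ref) / v_ref
}

#' Realized bycatch mortality from catch and abundance series
#'
#' The exploitation ratio of the equilibrium curve: mean annual catch over
#' the final five years divided by mean abundance over the same years. With
#' the annual-mean (time-integrated) abundance as denominator this equals
#' the imposed constant hazard up to numerics (Baranov identity
#' `catch = F * mean N`).
#'
#' @param catch_series Annual catches (individuals per year).
#' @param abundance_series Annual (mean) abundances, same length.
#' @return Realized mortality (per year).
#' @export
realized_mortality <- function(catch_series, abundance_series) {
  stopifnot(length(catch_series) == length(abundance_series))
  if (length(catch_series) < 5) {
    abort("need at least five years", class = "vaquitamse_domain_error")
  }
  nbar <- mean(utils::tail(abundance_series, 5))
  if (nbar <= 0) {
    abort("mean abundance over the final five years is zero",
          class = "vaquitamse_domain_error")
  }
  mean(utils::tail(catch_series, 5)) / nbar
}

#' Equilibrium curve over constant bycatch hazards
#'
#' Runs the no-management ecosystem once per hazard in `f_grid` (all other
#' fleets at their no-management settings) and records the realized
#' exploitation ratio and the last-five-year mean abundance of each run.
#'
#' @param model A `gulf_model`.
#' @param f_grid Constant vaquita bycatch hazards (per year), default
#'   0--0.20 by 0.01.
#' @param n0 Initial abundance.
#' @param horizon_years Run length (default 30).
#' @param dt Step length in years.
#' @return A tibble of class `gulf_sweep`, sorted by `f_nominal`, with
#'   columns `f_nominal`, `realized_f`, `equilibrium_abundance`
#'   (last-5-year mean), `abundance_y30`, `abundance_y0`, `mature_y30`.
#' @export
f_sweep <- function(model, f_grid = seq(0, 0.2, by = 0.01), n0 = 245,
                    horizon_years = 30, dt = 1 / 365) {
  if (any(f_grid < 0)) {
    abort("hazards must be non-negative", class = "vaquitamse_domain_error")
  }
  rows <- purrr::map(sort(unique(f_grid)), function(f) {
    sc <- build_scenario("no_management", n0 = n0,
                         horizon_years = horizon_years,
                         vaquita_f_total = f)
    run <- simulate_scenario(model, sc, dt = dt, record_polygons = FALSE)
    vaq <- run$vaquita
    tail_n <- min(5, horizon_years)
    last5 <- dplyr::filter(vaq, .data$year > horizon_years - tail_n)
    tibble::tibble(
      f_nominal = f,
      realized_f = mean(utils::tail(vaq$catch_individuals[-1], tail_n)) /
        mean(utils::tail(vaq$mean_abundance[-1], tail_n)),
      equilibrium_abundance = mean(last5$abundance),
      abundance_y30 = vaq$abundance[vaq$year == horizon_years],
      abundance_y0 = vaq$abundance[vaq$year == 0],
      mature_y30 = vaq$mature_abundance[vaq$year == horizon_years])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gulf_sweep", class(out))
  out
}

#' Maximum sustainable bycatch mortality
#'
#' The largest hazard on the grid for which year-30 total abundance is at
#' least the initial abundance. Returns 0 with a warning if no positive
#' hazard qualifies.
#'
#' @param sweep A `gulf_sweep` from [f_sweep()] (its grid must include 0),
#'   or a `gulf_model`, in which case the sweep is run first with `...`
#'   passed on.
#' @param ... Passed to [f_sweep()] when `sweep` is a model.
#' @return Hazard (per year).
#' @export
max_sustainable_f <- function(sweep, ...) {
  if (inherits(sweep, "gulf_model")) sweep <- f_sweep(sweep, ...)
  if (!any(sweep$f_nominal == 0)) {
    abort("sweep grid must include zero", class = "vaquitamse_config_error")
  }
  ok <- sweep$f_nominal[sweep$abundance_y30 >= sweep$abundance_y0]
  if (length(ok) == 0 || max(ok) == 0) {
    warn("no positive hazard sustains the population; returning 0")
    return(0)
  }
  max(ok)
}

#' Realized diet compositions
#'
#' Per-predator realized prey proportions from the consumption records of a
#' run (proportions of annual consumed tonnage, summing to 1 per
#' predator-year), reported for the first and final simulated year by
#' default.
#'
#' @param run A `gulf_run`.
#' @param years Years to report (default first and last).
#' @param predator Optional predator id filter.
#' @return Tibble with columns `year`, `predator`, `prey`, `proportion`.
#' @export
diet_summary <- function(run, years = NULL, predator = NULL) {
  d <- run$diet
  if (nrow(d) == 0) {
    abort("run carries no consumption records", class = "vaquitamse_config_error")
  }
  years <- years %||% c(min(d$year), max(d$year))
  d <- dplyr::filter(d, .data$year %in% years)
  if (!is.null(predator)) d <- dplyr::filter(d, .data$predator %in% !!predator)
  d
}

#' Run a scenario suite
#'
#' Simulates every scenario of a grid (see [scenario_suite()]) and collects
#' one summary row per run.
#'
#' @param model A `gulf_model`.
#' @param suite Scenario grid tibble from [scenario_suite()].
#' @param dt Step length in years.
#' @return A tibble of class `gulf_suite`: `name`, `rho`, `n0`, `npv` (USD),
#'   `mature_y30`, `mature_y1`, `abundance_y30`, `pct_change_mature`,
#'   `realized_f_mean` plus a `run` list-column.
#' @export
run_suite <- function(model, suite = scenario_suite(), dt = 1 / 365) {
  rows <- purrr::pmap(suite, function(name, rho, n0, scenario) {
    run <- simulate_scenario(model, scenario, dt = dt,
                             record_polygons = FALSE)
    vaq <- run$vaquita
    tibble::tibble(
      name = name, rho = rho, n0 = n0,
      npv = run$npv$npv,
      mature_y1 = vaq$mature_abundance[vaq$year == 1],
      mature_y30 = vaq$mature_abundance[vaq$year == scenario$horizon_years],
      abundance_y30 = vaq$abundance[vaq$year == scenario$horizon_years],
      pct_change_mature = percent_change(
        vaq, final_year = scenario$horizon_years),
      realized_f_mean = mean(vaq$realized_f[-1]),
      run = list(run))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gulf_suite", class(out))
  out
}

#' Conservation-economics trade-off table
#'
#' One point per run: scenario, shrimp-catch reduction, initial abundance,
#' NPV, and year-30 mature vaquita abundance — the data behind the NPV
#' versus abundance trade-off plot with its 250-mature-individuals
#' downlisting reference line.
#'
#' @param suite_results A `gulf_suite` from [run_suite()].
#' @return Tibble with columns `scenario`, `rho`, `n0`, `npv`,
#'   `mature_abundance_y30`.
#' @export
tradeoff_table <- function(suite_results) {
  tibble::tibble(
    scenario = suite_results$name,
    rho = suite_results$rho,
    n0 = suite_results$n0,
    npv = suite_results$npv,
    mature_abundance_y30 = suite_results$mature_y30)
}
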