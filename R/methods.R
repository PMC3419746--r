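#' @export
print.gulf_model <- function(x, ...) {
  cat("<gulf_model> calibrated synthetic Upper Gulf ecosystem\n")
  cat("  polygons:", nrow(x$domain), " groups:", nrow(x$foodweb$groups),
      " fleets:", nrow(x$fleets), "\n")
  cat("  initial vaquita:", x$n0, " seed:", x$seed, "\n")
  cat("  vaquita M:", signif(x$calibration$m, 4),
      " phi_max:", signif(x$calibration$phi_max, 4),
      " K achieved:", round(x$calibration$k_achieved), "\n")
  invisible(x)
}

#' @export
print.gulf_scenario <- function(x, ...) {
  cat("<gulf_scenario>", x$name, "\n")
  cat("  net closure:", x$net_closure, " light trawl:", x$light_trawl,
      " rho:", x$rho, "\n")
  cat("  N0:", x$n0, " horizon:", x$horizon_years, "y\n")
  invisible(x)
}

#' @export
print.gulf_run <- function(x, ...) {
  vaq <- x$vaquita
  hy <- x$scenario$horizon_years
  cat("<gulf_run>", x$scenario$name, "\n")
  cat("  mature vaquita: year 1", round(vaq$mature_abundance[vaq$year == 1], 1),
      "-> year", hy, round(vaq$mature_abundance[vaq$year == hy], 1), "\n")
  cat("  NPV (delta = ", x$npv$delta, "): ",
      format(round(x$npv$npv), big.mark = ","), " USD\n", sep = "")
  invisible(x)
}

#' @export
print.npv_result <- function(x, ...) {
  cat("<npv_result> total:", format(round(x$npv), big.mark = ","),
      "USD at delta =", x$delta, "\n")
  print(x$by_fleet)
  invisible(x)
}

#' Tidy a scenario run
#'
#' @param x A `gulf_run`.
#' @param ... Unused.
#' @return The annual trajectory tibble (year, group, abundance, biomass,
#'   mature_abundance, mean_abundance).
#' @export
tidy.gulf_run <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a scenario run
#'
#' @param x A `gulf_run`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, rho, n0, year-1 and year-30 mature
#'   vaquita abundance, percent change, mean realized bycatch hazard, and
#'   NPV.
#' @export
glance.gulf_run <- function(x, ...) {
  vaq <- x$vaquita
  hy <- x$scenario$horizon_years
  tibble::tibble(
    scenario = x$scenario$name,
    rho = x$scenario$rho,
    n0 = x$scenario$n0,
    mature_y1 = vaq$mature_abundance[vaq$year == 1],
    mature_y30 = vaq$mature_abundance[vaq$year == hy],
    pct_change_mature = percent_change(vaq, final_year = hy),
    realized_f_mean = mean(vaq$realized_f[-1]),
    npv = x$npv$npv)
}

#' Tidy an NPV result
#'
#' @param x An `npv_result`.
#' @param ... Unused.
#' @return Per-fleet NPV tibble.
#' @export
tidy.npv_result <- function(x, ...) x$by_fleet

#' Glance at an NPV result
#' @param x An `npv_result`.
#' @param ... Unused.
#' @return One-row tibble with `npv` and `delta`.
#' @export
glance.npv_result <- function(x, ...) {
  tibble::tibble(npv = x$npv, delta = x$delta)
}

#' Plot vaquita trajectories of a run
#'
#' @param object A `gulf_run`.
#' @param ... Unused.
#' @return A ggplot of mature vaquita abundance over time, with the
#'   250-individual downlisting reference line.
#' @export
autoplot.gulf_run <- function(object, ...) {
  ggplot2::ggplot(object$vaquita,
                  ggplot2::aes(x = .data$year, y = .data$mature_abundance)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 250, linetype = "dashed") +
    ggplot2::labs(x = "Year", y = "Mature vaquita abundance",
                  title = object$scenario$name) +
    ggplot2::theme_minimal()
}

#' Plot an equilibrium curve
#'
#' @param object A `gulf_sweep`.
#' @param ... Unused.
#' @return A ggplot of equilibrium abundance against realized bycatch
#'   mortality.
#' @export
autoplot.gulf_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$realized_f,
                                       y = .data$equilibrium_abundance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Realized bycatch mortality (per year)",
                  y = "Abundance (last-5-year mean)") +
    ggplot2::theme_minimal()
}

#' Plot the NPV-abundance trade-off
#'
#' @param object A `gulf_suite`.
#' @param ... Unused.
#' @return A ggplot of NPV against year-30 mature abundance, one point per
#'   run, with the 250-individual reference line.
#' @export
autoplot.gulf_suite <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mature_y30, y = .data$npv,
                                       colour = .data$name)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 250, linetype = "dashed") +
    ggplot2::labs(x = "Mature vaquita abundance, year 30", y = "NPV (USD)",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}
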