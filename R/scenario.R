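#' Management scenario names
#' @return Character vector of the five scenario names in increasing order of
#'   net-closure area.
#' @export
scenario_names <- function() {
  c("no_management", "vaquita_refuge", "extended_refuge", "primary_area",
    "distribution_area")
}

#' Build a management scenario
#'
#' Bundles the spatial-closure and gear rules of one of the five management
#' scenarios. All four management scenarios close the 1264 km^2 refuge to
#' industrial shrimp trawls, apply the 30% trawl-effort reduction inside the
#' Biosphere Reserve (as does no-management), close nets (finfish gillnet and
#' shrimp driftnet) over the scenario's zone with effort reduced
#' proportionally to area closed (no displacement), and let the light shrimp
#' trawl operate inside the net closure with shrimp catch reduced by `rho`
#' relative to the displaced driftnet.
#'
#' @param name One of [scenario_names()].
#' @param rho Shrimp-catch reduction for the light trawl (ignored under
#'   no-management).
#' @param n0 Initial vaquita abundance (245 by default; 68 and 884 are the
#'   95% CI bounds).
#' @param horizon_years Projection length (default 30).
#' @param vaquita_f_total Total nominal vaquita bycatch hazard to allocate
#'   over the net fleets; defaults to 0.15 per year. Used by the equilibrium
#'   sweep to impose arbitrary constant hazards.
#' @return A list of class `gulf_scenario`.
#' @examples
#' build_scenario("vaquita_refuge", rho = 0.1)
#' @export
build_scenario <- function(name, rho = 0.1, n0 = 245, horizon_years = 30,
                           vaquita_f_total = NULL) {
  if (!name %in% scenario_names()) {
    abort(paste0("unknown scenario '", name, "'; valid names: ",
                 paste(scenario_names(), collapse = ", ")),
          class = "vaquitamse_config_error")
  }
  if (rho < 0 || rho > 1) {
    abort("rho must lie in [0, 1]", class = "vaquitamse_domain_error")
  }
  stopifnot(n0 > 0, horizon_years >= 1)
  net_zone <- switch(name,
    no_management = "none",
    vaquita_refuge = "refuge",
    extended_refuge = "extended",
    primary_area = "primary",
    distribution_area = "distribution")
  structure(list(
    name = name,
    net_closure = net_zone,
    trawl_closure = if (name == "no_management") "none" else "refuge",
    trawl_reserve_multiplier = 0.7,
    light_trawl = name != "no_management",
    rho = if (name == "no_management") NA_real_ else rho,
    n0 = n0,
    horizon_years = horizon_years,
    vaquita_f_total = vaquita_f_total
  ), class = "gulf_scenario")
}

#' Full factorial scenario grid
#'
#' The four management scenarios crossed with the shrimp-catch reductions and
#' initial abundances, plus no-management at each initial abundance: the
#' default grid has `4 * 5 * 3 + 3 = 63` scenarios, in deterministic order.
#'
#' @param rho_grid Shrimp-catch reductions (default 0.1--0.5).
#' @param n0_set Initial vaquita abundances (default 68, 245, 884).
#' @param horizon_years Projection length.
#' @return A tibble with columns `name`, `rho`, `n0` and a `scenario`
#'   list-column.
#' @export
scenario_suite <- function(rho_grid = seq(0.1, 0.5, by = 0.1),
                           n0_set = c(68, 245, 884), horizon_years = 30) {
  mgmt <- tidyr::expand_grid(
    name = setdiff(scenario_names(), "no_management"),
    rho = rho_grid, n0 = n0_set)
  base <- tibble::tibble(name = "no_management", rho = NA_real_, n0 = n0_set)
  grid <- dplyr::bind_rows(base, mgmt)
  grid$scenario <- purrr::pmap(grid, function(name, rho, n0) {
    build_scenario(name, rho = if (is.na(rho)) 0.1 else rho, n0 = n0,
                   horizon_years = horizon_years)
  })
  grid
}

#' Fraction of a fleet's grounds left open by a closure
#'
#' Exposure-weighted fraction of the fleet's allowed polygons that remain
#' open: 1 with no closure, 0 when every allowed polygon is closed. Exposure
#' weights (for example a stock's spatial distribution, or polygon areas for
#' uniform effort) are normalized over the allowed set.
#'
#' @param allowed Integer vector of the fleet's allowed polygon ids
#'   (non-empty).
#' @param closure Integer vector of closed polygon ids.
#' @param exposure Non-negative exposure weights indexed by polygon id over
#'   the whole domain.
#' @return Open fraction in `[0, 1]`.
#' @examples
#' open_fraction(1:4, closure = 1:2, exposure = rep(1, 4))
#' @export
open_fraction <- function(allowed, closure, exposure) {
  if (length(allowed) == 0) {
    abort("fleet has no allowed polygons", class = "vaquitamse_config_error")
  }
  w <- exposure[allowed]
  if (any(w < 0) || sum(w) <= 0) {
    abort("exposure weights must be non-negative with positive sum",
          class = "vaquitamse_domain_error")
  }
  w <- w / sum(w)
  sum(w[!allowed %in% closure])
}

#' Realized fishing mortality arrays for a scenario
#'
#' Applies a scenario's closures and effort rules to the model's fleets and
#' returns per-fleet instantaneous fishing mortality matrices (group x
#' polygon), including the allocated vaquita hazard for the net gears and
#' the derived light-trawl fleet where enabled. Effort in closed polygons is
#' removed, not displaced.
#'
#' @param model A `gulf_model` from [generate_gulf()].
#' @param scenario A `gulf_scenario` from [build_scenario()].
#' @return A list of class `gulf_effort`: `fleets` (metadata tibble), `f`
#'   (named list of group x polygon rate matrices), and `f_total` (their
#'   sum).
#' @export
apply_scenario <- function(model, scenario) {
  domain <- model$domain
  fw <- model$foodweb
  fleets <- model$fleets
  ids <- fw$groups$id
  np <- nrow(domain)

  net_closed <- zone_polygons(domain, scenario$net_closure)
  trawl_closed <- zone_polygons(domain, scenario$trawl_closure)
  reserve <- zone_polygons(domain, "reserve")

  vaq_f <- if (is.null(scenario$vaquita_f_total)) {
    fleets$vaquita_f
  } else {
    allocate_vaquita_bycatch(scenario$vaquita_f_total, fleets)
  }

  if (scenario$light_trawl) {
    lt <- light_trawl_fleet(fleets[fleets$id == "shrimp_driftnet", ],
                            rho = scenario$rho, closure = net_closed,
                            foodweb = fw, domain = domain,
                            constants = model$constants)
    fleets <- dplyr::bind_rows(fleets, lt)
    vaq_f <- c(vaq_f, 0)
  }

  f_list <- vector("list", nrow(fleets))
  names(f_list) <- fleets$id
  for (i in seq_len(nrow(fleets))) {
    fmat <- matrix(0, length(ids), np, dimnames = list(ids, NULL))
    open <- fleets$allowed[[i]]
    gear <- fleets$gear[i]
    if (gear %in% c("finfish_gillnet", "shrimp_driftnet")) {
      open <- setdiff(open, net_closed)
    }
    if (gear == "industrial_trawl") {
      open <- setdiff(open, trawl_closed)
    }
    fb <- fleets$f_base[[i]]
    if (length(open) > 0) {
      fmat[names(fb), open] <- rep(fb, times = length(open))
      if (vaq_f[i] > 0) fmat["vaquita", open] <- vaq_f[i]
      if (gear == "industrial_trawl") {
        in_res <- intersect(open, reserve)
        fmat[, in_res] <- fmat[, in_res] * scenario$trawl_reserve_multiplier
      }
    }
    f_list[[i]] <- fmat
  }
  f_total <- Reduce(`+`, f_list)
  structure(list(
    fleets = fleets[, c("id", "gear", "sector", "cost_rate", "permits")] |>
      dplyr::mutate(retained = fleets$retained, vaquita_f = vaq_f),
    f = f_list,
    f_total = f_total
  ), class = "gulf_effort")
}

#' Population-level realized fishing mortality
#'
#' The stock-distribution-weighted mean of a fleet's per-polygon rate on a
#' group under a scenario: base effort scaled by closures and effort
#' multipliers. Non-increasing in closed area for every fleet and group.
#'
#' @param model A `gulf_model`.
#' @param scenario A `gulf_scenario`.
#' @param fleet Fleet id (e.g. `"finfish_gillnet"`).
#' @param group Group id (e.g. `"vaquita"`).
#' @return Realized rate (per year).
#' @export
realized_fishing_mortality <- function(model, scenario, fleet, group) {
  effort <- apply_scenario(model, scenario)
  if (!fleet %in% names(effort$f)) {
    abort(paste("unknown fleet:", fleet), class = "vaquitamse_config_error")
  }
  w <- model$foodweb$habitat[group, ]
  sum(w * effort$f[[fleet]][group, ])
}
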