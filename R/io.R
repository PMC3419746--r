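# matrix <-> plain-list codec for the YAML config
mat_to_list <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), rownames = rownames(m),
       values = as.vector(m))
}
list_to_mat <- function(x) {
  m <- matrix(x$values, x$nrow, x$ncol)
  if (!is.null(x$rownames)) rownames(m) <- unlist(x$rownames)
  m
}

#' Write a generated model to a structured text config
#'
#' Serializes the full model bundle (domain, groups, diet, habitat,
#' availabilities, pool capacities, initial state, fleets, calibration,
#' economics, seed) to a nested YAML file. The file is byte-identical across
#' calls for the same generated model, and [read_gulf_config()] reconstructs
#' the model from it.
#'
#' @param model A `gulf_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gulf_config <- function(model, path) {
  domain <- model$domain
  cfg <- list(
    package = "vaquitamse",
    seed = model$seed,
    n0 = model$n0,
    options = model$options,
    constants = lapply(model$constants, function(x) {
      if (!is.null(names(x))) as.list(x) else x
    }),
    domain = list(
      polygon = domain$polygon, area = domain$area, zone = domain$zone,
      in_refuge = domain$in_refuge, in_extended = domain$in_extended,
      in_primary = domain$in_primary,
      in_distribution = domain$in_distribution,
      in_reserve = domain$in_reserve,
      neighbors = domain$neighbors,
      vaquita_weight = domain$vaquita_weight),
    groups = as.list(model$foodweb$groups),
    diet = mat_to_list(model$foodweb$diet),
    habitat = mat_to_list(model$foodweb$habitat),
    availability = mat_to_list(model$availability),
    handling = model$handling,
    pool_k = mat_to_list(model$pool_k),
    iref = model$iref,
    init = list(
      n = lapply(model$init$n, mat_to_list),
      w = lapply(model$init$w, mat_to_list),
      b = mat_to_list(model$init$b)),
    fleets = list(
      id = model$fleets$id, gear = model$fleets$gear,
      sector = model$fleets$sector, permits = model$fleets$permits,
      cost_rate = model$fleets$cost_rate,
      vaquita_f = model$fleets$vaquita_f,
      allowed = model$fleets$allowed,
      f_base = lapply(model$fleets$f_base, as.list),
      retained = model$fleets$retained),
    calibration = c(
      model$calibration[setdiff(names(model$calibration), "report")],
      list(report = as.list(model$calibration$report))),
    economics = list(prices = as.list(model$economics$prices),
                     discount_rate = model$economics$discount_rate)
  )
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

#' Read a model back from its config
#'
#' @param path Path written by [write_gulf_config()].
#' @return A `gulf_model`.
#' @export
read_gulf_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$package, "vaquitamse")) {
    abort("not a vaquitamse config file", class = "vaquitamse_config_error")
  }
  listify <- function(x) lapply(x, function(e) unlist(e, use.names = TRUE))
  domain <- tibble::tibble(
    polygon = unlist(cfg$domain$polygon),
    area = unlist(cfg$domain$area),
    zone = unlist(cfg$domain$zone),
    in_refuge = unlist(cfg$domain$in_refuge),
    in_extended = unlist(cfg$domain$in_extended),
    in_primary = unlist(cfg$domain$in_primary),
    in_distribution = unlist(cfg$domain$in_distribution),
    in_reserve = unlist(cfg$domain$in_reserve),
    neighbors = lapply(cfg$domain$neighbors, unlist),
    vaquita_weight = unlist(cfg$domain$vaquita_weight))
  class(domain) <- c("gulf_domain", class(domain))
  groups <- tibble::as_tibble(lapply(cfg$groups, function(col) {
    if (all(vapply(col, is.null, logical(1)))) rep(NA_real_, length(col))
    else unlist(lapply(col, function(x) if (is.null(x)) NA else x))
  }))
  fw <- structure(list(groups = groups,
                       diet = list_to_mat(cfg$diet),
                       habitat = list_to_mat(cfg$habitat)),
                  class = "gulf_foodweb")
  colnames(fw$diet) <- rownames(fw$diet)
  fleets <- tibble::tibble(
    id = unlist(cfg$fleets$id), gear = unlist(cfg$fleets$gear),
    sector = unlist(cfg$fleets$sector),
    permits = unlist(cfg$fleets$permits),
    allowed = lapply(cfg$fleets$allowed, unlist),
    f_base = listify(cfg$fleets$f_base),
    cost_rate = unlist(cfg$fleets$cost_rate),
    retained = lapply(cfg$fleets$retained, unlist),
    vaquita_f = unlist(cfg$fleets$vaquita_f))
  class(fleets) <- c("gulf_fleets", class(fleets))
  cal <- cfg$calibration
  cal$report <- tibble::as_tibble(lapply(cal$report, unlist))
  structure(list(
    domain = domain,
    foodweb = fw,
    fleets = fleets,
    availability = `dimnames<-`(list_to_mat(cfg$availability),
                                list(groups$id, groups$id)),
    handling = unlist(cfg$handling),
    pool_k = list_to_mat(cfg$pool_k),
    init = list(n = lapply(cfg$init$n, list_to_mat),
                w = lapply(cfg$init$w, list_to_mat),
                b = `rownames<-`(list_to_mat(cfg$init$b), groups$id)),
    calibration = cal,
    economics = list(prices = unlist(cfg$economics$prices),
                     discount_rate = cfg$economics$discount_rate),
    iref = unlist(cfg$iref),
    constants = lapply(cfg$constants, function(x) {
      if (is.list(x)) unlist(x) else x
    }),
    options = cfg$options,
    n0 = cfg$n0,
    seed = cfg$seed
  ), class = "gulf_model")
}

#' Write the standard outputs of a run
#'
#' Writes the annual trajectory, catch records, fleet economics and realized
#' diets as CSV plus a JSON manifest linking the outputs to the
#' configuration and seed.
#'
#' @param run A `gulf_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$trajectory, file.path(dir, "trajectory.csv"))
  readr::write_csv(run$vaquita, file.path(dir, "vaquita.csv"))
  readr::write_csv(run$catch, file.path(dir, "catch.csv"))
  readr::write_csv(run$economics, file.path(dir, "economics.csv"))
  if (nrow(run$diet) > 0) {
    readr::write_csv(run$diet, file.path(dir, "diet.csv"))
  }
  manifest <- c(run$manifest,
                list(npv = run$npv$npv,
                     outputs = c("trajectory.csv", "vaquita.csv", "catch.csv",
                                 "economics.csv", "diet.csv")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a model and write its config and calibration report
#'
#' @param dir Output directory.
#' @param seed,n0,overrides Passed to [generate_gulf()].
#' @return The `gulf_model`, invisibly.
#' @export
mse_generate <- function(dir, seed = 1, n0 = 245, overrides = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- generate_gulf(seed = seed, n0 = n0, overrides = overrides)
  write_gulf_config(model, file.path(dir, "config.yaml"))
  readr::write_csv(model$calibration$report,
                   file.path(dir, "calibration_report.csv"))
  invisible(model)
}

#' Simulate one scenario and write its outputs
#'
#' @param model A `gulf_model` or a path to a config written by
#'   [mse_generate()].
#' @param dir Output directory.
#' @param name,rho,n0,horizon_years Scenario parameters
#'   (see [build_scenario()]).
#' @param dt Step length in years.
#' @return The `gulf_run`, invisibly.
#' @export
mse_simulate <- function(model, dir, name = "no_management", rho = 0.1,
                         n0 = 245, horizon_years = 30, dt = 1 / 365) {
  if (is.character(model)) model <- read_gulf_config(model)
  run <- simulate_scenario(model,
                           build_scenario(name, rho = rho, n0 = n0,
                                          horizon_years = horizon_years),
                           dt = dt)
  write_run_outputs(run, dir)
  invisible(run)
}

#' Run the equilibrium sweep and write the curve
#'
#' @param model A `gulf_model` or config path.
#' @param dir Output directory.
#' @param f_grid,n0,horizon_years,dt Passed to [f_sweep()].
#' @return The `gulf_sweep`, invisibly.
#' @export
mse_sweep <- function(model, dir, f_grid = seq(0, 0.2, by = 0.01), n0 = 245,
                      horizon_years = 30, dt = 1 / 365) {
  if (is.character(model)) model <- read_gulf_config(model)
  if (length(f_grid) == 0) {
    abort("empty hazard grid", class = "vaquitamse_config_error")
  }
  sweep <- f_sweep(model, f_grid = f_grid, n0 = n0,
                   horizon_years = horizon_years, dt = dt)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sweep, file.path(dir, "equilibrium_curve.csv"))
  jsonlite::write_json(
    list(max_sustainable_f = max_sustainable_f(sweep),
         f_grid = f_grid, n0 = n0, seed = model$seed),
    file.path(dir, "sweep_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(sweep)
}

#' Run a scenario suite and write the trade-off outputs
#'
#' Writes the per-run summary, the trade-off table (NPV versus year-30
#' mature abundance) and an NPV matrix with one row per management scenario
#' and one column per shrimp-catch reduction (initial abundance 245).
#'
#' @param model A `gulf_model` or config path.
#' @param dir Output directory.
#' @param suite Scenario grid (default [scenario_suite()]).
#' @param dt Step length in years.
#' @return The `gulf_suite`, invisibly.
#' @export
mse_suite <- function(model, dir, suite = scenario_suite(), dt = 1 / 365) {
  if (is.character(model)) model <- read_gulf_config(model)
  res <- run_suite(model, suite, dt = dt)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::select(res, -"run"),
                   file.path(dir, "suite_summary.csv"))
  readr::write_csv(tradeoff_table(res), file.path(dir, "tradeoff.csv"))
  mat <- res |>
    dplyr::filter(.data$n0 == 245) |>
    dplyr::select("name", "rho", "npv") |>
    tidyr::pivot_wider(names_from = "rho", values_from = "npv",
                       names_prefix = "rho_")
  readr::write_csv(mat, file.path(dir, "npv_matrix.csv"))
  invisible(res)
}
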