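#' Build the reduced Upper Gulf food web
#'
#' Defines the ~14 functional groups of the synthetic ecosystem: vaquita,
#' its only predator (large pelagic sharks), the named prey groups that
#' dominate its diet (small pelagic fish, mojarra, scorpionfish, flatfish,
#' drums and croakers, squid, crabs and lobsters, totoaba), the two
#' commercial invertebrate targets (penaeid shrimp, blue crab), herbivorous
#' fish, and a plankton/benthos base pool. Vertebrates are age-structured
#' (abundance and weight-at-age); invertebrates are biomass pools. The diet
#' matrix rows are initial diet proportions (each row sums to 1); the
#' vaquita row is dominated by small pelagic fish.
#'
#' Biomasses, rates and diet fractions other than the vaquita demography are
#' synthetic: sized to be order-of-magnitude plausible for the Northern Gulf
#' and to remain stable over a 30-year projection, with no claim of matching
#' the real stocks.
#'
#' @param domain A `gulf_domain` from [make_domain()].
#' @param constants Constants from [vaquita_constants()].
#' @return A list of class `gulf_foodweb` with elements `groups` (tibble: one
#'   row per functional group), `diet` (predator x prey proportion matrix)
#'   and `habitat` (group x polygon weight matrix, rows sum to 1).
#' @examples
#' fw <- make_foodweb(make_domain())
#' rowSums(fw$diet[rowSums(fw$diet) > 0, , drop = FALSE])
#' @export
make_foodweb <- function(domain, constants = vaquita_constants()) {
  groups <- tibble::tribble(
    ~id,              ~kind,           ~n_classes, ~years_per_class, ~maturity_age, ~recruit, ~fecundity, ~m,   ~w_juv, ~w_adult, ~cons_rate, ~assim, ~move, ~pool_r, ~b0,
    "vaquita",        "age_structured", 10L,        2L,               10,            "fixed",  0.26,       NA,   22.3,   22.3,     40,         0.2,    TRUE,  NA,      NA,
    "shark",          "age_structured", 2L,         10L,              10,            "fixed",  NA,         0.15, 20,     60,       3,          0.2,    TRUE,  NA,      10000,
    "totoaba",        "age_structured", 2L,         8L,               8,             "bh",     NA,         0.25, 5,      25,       4,          0.2,    FALSE, NA,      8000,
    "small_pelagic",  "age_structured", 2L,         1L,               1,             "bh",     NA,         0.60, 0.015,  0.03,     5,          0.2,    TRUE,  NA,      300000,
    "mojarra",        "age_structured", 2L,         2L,               2,             "bh",     NA,         0.45, 0.10,   0.25,     4,          0.2,    FALSE, NA,      30000,
    "drums_croakers", "age_structured", 2L,         3L,               3,             "bh",     NA,         0.35, 0.30,   0.90,     4,          0.2,    FALSE, NA,      40000,
    "scorpionfish",   "age_structured", 2L,         3L,               3,             "bh",     NA,         0.40, 0.20,   0.60,     4,          0.2,    FALSE, NA,      15000,
    "flatfish",       "age_structured", 2L,         2L,               2,             "bh",     NA,         0.45, 0.15,   0.40,     4,          0.2,    FALSE, NA,      20000,
    "herbivorous_fish", "age_structured", 2L,       2L,               2,             "bh",     NA,         0.50, 0.10,   0.30,     4,          0.2,    FALSE, NA,      80000,
    "squid",          "biomass_pool",   NA,         NA,               NA,            "pool",   NA,         0,    NA,     NA,       8,          0.2,    FALSE, 2.5,     50000,
    "crabs_lobsters", "biomass_pool",   NA,         NA,               NA,            "pool",   NA,         0,    NA,     NA,       5,          0.2,    FALSE, 1.5,     50000,
    "penaeid_shrimp", "biomass_pool",   NA,         NA,               NA,            "pool",   NA,         0,    NA,     NA,       6,          0.2,    FALSE, 2.2,     80000,
    "blue_crab",      "biomass_pool",   NA,         NA,               NA,            "pool",   NA,         0,    NA,     NA,       5,          0.2,    FALSE, 1.6,     30000,
    "plankton_benthos", "biomass_pool", NA,         NA,               NA,            "pool",   NA,         0,    NA,     NA,       0,          0.2,    FALSE, 10,      2500000
  )
  groups$fecundity[groups$id == "vaquita"] <- constants$fecundity
  groups$max_weight <- ifelse(groups$kind == "age_structured",
                              1.5 * groups$w_adult, NA)
  # handling time puts baseline intake at half the saturation ceiling
  groups$handling <- ifelse(groups$cons_rate > 0, 1 / (2 * groups$cons_rate), 0)

  ids <- groups$id
  diet <- matrix(0, nrow(groups), nrow(groups), dimnames = list(ids, ids))
  set_diet <- function(pred, ...) {
    x <- c(...)
    diet[pred, names(x)] <<- x
  }
  set_diet("vaquita", small_pelagic = 0.45, mojarra = 0.12,
           drums_croakers = 0.08, scorpionfish = 0.08, flatfish = 0.07,
           squid = 0.09, crabs_lobsters = 0.05, penaeid_shrimp = 0.03,
           totoaba = 0.01, herbivorous_fish = 0.02)
  set_diet("shark", small_pelagic = 0.30, mojarra = 0.08,
           drums_croakers = 0.14, herbivorous_fish = 0.15, totoaba = 0.08,
           squid = 0.10, flatfish = 0.05, scorpionfish = 0.05,
           crabs_lobsters = 0.048, vaquita = 0.002)
  set_diet("totoaba", small_pelagic = 0.40, penaeid_shrimp = 0.10,
           crabs_lobsters = 0.10, squid = 0.10, mojarra = 0.08,
           herbivorous_fish = 0.10, plankton_benthos = 0.12)
  set_diet("small_pelagic", plankton_benthos = 1)
  set_diet("mojarra", plankton_benthos = 0.81, penaeid_shrimp = 0.05,
           crabs_lobsters = 0.10, blue_crab = 0.04)
  set_diet("drums_croakers", small_pelagic = 0.20, penaeid_shrimp = 0.08,
           squid = 0.07, crabs_lobsters = 0.05, blue_crab = 0.03,
           plankton_benthos = 0.57)
  set_diet("scorpionfish", small_pelagic = 0.25, penaeid_shrimp = 0.10,
           crabs_lobsters = 0.10, plankton_benthos = 0.55)
  set_diet("flatfish", penaeid_shrimp = 0.12, blue_crab = 0.06,
           crabs_lobsters = 0.07, plankton_benthos = 0.75)
  set_diet("herbivorous_fish", plankton_benthos = 1)
  set_diet("squid", small_pelagic = 0.25, penaeid_shrimp = 0.05,
           plankton_benthos = 0.70)
  set_diet("crabs_lobsters", plankton_benthos = 1)
  set_diet("penaeid_shrimp", plankton_benthos = 1)
  set_diet("blue_crab", plankton_benthos = 1)

  fed <- rowSums(diet) > 0
  if (any(abs(rowSums(diet[fed, , drop = FALSE]) - 1) > 1e-9)) {
    abort("diet rows must sum to 1", class = "vaquitamse_config_error")
  }

  # spatial distributions: uniform density except shrimp/blue crab
  # (concentrated in the upper gulf) and vaquita (calibrated exposure)
  np <- nrow(domain)
  habitat <- matrix(0, nrow(groups), np, dimnames = list(ids, NULL))
  area_w <- domain$area / sum(domain$area)
  for (g in ids) habitat[g, ] <- area_w
  inshore <- domain$area * ifelse(domain$in_distribution, 3, 1)
  habitat["penaeid_shrimp", ] <- inshore / sum(inshore)
  habitat["blue_crab", ] <- inshore / sum(inshore)
  habitat["vaquita", ] <- domain$vaquita_weight

  structure(list(groups = groups, diet = diet, habitat = habitat),
            class = "gulf_foodweb")
}

#' Build the fishing fleets
#'
#' One fleet per gear class operating in the Upper Gulf: finfish gillnet and
#' shrimp driftnet (the two vaquita-bycatch gears, artisanal, with permit
#' counts used to allocate the total vaquita hazard), industrial shrimp
#' trawl (retains only shrimp and blue crab; everything else discarded),
#' purse seine, longline, handline, trap and diving. The light shrimp trawl
#' is not a base fleet: it is created by the scenario machinery via
#' [light_trawl_fleet()]. `f_base` values are nominal full-effort fishing
#' mortalities applied inside each fleet's allowed polygons; they are sized
#' so that no stock collapses over a 30-year no-management run.
#'
#' @param domain A `gulf_domain`.
#' @param foodweb A `gulf_foodweb`.
#' @param total_vaquita_f Total vaquita bycatch hazard (per year) to allocate
#'   across the net fleets by permit count.
#' @param constants Constants from [vaquita_constants()].
#' @return A tibble of class `gulf_fleets`, one row per fleet, with
#'   list-columns `allowed` (polygon ids), `f_base` (named per-group rates,
#'   targets and non-vaquita bycatch), `retained` (group ids with market
#'   value), and column `vaquita_f` (allocated hazard, net gears only).
#' @export
make_fleets <- function(domain, foodweb, total_vaquita_f = NULL,
                        constants = vaquita_constants()) {
  total_vaquita_f <- total_vaquita_f %||% constants$f_nominal_no_mgmt
  upper <- domain$polygon[domain$in_distribution]
  everywhere <- domain$polygon
  offshore <- domain$polygon[domain$polygon >= 4]

  fleets <- tibble::tribble(
    ~id,               ~gear,              ~sector,      ~permits, ~allowed,
    "finfish_gillnet", "finfish_gillnet",  "artisanal",  600,      upper,
    "shrimp_driftnet", "shrimp_driftnet",  "artisanal",  400,      upper,
    "industrial_trawl", "industrial_trawl", "industrial", 0,       everywhere,
    "purse_seine",     "purse_seine",      "industrial", 0,        offshore,
    "longline",        "longline",         "artisanal",  120,      offshore,
    "handline",        "handline",         "artisanal",  150,      upper,
    "trap",            "trap",             "artisanal",  90,       upper,
    "diving",          "diving",           "artisanal",  60,       upper
  )

  f_base <- list(
    finfish_gillnet = c(mojarra = 0.30, drums_croakers = 0.25,
                        scorpionfish = 0.15, flatfish = 0.20,
                        herbivorous_fish = 0.10),
    shrimp_driftnet = c(penaeid_shrimp = 0.15),  # bycatch appended below
    industrial_trawl = c(penaeid_shrimp = 0.45, blue_crab = 0.30,
                         mojarra = 0.05, flatfish = 0.10,
                         scorpionfish = 0.05, drums_croakers = 0.05),
    purse_seine = c(small_pelagic = 0.30),
    longline = c(shark = 0.10, drums_croakers = 0.08),
    handline = c(drums_croakers = 0.10, mojarra = 0.08, scorpionfish = 0.05),
    trap = c(blue_crab = 0.20, crabs_lobsters = 0.15),
    diving = c(crabs_lobsters = 0.10, herbivorous_fish = 0.05)
  )

  # driftnet fish bycatch: uniform rate over the bycatch complex such that
  # the baseline shrimp:bycatch catch ratio inside its grounds is 1.23
  bycatch_groups <- c("mojarra", "drums_croakers", "flatfish", "scorpionfish")
  b_in <- group_biomass_in(foodweb, domain, upper)
  f_by <- f_base$shrimp_driftnet[["penaeid_shrimp"]] *
    b_in[["penaeid_shrimp"]] /
    (constants$shrimp_bycatch_ratio_driftnet * sum(b_in[bycatch_groups]))
  f_base$shrimp_driftnet <- c(f_base$shrimp_driftnet,
                              setNames(rep(f_by, length(bycatch_groups)),
                                       bycatch_groups))

  fleets$f_base <- f_base[fleets$id]
  fleets$cost_rate <- ifelse(fleets$sector == "industrial",
                             constants$cost_rate_industrial,
                             constants$cost_rate_artisanal)
  fleets$retained <- purrr::map2(fleets$id, fleets$f_base, function(id, fb) {
    if (id == "industrial_trawl") c("penaeid_shrimp", "blue_crab")
    else names(fb)
  })
  fleets$vaquita_f <- allocate_vaquita_bycatch(total_vaquita_f, fleets)
  class(fleets) <- c("gulf_fleets", class(fleets))
  fleets
}

# baseline biomass of each group inside a polygon set (tonnes)
group_biomass_in <- function(foodweb, domain, polygons) {
  share <- rowSums(foodweb$habitat[, polygons, drop = FALSE])
  b0 <- foodweb$groups$b0
  b0[is.na(b0)] <- 0
  setNames(b0 * share, foodweb$groups$id)
}

#' Allocate total vaquita bycatch mortality across net fleets by permits
#'
#' Only the finfish gillnet and shrimp driftnet gears entangle vaquita; the
#' total hazard is split between them in proportion to fishing permits, so
#' allocations always sum to the total.
#'
#' @param total_f Total vaquita bycatch hazard (per year), >= 0.
#' @param fleets A `gulf_fleets` tibble (needs `gear` and `permits`).
#' @return Numeric vector of per-fleet hazards aligned with `fleets` rows
#'   (zero for all gears other than the two net gears).
#' @examples
#' \dontrun{
#' allocate_vaquita_bycatch(0.15, fleets)
#' }
#' @export
allocate_vaquita_bycatch <- function(total_f, fleets) {
  if (total_f < 0) {
    abort("total vaquita mortality must be non-negative",
          class = "vaquitamse_domain_error")
  }
  net <- fleets$gear %in% c("finfish_gillnet", "shrimp_driftnet")
  permits <- ifelse(net, fleets$permits, 0)
  if (sum(permits) <= 0) {
    abort("no net-fleet permits to allocate vaquita bycatch over",
          class = "vaquitamse_config_error")
  }
  total_f * permits / sum(permits)
}

#' Derive the light-trawl fleet from the displaced shrimp driftnet
#'
#' The light trawl replaces the shrimp driftnet inside a closure zone. Its
#' shrimp fishing mortality is `(1 - rho)` times the displaced driftnet rate
#' (so its expected shrimp catch is the driftnet's inside-closure baseline
#' reduced by `rho`), its fish bycatch rate is set so the shrimp:bycatch
#' catch ratio is 1.37 at baseline biomasses (versus 1.23 for the driftnet),
#' and its vaquita mortality is zero.
#'
#' @param driftnet One-row `gulf_fleets` slice for the shrimp driftnet.
#' @param rho Shrimp-catch reduction relative to the driftnet, in `[0, 1]`.
#' @param closure Polygon ids of the net-closure zone where it operates.
#' @param foodweb,domain Used to size the bycatch rate from baseline
#'   biomasses inside the closure.
#' @param constants Constants from [vaquita_constants()].
#' @return A one-row fleet tibble with id `"shrimp_light_trawl"`.
#' @export
light_trawl_fleet <- function(driftnet, rho, closure, foodweb, domain,
                              constants = vaquita_constants()) {
  if (rho < 0 || rho > 1) {
    abort("rho must lie in [0, 1]", class = "vaquitamse_domain_error")
  }
  f_dn <- driftnet$f_base[[1]]
  bycatch_groups <- setdiff(names(f_dn), "penaeid_shrimp")
  f_shrimp <- (1 - rho) * f_dn[["penaeid_shrimp"]]
  b_in <- group_biomass_in(foodweb, domain, closure)
  f_by <- if (sum(b_in[bycatch_groups]) > 0) {
    f_shrimp * b_in[["penaeid_shrimp"]] /
      (constants$shrimp_bycatch_ratio_light_trawl * sum(b_in[bycatch_groups]))
  } else 0
  out <- driftnet
  out$id <- "shrimp_light_trawl"
  out$gear <- "shrimp_light_trawl"
  out$allowed <- list(intersect(driftnet$allowed[[1]], closure))
  out$f_base <- list(c(penaeid_shrimp = f_shrimp,
                       setNames(rep(f_by, length(bycatch_groups)),
                                bycatch_groups)))
  out$retained <- list(names(out$f_base[[1]]))
  out$vaquita_f <- 0
  out$permits <- 0
  out
}
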