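#' Calibration constants for the vaquita system
#'
#' Returns the demographic and management constants that anchor the synthetic
#' Upper Gulf ecosystem: vaquita life history (10 age classes of two years,
#' longevity 20 y, maturity at 10 y, 0.26 viable offspring per female per
#' year, mean body weight 22.3 kg), the 2008 abundance estimate (245, 95% CI
#' 68--884), the nominal no-management bycatch hazard (0.15 per year), the
#' unfished carrying capacity target (773 individuals), and two derived
#' quantities: the low-density population growth rate and the fraction of
#' vaquita spatial exposure that lies inside each nested management zone.
#'
#' The low-density growth rate is back-calculated from the no-management
#' 29-year decline of -96%: `r = F + log(0.04)/29` with `F = 0.15`. The
#' refuge exposure share is back-calculated the same way from the refuge
#' scenario decline of -80%, and the primary-area share from the 0.03 per
#' year bycatch hazard realized when nets are excluded from the 5339 km^2
#' primary area (`0.15 * (1 - share) = 0.03`). The extended-refuge share is
#' interpolated linearly in area between those two anchors.
#'
#' @return A named list of constants; see Details.
#' @examples
#' const <- vaquita_constants()
#' const$r_lowdensity
#' @export
vaquita_constants <- function() {
  f_nominal <- 0.15
  horizon <- 30
  decline_nomgmt <- 0.04   # year-30 / year-1 abundance ratio, no management
  decline_refuge <- 0.20   # same ratio, refuge scenario
  r_low <- f_nominal + log(decline_nomgmt) / (horizon - 1)
  refuge_share <- 1 - (r_low - log(decline_refuge) / (horizon - 1)) / f_nominal
  primary_share <- 1 - 0.03 / f_nominal
  zone_areas <- c(refuge = 1264, extended = 3579, primary = 5339,
                  distribution = 8432)
  extended_share <- refuge_share +
    (primary_share - refuge_share) *
      (zone_areas[["extended"]] - zone_areas[["refuge"]]) /
      (zone_areas[["primary"]] - zone_areas[["refuge"]])
  list(
    n_classes = 10L,
    years_per_class = 2L,
    longevity = 20,
    maturity_age = 10,
    fecundity = 0.26,
    mean_weight_kg = 22.3,
    n0_default = 245,
    n0_ci = c(lower = 68, upper = 884),
    f_nominal_no_mgmt = f_nominal,
    k_unfished = 773,
    horizon_years = horizon,
    r_lowdensity = r_low,
    total_area = 57800,
    zone_areas = zone_areas,
    exposure_shares = c(refuge = refuge_share, extended = extended_share,
                        primary = primary_share, distribution = 1),
    trawl_reserve_multiplier = 0.7,
    shrimp_bycatch_ratio_light_trawl = 1.37,
    shrimp_bycatch_ratio_driftnet = 1.23,
    discount_rate = 0.036,
    cost_rate_artisanal = 0.32,
    cost_rate_industrial = 0.96
  )
}

#' Build the reduced spatial domain
#'
#' Constructs a 12-polygon concentric reduction of the Upper Gulf geometry.
#' The four nested management zones (vaquita refuge, extended refuge, primary
#' area, full distribution area) have exact areas 1264, 3579, 5339 and
#' 8432 km^2 inside a 57,800 km^2 total domain; three outer polygons make up
#' the remainder. The Biosphere Reserve (where industrial trawl effort is
#' reduced by 30% in every scenario) is taken to coincide with the primary
#' area. Vaquita habitat weights place the calibrated exposure share inside
#' each zone and zero weight outside the distribution area.
#'
#' @param n_polygons Number of polygons; the default 12 is the smallest count
#'   that resolves every zone ring. Values other than 12 are not supported.
#' @param constants Constants list from [vaquita_constants()].
#' @return A tibble of class `gulf_domain`, one row per polygon, with columns
#'   `polygon`, `area` (km^2), `zone` (innermost ring the polygon belongs
#'   to), logical zone memberships `in_refuge`, `in_extended`, `in_primary`,
#'   `in_distribution`, `in_reserve`, a `neighbors` list-column, and
#'   `vaquita_weight` (habitat weights summing to 1).
#' @examples
#' dom <- make_domain()
#' sum(dom$area)
#' sum(dom$vaquita_weight[dom$in_refuge])
#' @export
make_domain <- function(n_polygons = 12, constants = vaquita_constants()) {
  if (n_polygons != 12) {
    abort("only the 12-polygon reduced geometry is supported",
          class = "vaquitamse_config_error")
  }
  za <- constants$zone_areas
  ring_area <- c(za[["refuge"]],
                 za[["extended"]] - za[["refuge"]],
                 za[["primary"]] - za[["extended"]],
                 za[["distribution"]] - za[["primary"]],
                 constants$total_area - za[["distribution"]])
  # polygon areas by ring: refuge split in 3, the middle rings in 2, outer in 3
  areas <- c(ring_area[1] / 3, ring_area[1] / 3, ring_area[1] / 3,
             ring_area[2] / 2, ring_area[2] / 2,
             ring_area[3] / 2, ring_area[3] / 2,
             ring_area[4] / 2, ring_area[4] / 2,
             ring_area[5] / 3, ring_area[5] / 3, ring_area[5] / 3)
  ring <- c(1, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5)
  zone <- c("refuge", "extended", "primary", "distribution", "outer")[ring]

  shares <- constants$exposure_shares
  ring_share <- c(shares[["refuge"]],
                  shares[["extended"]] - shares[["refuge"]],
                  shares[["primary"]] - shares[["extended"]],
                  shares[["distribution"]] - shares[["primary"]],
                  0)
  w <- ring_share[ring] * areas / vapply(ring, function(r) {
    sum(areas[ring == r])
  }, numeric(1))
  w <- w / sum(w)

  neighbors <- lapply(seq_len(12), function(i) {
    same <- setdiff(which(ring == ring[i]), i)
    adj <- which(abs(ring - ring[i]) == 1)
    sort(c(same, adj))
  })

  out <- tibble::tibble(
    polygon = seq_len(12),
    area = areas,
    zone = zone,
    in_refuge = ring <= 1,
    in_extended = ring <= 2,
    in_primary = ring <= 3,
    in_distribution = ring <= 4,
    in_reserve = ring <= 3,
    neighbors = neighbors,
    vaquita_weight = w
  )
  class(out) <- c("gulf_domain", class(out))
  validate_domain(out, constants)
  out
}

#' Validate a spatial domain
#'
#' Checks the structural invariants of a [make_domain()] result: positive
#' areas summing to the configured total, zone nesting
#' (refuge within extended within primary within distribution), zone areas at
#' their configured targets within 1 km^2, and habitat weights that are
#' non-negative, sum to 1, and vanish outside the distribution area.
#'
#' @param domain A `gulf_domain` tibble.
#' @param constants Constants list from [vaquita_constants()].
#' @return `domain`, invisibly; errors on violation.
#' @export
validate_domain <- function(domain, constants = vaquita_constants()) {
  stopifnot(all(domain$area > 0))
  if (abs(sum(domain$area) - constants$total_area) > 1e-6) {
    abort("polygon areas do not sum to the domain total",
          class = "vaquitamse_config_error")
  }
  nests <- list(c("in_refuge", "in_extended"), c("in_extended", "in_primary"),
                c("in_primary", "in_distribution"))
  for (nz in nests) {
    if (any(domain[[nz[1]]] & !domain[[nz[2]]])) {
      abort(paste0("zone nesting violated: ", nz[1], " not within ", nz[2]),
            class = "vaquitamse_config_error")
    }
  }
  za <- constants$zone_areas
  got <- c(refuge = sum(domain$area[domain$in_refuge]),
           extended = sum(domain$area[domain$in_extended]),
           primary = sum(domain$area[domain$in_primary]),
           distribution = sum(domain$area[domain$in_distribution]))
  if (any(abs(got - za) > 1)) {
    abort("zone areas deviate from configured targets by more than 1 km^2",
          class = "vaquitamse_config_error")
  }
  w <- domain$vaquita_weight
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-9,
            all(w[!domain$in_distribution] == 0))
  invisible(domain)
}

#' Polygons belonging to a named zone
#'
#' @param domain A `gulf_domain` tibble.
#' @param zone One of `"refuge"`, `"extended"`, `"primary"`,
#'   `"distribution"`, `"reserve"`, or `"none"` (empty set).
#' @return Integer vector of polygon ids.
#' @export
zone_polygons <- function(domain, zone) {
  zone <- match.arg(zone, c("refuge", "extended", "primary", "distribution",
                            "reserve", "none"))
  if (zone == "none") return(integer(0))
  domain$polygon[domain[[paste0("in_", zone)]]]
}
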