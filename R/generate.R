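#' Generate the calibrated synthetic Upper Gulf model
#'
#' Builds the full desk-scale model bundle: the 12-polygon domain, the
#' reduced food web, the fishing fleets, availability coefficients scaled so
#' realized initial diets match the diet matrix and baseline intake sits at
#' half the Holling ceiling, logistic pool capacities and Beverton-Holt
#' recruitment parameters solved for baseline stationarity under
#' no-management fishing, the calibrated vaquita demography
#' ([calibrate_vaquita()]), and the economic parameters. Everything is
#' deterministic for a fixed seed; the seed drives a mild lognormal jitter
#' (sd 3%) on the non-vaquita initial biomasses.
#'
#' @param seed Integer seed.
#' @param n0 Initial vaquita abundance (total individuals).
#' @param overrides Optional named list: `total_vaquita_f`,
#'   `dynamic_shark_predation` (default `FALSE`: shark predation on vaquita
#'   is carried as a constant component of natural mortality), `jitter_sd`,
#'   `prices` (named vector, USD per tonne).
#' @return A list of class `gulf_model`.
#' @examples
#' \donttest{
#' model <- generate_gulf(seed = 1)
#' model$calibration$report
#' }
#' @export
generate_gulf <- function(seed = 1, n0 = 245, overrides = list()) {
  set.seed(seed)
  constants <- vaquita_constants()
  domain <- make_domain(constants = constants)
  fw <- make_foodweb(domain, constants)
  groups <- fw$groups
  ids <- groups$id
  ng <- length(ids)
  np <- nrow(domain)
  vq <- which(ids == "vaquita")

  jitter_sd <- overrides$jitter_sd %||% 0.03
  jit <- exp(stats::rnorm(ng, 0, jitter_sd))
  groups$b0 <- ifelse(is.na(groups$b0), NA, groups$b0 * jit)
  fw$groups <- groups

  fleets <- make_fleets(domain, fw,
                        total_vaquita_f = overrides$total_vaquita_f,
                        constants = constants)

  # baseline biomass field (tonnes); vaquita biomass from abundance
  b0_tot <- groups$b0
  b0_tot[vq] <- n0 * constants$mean_weight_kg / 1000
  bmat0 <- fw$habitat * b0_tot

  # availabilities: realized initial diet equals the diet matrix and baseline
  # intake equals cons_rate (half the 1/h ceiling)
  avail <- matrix(0, ng, ng, dimnames = list(ids, ids))
  for (j in seq_len(ng)) {
    avail[j, ] <- fw$diet[j, ] * 2 * groups$cons_rate[j] / b0_tot
  }
  dynamic_shark <- isTRUE(overrides$dynamic_shark_predation)
  if (!dynamic_shark) avail["shark", "vaquita"] <- 0
  handling <- groups$handling

  gamma <- 6
  n_scale <- 450

  # baseline no-management effort for the stationarity closure
  prov <- structure(list(domain = domain, foodweb = fw, fleets = fleets,
                         constants = constants), class = "gulf_model")
  effort0 <- apply_scenario(prov, build_scenario("no_management", n0 = n0))

  rates0 <- predation_rates(bmat0, avail, handling, vq,
                            u = rep((n0 / n_scale)^gamma, np))
  mpred0 <- rates0$mpred
  z0 <- mpred0 + effort0$f_total

  # logistic capacity per polygon solved so pools are stationary at baseline
  pool_k <- matrix(0, ng, np, dimnames = list(ids, NULL))
  for (g in which(groups$kind == "biomass_pool")) {
    r_g <- groups$pool_r[g]
    for (p in seq_len(np)) {
      if (bmat0[g, p] <= 0) next
      if (z0[g, p] >= 0.75 * r_g) {
        abort(paste0("baseline mortality on pool '", ids[g], "' in polygon ",
                     p, " (", round(z0[g, p], 2), "/y) exceeds 75% of its ",
                     "intrinsic rate ", r_g, "/y; reduce fishing or predation"),
              class = "vaquitamse_calibration_error")
      }
      pool_k[g, p] <- bmat0[g, p] / (1 - z0[g, p] / r_g)
    }
  }

  # age-structured stationarity: population-mean total mortality, then the
  # juvenile/adult split and recruitment that hold the stock at b0
  groups$bh_alpha <- NA_real_
  groups$bh_beta <- NA_real_
  init_n <- list()
  init_w <- list()
  share <- fw$habitat
  for (g in which(groups$kind == "age_structured")) {
    id <- ids[g]
    if (id == "vaquita") next
    y <- groups$years_per_class[g]
    zbar <- sum(share[g, ] * (groups$m[g] + z0[g, ]))
    s <- exp(-zbar)
    stay <- (1 - 1 / y) * s
    ratio_aj <- (s / y) / (1 - stay)
    wj <- groups$w_juv[g]; wa <- groups$w_adult[g]
    # stationary mean adult weight: cohorts enter at wj and grow toward wa
    # at rate 4/ypc while being replaced at rate (1 - stay)
    g_w <- 4 / y
    rin <- 1 - stay
    weff <- (rin * wj + g_w * wa) / (rin + g_w)
    j0 <- 1000 * b0_tot[g] / (wj + weff * ratio_aj)
    a0 <- j0 * ratio_aj
    rstar <- j0 * (1 - stay)
    # recruitment is evaluated on the post-survival spawning stock at the
    # year boundary, so the stationarity anchor is s * A0
    if (groups$recruit[g] == "bh") {
      groups$bh_beta[g] <- s * a0 * weff / 1000
      groups$bh_alpha[g] <- 2 * rstar
    } else {
      groups$fecundity[g] <- rstar / (s * a0 / 2)
    }
    init_n[[id]] <- rbind(j0 * share[g, ], a0 * share[g, ])
    init_w[[id]] <- matrix(c(wj, weff), 2, np)
  }

  # vaquita: interference-adjusted Holling intake at the baseline prey field
  intake_fn <- function(n) {
    u <- (n / n_scale)^gamma
    sa <- as.vector(avail[vq, ] %*% bmat0) / (1 + u)
    i_p <- sa / (1 + handling[vq] * sa)
    sum(fw$habitat[vq, ] * i_p)
  }
  calibration <- calibrate_vaquita(constants, intake_fn, gamma = gamma,
                                   n_scale = n_scale)
  groups$m[vq] <- calibration$m
  if (dynamic_shark) {
    # shark predation becomes dynamic; remove its baseline rate from M so the
    # calibrated total is unchanged at the initial state
    shark_rate <- sum(fw$habitat[vq, ] * mpred0[vq, ])
    groups$m[vq] <- max(0, calibration$m - shark_rate)
  }
  A0 <- leslie_matrix(calibration$m, calibration$phi_hi,
                      fecundity = constants$fecundity,
                      n_classes = constants$n_classes,
                      years_per_class = constants$years_per_class,
                      maturity_age = constants$maturity_age)
  ev <- Re(eigen(A0)$vectors[, 1])
  stable_age <- abs(ev) / sum(abs(ev))
  init_n[["vaquita"]] <- outer(stable_age * n0, fw$habitat[vq, ])
  init_w[["vaquita"]] <- matrix(constants$mean_weight_kg,
                                constants$n_classes, np)

  init_b <- bmat0
  init_b[groups$kind != "biomass_pool", ] <- 0

  # reference per-biomass intake for the weight-condition response
  iref <- vapply(seq_len(ng), function(g) {
    bt <- sum(bmat0[g, ])
    if (bt <= 0 || groups$cons_rate[g] <= 0) return(0)
    sum(bmat0[g, ] * rates0$intake[g, ]) / bt
  }, numeric(1))

  prices <- overrides$prices %||% c(
    penaeid_shrimp = 9000, blue_crab = 2500, crabs_lobsters = 6000,
    mojarra = 1200, drums_croakers = 1800, scorpionfish = 2000,
    flatfish = 2500, herbivorous_fish = 900, small_pelagic = 300,
    squid = 1100, shark = 1500, totoaba = 0, vaquita = 0,
    plankton_benthos = 0)

  fw$groups <- groups
  model <- structure(list(
    domain = domain,
    foodweb = fw,
    fleets = fleets,
    availability = avail,
    handling = handling,
    pool_k = pool_k,
    init = list(n = init_n, w = init_w, b = init_b),
    calibration = calibration,
    economics = list(prices = prices,
                     discount_rate = constants$discount_rate),
    iref = iref,
    constants = constants,
    options = list(dynamic_shark_predation = dynamic_shark,
                   weight_kappa = 0.3),
    n0 = n0,
    seed = seed
  ), class = "gulf_model")

  # re-anchor the condition multiplier on realized annual-mean intake: one
  # pilot year at each calibration abundance with zero vaquita hazard; the
  # annual mean sits below the instantaneous rate because prey biomass
  # cycles within the year around its recruitment pulse
  pilot_intake <- function(n_anchor) {
    sc <- build_scenario("no_management", n0 = n_anchor,
                         vaquita_f_total = 0, horizon_years = 1)
    eng <- engine_context(model, apply_scenario(model, sc))
    st <- initial_state(model)
    st$n[["vaquita"]] <- st$n[["vaquita"]] * (n_anchor / model$n0)
    pn <- 0; pd <- 0
    for (s in seq_len(365)) {
      res <- ecosystem_step_core(st, eng, 1 / 365)
      st <- res$state
      pn <- pn + res$p_num
      pd <- pd + res$p_den
    }
    pn / pd
  }
  p1r <- pilot_intake(constants$n0_default)
  p2r <- pilot_intake(constants$k_unfished)
  model$calibration <- calibrate_vaquita(constants, intake_fn,
                                         gamma = gamma, n_scale = n_scale,
                                         anchors = c(p1r, p2r))
  model
}

# instantaneous predation rates at a biomass field: per-prey mortality and
# per-predator intake, with vaquita interference u per polygon
predation_rates <- function(bmat, avail, handling, vq, u) {
  sa <- avail %*% bmat
  sa[vq, ] <- sa[vq, ] / (1 + u)
  denom <- 1 + handling * sa
  bd <- bmat / denom
  bd[vq, ] <- bd[vq, ] / (1 + u)
  list(mpred = crossprod(avail, bd), intake = sa / denom, denom = denom,
       bd = bd)
}
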