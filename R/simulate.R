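#' Initial ecosystem state
#'
#' The generated model's initial condition as a state object: abundance and
#' weight-at-age matrices (class x polygon) for age-structured groups and a
#' biomass matrix for pools, at time 0.
#'
#' @param model A `gulf_model`.
#' @return A list of class `gulf_state` with elements `n`, `w`, `b`, `time`.
#' @export
initial_state <- function(model) {
  structure(list(n = model$init$n, w = model$init$w, b = model$init$b,
                 time = 0), class = "gulf_state")
}

#' Tidy snapshot of an ecosystem state
#'
#' One row per group, polygon and (for age-structured groups) age class:
#' abundance `n`, weight-at-age `w` (kg) and, for pools, biomass `b`
#' (tonnes). Suitable for writing with `readr::write_csv()`.
#'
#' @param state A `gulf_state`.
#' @param model The `gulf_model` it belongs to.
#' @return A tibble with columns `time`, `group`, `polygon`, `class`, `n`,
#'   `w`, `b`.
#' @export
state_snapshot <- function(state, model) {
  groups <- model$foodweb$groups
  np <- nrow(model$domain)
  rows <- purrr::map(seq_len(nrow(groups)), function(g) {
    id <- groups$id[g]
    if (groups$kind[g] == "age_structured") {
      nc <- groups$n_classes[g]
      tibble::tibble(
        time = state$time, group = id,
        polygon = rep(seq_len(np), each = nc),
        class = rep(seq_len(nc), times = np),
        n = as.vector(state$n[[id]]),
        w = as.vector(state$w[[id]]),
        b = NA_real_)
    } else {
      tibble::tibble(time = state$time, group = id, polygon = seq_len(np),
                     class = NA_integer_, n = NA_real_, w = NA_real_,
                     b = state$b[g, ])
    }
  })
  dplyr::bind_rows(rows)
}

# precomputed context shared by the stepper and the annual update
engine_context <- function(model, effort) {
  groups <- model$foodweb$groups
  ids <- groups$id
  ng <- length(ids)
  vq <- which(ids == "vaquita")
  m_vec <- ifelse(is.na(groups$m), 0, groups$m)
  m_vec[groups$kind == "biomass_pool"] <- 0
  cal <- model$calibration
  list(
    ids = ids, ng = ng, np = nrow(model$domain), vq = vq,
    age_idx = which(groups$kind == "age_structured"),
    pool_idx = which(groups$kind == "biomass_pool"),
    avail = model$availability, handling = model$handling,
    m_vec = m_vec,
    pool_r = ifelse(is.na(groups$pool_r), 0, groups$pool_r),
    pool_k = model$pool_k,
    hab = model$foodweb$habitat,
    area = model$domain$area,
    groups = groups,
    n_classes = ifelse(is.na(groups$n_classes), 0L, groups$n_classes),
    ypc = groups$years_per_class,
    mature = lapply(seq_len(ng), function(g) {
      if (groups$kind[g] != "age_structured") return(integer(0))
      mature_classes(groups$n_classes[g], groups$years_per_class[g],
                     groups$maturity_age[g])
    }),
    w_ref = lapply(seq_len(ng), function(g) {
      if (groups$kind[g] != "age_structured") return(numeric(0))
      if (ids[g] == "vaquita") {
        rep(model$constants$mean_weight_kg, groups$n_classes[g])
      } else {
        seq(groups$w_juv[g], groups$w_adult[g],
            length.out = groups$n_classes[g])
      }
    }),
    max_w = groups$max_weight,
    # growth rate toward the reference schedule; vaquita weight is fixed
    # (determinate growth), its condition acts through phi instead
    g_w = ifelse(groups$kind == "age_structured" & ids != "vaquita",
                 4 / ifelse(is.na(groups$years_per_class), 1,
                            groups$years_per_class), 0),
    iref = model$iref %||% rep(0, ng),
    move_idx = which(groups$move %in% TRUE),
    gamma = cal$gamma, n_scale = cal$n_scale,
    phi_max = cal$phi_max, p_half = cal$p_half,
    fecundity = ifelse(is.na(groups$fecundity), 0, groups$fecundity),
    recruit = groups$recruit,
    bh_alpha = groups$bh_alpha, bh_beta = groups$bh_beta,
    fleet_ids = effort$fleets$id,
    f_list = effort$f, f_total = effort$f_total,
    retained = effort$fleets$retained
  )
}

# biomass field (tonnes, group x polygon) of a state
state_biomass <- function(state, eng) {
  bmat <- state$b
  for (g in eng$age_idx) {
    bmat[g, ] <- colSums(state$n[[eng$ids[g]]] * state$w[[eng$ids[g]]]) / 1000
  }
  bmat
}

# vaquita foraging-interference term: range-wide density relative to the
# interference scale (the calibration anchors phi to total abundance)
interference_u <- function(state, eng) {
  nv <- sum(state$n[["vaquita"]])
  rep((nv / eng$n_scale)^eng$gamma, eng$np)
}

# one sub-annual step: predation -> pool production -> weight growth ->
# combined natural/predation/fishing mortality (Baranov partitioning).
# Returns the new state plus per-step accounting used by the caller.
ecosystem_step_core <- function(state, eng, dt, diagnostics = FALSE) {
  bmat <- state_biomass(state, eng)
  if (any(!is.finite(bmat)) || any(bmat < -1e-9)) {
    abort("non-finite or negative biomass encountered; diagnostic dump attached",
          class = "vaquitamse_state_error",
          body = c(i = paste("time =", state$time)))
  }
  u <- interference_u(state, eng)
  rates <- predation_rates(bmat, eng$avail, eng$handling, eng$vq, u)
  mpred <- rates$mpred
  irate <- rates$intake

  cons <- (eng$avail * (rates$bd %*% t(bmat))) * dt
  p_num <- sum(irate[eng$vq, ] * bmat[eng$vq, ]) * dt
  p_den <- sum(bmat[eng$vq, ]) * dt

  # pool production (logistic toward the stationarity-solved capacity)
  for (g in eng$pool_idx) {
    k <- eng$pool_k[g, ]
    pos <- k > 0 & state$b[g, ] > 0
    if (any(pos)) {
      b <- state$b[g, pos]
      state$b[g, pos] <- b + eng$pool_r[g] * b * (1 - b / k[pos]) * dt
    }
  }

  # weight-at-age: relaxation toward the condition-scaled reference
  # schedule (assimilation-driven growth), capped at max_weight
  for (g in eng$age_idx) {
    if (eng$g_w[g] <= 0 || eng$iref[g] <= 0) next
    id <- eng$ids[g]
    nc <- eng$n_classes[g]
    cond <- pmin(pmax(irate[g, ] / eng$iref[g], 0.5), 1.5)
    target <- outer(eng$w_ref[[g]], cond)
    w <- state$w[[id]] + eng$g_w[g] * (target - state$w[[id]]) * dt
    state$w[[id]] <- pmin(pmax(w, 0.25 * eng$w_ref[[g]]), eng$max_w[g])
  }

  z <- eng$m_vec + mpred + eng$f_total
  surv <- exp(-z * dt)
  dfrac <- 1 - surv
  deaths_bio <- bmat * dfrac
  zi <- ifelse(z > 0, 1 / z, 0)

  nf <- length(eng$f_list)
  catch_bio <- vector("list", nf)
  catch_ind <- numeric(nf)
  nv_tot <- colSums(state$n[["vaquita"]])
  dead_nv <- nv_tot * dfrac[eng$vq, ]
  for (f in seq_len(nf)) {
    sel <- eng$f_list[[f]] * zi
    catch_bio[[f]] <- sel * deaths_bio
    catch_ind[f] <- sum(sel[eng$vq, ] * dead_nv)
  }

  for (g in eng$age_idx) {
    id <- eng$ids[g]
    nc <- eng$n_classes[g]
    state$n[[id]] <- state$n[[id]] * rep(surv[g, ], each = nc)
  }
  for (g in eng$pool_idx) state$b[g, ] <- state$b[g, ] * surv[g, ]
  state$time <- state$time + dt

  out <- list(state = state, catch_bio = catch_bio, catch_ind = catch_ind,
              cons = cons, p_num = p_num, p_den = p_den, bmat = bmat)
  if (diagnostics) {
    fish_frac <- eng$f_total * zi
    pred_frac <- mpred * zi
    nat_frac <- eng$m_vec * zi
    out$diagnostics <- list(
      deaths_bio = deaths_bio,
      fishery_bio = fish_frac * deaths_bio,
      predation_bio = pred_frac * deaths_bio,
      natural_bio = nat_frac * deaths_bio
    )
  }
  out
}

# annual update: recruitment (from post-survival, pre-aging mature stock) ->
# aging -> newborns into class 1 -> density-dependent movement
ecosystem_annual_core <- function(state, eng, phi_vaquita) {
  bmat <- state_biomass(state, eng)
  recruits <- numeric(eng$ng)
  rec_dist <- vector("list", eng$ng)
  for (g in eng$age_idx) {
    id <- eng$ids[g]
    n <- state$n[[id]]
    mat_cls <- eng$mature[[g]]
    # recruits settle by habitat suitability (larval dispersal), not by the
    # adult distribution: keeps spatial structure stable under uneven F
    rec_dist[[g]] <- eng$hab[g, ]
    if (eng$recruit[g] == "bh") {
      s_t <- sum(n[mat_cls, , drop = FALSE] *
                   state$w[[id]][mat_cls, , drop = FALSE]) / 1000
      recruits[g] <- beverton_holt(s_t, eng$bh_alpha[g], eng$bh_beta[g])
    } else if (eng$recruit[g] == "fixed") {
      phi <- if (g == eng$vq) phi_vaquita else 1
      mat_n <- sum(n[mat_cls, , drop = FALSE])
      recruits[g] <- fixed_recruits(mat_n, eng$fecundity[g], phi = phi,
                                    dt = 1)
    }
  }
  for (g in eng$age_idx) {
    id <- eng$ids[g]
    aged <- promote_with_weights(state$n[[id]], state$w[[id]], eng$ypc[g])
    n <- aged$n
    w <- aged$w
    radd <- recruits[g] * rec_dist[[g]]
    tot1 <- n[1, ] + radd
    w1 <- ifelse(tot1 > 0,
                 (n[1, ] * w[1, ] + radd * eng$w_ref[[g]][1]) / tot1,
                 eng$w_ref[[g]][1])
    n[1, ] <- tot1
    w[1, ] <- w1
    state$n[[id]] <- n
    state$w[[id]] <- w
  }
  bmat <- state_biomass(state, eng)
  for (g in eng$move_idx) {
    id <- eng$ids[g]
    dens <- as.vector(eng$avail[g, ] %*% bmat) / eng$area
    wts <- redistribute_weights(eng$hab[g, ], dens)
    n <- state$n[[id]]
    tot_cls <- rowSums(n)
    state$n[[id]] <- outer(tot_cls, wts)
    w_cls <- ifelse(tot_cls > 0, rowSums(n * state$w[[id]]) / tot_cls,
                    eng$w_ref[[g]])
    state$w[[id]] <- matrix(w_cls, nrow(n), eng$np)
  }
  state
}

# promotion with abundance-weighted blending of weights-at-age
promote_with_weights <- function(n, w, ypc) {
  mov <- n / ypc
  stay <- n - mov
  k <- nrow(n)
  new_n <- stay
  new_w <- w
  if (k > 1) {
    for (cls in 2:k) {
      tot <- stay[cls, ] + mov[cls - 1, ]
      new_w[cls, ] <- ifelse(tot > 0,
                             (stay[cls, ] * w[cls, ] +
                                mov[cls - 1, ] * w[cls - 1, ]) / tot,
                             w[cls, ])
      new_n[cls, ] <- tot
    }
  }
  list(n = new_n, w = new_w)
}

#' Advance the ecosystem by one time step
#'
#' Applies, in fixed order: Holling predation intake, pool production,
#' condition-driven weight-at-age growth, then combined natural + predation
#' + fishing mortality with Baranov competing-risks partitioning. If the
#' step crosses a year boundary, annual recruitment, aging and
#' density-dependent movement are applied at the boundary. `dt` must divide
#' one year evenly.
#'
#' @param state A `gulf_state`.
#' @param model A `gulf_model`.
#' @param effort A `gulf_effort` from [apply_scenario()].
#' @param dt Step length in years (default 12 hours).
#' @param diagnostics Attach the per-step mortality decomposition
#'   (survivors, natural, predation and fishery removals in biomass)?
#' @return The new `gulf_state`; with `diagnostics = TRUE`, attributes
#'   `diagnostics`, `catch_bio` and `catch_ind` are attached.
#' @export
step_ecosystem <- function(state, model, effort, dt = 0.5 / 365,
                           diagnostics = FALSE) {
  spy <- round(1 / dt)
  if (abs(spy - 1 / dt) > 1e-8) {
    abort("dt must divide one year evenly", class = "vaquitamse_config_error")
  }
  eng <- engine_context(model, effort)
  res <- ecosystem_step_core(state, eng, dt, diagnostics = diagnostics)
  state <- res$state
  at_boundary <- abs(state$time - round(state$time)) < dt * 1e-6
  if (at_boundary) {
    phi <- if (res$p_den > 0) {
      p <- res$p_num / res$p_den
      eng$phi_max * p / (p + eng$p_half)
    } else 1
    state <- ecosystem_annual_core(state, eng, phi)
  }
  if (diagnostics) {
    attr(state, "diagnostics") <- res$diagnostics
    attr(state, "catch_bio") <- res$catch_bio
    attr(state, "catch_ind") <- res$catch_ind
  }
  state
}

#' Run one management scenario
#'
#' Projects the generated ecosystem under a scenario's closures and effort
#' rules, on a sub-daily clock with annual recruitment, aging and movement,
#' and returns annual trajectories, catch records, realized diet
#' compositions, and fleet economics (gross/net benefit and NPV).
#'
#' @param model A `gulf_model`.
#' @param scenario A `gulf_scenario`. Its `n0` overrides the model's initial
#'   vaquita abundance by rescaling the initial age distribution.
#' @param dt Step length in years; the default is the 12-hour step
#'   (`0.5/365`). Analyses at scale use `1/365`.
#' @param record_polygons Keep per-polygon catch records (otherwise catches
#'   are aggregated over polygons)?
#' @return A list of class `gulf_run`: `trajectory` (tibble: year, group,
#'   abundance, biomass, mature_abundance, mean_abundance), `vaquita`
#'   (tibble with annual catch, realized hazard, condition multiplier),
#'   `catch` (tibble: year, fleet, group, polygon, quantity_t, individuals,
#'   retained), `diet` (tibble: year, predator, prey, proportion),
#'   `economics` (tibble: fleet, year, gb, nb), `npv` (an `npv_result`),
#'   `scenario`, and `manifest`.
#' @examples
#' \donttest{
#' model <- generate_gulf(seed = 1)
#' run <- simulate_scenario(model, build_scenario("no_management"),
#'                          dt = 1 / 365)
#' glance(run)
#' }
#' @export
simulate_scenario <- function(model, scenario, dt = 0.5 / 365,
                              record_polygons = TRUE) {
  spy <- round(1 / dt)
  if (abs(spy - 1 / dt) > 1e-8) {
    abort("dt must divide one year evenly", class = "vaquitamse_config_error")
  }
  effort <- apply_scenario(model, scenario)
  eng <- engine_context(model, effort)
  state <- initial_state(model)
  if (!is.null(scenario$n0) && scenario$n0 != model$n0) {
    state$n[["vaquita"]] <- state$n[["vaquita"]] * (scenario$n0 / model$n0)
  }

  horizon <- scenario$horizon_years
  nf <- length(eng$f_list)
  years <- vector("list", horizon + 1)
  vaq_rows <- vector("list", horizon + 1)
  catch_rows <- vector("list", horizon)
  diet_rows <- vector("list", horizon)

  snapshot <- function(state, year, nint, vaq_extra) {
    bmat <- state_biomass(state, eng)
    ab <- vapply(seq_len(eng$ng), function(g) {
      if (eng$groups$kind[g] == "age_structured") {
        sum(state$n[[eng$ids[g]]])
      } else NA_real_
    }, numeric(1))
    mat <- vapply(seq_len(eng$ng), function(g) {
      if (eng$groups$kind[g] != "age_structured") return(NA_real_)
      sum(state$n[[eng$ids[g]]][eng$mature[[g]], , drop = FALSE])
    }, numeric(1))
    tibble::tibble(year = year, group = eng$ids, abundance = ab,
                   biomass = rowSums(bmat), mature_abundance = mat,
                   mean_abundance = nint)
  }
  years[[1]] <- snapshot(state, 0, rep(NA_real_, eng$ng), NULL)
  vaq_rows[[1]] <- tibble::tibble(
    year = 0, abundance = sum(state$n[["vaquita"]]),
    mature_abundance = sum(state$n[["vaquita"]][eng$mature[[eng$vq]], ]),
    mean_abundance = NA_real_, catch_individuals = NA_real_,
    realized_f = NA_real_, phi = NA_real_, intake = NA_real_)

  for (year in seq_len(horizon)) {
    cons_acc <- matrix(0, eng$ng, eng$ng, dimnames = list(eng$ids, eng$ids))
    catch_acc <- lapply(seq_len(nf), function(f)
      matrix(0, eng$ng, eng$np, dimnames = list(eng$ids, NULL)))
    ind_acc <- numeric(nf)
    p_num <- 0; p_den <- 0
    nint <- numeric(eng$ng)
    for (s in seq_len(spy)) {
      res <- ecosystem_step_core(state, eng, dt)
      state <- res$state
      cons_acc <- cons_acc + res$cons
      for (f in seq_len(nf)) catch_acc[[f]] <- catch_acc[[f]] + res$catch_bio[[f]]
      ind_acc <- ind_acc + res$catch_ind
      p_num <- p_num + res$p_num
      p_den <- p_den + res$p_den
      nint <- nint + vapply(seq_len(eng$ng), function(g) {
        if (eng$groups$kind[g] == "age_structured") {
          sum(state$n[[eng$ids[g]]])
        } else sum(state$b[g, ])
      }, numeric(1)) * dt
    }
    p_year <- if (p_den > 0) p_num / p_den else 0
    phi <- if (p_den > 0) eng$phi_max * p_year / (p_year + eng$p_half) else 1
    state <- ecosystem_annual_core(state, eng, phi)
    state$time <- year  # absorb float drift at the boundary

    years[[year + 1]] <- snapshot(state, year, nint, NULL)
    vaq_rows[[year + 1]] <- tibble::tibble(
      year = year, abundance = sum(state$n[["vaquita"]]),
      mature_abundance = sum(state$n[["vaquita"]][eng$mature[[eng$vq]], ]),
      mean_abundance = nint[eng$vq],
      catch_individuals = sum(ind_acc),
      realized_f = if (nint[eng$vq] > 0) sum(ind_acc) / nint[eng$vq] else 0,
      phi = phi, intake = p_year)

    catch_rows[[year]] <- catch_tibble(catch_acc, ind_acc, eng, year,
                                       record_polygons)
    fed <- rowSums(cons_acc) > 0
    if (any(fed)) {
      props <- cons_acc[fed, , drop = FALSE] /
        rowSums(cons_acc[fed, , drop = FALSE])
      diet_rows[[year]] <- tibble::tibble(
        year = year,
        predator = rep(rownames(props), times = ncol(props)),
        prey = rep(colnames(props), each = nrow(props)),
        proportion = as.vector(props)) |>
        dplyr::filter(.data$proportion > 0)
    }
  }

  trajectory <- dplyr::bind_rows(years)
  catch <- dplyr::bind_rows(catch_rows)
  run <- structure(list(
    trajectory = trajectory,
    vaquita = dplyr::bind_rows(vaq_rows),
    catch = catch,
    diet = dplyr::bind_rows(diet_rows),
    scenario = scenario,
    fleets = effort$fleets,
    manifest = list(seed = model$seed, n0 = scenario$n0, dt = dt,
                    scenario = scenario$name, rho = scenario$rho,
                    horizon_years = horizon,
                    package_version = as.character(
                      utils::packageVersion("vaquitamse")))
  ), class = "gulf_run")
  run$economics <- fleet_economics(run, model)
  run$npv <- npv(run$economics, model$economics$discount_rate)
  run
}

catch_tibble <- function(catch_acc, ind_acc, eng, year, record_polygons) {
  nf <- length(catch_acc)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    m <- catch_acc[[f]]
    if (!record_polygons) {
      q <- rowSums(m)
      keep <- q > 1e-12
      if (!any(keep)) next
      tb <- tibble::tibble(year = year, fleet = eng$fleet_ids[f],
                           group = eng$ids[keep], polygon = NA_integer_,
                           quantity_t = q[keep])
    } else {
      keep <- which(m > 1e-12, arr.ind = TRUE)
      if (nrow(keep) == 0) next
      tb <- tibble::tibble(year = year, fleet = eng$fleet_ids[f],
                           group = eng$ids[keep[, 1]],
                           polygon = as.integer(keep[, 2]),
                           quantity_t = m[keep])
    }
    tb$individuals <- ifelse(tb$group == "vaquita",
                             ind_acc[f] * tb$quantity_t /
                               sum(tb$quantity_t[tb$group == "vaquita"]),
                             NA_real_)
    tb$retained <- purrr::map2_lgl(tb$fleet, tb$group, function(fl, gr) {
      gr %in% eng$retained[[match(fl, eng$fleet_ids)]]
    })
    out[[f]] <- tb
  }
  dplyr::bind_rows(out)
}
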