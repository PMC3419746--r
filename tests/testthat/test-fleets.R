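test_that("open_fraction: identity, proportionality, vaquita refuge exposure", {
  expect_equal(open_fraction(1:4, integer(0), rep(1, 4)), 1)
  expect_equal(open_fraction(1:4, 1:2, rep(1, 4)), 0.5)
  # with the calibrated vaquita exposure weights, closing the refuge leaves
  # 63% of exposure open
  dom <- make_domain()
  of <- open_fraction(dom$polygon[dom$in_distribution],
                      zone_polygons(dom, "refuge"), dom$vaquita_weight)
  expect_equal(of, 1 - vaquita_constants()$exposure_shares[["refuge"]],
               tolerance = 1e-9)
  expect_equal(of, 0.63, tolerance = 1e-3)
  expect_error(open_fraction(integer(0), 1, numeric(0)),
               class = "vaquitamse_config_error")
})

test_that("realized fishing mortality follows closures and effort rules", {
  model <- default_model()
  # no-management gillnet rate on mojarra equals its base rate
  f_nm <- realized_fishing_mortality(model, build_scenario("no_management"),
                                     "finfish_gillnet", "mojarra")
  f_base <- model$fleets$f_base[[
    which(model$fleets$id == "finfish_gillnet")]][["mojarra"]]
  share_allowed <- sum(model$foodweb$habitat["mojarra",
    model$fleets$allowed[[which(model$fleets$id == "finfish_gillnet")]]])
  expect_equal(f_nm, f_base * share_allowed, tolerance = 1e-9)

  # industrial trawl effort is reduced 30% inside the Biosphere Reserve in
  # every scenario, including no-management
  eff <- apply_scenario(model, build_scenario("no_management"))
  res <- zone_polygons(model$domain, "reserve")
  outside <- setdiff(model$domain$polygon, res)
  f_tr <- eff$f[["industrial_trawl"]]["penaeid_shrimp", ]
  expect_equal(unique(f_tr[res]) / unique(f_tr[outside]), 0.7,
               tolerance = 1e-9)

  # full-range closure drives realized vaquita mortality to zero
  for (fl in c("finfish_gillnet", "shrimp_driftnet")) {
    expect_equal(realized_fishing_mortality(
      model, build_scenario("distribution_area"), fl, "vaquita"), 0)
  }

  # realized F is non-increasing in closure area for every fleet and group
  sc_list <- lapply(scenario_names(), build_scenario)
  for (fl in c("finfish_gillnet", "shrimp_driftnet", "industrial_trawl")) {
    for (gr in c("vaquita", "mojarra", "penaeid_shrimp")) {
      f_seq <- vapply(sc_list, function(s) {
        realized_fishing_mortality(model, s, fl, gr)
      }, numeric(1))
      expect_true(all(diff(f_seq) <= 1e-12))
    }
  }
})

test_that("vaquita bycatch allocation is proportional to permits and conservative", {
  fleets <- tibble::tibble(
    gear = c("finfish_gillnet", "shrimp_driftnet", "trap"),
    permits = c(600, 400, 90))
  alloc <- allocate_vaquita_bycatch(0.15, fleets)
  expect_equal(alloc, c(0.09, 0.06, 0))
  # single net fleet receives everything
  one <- tibble::tibble(gear = "finfish_gillnet", permits = 17)
  expect_equal(allocate_vaquita_bycatch(0.12, one), 0.12)
  # conservation for arbitrary permit vectors
  set.seed(5)
  for (rep in 1:20) {
    fl <- tibble::tibble(gear = c("finfish_gillnet", "shrimp_driftnet"),
                         permits = sample(1:2000, 2))
    expect_equal(sum(allocate_vaquita_bycatch(0.15, fl)), 0.15)
  }
  none <- tibble::tibble(gear = "trap", permits = 50)
  expect_error(allocate_vaquita_bycatch(0.1, none),
               class = "vaquitamse_config_error")
})

test_that("light trawl substitutes the driftnet with zero vaquita mortality", {
  model <- default_model()
  dn <- model$fleets[model$fleets$id == "shrimp_driftnet", ]
  closure <- zone_polygons(model$domain, "refuge")
  lt0 <- light_trawl_fleet(dn, rho = 0, closure, model$foodweb,
                           model$domain)
  expect_equal(lt0$f_base[[1]][["penaeid_shrimp"]],
               dn$f_base[[1]][["penaeid_shrimp"]])
  lt <- light_trawl_fleet(dn, rho = 0.1, closure, model$foodweb,
                          model$domain)
  expect_equal(lt$f_base[[1]][["penaeid_shrimp"]],
               0.9 * dn$f_base[[1]][["penaeid_shrimp"]])
  expect_equal(lt$vaquita_f, 0)
  # expected shrimp:bycatch catch ratio at baseline biomasses is 1.37
  b_in <- vaquitamse:::group_biomass_in(model$foodweb, model$domain, closure)
  fb <- lt$f_base[[1]]
  by_groups <- setdiff(names(fb), "penaeid_shrimp")
  ratio <- fb[["penaeid_shrimp"]] * b_in[["penaeid_shrimp"]] /
    sum(fb[by_groups] * b_in[by_groups])
  expect_equal(unname(ratio), 1.37, tolerance = 1e-9)
  expect_error(light_trawl_fleet(dn, rho = 1.2, closure, model$foodweb,
                                 model$domain),
               class = "vaquitamse_domain_error")

  # in a full run, the light trawl catches no vaquita
  run <- scenario_run("vaquita_refuge")
  lt_catch <- dplyr::filter(run$catch, .data$fleet == "shrimp_light_trawl",
                            .data$group == "vaquita")
  expect_equal(nrow(lt_catch), 0)
})

test_that("closing part of a fleet's grounds scales its catch proportionally", {
  model <- default_model()
  eff_open <- apply_scenario(model, build_scenario("no_management"))
  eff_closed <- apply_scenario(model, build_scenario("vaquita_refuge"))
  st <- initial_state(model)
  s1 <- step_ecosystem(st, model, eff_open, dt = 1 / 365,
                       diagnostics = TRUE)
  s2 <- step_ecosystem(st, model, eff_closed, dt = 1 / 365,
                       diagnostics = TRUE)
  gid <- which(model$foodweb$groups$id == "mojarra")
  fl <- which(names(eff_open$f) == "finfish_gillnet")
  c1 <- sum(attr(s1, "catch_bio")[[fl]][gid, ])
  c2 <- sum(attr(s2, "catch_bio")[[fl]][gid, ])
  of <- open_fraction(
    model$fleets$allowed[[which(model$fleets$id == "finfish_gillnet")]],
    zone_polygons(model$domain, "refuge"),
    model$foodweb$habitat[gid, ])
  expect_equal(c2 / c1, of, tolerance = 0.02)
})

test_that("industrial trawl retains only shrimp and blue crab", {
  model <- default_model()
  tr <- model$fleets$retained[[which(model$fleets$id == "industrial_trawl")]]
  expect_setequal(tr, c("penaeid_shrimp", "blue_crab"))
  run <- scenario_run("no_management")
  tr_catch <- dplyr::filter(run$catch, .data$fleet == "industrial_trawl")
  expect_true(all(!tr_catch$retained[
    !tr_catch$group %in% c("penaeid_shrimp", "blue_crab")]))
  expect_true(all(tr_catch$retained[
    tr_catch$group %in% c("penaeid_shrimp", "blue_crab")]))
})
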