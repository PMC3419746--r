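test_that("mature abundance sums classes at or above the maturity age", {
  model <- default_model()
  st <- initial_state(model)
  np <- nrow(model$domain)
  # all abundance in the first class -> none mature
  st$n[["vaquita"]] <- rbind(matrix(10, 1, np), matrix(0, 9, np))
  expect_equal(mature_abundance(st, model), 0)
  # all in the terminal class -> everything mature
  st$n[["vaquita"]] <- rbind(matrix(0, 9, np), matrix(2, 1, np))
  expect_equal(mature_abundance(st, model), 2 * np)
  # the generated initial state carries the stable-age mature fraction
  st0 <- initial_state(model)
  a <- oracle_leslie(model$calibration$m, model$calibration$phi_hi)
  v <- Re(eigen(a)$vectors[, 1]); v <- abs(v) / sum(abs(v))
  expect_equal(mature_abundance(st0, model), sum(v[6:10]) * 245,
               tolerance = 1e-6)
})

test_that("percent change arithmetic and error cases", {
  tr <- tibble::tibble(year = c(1, 30), mature_abundance = c(100, 4))
  expect_equal(percent_change(tr), -96)
  tr2 <- tibble::tibble(year = c(1, 30), mature_abundance = c(245, 735))
  expect_equal(percent_change(tr2), 200)
  flat <- tibble::tibble(year = c(1, 30), mature_abundance = c(5, 5))
  expect_equal(percent_change(flat), 0)
  zero <- tibble::tibble(year = c(1, 30), mature_abundance = c(0, 5))
  expect_error(percent_change(zero), class = "vaquitamse_domain_error")
})

test_that("realized mortality is the last-five-year catch/abundance ratio", {
  expect_equal(realized_mortality(rep(15, 6), rep(100, 6)), 0.15)
  expect_equal(realized_mortality(rep(0, 5), rep(50, 5)), 0)
  # scale invariance
  expect_equal(realized_mortality(rep(7, 8), rep(140, 8)),
               realized_mortality(rep(3.5, 8), rep(70, 8)))
  expect_error(realized_mortality(rep(1, 3), rep(1, 3)),
               class = "vaquitamse_domain_error")
  # a run driven by a constant hazard realizes that hazard within 2%
  run <- scenario_run("no_management")
  vaq <- run$vaquita
  r <- realized_mortality(vaq$catch_individuals[-1], vaq$mean_abundance[-1])
  expect_equal(r, 0.15, tolerance = 0.02)
})

test_that("realized diets are normalized and respond to prey availability", {
  run <- scenario_run("no_management")
  d <- diet_summary(run)
  sums <- d |>
    dplyr::group_by(.data$year, .data$predator) |>
    dplyr::summarise(s = sum(.data$proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # vaquita diet is dominated by small pelagic fish
  vd <- dplyr::filter(d, .data$predator == "vaquita", .data$year == 1)
  expect_equal(vd$prey[which.max(vd$proportion)], "small_pelagic")
  # Holling monotonicity: boosting one prey's biomass raises its share
  a <- c(p1 = 0.5, p2 = 0.5)
  base <- holling_intake(a, 0.1, c(p1 = 10, p2 = 10))
  more <- holling_intake(a, 0.1, c(p1 = 100, p2 = 10))
  expect_gt(more[["p1"]] / sum(more), base[["p1"]] / sum(base))
})

test_that("suite summaries and the trade-off table are consistent", {
  model <- default_model()
  suite <- cached("suite5", {
    run_suite(model, scenario_suite(rho_grid = 0.1, n0_set = 245))
  })
  expect_equal(nrow(suite), 5)
  tt <- tradeoff_table(suite)
  expect_equal(nrow(tt), 5)
  expect_true(all(is.na(tt$rho[tt$scenario == "no_management"])))
  expect_equal(tt$npv, suite$npv)
  # glance() agrees with the suite rows
  g <- glance(suite$run[[which(suite$name == "no_management")]])
  expect_equal(g$mature_y30,
               suite$mature_y30[suite$name == "no_management"])
})

test_that("tidy, glance and autoplot methods return the expected shapes", {
  run <- scenario_run("no_management")
  tr <- tidy(run)
  expect_true(all(c("year", "group", "abundance", "biomass",
                    "mature_abundance") %in% names(tr)))
  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(tidy(run$npv), "tbl_df")
  expect_equal(glance(run$npv)$npv, run$npv$npv)
})
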