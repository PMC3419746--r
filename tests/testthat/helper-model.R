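# shared fixtures: the default calibrated model and a handful of 30-year
# runs are expensive, so they are generated once per session and cached
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_model <- function() cached("model", generate_gulf(seed = 42))

# one run per management scenario at rho = 0.1, N0 = 245, daily steps
scenario_run <- function(name, rho = 0.1) {
  cached(paste0("run_", name, "_", rho), {
    simulate_scenario(default_model(),
                      build_scenario(name, rho = rho, n0 = 245),
                      dt = 1 / 365, record_polygons = FALSE)
  })
}

# Leslie annual projection assembled independently (explicit bookkeeping of
# survival, birth and promotion flows) as the oracle for the simulator
oracle_leslie <- function(m, phi, f = 0, fecundity = 0.26, n_classes = 10,
                          ypc = 2, maturity_age = 10) {
  s <- exp(-(m + f))
  a <- matrix(0, n_classes, n_classes)
  for (k in seq_len(n_classes)) {
    surv_k <- s                      # continuous survival through the year
    stay <- surv_k * (1 - 1 / ypc)   # fraction not promoted
    move <- surv_k * (1 / ypc)       # promoted (terminal class exits)
    a[k, k] <- a[k, k] + stay
    if (k < n_classes) a[k + 1, k] <- a[k + 1, k] + move
    if ((k - 1) * ypc >= maturity_age) {
      a[1, k] <- a[1, k] + surv_k * fecundity * phi / 2
    }
  }
  a
}

oracle_lambda <- function(a) max(Re(eigen(a, only.values = TRUE)$values))
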