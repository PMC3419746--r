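#' Calibrate the vaquita demographic submodel
#'
#' Solves the vaquita natural mortality and the parameters of the saturating
#' fecundity condition multiplier so that the projected population has the
#' documented dynamic regime:
#'
#' 1. natural mortality `M` is found by bisection so the annual Leslie
#'    projection at baseline condition (`phi = 1`) is exactly stationary
#'    (dominant eigenvalue 1) — baseline condition corresponds to the
#'    population at carrying capacity;
#' 2. the elevated condition `phi_hi` reached at low density is found by
#'    bisection so the eigenvalue equals `1 + r_lowdensity`;
#' 3. the condition multiplier `phi = phi_max * P / (P + p_half)` on
#'    per-capita prey intake `P` is solved in closed form through two
#'    anchors: `phi` equals `phi_hi` at the intake realized at the 2008
#'    abundance (245) and 1 at the intake realized at carrying capacity
#'    (773).
#'
#' Per-capita intake declines with vaquita density through a conspecific
#' foraging-interference term (`P ~ 1 / (1 + (N/n_scale)^gamma)` at fixed
#' prey field), which is what generates a finite carrying capacity at desk
#' scale; see the methods vignette. The default `intake_fn` is this
#' normalized interference curve; [generate_gulf()] supplies the actual
#' Holling intake of the generated prey field.
#'
#' @param constants Constants from [vaquita_constants()].
#' @param intake_fn Function mapping total vaquita abundance to per-capita
#'   (per-biomass) prey intake at the baseline prey field.
#' @param gamma,n_scale Interference exponent and scale (individuals) used by
#'   the default `intake_fn` and stored for the simulator.
#' @param anchors Optional numeric pair: realized annual-mean intakes at the
#'   2008 abundance and at carrying capacity (as measured by pilot runs of
#'   the full simulator), used in place of `intake_fn` evaluations for the
#'   two anchor points. This makes the calibration consistent with the
#'   simulator's annual-mean intake accounting, which sits below the
#'   instantaneous rate because of the within-year prey recruitment cycle.
#' @return A list with elements `m` (natural mortality), `phi_max`,
#'   `p_half`, `p_ref` (intake at the 2008 abundance), `gamma`, `n_scale`,
#'   `r_lowdensity`, `k_target`, `k_achieved` (semi-analytic equilibrium of
#'   the annual projection under the calibrated multiplier), and a `report`
#'   tibble of targets versus achieved values.
#' @examples
#' cal <- calibrate_vaquita()
#' cal$report
#' @export
calibrate_vaquita <- function(constants = vaquita_constants(),
                              intake_fn = NULL, gamma = 6, n_scale = 450,
                              anchors = NULL) {
  if (is.null(intake_fn)) {
    intake_fn <- function(n) 1 / (1 + (n / n_scale)^gamma)
  }
  lam <- function(m, phi) {
    max(Re(eigen(leslie_matrix(
      m, phi, fecundity = constants$fecundity,
      n_classes = constants$n_classes,
      years_per_class = constants$years_per_class,
      maturity_age = constants$maturity_age), only.values = TRUE)$values))
  }
  if (lam(0, 1) <= 1) {
    abort("fecundity too low: population cannot be stationary at phi = 1",
          class = "vaquitamse_calibration_error")
  }
  m <- uniroot(function(x) lam(x, 1) - 1, c(0, 0.5), tol = 1e-12)$root

  r <- constants$r_lowdensity
  phi_upper <- 8
  if (lam(m, phi_upper) < 1 + r) {
    abort(paste0("growth target infeasible: max eigenvalue at phi = ",
                 phi_upper, " is ", round(lam(m, phi_upper), 4),
                 " < ", round(1 + r, 4)),
          class = "vaquitamse_calibration_error")
  }
  phi_hi <- uniroot(function(p) lam(m, p) - (1 + r), c(1, phi_upper),
                    tol = 1e-12)$root

  if (is.null(anchors)) {
    p1 <- intake_fn(constants$n0_default)
    p2 <- intake_fn(constants$k_unfished)
  } else {
    p1 <- anchors[1]
    p2 <- anchors[2]
  }
  if (p1 - phi_hi * p2 <= 0) {
    abort("interference too weak: intake at carrying capacity too close to intake at N0",
          class = "vaquitamse_calibration_error")
  }
  p_half <- p1 * p2 * (phi_hi - 1) / (p1 - phi_hi * p2)
  phi_max <- phi_hi * (p1 + p_half) / p1

  phi_of_n <- function(n) {
    # scale the instantaneous intake curve through the first anchor so the
    # equilibrium iteration below uses the anchored units
    p <- p1 * intake_fn(n) / intake_fn(constants$n0_default)
    phi_max * p / (p + p_half)
  }
  # semi-analytic equilibrium of the annual projection at fixed prey field
  k_achieved <- local({
    A0 <- leslie_matrix(m, phi_hi, fecundity = constants$fecundity,
                        n_classes = constants$n_classes,
                        years_per_class = constants$years_per_class,
                        maturity_age = constants$maturity_age)
    v <- Re(eigen(A0)$vectors[, 1]); v <- abs(v) / sum(abs(v))
    n <- v * constants$n0_default
    for (t in seq_len(400)) {
      A <- leslie_matrix(m, phi_of_n(sum(n)),
                         fecundity = constants$fecundity,
                         n_classes = constants$n_classes,
                         years_per_class = constants$years_per_class,
                         maturity_age = constants$maturity_age)
      n <- as.vector(A %*% n)
    }
    sum(n)
  })

  report <- tibble::tibble(
    quantity = c("low-density annual growth factor",
                 "unfished equilibrium abundance",
                 "stationary eigenvalue at phi = 1"),
    target = c(1 + r, constants$k_unfished, 1),
    achieved = c(lam(m, phi_hi), k_achieved, lam(m, 1))
  )
  report$ok <- abs(report$achieved / report$target - 1) <
    c(1e-3, 0.05, 1e-6)

  list(m = m, phi_max = phi_max, p_half = p_half, p_ref = p1,
       phi_hi = phi_hi, gamma = gamma, n_scale = n_scale,
       r_lowdensity = r, k_target = constants$k_unfished,
       k_achieved = k_achieved, report = report)
}
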