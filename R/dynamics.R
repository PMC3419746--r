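#' Holling type II intake rates
#'
#' Computes saturating per-predator-biomass intake rates
#' `I_k = a_k B_k / (1 + h * sum_m a_m B_m)` for each prey. Total intake is
#' monotone non-decreasing in every prey biomass and bounded above by `1/h`
#' when handling time is positive.
#'
#' @param availability Named non-negative vector of availability coefficients
#'   `a_k` (per tonne per year scale). Prey present in `prey_biomass` but
#'   absent here are treated as unavailable (`a = 0`) with a message.
#' @param handling Handling time `h` (years per unit intake), scalar >= 0.
#' @param prey_biomass Named non-negative vector of prey biomasses (tonnes).
#' @return Named vector of intake rates (tonnes per tonne of predator per
#'   year), one per element of `prey_biomass`.
#' @examples
#' holling_intake(c(fish = 1), handling = 0.1, prey_biomass = c(fish = 990))
#' @export
holling_intake <- function(availability, handling, prey_biomass) {
  if (any(prey_biomass < 0)) {
    abort("prey biomass must be non-negative", class = "vaquitamse_domain_error")
  }
  if (handling < 0) {
    abort("handling time must be non-negative", class = "vaquitamse_domain_error")
  }
  missing <- setdiff(names(prey_biomass), names(availability))
  if (length(missing) > 0) {
    inform(paste("no availability for prey, treated as zero:",
                 paste(missing, collapse = ", ")))
  }
  a <- availability[names(prey_biomass)]
  a[is.na(a)] <- 0
  denom <- 1 + handling * sum(a * prey_biomass)
  out <- a * prey_biomass / denom
  names(out) <- names(prey_biomass)
  out
}

#' Beverton-Holt recruitment
#'
#' `R = alpha * S / (beta + S)`: monotone increasing and concave in spawning
#' biomass, saturating at `alpha` recruits with half-saturation at `S = beta`.
#'
#' @param s Spawning biomass (tonnes), non-negative (vectorized).
#' @param alpha Asymptotic recruitment (recruits), > 0.
#' @param beta Half-saturation spawning biomass (tonnes), > 0.
#' @return Recruits, same length as `s`.
#' @examples
#' beverton_holt(100, alpha = 1e6, beta = 100)  # alpha/2
#' @export
beverton_holt <- function(s, alpha, beta) {
  if (any(s < 0)) {
    abort("spawning biomass must be non-negative",
          class = "vaquitamse_domain_error")
  }
  stopifnot(alpha > 0, beta > 0)
  alpha * s / (beta + s)
}

#' Fixed per-female recruitment
#'
#' Mammals, elasmobranchs and other fixed-fecundity groups produce
#' `fecundity * phi * (mature / 2) * dt` newborns, assuming a 1:1 sex ratio
#' (females are half the mature abundance). `phi` is a dimensionless
#' condition multiplier on fecundity; for vaquita it carries the
#' prey-intake-driven density dependence.
#'
#' @param mature_abundance Mature individuals, >= 0.
#' @param fecundity Viable offspring per female per year.
#' @param phi Condition multiplier, > 0.
#' @param dt Interval in years over which births accrue.
#' @return Newborn individuals (enter the first age class).
#' @examples
#' fixed_recruits(200, fecundity = 0.26)  # 26 newborns
#' @export
fixed_recruits <- function(mature_abundance, fecundity, phi = 1, dt = 1) {
  if (any(mature_abundance < 0)) {
    abort("mature abundance must be non-negative",
          class = "vaquitamse_domain_error")
  }
  stopifnot(phi > 0)
  fecundity * phi * (mature_abundance / 2) * dt
}

#' Exponential survival with annual age-class promotion
#'
#' Scales each age class by `exp(-(M + F) * dt)`; when `promote = TRUE`
#' (once per simulated year) a fraction `1 / years_per_class` of each class
#' advances to the next, and survivors promoted out of the terminal class
#' exit the population (longevity cap). Total abundance never increases.
#'
#' @param n Abundance vector by age class.
#' @param m Natural mortality (per year).
#' @param f Fishing mortality (per year).
#' @param dt Time step (years), > 0.
#' @param years_per_class Years spanned by each age class.
#' @param promote Apply the annual promotion after survival?
#' @return Abundance vector after survival (and promotion).
#' @examples
#' survive_and_age(c(1000, 0), m = 0.1, f = 0, dt = 1, promote = FALSE)
#' @export
survive_and_age <- function(n, m, f, dt, years_per_class = 2,
                            promote = FALSE) {
  stopifnot(m >= 0, f >= 0, dt > 0)
  n <- n * exp(-(m + f) * dt)
  if (promote) {
    n <- promote_classes(n, years_per_class)
  }
  n
}

# fraction 1/ypc of each class moves up; terminal promotions leave the
# population (longevity cap)
promote_classes <- function(n, years_per_class) {
  moving <- n / years_per_class
  n <- n - moving
  k <- length(n)
  if (k > 1) n[2:k] <- n[2:k] + moving[1:(k - 1)]
  n
}

#' Baranov competing-risks harvest partitioning
#'
#' Deaths over an interval are `N (1 - exp(-Z dt))` with total hazard
#' `Z = M + sum(F)`; each source removes its proportional share `F_i / Z`.
#' The partition is exact: survivors plus all removals equal the initial
#' abundance.
#'
#' @param n Initial abundance (or biomass).
#' @param m Natural (plus predation) mortality, per year.
#' @param f Named vector of fleet fishing mortalities, per year.
#' @param dt Interval in years.
#' @return List with `survivors`, `natural_deaths`, and `catch` (named per
#'   fleet).
#' @examples
#' harvest_partition(1000, m = 0.1, f = c(fleet_a = 0.1), dt = 1)$catch
#' @export
harvest_partition <- function(n, m, f, dt = 1) {
  stopifnot(n >= 0, m >= 0, all(f >= 0), dt > 0)
  z <- m + sum(f)
  if (z == 0) {
    return(list(survivors = n, natural_deaths = 0,
                catch = setNames(rep(0, length(f)), names(f))))
  }
  deaths <- n * (1 - exp(-z * dt))
  list(survivors = n - deaths,
       natural_deaths = deaths * m / z,
       catch = deaths * f / z)
}

#' Density-dependent redistribution weights
#'
#' Movement weights for a foraging predator:
#' `w_p ~ habitat_p * (1 + D_p / Dbar)` where `D_p` is the available prey
#' density in polygon `p` (availability-weighted prey biomass per km^2) and
#' `Dbar` its habitat-weighted mean. Uniform prey density reproduces the
#' habitat weights exactly; prey-rich polygons are up-weighted. If all
#' weights collapse to zero the habitat weights are returned with a message.
#'
#' @param habitat Non-negative habitat weights per polygon (sum > 0).
#' @param prey_density Available prey density per polygon (any non-negative
#'   scale; only relative values matter).
#' @return Weights summing to 1.
#' @examples
#' redistribute_weights(c(0.5, 0.5), c(3, 1))
#' @export
redistribute_weights <- function(habitat, prey_density) {
  stopifnot(length(habitat) == length(prey_density), all(habitat >= 0),
            sum(habitat) > 0, all(prey_density >= 0))
  habitat <- habitat / sum(habitat)
  dbar <- sum(habitat * prey_density)
  rel <- if (dbar > 0) prey_density / dbar else rep(1, length(habitat))
  w <- habitat * (1 + rel)
  if (sum(w) <= 0) {
    inform("all redistribution weights zero; falling back to habitat weights")
    return(habitat)
  }
  w / sum(w)
}

#' Annual Leslie projection matrix
#'
#' The annual linear projection implied by the simulator's within-year order
#' for an age-structured group with uniform mortality: continuous survival
#' `exp(-(M+F))`, recruitment of `fecundity * phi / 2` newborns per
#' post-survival mature individual into class 1, then promotion of
#' `1/years_per_class` of each class (terminal promotions exit). Its dominant
#' eigenvalue is the annual population growth factor; its dominant
#' eigenvector the stable age structure.
#'
#' @param m Natural mortality (per year).
#' @param phi Fecundity condition multiplier.
#' @param f Fishing mortality (per year), uniform over classes.
#' @param fecundity Offspring per female per year.
#' @param n_classes,years_per_class Age structure.
#' @param maturity_age Age (years) at maturity; classes whose lower age bound
#'   is at least this are mature.
#' @return `n_classes` x `n_classes` projection matrix.
#' @examples
#' lam <- function(m) max(Re(eigen(leslie_matrix(m))$values))
#' lam(0)
#' @export
leslie_matrix <- function(m, phi = 1, f = 0, fecundity = 0.26,
                          n_classes = 10, years_per_class = 2,
                          maturity_age = 10) {
  s <- exp(-(m + f))
  mature <- which((seq_len(n_classes) - 1) * years_per_class >= maturity_age)
  G <- diag(1 - 1 / years_per_class, n_classes)
  for (k in seq_len(n_classes - 1)) G[k + 1, k] <- 1 / years_per_class
  R <- matrix(0, n_classes, n_classes)
  R[1, mature] <- fecundity * phi / 2
  (G + R) * s
}

#' Mature classes of an age-structured group
#'
#' @param n_classes,years_per_class,maturity_age Age structure; a class is
#'   mature when its lower age bound `(k-1)*years_per_class` is at least
#'   `maturity_age`.
#' @return Integer vector of mature class indices.
#' @export
mature_classes <- function(n_classes, years_per_class, maturity_age) {
  which((seq_len(n_classes) - 1) * years_per_class >= maturity_age)
}
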