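#' Behavioral parameter set
#'
#' The six behavioral parameters governing the three preconditions of
#' sex selection, with their theoretically plausible ranges, plus the
#' son-preference curve coefficients and the male conception probability.
#'
#' \describe{
#'   \item{gamma}{son-preference intensity, \code{[0, 1]}: proportional
#'     expansion of the birth hazard for women with unmet son preference
#'     (differential stopping behavior). 0.2 means a 20\% higher fertility
#'     risk than the period age-specific schedule.}
#'   \item{alpha}{birth-risk adjustment once son preference is met,
#'     \code{[0, 1]}: the hazard is scaled by \code{1 - alpha}.}
#'   \item{sigma}{fertility-squeeze scale for parity >= 1, \code{[0, 2.5]}.}
#'   \item{beta}{fertility-squeeze scale for parity 0, \code{[0, 0.5]}.}
#'   \item{rho}{rate of logistic technology diffusion, \code{[0, 2]}.}
#'   \item{phi}{inflection time-step of the diffusion curve, \code{[0, 20]}
#'     (model time, 0 at simulation start).}
#'   \item{delta0, delta1, reference_year}{son-preference logistic curve:
#'     the population probability of wanting a son in calendar year \eqn{y}
#'     is \code{plogis(delta0 + delta1 * (y - reference_year))}. Defaults
#'     solve the curve exactly through stated-preference anchors of 48\% in
#'     1985 and 26\% in 1994 with reference year 1980.}
#'   \item{p_male}{male probability at conception, default 0.5122,
#'     corresponding to a natural SRB of 105.}
#' }
#'
#' @param gamma,alpha,sigma,beta,rho,phi behavioral parameters (see Details).
#' @param delta0,delta1 log-odds intercept and per-year slope of the
#'   son-preference curve.
#' @param reference_year calendar year where the curve's time covariate is 0.
#' @param p_male male conception probability in (0, 1).
#' @return An object of class \code{srb_params}.
#' @examples
#' p <- param_set()          # calibration defaults
#' p$gamma
#' param_set(sigma = 0, beta = 0)  # no-abortion counterfactual
#' @export
param_set <- function(gamma = 0.2, alpha = 0.075, sigma = 1.7, beta = 0.2,
                      rho = 0.5, phi = 7, delta0 = NULL, delta1 = NULL,
                      reference_year = 1980, p_male = 0.5122) {
  if (is.null(delta0) || is.null(delta1)) {
    anchor <- fit_son_preference(c(1985, 1994), c(0.48, 0.26),
                                 reference_year = reference_year)
    if (is.null(delta0)) delta0 <- anchor$delta0
    if (is.null(delta1)) delta1 <- anchor$delta1
  }
  check_range <- function(v, lo, hi, name) {
    .assert(is.numeric(v) && length(v) == 1 && is.finite(v) && v >= lo && v <= hi,
            "%s must be a number in [%g, %g]", name, lo, hi)
  }
  check_range(gamma, 0, 1, "gamma")
  check_range(alpha, 0, 1, "alpha")
  check_range(sigma, 0, 2.5, "sigma")
  check_range(beta, 0, 0.5, "beta")
  check_range(rho, 0, 2, "rho")
  check_range(phi, 0, 20, "phi")
  .assert(p_male > 0 && p_male < 1, "p_male must be in (0, 1)")
  structure(
    list(gamma = gamma, alpha = alpha, sigma = sigma, beta = beta,
         rho = rho, phi = phi, delta0 = delta0, delta1 = delta1,
         reference_year = reference_year, p_male = p_male),
    class = "srb_params"
  )
}

#' @export
print.srb_params <- function(x, ...) {
  cat(sprintf(
    paste0("<srb_params> gamma=%.3g alpha=%.3g sigma=%.3g beta=%.3g ",
           "rho=%.3g phi=%.3g | sp curve: %.4g %+.4g/yr (ref %d) | p_male=%.4f\n"),
    x$gamma, x$alpha, x$sigma, x$beta, x$rho, x$phi,
    x$delta0, x$delta1, x$reference_year, x$p_male))
  invisible(x)
}

#' Plausible parameter ranges for design-of-experiments
#'
#' The box over which calibration designs are drawn: gamma and alpha in
#' \code{[0, 1]}, sigma in \code{[0, 2.5]}, beta in \code{[0, 0.5]}, rho in
#' \code{[0, 2]}, phi in \code{[0, 20]}.
#'
#' @return A named list of \code{c(min, max)} pairs.
#' @export
default_parameter_ranges <- function() {
  list(gamma = c(0, 1), alpha = c(0, 1), sigma = c(0, 2.5),
       beta = c(0, 0.5), rho = c(0, 2), phi = c(0, 20))
}

#' Differential-stopping-behavior fertility hazard
#'
#' Modifies the standard period age-specific birth hazard according to a
#' woman's son preference and living sons: women with no son preference keep
#' the base rate; women with unmet preference (\code{so < sp}) get the rate
#' expanded by \code{1 + gamma} (capped at 1); women whose preference is met
#' (\code{so >= sp}, \code{sp != 0}) get it reduced by \code{1 - alpha}.
#'
#' All arguments are vectorized over agents.
#'
#' @param base_rate standard age-specific hazard(s) in \code{[0, 1]}.
#' @param sp son preference (0/1); \code{NA} is treated as 0 (no preference).
#' @param so living sons (non-negative count).
#' @param params a [param_set()].
#' @return Per-year conception probability(ies) in \code{[0, 1]}.
#' @examples
#' p <- param_set(gamma = 0.2, alpha = 0.075)
#' fertility_hazard(0.10, sp = 1, so = 0, params = p)  # 0.12: 20% higher
#' fertility_hazard(0.10, sp = 1, so = 1, params = p)  # 0.0925
#' @export
fertility_hazard <- function(base_rate, sp, so, params) {
  .assert(all(base_rate >= 0 & base_rate <= 1), "base_rate must be in [0, 1]")
  n <- max(length(base_rate), length(sp), length(so))
  base_rate <- rep_len(base_rate, n)
  sp <- rep_len(sp, n)
  so <- rep_len(so, n)
  sp <- ifelse(is.na(sp), 0L, sp)
  h <- base_rate
  unmet <- sp > 0L & so < sp
  met <- sp > 0L & so >= sp
  h[unmet] <- pmin(base_rate[unmet] * (1 + params$gamma), 1)
  h[met] <- base_rate[met] * (1 - params$alpha)
  h
}

#' Draw sexes at conception
#'
#' Sex is determined at conception: male with probability \code{p_male}
#' (default 0.5122, a natural sex ratio at birth of 105 males per 100
#' females).
#'
#' @param n number of conceptions.
#' @param params a [param_set()].
#' @return Character vector in \code{c("female", "male")}.
#' @export
draw_sex <- function(n, params) {
  c("female", "male")[rbinom(n, 1L, params$p_male) + 1L]
}
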