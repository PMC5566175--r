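#' Son-preference curve (willingness)
#'
#' The population probability of wanting a son is modeled on the log-odds
#' scale as linear in calendar time: \code{plogis(delta0 + delta1 * (year -
#' reference_year))}. The curve is fitted to survey proportions of women
#' stating they must have a son.
#'
#' @param delta0 intercept on the log-odds scale (at the reference year).
#' @param delta1 per-year slope on the log-odds scale.
#' @param reference_year calendar year where the time covariate is 0.
#' @return An object of class \code{srb_sp_curve}.
#' @export
son_preference_curve <- function(delta0, delta1, reference_year = 1980) {
  .assert(is.finite(delta0) && is.finite(delta1), "coefficients must be finite")
  structure(list(delta0 = delta0, delta1 = delta1,
                 reference_year = as.integer(reference_year)),
            class = "srb_sp_curve")
}

#' Probability of son preference in a calendar year
#'
#' @param curve a [son_preference_curve()] or a [param_set()] (whose
#'   \code{delta0}/\code{delta1}/\code{reference_year} are used).
#' @param year calendar year(s).
#' @return Probability(ies) in (0, 1), monotone in year with the sign of
#'   \code{delta1}.
#' @examples
#' crv <- fit_son_preference(c(1985, 1994), c(0.48, 0.26))
#' son_preference_probability(crv, c(1985, 1994))  # 0.48, 0.26
#' @export
son_preference_probability <- function(curve, year) {
  plogis(curve$delta0 + curve$delta1 * (year - curve$reference_year))
}

#' Fit the son-preference curve to observed proportions
#'
#' With exactly two observations the logistic is solved exactly through both
#' points (a two-parameter system on the logit scale); with more, a
#' least-squares fit of the logit-transformed proportions against year is
#' used, which interpolates exactly when the points are collinear on the
#' logit scale.
#'
#' @param years calendar years of the observations (>= 2).
#' @param proportions observed proportions, strictly inside (0, 1).
#' @param reference_year calendar year where the curve's time covariate is 0
#'   (default: the earliest observation year).
#' @return A [son_preference_curve()].
#' @export
fit_son_preference <- function(years, proportions, reference_year = min(years)) {
  .assert(length(years) == length(proportions) && length(years) >= 2,
          "need at least 2 (year, proportion) observations")
  .assert(all(proportions > 0 & proportions < 1),
          "proportions must be strictly inside (0, 1)")
  z <- qlogis(proportions)
  tt <- years - reference_year
  if (length(years) == 2) {
    .assert(years[1] != years[2], "observation years must differ")
    delta1 <- (z[2] - z[1]) / (tt[2] - tt[1])
    delta0 <- z[1] - delta1 * tt[1]
  } else {
    fit <- lm(z ~ tt)
    delta0 <- unname(coef(fit)[1])
    delta1 <- unname(coef(fit)[2])
  }
  son_preference_curve(delta0, delta1, reference_year)
}

#' Logistic technology-diffusion curve (ability)
#'
#' The probability that an individual has gained access to prenatal
#' sex-determination technology by model time-step \code{t} follows the
#' logistic diffusion-of-innovations curve
#' \code{exp(rho * (t - phi)) / (1 + exp(rho * (t - phi)))}: \code{rho}
#' is the diffusion rate and \code{phi} the inflection time-step, where the
#' curve passes 0.5. Model time is counted from the simulation start
#' (t = 0 in the first simulated year).
#'
#' @param rho diffusion rate (slope), non-negative.
#' @param phi inflection time-step.
#' @return An object of class \code{srb_diffusion_curve}.
#' @export
diffusion_curve <- function(rho, phi) {
  .assert(is.finite(rho) && is.finite(phi), "rho and phi must be finite")
  structure(list(rho = rho, phi = phi), class = "srb_diffusion_curve")
}

#' Probability of technology access at a model time-step
#'
#' @param curve a [diffusion_curve()] or [param_set()] (whose
#'   \code{rho}/\code{phi} are used).
#' @param t model time-step(s) (0 at simulation start).
#' @return Probability(ies) in (0, 1); 0.5 at \code{t = phi}; non-decreasing
#'   in \code{t} when \code{rho > 0}.
#' @examples
#' ability_probability(diffusion_curve(0.5, 7), 7)   # 0.5
#' ability_probability(diffusion_curve(0.5, 7), 0)   # 1 / (1 + exp(3.5))
#' @export
ability_probability <- function(curve, t) {
  plogis(curve$rho * (t - curve$phi))
}

#' Update women's technology access
#'
#' Each woman draws a fresh uniform; if it falls below the prevailing
#' \code{Ability(t)} her \code{tech} flag is set. In the default
#' \code{"absorbing"} mode access, once gained, persists (diffusion
#' saturates); in \code{"redraw"} mode the flag is re-determined from the
#' fresh draw every tick, so the population share with access tracks
#' \code{Ability(t)} itself.
#'
#' @param tech logical vector of current access flags.
#' @param curve a [diffusion_curve()] or [param_set()].
#' @param t model time-step.
#' @param mode \code{"absorbing"} (default) or \code{"redraw"}.
#' @param ability optional constant overriding \code{Ability(t)} (used by
#'   constant-availability scenarios).
#' @return Updated logical vector.
#' @export
update_tech_access <- function(tech, curve, t, mode = c("absorbing", "redraw"),
                               ability = NULL) {
  mode <- match.arg(mode)
  a <- ability %||% ability_probability(curve, t)
  hit <- runif(length(tech)) < a
  if (mode == "absorbing") tech | hit else hit
}

#' Readiness to abort under the fertility squeeze
#'
#' Given that a woman is willing (unmet son preference) and able (technology
#' access), her probability of aborting a female conception is driven by the
#' fertility squeeze: the ratio of her current parity to prevailing fertility
#' levels, scaled by \code{sigma} for parity >= 1 and by \code{beta} at
#' parity 0, capped at 1:
#' \code{min(1, beta / TFR)} at parity 0 and
#' \code{min(1, parity * sigma / TFR)} at parity >= 1.
#' Lower prevailing fertility means a stronger squeeze: at a TFR of 3 a
#' parity-1 woman has probability \code{sigma / 3}; once the TFR has fallen
#' to 2.5, \code{0.4 * sigma}.
#'
#' @param parity current parity (vectorized, non-negative).
#' @param tfr_prev prevailing (previous-period, model-generated) TFR, > 0.
#' @param params a [param_set()].
#' @return Probability(ies) in \code{[0, 1]}.
#' @export
readiness_probability <- function(parity, tfr_prev, params) {
  .assert(all(tfr_prev > 0), "tfr_prev must be positive")
  .assert(all(parity >= 0), "parity must be non-negative")
  ifelse(parity == 0L,
         pmin(1, params$beta / tfr_prev),
         pmin(1, parity * params$sigma / tfr_prev))
}

#' One woman-year of the conception/abortion decision flow
#'
#' Runs the per-tick reproduction decision for one or more women: a
#' Bernoulli conception at the DSB-modified hazard; sex determined at
#' conception; then, for a female fetus, a sex-selective abortion if and only
#' if the woman is willing (\code{sp > so}), able (\code{tech}), and a
#' uniform draw falls below her readiness. At most one event occurs per
#' woman per tick; male fetuses are never aborted.
#'
#' @param base_rate standard age-specific hazard(s).
#' @param sp,so,parity,tech the woman's (women's) state.
#' @param tfr_prev prevailing TFR entering the readiness ratio.
#' @param params a [param_set()].
#' @return Character vector over \code{c("no_conception", "female_birth",
#'   "male_birth", "sex_selective_abortion")}.
#' @export
conception_step <- function(base_rate, sp, so, parity, tech, tfr_prev, params) {
  n <- max(length(base_rate), length(sp), length(so), length(parity),
           length(tech))
  base_rate <- rep_len(base_rate, n)
  sp <- rep_len(ifelse(is.na(sp), 0L, sp), n)
  so <- rep_len(so, n)
  parity <- rep_len(parity, n)
  tech <- rep_len(tech, n)

  h <- fertility_hazard(base_rate, sp, so, params)
  conceived <- runif(n) < h
  male <- logical(n)
  male[conceived] <- runif(sum(conceived)) < params$p_male

  event <- rep("no_conception", n)
  event[conceived & male] <- "male_birth"
  fem <- conceived & !male
  if (any(fem)) {
    willing_able <- fem & sp > so & tech
    abort <- willing_able
    if (any(willing_able)) {
      r <- readiness_probability(parity[willing_able], tfr_prev, params)
      abort[willing_able] <- runif(sum(willing_able)) < r
    }
    event[fem & !abort] <- "female_birth"
    event[fem & abort] <- "sex_selective_abortion"
  }
  event
}
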