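#' Synthesize a declining-fertility, declining-mortality rate schedule
#'
#' Generates a smooth rate schedule with the statistical shape the simulation
#' assumes, emulating a population moving through the fertility transition:
#' the age-specific fertility surface keeps a fixed unimodal age shape
#' (peaking near ages 24--28) while the schedule TFR interpolates
#' log-linearly from \code{tfr_start} to \code{tfr_end}; yearly death
#' probabilities follow a child/adult (Gompertz-like) age profile whose level
#' declines monotonically over the years. The output is deterministic given
#' the arguments.
#'
#' @param start_year first calendar year of the schedule.
#' @param n_years number of contiguous years (>= 1).
#' @param tfr_start,tfr_end schedule TFR (children per woman) in the first
#'   and last year; both must be positive.
#' @param e0_proxy mortality-improvement knob in (0, 1]: the ratio of
#'   final-year to first-year mortality level. 1 keeps mortality constant;
#'   smaller values give faster decline. Default 0.35.
#' @param seed accepted for interface symmetry with the other generators;
#'   the schedule is deterministic, so the seed has no effect.
#' @return A [rate_schedule()].
#' @examples
#' sched <- synthesize_schedule(1945, 66, tfr_start = 2.8, tfr_end = 1.2)
#' range(sched$schedule_tfr)
#' @export
synthesize_schedule <- function(start_year, n_years, tfr_start = 2.8,
                                tfr_end = 1.2, e0_proxy = 0.35, seed = NULL) {
  .assert(n_years >= 1, "n_years must be >= 1")
  .assert(tfr_start > 0 && tfr_end > 0, "TFR values must be positive")
  .assert(e0_proxy > 0 && e0_proxy <= 1, "e0_proxy must be in (0, 1]")
  years <- as.integer(start_year) + seq_len(n_years) - 1L
  ages_f <- 15:49
  ages_m <- 0:50

  # Fixed unimodal age shape: a beta density over the reproductive span,
  # mode near age 25; packaged constant so downstream tests are deterministic.
  u <- (ages_f - 14.5) / 36
  shape <- stats::dbeta(u, 3.1, 5.9)
  shape <- shape / sum(shape)

  frac <- if (n_years == 1) 0 else (seq_len(n_years) - 1) / (n_years - 1)
  tfr <- tfr_start * (tfr_end / tfr_start)^frac
  fert <- outer(tfr, shape)
  .assert(all(fert <= 1), "fertility shape x TFR exceeds 1; lower tfr_start")

  # Age profile of death probability: infant/child component decaying in
  # age, a floor, and a Gompertz adult component; males ~15% excess.
  q_profile <- 0.055 * exp(-ages_m / 2.5) + 8e-4 + 1.2e-4 * exp(0.09 * ages_m)
  level <- e0_proxy^frac
  qf <- outer(level, q_profile)
  qm <- pmin(outer(level, q_profile * 1.15), 1)

  rate_schedule(years, fert, qf, qm)
}

# Stable-population age structure implied by one year of rates: female
# Leslie matrix dominant eigenvector; males scaled by the sex ratio at birth
# and the male/female survivorship ratio (both sexes share the stable growth
# factor, which cancels).
.stable_structure <- function(schedule, year, p_male) {
  i <- .schedule_year_index(schedule, year)
  qf <- schedule$mortality$female[i, ]
  qm <- schedule$mortality$male[i, ]
  asfr <- numeric(51)
  asfr[schedule$fert_ages + 1L] <- schedule$fertility[i, ]

  L <- matrix(0, 51, 51)
  # survival sub-diagonal; age 50 is absorbing removal, no row needed
  for (x in 0:49) L[x + 2L, x + 1L] <- 1 - qf[x + 1L]
  # female births per woman aged x at tick start: mortality precedes
  # conception within a tick, so mothers must first survive the year
  L[1L, ] <- (1 - qf) * asfr * (1 - p_male)
  eig <- eigen(L)
  k <- which.max(Re(eig$values))
  v <- abs(Re(eig$vectors[, k]))
  female <- v / sum(v)

  lf <- cumprod(c(1, 1 - qf[1:50]))
  lm <- cumprod(c(1, 1 - qm[1:50]))
  male <- female * (p_male / (1 - p_male)) * (lm / lf)
  probs <- cbind(female = female, male = male)
  probs / sum(probs)
}

#' Synthesize an initial population from a schedule's first-year rates
#'
#' Draws \code{size} individuals from the stable age/sex structure implied by
#' the schedule's first-year fertility and mortality rates (female Leslie
#' matrix dominant eigenvector; males scaled by the sex ratio at birth and
#' relative survivorship). This gives the burn-in a plausible starting
#' pyramid; the burn-in itself then generates realistic parity distributions.
#'
#' @param schedule a [rate_schedule()].
#' @param size total number of individuals (> 0).
#' @param seed RNG seed for the multinomial draw; \code{NULL} uses the
#'   current RNG stream (for callers managing their own seeding).
#' @param p_male male probability at conception used for the newborn slice
#'   (default 0.5122, a natural SRB of 105).
#' @return An [initial_population()] whose counts total \code{size}.
#' @export
synthesize_initial_population <- function(schedule, size, seed = 1L,
                                          p_male = 0.5122) {
  .assert(inherits(schedule, "srb_rate_schedule"),
          "schedule must be an srb_rate_schedule")
  .assert(is.numeric(size) && size > 0, "size must be positive")
  probs <- .stable_structure(schedule, schedule$years[1], p_male)
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- rmultinom(1, as.integer(size), as.vector(probs))
  initial_population(matrix(draw, nrow = 51, ncol = 2))
}
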