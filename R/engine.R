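#' Scenario configuration
#'
#' Bundles everything one simulation run needs besides the rate schedule:
#' the simulated period, burn-in length, initial population size, behavioral
#' parameters, behavioral-mode flags, counterfactual overrides, replicate
#' count and base seed.
#'
#' @param start_year,end_year simulated calendar period (inclusive);
#'   model time \code{t} is 0 at \code{start_year}.
#' @param burnin_years years of pre-period burn-in (default 35) during which
#'   agents die and reproduce by the plain schedule rates, with no
#'   differential stopping behavior and no abortion, so that women entering
#'   the period carry realistic parity histories.
#' @param population_size initial agent count at the burn-in start.
#' @param params a [param_set()].
#' @param sp_mode \code{"annual_redraw"} (default: son preference re-drawn
#'   each year for every woman 15--49 so the population proportion tracks the
#'   period curve) or \code{"cohort_fixed"} (assigned once at age 15).
#' @param sp_override \code{NULL}, or a constant son-preference proportion
#'   replacing the fitted curve (constant-willingness scenarios).
#' @param ability_override \code{NULL}, or a constant technology-availability
#'   proportion replacing the diffusion curve; forces per-tick redraw so the
#'   population share with access stays at the override level.
#' @param tech_mode \code{"absorbing"} (default) or \code{"redraw"}; see
#'   [update_tech_access()].
#' @param dsb_in_burnin apply differential stopping behavior during burn-in
#'   (default \code{FALSE}; sensitivity flag).
#' @param n_replicates number of independent replicate runs.
#' @param seed base RNG seed; replicate \code{r} runs on \code{seed + r}.
#' @return An object of class \code{srb_config}.
#' @export
scenario_config <- function(start_year = 1980, end_year = 2010,
                            burnin_years = 35, population_size = 20000,
                            params = param_set(),
                            sp_mode = c("annual_redraw", "cohort_fixed"),
                            sp_override = NULL, ability_override = NULL,
                            tech_mode = c("absorbing", "redraw"),
                            dsb_in_burnin = FALSE,
                            n_replicates = 20, seed = 1L) {
  sp_mode <- match.arg(sp_mode)
  tech_mode <- match.arg(tech_mode)
  .assert(end_year > start_year, "end_year must exceed start_year")
  .assert(burnin_years >= 0, "burnin_years must be non-negative")
  .assert(population_size > 0, "population_size must be positive")
  .assert(inherits(params, "srb_params"), "params must be a param_set()")
  .assert(n_replicates >= 1, "n_replicates must be >= 1")
  if (!is.null(sp_override))
    .assert(sp_override >= 0 && sp_override <= 1, "sp_override must be in [0, 1]")
  if (!is.null(ability_override))
    .assert(ability_override >= 0 && ability_override <= 1,
            "ability_override must be in [0, 1]")
  structure(
    list(start_year = as.integer(start_year), end_year = as.integer(end_year),
         burnin_years = as.integer(burnin_years),
         population_size = as.integer(population_size), params = params,
         sp_mode = sp_mode, sp_override = sp_override,
         ability_override = ability_override, tech_mode = tech_mode,
         dsb_in_burnin = isTRUE(dsb_in_burnin),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "srb_config"
  )
}

#' @export
print.srb_config <- function(x, ...) {
  cat(sprintf(
    "<srb_config> %d-%d (burn-in %d yr), %d agents x %d replicates, seed %d\n",
    x$start_year, x$end_year, x$burnin_years, x$population_size,
    x$n_replicates, x$seed))
  print(x$params)
  invisible(x)
}

# One simulated year. Within-tick order: technology update -> son-preference
# assignment -> mortality (son deaths feed back on mothers the same year) ->
# conception / abortion / birth (readiness uses tfr_prev, frozen at entry) ->
# aging and retirement at 50, newborns appended at age 0.
# behavior = FALSE runs the plain demographic tick (burn-in).
.tick <- function(pop, schedule, year, t, params, tfr_prev, opts,
                  behavior = TRUE) {
  yi <- .schedule_year_index(schedule, year)

  if (behavior) {
    wi <- which(pop$sex == SEX_FEMALE & pop$age >= 15L & pop$age <= 49L)
    if (!is.null(opts$ability_override)) {
      a <- opts$ability_override
      mode <- "redraw"
    } else {
      a <- plogis(params$rho * (t - params$phi))
      mode <- opts$tech_mode %||% "absorbing"
    }
    hit <- runif(length(wi)) < a
    pop$tech[wi] <- if (mode == "absorbing") pop$tech[wi] | hit else hit

    spv <- opts$sp_override %||%
      plogis(params$delta0 + params$delta1 * (year - params$reference_year))
    if ((opts$sp_mode %||% "annual_redraw") == "annual_redraw") {
      pop$sp[wi] <- as.integer(runif(length(wi)) < spv)
    } else {
      newly <- wi[is.na(pop$sp[wi])]
      pop$sp[newly] <- as.integer(runif(length(newly)) < spv)
    }
  }

  mres <- apply_mortality(pop, schedule, year)
  pop <- register_son_deaths(mres$population, mres$son_deaths)

  wi <- which(pop$sex == SEX_FEMALE & pop$age >= 15L & pop$age <= 49L)
  n_w <- length(wi)
  base <- schedule$fertility[yi, pop$age[wi] - 14L]
  if (behavior) {
    sp <- pop$sp[wi]
    sp[is.na(sp)] <- 0L
    so <- pop$so[wi]
    h <- fertility_hazard(base, sp, so, params)
  } else {
    sp <- integer(n_w)
    so <- integer(n_w)
    h <- base
  }
  conceive <- runif(n_w) < h
  ci <- wi[conceive]
  n_c <- length(ci)
  male <- runif(n_c) < params$p_male

  abort <- logical(n_c)
  if (behavior && n_c > 0) {
    spc <- sp[conceive]
    soc <- so[conceive]
    cand <- !male & spc > soc & pop$tech[ci]
    if (any(cand)) {
      r <- readiness_probability(pop$p[ci[cand]], tfr_prev, params)
      abort[cand] <- runif(sum(cand)) < r
    }
  }

  bi <- ci[!abort]
  born_male <- male[!abort]
  ai <- ci[abort]

  parity_at_abort <- pop$p[ai]
  pop$ab[ai] <- pop$ab[ai] + 1L
  pop$p[bi] <- pop$p[bi] + 1L
  sons <- bi[born_male]
  pop$so[sons] <- pop$so[sons] + 1L

  male_births <- sum(born_male)
  female_births <- length(bi) - male_births

  w_by_age <- tabulate(pop$age[wi] - 14L, 35L)
  b_by_age <- tabulate(pop$age[bi] - 14L, 35L)
  pos <- w_by_age > 0
  realized_tfr <- sum(b_by_age[pos] / w_by_age[pos])

  out <- data.frame(
    year = year,
    conceptions = n_c,
    male_births = male_births,
    female_births = female_births,
    abortions = length(ai),
    srb = if (female_births > 0) 100 * male_births / female_births else NA_real_,
    tfr = realized_tfr,
    abortions_p0 = sum(parity_at_abort == 0L),
    abortions_p1 = sum(parity_at_abort == 1L),
    abortions_p2 = sum(parity_at_abort == 2L),
    abortions_p3plus = sum(parity_at_abort >= 3L),
    prop_willing = if (n_w > 0 && behavior) mean(sp == 1L) else NA_real_,
    prop_able = if (n_w > 0 && behavior) mean(pop$tech[wi]) else NA_real_,
    women_15_49 = n_w,
    population = pop_size(pop)
  )

  newborn_sex <- ifelse(born_male, SEX_MALE, SEX_FEMALE)
  newborn_mother <- pop$id[bi]
  pop$age <- pop$age + 1L
  pop <- retire_at_50(pop)
  pop <- pop_append_births(pop, newborn_sex, newborn_mother, year)

  list(population = pop, output = out)
}

#' Run the burn-in initialization
#'
#' Evolves a starting population from \code{burnin_years} before
#' \code{start_year} up to \code{start_year} under plain mortality and
#' fertility: no differential stopping behavior and no abortion are modeled
#' before the simulated period (unless \code{dsb_in_burnin} is set, in which
#' case DSB applies but abortion still does not). The burn-in gives women
#' entering the period completed or in-progress fertility careers, so the
#' period starts from a realistic parity distribution.
#'
#' Uses the current RNG stream; seed it (or use [run_scenario()], which
#' manages replicate seeds) for reproducibility.
#'
#' @param config a [scenario_config()].
#' @param schedule a [rate_schedule()] covering the burn-in years.
#' @param init optional [initial_population()]; synthesized from the
#'   schedule's first burn-in year when omitted.
#' @return The \code{srb_population} as of \code{start_year}.
#' @export
run_burnin <- function(config, schedule, init = NULL) {
  first <- config$start_year - config$burnin_years
  assert_schedule_covers(schedule, first:max(first, config$start_year - 1L))
  if (is.null(init)) {
    init <- synthesize_initial_population(schedule, config$population_size,
                                          seed = NULL,
                                          p_male = config$params$p_male)
  }
  pop <- population_from_counts(init, first)
  if (config$burnin_years == 0L) return(pop)
  if (config$dsb_in_burnin) {
    # DSB without abortion: zero squeeze parameters shut the abortion path.
    prm <- config$params
    prm$sigma <- 0
    prm$beta <- 0
    for (y in first:(config$start_year - 1L)) {
      res <- .tick(pop, schedule, y, y - config$start_year, prm,
                   tfr_prev = unname(schedule$schedule_tfr[as.character(y)]),
                   opts = config, behavior = TRUE)
      pop <- res$population
    }
  } else {
    for (y in first:(config$start_year - 1L)) {
      pop <- .tick(pop, schedule, y, NA, config$params, NULL,
                   opts = config, behavior = FALSE)$population
    }
  }
  pop
}

#' Advance the simulation by one year
#'
#' Applies the full per-tick procedure (technology update, son-preference
#' assignment, mortality with son-death feedback, conception with the
#' ready/willing/able abortion decision, aging) and returns the yearly
#' aggregates: births by sex, SRB, realized period TFR, abortion counts by
#' parity, and the proportions of reproductive-age women willing and able.
#'
#' @param pop an \code{srb_population}.
#' @param schedule a [rate_schedule()] covering \code{year}.
#' @param params a [param_set()].
#' @param tfr_prev previous-year model-generated TFR feeding the readiness
#'   ratio (> 0; the first tick uses the schedule TFR).
#' @param year calendar year.
#' @param t model time-step (0 at the scenario's start year).
#' @param opts list of behavioral-mode options (\code{sp_mode},
#'   \code{sp_override}, \code{ability_override}, \code{tech_mode}), as in
#'   [scenario_config()]; defaults apply when omitted.
#' @return A list with \code{population} (advanced one year) and
#'   \code{output} (one-row data frame of yearly aggregates). Conservation
#'   holds exactly: \code{conceptions = male_births + female_births +
#'   abortions}.
#' @export
step_year <- function(pop, schedule, params, tfr_prev, year, t, opts = list()) {
  .assert(is.finite(tfr_prev) && tfr_prev > 0, "tfr_prev must be positive")
  .tick(pop, schedule, year, t, params, tfr_prev, opts, behavior = TRUE)
}

.run_replicate <- function(config, schedule, rep_seed, init = NULL,
                           burnin_pop = NULL) {
  set.seed(rep_seed)
  pop <- burnin_pop %||% run_burnin(config, schedule, init)
  years <- config$start_year:config$end_year
  rows <- vector("list", length(years))
  tfr_prev <- unname(schedule$schedule_tfr[as.character(config$start_year)])
  for (k in seq_along(years)) {
    y <- years[k]
    res <- .tick(pop, schedule, y, y - config$start_year, config$params,
                 tfr_prev, opts = config, behavior = TRUE)
    pop <- res$population
    rows[[k]] <- res$output
    # Degenerate tiny-population years fall back to the schedule TFR so the
    # readiness ratio stays defined.
    tfr_prev <- if (is.finite(res$output$tfr) && res$output$tfr > 0)
      res$output$tfr
    else unname(schedule$schedule_tfr[as.character(y)])
  }
  list(yearly = do.call(rbind, rows), population = pop)
}

#' Run a replicate ensemble of one scenario
#'
#' Runs \code{n_replicates} independent simulations (replicate \code{r} is
#' seeded with \code{seed + r}, so ensembles are bit-reproducible), and
#' summarizes the ensemble: per-year means and empirical 2.5/5/95/97.5
#' percentiles of SRB and TFR, plus 5-year centered moving averages of the
#' means.
#'
#' @param config a [scenario_config()].
#' @param schedule a [rate_schedule()] covering burn-in through
#'   \code{end_year}.
#' @param verbose log per-replicate progress to stderr.
#' @return An object of class \code{srb_ensemble}: list with
#'   \code{trajectories} (tidy per-replicate yearly data frame),
#'   \code{summary} (per-year ensemble mean and percentile bands),
#'   \code{smoothed} (5-year moving averages of the mean SRB and TFR) and
#'   \code{config}.
#' @export
run_scenario <- function(config, schedule, verbose = FALSE) {
  assert_schedule_covers(
    schedule, (config$start_year - config$burnin_years):config$end_year)
  traj <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    res <- .run_replicate(config, schedule, config$seed + r)
    res$yearly$replicate <- r
    traj[[r]] <- res$yearly
    if (verbose) {
      message(sprintf("[replicate %d] years %d-%d done (final SRB %.1f)",
                      r, config$start_year, config$end_year,
                      res$yearly$srb[nrow(res$yearly)]))
    }
  }
  trajectories <- do.call(rbind, traj)
  ens <- list(trajectories = trajectories,
              summary = .summarize_ensemble(trajectories),
              config = config)
  ens$smoothed <- data.frame(
    year = ens$summary$year,
    srb_ma5 = moving_average(ens$summary$srb_mean, 5L),
    tfr_ma5 = moving_average(ens$summary$tfr_mean, 5L)
  )
  structure(ens, class = "srb_ensemble")
}

.summarize_ensemble <- function(trajectories) {
  years <- sort(unique(trajectories$year))
  qs <- c(0.025, 0.05, 0.95, 0.975)
  one <- function(y) {
    d <- trajectories[trajectories$year == y, ]
    sq <- quantile(d$srb, qs, na.rm = TRUE, names = FALSE)
    tq <- quantile(d$tfr, qs, na.rm = TRUE, names = FALSE)
    data.frame(year = y,
               srb_mean = mean(d$srb, na.rm = TRUE),
               srb_p2.5 = sq[1], srb_p5 = sq[2], srb_p95 = sq[3],
               srb_p97.5 = sq[4],
               tfr_mean = mean(d$tfr, na.rm = TRUE),
               tfr_p2.5 = tq[1], tfr_p5 = tq[2], tfr_p95 = tq[3],
               tfr_p97.5 = tq[4],
               abortions_mean = mean(d$abortions),
               prop_willing_mean = mean(d$prop_willing, na.rm = TRUE),
               prop_able_mean = mean(d$prop_able, na.rm = TRUE))
  }
  do.call(rbind, lapply(years, one))
}

#' @export
print.srb_ensemble <- function(x, ...) {
  s <- x$summary
  peak <- s$year[which.max(s$srb_mean)]
  cat(sprintf(
    "<srb_ensemble> %d replicates, %d-%d; peak mean SRB %.1f in %d\n",
    x$config$n_replicates, min(s$year), max(s$year), max(s$srb_mean), peak))
  invisible(x)
}

#' Plot an ensemble's SRB and TFR trajectories
#'
#' Draws the ensemble-mean SRB (5-year moving average) with its empirical
#' 95\% band, and the smoothed mean TFR on a second panel.
#'
#' @param x an \code{srb_ensemble}.
#' @param ... passed to \code{plot}.
#' @export
plot.srb_ensemble <- function(x, ...) {
  s <- x$summary
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plot(s$year, moving_average(s$srb_mean), type = "l", lwd = 2,
       xlab = "year", ylab = "SRB (male births per 100 female)",
       main = "sex ratio at birth", ylim = range(s$srb_p2.5, s$srb_p97.5,
                                                 na.rm = TRUE), ...)
  graphics::polygon(c(s$year, rev(s$year)),
                    c(moving_average(s$srb_p2.5),
                      rev(moving_average(s$srb_p97.5))),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(s$year, moving_average(s$srb_mean), lwd = 2)
  graphics::abline(h = 105, lty = 3)
  plot(s$year, moving_average(s$tfr_mean), type = "l", lwd = 2,
       xlab = "year", ylab = "TFR (children per woman)",
       main = "total fertility rate")
  invisible(x)
}

#' Centered moving average
#'
#' Centered mean over an odd window, with the window shrinking at the series
#' edges; missing values (e.g. SRB in years with no female births) are
#' skipped.
#'
#' @param x numeric series.
#' @param window odd window width (default 5).
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(x, window = 5L) {
  .assert(length(x) > 0, "series must be non-empty")
  .assert(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    v <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' TFR gap between a scenario and its no-abortion counterfactual
#'
#' Compares ensemble-mean TFR trajectories of a run with sex-selective
#' abortion against the counterfactual with the abortion pathway shut
#' (\code{sigma = 0}, \code{beta = 0}, all else equal): the per-year absolute
#' gap (TFR without minus TFR with) and the percentage gap relative to the
#' with-abortion level.
#'
#' @param with_abortion,without \code{srb_ensemble} objects over the same
#'   years.
#' @return Data frame with \code{year}, \code{tfr_with}, \code{tfr_without},
#'   \code{gap}, \code{gap_pct}.
#' @export
counterfactual_tfr_gap <- function(with_abortion, without) {
  sw <- with_abortion$summary
  so <- without$summary
  .assert(identical(sw$year, so$year), "ensembles cover different years")
  gap <- so$tfr_mean - sw$tfr_mean
  data.frame(year = sw$year, tfr_with = sw$tfr_mean,
             tfr_without = so$tfr_mean, gap = gap,
             gap_pct = 100 * gap / sw$tfr_mean)
}

#' Write ensemble outputs as tidy CSV
#'
#' Writes \code{trajectories.csv} (one row per replicate-year, with the
#' columns replicate, year, male_births, female_births, srb, tfr,
#' abortions_p0, abortions_p1, abortions_p2plus, prop_willing, prop_able,
#' plus conceptions and total abortions) and \code{summary.csv} (per-year
#' ensemble means and percentile bands).
#'
#' @param ensemble an \code{srb_ensemble}.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- ensemble$trajectories
  out <- data.frame(
    replicate = tr$replicate, year = tr$year,
    male_births = tr$male_births, female_births = tr$female_births,
    srb = tr$srb, tfr = tr$tfr,
    abortions_p0 = tr$abortions_p0, abortions_p1 = tr$abortions_p1,
    abortions_p2plus = tr$abortions_p2 + tr$abortions_p3plus,
    prop_willing = tr$prop_willing, prop_able = tr$prop_able,
    conceptions = tr$conceptions, abortions = tr$abortions
  )
  p1 <- file.path(dir, "trajectories.csv")
  p2 <- file.path(dir, "summary.csv")
  write.csv(out, p1, row.names = FALSE)
  write.csv(ensemble$summary, p2, row.names = FALSE)
  invisible(c(trajectories = p1, summary = p2))
}
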