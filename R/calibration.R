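#' Model-fit measure: RMSE between simulated and reference SRB series
#'
#' The average yearly error between a simulated SRB trajectory and a
#' reference (e.g. vital-statistics estimates) over a calibration window:
#' \deqn{\sqrt{\sum_t (ref(t) - sim(t))^2 / (end - start)}}
#' The denominator is the year span \code{end_year - start_year} (30 for a
#' 1980--2010 window) even though the sum runs over the
#' \code{end_year - start_year + 1} yearly terms, following the printed
#' convention of the fit measure this implements.
#'
#' @param simulated,reference data frames with columns \code{year} and
#'   \code{srb}, or numeric vectors named by year. Both must cover every
#'   year of the window with finite values.
#' @param start_year,end_year calibration window (inclusive).
#' @return The RMSE fit value (lower is better).
#' @examples
#' ref <- data.frame(year = 1980:1981, srb = c(105, 110))
#' sim <- data.frame(year = 1980:1981, srb = c(106, 108))
#' model_fit_rmse(sim, ref, 1980, 1981)  # sqrt((1 + 4) / 1)
#' @export
model_fit_rmse <- function(simulated, reference, start_year, end_year) {
  .assert(end_year > start_year, "end_year must exceed start_year")
  years <- start_year:end_year
  pick <- function(x, label) {
    if (is.data.frame(x)) {
      .assert(all(c("year", "srb") %in% names(x)),
              "%s must have columns year and srb", label)
      v <- x$srb[match(years, x$year)]
    } else {
      v <- x[match(as.character(years), names(x))]
    }
    .assert(!anyNA(v) && all(is.finite(v)),
            "%s series does not cover %d-%d with finite values",
            label, start_year, end_year)
    as.numeric(v)
  }
  sim <- pick(simulated, "simulated")
  ref <- pick(reference, "reference")
  sqrt(sum((ref - sim)^2) / (end_year - start_year))
}

# A design point whose trajectory leaves the SRB undefined in some window
# year (no female births; extreme abortion regimes in small populations)
# cannot be scored against the reference and is ranked last with an
# infinite fit value.
.fit_or_inf <- function(yearly, reference, start_year, end_year) {
  srb <- yearly$srb[match(start_year:end_year, yearly$year)]
  if (anyNA(srb) || any(!is.finite(srb))) return(Inf)
  model_fit_rmse(yearly, reference, start_year, end_year)
}

#' Latin hypercube design over the behavioral parameter box
#'
#' Draws a space-filling Latin hypercube sample over the six behavioral
#' parameters: each parameter's \code{n_points} values stratify its range
#' with exactly one point per equal-probability bin. A random subset of
#' \code{n_replicated} design points is flagged for \code{reps} repeated
#' simulation runs (the rest get one run each), reproducing the
#' 224-point / 400-run bookkeeping of an exploratory calibration
#' (180 x 1 + 44 x 5) at the defaults.
#'
#' @param ranges named list of \code{c(min, max)} per parameter; default
#'   [default_parameter_ranges()].
#' @param n_points number of design points (default 224).
#' @param n_replicated number of points flagged for repetition (default 44).
#' @param reps repetitions at flagged points (default 5).
#' @param seed RNG seed for the design draw.
#' @return An object of class \code{srb_design}: a data frame with
#'   \code{point_id}, one column per parameter, and \code{n_runs}; attribute
#'   \code{planned_runs} gives \code{sum(n_runs)}, and \code{ranges} echoes
#'   the box.
#' @export
latin_hypercube_design <- function(ranges = default_parameter_ranges(),
                                   n_points = 224, n_replicated = 44,
                                   reps = 5, seed = 1L) {
  .assert(n_points >= 1, "n_points must be >= 1")
  .assert(n_replicated >= 0 && n_replicated <= n_points,
          "n_replicated must be between 0 and n_points")
  .assert(reps >= 1, "reps must be >= 1")
  for (nm in names(ranges)) {
    .assert(length(ranges[[nm]]) == 2 && ranges[[nm]][1] < ranges[[nm]][2],
            "range for %s must be c(min, max) with min < max", nm)
  }
  set.seed(as.integer(seed))
  unit <- lhs::randomLHS(n_points, length(ranges))
  design <- as.data.frame(mapply(function(u, r) r[1] + u * (r[2] - r[1]),
                                 as.data.frame(unit), ranges))
  names(design) <- names(ranges)
  design <- cbind(point_id = seq_len(n_points), design)
  design$n_runs <- 1L
  if (n_replicated > 0) {
    design$n_runs[sample.int(n_points, n_replicated)] <- as.integer(reps)
  }
  structure(design, class = c("srb_design", "data.frame"),
            planned_runs = sum(design$n_runs), ranges = ranges)
}

#' Evaluate a design: simulate at every point and score the fit
#'
#' Runs the simulation at each design point (with the point's behavioral
#' parameters substituted into the configuration template) and scores each
#' run's SRB trajectory against the reference with [model_fit_rmse()] over
#' \code{[config$start_year, config$end_year]}. Runs at the same point use
#' consecutive sub-seeds; all points share common random numbers per run
#' index through the burn-in, which is parameter-free (no stopping behavior
#' or abortion before the period) and therefore computed once per run index
#' and reused across points.
#'
#' @param design an [latin_hypercube_design()] (or any data frame with the
#'   six parameter columns and \code{n_runs}).
#' @param schedule a [rate_schedule()].
#' @param config a [scenario_config()] template; its \code{params} supply
#'   the non-searched fields (son-preference curve, \code{p_male}).
#' @param reference reference SRB series (data frame \code{year,srb}).
#' @param score how a multi-run point is scored: \code{"mean_rmse"}
#'   (default; each run's trajectory is scored and the RMSEs averaged) or
#'   \code{"rmse_of_mean"} (the point's runs are first averaged into an
#'   ensemble-mean SRB trajectory, which is then scored). At desk-scale
#'   population sizes the per-run score carries a Monte Carlo noise floor
#'   that differs across design points with different birth counts;
#'   ensemble-mean scoring shrinks that floor and discriminates parameter
#'   regions more sharply.
#' @param verbose log per-point progress.
#' @return The design with columns \code{mean_fit} (mean RMSE over the
#'   point's runs) and \code{sd_fit} appended, ranked best-first; attribute
#'   \code{fit_runs} holds the per-run fit matrix. Points whose trajectories
#'   leave the SRB undefined in a window year (no female births under
#'   extreme abortion regimes in small populations) score \code{Inf} and
#'   rank last.
#' @export
evaluate_design <- function(design, schedule, config, reference,
                            score = c("mean_rmse", "rmse_of_mean"),
                            verbose = FALSE) {
  score <- match.arg(score)
  pars <- c("gamma", "alpha", "sigma", "beta", "rho", "phi")
  .assert(all(pars %in% names(design)), "design must have columns %s",
          paste(pars, collapse = ","))
  window <- config$start_year:config$end_year
  max_runs <- max(design$n_runs)
  burnins <- vector("list", max_runs)
  for (j in seq_len(max_runs)) {
    set.seed(config$seed + j)
    burnins[[j]] <- run_burnin(config, schedule)
  }
  fits <- matrix(NA_real_, nrow = nrow(design), ncol = max_runs)
  ens_fits <- rep(NA_real_, nrow(design))
  for (i in seq_len(nrow(design))) {
    prm <- config$params
    for (nm in pars) prm[[nm]] <- design[[nm]][i]
    cfg <- config
    cfg$params <- prm
    srb_runs <- matrix(NA_real_, nrow = design$n_runs[i],
                       ncol = length(window))
    for (j in seq_len(design$n_runs[i])) {
      # Common random numbers: run index j shares its seed (and burn-in)
      # across all design points, making point comparisons lower-variance
      # and identical parameter rows bit-identical. The period stream is
      # offset so it does not reuse the burn-in's draws.
      res <- .run_replicate(cfg, schedule,
                            rep_seed = config$seed + 500000L + j,
                            burnin_pop = burnins[[j]])
      fits[i, j] <- .fit_or_inf(res$yearly, reference,
                                config$start_year, config$end_year)
      srb_runs[j, ] <- res$yearly$srb[match(window, res$yearly$year)]
    }
    if (score == "rmse_of_mean") {
      sim_mean <- data.frame(year = window, srb = colMeans(srb_runs))
      ens_fits[i] <- .fit_or_inf(sim_mean, reference,
                                 config$start_year, config$end_year)
    }
    if (verbose) {
      message(sprintf("[design point %d/%d] mean fit %.3f",
                      i, nrow(design), mean(fits[i, ], na.rm = TRUE)))
    }
  }
  design$mean_fit <- if (score == "rmse_of_mean") ens_fits
                     else rowMeans(fits, na.rm = TRUE)
  design$sd_fit <- apply(fits, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) else NA_real_
  })
  out <- design[order(design$mean_fit), ]
  attr(out, "fit_runs") <- fits
  attr(out, "ranges") <- attr(design, "ranges")
  class(out) <- c("srb_design", "data.frame")
  out
}

#' Rank design points by model fit (best-fit search)
#'
#' Convenience wrapper: evaluates the design against the reference and
#' returns it ranked by mean fit, optionally attaching metamodel-based
#' interpolation of the fit surface and its grid argmin as a refinement
#' suggestion.
#'
#' @inheritParams evaluate_design
#' @param refine fit a quadratic-plus-interactions metamodel to the evaluated
#'   design and report the fit-surface argmin over a grid (default TRUE).
#' @param grid_levels levels per parameter for the refinement grid.
#' @return The evaluated, ranked design; if \code{refine}, attributes
#'   \code{metamodel} and \code{surface_argmin}.
#' @export
best_fit_search <- function(design, schedule, config, reference,
                            refine = TRUE, grid_levels = 7, verbose = FALSE) {
  ranked <- evaluate_design(design, schedule, config, reference,
                            verbose = verbose)
  if (refine) {
    mm <- fit_metamodel(ranked, outcome = "mean_fit")
    ranges <- attr(design, "ranges") %||% default_parameter_ranges()
    grid <- lapply(ranges, function(r) seq(r[1], r[2], length.out = grid_levels))
    surf <- interpolate_fit_surface(mm, grid)
    attr(ranked, "metamodel") <- mm
    attr(ranked, "surface_argmin") <- surf[which.min(surf$.pred), ]
  }
  ranked
}

.metamodel_formula <- function(pars, terms) {
  lin <- pars
  quad <- if ("quadratic" %in% terms) paste0("I(", pars, "^2)") else NULL
  inter <- if ("interactions" %in% terms) {
    combn(pars, 2, FUN = function(p) paste(p, collapse = ":"))
  } else NULL
  stats::as.formula(paste(".outcome ~", paste(c(lin, quad, inter),
                                              collapse = " + ")))
}

#' Fit a regression metamodel to design outcomes
#'
#' Least-squares regression of a simulation outcome on the design
#' parameters with linear, quadratic, and pairwise-interaction terms, plus an
#' ANOVA variance decomposition: each term's share of the outcome variance
#' from sequential (type-I) sums of squares, parameters entered
#' main-effects-first in the fixed order gamma, alpha, sigma, beta, rho, phi,
#' then quadratics, then interactions. Parameters are centered on their
#' design means before squaring/interacting to reduce order sensitivity.
#' Shares are non-negative and sum with the residual share to 100.
#'
#' @param design an evaluated design (data frame with parameter columns and
#'   the outcome column).
#' @param outcome name of the outcome column (e.g. \code{"mean_fit"}, an SRB
#'   level at a given year, or the maximum SRB reached).
#' @param terms which term blocks to include: subset of
#'   \code{c("linear", "quadratic", "interactions")}.
#' @param log_outcome model the outcome on the log scale (default FALSE,
#'   raw scale).
#' @return An object of class \code{srb_metamodel}: list with \code{model}
#'   (the \code{lm} fit), \code{shares} (data frame term/share in percent),
#'   \code{residual_share}, \code{r_squared}, \code{centers}, \code{ranges}.
#' @export
fit_metamodel <- function(design, outcome = "mean_fit",
                          terms = c("linear", "quadratic", "interactions"),
                          log_outcome = FALSE) {
  pars <- c("gamma", "alpha", "sigma", "beta", "rho", "phi")
  pars <- pars[pars %in% names(design)]
  .assert(length(pars) >= 1, "design has no parameter columns")
  .assert(outcome %in% names(design), "no outcome column '%s'", outcome)
  terms <- match.arg(terms, several.ok = TRUE)
  dat <- as.data.frame(design)[, c(pars, outcome)]
  dat <- dat[complete.cases(dat) & is.finite(dat[[outcome]]), ]
  centers <- vapply(dat[pars], mean, numeric(1))
  for (nm in pars) dat[[nm]] <- dat[[nm]] - centers[[nm]]
  dat$.outcome <- if (log_outcome) log(dat[[outcome]]) else dat[[outcome]]
  form <- .metamodel_formula(pars, terms)
  n_terms <- length(attr(stats::terms(form), "term.labels"))
  .assert(nrow(dat) >= 2 * n_terms,
          "need at least %d design points for %d terms (rank safety)",
          2 * n_terms, n_terms)
  fit <- lm(form, data = dat)
  .assert(!anyNA(coef(fit)), "rank-deficient metamodel; drop terms or add points")
  # only the sums of squares are consumed; silence the perfect-fit warning
  # anova.lm emits about its F-tests on noiseless planted surfaces
  aov_tab <- suppressWarnings(anova(fit))
  ss <- aov_tab[["Sum Sq"]]
  labels <- rownames(aov_tab)
  total <- sum(ss)
  shares <- data.frame(term = labels[labels != "Residuals"],
                       share = 100 * ss[labels != "Residuals"] / total)
  structure(
    list(model = fit,
         shares = shares,
         residual_share = 100 * ss[labels == "Residuals"] / total,
         r_squared = suppressWarnings(summary(fit))$r.squared,
         centers = centers,
         log_outcome = log_outcome,
         outcome = outcome,
         ranges = attr(design, "ranges")),
    class = "srb_metamodel"
  )
}

#' @export
print.srb_metamodel <- function(x, ...) {
  cat(sprintf("<srb_metamodel> outcome '%s', R^2 = %.3f, residual %.1f%%\n",
              x$outcome, x$r_squared, x$residual_share))
  top <- x$shares[order(-x$shares$share), ]
  top <- top[seq_len(min(6, nrow(top))), ]
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-14s %6.2f%%\n", top$term[i], top$share[i]))
  }
  invisible(x)
}

#' Interpolate the fit surface over a parameter grid
#'
#' Predicts the metamodel outcome over the full factorial grid spanned by the
#' supplied per-parameter value lists (the regression-metamodel interpolation
#' step of the calibration), enabling argmin extraction over parameter
#' combinations far denser than the simulated design.
#'
#' @param metamodel an [fit_metamodel()] result.
#' @param grid named list of value vectors, one per model parameter; values
#'   must lie within the design ranges when those are known.
#' @return Data frame of the grid with prediction column \code{.pred}.
#' @export
interpolate_fit_surface <- function(metamodel, grid) {
  pars <- names(metamodel$centers)
  .assert(all(pars %in% names(grid)), "grid must supply values for %s",
          paste(pars, collapse = ","))
  if (!is.null(metamodel$ranges)) {
    for (nm in pars) {
      r <- metamodel$ranges[[nm]]
      .assert(all(grid[[nm]] >= r[1] & grid[[nm]] <= r[2]),
              "grid values for %s outside design range [%g, %g]", nm, r[1], r[2])
    }
  }
  full <- expand.grid(grid[pars], KEEP.OUT.ATTRS = FALSE)
  centered <- full
  for (nm in pars) centered[[nm]] <- centered[[nm]] - metamodel$centers[[nm]]
  pred <- predict(metamodel$model, newdata = centered)
  full$.pred <- if (metamodel$log_outcome) exp(pred) else pred
  full
}

#' Read or write a design table as CSV
#' @param design an \code{srb_design} (possibly evaluated).
#' @param path CSV path.
#' @return \code{write_design}: invisibly the path; \code{read_design}: the
#'   design data frame.
#' @export
write_design <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  d <- read.csv(path)
  class(d) <- c("srb_design", "data.frame")
  d
}

#' Read a reference SRB series from CSV
#' @param path CSV with columns \code{year,srb}.
#' @return Data frame \code{year,srb}.
#' @export
read_reference_srb <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  tab <- read.csv(path)
  .assert(all(c("year", "srb") %in% names(tab)),
          "reference CSV must have columns year,srb")
  tab[, c("year", "srb")]
}
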