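test_that("the RMSE fit measure matches hand and brute-force computation", {
  ref <- data.frame(year = 1980:1981, srb = c(105, 110))
  sim <- data.frame(year = 1980:1981, srb = c(106, 108))
  # two-year toy series, denominator end - start = 1... then a denominator-2
  # window: sqrt((1 + 4) / 2)
  expect_equal(model_fit_rmse(sim, ref, 1980, 1981), sqrt(5), tolerance = 1e-12)
  ref3 <- data.frame(year = 1980:1982, srb = c(105, 110, 112))
  sim3 <- data.frame(year = 1980:1982, srb = c(106, 108, 112))
  expect_equal(model_fit_rmse(sim3, ref3, 1980, 1982), sqrt(5 / 2),
               tolerance = 1e-12)
  # identical series: zero
  expect_equal(model_fit_rmse(ref, ref, 1980, 1981), 0)
  # constant offset d: closed form d * sqrt(n_terms / span)
  off <- ref3
  off$srb <- off$srb + 2
  expect_equal(model_fit_rmse(off, ref3, 1980, 1982), 2 * sqrt(3 / 2),
               tolerance = 1e-12)
  # brute-force loop equivalence on random series
  set.seed(21)
  for (k in 1:5) {
    years <- 1980:2010
    a <- data.frame(year = years, srb = runif(31, 100, 120))
    b <- data.frame(year = years, srb = runif(31, 100, 120))
    acc <- 0
    for (y in years) {
      acc <- acc + (a$srb[a$year == y] - b$srb[b$year == y])^2
    }
    expect_equal(model_fit_rmse(b, a, 1980, 2010), sqrt(acc / 30),
                 tolerance = 1e-12)
  }
  expect_error(model_fit_rmse(sim, ref, 1979, 1981), "cover")
})

test_that("the Latin hypercube stratifies every parameter", {
  d <- latin_hypercube_design(n_points = 50, n_replicated = 0, seed = 3)
  ranges <- default_parameter_ranges()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    u <- (d[[nm]] - r[1]) / (r[2] - r[1])
    expect_true(all(u >= 0 & u <= 1))
    # exactly one point per equal-probability bin
    bins <- as.integer(floor(u * 50))
    expect_identical(sort(bins), 0:49)
  }
  # identical seed, identical design
  d2 <- latin_hypercube_design(n_points = 50, n_replicated = 0, seed = 3)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("the default design plans 224 points and 400 runs", {
  d <- latin_hypercube_design(seed = 5)
  expect_identical(nrow(d), 224L)
  expect_identical(sum(d$n_runs == 1L), 180L)
  expect_identical(sum(d$n_runs == 5L), 44L)
  expect_identical(attr(d, "planned_runs"), 400L)
})

test_that("a planted single-parameter signal claims all the variance", {
  d <- latin_hypercube_design(n_points = 100, n_replicated = 0, seed = 6)
  d$mean_fit <- 2 * d$sigma
  mm <- fit_metamodel(d, "mean_fit")
  expect_equal(mm$r_squared, 1, tolerance = 1e-9)
  # sequential decomposition: the slightly correlated design columns entered
  # before sigma can siphon a fraction of a percent
  expect_gt(mm$shares$share[mm$shares$term == "sigma"], 98)
  expect_lt(sum(mm$shares$share[mm$shares$term != "sigma"]), 2)
  expect_lt(mm$residual_share, 1e-6)
})

test_that("variance shares are non-negative and sum with residual to 100", {
  set.seed(30)
  d <- latin_hypercube_design(n_points = 120, n_replicated = 0, seed = 8)
  d$mean_fit <- 3 + d$sigma * d$phi + d$rho^2 + rnorm(120, 0, 0.5)
  mm <- fit_metamodel(d, "mean_fit")
  expect_true(all(mm$shares$share >= 0))
  expect_equal(sum(mm$shares$share) + mm$residual_share, 100,
               tolerance = 0.1)
})

test_that("planted orthogonal response surfaces return their shares", {
  # Build the outcome from Gram-Schmidt-orthogonalized metamodel columns
  # (in the decomposition's fixed term order) with chosen weights: the
  # sequential ANOVA must hand each term exactly its planted variance share.
  d <- latin_hypercube_design(n_points = 150, n_replicated = 0, seed = 12)
  pars <- c("gamma", "alpha", "sigma", "beta", "rho", "phi")
  Xc <- sweep(as.matrix(d[pars]), 2, colMeans(as.matrix(d[pars])))
  quads <- Xc^2
  colnames(quads) <- paste0("I(", pars, "^2)")
  pairs <- combn(pars, 2)
  inters <- apply(pairs, 2, function(p) Xc[, p[1]] * Xc[, p[2]])
  colnames(inters) <- apply(pairs, 2, paste, collapse = ":")
  M <- cbind(Xc, quads, inters)
  # modified Gram-Schmidt against the intercept and all previous columns
  Q <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  prev <- matrix(1 / sqrt(nrow(M)), nrow(M), 1)
  for (k in seq_len(ncol(M))) {
    v <- M[, k]
    for (j in seq_len(ncol(prev))) v <- v - sum(v * prev[, j]) * prev[, j]
    v <- v / sqrt(sum(v^2))
    Q[, k] <- v
    prev <- cbind(prev, v)
  }
  w <- setNames(numeric(ncol(M)), colnames(M))
  w[c("gamma", "sigma", "beta", "phi", "I(rho^2)", "sigma:phi")] <-
    c(2, 1.5, 0.5, 3, 2.5, 1)
  planted <- 100 * w^2 / sum(w^2)
  d$mean_fit <- as.numeric(Q %*% w)
  mm <- fit_metamodel(d, "mean_fit")
  got <- setNames(mm$shares$share, mm$shares$term)
  expect_true(all(names(w) %in% names(got)))
  expect_lt(max(abs(got[names(w)] - planted)), 2)
  expect_lt(mm$residual_share, 1e-6)
})

test_that("surface interpolation predicts exactly at noiseless design points", {
  d <- latin_hypercube_design(n_points = 120, n_replicated = 0, seed = 9)
  d$mean_fit <- 1 + 0.5 * d$gamma + 0.2 * d$sigma^2 - 0.1 * d$rho * d$phi
  mm <- fit_metamodel(d, "mean_fit")
  expect_equal(mm$r_squared, 1, tolerance = 1e-9)
  grid <- as.list(d[3, c("gamma", "alpha", "sigma", "beta", "rho", "phi")])
  pred <- interpolate_fit_surface(mm, grid)
  expect_equal(pred$.pred, d$mean_fit[3], tolerance = 1e-8)
  # grid of one point gives one prediction
  expect_identical(nrow(pred), 1L)
  expect_error(
    interpolate_fit_surface(mm, within(grid, gamma <- 2)), "range")
})

test_that("the argmin of a planted convex quadratic surface is its vertex", {
  d <- latin_hypercube_design(n_points = 200, n_replicated = 0, seed = 10)
  # convex in sigma and rho with vertex at (1.25, 0.8); flat elsewhere
  d$mean_fit <- (d$sigma - 1.25)^2 + 0.5 * (d$rho - 0.8)^2
  mm <- fit_metamodel(d, "mean_fit")
  grid <- list(gamma = 0.5, alpha = 0.5, beta = 0.25, phi = 10,
               sigma = seq(0, 2.5, length.out = 51),
               rho = seq(0, 2, length.out = 41))
  surf <- interpolate_fit_surface(mm, grid)
  best <- surf[which.min(surf$.pred), ]
  expect_equal(best$sigma, 1.25, tolerance = 0.03)
  expect_equal(best$rho, 0.8, tolerance = 0.03)
})

test_that("rank deficiency is reported when points cannot support the terms", {
  d <- latin_hypercube_design(n_points = 20, n_replicated = 0, seed = 2)
  d$mean_fit <- d$sigma
  expect_error(fit_metamodel(d, "mean_fit"), "design points")
})

test_that("design evaluation ranks parameter sets by fit deterministically", {
  sched <- tiny_schedule()
  cfg <- tiny_config(population_size = 2000, n_replicates = 1)
  # reference from the simulator itself
  set.seed(cfg$seed + 1)
  ref_run <- run_scenario(tiny_config(population_size = 2000,
                                      n_replicates = 2), sched)
  ref <- data.frame(year = ref_run$summary$year,
                    srb = ref_run$summary$srb_mean)
  d <- latin_hypercube_design(n_points = 6, n_replicated = 1, reps = 2,
                              seed = 1)
  r1 <- evaluate_design(d, sched, cfg, ref)
  r2 <- evaluate_design(d, sched, cfg, ref)
  expect_identical(r1$mean_fit, r2$mean_fit)
  expect_false(is.unsorted(r1$mean_fit))
  # two rows with identical parameters score identical mean fit
  d2 <- d[c(1, 1, 2:6), ]
  d2$point_id <- seq_len(nrow(d2))
  d2$n_runs <- 1L
  r3 <- evaluate_design(d2, sched, cfg, ref)
  same <- r3$mean_fit[match(c(1, 2), r3$point_id)]
  expect_identical(same[1], same[2])
})
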