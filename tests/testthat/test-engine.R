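test_that("zero burn-in returns the initial structure unchanged", {
  sched <- tiny_schedule()
  cfg <- tiny_config(burnin_years = 0)
  init <- synthesize_initial_population(sched, 2000, seed = 4)
  pop <- run_burnin(cfg, sched, init = init)
  expect_identical(length(pop$id), 2000L)
  snap <- population_snapshot(pop)
  counts <- table(factor(snap$age, levels = 0:50),
                  factor(snap$sex, levels = c("female", "male")))
  expect_identical(as.integer(counts), as.integer(init$counts))
})

test_that("burn-in births carry the natural sex ratio", {
  sched <- tiny_schedule(start = 1960, n_years = 40)
  cfg <- scenario_config(1990, 2000, burnin_years = 30,
                         population_size = 20000, n_replicates = 1, seed = 8)
  set.seed(cfg$seed)
  pop <- run_burnin(cfg, sched)
  snap <- population_snapshot(pop)
  born <- snap[snap$age < 30, ]  # born during burn-in
  n <- nrow(born)
  p_hat <- mean(born$sex == "male")
  # male fraction at birth 0.5122; survival differences are second order,
  # so allow 4 binomial SD
  expect_lt(abs(p_hat - 0.5122), 4 * sqrt(0.5122 * 0.4878 / n))
  # burn-in leaves parity histories behind
  women <- snap[snap$sex == "female" & snap$age >= 20 & snap$age < 50, ]
  expect_gt(mean(women$p), 0.3)
  expect_true(all(women$so <= women$p))
})

test_that("burn-in drives a distorted pyramid toward the stable structure", {
  # stationary high-fertility rates: the stable pyramid is strongly
  # young-heavy, far from the flat starting structure
  sched <- synthesize_schedule(1900, 80, 3.8, 3.8, e0_proxy = 1)
  stable <- srbsim:::.stable_structure(sched, 1900, 0.5122)
  flat <- initial_population(matrix(400, 51, 2))
  tv <- function(burnin) {
    cfg <- scenario_config(1900 + burnin, 1901 + burnin,
                           burnin_years = burnin, population_size = 40000,
                           n_replicates = 1, seed = 2)
    set.seed(2)
    pop <- run_burnin(cfg, sched, init = flat)
    snap <- population_snapshot(pop)
    counts <- table(factor(snap$age, levels = 0:50),
                    factor(snap$sex, levels = c("female", "male")))
    emp <- as.matrix(counts) / nrow(snap)
    sum(abs(emp - stable)) / 2
  }
  d5 <- tv(5)
  d45 <- tv(45)
  expect_lt(d45, d5 - 0.02)
  expect_lt(d45, 0.07)
})

test_that("identical configuration and seed give bit-identical ensembles", {
  sched <- tiny_schedule()
  cfg <- tiny_config()
  e1 <- run_scenario(cfg, sched)
  e2 <- run_scenario(cfg, sched)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_identical(e1$summary, e2$summary)
})

test_that("conservation holds exactly: conceptions = births + abortions", {
  sched <- tiny_schedule()
  ens <- run_scenario(tiny_config(n_replicates = 3), sched)
  tr <- ens$trajectories
  expect_identical(tr$conceptions,
                   tr$male_births + tr$female_births + tr$abortions)
  expect_identical(tr$abortions,
                   tr$abortions_p0 + tr$abortions_p1 + tr$abortions_p2 +
                     tr$abortions_p3plus)
})

test_that("without son preference, realized TFR tracks the schedule", {
  sched <- tiny_schedule()
  cfg <- tiny_config(sp_override = 0, population_size = 8000,
                     n_replicates = 10, params = param_set(sigma = 0, beta = 0))
  ens <- run_scenario(cfg, sched)
  s <- ens$summary
  sched_tfr <- unname(sched$schedule_tfr[as.character(s$year)])
  # hazards equal schedule rates; ensemble-mean realized TFR within a few
  # percent of the schedule TFR (Monte Carlo error)
  expect_lt(mean(abs(s$tfr_mean - sched_tfr) / sched_tfr), 0.04)
})

test_that("no-ability scenarios record zero abortions", {
  sched <- tiny_schedule()
  cfg <- tiny_config(ability_override = 0, n_replicates = 2)
  ens <- run_scenario(cfg, sched)
  expect_true(all(ens$trajectories$abortions == 0))
  expect_true(all(ens$trajectories$prop_able == 0))
})

test_that("scenario overrides pin the willing/able proportions", {
  sched <- tiny_schedule()
  ens_sp <- run_scenario(tiny_config(sp_override = 1, n_replicates = 1), sched)
  expect_true(all(ens_sp$trajectories$prop_willing == 1))
  ens_ab <- run_scenario(tiny_config(ability_override = 0.5,
                                     n_replicates = 3), sched)
  pa <- ens_ab$trajectories$prop_able
  expect_lt(abs(mean(pa) - 0.5), 0.02)
})

test_that("ensemble SRB is non-decreasing in the readiness scale", {
  sched <- tiny_schedule()
  mean_srb <- function(sig) {
    cfg <- tiny_config(population_size = 6000, n_replicates = 6,
                       params = param_set(sigma = sig, beta = 0.2,
                                          rho = 1, phi = 2))
    tr <- run_scenario(cfg, sched)$trajectories
    100 * sum(tr$male_births) / sum(tr$female_births)
  }
  srbs <- vapply(c(0, 1.2, 2.4), mean_srb, numeric(1))
  # common base seeds; allow slight Monte Carlo slack on the ordering
  expect_true(all(diff(srbs) > -0.5))
  expect_gt(srbs[3], srbs[1] + 5)
})

test_that("the no-abortion counterfactual has higher fertility", {
  sched <- tiny_schedule()
  cfg_with <- tiny_config(population_size = 8000, n_replicates = 8,
                          params = param_set(sigma = 2, beta = 0.3,
                                             rho = 1, phi = 2))
  cfg_without <- cfg_with
  cfg_without$params$sigma <- 0
  cfg_without$params$beta <- 0
  gap <- counterfactual_tfr_gap(run_scenario(cfg_with, sched),
                                run_scenario(cfg_without, sched))
  # abortions only remove births: mean gap positive, and per-year gaps
  # non-negative up to Monte Carlo noise
  expect_gt(mean(gap$gap), 0)
  expect_true(all(gap$gap > -0.15))
  expect_equal(gap$gap_pct, 100 * gap$gap / gap$tfr_with, tolerance = 1e-12)
  # identical ensembles give zero gap
  e <- run_scenario(tiny_config(n_replicates = 1), sched)
  g0 <- counterfactual_tfr_gap(e, e)
  expect_true(all(g0$gap == 0))
})

test_that("moving averages are centered with shrinking edges", {
  expect_equal(moving_average(rep(7, 10)), rep(7, 10))
  expect_equal(moving_average(1:5, window = 1), as.numeric(1:5))
  x <- c(100, 105, 110, 115, 120)
  expect_equal(moving_average(x, 5)[3], 110)
  expect_equal(moving_average(x, 5)[1], mean(x[1:3]))
  # missing values are skipped
  expect_equal(moving_average(c(1, NA, 3), 3)[2], 2)
  expect_error(moving_average(numeric(0)), "non-empty")
  expect_error(moving_average(1:3, window = 2), "odd")
})

test_that("ensemble summaries nest their percentile bands", {
  sched <- tiny_schedule()
  ens <- run_scenario(tiny_config(n_replicates = 5), sched)
  s <- ens$summary
  expect_true(all(s$srb_p2.5 <= s$srb_p5 & s$srb_p5 <= s$srb_p95 &
                    s$srb_p95 <= s$srb_p97.5))
  expect_true(all(s$tfr_p2.5 <= s$tfr_p5 & s$tfr_p5 <= s$tfr_p95 &
                    s$tfr_p95 <= s$tfr_p97.5))
  # single replicate: bands collapse onto the trajectory
  e1 <- run_scenario(tiny_config(n_replicates = 1), sched)
  expect_equal(e1$summary$srb_p2.5, e1$summary$srb_p97.5)
  expect_equal(e1$summary$srb_mean, e1$summary$srb_p95)
})

test_that("ensemble CSVs round-trip the required columns", {
  sched <- tiny_schedule()
  ens <- run_scenario(tiny_config(n_replicates = 2), sched)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  tr <- read.csv(file.path(dir, "trajectories.csv"))
  expect_true(all(c("replicate", "year", "male_births", "female_births",
                    "srb", "tfr", "abortions_p0", "abortions_p1",
                    "abortions_p2plus", "prop_willing", "prop_able") %in%
                    names(tr)))
  expect_equal(nrow(tr), 2 * 16)
  expect_true(file.exists(file.path(dir, "summary.csv")))
})
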