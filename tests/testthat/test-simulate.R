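test_that("a stable equilibrium is invariant under integration", {
  p <- cone_parameters()
  eqs <- find_equilibria(p)
  healthy <- Filter(function(e) identical(e$label, "healthy"), eqs)[[1]]
  sc <- cone_scenario(p, healthy$state, t_span = c(0, 240))
  tr <- integrate_scenario(sc)
  dev <- apply(abs(sweep(tr$state, 2, healthy$state)), 1, max)
  expect_lt(max(dev), 1e-6)
})

test_that("initial internal glucose selects the long-run state", {
  p <- cone_parameters()
  eqs <- find_equilibria(p)
  # higher initial glucose converges to the healthy state
  scA <- cone_scenario(p, cone_state(G = 2, LACT = 9.4), t_span = c(0, 2000))
  expect_identical(classify_outcome(integrate_scenario(scA, seq(0, 2000, 10)),
                                    eqs), "healthy")
  # low initial glucose converges to the pathological state
  scB <- cone_scenario(p, cone_state(G = 0.02, LACT = 9.4),
                       t_span = c(0, 2000))
  expect_identical(classify_outcome(integrate_scenario(scB, seq(0, 2000, 10)),
                                    eqs), "pathological")
  # at lambda = 0.09 even the low start recovers
  p9 <- cone_parameters(lambda = 0.09)
  eqs9 <- find_equilibria(p9)
  sc9 <- cone_scenario(p9, cone_state(G = 0.02, LACT = 9.4),
                       t_span = c(0, 3000))
  expect_identical(classify_outcome(integrate_scenario(sc9, seq(0, 3000, 10)),
                                    eqs9), "healthy")
})

test_that("a zero-length clamp window leaves the trajectory unchanged", {
  p <- cone_parameters()
  s0 <- cone_state(G = 2, LACT = 9.4)
  tr0 <- integrate_scenario(cone_scenario(p, s0, t_span = c(0, 120)))
  tr1 <- integrate_scenario(cone_scenario(p, s0, t_span = c(0, 120),
                                          clamp_windows = list(c(60, 60))))
  expect_equal(tr0$state, tr1$state, tolerance = 1e-7)
  expect_identical(tr0$time, tr1$time)
})

test_that("scenario validation enforces window invariants", {
  p <- cone_parameters()
  s0 <- cone_state(G = 2, LACT = 9.4)
  expect_error(cone_scenario(p, s0, t_span = c(0, 100),
                             clamp_windows = list(c(50, 150))),
               "outside t_span")
  expect_error(cone_scenario(p, s0, t_span = c(0, 100),
                             clamp_windows = list(c(60, 40))),
               "t_on <= t_off")
  expect_error(cone_scenario(p, s0, t_span = c(0, 100),
                             clamp_windows = list(c(10, 50), c(40, 80))),
               "overlap")
})

test_that("glucose deprivation starves the oxidative pools by 50 min", {
  tr <- run_deprivation_experiment("baseline_starved")
  d <- as.data.frame(tr)
  i50 <- which(d$time_min == 50)
  # oxidative intermediates collapse to sub-micromolar levels
  expect_lt(d$ACoA[i50], 5e-4)
  expect_lt(d$CIT[i50], 2e-3)
  expect_gt(d$ACoA[i50], 1e-5)
  # internal glucose decreases monotonically toward zero under the clamp
  expect_true(all(diff(d$G) <= 1e-12))
  expect_lt(utils::tail(d$G, 1), 0.01)
})

test_that("fuel supplementation sustains oxidative metabolism temporarily", {
  starved <- as.data.frame(run_deprivation_experiment("baseline_starved"))
  boosted <- as.data.frame(run_deprivation_experiment("g3p_boost"))
  mid <- starved$time_min >= 20 & starved$time_min <= 60
  expect_true(all(boosted$ACoA[mid] > starved$ACoA[mid]))
  expect_true(all(boosted$CIT[mid] > starved$CIT[mid]))
  # the rescue is transient: by the end of a longer run the boosted pools
  # have collapsed as well
  long <- as.data.frame(run_deprivation_experiment("g3p_boost", t_end = 150))
  expect_lt(utils::tail(long$ACoA, 1), 1e-3)
})

test_that("outcome classification agrees with an extended-integration oracle", {
  set.seed(77)
  p <- cone_parameters()
  eqs <- find_equilibria(p)
  st <- Filter(function(e) e$stable, eqs)
  for (ii in 1:10) {
    y0 <- cone_state(G = stats::runif(1, 0.001, 4),
                     G3P = stats::runif(1, 0, 0.5),
                     PYR = stats::runif(1, 0, 0.3),
                     LACT = stats::runif(1, 7, 11),
                     ACoA = stats::runif(1, 0, 0.2),
                     CIT = stats::runif(1, 0, 0.05))
    lab <- classify_outcome(y0, st, params = p, horizon = 2000)
    # oracle: plain long integration, five times the horizon
    f <- conemet:::.rhs_fun(p)
    sol <- deSolve::ode(y = y0, times = c(0, 10000), func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    yT <- pmax(as.numeric(sol[2, -1]), 0)
    d <- vapply(st, function(e) max(abs(yT - e$state)), 0)
    expect_identical(lab, st[[which.min(d)]]$label)
  }
})

test_that("trajectories export as tidy tables", {
  tr <- run_shutdown_experiment(alpha = 0.1, shutdown = c(40, 130),
                                t_end = 200)
  d <- as.data.frame(tr)
  expect_identical(names(d), c("time_min", "G", "G3P", "PYR", "LACT",
                               "ACoA", "CIT", "scenario_id"))
  expect_true(all(diff(d$time_min) > 0))
  expect_true(all(as.matrix(d[, 2:7]) >= 0))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(d))
})
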