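test_that("PRCC recovers monotone dependence on the linear benchmark", {
  b <- benchmark_function("additive_linear")
  s <- lhs_sample(b$factors, 120, seed = 4)
  # replicate the static response over a fake time grid; a little output
  # noise keeps the inert-factor partial correlation well defined (with a
  # noiseless deterministic response the output residual is numerically
  # zero and its correlation is meaningless)
  set.seed(44)
  y <- matrix(b$fun(s$values) + stats::rnorm(120, sd = 0.02),
              nrow = 120, ncol = 5)
  pr <- prcc_over_time(s, y, times = 1:5)
  expect_true(all(pr$value[, "x1"] > 0.95))
  expect_true(all(pr$value[, "x2"] < -0.95))
  expect_true(all(pr$p_value[, "x1"] < 1e-10))
  # the inert factor stays below the influence criteria at all times
  expect_true(all(abs(pr$value[, "x3"]) < 0.2))
  expect_true(all(pr$p_value[, "x3"] > 0.001))
  iv <- influential_set(pr, window = c(1, 5))
  expect_identical(iv$influential, c(TRUE, TRUE, FALSE))
})

test_that("PRCC is bounded, antisymmetric under output sign flip, and
           invariant under joint row permutation", {
  b <- benchmark_function("additive_linear")
  s <- lhs_sample(b$factors, 80, seed = 6)
  y <- b$fun(s$values) + stats::rnorm(80, sd = 0.05)
  pr <- prcc_over_time(s, matrix(y, ncol = 1))
  expect_true(all(abs(pr$value) <= 1))
  flip <- prcc_over_time(s, matrix(-y, ncol = 1))
  expect_equal(flip$value, -pr$value, tolerance = 1e-12)
  set.seed(8)
  perm <- sample.int(80)
  pr2 <- prcc_over_time(s$values[perm, ], matrix(y[perm], ncol = 1))
  expect_equal(unname(pr2$value), unname(pr$value), tolerance = 1e-12)
})

test_that("degenerate outputs yield missing PRCC, not zero", {
  b <- benchmark_function("constant")
  s <- lhs_sample(b$factors, 50, seed = 10)
  y <- matrix(b$fun(s$values), ncol = 1)
  pr <- prcc_over_time(s, y)
  expect_true(all(is.na(pr$value)))
})

test_that("PRCC refuses underdetermined designs", {
  b <- benchmark_function("additive_linear")
  s <- lhs_sample(b$factors, 5, seed = 1)
  expect_error(prcc_over_time(s, matrix(1:5, ncol = 1)), "N > k")
})

test_that("eFAST reproduces the analytic indices of the Ishigami function", {
  b <- benchmark_function("ishigami")
  d <- efast_sample(b$factors, Ns = 257, M = 4, Nr = 2, seed = 12)
  Y <- do.call(rbind, lapply(d$curves, function(cv)
    matrix(rep(b$fun(cv$values), 3), ncol = 3)))  # identical "time points"
  ef <- efast_over_time(d, Y, times = 1:3)
  for (tt in 1:3) {
    expect_equal(unname(ef$Si[tt, ]), unname(b$analytic$Si),
                 tolerance = 0.05)
  }
  # first-order never exceeds total-order beyond estimator slack
  expect_true(all(ef$Si <= ef$STi + 0.05))
})

test_that("eFAST separates additive structure (STi - Si small)", {
  b <- benchmark_function("additive_linear")
  d <- efast_sample(b$factors, Ns = 129, M = 4, seed = 14)
  Y <- do.call(rbind, lapply(d$curves, function(cv)
    matrix(b$fun(cv$values), ncol = 1)))
  ef <- efast_over_time(d, Y, times = 1)
  expect_equal(unname(ef$Si[1, ]), unname(b$analytic$Si), tolerance = 0.05)
  expect_true(all(ef$STi[1, ] - ef$Si[1, ] < 0.05))
  iv <- influential_set(ef, window = c(1, 1 + 1e-9))
})

test_that("a baseline sample row reproduces the baseline trajectory", {
  tmpl <- gsa_template(0.02)
  fl <- cone_factors("prcc_low")
  vals <- matrix(NA_real_, 2, nrow(fl),
                 dimnames = list(NULL, fl$name))
  base <- unclass(cone_parameters())
  for (nm in fl$name) {
    vals[, nm] <- if (nm %in% names(base)) base[[nm]] else
      switch(nm, G_0 = 0.02, G3P_0 = 0, PYR_0 = 0, LACT_0 = 9.4,
             ACoA_0 = 0, CIT_0 = 0)
  }
  vals[2, "alpha"] <- 0.4  # second row differs
  en <- evaluate_ensemble(vals, tmpl, output_times = seq(0, 60, 5))
  ref <- integrate_scenario(cone_scenario(cone_parameters(),
                                          cone_state(G = 0.02, LACT = 9.4),
                                          t_span = c(0, 240)),
                            seq(0, 60, 5))
  expect_equal(en$outputs$G[1, ], unname(ref$state[, "G"]),
               tolerance = 1e-5)
  expect_false(isTRUE(all.equal(en$outputs$G3P[2, ], en$outputs$G3P[1, ])))
})

test_that("ensemble evaluation is reproducible and flags unknown columns", {
  tmpl <- gsa_template(2)
  f <- cone_factors("prcc_high")[1:4, ]
  s <- lhs_sample(f, 6, seed = 21)
  en1 <- evaluate_ensemble(s, tmpl, output_times = seq(0, 30, 10))
  en2 <- evaluate_ensemble(s, tmpl, output_times = seq(0, 30, 10))
  expect_identical(en1$outputs$G, en2$outputs$G)
  bad <- s
  colnames(bad$values)[1] <- "mystery"
  expect_error(evaluate_ensemble(bad, tmpl, output_times = c(0, 10)),
               "mystery")
})

test_that("time-integrated indices summarise a series sensibly", {
  b <- benchmark_function("additive_linear")
  s <- lhs_sample(b$factors, 100, seed = 31)
  y <- matrix(b$fun(s$values), nrow = 100, ncol = 11)
  pr <- prcc_over_time(s, y, times = seq(0, 100, 10))
  avg <- integrate_series(pr, window = c(0, 100))
  expect_gt(avg[["x1"]], 0.95)
  expect_lt(avg[["x2"]], -0.95)
})
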