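test_that("baseline conditions are bistable with a low-glucose separatrix", {
  eqs <- find_equilibria(cone_parameters())
  expect_length(eqs, 3)
  expect_identical(vapply(eqs, function(e) e$label, ""),
                   c("pathological", "unstable", "healthy"))
  for (e in eqs) expect_lt(e$residual, 1e-9)
  gs <- vapply(eqs, function(e) e$state[["G"]], 0)
  # the healthy state holds far more glucose than the pathological one, and
  # the unstable separatrix sits at low glucose between them
  expect_gt(gs[3], 1)
  expect_lt(gs[1], 0.05)
  expect_true(gs[1] < gs[2] && gs[2] < gs[3])
})

test_that("raising GLUT1 efficiency to 0.09 leaves a unique healthy state", {
  eqs <- find_equilibria(cone_parameters(lambda = 0.09))
  st <- Filter(function(e) e$stable, eqs)
  expect_length(st, 1)
  expect_identical(st[[1]]$label, "healthy")
})

test_that("stability flags are consistent with the Jacobian eigenvalues", {
  eqs <- find_equilibria(cone_parameters())
  for (e in eqs) {
    ev <- eigen(cone_jacobian(e$state, e$params))$values
    expect_identical(e$stable, all(Re(ev) < 1e-8))
  }
})

test_that("equilibrium counts agree with a dense-multistart oracle", {
  set.seed(101)
  for (ii in 1:5) {
    p <- random_params()
    base <- find_equilibria(p, n_starts = 24, seed = 1729)
    dense <- find_equilibria(p, n_starts = 240, seed = 2904)
    expect_identical(length(base), length(dense))
    if (length(base)) {
      a <- t(vapply(base, function(e) e$state, numeric(6)))
      b <- t(vapply(dense, function(e) e$state, numeric(6)))
      expect_equal(a[order(a[, 1]), ], b[order(b[, 1]), ], tolerance = 1e-6)
    }
  }
})

test_that("branch continuation finds two folds and matches a bisection oracle", {
  p <- cone_parameters(G_E = 5)
  br <- continue_branch(p, "lambda", c(0.005, 0.25))
  expect_length(br$folds, 2)
  fold_vals <- sort(vapply(br$folds, function(f) f$value, 0))
  # each fold has a near-singular Jacobian
  for (f in br$folds) {
    pr <- p; pr["lambda"] <- f$value
    ev <- eigen(cone_jacobian(f$state, pr))$values
    expect_lt(min(abs(Re(ev))), 1e-5)
  }
  # bisection on the stable-equilibrium count brackets the same locations
  for (fv in fold_vals) {
    lo <- fv - 5e-3; hi <- fv + 5e-3
    n_lo <- n_stable_at(p, lo); n_hi <- n_stable_at(p, hi)
    expect_true(n_lo != n_hi)
    for (k in 1:14) {
      mid <- (lo + hi) / 2
      if (n_stable_at(p, mid) == n_lo) lo <- mid else hi <- mid
    }
    expect_lt(abs((lo + hi) / 2 - fv), 1e-3)
  }
})

test_that("branch labels are continuous and ordered by internal glucose", {
  br <- label_branches(continue_branch(cone_parameters(G_E = 5), "lambda",
                                       c(0.005, 0.25)))
  pts <- br$points
  expect_setequal(unique(pts$label),
                  c("pathological", "unstable", "healthy"))
  # no label switch without a stability change (fold crossing)
  sw <- which(pts$label[-1] != pts$label[-nrow(pts)])
  for (s in sw)
    expect_true(pts$stable[s] != pts$stable[s + 1])
  # coexisting stable branches are ordered
  expect_gt(mean(pts$G[pts$label == "healthy"]),
            mean(pts$G[pts$label == "pathological"]))
  # endpoints match direct equilibrium location
  p_end <- cone_parameters(G_E = 5)
  p_end["lambda"] <- 0.005
  direct <- find_equilibria(p_end)
  expect_equal(pts$G[1],
               direct[[1]]$state[["G"]], tolerance = 1e-6)
})

test_that("branch labels agree with basin membership from integration", {
  p <- cone_parameters()
  eqs <- find_equilibria(p)
  st <- Filter(function(e) e$stable, eqs)
  for (e in st) {
    # a small perturbation of a stable equilibrium flows back to it
    y0 <- pmax(e$state * 1.02 + 1e-5, 0)
    lab <- classify_outcome(y0, st, params = p, horizon = 3000)
    expect_identical(lab, e$label)
  }
})

test_that("random start counts are reproducible under the seed contract", {
  p <- cone_parameters(G_E = 8)
  a <- find_equilibria(p, n_starts = 16, seed = 5)
  b <- find_equilibria(p, n_starts = 16, seed = 5)
  expect_identical(lapply(a, function(e) e$state),
                   lapply(b, function(e) e$state))
})
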