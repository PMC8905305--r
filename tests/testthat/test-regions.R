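test_that("traced fold points satisfy the saddle-node conditions", {
  p <- cone_parameters(G_E = 10)
  br <- continue_branch(p, "alpha", c(0.02, 1))
  expect_length(br$folds, 2)
  sf <- br$folds[[which.min(vapply(br$folds, function(f) f$value, 0))]]
  fc <- trace_fold_curve(p, "alpha", "G_E", sf,
                         range1 = c(0.001, 1.1), range2 = c(2, 12),
                         max_steps = 120)
  pts <- fc$points
  expect_gt(nrow(pts), 5)
  idx <- unique(round(seq(1, nrow(pts), length.out = 6)))
  for (ii in idx) {
    pr <- p
    pr["alpha"] <- pts$alpha[ii]; pr["G_E"] <- pts$G_E[ii]
    s <- as.numeric(pts[ii, conemet:::.state_names])
    expect_lt(max(abs(cone_rhs(s, pr))), 1e-8)
    ev <- eigen(cone_jacobian(s, pr))$values
    expect_lt(min(abs(Re(ev))), 1e-5)
  }
})

test_that("fold-curve points are re-detected by fresh one-parameter continuation", {
  p <- cone_parameters(G_E = 10)
  br <- continue_branch(p, "alpha", c(0.02, 1))
  sf <- br$folds[[which.min(vapply(br$folds, function(f) f$value, 0))]]
  fc <- trace_fold_curve(p, "alpha", "G_E", sf,
                         range1 = c(0.001, 1.1), range2 = c(2, 12),
                         max_steps = 120)
  pts <- fc$points
  idx <- unique(round(seq(2, nrow(pts) - 1, length.out = 3)))
  for (ii in idx) {
    pr <- p; pr["G_E"] <- pts$G_E[ii]
    br2 <- continue_branch(pr, "alpha", c(0.002, 1))
    expect_gt(length(br2$folds), 0)
    best <- min(abs(vapply(br2$folds, function(f) f$value, 0) -
                      pts$alpha[ii]))
    expect_lt(best, 1e-3)
  }
})

test_that("the two fold curves in (alpha, G_E) approach a cusp near the origin", {
  p <- cone_parameters(G_E = 10)
  br <- continue_branch(p, "alpha", c(0.02, 1))
  fl <- vapply(br$folds, function(f) f$value, 0)
  lo <- br$folds[[which.min(fl)]]; hi <- br$folds[[which.max(fl)]]
  fc1 <- trace_fold_curve(p, "alpha", "G_E", lo,
                          range1 = c(5e-4, 1.1), range2 = c(0.15, 12))
  fc2 <- trace_fold_curve(p, "alpha", "G_E", hi,
                          range1 = c(5e-4, 1.1), range2 = c(0.15, 12))
  cusp <- estimate_cusp(fc1, fc2)
  expect_lt(cusp[["alpha"]], 0.05)
  expect_lt(cusp[["G_E"]], 1.5)
})

test_that("swapping the roles of the two parameters traces the same locus", {
  p <- cone_parameters(G_E = 10)
  br <- continue_branch(p, "alpha", c(0.02, 1))
  sf <- br$folds[[which.min(vapply(br$folds, function(f) f$value, 0))]]
  fc_a <- trace_fold_curve(p, "alpha", "G_E", sf,
                           range1 = c(0.001, 1.1), range2 = c(4, 12),
                           max_steps = 80)
  fc_b <- trace_fold_curve(p, "G_E", "alpha", list(state = sf$state,
                                                   value = 10, v = sf$v),
                           range1 = c(4, 12), range2 = c(0.001, 1.1),
                           max_steps = 80)
  # compare G_E at matched alpha by interpolation
  a <- fc_a$points; b <- fc_b$points
  common <- range(max(min(a$alpha), min(b$alpha)),
                  min(max(a$alpha), max(b$alpha)))
  probe <- seq(common[1], common[2], length.out = 5)
  ga <- stats::approx(a$alpha, a$G_E, probe)$y
  gb <- stats::approx(b$alpha, b$G_E, probe)$y
  expect_equal(ga, gb, tolerance = 1e-3)
})

test_that("region-map labels change only across the fold curves", {
  p <- cone_parameters(G_E = 10)
  br <- continue_branch(p, "alpha", c(0.02, 1))
  fl <- sort(vapply(br$folds, function(f) f$value, 0))
  rm <- map_regions(p, "alpha", c(0.05, 0.8), "G_E", c(8, 12),
                    resolution = c(12, 5), n_starts = 4)
  # along each G_E row, labels partition as healthy / bistable / pathological
  order_ref <- c("healthy-only", "bistable", "pathological-only")
  for (jj in seq_along(rm$grid2)) {
    runs <- rle(rm$label[, jj])$values
    expect_lte(length(runs), 3)
    # increasing alpha can only move the regime towards pathological
    expect_true(all(diff(match(runs, order_ref)) > 0))
  }
  # cross-check the middle row against the fold values at G_E = 10
  jmid <- which.min(abs(rm$grid2 - 10))
  labs <- rm$label[, jmid]
  disagree <- 0
  for (ii in seq_along(rm$grid1)) {
    a <- rm$grid1[ii]
    want <- if (a < fl[1]) "healthy-only" else if (a > fl[2])
      "pathological-only" else "bistable"
    if (labs[ii] != want) disagree <- disagree + 1
  }
  expect_lte(disagree / length(labs), 0.01)
})

test_that("threshold bisection agrees with a fine uniform scan", {
  p <- cone_parameters()
  thr <- pathological_only_threshold(p, lambda_range = c(0.062, 0.093),
                                     G_E_range = c(0.5, 4), n_lambda = 6,
                                     tol = 0.02, n_starts = 4)
  ges <- seq(thr - 0.3, thr + 0.3, by = 0.05)
  lams <- seq(0.062, 0.093, length.out = 6)
  fine <- vapply(ges, function(GE) {
    for (l in lams) {
      pr <- p; pr["lambda"] <- l; pr["G_E"] <- GE
      st <- Filter(function(e) e$stable,
                   find_equilibria(pr, n_starts = 4))
      if (length(st) >= 2 ||
          (length(st) == 1 && st[[1]]$label == "healthy")) return(FALSE)
    }
    TRUE
  }, TRUE)
  # the fine scan flips from pathological-only to not within one grid cell
  # of the bisection result
  flip <- ges[max(which(fine))]
  expect_lt(abs(flip - thr), 0.076)
})
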