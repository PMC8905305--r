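# ---- two-parameter analysis: fold curves and regime maps -------------------

#' Trace a saddle-node curve in two parameters
#'
#' Continues the augmented fold system `{rhs = 0, J v = 0, ||v||^2 = 1}` in
#' (state, null vector, p1, p2) by pseudo-arclength continuation, starting
#' from a fold point obtained in a one-parameter continuation
#' ([continue_branch()]). The trace stops at the boundary of the requested
#' ranges, or earlier if the fold is lost (e.g. close to a cusp), in which
#' case the curve is truncated and flagged.
#'
#' @param params base parameter set (values of `p1`, `p2` are overridden
#'   along the curve).
#' @param p1,p2 names of the two active parameters.
#' @param seed_fold a fold point (list with `state`, `value`, optionally `v`)
#'   from [continue_branch()], located at `params[[p2]]` for the `p2` value
#'   in `params`.
#' @param range1,range2 admissible intervals for `p1` and `p2`.
#' @param step0 initial arclength step (in normalised parameter units).
#' @param max_steps cap on steps per direction.
#' @return object of class `"cone_fold_curve"`: data frame `points` with
#'   columns `p1`, `p2` and the six fold-state columns, plus `truncated`.
#' @export
trace_fold_curve <- function(params, p1, p2, seed_fold,
                             range1, range2,
                             step0 = 0.01, max_steps = 800) {
  validate_parameters(params)
  range1 <- sort(as.numeric(range1)); range2 <- sort(as.numeric(range2))
  sc1 <- diff(range1); sc2 <- diff(range2)

  Fsys <- function(u) {
    x <- pmax(u[1:6], 0); v <- u[7:12]
    pr <- unclass(params)
    pr[p1] <- max(u[13], 0); pr[p2] <- max(u[14], 0)
    J <- .jac_raw(x, pr)
    fx <- as.numeric(recombine_fluxes(.fluxes_raw(x, pr)))
    c(fx, as.numeric(J %*% v), sum(v^2) - 1)
  }
  jacFD <- function(u, fy) {
    A <- matrix(0, 13, 14)
    for (jj in 1:14) {
      h <- 1e-7 * max(1, abs(u[jj]))
      up <- u; up[jj] <- up[jj] + h
      A[, jj] <- (Fsys(up) - fy) / h
    }
    A
  }
  # weights make the arclength roughly isotropic in normalised parameters
  wts <- c(rep(1, 12), 1 / sc1, 1 / sc2)

  tangent <- function(u, orient = NULL) {
    fy <- Fsys(u)
    A <- jacFD(u, fy)
    z <- svd(A, nv = 14)$v[, 14]
    z <- z / sqrt(sum((z * wts)^2))
    if (!is.null(orient) && sum(z * orient * wts^2) < 0) z <- -z
    z
  }
  correct <- function(u_pred, z0) {
    u <- u_pred
    for (it in 1:25) {
      fy <- Fsys(u)
      g <- sum(z0 * wts^2 * (u - u_pred))
      if (max(abs(fy)) < 1e-9 && abs(g) < 1e-10)
        return(list(u = u, iters = it))
      A <- rbind(jacFD(u, fy), z0 * wts^2)
      du <- tryCatch(solve(A, -c(fy, g)), error = function(e) NULL)
      if (is.null(du)) return(NULL)
      u <- u + du
    }
    NULL
  }

  # initial point: re-solve the fold at the seed in p1 with p2 fixed
  p2val <- params[[p2]]
  f0 <- .solve_fold({
    pr <- params; pr[p2] <- p2val; pr
  }, p1, seed_fold$state, seed_fold$value, seed_fold$v %||% NULL)
  if (is.null(f0)) stop("could not re-solve the seed fold point")
  u0 <- c(as.numeric(f0$state), f0$v, f0$value, p2val)

  run_dir <- function(dirsign) {
    u <- u0
    z <- tangent(u)
    z <- z * dirsign
    ds <- step0
    pts <- list()
    trunc <- FALSE
    for (it in seq_len(max_steps)) {
      res <- correct(u + ds * z, z)
      if (is.null(res)) {
        ds <- ds / 2
        if (ds < 1e-6) { trunc <- TRUE; break }
        next
      }
      u <- res$u
      z <- tangent(u, orient = z)
      pts[[length(pts) + 1]] <- c(u[13], u[14], pmax(u[1:6], 0))
      ds <- if (res$iters <= 3) min(ds * 2, step0 * 10) else
            if (res$iters >= 8) ds / 2 else ds
      if (u[13] < range1[1] || u[13] > range1[2] ||
          u[14] < range2[1] || u[14] > range2[2]) break
    }
    list(pts = pts, trunc = trunc)
  }
  fwd <- run_dir(1)
  bwd <- run_dir(-1)
  all_pts <- c(rev(bwd$pts), list(c(u0[13], u0[14], pmax(u0[1:6], 0))),
               fwd$pts)
  pm <- do.call(rbind, all_pts)
  colnames(pm) <- c(p1, p2, .state_names)
  structure(list(points = as.data.frame(pm),
                 p1 = p1, p2 = p2,
                 truncated = fwd$trunc || bwd$trunc,
                 params = params),
            class = "cone_fold_curve")
}

#' @export
print.cone_fold_curve <- function(x, ...) {
  cat("fold curve in (", x$p1, ", ", x$p2, "): ", nrow(x$points),
      " points", if (x$truncated) " [truncated]", "\n", sep = "")
  invisible(x)
}

#' Map dynamic regimes over a two-parameter plane
#'
#' Counts stable equilibria on a grid over two parameters (via
#' [find_equilibria()]) and assigns each cell a regime label:
#' `"healthy-only"`, `"bistable"` or `"pathological-only"`.
#'
#' @param params base parameter set.
#' @param p1,p2 names of the grid parameters.
#' @param range1,range2 numeric length-2 ranges.
#' @param resolution integer length-1 or -2; grid size (minimum 20 per axis
#'   for production maps, smaller grids are allowed for quick looks).
#' @param n_starts random multistarts per cell passed to [find_equilibria()]
#'   (chain-consistent deterministic starts are always included).
#' @param seed RNG seed for the multistarts.
#' @return object of class `"cone_region_map"`: list with `p1`, `p2`,
#'   `grid1`, `grid2`, `label` (matrix `length(grid1) x length(grid2)`),
#'   `n_stable` (same shape).
#' @examples
#' \donttest{
#' rm <- map_regions(cone_parameters(), "lambda", c(0.05, 0.1),
#'                   "G_E", c(5, 15), resolution = c(8, 6))
#' table(rm$label)
#' }
#' @export
map_regions <- function(params, p1, range1, p2, range2,
                        resolution = c(25, 25), n_starts = 8,
                        seed = 1729) {
  validate_parameters(params)
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  g1 <- seq(range1[1], range1[2], length.out = resolution[1])
  g2 <- seq(range2[1], range2[2], length.out = resolution[2])
  lab <- matrix(NA_character_, length(g1), length(g2))
  nst <- matrix(NA_integer_, length(g1), length(g2))
  for (jj in seq_along(g2)) {
    for (ii in seq_along(g1)) {
      pr <- params; pr[p1] <- g1[ii]; pr[p2] <- g2[jj]
      eqs <- find_equilibria(pr, n_starts = n_starts, seed = seed)
      st <- Filter(function(e) e$stable, eqs)
      nst[ii, jj] <- length(st)
      lab[ii, jj] <- if (length(st) >= 2) "bistable"
      else if (length(st) == 1)
        paste0(st[[1]]$label, "-only")
      else "none"
    }
  }
  structure(list(p1 = p1, p2 = p2, grid1 = g1, grid2 = g2,
                 label = lab, n_stable = nst, params = params),
            class = "cone_region_map")
}

#' @export
print.cone_region_map <- function(x, ...) {
  cat("regime map over (", x$p1, ", ", x$p2, "), ",
      length(x$grid1), " x ", length(x$grid2), " cells:\n", sep = "")
  print(table(x$label))
  invisible(x)
}

#' @export
as.data.frame.cone_region_map <- function(x, ...) {
  d <- expand.grid(x$grid1, x$grid2)
  names(d) <- c(x$p1, x$p2)
  d$label <- as.vector(x$label)
  d$n_stable <- as.vector(x$n_stable)
  d
}

#' External-glucose ceiling of the pathological-only regime
#'
#' Finds the largest external-glucose level below which the system is
#' pathological-only for every GLUT1 efficiency in a scan range, refined by
#' bisection to a requested tolerance. The default scan range for `lambda`
#' is the physiological interval \[0.062, 0.093\]; the wider interval
#' \[0.02, 0.15\] reproduces the qualitative maps.
#'
#' @param params base parameter set (`alpha` etc. at their intended values).
#' @param lambda_range scan interval for the GLUT1 efficiency.
#' @param G_E_range search interval for the ceiling.
#' @param n_lambda number of scan points across `lambda_range`.
#' @param tol bisection tolerance in mM.
#' @param n_starts multistarts per equilibrium count.
#' @param seed RNG seed for the multistarts.
#' @return the ceiling (mM), with attribute `"bracket"`.
#' @export
pathological_only_threshold <- function(params = cone_parameters(),
                                        lambda_range = c(0.062, 0.093),
                                        G_E_range = c(0.05, 5),
                                        n_lambda = 16, tol = 0.01,
                                        n_starts = 8, seed = 1729) {
  validate_parameters(params)
  lams <- seq(lambda_range[1], lambda_range[2], length.out = n_lambda)
  path_only <- function(GE) {
    for (l in lams) {
      pr <- params; pr["lambda"] <- l; pr["G_E"] <- GE
      eqs <- find_equilibria(pr, n_starts = n_starts, seed = seed)
      st <- Filter(function(e) e$stable, eqs)
      if (length(st) >= 2) return(FALSE)
      if (length(st) == 1 && st[[1]]$label == "healthy") return(FALSE)
    }
    TRUE
  }
  lo <- G_E_range[1]; hi <- G_E_range[2]
  if (!path_only(lo))
    stop("lower end of G_E_range is not pathological-only; extend the range")
  if (path_only(hi))
    stop("upper end of G_E_range is still pathological-only; extend the range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (path_only(mid)) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi))
}

#' Estimate the cusp point of two fold curves
#'
#' The cusp is located as the point where the two saddle-node branches
#' coalesce, estimated by minimising the distance between the traced curves
#' in normalised parameter coordinates.
#'
#' @param curve1,curve2 `cone_fold_curve` objects over the same parameters.
#' @return named numeric length-2 (the two parameter values at the cusp
#'   estimate), with attribute `"distance"` (normalised gap between curves).
#' @export
estimate_cusp <- function(curve1, curve2) {
  stopifnot(curve1$p1 == curve2$p1, curve1$p2 == curve2$p2)
  a <- as.matrix(curve1$points[, 1:2])
  b <- as.matrix(curve2$points[, 1:2])
  sc <- pmax(apply(rbind(a, b), 2, function(x) diff(range(x))), 1e-12)
  an <- sweep(a, 2, sc, "/"); bn <- sweep(b, 2, sc, "/")
  dmin <- Inf; best <- c(NA, NA)
  for (ii in seq_len(nrow(an))) {
    d2 <- colSums((t(bn) - an[ii, ])^2)
    jj <- which.min(d2)
    if (d2[jj] < dmin) {
      dmin <- d2[jj]
      best <- (a[ii, ] + b[jj, ]) / 2
    }
  }
  structure(stats::setNames(best, c(curve1$p1, curve1$p2)),
            distance = sqrt(dmin))
}

#' Export a regime map as CSV
#'
#' @param map a `cone_region_map`.
#' @param file output CSV path (`p1`, `p2`, `label`, `n_stable`).
#' @export
write_region_map <- function(map, file) {
  utils::write.csv(as.data.frame(map), file, row.names = FALSE)
  invisible(file)
}
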