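# ---- Newton solver for equilibria -----------------------------------------

# damped Newton iteration on cone_rhs(.) = 0 using the analytic Jacobian;
# returns the root (>= 0 componentwise) or NULL
.newton_eq <- function(start, params, tol = 1e-11, maxit = 80) {
  p <- unclass(params)
  y <- pmax(as.numeric(start), 0)
  f <- function(s) as.numeric(recombine_fluxes(.fluxes_raw(s, p)))
  fy <- f(y)
  for (it in seq_len(maxit)) {
    if (max(abs(fy)) < tol) break
    J <- .jac_raw(y, p)
    dy <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(dy)) return(NULL)
    lam <- 1
    repeat {
      yn <- pmax(y + lam * dy, 0)
      fn <- f(yn)
      if (all(is.finite(fn)) &&
          (max(abs(fn)) <= (1 - 0.25 * lam) * max(abs(fy)) + 1e-14)) {
        y <- yn; fy <- fn; break
      }
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
  }
  if (max(abs(fy)) < tol) y else NULL
}

# unvalidated flux/jacobian kernels (hot path)
.fluxes_raw <- function(s, p, clamp = FALSE) {
  G <- s[1]; G3P <- s[2]; PYR <- s[3]; LACT <- s[4]; ACoA <- s[5]; CIT <- s[6]
  grad <- if (clamp) 0 else p[["G_E"]] - G
  R <- p[["delta"]] * G3P
  list(a = p[["lambda"]] * p[["n"]] * grad,
       b = p[["lambda"]] * grad * p[["V_G"]] * (R / (p[["K_G"]] + R))^2,
       c = p[["q"]] * p[["V_G3P"]] * G / (p[["K_G3P"]] + G),
       d = (1 - p[["q"]]) * p[["V_PYR"]] * G^2 / (p[["K_PYR"]]^2 + G^2) /
         (1 + p[["beta"]] * CIT),
       f = p[["psi"]] * max(LACT - p[["L_E"]], 0),
       g = p[["psi"]] * p[["V_LACT"]] * PYR / (p[["K_LACT"]] + PYR),
       h = (p[["gamma"]] / p[["kappa"]]) * max(p[["L_E"]] - LACT, 0),
       i = p[["rho"]] * p[["V_ACoA"]] * PYR / (p[["K_ACoA"]] + PYR),
       j = p[["V_CIT"]] * ACoA / (p[["K_CIT"]] + ACoA),
       k = p[["alpha"]] * .KU * G3P / (.KU + G3P),
       l = p[["phi"]] * CIT,
       m = .R0 * G3P)
}

.jac_raw <- function(s, p, clamp = FALSE) {
  J <- .cone_jacobian_raw(s, p, clamp)
  dimnames(J) <- list(.state_names, .state_names)
  J
}

# chain-consistent start states: for a grid of G values, slave the remaining
# pools to their conditional equilibria. Every equilibrium of the full system
# lies on this manifold, which makes the grid an efficient deterministic
# complement to random multistarts.
.chain_starts <- function(params, n_grid = 40) {
  p <- unclass(params)
  gmax <- max(p[["G_E"]], 1e-3)
  Gs <- c(0, exp(seq(log(1e-6), log(gmax * 0.999), length.out = n_grid)))
  out <- matrix(0, nrow = length(Gs), ncol = 6)
  for (ii in seq_along(Gs)) {
    G <- Gs[ii]
    cc <- p[["q"]] * p[["V_G3P"]] * G / (p[["K_G3P"]] + G)
    # G3P from c = alpha*KU*x/(KU+x) + r0*x  (positive root of a quadratic)
    A <- .R0
    B <- p[["alpha"]] * .KU + .R0 * .KU - cc
    Cc <- -cc * .KU
    G3P <- if (cc <= 0) 0 else (-B + sqrt(B^2 - 4 * A * Cc)) / (2 * A)
    CIT <- 0
    PYR <- 0
    for (it in 1:25) {
      d <- (1 - p[["q"]]) * p[["V_PYR"]] * G^2 / (p[["K_PYR"]]^2 + G^2) /
        (1 + p[["beta"]] * CIT)
      a1 <- p[["psi"]] * p[["V_LACT"]]; b1 <- p[["K_LACT"]]
      a2 <- p[["rho"]] * p[["V_ACoA"]]; b2 <- p[["K_ACoA"]]
      PYR <- if (d <= 0 || a1 + a2 <= d) 0 else {
        Bq <- a1 * b2 + a2 * b1 - d * (b1 + b2)
        (-Bq + sqrt(Bq^2 + 4 * (a1 + a2 - d) * d * b1 * b2)) /
          (2 * (a1 + a2 - d))
      }
      i <- a2 * PYR / (b2 + PYR)
      k <- p[["alpha"]] * .KU * G3P / (.KU + G3P)
      inp <- i + k
      CITn <- if (inp >= p[["V_CIT"]]) p[["V_CIT"]] / p[["phi"]] else
        inp / p[["phi"]]
      if (abs(CITn - CIT) < 1e-13) { CIT <- CITn; break }
      CIT <- CITn
    }
    g <- p[["psi"]] * p[["V_LACT"]] * PYR / (p[["K_LACT"]] + PYR)
    LACT <- p[["L_E"]] + g / p[["psi"]]
    inp <- p[["rho"]] * p[["V_ACoA"]] * PYR / (p[["K_ACoA"]] + PYR) +
      p[["alpha"]] * .KU * G3P / (.KU + G3P)
    ACoA <- if (inp < p[["V_CIT"]])
      p[["K_CIT"]] * inp / (p[["V_CIT"]] - inp) else 1
    out[ii, ] <- c(G, G3P, PYR, LACT, ACoA, CIT)
  }
  out
}

#' Locate the equilibria of the model
#'
#' Finds the steady states of the vector field by damped Newton iteration
#' from a deterministic set of chain-consistent start states plus random
#' multistart guesses drawn log-uniformly over \[1e-6, 30\] mM (and the
#' origin neighbourhood), then de-duplicates the roots (1e-6 mM max-norm)
#' and classifies each by the eigenvalues of the analytic Jacobian.
#'
#' Stable equilibria are labelled by their position: where two stable states
#' coexist, the one with larger internal glucose is `"healthy"` and the other
#' `"pathological"`; an isolated stable state is labelled by its G3P level
#' (the healthy branch carries two orders of magnitude more G3P than the
#' pathological one in all explored regimes). Unstable states are labelled
#' `"unstable"`.
#'
#' @param params a [cone_parameters()] vector.
#' @param n_starts number of random multistart guesses.
#' @param seed RNG seed for the random starts (default 1729).
#' @param tol residual tolerance (max norm of the vector field).
#' @return a list of equilibrium points; each is a list with `state`,
#'   `params`, `eigenvalues`, `stable`, `label`, `residual`.
#' @examples
#' eqs <- find_equilibria(cone_parameters(), n_starts = 24)
#' vapply(eqs, function(e) e$label, "")
#' @export
find_equilibria <- function(params, n_starts = 48, seed = 1729,
                            tol = 1e-11) {
  validate_parameters(params)
  if (n_starts < 1) stop("n_starts must be >= 1")
  starts <- .chain_starts(params)
  if (n_starts > 0) {
    rs <- withr_seed(seed, {
      matrix(exp(stats::runif(6 * n_starts, log(1e-6), log(30))),
             ncol = 6)
    })
    starts <- rbind(starts, rs, rep(1e-5, 6))
  }
  roots <- list()
  for (r in seq_len(nrow(starts))) {
    y <- .newton_eq(starts[r, ], params, tol = tol)
    if (is.null(y)) next
    if (!length(roots) ||
        all(vapply(roots, function(z) max(abs(z - y)) >= 1e-6, TRUE)))
      roots[[length(roots) + 1]] <- y
  }
  eqs <- lapply(roots, function(y) {
    J <- .jac_raw(y, unclass(params))
    ev <- eigen(J, only.values = TRUE)$values
    list(state = stats::setNames(y, .state_names),
         params = params,
         eigenvalues = ev,
         stable = all(Re(ev) < 1e-8),
         residual = max(abs(cone_rhs(y, params))),
         label = NA_character_)
  })
  # order by internal glucose and label
  if (length(eqs)) {
    eqs <- eqs[order(vapply(eqs, function(e) e$state[["G"]], 0))]
    st <- which(vapply(eqs, function(e) e$stable, TRUE))
    if (length(st) >= 2) {
      gs <- vapply(eqs[st], function(e) e$state[["G"]], 0)
      if (max(gs) - min(gs) < 1e-9)
        stop("ambiguous labelling: coexisting stable equilibria with equal [G]")
      for (ii in seq_along(st))
        eqs[[st[ii]]]$label <- if (ii == which.max(gs)) "healthy"
                               else "pathological"
    } else if (length(st) == 1) {
      eqs[[st]]$label <-
        if (eqs[[st]]$state[["G3P"]] >= 0.05) "healthy" else "pathological"
    }
    for (ii in seq_along(eqs))
      if (!eqs[[ii]]$stable) eqs[[ii]]$label <- "unstable"
  }
  eqs
}

# run expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- one-parameter continuation -------------------------------------------

# parameter derivative of the vector field (central differences)
.dF_dp <- function(y, params, vary) {
  pv <- params[[vary]]
  h <- max(1e-7, 1e-7 * abs(pv))
  p1 <- params; p1[vary] <- pv + h
  p2 <- params; p2[vary] <- pv - h
  (as.numeric(cone_rhs(y, p1)) - as.numeric(cone_rhs(y, p2))) / (2 * h)
}

# tangent of the equilibrium curve in (state, p), normalised, oriented
.tangent <- function(y, params, vary, orient = NULL) {
  J <- .jac_raw(y, unclass(params))
  Fp <- .dF_dp(y, params, vary)
  A <- rbind(cbind(J, Fp), c(rep(0, 6), 1))
  z <- tryCatch(solve(A, c(rep(0, 6), 1)), error = function(e) NULL)
  if (is.null(z)) {  # fold region: parameter component ~ 0; use SVD null space
    M <- cbind(J, Fp)
    z <- svd(M, nv = 7)$v[, 7]
  }
  z <- z / sqrt(sum(z^2))
  if (!is.null(orient) && sum(z * orient) < 0) z <- -z
  z
}

# corrector: Newton on {rhs = 0, z0 . (u - u_pred) = 0}; steps that wander
# further than the predictor distance indicate a branch jump and are rejected
.correct <- function(u_pred, z0, params, vary, ds, tol = 1e-11, maxit = 25) {
  u <- u_pred
  for (it in seq_len(maxit)) {
    pr <- params; pr[vary] <- u[7]
    fy <- as.numeric(cone_rhs(pmax(u[1:6], 0), pr))
    g <- sum(z0 * (u - u_pred))
    if (max(abs(fy)) < tol && abs(g) < 1e-12)
      return(list(u = u, iters = it))
    J <- .jac_raw(pmax(u[1:6], 0), unclass(pr))
    Fp <- .dF_dp(pmax(u[1:6], 0), pr, vary)
    A <- rbind(cbind(J, Fp), z0)
    du <- tryCatch(solve(A, -c(fy, g)), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    u <- u + du
    if (u[7] < 0) return(NULL)
    if (sqrt(sum((u - u_pred)^2)) > 3 * ds) return(NULL)
  }
  NULL
}

# solve the fold (saddle-node) system {rhs = 0, J v = 0, ||v||^2 = 1} in
# (state, v, p) by Newton with finite-difference derivatives of J v
.solve_fold <- function(params, vary, x0, p0, v0 = NULL, tol = 1e-9) {
  if (is.null(v0)) {
    J <- .jac_raw(x0, unclass(params))
    sv <- svd(J)
    v0 <- sv$v[, 6]
  }
  u <- c(x0, v0, p0)
  Fsys <- function(u) {
    x <- pmax(u[1:6], 0); v <- u[7:12]
    pr <- unclass(params); pr[vary] <- max(u[13], 0)
    J <- .jac_raw(x, pr)
    fx <- as.numeric(recombine_fluxes(.fluxes_raw(x, pr)))
    c(fx, as.numeric(J %*% v), sum(v^2) - 1)
  }
  fy <- Fsys(u)
  for (it in 1:60) {
    if (max(abs(fy)) < tol) break
    A <- matrix(0, 13, 13)
    h0 <- 1e-7
    for (jj in 1:13) {
      h <- h0 * max(1, abs(u[jj]))
      up <- u; up[jj] <- up[jj] + h
      A[, jj] <- (Fsys(up) - fy) / h
    }
    du <- tryCatch(solve(A, -fy), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    lam <- 1
    repeat {
      un <- u + lam * du
      fn <- Fsys(un)
      if (all(is.finite(fn)) &&
          max(abs(fn)) <= (1 - 0.25 * lam) * max(abs(fy)) + 1e-13) {
        u <- un; fy <- fn; break
      }
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
  }
  if (max(abs(fy)) >= tol) return(NULL)
  list(state = stats::setNames(pmax(u[1:6], 0), .state_names),
       v = u[7:12], value = u[13])
}

#' Continue an equilibrium branch in one parameter
#'
#' Pseudo-arclength continuation (tangent predictor, Newton corrector on the
#' arclength-constrained system) of the equilibrium curve as one named
#' parameter varies over an interval. Saddle-node (fold) points are detected
#' by sign changes of the parameter component of the tangent and refined by
#' solving the augmented fold system to an eigenvalue magnitude below 1e-6.
#'
#' @param params parameter set defining all non-varied parameters.
#' @param vary name of the continuation parameter (e.g. `"lambda"`).
#' @param range numeric length-2 interval for `vary`.
#' @param start optional equilibrium point (from [find_equilibria()]) at one
#'   end of `range`; by default the branch is grown from every equilibrium
#'   found at `range[1]`.
#' @param step0 initial arclength step as a fraction of the range (the step
#'   adapts by factors of 2 on corrector performance).
#' @param max_steps cap on continuation steps.
#' @return an object of class `"cone_branch"`: list with `points` (a data
#'   frame: parameter value, six state columns, leading eigenvalue real part,
#'   `stable`), `folds` (list of fold points with `value` and `state`),
#'   `vary`, `params`, and `complete` (FALSE if the continuation stalled).
#' @examples
#' \donttest{
#' br <- continue_branch(cone_parameters(G_E = 5), "lambda", c(0.02, 0.15))
#' length(br$folds)
#' }
#' @export
continue_branch <- function(params, vary, range, start = NULL,
                            step0 = 1e-3, max_steps = 3000) {
  validate_parameters(params)
  if (!vary %in% names(unclass(params))) stop("unknown parameter: ", vary)
  range <- sort(as.numeric(range))
  p0 <- params; p0[vary] <- range[1]
  if (is.null(start)) {
    eqs <- find_equilibria(p0)
    if (!length(eqs)) stop("no equilibrium found at range[1]")
    start <- eqs[[1]]
    extra <- if (length(eqs) > 1) eqs[-1] else list()
  } else extra <- list()

  span <- range[2] - range[1]
  ds0 <- step0 * span
  pstart <- tryCatch(start$params[[vary]], error = function(e) NULL)
  if (is.null(pstart) || !is.finite(pstart)) pstart <- range[1]
  u <- c(as.numeric(start$state), pstart)
  pts <- list(); folds <- list(); complete <- TRUE
  # head into the interior of the range
  dirp <- if (abs(pstart - range[2]) < abs(pstart - range[1])) -1 else 1
  pst <- params; pst[vary] <- pstart
  z <- .tangent(u[1:6], pst, vary, orient = c(rep(0, 6), dirp))
  ds <- ds0 * 10
  push <- function(u) {
    pr <- params; pr[vary] <- u[7]
    J <- .jac_raw(pmax(u[1:6], 0), unclass(pr))
    ev <- eigen(J, only.values = TRUE)$values
    pts[[length(pts) + 1]] <<- c(u[7], u[1:6], max(Re(ev)),
                                 as.numeric(all(Re(ev) < 1e-8)))
  }
  push(u)
  for (it in seq_len(max_steps)) {
    u_pred <- u + ds * z
    pr <- params; pr[vary] <- u[7]
    res <- .correct(u_pred, z, pr, vary, ds)
    if (is.null(res)) {
      ds <- ds / 2
      if (ds < 1e-7 * span) { complete <- FALSE; break }
      next
    }
    u_new <- res$u
    z_new <- .tangent(pmax(u_new[1:6], 0), {
      pr2 <- params; pr2[vary] <- u_new[7]; pr2
    }, vary, orient = z)
    # fold: parameter component of tangent changes sign
    if (sign(z_new[7]) != sign(z[7]) && abs(z[7]) > 0) {
      fl <- .solve_fold(params, vary, pmax(u_new[1:6], 0), u_new[7])
      if (!is.null(fl) && fl$value >= range[1] - 1e-9 &&
          fl$value <= range[2] + 1e-9 &&
          (!length(folds) ||
           all(vapply(folds, function(f)
             abs(f$value - fl$value) > 1e-6 ||
               max(abs(f$state - fl$state)) > 1e-5, TRUE))))
        folds[[length(folds) + 1]] <- fl
    }
    u <- u_new; z <- z_new
    push(u)
    ds <- if (res$iters <= 3) min(ds * 2, ds0 * 50) else
          if (res$iters >= 8) ds / 2 else ds
    if (u[7] > range[2] + 1e-9 || u[7] < range[1] - 1e-9) break
  }
  if (!complete) warning("continuation stalled; partial branch returned")
  pm <- do.call(rbind, pts)
  colnames(pm) <- c(vary, .state_names, "re_lead", "stable")
  structure(list(points = as.data.frame(pm),
                 folds = folds, vary = vary, range = range,
                 params = params, complete = complete,
                 seeds_unused = extra),
            class = "cone_branch")
}

#' @export
print.cone_branch <- function(x, ...) {
  cat("equilibrium branch in '", x$vary, "': ", nrow(x$points),
      " points, ", length(x$folds), " fold(s)",
      if (!x$complete) " [stalled]", "\n", sep = "")
  for (f in x$folds)
    cat(sprintf("  fold at %s = %.6g (G = %.4g)\n", x$vary, f$value,
                f$state[["G"]]))
  invisible(x)
}

#' Label the stable segments of continued branches
#'
#' Splits each branch at its fold points, then labels stable segments:
#' where two stable segments coexist over a parameter interval, the one with
#' larger internal glucose is `"healthy"` and the other `"pathological"`.
#' Unstable segments are `"unstable"`. Labels are constant between folds
#' (continuity), and an error is raised if coexisting stable segments cannot
#' be ordered by `[G]`.
#'
#' @param branch a `cone_branch` from [continue_branch()].
#' @return the branch with a `label` column added to `points`.
#' @export
label_branches <- function(branch) {
  stopifnot(inherits(branch, "cone_branch"))
  pts <- branch$points
  # segment at stability changes (these coincide with folds along a branch)
  seg_id <- cumsum(c(1, abs(diff(pts$stable)) > 0))
  lab <- rep("unstable", nrow(pts))
  stable_segs <- unique(seg_id[pts$stable == 1])
  if (length(stable_segs) >= 2) {
    mg <- vapply(stable_segs, function(sg) mean(pts$G[seg_id == sg]), 0)
    if (abs(max(mg) - min(mg)) < 1e-9)
      stop("ambiguous labelling: stable segments with equal [G]")
    for (ii in seq_along(stable_segs)) {
      sg <- stable_segs[ii]
      lab[seg_id == sg] <- if (mg[ii] == max(mg)) "healthy" else "pathological"
    }
  } else if (length(stable_segs) == 1) {
    # isolated stable segment: use the G3P separation between the branches
    sg <- stable_segs[1]
    lab[seg_id == sg] <- if (mean(pts$G3P[seg_id == sg]) >= 0.05)
      "healthy" else "pathological"
  }
  branch$points$label <- lab
  branch
}

#' Export a branch as CSV
#'
#' Writes the branch points (parameter value, six state columns, leading
#' eigenvalue real part, stability and, if present, label) and optionally the
#' fold points to CSV files.
#'
#' @param branch a `cone_branch`.
#' @param file output CSV for the points.
#' @param fold_file optional output CSV for the folds.
#' @export
write_branch <- function(branch, file, fold_file = NULL) {
  utils::write.csv(branch$points, file, row.names = FALSE)
  if (!is.null(fold_file)) {
    fd <- do.call(rbind, lapply(branch$folds, function(f)
      data.frame(parameter = branch$vary, value = f$value,
                 t(as.matrix(f$state)))))
    utils::write.csv(fd %||% data.frame(), fold_file, row.names = FALSE)
  }
  invisible(file)
}
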