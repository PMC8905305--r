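# ---- time-varying global sensitivity analysis ------------------------------

# apply one sample row (parameters and/or initial conditions) to a template
.apply_row <- function(row, params, initial) {
  nm <- names(row)
  ic_map <- c(G_0 = "G", G3P_0 = "G3P", PYR_0 = "PYR", LACT_0 = "LACT",
              ACoA_0 = "ACoA", CIT_0 = "CIT")
  for (jj in seq_along(row)) {
    key <- nm[jj]
    if (key %in% names(unclass(params))) {
      params[key] <- row[jj]
    } else if (key %in% names(ic_map)) {
      initial[ic_map[[key]]] <- row[jj]
    } else if (!startsWith(key, "dummy")) {
      stop("sample column '", key, "' is neither a model parameter nor an ",
           "initial condition")
    }
  }
  list(params = params, initial = initial)
}

#' Simulate the model over an input-factor ensemble
#'
#' Integrates one trajectory per sample row (or per search-curve point for
#' eFAST designs), evaluated on a common output grid. Sample columns named
#' after model parameters override the template parameters; columns `G_0`,
#' ..., `CIT_0` override initial conditions; columns starting with `dummy`
#' are ignored by the model (useful as null factors). Failed integrations
#' are recorded and excluded; more than 5% failures aborts with a
#' diagnostic.
#'
#' @param samples a `cone_samples` matrix or a `cone_efast_design`.
#' @param template a [cone_scenario()] fixing everything not sampled (for
#'   the reference analyses: nominal parameters, initial glucose 0.02 or
#'   2 mM, lactate 9.4 mM, other pools empty, 0-240 min).
#' @param output_times report grid (default 1-min spacing over the template
#'   span).
#' @param rtol,atol solver tolerances (slightly looser than the scenario
#'   default, appropriate for ensemble sweeps).
#' @return object of class `"cone_ensemble"`: list with `outputs` (one
#'   `N x T` matrix per metabolite), `times`, `failed` (row indices),
#'   `samples`.
#' @export
evaluate_ensemble <- function(samples, template, output_times = NULL,
                              rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(template, "cone_scenario"))
  ts <- template$t_span
  if (is.null(output_times)) output_times <- seq(ts[1], ts[2], by = 1)
  if (inherits(samples, "cone_efast_design")) {
    vals <- do.call(rbind, lapply(samples$curves, function(cv) cv$values))
  } else if (inherits(samples, "cone_samples")) {
    vals <- samples$values
  } else if (is.matrix(samples)) {
    vals <- samples
  } else stop("unsupported samples object")
  N <- nrow(vals); Tn <- length(output_times)
  outs <- lapply(.state_names, function(nm) matrix(NA_real_, N, Tn))
  names(outs) <- .state_names
  failed <- integer(0)
  for (r in seq_len(N)) {
    cfg <- .apply_row(vals[r, ], template$params, template$initial)
    tr <- tryCatch(withCallingHandlers({
      sc <- cone_scenario(cfg$params, cfg$initial, t_span = ts,
                          clamp_windows = template$clamp_windows,
                          label = template$label)
      integrate_scenario(sc, output_times, rtol = rtol, atol = atol)
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
    if (is.null(tr)) { failed <- c(failed, r); next }
    for (nm in .state_names) outs[[nm]][r, ] <- tr$state[, nm]
  }
  if (length(failed) > 0.05 * N)
    stop(sprintf("%d of %d ensemble integrations failed (> 5%%)",
                 length(failed), N))
  structure(list(outputs = outs, times = output_times, failed = failed,
                 samples = samples),
            class = "cone_ensemble")
}

#' @export
print.cone_ensemble <- function(x, ...) {
  cat("model ensemble: ", nrow(x$outputs[[1]]), " runs x ",
      length(x$times), " time points (", length(x$failed), " failed)\n",
      sep = "")
  invisible(x)
}

.midrank <- function(x) rank(x, ties.method = "average")

#' Time-varying partial rank correlation coefficients
#'
#' At each output time, all input factors and the output are rank
#' transformed (midranks for ties) and the PRCC of factor `i` is the
#' correlation between the residuals of factor `i` and of the output after
#' linearly removing all other factors in rank space (computed through the
#' inverse of the rank correlation matrix). Significance uses the
#' t-distribution approximation with `N - 2 - (k - 1)` degrees of freedom.
#' Time points with a degenerate (constant) output yield `NA`, reported as
#' missing rather than zero.
#'
#' @param samples the `cone_samples` object used for the ensemble (or a bare
#'   matrix of factor values).
#' @param outputs either a `cone_ensemble` (with `output` naming the
#'   metabolite) or an `N x T` numeric matrix.
#' @param output metabolite name when `outputs` is an ensemble.
#' @param times optional time grid (taken from the ensemble if present).
#' @return object of class `"cone_sensitivity"` with `method = "PRCC"`:
#'   `value` and `p_value` are `T x k` matrices.
#' @examples
#' b <- benchmark_function("additive_linear")
#' s <- lhs_sample(b$factors, 60, seed = 2)
#' y <- matrix(b$fun(s$values), ncol = 1)
#' pr <- prcc_over_time(s, y)
#' pr$value
#' @export
prcc_over_time <- function(samples, outputs, output = "G", times = NULL) {
  X <- if (inherits(samples, "cone_samples")) samples$values else
    as.matrix(samples)
  if (inherits(outputs, "cone_ensemble")) {
    times <- outputs$times
    keep <- setdiff(seq_len(nrow(X)), outputs$failed)
    Y <- outputs$outputs[[output]][keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  } else {
    Y <- as.matrix(outputs)
  }
  N <- nrow(X); k <- ncol(X)
  if (N <= k + 2)
    stop("PRCC requires more samples than factors + 2 (N > k + 2)")
  if (is.null(times)) times <- seq_len(ncol(Y))
  Xr <- apply(X, 2, .midrank)
  dfree <- N - 2 - (k - 1)
  val <- pval <- matrix(NA_real_, length(times), k,
                        dimnames = list(NULL, colnames(X)))
  for (tt in seq_along(times)) {
    y <- Y[, tt]
    if (!all(is.finite(y)) || stats::sd(y) == 0) next
    M <- cbind(Xr, y = .midrank(y))
    C <- stats::cor(M)
    W <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(W)) next
    r <- -W[seq_len(k), k + 1] / sqrt(diag(W)[seq_len(k)] * W[k + 1, k + 1])
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(dfree / pmax(1 - r^2, 1e-12))
    val[tt, ] <- r
    pval[tt, ] <- 2 * stats::pt(-abs(tstat), df = dfree)
  }
  structure(list(method = "PRCC", output = output, times = times,
                 value = val, p_value = pval, factors = colnames(X),
                 n = N),
            class = "cone_sensitivity")
}

#' @export
print.cone_sensitivity <- function(x, ...) {
  cat("time-varying ", x$method, " for output ", x$output, ": ",
      length(x$times), " time points x ", length(x$factors),
      " factors\n", sep = "")
  invisible(x)
}

# spectral variance components for one search curve
.efast_spectrum <- function(y, s, om_i, M) {
  Ns <- length(y)
  nh <- floor((Ns - 1) / 2)
  js <- seq_len(nh)
  A <- vapply(js, function(j) mean(y * cos(j * s)), 0)
  B <- vapply(js, function(j) mean(y * sin(j * s)), 0)
  Vj <- 2 * (A^2 + B^2)
  V <- sum(Vj)
  hi <- om_i * seq_len(M)
  hi <- hi[hi <= nh]
  Vi <- sum(Vj[hi])
  Vci <- sum(Vj[seq_len(min(nh, max(1, floor(om_i / 2))))])
  c(V = V, Vi = Vi, Vci = Vci)
}

#' Time-varying eFAST sensitivity indices
#'
#' For each factor of interest and each output time, the model output along
#' the factor's search curves is Fourier-decomposed: the first-order index
#' `Si` is the spectral variance at the distinguished frequency and its
#' harmonics up to order `M`, and the total-order index `STi` is the
#' complement of the variance at the low (complementary) frequencies; both
#' are normalised by the total spectral variance and averaged over resample
#' curves. Spectral leakage is flagged when the complementary band of an
#' inert-output curve carries essentially all variance yet `Si` is negative
#' or exceeds 1 beyond estimator tolerance.
#'
#' @param design the `cone_efast_design` used for the ensemble.
#' @param outputs a `cone_ensemble` from [evaluate_ensemble()] run on the
#'   design, or an `(Ns * ncurves) x T` matrix in curve order.
#' @param output metabolite name when `outputs` is an ensemble.
#' @param times optional time grid.
#' @return `"cone_sensitivity"` with `method = "eFAST"`: `Si` and `STi` are
#'   `T x k` matrices; `value` aliases `STi`.
#' @export
efast_over_time <- function(design, outputs, output = "G", times = NULL) {
  stopifnot(inherits(design, "cone_efast_design"))
  if (inherits(outputs, "cone_ensemble")) {
    times <- outputs$times
    Y <- outputs$outputs[[output]]
    if (length(outputs$failed))
      stop("eFAST requires complete curves; ", length(outputs$failed),
           " integrations failed")
  } else {
    Y <- as.matrix(outputs)
  }
  Ns <- design$Ns
  if (is.null(times)) times <- seq_len(ncol(Y))
  fnames <- design$factors$name
  k <- length(fnames)
  Si <- STi <- matrix(0, length(times), k, dimnames = list(NULL, fnames))
  cnt <- stats::setNames(numeric(k), fnames)
  warn_leak <- FALSE
  for (ci in seq_along(design$curves)) {
    cv <- design$curves[[ci]]
    rows <- (ci - 1) * Ns + seq_len(Ns)
    fi <- cv$factor
    for (tt in seq_along(times)) {
      y <- Y[rows, tt]
      sp <- .efast_spectrum(y, cv$s, cv$omega_i, design$M)
      if (sp[["V"]] <= .Machine$double.eps) next
      si <- sp[["Vi"]] / sp[["V"]]
      sti <- 1 - sp[["Vci"]] / sp[["V"]]
      if (si < -0.05 || si > 1.05) warn_leak <- TRUE
      Si[tt, fi] <- Si[tt, fi] + si
      STi[tt, fi] <- STi[tt, fi] + sti
    }
    cnt[fi] <- cnt[fi] + 1
  }
  for (fi in fnames) if (cnt[fi] > 0) {
    Si[, fi] <- Si[, fi] / cnt[fi]
    STi[, fi] <- STi[, fi] / cnt[fi]
  }
  res <- structure(list(method = "eFAST", output = output, times = times,
                        value = STi, Si = Si, STi = STi, factors = fnames,
                        M = design$M, Ns = Ns, leakage_flag = warn_leak),
                   class = "cone_sensitivity")
  if (warn_leak)
    warning("possible spectral leakage: first-order estimates outside ",
            "[0, 1] tolerance band")
  res
}

#' Time-integrated sensitivity indices
#'
#' Integrates a per-timepoint sensitivity series over a window by the
#' trapezoidal rule, normalised by the window length, giving one summary
#' value per factor.
#'
#' @param series a `cone_sensitivity`.
#' @param window numeric length-2 time window (defaults to the full grid).
#' @param what which matrix to integrate (`"value"`, `"Si"` or `"STi"`).
#' @return named numeric vector, one value per factor.
#' @export
integrate_series <- function(series, window = NULL, what = "value") {
  tt <- series$times
  V <- series[[what]]
  if (is.null(window)) window <- range(tt)
  sel <- tt >= window[1] & tt <= window[2]
  tt <- tt[sel]; V <- V[sel, , drop = FALSE]
  if (length(tt) < 2) stop("window contains fewer than two time points")
  w <- diff(tt)
  out <- vapply(seq_len(ncol(V)), function(j) {
    v <- V[, j]
    ok <- is.finite(v)
    if (sum(ok) < 2) return(NA_real_)
    sum(w[ok[-1] & ok[-length(ok)]] *
          (v[-1] + v[-length(v)])[ok[-1] & ok[-length(ok)]] / 2) /
      (max(tt[ok]) - min(tt[ok]))
  }, 0)
  stats::setNames(out, colnames(V))
}

#' Extract the influential input factors
#'
#' PRCC series: a factor is influential if `|PRCC| > threshold` with
#' `p < p_max` somewhere in the window (defaults: 0.4 and 0.001, matching
#' the reference criteria). eFAST series: a factor is influential if its
#' total-order index exceeds the cross-factor median by at least `n_mad`
#' median absolute deviations somewhere in the window (operationalising the
#' "stands out from the clustered bulk" reading of the index plots).
#'
#' @param series a `cone_sensitivity`.
#' @param window numeric length-2 time window in the series' units.
#' @param threshold PRCC magnitude threshold.
#' @param p_max PRCC significance threshold.
#' @param n_mad eFAST separation threshold in MAD units.
#' @return data frame with columns `factor`, `influential`, and the
#'   supporting statistic (`max_abs_prcc` or `max_separation`).
#' @export
influential_set <- function(series, window = NULL, threshold = 0.4,
                            p_max = 0.001, n_mad = 2) {
  stopifnot(inherits(series, "cone_sensitivity"))
  tt <- series$times
  if (is.null(window)) window <- range(tt)
  if (window[2] <= window[1]) stop("empty window")
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop("empty window")
  if (series$method == "PRCC") {
    V <- series$value[sel, , drop = FALSE]
    P <- series$p_value[sel, , drop = FALSE]
    hit <- abs(V) > threshold & P < p_max
    data.frame(factor = series$factors,
               influential = apply(hit, 2, any, na.rm = TRUE),
               max_abs_prcc = apply(abs(V), 2, max, na.rm = TRUE),
               row.names = NULL)
  } else {
    V <- series$STi[sel, , drop = FALSE]
    sep <- matrix(0, nrow(V), ncol(V))
    for (tt2 in seq_len(nrow(V))) {
      med <- stats::median(V[tt2, ], na.rm = TRUE)
      md <- stats::mad(V[tt2, ], na.rm = TRUE)
      sep[tt2, ] <- if (md > 0) (V[tt2, ] - med) / md else 0
    }
    data.frame(factor = series$factors,
               influential = apply(sep >= n_mad, 2, any, na.rm = TRUE),
               max_separation = apply(sep, 2, max, na.rm = TRUE),
               row.names = NULL)
  }
}

#' Export a sensitivity series as long-format CSV
#'
#' Columns: `time_min`, `factor`, `value`, `p_value` (PRCC only; `Si` for
#' eFAST), `method`, `output`.
#'
#' @param series a `cone_sensitivity`.
#' @param file output path.
#' @export
write_sensitivity <- function(series, file) {
  long <- do.call(rbind, lapply(seq_along(series$factors), function(j) {
    f <- series$factors[j]
    d <- data.frame(time_min = series$times, factor = f,
                    value = series$value[, f],
                    method = series$method, output = series$output,
                    stringsAsFactors = FALSE)
    if (series$method == "PRCC") d$p_value <- series$p_value[, f]
    else d$Si <- series$Si[, f]
    d
  }))
  utils::write.csv(long, file, row.names = FALSE)
  invisible(file)
}

#' Scenario template for the reference sensitivity analyses
#'
#' Nominal parameters, initial lactate 9.4 mM, other pools empty, and the
#' requested initial internal glucose; horizon 0-240 min.
#'
#' @param G0 initial internal glucose, mM (0.02 for the severe-stress arm,
#'   2 for the nutrient-sufficient arm).
#' @return a [cone_scenario()].
#' @export
gsa_template <- function(G0 = 0.02) {
  cone_scenario(cone_parameters(), cone_state(G = G0, LACT = 9.4),
                t_span = c(0, 240), label = sprintf("gsa_G0_%g", G0))
}
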