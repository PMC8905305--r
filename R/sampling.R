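# ---- sampling designs for global sensitivity analysis ----------------------

#' Input-factor specifications
#'
#' Loads the machine-readable table of factor ranges bundled with the
#' package. The `"efast"` column holds the full physiological parameter
#' ranges (25 parameters); the `"prcc_low"` and `"prcc_high"` columns hold
#' the ranges restricted for monotonicity under low (`[G](0) = 0.02` mM) and
#' higher (`[G](0) = 2` mM) initial internal glucose, and additionally
#' include the six initial conditions as factors (`G_0`, ..., `CIT_0`).
#'
#' @param column which range column to use: `"efast"`, `"prcc_low"` or
#'   `"prcc_high"`.
#' @return a data frame with columns `name`, `lower`, `upper`, `role`,
#'   `column`.
#' @examples
#' nrow(cone_factors("efast"))      # 25 parameters
#' nrow(cone_factors("prcc_low"))   # 31 incl. initial conditions
#' @export
cone_factors <- function(column = c("efast", "prcc_low", "prcc_high")) {
  column <- match.arg(column)
  path <- system.file("extdata", "factor_ranges.csv", package = "conemet")
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- switch(column,
                 efast = c("efast_lo", "efast_hi"),
                 prcc_low = c("prcc_low_lo", "prcc_low_hi"),
                 prcc_high = c("prcc_high_lo", "prcc_high_hi"))
  d <- data.frame(name = tb$name,
                  lower = tb[[cols[1]]],
                  upper = tb[[cols[2]]],
                  role = tb$role,
                  column = column,
                  stringsAsFactors = FALSE)
  d <- d[!is.na(d$lower) & !is.na(d$upper), ]
  if (any(d$lower >= d$upper))
    stop("invalid factor bounds in range table")
  rownames(d) <- NULL
  d
}

.check_factors <- function(factors) {
  if (!is.data.frame(factors) ||
      !all(c("name", "lower", "upper") %in% names(factors)))
    stop("factors must be a data frame with columns name, lower, upper")
  if (any(!is.finite(factors$lower)) || any(!is.finite(factors$upper)) ||
      any(factors$lower >= factors$upper))
    stop("factor bounds must be finite with lower < upper")
  invisible(factors)
}

#' Latin hypercube sample of the input factors
#'
#' Stratified uniform sampling: each factor's marginal hits each of the `N`
#' equal-probability strata exactly once, with random permutations across
#' factors. Reproducible under `seed`.
#'
#' @param factors a factor table ([cone_factors()] or compatible).
#' @param N number of samples (>= 2).
#' @param seed RNG seed.
#' @return object of class `"cone_samples"`: list with `values`
#'   (`N x k` matrix, columns named by factor), `factors`, `method`
#'   (`"LHS"`), `seed`.
#' @examples
#' s <- lhs_sample(cone_factors("prcc_low"), N = 10, seed = 1)
#' dim(s$values)
#' @export
lhs_sample <- function(factors, N, seed = 1) {
  .check_factors(factors)
  if (N < 2) stop("N must be >= 2")
  k <- nrow(factors)
  u <- withr_seed(seed, lhs::randomLHS(N, k))
  vals <- sweep(u, 2, factors$upper - factors$lower, "*")
  vals <- sweep(vals, 2, factors$lower, "+")
  colnames(vals) <- factors$name
  structure(list(values = vals, factors = factors, method = "LHS",
                 seed = seed),
            class = "cone_samples")
}

#' @export
print.cone_samples <- function(x, ...) {
  cat("sample matrix (", x$method, "): ", nrow(x$values), " x ",
      ncol(x$values), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# spread nc complementary frequencies over 1..maxf (cycled when nc > maxf)
.comp_freqs <- function(nc, maxf) {
  maxf <- max(1, maxf)
  if (nc <= maxf) unique(round(seq(1, maxf, length.out = nc)))[seq_len(nc)]
  else (seq_len(nc) - 1) %% maxf + 1
}

#' eFAST search-curve sample
#'
#' For each factor of interest, generates `Ns` points along the sinusoidal
#' search curve `x_i(s) = lo_i + (hi_i - lo_i) * (1/2 + asin(sin(w_i s +
#' phi_i))/pi)` over `s` in (-pi, pi), with the factor of interest at the
#' distinguished high frequency `w_max = floor((Ns - 1) / (2 M))` and the
#' complementary factors at low frequencies no higher than
#' `max(1, floor(w_max / (2 M)))`, so that no complementary harmonic up to
#' order `M` collides with the distinguished frequency's harmonics. Each of
#' the `Nr` resample curves uses independent random phase shifts.
#'
#' @param factors factor table (typically `cone_factors("efast")`).
#' @param Ns samples per search curve; must satisfy `Ns >= 4 * M + 1` (so
#'   that the distinguished frequency exists and is Nyquist-resolved).
#' @param M interference factor (number of harmonics kept).
#' @param Nr number of resample curves.
#' @param seed RNG seed for the phase shifts.
#' @return object of class `"cone_efast_design"`: list with `curves` (one
#'   element per factor-of-interest x resample curve, each holding `values`
#'   (`Ns x k`), `factor`, `resample`, `omega_i`, `omega_c`, `phase`, `s`),
#'   plus `factors`, `Ns`, `M`, `Nr`, `seed`.
#' @examples
#' d <- efast_sample(cone_factors("efast"), Ns = 65, M = 4, seed = 1)
#' length(d$curves)   # 25 factors x 1 resample
#' @export
efast_sample <- function(factors, Ns = 325, M = 4, Nr = 1, seed = 1) {
  .check_factors(factors)
  k <- nrow(factors)
  if (Ns < 4 * M + 1)
    stop("Ns must be at least 4*M + 1 for the chosen interference factor")
  om_i <- floor((Ns - 1) / (2 * M))
  om_c_max <- max(1, floor(om_i / (2 * M)))
  if (om_c_max * M >= om_i)
    stop("frequency set violates interference constraints; increase Ns")
  s <- pi * (2 * seq_len(Ns) - Ns - 1) / Ns
  lo <- factors$lower; hi <- factors$upper
  curves <- list()
  withr_seed(seed, {
    for (fi in seq_len(k)) {
      for (r in seq_len(Nr)) {
        om <- numeric(k)
        om[fi] <- om_i
        om[-fi] <- .comp_freqs(k - 1, om_c_max)
        phase <- stats::runif(k, 0, 2 * pi)
        vals <- matrix(0, Ns, k)
        for (jj in seq_len(k)) {
          g <- 0.5 + asin(sin(om[jj] * s + phase[jj])) / pi
          vals[, jj] <- lo[jj] + (hi[jj] - lo[jj]) * g
        }
        colnames(vals) <- factors$name
        curves[[length(curves) + 1]] <-
          list(values = vals, factor = factors$name[fi], resample = r,
               omega_i = om_i, omega_c = om[-fi], phase = phase, s = s)
      }
    }
  })
  structure(list(curves = curves, factors = factors, Ns = Ns, M = M,
                 Nr = Nr, seed = seed, method = "eFAST"),
            class = "cone_efast_design")
}

#' @export
print.cone_efast_design <- function(x, ...) {
  cat("eFAST design: ", nrow(x$factors), " factors x ", x$Nr,
      " resample curve(s), Ns = ", x$Ns, ", M = ", x$M,
      ", distinguished frequency ", x$curves[[1]]$omega_i, "\n", sep = "")
  invisible(x)
}

#' Analytic benchmark functions for validating the GSA estimators
#'
#' Returns an evaluable test function together with its factor ranges and
#' analytically known sensitivity values.
#'
#' * `"ishigami"`: `y = sin(x1) + a sin(x2)^2 + b x3^4 sin(x1)` with
#'   `a = 7`, `b = 0.1` on `[-pi, pi]^3`; first- and total-order Sobol
#'   indices from the closed-form variance decomposition.
#' * `"additive_linear"`: `y = 2 x1 - x2` on `[0, 1]^2` plus an inert factor
#'   `x3`; exact Sobol indices (`0.8, 0.2, 0`) and the signs of the partial
#'   correlations.
#' * `"constant"`: `y = 1`; all sensitivity indices are zero (the output
#'   variance vanishes).
#'
#' @param name benchmark name.
#' @return list with `fun` (matrix-in, vector-out), `factors`, and
#'   `analytic` (list with `Si`, `STi`, and for the linear case
#'   `prcc_sign`).
#' @examples
#' b <- benchmark_function("ishigami")
#' b$analytic$Si
#' @export
benchmark_function <- function(name = c("ishigami", "additive_linear",
                                        "constant")) {
  name <- match.arg(name)
  if (name == "ishigami") {
    a <- 7; b <- 0.1
    V1 <- 0.5 * (1 + b * pi^4 / 5)^2
    V2 <- a^2 / 8
    V13 <- 8 * b^2 * pi^8 / 225
    V <- V1 + V2 + V13
    list(fun = function(X)
           sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1]),
         factors = data.frame(name = c("x1", "x2", "x3"),
                              lower = -pi, upper = pi),
         analytic = list(Si = c(x1 = V1 / V, x2 = V2 / V, x3 = 0),
                         STi = c(x1 = (V1 + V13) / V, x2 = V2 / V,
                                 x3 = V13 / V)))
  } else if (name == "additive_linear") {
    V <- 4 / 12 + 1 / 12
    list(fun = function(X) 2 * X[, 1] - X[, 2],
         factors = data.frame(name = c("x1", "x2", "x3"),
                              lower = 0, upper = 1),
         analytic = list(Si = c(x1 = (4 / 12) / V, x2 = (1 / 12) / V,
                                x3 = 0),
                         STi = c(x1 = (4 / 12) / V, x2 = (1 / 12) / V,
                                 x3 = 0),
                         prcc_sign = c(x1 = 1, x2 = -1, x3 = 0)))
  } else {
    list(fun = function(X) rep(1, nrow(X)),
         factors = data.frame(name = c("x1", "x2", "x3"),
                              lower = 0, upper = 1),
         analytic = list(Si = c(x1 = 0, x2 = 0, x3 = 0),
                         STi = c(x1 = 0, x2 = 0, x3 = 0)))
  }
}

#' Export a sample matrix with a JSON sidecar
#'
#' Writes the sample values as CSV and the design metadata (method, seed,
#' and for eFAST designs the frequency assignment) as a JSON sidecar next to
#' it.
#'
#' @param samples a `cone_samples` or `cone_efast_design` object.
#' @param file CSV output path; the sidecar is written to `<file>.json`.
#' @export
write_samples <- function(samples, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for the JSON sidecar")
  if (inherits(samples, "cone_samples")) {
    utils::write.csv(samples$values, file, row.names = FALSE)
    meta <- list(method = samples$method, seed = samples$seed,
                 N = nrow(samples$values))
  } else if (inherits(samples, "cone_efast_design")) {
    big <- do.call(rbind, lapply(seq_along(samples$curves), function(ii) {
      cv <- samples$curves[[ii]]
      data.frame(curve = ii, factor_of_interest = cv$factor,
                 resample = cv$resample, cv$values)
    }))
    utils::write.csv(big, file, row.names = FALSE)
    meta <- list(method = "eFAST", seed = samples$seed, Ns = samples$Ns,
                 M = samples$M, Nr = samples$Nr,
                 omega_i = samples$curves[[1]]$omega_i)
  } else stop("unsupported sample object")
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
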