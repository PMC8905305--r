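#' Kinetic parameters of the cone metabolism model
#'
#' Construct the 25-parameter set of the single-cone metabolic network. With
#' no arguments the nominal ("baseline") parameterisation is returned; any
#' parameter can be overridden by name. Units are mM and minutes throughout.
#'
#' The parameters are, in order: `lambda` (GLUT1 transport efficiency,
#' /mM/min per unit uptake activity), `V_G` and `K_G` (maximum rate and
#' half-limiting value of RdCVF-stimulated glucose uptake), `n` (basal uptake
#' activity), `delta` (rod-abundance scaling applied to [G3P] to proxy the
#' RdCVF supply), `q` (fraction of internal glucose diverted to the Kennedy
#' pathway), `V_G3P`/`K_G3P` (G3P synthesis kinetics), `V_PYR`/`K_PYR`
#' (pyruvate synthesis kinetics), `beta` (strength of citrate inhibition of
#' glycolysis), `alpha` (G3P utilisation / fatty-acid beta-oxidation rate,
#' /min), `rho` (fraction of pyruvate entering the mitochondria),
#' `V_LACT`/`K_LACT` (lactate synthesis kinetics), `V_ACoA`/`K_ACoA`
#' (acetyl-CoA-from-pyruvate kinetics), `phi` (citrate-to-ATP conversion
#' factor, /min), `V_CIT`/`K_CIT` (citrate synthesis kinetics), `psi`
#' (lactate-handling capacity factor scaling LDHA throughput and export),
#' `kappa` (attenuation of the external-lactate import branch), `gamma`
#' (external-lactate-to-pyruvate conversion factor, LDHB pathway), `G_E`
#' (external glucose, mM) and `L_E` (external lactate, mM).
#'
#' @param ... named parameter overrides, e.g. `cone_parameters(alpha = 0.1)`.
#' @return A named numeric vector of class `"cone_parameters"`.
#' @examples
#' p <- cone_parameters()
#' p[["lambda"]]
#' cone_parameters(alpha = 0.18, G_E = 10)[["alpha"]]
#' @seealso [cone_rhs()], [read_parameters()]
#' @export
cone_parameters <- function(...) {
  p <- c(lambda = 0.0755, V_G = 1.2, K_G = 19, n = 0.001, delta = 65,
         q = 0.18, V_G3P = 0.15, K_G3P = 0.143, V_PYR = 0.15, K_PYR = 1.7,
         beta = 1, alpha = 0.2, rho = 0.05, V_LACT = 0.14, K_LACT = 0.125,
         V_ACoA = 0.15, K_ACoA = 0.02, phi = 1, V_CIT = 0.03,
         K_CIT = 0.0054, psi = 8, kappa = 10, gamma = 1,
         G_E = 11.5, L_E = 10)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- vapply(ov, as.numeric, numeric(1))
  }
  p <- structure(p, class = "cone_parameters")
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks finiteness, non-negativity and that the fractional parameters
#' `q` and `rho` lie in \[0, 1\].
#'
#' @param params a named numeric vector as returned by [cone_parameters()].
#' @return `params`, invisibly, if valid; otherwise an error is thrown
#'   naming the offending field.
#' @export
validate_parameters <- function(params) {
  need <- names(unclass(cone_parameters.default_names()))
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  v <- as.numeric(params[need])
  bad <- need[!is.finite(v)]
  if (length(bad))
    stop("non-finite parameter(s): ", paste(bad, collapse = ", "))
  bad <- need[v < 0]
  if (length(bad))
    stop("negative parameter(s): ", paste(bad, collapse = ", "))
  for (fr in c("q", "rho"))
    if (params[[fr]] > 1)
      stop("parameter '", fr, "' must lie in [0, 1]")
  invisible(params)
}

# canonical ordering used by validate/IO
cone_parameters.default_names <- function() {
  c(lambda = 0, V_G = 0, K_G = 0, n = 0, delta = 0, q = 0, V_G3P = 0,
    K_G3P = 0, V_PYR = 0, K_PYR = 0, beta = 0, alpha = 0, rho = 0,
    V_LACT = 0, K_LACT = 0, V_ACoA = 0, K_ACoA = 0, phi = 0, V_CIT = 0,
    K_CIT = 0, psi = 0, kappa = 0, gamma = 0, G_E = 0, L_E = 0)
}

#' @export
print.cone_parameters <- function(x, ...) {
  cat("cone metabolism parameters (mM, min):\n")
  print(round(unclass(x), 6), ...)
  invisible(x)
}

#' Read or write a parameter set as a flat key-value file
#'
#' Parameter sets are stored as two-column CSV (`name,value`), with keys
#' named exactly as the model symbols (`lambda`, `V_G`, `K_G3P`, ...).
#'
#' @param file path to a CSV file.
#' @return `read_parameters()` returns a `cone_parameters` vector;
#'   `write_parameters()` returns `file` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_parameters(cone_parameters(alpha = 0.1), f)
#' read_parameters(f)[["alpha"]]
#' @export
read_parameters <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(d)))
    stop("parameter file must have columns 'name' and 'value': ", file)
  do.call(cone_parameters, as.list(stats::setNames(d$value, d$name)))
}

#' @rdname read_parameters
#' @param params a `cone_parameters` vector to serialise.
#' @export
write_parameters <- function(params, file) {
  validate_parameters(params)
  utils::write.csv(
    data.frame(name = names(unclass(params)),
               value = as.numeric(params)),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Initial metabolite concentrations
#'
#' Helper building a six-component state vector in the canonical order
#' G, G3P, PYR, LACT, ACoA, CIT (all mM).
#'
#' @param G,G3P,PYR,LACT,ACoA,CIT concentrations in mM.
#' @return named numeric vector of length 6.
#' @examples
#' cone_state(G = 2, LACT = 9.4)
#' @export
cone_state <- function(G = 0, G3P = 0, PYR = 0, LACT = 0, ACoA = 0, CIT = 0) {
  c(G = G, G3P = G3P, PYR = PYR, LACT = LACT, ACoA = ACoA, CIT = CIT)
}

# state variable names, fixed order
.state_names <- c("G", "G3P", "PYR", "LACT", "ACoA", "CIT")
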