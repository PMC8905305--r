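# Auxiliary kinetic constants of the G3P utilisation split. The beta-oxidation
# branch (pathway k) saturates with half-constant .KU (mM); the first-order
# non-oxidative turnover .R0 (/min) removes G3P without returning acetyl-CoA
# (lipid incorporated into outer-segment membranes that leaves the modelled
# carbon pool). Both are structural constants of the vector field, not members
# of the 25-parameter set varied in the sensitivity analyses.
.KU <- 0.2
.R0 <- 0.0125

.check_state <- function(state) {
  if (length(state) != 6)
    stop("state must have 6 components (G, G3P, PYR, LACT, ACoA, CIT)")
  s <- as.numeric(state)
  if (any(!is.finite(s))) {
    nm <- if (!is.null(names(state))) names(state) else .state_names
    stop("non-finite state component: ",
         paste(nm[!is.finite(s)], collapse = ", "))
  }
  s
}

#' Pathway fluxes of the cone metabolic network
#'
#' Evaluates the signed flux (mM/min) carried by each labelled pathway of the
#' metabolic map at a given state and parameter set. Pathways follow the
#' network diagram: (a) basal glucose uptake along the `G_E - [G]` gradient,
#' (b) RdCVF-stimulated glucose uptake (the RdCVF supply is proxied by
#' `delta * [G3P]` and acts as a cooperative switch on the transporter),
#' (c) G3P synthesis via the Kennedy-pathway diversion `q`, (d) pyruvate
#' synthesis by glycolysis under allosteric citrate inhibition, (f) outward
#' lactate transport (gradient-driven export, active when `[LACT] > L_E`),
#' (g) lactate synthesis from pyruvate (LDHA), (h) inward transport of
#' external lactate converted to pyruvate (LDHB; active when `L_E > [LACT]`),
#' (i) pyruvate entry into the mitochondria yielding acetyl-CoA, (j) citrate
#' synthesis, (k) acetyl-CoA synthesis from beta-HB derived from oxidised POS
#' fatty acids (driven by the G3P pool via `alpha`), (l) diversion of citrate
#' to ATP production and the cytosol, and (m) non-oxidative G3P turnover.
#'
#' The stoichiometric recombination of these fluxes ([recombine_fluxes()])
#' reproduces [cone_rhs()] exactly.
#'
#' @param state numeric state vector (G, G3P, PYR, LACT, ACoA, CIT), mM.
#' @param params a [cone_parameters()] vector.
#' @param clamp logical; if `TRUE` the glucose gradient is suppressed
#'   (`G_E` held equal to the instantaneous `[G]`), which zeroes pathways
#'   a and b. Used to represent glucose shutdown.
#' @return named numeric vector of fluxes `a` to `m` (mM/min).
#' @examples
#' pathway_fluxes(cone_state(G = 5, LACT = 9.4), cone_parameters())
#' @export
pathway_fluxes <- function(state, params, clamp = FALSE) {
  s <- .check_state(state)
  validate_parameters(params)
  G <- s[1]; G3P <- s[2]; PYR <- s[3]; LACT <- s[4]; ACoA <- s[5]; CIT <- s[6]
  p <- unclass(params)
  grad <- if (clamp) 0 else p[["G_E"]] - G
  R <- p[["delta"]] * G3P
  c(a = p[["lambda"]] * p[["n"]] * grad,
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

#' Stoichiometric recombination of pathway fluxes
#'
#' Maps a flux breakdown back onto the six state derivatives. Used to verify
#' the flux-decomposition identity `recombine_fluxes(pathway_fluxes(s, p))
#' == cone_rhs(s, p)`.
#'
#' @param fluxes named flux vector from [pathway_fluxes()].
#' @return named numeric vector of state derivatives (mM/min).
#' @export
recombine_fluxes <- function(fluxes) {
  fx <- as.list(fluxes)
  c(G    = fx$a + fx$b - fx$c - fx$d,
    G3P  = fx$c - fx$k - fx$m,
    PYR  = fx$d + fx$h - fx$g - fx$i,
    LACT = fx$g - fx$f,
    ACoA = fx$i + fx$k - fx$j,
    CIT  = fx$j - fx$l)
}

#' Vector field of the cone metabolism model
#'
#' Time derivative of the six metabolite concentrations, in mM/min.
#' See [pathway_fluxes()] for the pathway-level decomposition.
#'
#' @inheritParams pathway_fluxes
#' @return named numeric vector `d[state]/dt` of length 6.
#' @examples
#' cone_rhs(cone_state(G = 5, LACT = 9.4), cone_parameters())
#' @export
cone_rhs <- function(state, params, clamp = FALSE) {
  recombine_fluxes(pathway_fluxes(state, params, clamp))
}

# rhs closure for the integrator: parameters captured once, no validation in
# the hot loop; negative excursions (within solver tolerance) are clipped
# before evaluating the kinetics.
.rhs_fun <- function(params, clamp = FALSE) {
  p <- unclass(params)
  lambda <- p[["lambda"]]; V_G <- p[["V_G"]]; K_G <- p[["K_G"]]
  n_b <- p[["n"]]; delta <- p[["delta"]]; q <- p[["q"]]
  V_G3P <- p[["V_G3P"]]; K_G3P <- p[["K_G3P"]]
  V_PYR <- p[["V_PYR"]]; K_PYR2 <- p[["K_PYR"]]^2
  beta <- p[["beta"]]; alpha <- p[["alpha"]]; rho <- p[["rho"]]
  V_LACT <- p[["V_LACT"]]; K_LACT <- p[["K_LACT"]]
  V_ACoA <- p[["V_ACoA"]]; K_ACoA <- p[["K_ACoA"]]
  phi <- p[["phi"]]; V_CIT <- p[["V_CIT"]]; K_CIT <- p[["K_CIT"]]
  psi <- p[["psi"]]; kappa <- p[["kappa"]]; gamma <- p[["gamma"]]
  G_E <- p[["G_E"]]; L_E <- p[["L_E"]]
  function(t, y, parms) {
    s <- pmax(y, 0)
    G <- s[1]; G3P <- s[2]; PYR <- s[3]; LACT <- s[4]; ACoA <- s[5]; CIT <- s[6]
    grad <- if (clamp) 0 else G_E - G
    R <- delta * G3P
    upt <- lambda * grad * (n_b + V_G * (R / (K_G + R))^2)
    fc <- q * V_G3P * G / (K_G3P + G)
    fd <- (1 - q) * V_PYR * G^2 / (K_PYR2 + G^2) / (1 + beta * CIT)
    fg <- psi * V_LACT * PYR / (K_LACT + PYR)
    ff <- psi * max(LACT - L_E, 0)
    fh <- (gamma / kappa) * max(L_E - LACT, 0)
    fi <- rho * V_ACoA * PYR / (K_ACoA + PYR)
    fk <- alpha * .KU * G3P / (.KU + G3P)
    fj <- V_CIT * ACoA / (K_CIT + ACoA)
    list(c(upt - fc - fd,
           fc - fk - .R0 * G3P,
           fd + fh - fg - fi,
           fg - ff,
           fi + fk - fj,
           fj - phi * CIT))
  }
}

#' Jacobian of the cone metabolism vector field
#'
#' Analytic 6x6 derivative matrix of [cone_rhs()] with respect to the state.
#' The gradient-driven lactate transport terms are piecewise linear in
#' `[LACT]`; at the kink `[LACT] == L_E` the one-sided derivative from the
#' export side is used.
#'
#' @inheritParams pathway_fluxes
#' @return a 6x6 numeric matrix with rows/columns ordered as the state.
#' @examples
#' J <- cone_jacobian(cone_state(G = 5, G3P = 0.2, LACT = 9.4),
#'                    cone_parameters())
#' eigen(J)$values
#' @export
cone_jacobian <- function(state, params, clamp = FALSE) {
  s <- .check_state(state)
  validate_parameters(params)
  .cone_jacobian_raw(s, unclass(params), clamp)
}

.cone_jacobian_raw <- function(s, p, clamp = FALSE) {
  G <- s[1]; G3P <- s[2]; PYR <- s[3]; LACT <- s[4]; ACoA <- s[5]; CIT <- s[6]
  grad <- if (clamp) 0 else p[["G_E"]] - G
  R <- p[["delta"]] * G3P
  hfac <- (R / (p[["K_G"]] + R))^2
  dhfac_dG3P <- p[["delta"]] * 2 * R * p[["K_G"]] / (p[["K_G"]] + R)^3
  inh <- 1 / (1 + p[["beta"]] * CIT)

  upt <- p[["lambda"]] * (p[["n"]] + p[["V_G"]] * hfac)
  dup_dG <- if (clamp) 0 else -upt
  dup_dG3P <- p[["lambda"]] * grad * p[["V_G"]] * dhfac_dG3P

  dc_dG <- p[["q"]] * p[["V_G3P"]] * p[["K_G3P"]] / (p[["K_G3P"]] + G)^2
  dbase <- p[["V_PYR"]] * G^2 / (p[["K_PYR"]]^2 + G^2)
  dd_dG <- (1 - p[["q"]]) * inh *
    p[["V_PYR"]] * 2 * G * p[["K_PYR"]]^2 / (p[["K_PYR"]]^2 + G^2)^2
  dd_dCIT <- -(1 - p[["q"]]) * dbase * p[["beta"]] * inh^2

  dg_dPYR <- p[["psi"]] * p[["V_LACT"]] * p[["K_LACT"]] /
    (p[["K_LACT"]] + PYR)^2
  df_dLACT <- if (LACT >= p[["L_E"]]) p[["psi"]] else 0
  dh_dLACT <- if (LACT < p[["L_E"]]) -(p[["gamma"]] / p[["kappa"]]) else 0
  di_dPYR <- p[["rho"]] * p[["V_ACoA"]] * p[["K_ACoA"]] /
    (p[["K_ACoA"]] + PYR)^2
  dk_dG3P <- p[["alpha"]] * .KU^2 / (.KU + G3P)^2
  dj_dACoA <- p[["V_CIT"]] * p[["K_CIT"]] / (p[["K_CIT"]] + ACoA)^2

  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  J["G", "G"] <- dup_dG - dc_dG - dd_dG
  J["G", "G3P"] <- dup_dG3P
  J["G", "CIT"] <- -dd_dCIT
  J["G3P", "G"] <- dc_dG
  J["G3P", "G3P"] <- -dk_dG3P - .R0
  J["PYR", "G"] <- dd_dG
  J["PYR", "CIT"] <- dd_dCIT
  J["PYR", "PYR"] <- -dg_dPYR - di_dPYR
  J["PYR", "LACT"] <- dh_dLACT
  J["LACT", "PYR"] <- dg_dPYR
  J["LACT", "LACT"] <- -df_dLACT
  J["ACoA", "PYR"] <- di_dPYR
  J["ACoA", "G3P"] <- dk_dG3P
  J["ACoA", "ACoA"] <- -dj_dACoA
  J["CIT", "ACoA"] <- dj_dACoA
  J["CIT", "CIT"] <- -p[["phi"]]
  J
}
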