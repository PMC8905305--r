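# Independent oracles used across the suite.

# Second, independent transcription of the governing equations, written
# term-by-term from the pathway map (deliberately not sharing code with the
# package implementation).
oracle_rhs <- function(state, params, clamp = FALSE) {
  G <- state[[1]]; G3P <- state[[2]]; PYR <- state[[3]]
  LACT <- state[[4]]; ACoA <- state[[5]]; CIT <- state[[6]]
  p <- as.list(unclass(params))
  KU <- 0.2; r0 <- 0.0125
  gradient <- if (clamp) 0 else (p$G_E - G)
  rdcvf <- p$delta * G3P
  hill <- (rdcvf / (p$K_G + rdcvf))^2
  uptake_basal <- p$lambda * p$n * gradient
  uptake_rdcvf <- p$lambda * p$V_G * hill * gradient
  kennedy <- p$q * p$V_G3P * G / (p$K_G3P + G)
  glycolysis <- (1 - p$q) * p$V_PYR * G^2 / (p$K_PYR^2 + G^2) *
    (1 / (1 + p$beta * CIT))
  ldha <- p$psi * p$V_LACT * PYR / (p$K_LACT + PYR)
  mct_out <- if (LACT > p$L_E) p$psi * (LACT - p$L_E) else 0
  ldhb_in <- if (p$L_E > LACT) p$gamma * (p$L_E - LACT) / p$kappa else 0
  pdh <- p$rho * p$V_ACoA * PYR / (p$K_ACoA + PYR)
  bhb <- p$alpha * KU * G3P / (KU + G3P)
  turnover <- r0 * G3P
  citrate_syn <- p$V_CIT * ACoA / (p$K_CIT + ACoA)
  citrate_out <- p$phi * CIT
  c(uptake_basal + uptake_rdcvf - kennedy - glycolysis,
    kennedy - bhb - turnover,
    glycolysis + ldhb_in - ldha - pdh,
    ldha - mct_out,
    pdh + bhb - citrate_syn,
    citrate_syn - citrate_out)
}

# central finite-difference Jacobian of cone_rhs
fd_jacobian <- function(state, params, h = 1e-6, clamp = FALSE) {
  s <- as.numeric(state)
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    hp <- h * max(1, abs(s[j]))
    sp <- s; sp[j] <- sp[j] + hp
    sm <- s; sm[j] <- sm[j] - hp
    J[, j] <- (as.numeric(cone_rhs(sp, params, clamp)) -
                 as.numeric(cone_rhs(sm, params, clamp))) / (2 * hp)
  }
  J
}

# random strictly interior state (away from the lactate transport kink)
random_state <- function(L_E = 10) {
  s <- stats::runif(6, 0.001, 10)
  if (abs(s[4] - L_E) < 0.05) s[4] <- s[4] + 0.1
  s
}

# random parameter set within the physiological (eFAST) ranges
random_params <- function() {
  fx <- cone_factors("efast")
  vals <- stats::runif(nrow(fx), fx$lower, fx$upper)
  do.call(cone_parameters, as.list(stats::setNames(vals, fx$name)))
}

# count stable equilibria by scanning lambda, used as a bisection oracle for
# fold locations
n_stable_at <- function(params, lambda, n_starts = 12) {
  params["lambda"] <- lambda
  sum(vapply(find_equilibria(params, n_starts = n_starts),
             function(e) e$stable, TRUE))
}
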