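## Independent oracles used to cross-check the package's estimators.
## These deliberately use different algorithms from the implementation.

R_KCAL <- 1.987204e-3

## Bennett acceptance ratio by damped self-consistent (fixed-point)
## iteration -- independent of the package's monotone root bracketing.
## w_f: forward works; w_r: reverse works (both low->high convention on
## their own ensembles, w_r = -dH_reverse).
oracle_bar_fixed_point <- function(w_f, w_r, temperature = 300,
                                   tol = 1e-13, max_iter = 10000) {
  beta <- 1 / (R_KCAL * temperature)
  M <- log(length(w_f) / length(w_r))
  fermi <- function(x) 1 / (1 + exp(x))
  dG <- mean(c(mean(w_f), -mean(w_r)))
  for (k in seq_len(max_iter)) {
    num <- sum(fermi(-M + beta * (w_r + dG)))
    den <- sum(fermi(M + beta * (w_f - dG)))
    step <- log(num / den) / beta
    dG_new <- dG + 0.5 * step
    if (abs(dG_new - dG) < tol) return(dG_new)
    dG <- dG_new
  }
  dG
}

## Zwanzig exponential average of a Gaussian work distribution by numerical
## quadrature: dG = -kT log( int exp(-beta w) N(w; mu, sd^2) dw )
oracle_gaussian_zwanzig <- function(mu, sd, temperature = 300) {
  beta <- 1 / (R_KCAL * temperature)
  val <- stats::integrate(function(w) exp(-beta * w) * stats::dnorm(w, mu, sd),
                          mu - 12 * sd - 12 / beta, mu + 12 * sd,
                          rel.tol = 1e-12)$value
  -log(val) / beta
}

## ordinary least squares by the closed-form normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- (sum(y) - slope * sum(x)) / n
  list(slope = slope, intercept = intercept)
}

## brute-force dimer equilibrium: scalar root of 2*Ct*f^2/(1-f) = K
oracle_dimer_fraction <- function(T, dH, Tm, dCp, Ct, Ct_ref = Ct) {
  dG <- dH * (1 - T / Tm) + dCp * (T - Tm - T * log(T / Tm)) -
    R_KCAL * T * log(Ct_ref)
  K <- exp(-dG / (R_KCAL * T))
  stats::uniroot(function(f) 2 * Ct * f^2 / (1 - f) - K,
                 c(1e-15, 1 - 1e-15), tol = 1e-14)$root
}

## temperature at which the unfolded fraction crosses 1/2
oracle_half_transition <- function(dH, Tm, dCp, Ct, Ct_ref,
                                   interval = c(280, 360)) {
  stats::uniroot(function(T)
    oracle_dimer_fraction(T, dH, Tm, dCp, Ct, Ct_ref) - 0.5,
    interval, tol = 1e-10)$root
}

## eight degenerate legs yielding prescribed component ddGs exactly
make_cycle_legs <- function(ddG_ele, ddG_vdw, err = 0) {
  legs <- list()
  for (comp in c("ele", "vdw")) {
    for (st in c("folded", "unfolded")) {
      for (tr in c("XtoI", "YtoI")) {
        dg <- if (comp == "ele" && st == "folded" && tr == "XtoI") ddG_ele
              else if (comp == "vdw" && st == "folded" && tr == "XtoI") ddG_vdw
              else 0
        legs[[length(legs) + 1]] <-
          leg_result(dg, err, component = comp, state = st,
                     transformation = tr, subunit_scale = 0.5)
      }
    }
  }
  legs
}
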