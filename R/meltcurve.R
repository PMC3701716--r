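#' Gibbs free energy of unfolding for a dimeric two-state protein
#'
#' Gibbs-Helmholtz expression with a temperature-independent heat-capacity
#' change, anchored for a homodimer that dissociates on unfolding
#' (N2 <-> 2U). `Tm` is the melting temperature — the temperature at which
#' half the monomer population is unfolded — at total monomer concentration
#' `Ct`, which fixes the standard-state free energy at `Tm` to
#' `-R*Tm*log(Ct)`:
#' \deqn{\Delta G(T) = \Delta H (1 - T/T_m) +
#'   \Delta C_p (T - T_m - T \log(T/T_m)) - R T \log C_t}
#'
#' @param T temperature(s), K.
#' @param dH unfolding enthalpy at `Tm` (kcal/mol of dimer).
#' @param Tm melting temperature (K) at concentration `Ct`.
#' @param dCp heat-capacity change (kcal/mol/K).
#' @param Ct total monomer concentration (mol/L) at which `Tm` is defined.
#' @return unfolding free energy (kcal/mol), vectorized over `T`.
#' @export
dG_unfold <- function(T, dH, Tm, dCp, Ct = 4.2e-6) {
  if (any(T <= 0) || Tm <= 0) stop("temperatures must be positive (Kelvin)")
  if (Ct <= 0) stop("Ct must be positive")
  dH * (1 - T / Tm) + dCp * (T - Tm - T * log(T / Tm)) -
    .R_KCAL * T * log(Ct)
}

#' Fraction of unfolded monomers of a dissociating homodimer
#'
#' Solves the mass-action relation of N2 <-> 2U,
#' `K = 2 * Ct * f^2 / (1 - f)` with `K = exp(-dG/(R T))`, for the root in
#' (0, 1), in the overflow-safe form `f = 2 / (1 + sqrt(1 + 8 Ct / K))`.
#' The free energy is anchored at the reference concentration `Ct_ref`
#' (see [dG_unfold()]); the equilibrium itself is evaluated at `Ct`. With
#' `Ct = Ct_ref` (the default, and the situation when fitting data measured
#' at the concentration that defines `Tm`) the fraction at `T = Tm` is
#' exactly 1/2; raising `Ct` above `Ct_ref` stabilizes the dimer and pushes
#' the half-transition above `Tm`.
#'
#' @inheritParams dG_unfold
#' @param Ct total monomer concentration (mol/L) of the sample.
#' @param Ct_ref reference concentration at which `Tm` is defined; defaults
#'   to `Ct`.
#' @return unfolded fraction in (0, 1), vectorized over `T`.
#' @export
frac_unfolded <- function(T, dH, Tm, dCp, Ct = 4.2e-6, Ct_ref = Ct) {
  dG <- dG_unfold(T, dH, Tm, dCp, Ct = Ct_ref)
  ## r = 8*Ct/K; cap the exponent to avoid overflow (f -> 0 limit)
  r <- exp(pmin(log(8 * Ct) + dG / (.R_KCAL * T), 700))
  2 / (1 + sqrt(1 + r))
}

#' Fluorescence intensity of a partially unfolded sample
#'
#' Linear-baseline two-state observable:
#' `I(T) = (alpha_F + beta_F*T) * (1 - f) + (alpha_U + beta_U*T) * f`,
#' with `f` from [frac_unfolded()].
#'
#' @inheritParams frac_unfolded
#' @param alpha_F,alpha_U folded/unfolded baselines at 0 K (intensity units).
#' @param beta_F,beta_U baseline slopes (units/K).
#' @return intensity, vectorized over `T`.
#' @export
intensity_model <- function(T, dH, Tm, dCp, alpha_F, beta_F, alpha_U, beta_U,
                            Ct = 4.2e-6, Ct_ref = Ct) {
  f <- frac_unfolded(T, dH, Tm, dCp, Ct = Ct, Ct_ref = Ct_ref)
  (alpha_F + beta_F * T) * (1 - f) + (alpha_U + beta_U * T) * f
}

#' Thermal-denaturation curve container
#'
#' @param temperatures strictly increasing measurement temperatures (K).
#' @param intensities fluorescence intensities (arbitrary units).
#' @param intensity_errors optional per-point measurement errors (same
#'   units).
#' @param Ct total monomer concentration (mol/L).
#' @param Ct_ref reference concentration anchoring `Tm` (defaults to `Ct`).
#' @return object of class `"melt_curve"`.
#' @export
melt_curve <- function(temperatures, intensities, intensity_errors = NULL,
                       Ct = 4.2e-6, Ct_ref = Ct) {
  if (length(temperatures) < 8) stop("need at least 8 data points")
  if (length(intensities) != length(temperatures))
    stop("temperatures and intensities differ in length")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (Ct <= 0) stop("Ct must be positive")
  if (!is.null(intensity_errors)) {
    if (length(intensity_errors) != length(intensities))
      stop("intensity_errors length mismatch")
    if (any(intensity_errors <= 0)) stop("intensity_errors must be positive")
  }
  structure(list(temperatures = as.numeric(temperatures),
                 intensities = as.numeric(intensities),
                 intensity_errors = intensity_errors,
                 Ct = Ct, Ct_ref = Ct_ref),
            class = "melt_curve")
}

#' Read a melt curve from CSV
#'
#' Expects a header row and columns `temperature`, `intensity`, optionally
#' `error`.
#'
#' @param path CSV file.
#' @param celsius if `TRUE`, temperatures in the file are Celsius and are
#'   converted to Kelvin.
#' @param Ct,Ct_ref concentrations, see [melt_curve()].
#' @return a [melt_curve()].
#' @export
read_melt_csv <- function(path, celsius = FALSE, Ct = 4.2e-6, Ct_ref = Ct) {
  df <- utils::read.csv(path)
  if (!all(c("temperature", "intensity") %in% names(df)))
    stop("CSV needs columns 'temperature' and 'intensity'")
  temp <- df$temperature + if (celsius) 273.15 else 0
  melt_curve(temp, df$intensity,
             intensity_errors = df[["error"]], Ct = Ct, Ct_ref = Ct_ref)
}

#' Write a melt curve to CSV
#'
#' @param curve a [melt_curve()].
#' @param path output file.
#' @param celsius write temperatures in Celsius.
#' @return invisibly, `path`.
#' @export
write_melt_csv <- function(curve, path, celsius = FALSE) {
  df <- data.frame(temperature = curve$temperatures -
                     if (celsius) 273.15 else 0,
                   intensity = curve$intensities)
  if (!is.null(curve$intensity_errors)) df$error <- curve$intensity_errors
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Scale a melt curve so its maximum intensity is 100
#'
#' The standard pre-fit normalization; intensity errors are scaled by the
#' same factor.
#'
#' @param curve a [melt_curve()].
#' @return the rescaled [melt_curve()].
#' @export
scale_to_100 <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  m <- max(curve$intensities)
  if (m <= 0) stop("maximum intensity must be positive")
  s <- 100 / m
  curve$intensities <- curve$intensities * s
  if (!is.null(curve$intensity_errors))
    curve$intensity_errors <- curve$intensity_errors * s
  curve
}

## data-driven starting values: Tm at the steepest descent of the smoothed
## curve, baselines from the terminal plateaus, generic dH/dCp
.melt_start <- function(curve) {
  T <- curve$temperatures
  I <- curve$intensities
  sm <- stats::filter(I, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- I[is.na(sm)]
  slope <- diff(as.numeric(sm)) / diff(T)
  Tm0 <- mean(T[which.min(slope) + 0:1])
  k <- min(3, length(I))
  list(dH = 50, Tm = Tm0, dCp = 0.5,
       alpha_F = mean(utils::head(I, k)), alpha_U = mean(utils::tail(I, k)),
       beta_F = 0, beta_U = 0)
}

#' Fit the dimeric two-state model to a melt curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of [intensity_model()] to a fluorescence melt curve.
#' The curve is first scaled so its maximum is 100 (disable with
#' `scale = FALSE`). The 7-parameter model fits
#' `(dH, Tm, dCp, alpha_F, alpha_U, beta_F, beta_U)`; the 5-parameter model
#' constrains `beta_F = beta_U = 0`. Starting values come from the curve
#' itself (steepest-descent `Tm`, plateau baselines, `dH` = 50 kcal/mol,
#' `dCp` = 0.5 kcal/mol/K); `multistart` jittered restarts are attempted and
#' the lowest-chi-square converged fit kept.
#'
#' @param curve a [melt_curve()].
#' @param n_params 5 or 7.
#' @param scale scale the curve to max 100 before fitting (default `TRUE`).
#' @param multistart number of jittered restarts (default 5; 1 = single
#'   start).
#' @param start optional named list overriding the automatic starting values
#'   (any subset of the parameter names).
#' @param seed optional seed for the restart jitter.
#' @return object of class `"thermo_fit"`: parameter estimates, `chi2`
#'   (`sum(((obs - model)/sigma)^2)`, `sigma` = `intensity_errors` or 1),
#'   `n_points`, `n_params`, `converged`, the fitted curve, and `mc_errors`
#'   (`NULL` until [mc_errors()] is run).
#' @export
fit_melt <- function(curve, n_params = 5, scale = TRUE, multistart = 5,
                     start = NULL, seed = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  if (!n_params %in% c(5, 7)) stop("n_params must be 5 or 7")
  if (length(curve$temperatures) <= n_params)
    stop("need more data points than parameters")
  if (scale) curve <- scale_to_100(curve)
  if (!is.null(seed)) set.seed(seed)
  T <- curve$temperatures
  I <- curve$intensities
  sigma <- if (is.null(curve$intensity_errors)) rep(1, length(I))
           else curve$intensity_errors
  s0 <- .melt_start(curve)
  if (!is.null(start)) s0[names(start)] <- start
  free <- if (n_params == 7)
    c("dH", "Tm", "dCp", "alpha_F", "alpha_U", "beta_F", "beta_U")
  else c("dH", "Tm", "dCp", "alpha_F", "alpha_U")
  span <- max(T) - min(T)
  lower <- c(dH = 1, Tm = min(T) - span, dCp = -10,
             alpha_F = -1e4, alpha_U = -1e4, beta_F = -100, beta_U = -100)
  upper <- c(dH = 2000, Tm = max(T) + span, dCp = 50,
             alpha_F = 1e4, alpha_U = 1e4, beta_F = 100, beta_U = 100)
  model_fn <- function(p) {
    full <- s0
    full[free] <- as.list(p)
    if (n_params == 5) full$beta_F <- full$beta_U <- 0
    intensity_model(T, dH = full$dH, Tm = full$Tm, dCp = full$dCp,
                    alpha_F = full$alpha_F, beta_F = full$beta_F,
                    alpha_U = full$alpha_U, beta_U = full$beta_U,
                    Ct = curve$Ct, Ct_ref = curve$Ct_ref)
  }
  residual_fn <- function(p) (I - model_fn(p)) / sigma
  try_one <- function(p0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residual_fn,
                         lower = lower[free], upper = upper[free],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, chi2 = sum(residual_fn(fit$par)^2),
         converged = fit$info %in% 1:4)
  }
  p0 <- unlist(s0[free])
  starts <- list(p0)
  if (multistart > 1) {
    for (i in seq_len(multistart - 1)) {
      p <- p0
      p["Tm"] <- p["Tm"] + stats::runif(1, -0.1, 0.1) * span
      p["dH"] <- p["dH"] * exp(stats::runif(1, -0.7, 0.7))
      p["dCp"] <- p["dCp"] * exp(stats::runif(1, -1, 1))
      starts[[i + 1]] <- pmin(pmax(p, lower[free]), upper[free])
    }
  }
  fits <- Filter(Negate(is.null), lapply(starts, try_one))
  if (length(fits) == 0) stop("melt-curve fit failed from every start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "chi2"))]]
  par <- as.list(best$par)
  if (n_params == 5) par$beta_F <- par$beta_U <- 0
  structure(list(dH = par$dH, Tm = par$Tm, dCp = par$dCp,
                 alpha_F = par$alpha_F, alpha_U = par$alpha_U,
                 beta_F = par$beta_F, beta_U = par$beta_U,
                 chi2 = best$chi2, n_points = length(I),
                 n_params = as.integer(n_params),
                 converged = best$converged,
                 curve = curve, mc_errors = NULL),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf("%d-parameter dimer two-state fit (%d points): chi2 = %.3f%s\n",
              x$n_params, x$n_points, x$chi2,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  dH = %.1f kcal/mol, Tm = %.2f K (%.2f C), dCp = %.2f kcal/mol/K\n",
              x$dH, x$Tm, x$Tm - 273.15, x$dCp))
  cat(sprintf("  baselines: alpha_F = %.2f, alpha_U = %.2f, beta_F = %.3f, beta_U = %.3f\n",
              x$alpha_F, x$alpha_U, x$beta_F, x$beta_U))
  invisible(x)
}

#' Model intensities of a fitted melt curve
#'
#' @param fit a [fit_melt()] result.
#' @param T temperatures (K); default the fitted curve's grid.
#' @return model intensities.
#' @export
fitted_intensity <- function(fit, T = fit$curve$temperatures) {
  intensity_model(T, dH = fit$dH, Tm = fit$Tm, dCp = fit$dCp,
                  alpha_F = fit$alpha_F, beta_F = fit$beta_F,
                  alpha_U = fit$alpha_U, beta_U = fit$beta_U,
                  Ct = fit$curve$Ct, Ct_ref = fit$curve$Ct_ref)
}

#' Unfolding free energy derived from a fit
#'
#' @param fit a [fit_melt()] result.
#' @param T temperature(s), K.
#' @return `dG_unfold` at the fitted parameters (kcal/mol).
#' @export
fit_dG <- function(fit, T) {
  dG_unfold(T, dH = fit$dH, Tm = fit$Tm, dCp = fit$dCp,
            Ct = fit$curve$Ct_ref)
}

#' Nested-model F-test between two melt-curve fits
#'
#' @param fit_simple,fit_complex [fit_melt()] results on the same data with
#'   different parameter counts (e.g. 5 vs 7).
#' @param alpha significance level (default 0.05).
#' @return an `"f_test_result"`, see [f_statistic()].
#' @export
f_test <- function(fit_simple, fit_complex, alpha = 0.05) {
  stopifnot(inherits(fit_simple, "thermo_fit"),
            inherits(fit_complex, "thermo_fit"))
  if (fit_simple$n_points != fit_complex$n_points)
    stop("fits are not on the same data")
  if (fit_simple$n_params >= fit_complex$n_params)
    stop("fit_simple must have fewer parameters than fit_complex")
  f_statistic(fit_simple$chi2, fit_complex$chi2, fit_simple$n_points,
              p_simple = fit_simple$n_params,
              p_complex = fit_complex$n_params, alpha = alpha)
}

#' F statistic for nested least-squares models
#'
#' `F = ((chi2_simple - chi2_complex) / dp) / (chi2_complex / (N - p_complex))`
#' compared against the critical value of the F distribution at
#' `(dp, N - p_complex)` degrees of freedom. The chi-square inputs are the
#' residual sums of squares of the two fits. A complex fit that is worse than
#' the simple one (possible with independent nonlinear optimizations) floors
#' F at 0 with a warning.
#'
#' @param chi2_simple,chi2_complex residual chi-square of the
#'   fewer-/more-parameter fit.
#' @param n_points number of data points N.
#' @param p_simple,p_complex parameter counts (default 5 and 7).
#' @param alpha significance level.
#' @return object of class `"f_test_result"`: `F`, `df_num`, `df_den`,
#'   `F_critical`, `alpha`, `prefer_complex`.
#' @export
f_statistic <- function(chi2_simple, chi2_complex, n_points,
                        p_simple = 5, p_complex = 7, alpha = 0.05) {
  if (p_complex <= p_simple) stop("p_complex must exceed p_simple")
  df_num <- p_complex - p_simple
  df_den <- n_points - p_complex
  if (df_den < 1) stop("no residual degrees of freedom")
  if (chi2_simple < chi2_complex) {
    warning("complex fit is worse than simple fit; F floored at 0")
    F <- 0
  } else {
    F <- ((chi2_simple - chi2_complex) / df_num) / (chi2_complex / df_den)
  }
  F_crit <- stats::qf(1 - alpha, df_num, df_den)
  structure(list(F = F, df_num = df_num, df_den = df_den,
                 F_critical = F_crit, alpha = alpha,
                 prefer_complex = F > F_crit),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("F(%d,%d) = %.2f, critical %.2f at alpha = %g -> %s model\n",
              x$df_num, x$df_den, x$F, x$F_critical, x$alpha,
              if (x$prefer_complex) "complex" else "simple"))
  invisible(x)
}

#' Monte-Carlo parameter errors for a melt-curve fit
#'
#' Creates `n_sets` synthetic data sets by adding Gaussian noise (sd =
#' `noise_sd`) to the fitted model curve, refits each starting from the
#' original solution, and reports the standard deviation of every parameter
#' across the refits, plus the derived error of the unfolding free energy at
#' `T_ref`. More than 20% refit failures aborts.
#'
#' @param fit a converged [fit_melt()] result.
#' @param noise_sd noise standard deviation; defaults to the curve's
#'   `intensity_errors` (their mean) or, failing that, the fit's residual
#'   standard deviation.
#' @param n_sets number of synthetic data sets (default 100).
#' @param seed optional seed.
#' @param T_ref reference temperature for the derived dG error (default the
#'   fitted `Tm`).
#' @return list of class `"mc_errors"`: per-parameter standard deviations
#'   (`dH`, `Tm`, `dCp`, `alpha_F`, `alpha_U`, `beta_F`, `beta_U`),
#'   `dG_at_T_ref`, `T_ref`, `n_ok`, `n_failed`.
#' @export
mc_errors <- function(fit, noise_sd = NULL, n_sets = 100, seed = NULL,
                      T_ref = fit$Tm) {
  stopifnot(inherits(fit, "thermo_fit"))
  if (!fit$converged) stop("mc_errors needs a converged fit")
  if (is.null(noise_sd)) {
    noise_sd <- if (!is.null(fit$curve$intensity_errors))
      mean(fit$curve$intensity_errors)
    else sqrt(fit$chi2 / max(1, fit$n_points - fit$n_params))
  }
  if (!is.null(seed)) set.seed(seed)
  ideal <- fitted_intensity(fit)
  pars <- c("dH", "Tm", "dCp", "alpha_F", "alpha_U", "beta_F", "beta_U")
  start <- stats::setNames(lapply(pars, function(p) fit[[p]]), pars)
  res <- matrix(NA_real_, nrow = n_sets, ncol = length(pars),
                dimnames = list(NULL, pars))
  dGs <- rep(NA_real_, n_sets)
  n_failed <- 0
  for (i in seq_len(n_sets)) {
    curve_i <- fit$curve
    curve_i$intensities <- ideal + stats::rnorm(length(ideal), sd = noise_sd)
    refit <- tryCatch(
      fit_melt(curve_i, n_params = fit$n_params, scale = FALSE,
               multistart = 1, start = start),
      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) { n_failed <- n_failed + 1; next }
    res[i, ] <- unlist(refit[pars])
    dGs[i] <- fit_dG(refit, T_ref)
  }
  if (n_failed > 0.2 * n_sets)
    stop(sprintf("%d of %d Monte-Carlo refits failed", n_failed, n_sets))
  out <- as.list(apply(res, 2, stats::sd, na.rm = TRUE))
  out$dG_at_T_ref <- stats::sd(dGs, na.rm = TRUE)
  out$T_ref <- T_ref
  out$n_ok <- n_sets - n_failed
  out$n_failed <- n_failed
  class(out) <- "mc_errors"
  out
}

#' Experimental folding free-energy difference between two variants
#'
#' `ddG = dG_unfold(reference at T_ref) - dG_unfold(variant at T_ref)`, both
#' from fitted melt curves. With this sign convention a variant that unfolds
#' at higher temperature (more stable) gives a negative ddG, matching the
#' prediction-side convention.
#'
#' @param fit_ref,fit_variant converged [fit_melt()] results at the same
#'   concentration.
#' @param T_ref reference temperature (K); default the reference fit's `Tm`.
#' @return ddG (kcal/mol).
#' @export
ddG_experimental <- function(fit_ref, fit_variant, T_ref = fit_ref$Tm) {
  stopifnot(inherits(fit_ref, "thermo_fit"),
            inherits(fit_variant, "thermo_fit"))
  if (!isTRUE(all.equal(fit_ref$curve$Ct, fit_variant$curve$Ct)))
    stop("fits must share the protein concentration")
  rng <- range(c(fit_ref$curve$temperatures, fit_variant$curve$temperatures))
  if (T_ref < rng[1] || T_ref > rng[2])
    warning("T_ref lies outside both fitted temperature ranges")
  fit_dG(fit_ref, T_ref) - fit_dG(fit_variant, T_ref)
}
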