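#' Energy-difference samples bridging two adjacent lambda windows
#'
#' Container for the raw material of a BAR estimate. Both directions store
#' dH = H(lambda_high) - H(lambda_low): `forward` evaluated on configurations
#' sampled at `lambda_low`, `reverse` on configurations sampled at
#' `lambda_high`.
#'
#' @param lambda_low,lambda_high the two lambda values, `lambda_low <
#'   lambda_high`.
#' @param forward,reverse ordered dH sample vectors (kcal/mol), each with at
#'   least one value.
#' @param temperature temperature (K) of both ensembles.
#' @param sample_interval time between successive samples (ps), used by
#'   autocorrelation diagnostics.
#' @return object of class `"window_pair"`.
#' @export
window_pair <- function(lambda_low, lambda_high, forward, reverse,
                        temperature = 300, sample_interval = 1) {
  if (!(lambda_low < lambda_high)) stop("lambda_low must be < lambda_high")
  if (length(forward) < 1 || length(reverse) < 1)
    stop("both sample sets must be non-empty")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(lambda_low = lambda_low, lambda_high = lambda_high,
                 forward = as.numeric(forward), reverse = as.numeric(reverse),
                 temperature = temperature, sample_interval = sample_interval),
            class = "window_pair")
}

#' Reverse the direction of a window pair
#'
#' Returns the physically reversed transformation: sample roles are swapped
#' and dH signs flipped (the Hamiltonian difference changes sign when the
#' direction of the transformation is reversed). BAR on the reversed pair is
#' exactly the negative of BAR on the original.
#'
#' @param pair a [window_pair()].
#' @return a [window_pair()] for the reversed transformation (the lambda
#'   labels keep their order; only the sample roles and signs change).
#' @export
reverse_pair <- function(pair) {
  stopifnot(inherits(pair, "window_pair"))
  window_pair(pair$lambda_low, pair$lambda_high,
              forward = -pair$reverse, reverse = -pair$forward,
              temperature = pair$temperature,
              sample_interval = pair$sample_interval)
}

## BAR self-consistency in work space. w_f: forward works (= forward dH);
## w_r: reverse works (= -reverse dH). Solves
##   sum_i logistic(-(M + beta*(w_f_i - dG))) =
##   sum_j logistic(-(-M + beta*(w_r_j + dG))),  M = log(n_f/n_r),
## which is monotone increasing in dG, by root bracketing.
.bar_core <- function(w_f, w_r, beta, tol = 1e-12) {
  n_f <- length(w_f); n_r <- length(w_r)
  M <- log(n_f / n_r)
  g <- function(dG) {
    sum(stats::plogis(-(M + beta * (w_f - dG)))) -
      sum(stats::plogis(-(-M + beta * (w_r + dG))))
  }
  lo <- min(c(w_f, -w_r)) - 1
  hi <- max(c(w_f, -w_r)) + 1
  while (g(lo) > 0) lo <- lo - (hi - lo)
  while (g(hi) < 0) hi <- hi + (hi - lo)
  stats::uniroot(g, c(lo, hi), tol = tol)$root
}

#' Bennett acceptance-ratio estimate for one window pair
#'
#' Solves the BAR self-consistency condition (equality of summed Fermi
#' functions over the forward and reverse samples, with the standard
#' `log(n_f/n_r)` sample-size offset) by monotone root bracketing to a
#' root tolerance of 1e-12 kcal/mol. The error is the five-block standard
#' deviation of [block_error()] unless `n_blocks = 0`.
#'
#' If the two dH distributions do not overlap (minimum forward dH exceeds the
#' maximum reverse dH by more than `overlap_gap_kT` thermal units, or vice
#' versa) the estimate is still returned but flagged via attribute
#' `"overlap_warning"` and a warning, since BAR is unreliable without
#' overlap.
#'
#' @param pair a [window_pair()] with at least 2 samples per direction.
#' @param n_blocks number of contiguous blocks for the error estimate
#'   (default 5); 0 suppresses the error computation (`dG_error = NA`).
#' @param overlap_gap_kT gap (in units of kT) beyond which the forward and
#'   reverse sample ranges are considered non-overlapping.
#' @return object of class `"pair_estimate"`: list with `dG`, `dG_error`
#'   (kcal/mol), `n_blocks`, and logical `overlap_warning`.
#' @export
bar_estimate <- function(pair, n_blocks = 5, overlap_gap_kT = 10) {
  stopifnot(inherits(pair, "window_pair"))
  if (length(pair$forward) < 2 || length(pair$reverse) < 2)
    stop("BAR needs at least 2 samples in each direction")
  beta <- .beta(pair$temperature)
  kT <- 1 / beta
  gap <- max(min(pair$forward) - max(pair$reverse),
             min(pair$reverse) - max(pair$forward))
  overlap_warning <- is.finite(gap) && gap > overlap_gap_kT * kT
  if (overlap_warning)
    warning(sprintf(paste0("forward/reverse dH distributions do not overlap ",
                           "(gap %.2f kcal/mol > %g kT); BAR estimate is ",
                           "unreliable"), gap, overlap_gap_kT))
  dG <- .bar_core(pair$forward, -pair$reverse, beta)
  err <- if (n_blocks > 0) block_error(pair, n_blocks = n_blocks) else NA_real_
  structure(list(dG = dG, dG_error = err,
                 n_blocks = if (n_blocks > 0) as.integer(n_blocks) else 0L,
                 overlap_warning = overlap_warning),
            class = "pair_estimate")
}

#' @export
print.pair_estimate <- function(x, ...) {
  cat(sprintf("BAR pair estimate: dG = %.4f +/- %s kcal/mol (%d blocks)\n",
              x$dG, ifelse(is.na(x$dG_error), "NA",
                           sprintf("%.4f", x$dG_error)), x$n_blocks))
  invisible(x)
}

#' One-sided exponential (Zwanzig) free-energy average
#'
#' Free-energy difference of the low -> high transformation estimated from a
#' single direction: `-kT log(mean(exp(-beta dH)))` for the forward samples,
#' and the sign-converted `+kT log(mean(exp(+beta dH)))` for the reverse
#' samples (so both directions estimate the same quantity). Overflow-safe via
#' a max-shift. On well-overlapped data the two one-sided estimates bracket
#' the BAR estimate (forward biased high, reverse biased low).
#'
#' @param pair a [window_pair()].
#' @param direction `"forward"` or `"reverse"`.
#' @return free-energy estimate (kcal/mol).
#' @export
exp_average <- function(pair, direction = c("forward", "reverse")) {
  stopifnot(inherits(pair, "window_pair"))
  direction <- match.arg(direction)
  x <- pair[[direction]]
  if (length(x) == 0) stop("empty sample set")
  beta <- .beta(pair$temperature)
  if (direction == "forward") -(.log_mean_exp(-beta * x)) / beta
  else (.log_mean_exp(beta * x)) / beta
}

#' Block standard-deviation error of a BAR pair estimate
#'
#' Splits each direction's time series into `n_blocks` contiguous blocks,
#' re-estimates BAR on each forward/reverse block pair, and returns the
#' standard deviation of the block estimates.
#'
#' @param pair a [window_pair()].
#' @param n_blocks number of contiguous blocks (default 5); each block must
#'   contain at least 2 samples in each direction.
#' @return standard deviation of the block BAR estimates (kcal/mol).
#' @export
block_error <- function(pair, n_blocks = 5) {
  stopifnot(inherits(pair, "window_pair"))
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (length(pair$forward) < 2 * n_blocks || length(pair$reverse) < 2 * n_blocks)
    stop("too few samples: need at least 2 per direction per block")
  beta <- .beta(pair$temperature)
  split_blocks <- function(x) {
    idx <- floor(seq_along(x) * n_blocks / length(x) - 1e-9) + 1
    split(x, idx)
  }
  fb <- split_blocks(pair$forward)
  rb <- split_blocks(pair$reverse)
  est <- vapply(seq_len(n_blocks), function(i) {
    .bar_core(fb[[i]], -rb[[i]], beta)
  }, numeric(1))
  stats::sd(est)
}

#' Integrated autocorrelation time of an energy-difference series
#'
#' `tau = dt * (1 + 2 * sum(rho(k)))`, with the sum over the empirical
#' autocorrelation function truncated at the first non-positive lag. A
#' constant series is degenerate (no correlation information); it returns
#' `sample_interval` flagged with attribute `"degenerate"` and a warning.
#'
#' @param series ordered numeric samples (at least 50).
#' @param sample_interval spacing between samples (ps).
#' @return integrated autocorrelation time (ps).
#' @export
autocorr_time <- function(series, sample_interval = 1) {
  n <- length(series)
  if (n < 50) stop("need at least 50 samples to estimate a correlation time")
  if (stats::sd(series) == 0) {
    warning("constant series: autocorrelation time undefined, returning sample_interval")
    return(structure(sample_interval, degenerate = TRUE))
  }
  rho <- stats::acf(series, lag.max = n - 1, plot = FALSE,
                    demean = TRUE)$acf[-1]
  first_np <- which(rho <= 0)
  if (length(first_np) > 0) rho <- rho[seq_len(first_np[1] - 1)]
  sample_interval * (1 + 2 * sum(rho))
}

#' Free-energy result for one alchemical leg
#'
#' A leg is one component (Coulomb or van der Waals switching) of one
#' transformation (X->I or Y->I) in one state (folded protein or unfolded
#' model peptide), summed over its lambda windows.
#'
#' @param dG free-energy change (kcal/mol).
#' @param dG_error its error (kcal/mol, >= 0).
#' @param component `"ele"` or `"vdw"`.
#' @param state `"folded"` or `"unfolded"`.
#' @param transformation `"XtoI"` or `"YtoI"`.
#' @param subunit_scale 1.0, or 0.5 when the mutation is applied
#'   simultaneously in both subunits of a dimer and the computed free energy
#'   is halved to obtain the per-mutation value.
#' @return object of class `"leg_result"`.
#' @export
leg_result <- function(dG, dG_error, component = c("ele", "vdw"),
                       state = c("folded", "unfolded"),
                       transformation = c("XtoI", "YtoI"),
                       subunit_scale = 1.0) {
  component <- match.arg(component)
  state <- match.arg(state)
  transformation <- match.arg(transformation)
  if (dG_error < 0) stop("dG_error must be >= 0")
  if (!subunit_scale %in% c(0.5, 1.0))
    stop("subunit_scale must be 0.5 or 1.0")
  structure(list(dG = dG, dG_error = dG_error, component = component,
                 state = state, transformation = transformation,
                 subunit_scale = subunit_scale),
            class = "leg_result")
}

#' Assemble a full alchemical leg from its window pairs
#'
#' BAR-estimates every window pair, checks that the pairs tile the lambda
#' interval [0, 1] without gaps or overlaps, and combines:
#' `dG = subunit_scale * sum(pair dG)`, error in quadrature
#' (`subunit_scale * sqrt(sum(pair errors^2))`).
#'
#' @param pairs list of [window_pair()] objects covering [0, 1].
#' @param component,state,transformation,subunit_scale leg metadata, see
#'   [leg_result()].
#' @param n_blocks blocks for per-pair errors (default 5).
#' @return a [leg_result()] with attribute `"pair_estimates"`.
#' @export
leg_free_energy <- function(pairs, component = c("ele", "vdw"),
                            state = c("folded", "unfolded"),
                            transformation = c("XtoI", "YtoI"),
                            subunit_scale = 1.0, n_blocks = 5) {
  component <- match.arg(component)
  state <- match.arg(state)
  transformation <- match.arg(transformation)
  stopifnot(length(pairs) >= 1,
            all(vapply(pairs, inherits, logical(1), "window_pair")))
  ord <- order(vapply(pairs, `[[`, numeric(1), "lambda_low"))
  pairs <- pairs[ord]
  lo <- vapply(pairs, `[[`, numeric(1), "lambda_low")
  hi <- vapply(pairs, `[[`, numeric(1), "lambda_high")
  if (abs(lo[1]) > 1e-8 || abs(hi[length(hi)] - 1) > 1e-8 ||
      any(abs(hi[-length(hi)] - lo[-1]) > 1e-8))
    stop("window pairs must tile the lambda interval [0, 1] without gaps or overlaps")
  est <- lapply(pairs, bar_estimate, n_blocks = n_blocks)
  dGs <- vapply(est, `[[`, numeric(1), "dG")
  errs <- vapply(est, `[[`, numeric(1), "dG_error")
  out <- leg_result(dG = subunit_scale * sum(dGs),
                    dG_error = subunit_scale * sqrt(sum(errs^2)),
                    component = component, state = state,
                    transformation = transformation,
                    subunit_scale = subunit_scale)
  attr(out, "pair_estimates") <- est
  out
}
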