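#' Specification of a synthetic alchemical transformation
#'
#' Describes a set of lambda windows and the Gaussian work statistics used to
#' generate forward/reverse energy-difference (dH) samples with a known
#' ground-truth free-energy difference per window pair. Forward samples for a
#' pair are drawn from N(mu, sigma^2) on the lower-lambda ensemble; reverse
#' samples (same sign convention, dH = H(high) - H(low), evaluated on the
#' upper-lambda ensemble) from N(mu - beta*sigma^2, sigma^2), the unique
#' Gaussian pairing consistent with the Crooks fluctuation relation. The true
#' pair free energy is then mu - beta*sigma^2/2 in closed form.
#'
#' @param n_windows number of lambda states (e.g. 21 for a Coulomb switching
#'   leg, 41 for a van der Waals leg); ignored when `lambda_schedule` is given.
#' @param lambda_schedule strictly increasing vector of lambda values starting
#'   at 0 and ending at 1; default `seq(0, 1, length.out = n_windows)`.
#' @param pair_mean per-pair forward work mean mu (kcal/mol); scalar or one
#'   value per window pair.
#' @param pair_sd per-pair work standard deviation sigma (kcal/mol), >= 0;
#'   scalar or per pair.
#' @param samples_per_window number of dH samples per direction (>= 2).
#' @param autocorrelation_time target integrated autocorrelation time (ps) of
#'   the dH series, injected through an AR(1) process; equal to
#'   `sample_interval` means white noise.
#' @param sample_interval spacing between successive samples (ps).
#' @param temperature simulation temperature (K).
#' @param seed integer seed making the generated samples reproducible.
#' @return object of class `"alchemy_spec"`.
#' @seealso [gen_alchemy_windows()]
#' @export
alchemy_spec <- function(n_windows = 21, lambda_schedule = NULL,
                         pair_mean = 0.5, pair_sd = 0.5,
                         samples_per_window = 200,
                         autocorrelation_time = 3, sample_interval = 1,
                         temperature = 300, seed = 1L) {
  if (is.null(lambda_schedule))
    lambda_schedule <- seq(0, 1, length.out = n_windows)
  if (length(lambda_schedule) < 2 || any(diff(lambda_schedule) <= 0))
    stop("lambda_schedule must be strictly increasing")
  if (abs(lambda_schedule[1]) > 1e-12 ||
      abs(lambda_schedule[length(lambda_schedule)] - 1) > 1e-12)
    stop("lambda_schedule must start at 0 and end at 1")
  if (any(pair_sd < 0)) stop("pair_sd must be >= 0")
  if (samples_per_window < 2) stop("samples_per_window must be >= 2")
  if (autocorrelation_time < sample_interval)
    stop("autocorrelation_time must be >= sample_interval")
  if (temperature <= 0) stop("temperature must be positive")
  n_pairs <- length(lambda_schedule) - 1
  spec <- list(lambda_schedule = lambda_schedule,
               pair_mean = rep_len(pair_mean, n_pairs),
               pair_sd = rep_len(pair_sd, n_pairs),
               samples_per_window = as.integer(samples_per_window),
               autocorrelation_time = autocorrelation_time,
               sample_interval = sample_interval,
               temperature = temperature,
               seed = as.integer(seed))
  class(spec) <- "alchemy_spec"
  spec
}

## stationary AR(1) series with unit marginal variance and integrated
## autocorrelation time tau (in units of the sampling interval dt):
## phi = (tau - dt)/(tau + dt) so that dt*(1+phi)/(1-phi) = tau
.ar1_series <- function(n, tau, dt) {
  phi <- (tau - dt) / (tau + dt)
  if (phi <= 0) return(stats::rnorm(n))
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
  for (i in 2:n) z[i] <- phi * z[i - 1] + innov[i - 1]
  z
}

#' Generate synthetic lambda-window energy-difference samples
#'
#' For every adjacent pair of lambda states, draws forward samples on the
#' lower-lambda ensemble and reverse samples on the upper-lambda ensemble from
#' Crooks-consistent Gaussians (see [alchemy_spec()]), optionally with AR(1)
#' autocorrelation. The exact per-pair free-energy difference
#' `mu - beta*sigma^2/2` is attached as attribute `"truth"`.
#'
#' @param spec an [alchemy_spec()].
#' @return list of [window_pair()] objects, one per adjacent lambda pair, with
#'   attribute `"truth"`: a data.frame of `lambda_low`, `lambda_high`,
#'   `dG_true` (kcal/mol).
#' @export
gen_alchemy_windows <- function(spec) {
  stopifnot(inherits(spec, "alchemy_spec"))
  set.seed(spec$seed)
  beta <- .beta(spec$temperature)
  lam <- spec$lambda_schedule
  n_pairs <- length(lam) - 1
  n <- spec$samples_per_window
  tau <- spec$autocorrelation_time
  dt <- spec$sample_interval
  pairs <- vector("list", n_pairs)
  truth <- data.frame(lambda_low = lam[-length(lam)], lambda_high = lam[-1],
                      dG_true = spec$pair_mean - beta * spec$pair_sd^2 / 2)
  for (i in seq_len(n_pairs)) {
    mu <- spec$pair_mean[i]
    s <- spec$pair_sd[i]
    fwd <- mu + s * .ar1_series(n, tau, dt)
    rev <- (mu - beta * s^2) + s * .ar1_series(n, tau, dt)
    pairs[[i]] <- window_pair(lam[i], lam[i + 1], fwd, rev,
                              temperature = spec$temperature,
                              sample_interval = dt)
  }
  attr(pairs, "truth") <- truth
  pairs
}

#' Specification of a synthetic thermal-denaturation curve
#'
#' Parameters of the concentration-dependent dimeric two-state unfolding model
#' (see [frac_unfolded()]) plus fluorescence baselines and a homoscedastic
#' Gaussian noise level. The defaults emulate a moderately stable FbFP
#' measured at 4.2 uM monomer on a 0-100 fluorescence scale over a 14-68 C
#' temperature ramp.
#'
#' @param dH unfolding enthalpy at `Tm` (kcal/mol).
#' @param Tm melting temperature (K) at concentration `Ct_ref`.
#' @param dCp heat-capacity change of unfolding (kcal/mol/K), assumed
#'   temperature independent.
#' @param alpha_F,alpha_U folded/unfolded fluorescence baselines extrapolated
#'   to 0 K (intensity units).
#' @param beta_F,beta_U baseline slopes (units/K); both zero gives the
#'   five-parameter model.
#' @param Ct total monomer concentration of the simulated sample (mol/L).
#' @param Ct_ref reference concentration at which `Tm` is defined (mol/L);
#'   defaults to `Ct` so that the half-transition sits exactly at `Tm`.
#' @param temperatures ordered measurement grid (K).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed integer seed.
#' @return object of class `"melt_spec"`.
#' @export
melt_spec <- function(dH = 100, Tm = 316, dCp = 1,
                      alpha_F = 100, alpha_U = 15, beta_F = 0, beta_U = 0,
                      Ct = 4.2e-6, Ct_ref = Ct,
                      temperatures = seq(287, 341, by = 3),
                      noise_sd = 1, seed = 1L) {
  if (Ct <= 0 || Ct_ref <= 0) stop("Ct must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (Tm < min(temperatures) || Tm > max(temperatures))
    stop("Tm must lie within the temperature grid")
  spec <- list(dH = dH, Tm = Tm, dCp = dCp,
               alpha_F = alpha_F, alpha_U = alpha_U,
               beta_F = beta_F, beta_U = beta_U,
               Ct = Ct, Ct_ref = Ct_ref,
               temperatures = temperatures,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "melt_spec"
  spec
}

#' Generate a synthetic fluorescence melt curve
#'
#' Evaluates the dimeric two-state intensity model at the grid temperatures of
#' a [melt_spec()] and adds i.i.d. Gaussian noise. The generating parameters
#' are attached as attribute `"truth"` for recovery tests.
#'
#' @param spec a [melt_spec()].
#' @return a [melt_curve()] with `intensity_errors` set to the noise level
#'   (when positive) and attribute `"truth"` holding the spec.
#' @export
gen_melt_curve <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  set.seed(spec$seed)
  ideal <- intensity_model(spec$temperatures, dH = spec$dH, Tm = spec$Tm,
                           dCp = spec$dCp, alpha_F = spec$alpha_F,
                           beta_F = spec$beta_F, alpha_U = spec$alpha_U,
                           beta_U = spec$beta_U, Ct = spec$Ct,
                           Ct_ref = spec$Ct_ref)
  noisy <- ideal + stats::rnorm(length(ideal), sd = spec$noise_sd)
  errs <- if (spec$noise_sd > 0) rep(spec$noise_sd, length(ideal)) else NULL
  curve <- melt_curve(spec$temperatures, noisy, intensity_errors = errs,
                      Ct = spec$Ct, Ct_ref = spec$Ct_ref)
  attr(curve, "truth") <- spec
  curve
}

#' Specification of a synthetic protein alignment
#'
#' Fixes the exact per-column residue composition of an aligned homolog set,
#' so that downstream per-site frequencies are known by construction.
#'
#' @param n_sequences number of aligned sequences (default 83, a typical
#'   size for a de-duplicated FbFP homolog collection).
#' @param length number of alignment columns; required when
#'   `column_compositions` is `NULL`.
#' @param column_compositions list with one named integer vector per column
#'   (names are residue one-letter codes, `"-"` for gap); each must sum to
#'   `n_sequences`. When `NULL`, random compositions over 2-4 residues are
#'   drawn per column.
#' @param seed integer seed controlling both the random compositions (if any)
#'   and the within-column assignment of residues to sequences.
#' @return object of class `"alignment_spec"`.
#' @export
alignment_spec <- function(n_sequences = 83, length = NULL,
                           column_compositions = NULL, seed = 1L) {
  if (n_sequences < 1) stop("n_sequences must be >= 1")
  if (is.null(column_compositions)) {
    if (is.null(length)) stop("give either length or column_compositions")
    set.seed(seed)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    column_compositions <- lapply(seq_len(length), function(i) {
      k <- sample(2:4, 1)
      res <- sample(aa, k)
      counts <- as.vector(stats::rmultinom(1, n_sequences, rep(1 / k, k)))
      stats::setNames(counts, res)
    })
  }
  for (i in seq_along(column_compositions)) {
    cc <- column_compositions[[i]]
    if (is.null(names(cc)) || any(!nzchar(names(cc))))
      stop("column compositions must be named residue counts")
    if (sum(cc) != n_sequences)
      stop(sprintf("column %d counts sum to %d, not n_sequences = %d",
                   i, sum(cc), n_sequences))
  }
  spec <- list(n_sequences = as.integer(n_sequences),
               length = length(column_compositions),
               column_compositions = column_compositions,
               seed = as.integer(seed))
  class(spec) <- "alignment_spec"
  spec
}

#' Generate an alignment with exact per-column residue counts
#'
#' Residues are assigned to sequences by a seeded random permutation within
#' each column, and the sequence order itself is shuffled, so per-column
#' counts match the spec exactly while row-wise composition is randomized.
#'
#' @param spec an [alignment_spec()].
#' @return named character vector of aligned sequences (`seq_001` ...).
#' @export
gen_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  set.seed(spec$seed)
  n <- spec$n_sequences
  mat <- vapply(spec$column_compositions, function(cc) {
    sample(rep(names(cc), times = cc))
  }, character(n))
  if (n == 1) mat <- matrix(mat, nrow = 1)
  seqs <- apply(mat, 1, paste0, collapse = "")
  names(seqs) <- sprintf("seq_%03d", seq_len(n))
  seqs[sample(n)]
}

#' Write window-pair samples as plain tabular text
#'
#' One whitespace-delimited file per direction per window pair, two columns
#' (`time_ps`, `dH_kcal_mol`), named
#' `pair_<lambda_low>_<lambda_high>_<forward|reverse>.dat`.
#'
#' @param pairs list of [window_pair()] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_window_pairs <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (p in pairs) {
    for (direction in c("forward", "reverse")) {
      f <- file.path(dir, sprintf("pair_%.4f_%.4f_%s.dat",
                                  p$lambda_low, p$lambda_high, direction))
      x <- p[[direction]]
      df <- data.frame(time_ps = (seq_along(x) - 1) * p$sample_interval,
                       dH_kcal_mol = x)
      utils::write.table(df, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read window-pair samples written by [write_window_pairs()]
#'
#' @param dir directory containing `pair_*_{forward,reverse}.dat` files.
#' @param temperature temperature (K) to attach to the pairs.
#' @return list of [window_pair()] objects ordered by lambda.
#' @export
read_window_pairs <- function(dir, temperature = 300) {
  files <- list.files(dir, pattern = "^pair_.*_forward\\.dat$")
  if (length(files) == 0) stop("no window-pair files found in ", dir)
  info <- regmatches(files, regexec("^pair_([0-9.]+)_([0-9.]+)_forward\\.dat$",
                                    files))
  lam_lo <- vapply(info, function(m) as.numeric(m[2]), numeric(1))
  lam_hi <- vapply(info, function(m) as.numeric(m[3]), numeric(1))
  ord <- order(lam_lo)
  pairs <- lapply(ord, function(i) {
    fwd_df <- utils::read.table(file.path(dir, files[i]), header = TRUE)
    rev_file <- sub("_forward\\.dat$", "_reverse.dat", files[i])
    rev_df <- utils::read.table(file.path(dir, rev_file), header = TRUE)
    dt <- if (nrow(fwd_df) > 1) fwd_df$time_ps[2] - fwd_df$time_ps[1] else 1
    window_pair(lam_lo[i], lam_hi[i], fwd_df$dH_kcal_mol, rev_df$dH_kcal_mol,
                temperature = temperature, sample_interval = dt)
  })
  pairs
}

#' Write an alignment to aligned FASTA
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param path output FASTA file.
#' @return invisibly, `path`.
#' @export
write_alignment_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read an aligned FASTA file as a named character vector
#'
#' @param path FASTA file of equal-length aligned protein sequences.
#' @return named character vector.
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
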