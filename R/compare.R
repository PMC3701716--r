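#' Load the packaged mutant screening table (predicted vs experimental ddG)
#'
#' Per-mutant predicted folding free-energy differences (Coulomb-switching
#' and van der Waals-switching components plus total, kcal/mol) and the
#' experimentally determined ddG with errors. Mutants whose fluorescence is
#' lost at room temperature carry `NA` experimental values (never
#' zero-filled).
#'
#' @return data.frame of class `"screen_table"` with columns `mutant`,
#'   `ddG_coulomb`, `ddG_vdw`, `ddG_total`, `ddG_total_err`, `ddG_exp`,
#'   `ddG_exp_err`.
#' @export
load_screen_ddg <- function() {
  path <- system.file("extdata", "screen_ddg.csv", package = "lovtherm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$mutant)) stop("mutant labels must be unique")
  class(df) <- c("screen_table", "data.frame")
  df
}

#' Load the packaged melting-temperature table
#'
#' Melting temperatures (Celsius, with errors) of the wild type, all tested
#' single mutants and the multiple-mutant combinations. The `single` column
#' distinguishes single point mutants; a missing `tm_c` marks a variant
#' whose fluorescence was too weak to measure.
#'
#' @return data.frame with columns `mutant`, `tm_c`, `tm_err`, `single`.
#' @export
load_screen_tm <- function() {
  path <- system.file("extdata", "screen_tm.csv", package = "lovtherm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$single <- as.logical(df$single)
  df
}

#' Average per-subunit predictions of the same mutation
#'
#' Structure-based predictors give slightly different ddG values for the two
#' chemically identical subunits of an asymmetric dimer structure; the
#' per-mutation value is their arithmetic mean. If one subunit value is
#' missing the other is passed through with a warning.
#'
#' @param ddg_subunit1,ddg_subunit2 ddG predictions (kcal/mol), vectorized.
#' @return averaged ddG.
#' @export
average_subunits <- function(ddg_subunit1, ddg_subunit2) {
  out <- (ddg_subunit1 + ddg_subunit2) / 2
  miss1 <- is.na(ddg_subunit1); miss2 <- is.na(ddg_subunit2)
  if (any(miss1 | miss2)) {
    warning("missing subunit value(s): passing the other subunit through")
    out[miss1] <- ddg_subunit2[miss1]
    out[miss2] <- ddg_subunit1[miss2]
  }
  out
}

.usable <- function(table, exclude = NULL) {
  df <- table[!is.na(table$ddG_total) & !is.na(table$ddG_exp), , drop = FALSE]
  df[!df$mutant %in% exclude, , drop = FALSE]
}

#' Sign agreement between predicted and experimental ddG
#'
#' Counts mutants whose predicted and experimental ddG have the same sign
#' (zero counts as positive). Mutants with a missing experimental value are
#' excluded.
#'
#' @param table a [load_screen_ddg()]-style data.frame.
#' @param exclude mutant labels to drop.
#' @return list with `n_agree`, `n_total`, `disagreeing` (labels).
#' @export
sign_agreement <- function(table, exclude = NULL) {
  df <- .usable(table, exclude)
  sgn <- function(x) ifelse(x >= 0, 1, -1)
  agree <- sgn(df$ddG_total) == sgn(df$ddG_exp)
  list(n_agree = sum(agree), n_total = nrow(df),
       disagreeing = df$mutant[!agree])
}

#' Regression of predicted on experimental ddG
#'
#' Ordinary least squares of the predicted total ddG on the experimental
#' ddG, with the Pearson correlation of the same pairs.
#'
#' @param table a [load_screen_ddg()]-style data.frame.
#' @param exclude mutant labels to drop (e.g. outliers).
#' @return list with `slope`, `intercept` (kcal/mol), `pearson_r`, `n`.
#' @export
regression_line <- function(table, exclude = NULL) {
  df <- .usable(table, exclude)
  if (nrow(df) < 3) stop("need at least 3 usable records")
  if (stats::sd(df$ddG_exp) == 0) stop("degenerate experimental variance")
  fit <- stats::lm(ddG_total ~ ddG_exp, data = df)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(df$ddG_exp, df$ddG_total),
       n = nrow(df))
}

#' Mean absolute error of predicted vs experimental ddG
#'
#' With `correction = "none"`, `mean(|predicted - experimental|)`. With
#' `correction = "linear"`, residuals are taken about the fitted regression
#' line of predicted on experimental (i.e. the systematic slope/offset of
#' the predictor is removed before averaging absolute residuals).
#'
#' @param table a [load_screen_ddg()]-style data.frame.
#' @param exclude mutant labels to drop.
#' @param correction `"none"` or `"linear"`.
#' @return MAE (kcal/mol).
#' @export
mae <- function(table, exclude = NULL, correction = c("none", "linear")) {
  correction <- match.arg(correction)
  df <- .usable(table, exclude)
  if (nrow(df) < 1) stop("no usable records")
  if (correction == "none") return(mean(abs(df$ddG_total - df$ddG_exp)))
  line <- regression_line(table, exclude)
  mean(abs(df$ddG_total - (line$intercept + line$slope * df$ddG_exp)))
}

#' Count single mutants more stable than the wild type
#'
#' A single mutant counts as stabilized when its melting temperature is
#' strictly greater than `wt_tm`. Mutants with a missing Tm (e.g. lost
#' fluorescence) stay in the denominator but never the numerator.
#'
#' @param tm_table a [load_screen_tm()]-style data.frame (any consistent
#'   temperature unit).
#' @param wt_tm wild-type melting temperature, same unit.
#' @return list with `n_stable`, `n_total`, `stable` (labels).
#' @export
stability_count <- function(tm_table, wt_tm) {
  if (is.na(wt_tm)) stop("wt_tm must be present")
  df <- tm_table[tm_table$single %in% TRUE, , drop = FALSE]
  stable <- !is.na(df$tm_c) & df$tm_c > wt_tm
  list(n_stable = sum(stable), n_total = nrow(df),
       stable = df$mutant[stable])
}
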