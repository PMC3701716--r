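#' Free energy of the X -> Y transformation from its two half-steps
#'
#' A large mutation X -> Y is split through the pseudo-alanine intermediate I
#' (an alanine-like side chain with a CH1 C-beta): dG(X->Y) =
#' dG(X->I) - dG(Y->I), per component and state, with errors combined in
#' quadrature. Both legs must share component, state and subunit scaling.
#'
#' @param leg_XtoI,leg_YtoI [leg_result()] objects with
#'   `transformation = "XtoI"` and `"YtoI"` respectively.
#' @return list with `dG`, `dG_error`, `component`, `state` (kcal/mol).
#' @export
component_transform <- function(leg_XtoI, leg_YtoI) {
  stopifnot(inherits(leg_XtoI, "leg_result"), inherits(leg_YtoI, "leg_result"))
  if (leg_XtoI$component != leg_YtoI$component ||
      leg_XtoI$state != leg_YtoI$state)
    stop("legs must share component and state")
  if (leg_XtoI$subunit_scale != leg_YtoI$subunit_scale)
    stop("legs must share subunit scaling")
  if (leg_XtoI$transformation != "XtoI" || leg_YtoI$transformation != "YtoI")
    stop("expected one XtoI and one YtoI leg, in that order")
  list(dG = leg_XtoI$dG - leg_YtoI$dG,
       dG_error = sqrt(leg_XtoI$dG_error^2 + leg_YtoI$dG_error^2),
       component = leg_XtoI$component, state = leg_XtoI$state)
}

#' Assemble a mutant's thermodynamic cycle
#'
#' Combines the eight alchemical legs (2 components x 2 states x 2
#' transformations) of one point mutation X -> Y into the folding
#' free-energy difference:
#' \deqn{\Delta\Delta G_{ele} = \Delta G_{ele}(X\to Y)_{folded} -
#'   \Delta G_{ele}(X\to Y)_{unfolded}}
#' and likewise for the van der Waals component;
#' `ddG_total = ddG_ele + ddG_vdw` exactly, with the overall error taken in
#' quadrature over all eight leg errors. A negative total means the Y variant
#' is more stable than X.
#'
#' @param legs list of exactly eight [leg_result()] objects covering every
#'   combination of component, state and transformation once.
#' @param label mutant label, e.g. `"N124Y"`.
#' @return object of class `"mutant_cycle"`: list with `label`, `legs`,
#'   `ddG_ele`, `ddG_vdw`, `ddG_total`, `ddG_error` (kcal/mol).
#' @export
assemble_cycle <- function(legs, label) {
  stopifnot(is.list(legs),
            all(vapply(legs, inherits, logical(1), "leg_result")))
  key <- vapply(legs, function(l)
    paste(l$component, l$state, l$transformation, sep = "."), character(1))
  want <- as.vector(outer(
    as.vector(outer(c("ele", "vdw"), c("folded", "unfolded"), paste, sep = ".")),
    c("XtoI", "YtoI"), paste, sep = "."))
  if (length(legs) != 8 || !setequal(key, want) || anyDuplicated(key))
    stop("need exactly the eight legs: {ele,vdw} x {folded,unfolded} x {XtoI,YtoI}")
  names(legs) <- key
  comp_xy <- function(component, state) {
    component_transform(legs[[paste(component, state, "XtoI", sep = ".")]],
                        legs[[paste(component, state, "YtoI", sep = ".")]])
  }
  ddG_ele <- comp_xy("ele", "folded")$dG - comp_xy("ele", "unfolded")$dG
  ddG_vdw <- comp_xy("vdw", "folded")$dG - comp_xy("vdw", "unfolded")$dG
  err <- sqrt(sum(vapply(legs, `[[`, numeric(1), "dG_error")^2))
  structure(list(label = label, legs = legs,
                 ddG_ele = ddG_ele, ddG_vdw = ddG_vdw,
                 ddG_total = ddG_ele + ddG_vdw, ddG_error = err),
            class = "mutant_cycle")
}

#' @export
print.mutant_cycle <- function(x, ...) {
  cat(sprintf("%s: ddG_ele = %+.2f, ddG_vdw = %+.2f, ddG_total = %+.2f +/- %.2f kcal/mol\n",
              x$label, x$ddG_ele, x$ddG_vdw, x$ddG_total, x$ddG_error))
  invisible(x)
}

#' Ranked stability report over a set of mutant cycles
#'
#' Sorts cycles by total ddG (most stabilizing first) and applies a threshold
#' filter. Sites are parsed from the mutant labels (the integer part of e.g.
#' `"N124Y"`), so the number of distinct sites passing the filter is also
#' reported.
#'
#' @param cycles list of [assemble_cycle()] results.
#' @param threshold keep mutants with `ddG_total < threshold` (kcal/mol);
#'   default -1, the usual cut for "confidently stabilizing".
#' @return data.frame sorted ascending by `ddG_total` with columns `mutant`,
#'   `site`, `ddG_ele`, `ddG_vdw`, `ddG_total`, `ddG_error`, `pass`;
#'   attributes `n_pass` (mutants passing) and `n_sites_pass` (distinct sites
#'   among them).
#' @export
cycle_report <- function(cycles, threshold = -1) {
  stopifnot(length(cycles) >= 1,
            all(vapply(cycles, inherits, logical(1), "mutant_cycle")))
  df <- data.frame(
    mutant = vapply(cycles, `[[`, character(1), "label"),
    ddG_ele = vapply(cycles, `[[`, numeric(1), "ddG_ele"),
    ddG_vdw = vapply(cycles, `[[`, numeric(1), "ddG_vdw"),
    ddG_total = vapply(cycles, `[[`, numeric(1), "ddG_total"),
    ddG_error = vapply(cycles, `[[`, numeric(1), "ddG_error"),
    stringsAsFactors = FALSE)
  df$site <- suppressWarnings(as.integer(gsub("[^0-9]", "", df$mutant)))
  df$pass <- df$ddG_total < threshold
  df <- df[order(df$ddG_total),
           c("mutant", "site", "ddG_ele", "ddG_vdw", "ddG_total",
             "ddG_error", "pass")]
  rownames(df) <- NULL
  attr(df, "n_pass") <- sum(df$pass)
  attr(df, "n_sites_pass") <- length(unique(df$site[df$pass & !is.na(df$site)]))
  attr(df, "threshold") <- threshold
  df
}

#' Write a cycle report to CSV
#'
#' Emits the per-mutant Coulomb-switching, van der Waals-switching and total
#' ddG columns with the propagated error.
#'
#' @param report result of [cycle_report()].
#' @param path output CSV file.
#' @return invisibly, `path`.
#' @export
write_cycle_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
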