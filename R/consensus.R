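#' Pairwise sequence identity of two aligned sequences
#'
#' Fraction of matching positions over the aligned columns where at least
#' one sequence has a residue: columns gapped in both sequences are dropped
#' from the denominator, columns gapped in exactly one count as mismatches.
#'
#' @param seq_a,seq_b aligned sequences of equal length (character strings;
#'   `-` is the gap symbol).
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned lengths differ")
  keep <- !(a == "-" & b == "-")
  if (!any(keep)) stop("no aligned positions outside double gaps")
  sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

#' Filter an aligned homolog set by identity to a reference
#'
#' Mirrors the usual homolog-collection rules: sequences too distant from
#' the reference are dropped (`identity < min_id`), and near-duplicates are
#' removed greedily — scanning in input order with the reference kept first,
#' a sequence is discarded when its identity to any already-kept sequence
#' reaches `max_id`. Both thresholds are inclusive: identity exactly at
#' `min_id` is kept, identity exactly at `max_id` is treated as redundant
#' (so `max_id = 1, min_id = 0` keeps everything except exact duplicates).
#'
#' @param seqs named character vector of aligned sequences.
#' @param reference name of the reference sequence (kept unconditionally).
#' @param max_id redundancy threshold (default 0.90).
#' @param min_id minimum identity to the reference (default 0.45).
#' @return the surviving subset of `seqs`, reference first.
#' @export
filter_by_identity <- function(seqs, reference, max_id = 0.90,
                               min_id = 0.45) {
  if (!reference %in% names(seqs)) stop("reference sequence not found")
  ref_seq <- seqs[[reference]]
  others <- seqs[setdiff(names(seqs), reference)]
  id_ref <- vapply(others, pairwise_identity, numeric(1), seq_b = ref_seq)
  others <- others[id_ref >= min_id]
  kept <- stats::setNames(c(ref_seq), reference)
  for (nm in names(others)) {
    ids <- vapply(kept, pairwise_identity, numeric(1), seq_b = others[[nm]])
    if (all(ids < max_id)) kept[nm] <- others[[nm]]
  }
  if (length(kept) == 1)
    warning("only the reference survived the identity filters")
  kept
}

#' Per-site residue occurrence frequencies of an alignment
#'
#' Counts each symbol (residues and the gap `-`) per alignment column and
#' divides by the number of sequences, so column frequencies sum to 1.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return object of class `"site_frequencies"`: list with `freq` (matrix,
#'   symbols x columns) and `n_sequences`.
#' @export
site_frequencies <- function(seqs) {
  if (length(seqs) < 1) stop("empty alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences differ in aligned length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  symbols <- sort(unique(as.vector(mat)))
  freq <- apply(mat, 2, function(col)
    table(factor(col, levels = symbols)) / length(seqs))
  dimnames(freq) <- list(symbols, seq_len(ncol(mat)))
  structure(list(freq = freq, n_sequences = length(seqs)),
            class = "site_frequencies")
}

## map an ungapped residue position of the reference to its alignment column
.ref_site_to_column <- function(ref_seq, site) {
  res <- strsplit(ref_seq, "")[[1]]
  ungapped <- cumsum(res != "-")
  col <- which(ungapped == site & res != "-")
  if (length(col) != 1) stop("site ", site, " outside the reference sequence")
  col
}

#' Consensus lookup for a set of point mutations
#'
#' For mutations written `"V120I"` (wild-type residue, site, mutant
#' residue), reports the occurrence frequency of the wild-type and mutant
#' residues at the mutated site, the most frequent (consensus) residue
#' there, and whether the mutant residue is that consensus. Sites are
#' residue numbers in the ungapped reference sequence when `reference_seq`
#' is given, otherwise raw alignment columns.
#'
#' @param freqs a [site_frequencies()] result.
#' @param mutations character vector of mutation labels, e.g. `c("V120I")`;
#'   an empty vector yields an empty table.
#' @param reference_seq optional aligned reference sequence used to map
#'   residue numbers to alignment columns.
#' @return data.frame with columns `mutation`, `site`, `column`, `wt_res`,
#'   `wt_freq`, `mut_res`, `mut_freq`, `top_res`, `top_freq`,
#'   `is_consensus`.
#' @export
consensus_report <- function(freqs, mutations, reference_seq = NULL) {
  stopifnot(inherits(freqs, "site_frequencies"))
  empty <- data.frame(mutation = character(0), site = integer(0),
                      column = integer(0), wt_res = character(0),
                      wt_freq = numeric(0), mut_res = character(0),
                      mut_freq = numeric(0), top_res = character(0),
                      top_freq = numeric(0), is_consensus = logical(0))
  if (length(mutations) == 0) return(empty)
  m <- regmatches(mutations, regexec("^([A-Z])([0-9]+)([A-Z])$", mutations))
  if (any(vapply(m, length, integer(1)) != 4))
    stop("mutations must look like 'V120I'")
  rows <- lapply(seq_along(mutations), function(i) {
    wt <- m[[i]][2]; site <- as.integer(m[[i]][3]); mut <- m[[i]][4]
    col <- if (is.null(reference_seq)) site
           else .ref_site_to_column(reference_seq, site)
    if (col < 1 || col > ncol(freqs$freq))
      stop("site ", site, " maps outside the alignment")
    fcol <- freqs$freq[, col]
    if (!is.null(reference_seq)) {
      ref_res <- strsplit(reference_seq, "")[[1]][col]
      if (ref_res != wt)
        warning(sprintf("mutation %s: reference has %s at site %d",
                        mutations[i], ref_res, site))
    }
    lookup <- function(res) if (res %in% names(fcol)) unname(fcol[res]) else 0
    top <- names(fcol)[which.max(fcol)]
    data.frame(mutation = mutations[i], site = site, column = col,
               wt_res = wt, wt_freq = lookup(wt),
               mut_res = mut, mut_freq = lookup(mut),
               top_res = top, top_freq = max(fcol),
               is_consensus = top == mut)
  })
  do.call(rbind, rows)
}

#' Write per-site frequencies to CSV
#'
#' @param freqs a [site_frequencies()] result.
#' @param path output CSV (rows = symbols, columns = alignment columns).
#' @return invisibly, `path`.
#' @export
write_frequencies_csv <- function(freqs, path) {
  utils::write.csv(as.data.frame(freqs$freq), path)
  invisible(path)
}
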