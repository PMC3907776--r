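#' Theoretical b-/y-ion ladder for a peptide
#'
#' Computes the singly charged monoisotopic b- and y-ion masses
#' b1..b(n-1), y1..y(n-1) for a peptide of n residues:
#' `b_i = sum(first i residues) + proton` and
#' `y_i = sum(last i residues) + water + proton`. Complementary pairs satisfy
#' `b_i + y_(n-i) = M + 2 * proton`, with M the peptide monoisotopic mass.
#'
#' @param peptide peptide sequence in standard one-letter codes, length >= 2.
#' @return object of class `theoretical_ladder`: list with `peptide`,
#'   `b` and `y` mass vectors (Da), and `peptide_mass` (neutral M).
#' @export
#' @examples
#' theoretical_ladder("AG")$b  # 72.0444
theoretical_ladder <- function(peptide) {
  peptide <- toupper(peptide)
  res <- strsplit(peptide, "")[[1]]
  if (length(res) < 2) stop("peptide must have at least 2 residues")
  bad <- setdiff(res, names(.RESIDUE_MASSES))
  if (length(bad)) stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  m <- .RESIDUE_MASSES[res]
  n <- length(m)
  structure(list(
    peptide = peptide,
    b = cumsum(m)[seq_len(n - 1)] + PROTON_MASS,
    y = cumsum(rev(m))[seq_len(n - 1)] + WATER_MASS + PROTON_MASS,
    peptide_mass = sum(m) + WATER_MASS
  ), class = "theoretical_ladder")
}

#' @export
print.theoretical_ladder <- function(x, ...) {
  cat(sprintf("theoretical ladder for %s (M = %.5f Da)\n", x$peptide, x$peptide_mass))
  cat("  b:", paste(sprintf("%.4f", x$b), collapse = " "), "\n")
  cat("  y:", paste(sprintf("%.4f", x$y), collapse = " "), "\n")
  invisible(x)
}

#' Label spectrum peaks as b-, y- or unknown ions
#'
#' Matches experimental peaks against the theoretical ladder of the known
#' peptide: a peak within `tol` Da of a theoretical b (resp. y) mass is
#' labelled `b` (resp. `y`); all others are `u`. When several peaks fall in
#' one tolerance window, only the closest in mass takes the label (ties go to
#' the more intense peak); a peak inside both a b and a y window takes the
#' closer of the two. Matched labels are treated as ground truth: no
#' deisotoping or charge checking is performed.
#'
#' @param spec a [spectrum]; its `peptide` must be known unless `ladder` is
#'   supplied.
#' @param ladder optional [theoretical_ladder]; built from `spec$peptide` by
#'   default.
#' @param tol symmetric match tolerance in Da (default 0.2).
#' @return factor of per-peak labels with levels `b`, `y`, `u`.
#' @export
label_peaks <- function(spec, ladder = NULL, tol = 0.2) {
  stopifnot(tol > 0)
  if (is.null(ladder)) {
    if (is.na(spec$peptide)) stop("spectrum has no known peptide")
    ladder <- theoretical_ladder(spec$peptide)
  }
  k <- n_peaks(spec)
  labels <- rep("u", k)
  if (k) {
    theo <- c(ladder$b, ladder$y)
    type <- rep(c("b", "y"), c(length(ladder$b), length(ladder$y)))
    ## each theoretical ion claims its closest in-window peak
    claim_peak <- integer(0); claim_type <- character(0); claim_dist <- numeric(0)
    for (t in seq_along(theo)) {
      d <- abs(spec$mass - theo[t])
      inwin <- which(d <= tol)
      if (!length(inwin)) next
      best <- inwin[order(d[inwin], -spec$intensity[inwin])][1]
      claim_peak <- c(claim_peak, best)
      claim_type <- c(claim_type, type[t])
      claim_dist <- c(claim_dist, d[best])
    }
    ## a peak claimed by several ions keeps the closest one's type
    if (length(claim_peak)) {
      ord <- order(claim_dist)
      for (i in ord) {
        p <- claim_peak[i]
        if (labels[p] == "u") labels[p] <- claim_type[i]
      }
    }
  }
  factor(labels, levels = c("b", "y", "u"))
}

#' Target vectors for ion labels
#'
#' Encodes labels as the binary target vectors used to train the network:
#' b -> (1,0,0), y -> (0,1,0), u -> (0,0,1).
#'
#' @param labels factor or character vector of `b`/`y`/`u` labels.
#' @return numeric matrix with columns `b`, `y`, `u`; exactly one 1 per row.
#' @export
ion_targets <- function(labels) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("b", "y", "u")))
  t <- matrix(0, length(labels), 3, dimnames = list(NULL, c("b", "y", "u")))
  t[cbind(seq_along(labels), match(labels, c("b", "y", "u")))] <- 1
  t
}
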