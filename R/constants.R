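#' @useDynLib peakstage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rbinom rexp rlnorm rnorm rpois runif setNames predict coef
#' @importFrom utils head read.delim write.table modifyList
NULL

## Physical constants (Da, monoisotopic)
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
C13_SPACING <- 1.00335  # 13C - 12C

## Monoisotopic residue masses for the 20 standard amino acids
.RESIDUE_MASSES <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

## Neutral-loss offsets (Da) relative to the fragment peak
.NEUTRAL_LOSSES <- c(
  H2O     = -18.010565,
  NH3     = -17.026549,
  H2O_H2O = -36.021130,
  H2O_NH3 = -35.037114,
  CO      = -27.994915
)

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino acid
#' residues. Leucine and isoleucine share a mass.
#'
#' @param unique_mass if `TRUE`, collapse residues with indistinguishable
#'   masses (I is reported as L), as used for spectrum-graph edges.
#' @return named numeric vector of residue masses in Da.
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function(unique_mass = FALSE) {
  if (unique_mass) .RESIDUE_MASSES[names(.RESIDUE_MASSES) != "I"] else .RESIDUE_MASSES
}

#' Neutral-loss mass offsets
#'
#' Monoisotopic mass offsets (Da) of the satellite peaks modelled by the
#' neutral-loss features: loss of water, ammonia, two waters, water plus
#' ammonia, and carbon monoxide (the a-ion offset from a b-ion).
#'
#' @return named numeric vector of negative offsets in Da.
#' @export
neutral_losses <- function() .NEUTRAL_LOSSES

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
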