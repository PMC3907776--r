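## Fragmentation-pattern features. All feature functions are vectorised over
## the peaks of one spectrum and return one value (or one-hot row) per peak,
## in mass order.

#' Normalised, discretised peak intensity
#'
#' Intensity relative to the base peak, discretised into `n_bins` equal bins:
#' `floor(n * y/ymax) / n`, with the base peak itself mapped to 1.
#'
#' @param spec a [spectrum].
#' @param n_bins number of intensity bins (default 10).
#' @return numeric vector in `[0, 1]`, one value per peak.
#' @export
intensity_feature <- function(spec, n_bins = 10) {
  stopifnot(n_bins >= 1)
  if (n_peaks(spec) == 0) return(numeric(0))
  ymax <- max(spec$intensity)
  if (ymax <= 0) stop("degenerate spectrum: maximum intensity is 0")
  r <- spec$intensity / ymax
  ifelse(r >= 1, 1, floor(n_bins * r) / n_bins)
}

## intensity rank (1 = most intense, ties to lower mass) of each peak among an
## index set; `cand` is a list of integer vectors per peak
.window_bounds <- function(spec, window) {
  half <- window / 2
  lo <- findInterval(spec$mass - half, spec$mass, left.open = TRUE) + 1L
  hi <- findInterval(spec$mass + half, spec$mass)
  cbind(lo, hi)
}

#' Strong-peak indicator
#'
#' 1 when the peak is one of the `top_k` most intense peaks within a window of
#' `window` Da centred on it (rank ties broken in favour of the lower-mass
#' peak), else 0. With the defaults this is the classic top-3-per-56-Da
#' sliding-window criterion.
#'
#' @inheritParams intensity_feature
#' @param window total window width in Da (default 56, i.e. +/- 28 Da).
#' @param top_k number of peaks called strong per window (default 3).
#' @return integer vector of 0/1 flags.
#' @export
strong_peak <- function(spec, window = 56, top_k = 3) {
  stopifnot(window > 0, top_k >= 1)
  k <- n_peaks(spec)
  if (!k) return(integer(0))
  wb <- .window_bounds(spec, window)
  y <- spec$intensity
  out <- integer(k)
  for (i in seq_len(k)) {
    idx <- wb[i, 1]:wb[i, 2]
    yi <- y[idx]
    r <- sum(yi > y[i]) + sum(yi == y[i] & idx < i) + 1L
    out[i] <- as.integer(r <= top_k)
  }
  out
}

#' Local and global intensity ranks
#'
#' Intensity rank of each peak, normalised to `[0, 1]` as
#' `1 - (r - 1) / max(m - 1, 1)` so the most intense peak scores 1 and the
#' least intense 0. The local rank uses the peaks within `window` Da around
#' the peak; the global rank uses the whole spectrum.
#'
#' @inheritParams strong_peak
#' @return two-column matrix `local`, `global`.
#' @export
intensity_ranks <- function(spec, window = 56) {
  k <- n_peaks(spec)
  if (!k) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("local", "global"))))
  y <- spec$intensity
  wb <- .window_bounds(spec, window)
  loc <- numeric(k)
  for (i in seq_len(k)) {
    idx <- wb[i, 1]:wb[i, 2]
    r <- sum(y[idx] > y[i]) + sum(y[idx] == y[i] & idx < i) + 1L
    loc[i] <- 1 - (r - 1) / max(length(idx) - 1L, 1L)
  }
  rg <- integer(k)
  rg[order(-y, spec$mass)] <- seq_len(k)
  glob <- 1 - (rg - 1) / max(k - 1L, 1L)
  cbind(local = loc, global = glob)
}

#' Relative cleavage-position categories
#'
#' One-hot encoding of the spectrum region the peak falls in, based on its
#' mass relative to the parent ion mass: region `c` (0-based) covers
#' `c/n <= x/pI < (c+1)/n`; ratios at or above 1 clamp to the last region.
#'
#' @inheritParams intensity_feature
#' @param n_regions number of equal regions (default 5).
#' @return k x `n_regions` binary matrix, exactly one 1 per row.
#' @export
position_feature <- function(spec, n_regions = 5) {
  stopifnot(n_regions >= 1)
  if (spec$parent_ion_mass <= 0) stop("parent ion mass must be positive")
  k <- n_peaks(spec)
  out <- matrix(0, k, n_regions,
                dimnames = list(NULL, paste0("position_", seq_len(n_regions))))
  if (!k) return(out)
  cc <- pmin(floor(n_regions * spec$mass / spec$parent_ion_mass), n_regions - 1)
  cc <- pmax(cc, 0)
  out[cbind(seq_len(k), cc + 1)] <- 1
  out
}

#' Locate offset peaks
#'
#' For each peak at mass `x`, finds the maximum-intensity peak in
#' `[x + delta - eps, x + delta + eps]` and reports the experimental offset
#' `delta' = x - x_j + delta` and the relative intensity `y' = y_j / y`.
#'
#' @inheritParams intensity_feature
#' @param delta expected mass offset in Da (signed).
#' @param eps half-width of the search window in Da (default 0.2).
#' @return data frame with per-peak columns `found`, `idx`, `delta_prime`,
#'   `rel_intensity` (`NA` where not found).
#' @export
find_offset_peak <- function(spec, delta, eps = 0.2) {
  stopifnot(eps > 0)
  k <- n_peaks(spec)
  idx <- cpp_interval_max_idx(spec$mass, spec$intensity,
                              spec$mass + delta - eps, spec$mass + delta + eps)
  found <- idx > 0L
  dp <- rel <- rep(NA_real_, k)
  dp[found] <- spec$mass[found] - spec$mass[idx[found]] + delta
  rel[found] <- spec$intensity[idx[found]] / spec$intensity[found]
  data.frame(found = found, idx = ifelse(found, idx, NA_integer_),
             delta_prime = dp, rel_intensity = rel)
}

#' Gaussian offset score
#'
#' Score of an experimental mass offset under the Gaussian offset model
#' N(0, sigma), normalised to 1 at zero offset: `exp(-dp^2 / (2 sigma^2))`.
#' Used by the complement and neutral-loss features.
#'
#' @param delta_prime experimental offset(s) in Da.
#' @param sigma standard deviation of the offset model in Da (default 0.1).
#' @return values in `[0, 1]`.
#' @export
gaussian_offset <- function(delta_prime, sigma = 0.1) {
  stopifnot(sigma > 0)
  exp(-delta_prime^2 / (2 * sigma^2))
}

#' Principal-isotope log-odds histogram
#'
#' Builds the 2-D frequency model of the first isotopologue (+1 Da satellite)
#' of b-/y-ions: for every labelled peak with an offset peak found at
#' `iso_delta` Da, the (experimental offset, relative intensity) pair is
#' binned on a grid of `offset_bin` x `intensity_bin` cells, separately for
#' b-/y-labelled and u-labelled peaks. The feature value later sampled from
#' the histogram is the elementwise log-odds
#' `log((n_by + alpha) / (n_u + alpha))`.
#'
#' @param spectra list of [spectrum] objects (typically prefiltered).
#' @param labels list of per-peak label factors, parallel to `spectra`
#'   (see [label_peaks]).
#' @param eps offset search half-window in Da; the offset axis covers
#'   `[-eps, eps]`.
#' @param iso_delta isotopologue spacing in Da (default the 13C-12C mass
#'   difference, 1.00335).
#' @param offset_bin offset bin width in Da (default 0.05).
#' @param intensity_bin relative-intensity bin width (default 0.1).
#' @param y_cap upper cap of the relative-intensity axis; larger values clamp
#'   to the edge bin (default 2).
#' @param pseudocount additive smoothing `alpha` for the log-odds (default 1).
#' @return object of class `isotope_histogram` with the bin edges, both count
#'   grids (`by_counts`, `u_counts`) and the `log_odds` grid.
#' @export
build_isotope_histogram <- function(spectra, labels, eps = 0.2,
                                    iso_delta = C13_SPACING,
                                    offset_bin = 0.05, intensity_bin = 0.1,
                                    y_cap = 2, pseudocount = 1) {
  if (!length(spectra)) stop("empty training set")
  stopifnot(length(spectra) == length(labels))
  off_edges <- seq(-eps, eps, by = offset_bin)
  int_edges <- seq(0, y_cap, by = intensity_bin)
  no <- length(off_edges) - 1L; ni <- length(int_edges) - 1L
  by_counts <- matrix(0, no, ni)
  u_counts <- matrix(0, no, ni)
  n_lab <- 0L
  for (s in seq_along(spectra)) {
    sp <- spectra[[s]]
    if (!n_peaks(sp)) next
    hit <- find_offset_peak(sp, delta = iso_delta, eps = eps)
    lab <- as.character(labels[[s]])
    f <- which(hit$found)
    n_lab <- n_lab + length(f)
    if (!length(f)) next
    oi <- .clamp_bin(hit$delta_prime[f], off_edges)
    ii <- .clamp_bin(hit$rel_intensity[f], int_edges)
    is_by <- lab[f] %in% c("b", "y")
    for (j in seq_along(f)) {
      if (is_by[j]) by_counts[oi[j], ii[j]] <- by_counts[oi[j], ii[j]] + 1
      else u_counts[oi[j], ii[j]] <- u_counts[oi[j], ii[j]] + 1
    }
  }
  structure(list(offset_edges = off_edges, intensity_edges = int_edges,
                 by_counts = by_counts, u_counts = u_counts,
                 log_odds = log((by_counts + pseudocount) / (u_counts + pseudocount)),
                 iso_delta = iso_delta, eps = eps, pseudocount = pseudocount,
                 n_increments = sum(by_counts) + sum(u_counts),
                 n_offset_hits = n_lab),
            class = "isotope_histogram")
}

.clamp_bin <- function(x, edges) {
  pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
       length(edges) - 1L)
}

#' @export
print.isotope_histogram <- function(x, ...) {
  cat(sprintf("isotope histogram: %d x %d bins, %g b/y and %g u increments\n",
              nrow(x$by_counts), ncol(x$by_counts),
              sum(x$by_counts), sum(x$u_counts)))
  invisible(x)
}

#' Serialise / restore an isotope histogram
#' @param hist an `isotope_histogram`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `isotope_histogram`.
#' @export
write_isotope_histogram <- function(hist, path) {
  jsonlite::write_json(unclass(hist), path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_isotope_histogram
#' @export
read_isotope_histogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("by_counts", "u_counts", "log_odds"))
    x[[f]] <- matrix(x[[f]], length(x$offset_edges) - 1L, byrow = TRUE)
  structure(x, class = "isotope_histogram")
}

#' Principal-isotope feature
#'
#' Looks up the +1 Da isotopologue candidate of each peak in the log-odds
#' histogram: the feature value is the log-odds of the (offset, relative
#' intensity) bin of the candidate, or 0 when no peak sits in the isotope
#' window.
#'
#' @inheritParams intensity_feature
#' @param hist an [build_isotope_histogram] result.
#' @return numeric vector, one (possibly negative) value per peak.
#' @export
principal_isotope_feature <- function(spec, hist) {
  k <- n_peaks(spec)
  if (!k) return(numeric(0))
  hit <- find_offset_peak(spec, delta = hist$iso_delta, eps = hist$eps)
  out <- numeric(k)
  f <- which(hit$found)
  if (length(f)) {
    oi <- .clamp_bin(hit$delta_prime[f], hist$offset_edges)
    ii <- .clamp_bin(hit$rel_intensity[f], hist$intensity_edges)
    out[f] <- hist$log_odds[cbind(oi, ii)]
  }
  out
}

#' Isotopologue indicator
#'
#' 1 when the peak looks like the +1 Da isotopologue of a stronger peak: some
#' peak within `eps` of `x - iso_delta` has intensity at least the current
#' peak's.
#'
#' @inheritParams intensity_feature
#' @param eps search half-window in Da (default 0.2).
#' @param iso_delta isotopologue spacing in Da.
#' @return integer vector of 0/1 flags.
#' @export
isotopologue_flag <- function(spec, eps = 0.2, iso_delta = C13_SPACING) {
  k <- n_peaks(spec)
  if (!k) return(integer(0))
  idx <- cpp_interval_max_idx(spec$mass, spec$intensity,
                              spec$mass - iso_delta - eps,
                              spec$mass - iso_delta + eps)
  found <- idx > 0L
  out <- integer(k)
  out[found] <- as.integer(spec$intensity[idx[found]] >= spec$intensity[found])
  out
}

#' Complementary-ion feature (stage 1)
#'
#' If the current peak is a b-ion, its complementary y-ion is expected at
#' `pI - x + comp_offset` (and vice versa). The feature is the Gaussian offset
#' score of the most intense peak within `eps` of that mass, or 0 when no
#' candidate exists.
#'
#' @inheritParams intensity_feature
#' @param sigma offset model standard deviation in Da (default 0.1).
#' @param eps search half-window in Da (default 0.2).
#' @param comp_offset the constant in the complement relation (default the
#'   proton mass, from `b_i + y_(n-i) = pI + proton`).
#' @return numeric vector in `[0, 1]`.
#' @export
complement_feature_net1 <- function(spec, sigma = 0.1, eps = 0.2,
                                    comp_offset = PROTON_MASS) {
  k <- n_peaks(spec)
  if (!k) return(numeric(0))
  mc <- spec$parent_ion_mass - spec$mass + comp_offset
  idx <- cpp_interval_max_idx(spec$mass, spec$intensity, mc - eps, mc + eps)
  out <- numeric(k)
  found <- idx > 0L
  out[found] <- gaussian_offset(mc[found] - spec$mass[idx[found]], sigma)
  out
}

#' Neutral-loss feature
#'
#' Evidence for a satellite peak at a fixed negative offset (water, ammonia,
#' double water, water+ammonia, or CO for the a-ion): the sum of the
#' satellite's relative intensity and its Gaussian offset score,
#' `y'_j + X(delta')`; 0 when no peak sits in the offset window.
#'
#' @inheritParams complement_feature_net1
#' @param loss a loss name from [neutral_losses] or a numeric offset in Da.
#' @return numeric vector, values `>= 0`.
#' @export
neutral_loss_feature <- function(spec, loss, sigma = 0.1, eps = 0.2) {
  if (is.character(loss)) {
    if (!loss %in% names(.NEUTRAL_LOSSES)) stop("unknown neutral loss: ", loss)
    loss <- .NEUTRAL_LOSSES[[loss]]
  }
  k <- n_peaks(spec)
  if (!k) return(numeric(0))
  hit <- find_offset_peak(spec, delta = loss, eps = eps)
  out <- numeric(k)
  f <- hit$found
  out[f] <- hit$rel_intensity[f] + gaussian_offset(hit$delta_prime[f], sigma)
  out
}

#' Random-peak hypothesis feature
#'
#' Probability that at least one peak of a uniform random null spectrum of the
#' same density would land in a `+/- eps` window: `1 - exp(-lambda * 2 eps)`
#' with `lambda` the observed peak density (peaks per Da over the spectrum's
#' mass span). Captures how likely any offset match is by chance alone.
#'
#' @inheritParams complement_feature_net1
#' @param enabled when `FALSE` the feature is forced to 0 for every peak.
#' @return numeric vector in `[0, 1)`, constant across the spectrum.
#' @export
random_peak_feature <- function(spec, eps = 0.2, enabled = TRUE) {
  k <- n_peaks(spec)
  if (!k) return(numeric(0))
  if (!enabled || k < 2) return(numeric(k))
  span <- max(spec$mass) - min(spec$mass)
  if (span <= 0) return(numeric(k))
  rep(1 - exp(-(k / span) * 2 * eps), k)
}

.by_score <- function(net1_probs) {
  if (is.null(dim(net1_probs))) net1_probs <- matrix(net1_probs, ncol = 3)
  pmax(net1_probs[, 1], net1_probs[, 2])
}

#' Complementary-ion feature (stage 2)
#'
#' Stage-2 variant of the complement feature: instead of the offset score, the
#' feature is the largest stage-1 b/y probability `max(P_b, P_y)` among the
#' peaks within `eps` of the expected complement mass; 0 when none.
#'
#' @inheritParams complement_feature_net1
#' @param net1_probs k x 3 matrix of stage-1 class probabilities for the
#'   spectrum's peaks (columns b, y, u).
#' @return numeric vector in `[0, 1]`.
#' @export
complement_feature_net2 <- function(spec, net1_probs, eps = 0.2,
                                    comp_offset = PROTON_MASS) {
  k <- n_peaks(spec)
  if (!k) return(numeric(0))
  if (is.null(net1_probs)) stop("stage-2 complement feature requires net1 probabilities")
  score <- .by_score(net1_probs)
  if (length(score) != k) stop("net1 probabilities do not match the peak count")
  mc <- spec$parent_ion_mass - spec$mass + comp_offset
  idx <- cpp_interval_max_idx(spec$mass, score, mc - eps, mc + eps)
  out <- numeric(k)
  found <- idx > 0L
  out[found] <- score[idx[found]]
  out
}

#' Flanking-residue features (stage 2)
#'
#' Evidence that the peak sits in an ion ladder: the largest stage-1 b/y
#' probability of any peak one amino-acid mass away (within `tol`) on the
#' lower-mass side (`side = "N"`) or higher-mass side (`side = "C"`); 0 when
#' no residue-offset neighbour exists.
#'
#' @inheritParams complement_feature_net2
#' @param side `"N"` (lower mass) or `"C"` (higher mass).
#' @param tol residue-offset tolerance in Da (default 0.25).
#' @return numeric vector in `[0, 1]`.
#' @export
flanking_feature <- function(spec, net1_probs, side = c("N", "C"), tol = 0.25) {
  side <- match.arg(side)
  k <- n_peaks(spec)
  if (!k) return(numeric(0))
  if (is.null(net1_probs)) stop("flanking features require net1 probabilities")
  score <- .by_score(net1_probs)
  if (length(score) != k) stop("net1 probabilities do not match the peak count")
  sgn <- if (side == "N") -1 else 1
  out <- numeric(k)
  for (r in unique(.RESIDUE_MASSES)) {
    ctr <- spec$mass + sgn * r
    idx <- cpp_interval_max_idx(spec$mass, score, ctr - tol, ctr + tol)
    found <- idx > 0L
    out[found] <- pmax(out[found], score[idx[found]])
  }
  out
}

#' Assemble per-peak feature matrices
#'
#' Builds the full stage-1 (`net1`) or stage-2 (`net2`) feature matrix for a
#' spectrum, in the fixed order: intensity, strong peak, local rank, global
#' rank, position one-hot, random-peak hypothesis, principal isotope,
#' isotopologue, complement, and the five neutral losses; stage 2 appends the
#' N- and C-terminal flanking features and replaces the complement with its
#' stage-2 variant. With the default 5 position regions the stage-1 matrix
#' has 18 columns and the stage-2 matrix 20.
#'
#' @inheritParams intensity_feature
#' @param stage `"net1"` or `"net2"`.
#' @param hist [build_isotope_histogram] result.
#' @param net1_probs stage-1 probability matrix, required for `stage =
#'   "net2"`.
#' @param control feature configuration from [snn_control].
#' @return k x p numeric feature matrix with named columns.
#' @export
build_feature_vectors <- function(spec, stage = c("net1", "net2"), hist,
                                  net1_probs = NULL, control = snn_control()) {
  stage <- match.arg(stage)
  if (stage == "net2" && is.null(net1_probs))
    stop("stage net2 requires net1 probabilities")
  ctl <- control
  k <- n_peaks(spec)
  ranks <- intensity_ranks(spec, window = ctl$strong_window)
  comp <- if (stage == "net1")
    complement_feature_net1(spec, sigma = ctl$sigma, eps = ctl$eps,
                            comp_offset = ctl$comp_offset)
  else
    complement_feature_net2(spec, net1_probs, eps = ctl$eps,
                            comp_offset = ctl$comp_offset)
  nl <- matrix(0, k, length(.NEUTRAL_LOSSES),
               dimnames = list(NULL, paste0("nl_", names(.NEUTRAL_LOSSES))))
  for (nm in names(.NEUTRAL_LOSSES))
    nl[, paste0("nl_", nm)] <- neutral_loss_feature(
      spec, ctl$neutral_loss_offsets[[nm]], sigma = ctl$sigma, eps = ctl$eps)
  out <- cbind(
    intensity = intensity_feature(spec, n_bins = ctl$n_intensity_bins),
    strong_peak = strong_peak(spec, window = ctl$strong_window,
                              top_k = ctl$strong_top_k),
    local_rank = ranks[, "local"],
    global_rank = ranks[, "global"],
    position_feature(spec, n_regions = ctl$n_regions),
    random_peak = random_peak_feature(spec, eps = ctl$eps,
                                      enabled = ctl$random_peak_enabled),
    principal_isotope = principal_isotope_feature(spec, hist),
    isotopologue = isotopologue_flag(spec, eps = ctl$eps,
                                     iso_delta = ctl$iso_delta),
    complement = comp,
    nl
  )
  if (stage == "net2") {
    out <- cbind(out,
                 flank_N = flanking_feature(spec, net1_probs, "N", tol = ctl$flanking_tol),
                 flank_C = flanking_feature(spec, net1_probs, "C", tol = ctl$flanking_tol))
  }
  out
}
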