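#' Simulation settings for synthetic CID spectra
#'
#' Describes the generative model for synthetic doubly charged tryptic-like
#' spectra: random peptides of 8-20 residues with partially complete b-/y-ion
#' ladders, +1 Da isotopologue satellites, neutral-loss satellites, and
#' uniformly placed noise peaks with exponentially distributed (right-skewed)
#' intensities. Signal peaks are kept at least `min_separation` Da away from
#' every theoretical ladder mass they do not represent, so ground-truth
#' labelling at a 0.2 Da tolerance is exact by construction.
#'
#' @param n_spectra number of spectra to generate.
#' @param length_range inclusive peptide length range (default `c(8, 20)`).
#' @param ladder_completeness probability that each theoretical b/y ion is
#'   emitted (default 0.85).
#' @param fragment_meanlog,fragment_sdlog log-normal parameters of the
#'   fragment intensity distribution (defaults `log(500)`, 1).
#' @param fragment_floor additive intensity floor for fragment ions, keeping
#'   principal ions above the 50-unit prefilter (default 60).
#' @param isotope_prob probability that an emitted fragment carries a +1 Da
#'   isotopologue satellite (default 0.9).
#' @param isotope_mean,isotope_sd mean and sd of the satellite's relative
#'   intensity, clipped to `[0.15, 0.9]` (defaults 0.4, 0.1).
#' @param isotope_offset_sd mass jitter of the satellite around the 13C-12C
#'   spacing, in Da (default 0.01).
#' @param neutral_loss_prob named per-loss emission probabilities.
#' @param nl_rel_range relative-intensity range of neutral-loss satellites.
#' @param noise_density noise peaks per Da over `[50, pI]` (default 0.05).
#' @param noise_mean mean of the exponential noise intensity (default 80;
#'   about half of the noise then falls below the 50-unit prefilter floor).
#' @param mass_jitter_sd fragment mass jitter sd in Da (default 0.01,
#'   clamped to +/- 0.15).
#' @param min_separation minimum distance of any peak from theoretical
#'   ladder masses it does not represent (default 0.3).
#' @param center_weighted when `TRUE`, fragment intensities are boosted near
#'   the middle of the peptide and damped at the termini.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_spectra = 100, length_range = c(8, 20),
                       ladder_completeness = 0.85,
                       fragment_meanlog = log(500), fragment_sdlog = 1,
                       fragment_floor = 60,
                       isotope_prob = 0.9, isotope_mean = 0.4,
                       isotope_sd = 0.1, isotope_offset_sd = 0.01,
                       neutral_loss_prob = c(H2O = 0.3, NH3 = 0.2,
                                             H2O_H2O = 0.08, H2O_NH3 = 0.08,
                                             CO = 0.12),
                       nl_rel_range = c(0.1, 0.5),
                       noise_density = 0.05, noise_mean = 80,
                       mass_jitter_sd = 0.01, min_separation = 0.3,
                       center_weighted = FALSE, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(length_range[1] >= 2, length_range[2] >= length_range[1],
            ladder_completeness >= 0, ladder_completeness <= 1,
            all(neutral_loss_prob >= 0), all(neutral_loss_prob <= 1),
            noise_density >= 0, noise_mean > 0, min_separation > 0)
  structure(c(as.list(environment())), class = "sim_config")
}

## peptides whose b/y ladder masses come closer than `gap` are rejected so
## that each emitted fragment has a unique closest theoretical mass
.sample_peptide <- function(len, gap = 0.6, max_tries = 200) {
  aa <- names(.RESIDUE_MASSES)
  for (try in seq_len(max_tries)) {
    pep <- paste(sample(aa, len, replace = TRUE), collapse = "")
    lad <- theoretical_ladder(pep)
    theo <- sort(c(lad$b, lad$y))
    if (all(diff(theo) > gap)) return(pep)
  }
  stop("could not sample a peptide with well-separated ladder masses")
}

#' Generate synthetic labelled MS/MS spectra
#'
#' Draws spectra from the generative model in [sim_config] and returns them
#' together with exact per-peak provenance. Peaks are tagged `b`, `y`,
#' `isotope` (satellite of either ion series), `neutral_loss`, or `noise`;
#' [truth_to_labels] converts tags to the b/y/u classes. Output is fully
#' deterministic given the config seed.
#'
#' @param config a [sim_config].
#' @return object of class `sim_set`: list with `spectra` (list of
#'   [spectrum]) and `truth` (list of per-peak provenance tag vectors,
#'   parallel to each spectrum's mass-sorted peaks).
#' @export
simulate_spectra <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    spectra <- vector("list", config$n_spectra)
    truth <- vector("list", config$n_spectra)
    for (s in seq_len(config$n_spectra)) {
      len <- sample(config$length_range[1]:config$length_range[2], 1)
      pep <- .sample_peptide(len, gap = 2 * config$min_separation)
      lad <- theoretical_ladder(pep)
      pI <- lad$peptide_mass + PROTON_MASS
      theo <- c(lad$b, lad$y)
      theo_type <- rep(c("b", "y"), each = len - 1)

      mass <- numeric(0); intensity <- numeric(0); tag <- character(0)
      add_peak <- function(m, y, tg) {
        mass <<- c(mass, m); intensity <<- c(intensity, y); tag <<- c(tag, tg)
      }
      emitted <- runif(2 * (len - 1)) < config$ladder_completeness
      for (t in which(emitted)) {
        jit <- max(-0.15, min(0.15, rnorm(1, 0, config$mass_jitter_sd)))
        base <- config$fragment_floor +
          rlnorm(1, config$fragment_meanlog, config$fragment_sdlog)
        if (config$center_weighted) {
          pos <- theo[t] / pI
          base <- base * (0.4 + 1.2 * exp(-((pos - 0.5)^2) / 0.08))
        }
        add_peak(theo[t] + jit, base, theo_type[t])
        ## +1 Da isotopologue satellite
        if (runif(1) < config$isotope_prob) {
          im <- theo[t] + jit +
            rnorm(1, C13_SPACING, config$isotope_offset_sd)
          if (min(abs(im - theo)) > config$min_separation) {
            rel <- min(0.9, max(0.15, rnorm(1, config$isotope_mean,
                                            config$isotope_sd)))
            add_peak(im, rel * base, "isotope")
          }
        }
        ## neutral-loss satellites
        for (nm in names(config$neutral_loss_prob)) {
          if (runif(1) < config$neutral_loss_prob[[nm]]) {
            lm <- theo[t] + jit + .NEUTRAL_LOSSES[[nm]] + rnorm(1, 0, 0.01)
            if (lm > 50 && min(abs(lm - theo)) > config$min_separation) {
              rel <- runif(1, config$nl_rel_range[1], config$nl_rel_range[2])
              add_peak(lm, rel * base, "neutral_loss")
            }
          }
        }
      }
      ## uniform-mass noise with right-skewed intensities
      span <- pI - 50
      n_noise <- if (config$noise_density > 0 && span > 0)
        rpois(1, config$noise_density * span) else 0L
      placed <- 0L
      tries <- 0L
      while (placed < n_noise) {
        if (tries > 100L * n_noise + 100L)
          stop("noise placement failed: density too high for the separation constraint")
        tries <- tries + 1L
        nm <- runif(1, 50, pI)
        if (min(abs(nm - theo)) <= config$min_separation) next
        if (length(mass) && min(abs(nm - mass)) <= 0.05) next
        add_peak(nm, rexp(1, 1 / config$noise_mean), "noise")
        placed <- placed + 1L
      }
      ## drop accidental near-duplicate satellite masses (keep the stronger)
      ord <- order(mass)
      mass <- mass[ord]; intensity <- intensity[ord]; tag <- tag[ord]
      keep <- rep(TRUE, length(mass))
      if (length(mass) > 1) {
        for (i in 2:length(mass)) {
          if (mass[i] - mass[i - 1] < 1e-3 && keep[i - 1]) {
            if (intensity[i] >= intensity[i - 1]) keep[i - 1] <- FALSE
            else keep[i] <- FALSE
          }
        }
      }
      sp <- spectrum(mass[keep], intensity[keep],
                     precursor_mz = (lad$peptide_mass + 2 * PROTON_MASS) / 2,
                     charge = 2L, peptide = pep,
                     scan_id = sprintf("sim_%04d", s))
      spectra[[s]] <- sp
      truth[[s]] <- tag[keep][order(mass[keep])]
    }
    structure(list(spectra = spectra, truth = truth, config = config),
              class = "sim_set")
  })
}

#' @export
print.sim_set <- function(x, ...) {
  cat(sprintf("simulated set: %d spectra, %d peaks total (seed %d)\n",
              length(x$spectra),
              sum(vapply(x$spectra, n_peaks, 0L)), x$config$seed))
  invisible(x)
}

#' Convert simulation provenance to ion labels
#'
#' Only principal b- and y-ion peaks count as the positive classes; isotope
#' and neutral-loss satellites and noise are all `u`.
#'
#' @param tags character vector of provenance tags from [simulate_spectra]
#'   (or a list of them).
#' @return factor with levels `b`, `y`, `u` (or a list of factors).
#' @export
truth_to_labels <- function(tags) {
  if (is.list(tags)) return(lapply(tags, truth_to_labels))
  factor(ifelse(tags %in% c("b", "y"), tags, "u"), levels = c("b", "y", "u"))
}

#' Write simulation truth to a TSV sidecar
#'
#' @param sim a `sim_set` from [simulate_spectra].
#' @param path output TSV path (columns `scan_id`, `mass`, `provenance`).
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  rows <- Map(function(sp, tg)
    data.frame(scan_id = sp$scan_id, mass = sprintf("%.5f", sp$mass),
               provenance = tg),
    sim$spectra, sim$truth)
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
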