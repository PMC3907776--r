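# a convenience spectrum where masses/intensities are given directly
spec_of <- function(mass, intensity, pI = 1000) {
  spectrum(mass, intensity, precursor_mz = (pI + 1.007276) / 2, charge = 2)
}

test_that("intensity feature is floor-discretised relative intensity", {
  sp <- spec_of(c(100, 200, 300), c(37, 100, 99.9))
  f <- intensity_feature(sp, n_bins = 10)
  expect_equal(f[sp$intensity == 100], 1.0)       # base peak tops the scale
  expect_equal(f[sp$intensity == 37], 0.3)        # floor(10 * 0.37)/10
  expect_equal(f[sp$intensity == 99.9], 0.9)
  ## single bin: everything except the base peak collapses to 0
  f1 <- intensity_feature(sp, n_bins = 1)
  expect_equal(sort(f1), c(0, 0, 1))
  expect_error(intensity_feature(spec_of(100, 0)), "degenerate")
})

test_that("strong peak: isolation, rank cutoffs and the low-mass tie rule", {
  expect_equal(strong_peak(spec_of(500, 10)), 1L)  # rank 1 of 1
  ## 5 peaks inside one 56 Da window, the 4th strongest is not strong
  sp <- spec_of(c(500, 505, 510, 515, 520), c(50, 40, 30, 20, 10))
  expect_equal(strong_peak(sp), c(1L, 1L, 1L, 0L, 0L))
  ## two equal-intensity peaks compete for rank 3: lower mass wins
  sp2 <- spec_of(c(500, 505, 510, 515), c(50, 40, 30, 30))
  expect_equal(strong_peak(sp2), c(1L, 1L, 1L, 0L))
})

test_that("strong peak and intensity ranks match brute-force oracles", {
  withr::local_seed(7)
  for (rep in 1:8) {
    sp <- random_spectrum(k = 50)
    expect_equal(strong_peak(sp), oracle_strong_peak(sp))
    expect_equal(intensity_ranks(sp), oracle_ranks(sp))
  }
  ## boundary behaviour
  sp <- random_spectrum(k = 10)
  r <- intensity_ranks(sp)
  expect_equal(r[which.max(sp$intensity), "global"], 1.0, ignore_attr = TRUE)
  expect_equal(r[which.min(sp$intensity), "global"], 0.0, ignore_attr = TRUE)
})

test_that("position features are one-hot over relative-mass regions", {
  sp <- spec_of(c(100, 500, 999.99, 1000), c(1, 1, 1, 1), pI = 1000)
  p <- position_feature(sp, n_regions = 5)
  expect_equal(p[1, ], c(1, 0, 0, 0, 0), ignore_attr = TRUE)  # x/pI = 0.1
  expect_equal(p[2, ], c(0, 0, 1, 0, 0), ignore_attr = TRUE)  # x/pI = 0.5
  expect_equal(p[4, ], c(0, 0, 0, 0, 1), ignore_attr = TRUE)  # clamps at 1.0
  expect_true(all(rowSums(p) == 1))
})

test_that("offset peaks pick the maximum-intensity candidate in range", {
  sp <- spec_of(c(500, 518.9, 519.05, 540), c(100, 30, 20, 5))
  ## two peaks within 519 +/- 0.2: the more intense wins despite being
  ## farther from the expected offset
  hit <- find_offset_peak(sp, delta = 19, eps = 0.2)
  expect_true(hit$found[1])
  expect_equal(sp$mass[hit$idx[1]], 518.9)
  expect_equal(hit$delta_prime[1], 500 - 518.9 + 19, tolerance = 1e-12)
  expect_equal(hit$rel_intensity[1], 0.3)
  ## exact offset gives delta' = 0; empty range gives found = FALSE
  hit2 <- find_offset_peak(sp, delta = 40, eps = 0.2)
  expect_equal(hit2$delta_prime[1], 0)
  expect_false(find_offset_peak(sp, delta = 150, eps = 0.2)$found[1])
})

test_that("the Gaussian offset kernel is even, bounded and exact at anchors", {
  expect_equal(gaussian_offset(0), 1.0)
  expect_equal(gaussian_offset(0.1, sigma = 0.1), exp(-0.5))
  expect_equal(gaussian_offset(0.07), gaussian_offset(-0.07))
  d <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(gaussian_offset(d)) < 0))  # strictly decreasing in |d|
})

test_that("isotope histogram counts increments and conserves totals", {
  ## one b peak with a satellite at delta' ~ -0.01, y' = 0.45
  lad <- theoretical_ladder("PEPTIDEK")
  pI <- lad$peptide_mass + 1.007276
  sp <- spectrum(c(lad$b[2], lad$b[2] + 1.00335 + 0.01),
                 c(100, 45), precursor_mz = (pI + 1.007276) / 2,
                 peptide = "PEPTIDEK")
  lab <- label_peaks(sp)
  hist <- build_isotope_histogram(list(sp), list(lab))
  expect_equal(sum(hist$by_counts), 1)   # the b peak's satellite
  expect_equal(sum(hist$u_counts), 0)    # satellite itself has no +1 partner
  expect_equal(hist$n_increments, 1)
  ## equal counts in a bin give log-odds 0 there
  expect_true(all(hist$log_odds[hist$by_counts == hist$u_counts &
                                  hist$by_counts == 0] == 0))
  expect_true(all(is.finite(hist$log_odds)))
  expect_error(build_isotope_histogram(list(), list()), "empty")
})

test_that("log-odds is positive in central bins when b/y isotopes are tight", {
  withr::local_seed(11)
  spectra <- list(); labels <- list()
  for (i in 1:200) {
    lad <- theoretical_ladder("PEPTIDEK")
    pI <- lad$peptide_mass + 1.007276
    b <- lad$b[3]
    ## b-ion with tight isotope; u peak with a uniformly off isotope partner
    u <- 400 + runif(1, 0, 50)
    sp <- spectrum(c(b, b + 1.00335 + rnorm(1, 0, 0.01),
                     u, u + 1.00335 + runif(1, -0.19, 0.19)),
                   c(100, 45, 80, 40),
                   precursor_mz = (pI + 1.007276) / 2, peptide = "PEPTIDEK")
    spectra[[i]] <- sp
    labels[[i]] <- label_peaks(sp)
  }
  hist <- build_isotope_histogram(spectra, labels)
  center <- which(abs(hist$offset_edges[-1] - 0.025) < 0.026)
  expect_gt(max(hist$log_odds[center, ]), 0)
  ## conservation: every increment came from a labelled peak with a found hit
  found <- sum(vapply(spectra, function(sp)
    sum(find_offset_peak(sp, 1.00335, 0.2)$found), 0))
  expect_equal(hist$n_increments, found)
  ## feature sampled at the modal b/y bin is strictly positive,
  ## absent isotopes give 0
  f <- principal_isotope_feature(spectra[[1]], hist)
  expect_gt(f[1], 0)
  bare <- spec_of(c(300, 700), c(10, 10))
  expect_equal(principal_isotope_feature(bare, hist), c(0, 0))
})

test_that("isotopologue flags mark satellites, not principals", {
  sp <- spec_of(c(500, 501.00335, 600), c(1000, 400, 50))
  expect_equal(isotopologue_flag(sp), c(0L, 1L, 0L))
  withr::local_seed(9)
  for (rep in 1:5) {
    sp <- random_spectrum(k = 40)
    expect_equal(isotopologue_flag(sp), oracle_isotopologue(sp))
  }
})

test_that("stage-1 complement feature scores the expected complement mass", {
  pI <- 1000
  x <- 400
  comp <- pI - x + 1.007276
  sp <- spec_of(c(x, comp), c(100, 80), pI = pI)
  expect_equal(complement_feature_net1(sp), c(1, 1))  # exact pair
  sp_off <- spec_of(c(x, comp + 0.1), c(100, 80), pI = pI)
  expect_equal(complement_feature_net1(sp_off)[1], exp(-0.5), tolerance = 1e-9)
  sp_none <- spec_of(c(x, 800), c(100, 80), pI = pI)
  expect_equal(complement_feature_net1(sp_none)[1], 0)
  ## symmetry under x -> pI - x + offset on a two-peak spectrum
  withr::local_seed(2)
  for (rep in 1:10) {
    x <- runif(1, 150, 500)
    d <- runif(1, -0.15, 0.15)
    sp <- spec_of(c(x, pI - x + 1.007276 + d), c(50, 70), pI = pI)
    f <- complement_feature_net1(sp)
    expect_equal(f[1], f[2], tolerance = 1e-9)
  }
})

test_that("b/y pairs from a simulated ladder score high on complement", {
  sim <- simulate_spectra(sim_config(n_spectra = 10, ladder_completeness = 1,
                                     noise_density = 0, seed = 31))
  for (i in 1:10) {
    sp <- sim$spectra[[i]]
    lab <- truth_to_labels(sim$truth[[i]])
    f <- complement_feature_net1(sp)
    expect_true(all(f[lab %in% c("b", "y")] > 0.6))
  }
})

test_that("neutral-loss features add relative intensity and offset score", {
  x <- 600
  sp <- spec_of(c(x - 18.010565, x), c(30, 100))
  f <- neutral_loss_feature(sp, "H2O")
  expect_equal(f[2], 0.3 + 1.0, tolerance = 1e-9)
  ## a bare peak in an empty region scores 0 on all five losses
  bare <- spec_of(c(100, 700), c(10, 10))
  for (nm in names(neutral_losses()))
    expect_equal(neutral_loss_feature(bare, nm)[2], 0, info = nm)
  expect_error(neutral_loss_feature(sp, "XYZ"), "unknown neutral loss")
})

test_that("random-peak hypothesis follows the Poisson null closed form", {
  sp <- spec_of(seq(100, 1100, length.out = 100), rep(10, 100), pI = 1200)
  expect_equal(random_peak_feature(sp)[1], 1 - exp(-0.1 * 0.4), tolerance = 1e-9)
  ## denser spectrum scores strictly higher
  sp2 <- spec_of(seq(100, 1100, length.out = 200), rep(10, 200), pI = 1200)
  expect_gt(random_peak_feature(sp2)[1], random_peak_feature(sp)[1])
  expect_equal(random_peak_feature(spec_of(500, 10)), 0)  # single peak
  expect_equal(random_peak_feature(sp, enabled = FALSE), rep(0, 100))
})

test_that("stage-2 complement takes the best net1 b/y probability in window", {
  pI <- 1000
  sp <- spec_of(c(400, 600.95, 601.05), c(100, 50, 60), pI = pI)
  probs <- rbind(c(0.1, 0.1, 0.8), c(0.3, 0.1, 0.6), c(0.2, 0.7, 0.1))
  f <- complement_feature_net2(sp, probs)
  expect_equal(f[1], 0.7)  # the better of the two in-window candidates
  sp_none <- spec_of(c(400, 800), c(100, 50), pI = pI)
  expect_equal(complement_feature_net2(sp_none, probs[1:2, ])[1], 0)
  expect_error(complement_feature_net2(sp, NULL), "net1")
})

test_that("flanking features find residue-offset neighbours", {
  x <- 500
  sp <- spec_of(c(x - 71.037114, x, x + 99.068414), c(10, 100, 20))
  probs <- rbind(c(0.9, 0.05, 0.05), c(0.5, 0.2, 0.3), c(0.1, 0.6, 0.3))
  expect_equal(flanking_feature(sp, probs, "N")[2], 0.9)  # Ala below
  expect_equal(flanking_feature(sp, probs, "C")[2], 0.6)  # Val above
  ## non-residue offsets only
  sp2 <- spec_of(c(x - 50, x, x + 50), c(10, 100, 20))
  expect_equal(flanking_feature(sp2, probs, "N")[2], 0)
  expect_equal(flanking_feature(sp2, probs, "C")[2], 0)
})

test_that("interior peaks of a complete b-ladder have flanking support", {
  sim <- simulate_spectra(sim_config(n_spectra = 5, ladder_completeness = 1,
                                     noise_density = 0, seed = 41))
  for (i in 1:5) {
    sp <- sim$spectra[[i]]
    lab <- truth_to_labels(sim$truth[[i]])
    probs <- matrix(rep(c(0.8, 0.1, 0.1), each = length(sp$mass)),
                    ncol = 3)
    fn <- flanking_feature(sp, probs, "N")
    fc <- flanking_feature(sp, probs, "C")
    b_idx <- which(lab == "b")
    interior <- b_idx[-c(1, length(b_idx))]
    expect_true(all(fn[interior] > 0))
    expect_true(all(fc[interior] > 0))
  }
})

test_that("feature matrices have the documented shape and invariants", {
  sim <- simulate_spectra(sim_config(n_spectra = 10, seed = 51))
  spectra <- prefilter_intensity(sim$spectra)
  labels <- lapply(spectra, label_peaks)
  hist <- build_isotope_histogram(spectra, labels)
  ctl <- snn_control()
  binary_cols <- c("strong_peak", "isotopologue")
  for (sp in spectra[1:5]) {
    X1 <- build_feature_vectors(sp, "net1", hist, control = ctl)
    expect_equal(ncol(X1), 18)
    p1 <- matrix(runif(3 * nrow(X1)), ncol = 3)
    X2 <- build_feature_vectors(sp, "net2", hist, net1_probs = p1, control = ctl)
    expect_equal(ncol(X2), 20)
    ## shared features identical except the complement slot
    shared <- setdiff(colnames(X1), "complement")
    expect_equal(X2[, shared], X1[, shared])
    expect_true(all(is.finite(X1)) && all(is.finite(X2)))
    expect_true(all(X1[, binary_cols] %in% c(0, 1)))
    pos <- X1[, grep("^position_", colnames(X1)), drop = FALSE]
    expect_true(all(rowSums(pos) == 1))
  }
  expect_error(build_feature_vectors(spectra[[1]], "net2", hist, control = ctl),
               "net1")
  ## empty spectrum gives an empty matrix, not an error
  empty <- prefilter_intensity(spectra[[1]], floor = Inf)
  expect_equal(nrow(build_feature_vectors(empty, "net1", hist, control = ctl)), 0)
})
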