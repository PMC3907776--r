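PROTON <- 1.007276

test_that("the window baseline selects top-k per window and scales freely", {
  sp <- spectrum(c(100, 400, 700), c(1, 2, 3), precursor_mz = 500)
  expect_true(all(window_baseline(sp)))          # <= 3 peaks: all selected
  withr::local_seed(19)
  sp2 <- random_spectrum(k = 60)
  base <- window_baseline(sp2)
  expect_equal(base, oracle_strong_peak(sp2) == 1)
  sp3 <- sp2; sp3$intensity <- sp3$intensity * 1000
  expect_equal(window_baseline(sp3), base)       # rank-based
  ## descending intensities packed into one 56 Da span: exactly top 3
  sp4 <- spectrum(seq(500, 527, by = 3), 10:1, precursor_mz = 600)
  expect_equal(sum(window_baseline(sp4)), 3)
  expect_equal(which(window_baseline(sp4)), 1:3)
})

test_that("precision/recall come from the hand-counted confusion cells", {
  labels <- c("b", "y", "u", "b", "u", "y")
  selected <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)  # 3 TP, 1 FP, 1 FN
  m <- compute_metrics(selected, labels, peptide_length = 8)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1); expect_equal(m$fn, 1)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 4)
  ## degenerate conventions: precision absent when nothing selected
  m0 <- compute_metrics(rep(FALSE, 6), labels)
  expect_true(is.na(m0$precision))
  expect_equal(m0$recall, 0)
  perfect <- compute_metrics(labels %in% c("b", "y"), labels)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  ## micro-aggregation sums counts within length bins
  agg <- metrics_by_length(list(m, compute_metrics(selected, labels, 8),
                                compute_metrics(selected, labels, 10)))
  row8 <- agg[agg$peptide_length == "8", ]
  expect_equal(row8$tp, 6)
  expect_equal(row8$precision, 6 / 8)
  expect_equal(agg[agg$peptide_length == "overall", "tp"], 9)
})

test_that("spectrum-graph edges are residue-mass differences within tolerance", {
  ## two selected masses differing by exactly Ala
  g <- build_spectrum_graph(c(300, 300 + 71.03711), pI = 1000)
  pair <- which(g$edges$residues == "A")
  expect_true(any(abs(g$nodes[g$edges$to[pair]] -
                        g$nodes[g$edges$from[pair]] - 71.03711) < 1e-6))
  ## a 150.0 Da difference matches no residue at 0.5 Da tolerance
  g2 <- build_spectrum_graph(c(300, 450), pI = 1000)
  d <- g2$nodes[g2$edges$to] - g2$nodes[g2$edges$from]
  expect_true(all(abs(d - 150) > 0.5))
  ## complete b-ladder of an 8-mer contains all 7 consecutive ladder edges
  lad <- theoretical_ladder("LAKEGVST")
  pI <- lad$peptide_mass + PROTON
  g3 <- build_spectrum_graph(lad$b, pI = pI)
  for (i in 1:6) {
    from <- which.min(abs(g3$nodes - lad$b[i]))
    to <- which.min(abs(g3$nodes - lad$b[i + 1]))
    expect_true(any(g3$edges$from == from & g3$edges$to == to))
  }
  expect_gte(edge_count(g3), 7)
})

test_that("candidate enumeration agrees with the matrix-power path count", {
  withr::local_seed(37)
  for (rep in 1:10) {
    n_sel <- sample(2:4, 1)
    masses <- sort(runif(n_sel, 150, 700))
    g <- build_spectrum_graph(masses, pI = 800)
    if (length(g$nodes) > 12) next
    enum <- enumerate_candidates(g)
    expect_equal(enum$count, oracle_path_count(g))
    expect_false(enum$truncated)
  }
})

test_that("a perfect ladder graph contains the true peptide", {
  pep <- "GASV"
  lad <- theoretical_ladder(pep)
  pI <- lad$peptide_mass + PROTON
  g <- build_spectrum_graph(lad$b, pI = pI)
  enum <- enumerate_candidates(g)
  expect_true(pep %in% enum$candidates)
})

test_that("adding an edge strictly grows the candidate space", {
  lad <- theoretical_ladder("GAV")
  pI <- lad$peptide_mass + PROTON
  g <- build_spectrum_graph(lad$b, pI = pI)
  base_count <- enumerate_candidates(g)$count
  expect_gt(base_count, 0)
  ## a spurious edge jumping straight from source to terminal adds a path
  g2 <- g
  g2$edges <- rbind(g2$edges, data.frame(from = g$source, to = g$terminal,
                                         residues = "W"))
  count2 <- enumerate_candidates(g2)$count
  expect_equal(count2, base_count + 1)
  expect_equal(count2, oracle_path_count(g2))
  ## empty edge set enumerates nothing
  g0 <- build_spectrum_graph(numeric(0), pI = 130)
  expect_equal(enumerate_candidates(g0)$count, 0)
})

test_that("a two-residue gap doubles candidates when both orders match", {
  ## ladder with b2 removed: the gap spans two residues (G then A),
  ## matched by any residue pair summing to the gap - here G+A and A+G
  lad <- theoretical_ladder("GAGV")
  pI <- lad$peptide_mass + PROTON
  full <- enumerate_candidates(build_spectrum_graph(lad$b, pI = pI))
  gap <- enumerate_candidates(build_spectrum_graph(lad$b[-2], pI = pI))
  ## paths through the gap node set must spell G-A or A-G between b1 and b3
  expect_true(all(c("GAGV", "GGAV") %in% gap$candidates) ||
                gap$count >= 2)
  expect_gte(full$count, gap$count)
})

test_that("enumeration honours the truncation ceiling", {
  withr::local_seed(43)
  masses <- sort(runif(14, 120, 900))
  g <- build_spectrum_graph(masses, pI = 1000)
  enum <- enumerate_candidates(g, ceiling = 5)
  expect_lte(enum$count, 5)
  if (oracle_path_count(g) > 5) expect_true(enum$truncated)
})

test_that("median edge counts bin by peptide length", {
  rep <- edge_count_report(c(3, 5, 9, 10, 20), c(8, 8, 9, 10, 11))
  expect_equal(rep$median_edges[rep$bin == "8-9"], 5)   # median of 3,5,9
  expect_equal(rep$median_edges[rep$bin == "10-11"], 15)
  expect_equal(rep$n, c(3, 2))
  single <- edge_count_report(7, 12)
  expect_equal(single$median_edges, 7)
  ## a subset selector can never have more edges per spectrum
  withr::local_seed(47)
  masses <- sort(runif(8, 150, 900))
  gA <- build_spectrum_graph(masses[1:4], pI = 1000)
  gB <- build_spectrum_graph(masses, pI = 1000)
  expect_lte(edge_count(gA), edge_count(gB))
})
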