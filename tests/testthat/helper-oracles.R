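# Independent brute-force oracles and tiny fixture builders shared by the
# tests. These deliberately use the dumbest possible implementations.

# a random spectrum with no fragmentation structure
random_spectrum <- function(k = 50, mz_range = c(100, 1100), precursor_mz = 600) {
  mass <- sort(runif(k, mz_range[1], mz_range[2]))
  while (any(diff(mass) < 1e-3))
    mass <- sort(runif(k, mz_range[1], mz_range[2]))
  spectrum(mass, runif(k, 1, 1000), precursor_mz = precursor_mz, charge = 2)
}

# O(k^2) strong-peak oracle: rank by intensity (ties to lower mass) inside
# the centred window
oracle_strong_peak <- function(spec, window = 56, top_k = 3) {
  k <- length(spec$mass)
  out <- integer(k)
  for (i in seq_len(k)) {
    inwin <- which(abs(spec$mass - spec$mass[i]) <= window / 2)
    ord <- inwin[order(-spec$intensity[inwin], spec$mass[inwin])]
    out[i] <- as.integer(match(i, ord) <= top_k)
  }
  out
}

oracle_ranks <- function(spec, window = 56) {
  k <- length(spec$mass)
  loc <- glob <- numeric(k)
  rank_in <- function(i, idx) {
    ord <- idx[order(-spec$intensity[idx], spec$mass[idx])]
    r <- match(i, ord)
    1 - (r - 1) / max(length(idx) - 1, 1)
  }
  for (i in seq_len(k)) {
    loc[i] <- rank_in(i, which(abs(spec$mass - spec$mass[i]) <= window / 2))
    glob[i] <- rank_in(i, seq_len(k))
  }
  cbind(local = loc, global = glob)
}

oracle_isotopologue <- function(spec, eps = 0.2, iso_delta = 1.00335) {
  k <- length(spec$mass)
  out <- integer(k)
  for (i in seq_len(k)) {
    below <- which(abs(spec$mass - (spec$mass[i] - iso_delta)) <= eps)
    out[i] <- as.integer(length(below) > 0 &&
                           max(spec$intensity[below]) >= spec$intensity[i])
  }
  out
}

# residue-labelled path count between source and terminal via powers of the
# multiplicity-weighted adjacency matrix
oracle_path_count <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n)
  if (nrow(graph$edges))
    for (e in seq_len(nrow(graph$edges)))
      A[graph$edges$from[e], graph$edges$to[e]] <-
        length(strsplit(graph$edges$residues[e], "/")[[1]])
  total <- 0
  P <- diag(n)
  for (step in seq_len(n)) {
    P <- P %*% A
    if (all(P == 0)) break
    total <- total + P[graph$source, graph$terminal]
  }
  total
}

# numeric gradient of the cross-entropy for one instance by central differences
numeric_gradients <- function(net, x, t, h = 1e-5) {
  perturb <- function(field, idx) {
    f <- function(delta) {
      n2 <- net
      n2[[field]][idx] <- n2[[field]][idx] + delta
      cross_entropy(t, as.numeric(nn_forward(n2, x)))
    }
    (f(h) - f(-h)) / (2 * h)
  }
  lapply(setNames(nm = c("W1", "b1", "W2", "b2")), function(field) {
    g <- net[[field]]
    for (idx in seq_along(g)) g[idx] <- perturb(field, idx)
    g
  })
}

# per-spectrum evaluation shared by staged/baseline comparisons
eval_selection <- function(selected_list, sim, floor = 50) {
  Map(function(sel, sp, tg) {
    keep <- sp$intensity >= floor
    compute_metrics(sel, truth_to_labels(tg[keep]), nchar(sp$peptide))
  }, selected_list, sim$spectra, sim$truth)
}

overall_pr <- function(metrics_list) {
  tab <- metrics_by_length(metrics_list)
  as.list(tab[tab$peptide_length == "overall", c("precision", "recall")])
}
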