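#' Sliding-window intensity baseline
#'
#' The classic de novo preprocessing baseline: a peak is selected when it is
#' among the `top_k` most intense peaks inside the `window`-Da sliding
#' interval centred on it. Selection is rank-based and therefore invariant to
#' global intensity scaling.
#'
#' @param spec a [spectrum].
#' @param window window width in Da (default 56).
#' @param top_k peaks retained per window (default 3).
#' @return logical vector of per-peak selections.
#' @export
window_baseline <- function(spec, window = 56, top_k = 3) {
  strong_peak(spec, window = window, top_k = top_k) == 1L
}

#' Selection quality against ground-truth labels
#'
#' Counts true positives (selected b/y peaks), false positives (selected u
#' peaks) and false negatives (unselected b/y peaks) and derives precision
#' `TP/(TP+FP)` and recall `TP/(TP+FN)`. Undefined ratios are reported as
#' `NA`, not 0.
#'
#' @param selected logical vector of per-peak selections.
#' @param labels per-peak labels (`b`/`y`/`u`).
#' @param peptide_length optional peptide length carried into the result for
#'   binned aggregation.
#' @return data frame of class `selection_metrics` with columns
#'   `peptide_length`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
compute_metrics <- function(selected, labels, peptide_length = NA_integer_) {
  labels <- as.character(labels)
  stopifnot(length(selected) == length(labels))
  is_by <- labels %in% c("b", "y")
  tp <- sum(selected & is_by)
  fp <- sum(selected & !is_by)
  fn <- sum(!selected & is_by)
  structure(data.frame(peptide_length = peptide_length, tp = tp, fp = fp, fn = fn,
                       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = c("selection_metrics", "data.frame"))
}

#' Micro-averaged precision/recall by peptide length
#'
#' Aggregates per-spectrum counts within each peptide length (summed counts,
#' i.e. micro-averaging) and recomputes precision and recall per length.
#'
#' @param metrics_list list of [compute_metrics] results.
#' @return data frame with one row per peptide length plus an `overall` row.
#' @export
metrics_by_length <- function(metrics_list) {
  tab <- do.call(rbind, metrics_list)
  agg <- function(rows, label) {
    tp <- sum(rows$tp); fp <- sum(rows$fp); fn <- sum(rows$fn)
    data.frame(peptide_length = label, n_spectra = nrow(rows),
               tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  lens <- sort(unique(tab$peptide_length))
  out <- do.call(rbind, lapply(lens, function(l)
    agg(tab[tab$peptide_length == l, , drop = FALSE], as.character(l))))
  rbind(out, agg(tab, "overall"))
}

#' Build a spectrum graph from selected peaks
#'
#' Nodes are putative prefix (b-ion) masses: the N-terminal anchor (proton
#' mass, the empty prefix), the full-length prefix `pI - water` (the b_n
#' equivalent of the parent ion), each selected peak read as a b-ion (its
#' mass), and each selected peak read as a y-ion (`pI - x + comp_offset`,
#' the prefix complementary to a y interpretation). Nodes closer than `tol`
#' are merged.
#' A directed edge runs from a lighter to a heavier node when their mass
#' difference matches a residue mass within `tol`; edges are annotated with
#' every matching residue (I is reported as L).
#'
#' @param selected_masses masses (Da) of the selected peaks.
#' @param pI parent ion mass in Da.
#' @param tol edge/node mass tolerance in Da (default 0.5).
#' @param comp_offset complement-relation constant (default proton mass).
#' @return object of class `spectrum_graph`: node mass vector, edge data
#'   frame (`from`, `to`, `residues`), and the source/terminal node indices.
#' @export
build_spectrum_graph <- function(selected_masses, pI, tol = 0.5,
                                 comp_offset = PROTON_MASS) {
  terminus <- pI - WATER_MASS  # full-length prefix mass b_n
  raw <- c(PROTON_MASS, terminus, selected_masses,
           pI - selected_masses + comp_offset)
  raw <- sort(raw[raw > 0 & raw <= pI + tol])
  ## greedy dedup: keep a node only when > tol above the last kept one
  nodes <- numeric(0)
  for (m in raw)
    if (!length(nodes) || m - nodes[length(nodes)] > tol)
      nodes <- c(nodes, m)
  res <- residue_masses(unique_mass = TRUE)
  from <- integer(0); to <- integer(0); residues <- character(0)
  n <- length(nodes)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- nodes[j] - nodes[i]
      if (d > max(res) + tol) break
      hit <- names(res)[abs(res - d) <= tol]
      if (length(hit)) {
        from <- c(from, i); to <- c(to, j)
        residues <- c(residues, paste(hit, collapse = "/"))
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, residues = residues),
                 source = which.min(abs(nodes - PROTON_MASS)),
                 terminal = which.min(abs(nodes - terminus)),
                 pI = pI, tol = tol),
            class = "spectrum_graph")
}

#' @export
print.spectrum_graph <- function(x, ...) {
  cat(sprintf("spectrum graph: %d nodes, %d edges (pI %.3f, tol %.2f Da)\n",
              length(x$nodes), nrow(x$edges), x$pI, x$tol))
  invisible(x)
}

#' Count spectrum-graph edges
#' @param graph a [build_spectrum_graph] result.
#' @return integer edge count.
#' @export
edge_count <- function(graph) nrow(graph$edges)

#' Enumerate candidate peptides from a spectrum graph
#'
#' Depth-first enumeration of every residue-labelled path from the
#' N-terminal anchor node to the terminal (parent-mass) node; each path
#' spells one candidate peptide, with edges matching several residues
#' contributing one candidate per residue. The candidate space is exponential
#' in the graph size, so enumeration stops (with `truncated = TRUE`) once
#' `ceiling` candidates have been collected.
#'
#' @param graph a [build_spectrum_graph] result.
#' @param max_length maximum path length in residues (default 30).
#' @param ceiling maximum number of candidates to enumerate (default 1e6).
#' @return list with `candidates` (character vector), `count`, and
#'   `truncated`.
#' @export
enumerate_candidates <- function(graph, max_length = 30, ceiling = 1e6) {
  edges <- graph$edges
  n <- length(graph$nodes)
  out_edges <- split(seq_len(nrow(edges)), factor(edges$from, levels = seq_len(n)))
  env <- new.env()
  env$cands <- character(0)
  env$truncated <- FALSE
  walk <- function(node, path) {
    if (env$truncated) return(invisible())
    if (node == graph$terminal) {
      if (length(env$cands) >= ceiling) { env$truncated <- TRUE; return(invisible()) }
      env$cands <- c(env$cands, paste(path, collapse = ""))
      return(invisible())
    }
    if (length(path) >= max_length) return(invisible())
    for (e in out_edges[[node]]) {
      for (r in strsplit(edges$residues[e], "/")[[1]]) {
        walk(edges$to[e], c(path, r))
        if (env$truncated) return(invisible())
      }
    }
  }
  walk(graph$source, character(0))
  list(candidates = env$cands, count = length(env$cands),
       truncated = env$truncated)
}

#' Median edge counts by peptide-length bin
#'
#' Groups per-spectrum edge counts into peptide-length bins of `bin_width`
#' residues and reports the median count per bin; the search space measure
#' used to compare peak selectors.
#'
#' @param edge_counts integer vector of per-spectrum edge counts.
#' @param peptide_lengths matching peptide lengths.
#' @param bin_width bin width in residues (default 2).
#' @return data frame with `bin` (label), `length_lo`, `median_edges`, `n`.
#' @export
edge_count_report <- function(edge_counts, peptide_lengths, bin_width = 2) {
  stopifnot(length(edge_counts) == length(peptide_lengths))
  lo <- min(peptide_lengths) -
    ((min(peptide_lengths) - 8) %% bin_width)  # anchor bins at length 8
  bin_lo <- lo + bin_width * ((peptide_lengths - lo) %/% bin_width)
  bins <- sort(unique(bin_lo))
  do.call(rbind, lapply(bins, function(b) {
    sel <- bin_lo == b
    data.frame(bin = sprintf("%d-%d", b, b + bin_width - 1),
               length_lo = b,
               median_edges = median(edge_counts[sel]),
               n = sum(sel))
  }))
}
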