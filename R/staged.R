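#' Control parameters for the staged classifier
#'
#' Collects every tunable of the pipeline in one object, serialised into
#' every trained model for provenance.
#'
#' @param intensity_floor raw-intensity prefilter floor (default 50).
#' @param label_tol ground-truth labelling tolerance in Da (default 0.2).
#' @param eps offset-peak search half-window in Da (default 0.2).
#' @param sigma Gaussian offset-model standard deviation in Da (default 0.1).
#' @param strong_window sliding-window width in Da for the strong-peak and
#'   local-rank features and the window baseline (default 56).
#' @param strong_top_k peaks called strong per window (default 3).
#' @param n_intensity_bins intensity discretisation bins (default 10).
#' @param n_regions relative-position regions (default 5).
#' @param flanking_tol flanking-residue offset tolerance in Da (default 0.25).
#' @param balance_ratio u instances per b/y instance after class balancing
#'   (default 1).
#' @param split_fraction fraction of training spectra used for
#'   backpropagation; the rest form the early-stopping validation set
#'   (default 0.95).
#' @param hidden_multiplier hidden-layer width as a multiple of the input
#'   width (default 2).
#' @param learning_rate,momentum,max_epochs SGD settings (defaults 0.1, 0.9,
#'   50).
#' @param graph_tol spectrum-graph edge mass tolerance in Da (default 0.5).
#' @param iso_delta isotopologue spacing in Da (default 1.00335).
#' @param comp_offset complement-relation constant in Da (default the proton
#'   mass).
#' @param offset_bin,intensity_bin,y_cap,pseudocount isotope-histogram
#'   binning (defaults 0.05 Da, 0.1, 2, 1).
#' @param random_peak_enabled compute the random-peak hypothesis feature
#'   (default `TRUE`; when `FALSE` the feature is 0).
#' @param neutral_loss_offsets named offsets in Da for the five neutral-loss
#'   features (defaults from [neutral_losses]).
#' @return list of class `snn_control`.
#' @export
snn_control <- function(intensity_floor = 50, label_tol = 0.2, eps = 0.2,
                        sigma = 0.1, strong_window = 56, strong_top_k = 3,
                        n_intensity_bins = 10, n_regions = 5,
                        flanking_tol = 0.25, balance_ratio = 1,
                        split_fraction = 0.95, hidden_multiplier = 2,
                        learning_rate = 0.1, momentum = 0.9, max_epochs = 50,
                        graph_tol = 0.5, iso_delta = C13_SPACING,
                        comp_offset = PROTON_MASS,
                        offset_bin = 0.05, intensity_bin = 0.1, y_cap = 2,
                        pseudocount = 1, random_peak_enabled = TRUE,
                        neutral_loss_offsets = neutral_losses()) {
  stopifnot(split_fraction > 0, split_fraction < 1, balance_ratio > 0,
            all(names(neutral_losses()) %in% names(neutral_loss_offsets)))
  structure(as.list(environment()), class = "snn_control")
}

#' Fit the staged b-/y-ion classifier
#'
#' Trains the two-stage peak classifier on spectra with known peptides:
#' spectra are intensity-prefiltered and their peaks labelled against the
#' theoretical b-/y-ladder; the isotope log-odds histogram is built from the
#' training peaks; stage-1 features are computed and `net1` trained (on a
#' seeded 95/5 spectrum-level backpropagation/validation split, with the
#' backpropagation classes balanced); `net1` then classifies every training
#' peak, its probability estimates feed the stage-2 complement and flanking
#' features, and `net2` is trained on the same split membership.
#'
#' @param spectra list of [spectrum] objects with known peptides (>= 2).
#' @param control a [snn_control].
#' @param seed master seed; the split, balancing and both network trainings
#'   derive their seeds from it.
#' @return object of class `snn` bundling `net1`, `net2`, the
#'   `isotope_histogram`, the `control` used, the split membership and label
#'   counts. Use [predict.snn] to classify new spectra.
#' @seealso [predict.snn], [select_peaks], [write_snn]
#' @export
snn_fit <- function(spectra, control = snn_control(), seed = 1L) {
  if (length(spectra) < 2) stop("need at least 2 training spectra")
  spectra <- prefilter_intensity(spectra, floor = control$intensity_floor)
  labels <- lapply(spectra, label_peaks, tol = control$label_tol)
  hist <- build_isotope_histogram(
    spectra, labels, eps = control$eps, iso_delta = control$iso_delta,
    offset_bin = control$offset_bin, intensity_bin = control$intensity_bin,
    y_cap = control$y_cap, pseudocount = control$pseudocount)

  n <- length(spectra)
  n_bp <- max(1L, min(n - 1L, round(control$split_fraction * n)))
  bp_spectra <- with_seed(seed, sort(sample.int(n, n_bp)))
  in_bp <- rep(seq_len(n) %in% bp_spectra, vapply(spectra, n_peaks, 0L))

  lab_vec <- factor(unlist(lapply(labels, as.character)),
                    levels = c("b", "y", "u"))
  X1 <- do.call(rbind, lapply(spectra, build_feature_vectors, stage = "net1",
                              hist = hist, control = control))
  T1 <- ion_targets(lab_vec)
  keep <- balance_classes(lab_vec[in_bp], ratio = control$balance_ratio,
                          seed = seed + 1L)
  bp_idx <- which(in_bp)[keep]
  val_idx <- which(!in_bp)
  if (!length(val_idx)) stop("validation split is empty; need more spectra")

  cfg1 <- net_config(ncol(X1), hidden_dim = round(control$hidden_multiplier * ncol(X1)),
                     learning_rate = control$learning_rate,
                     momentum = control$momentum,
                     max_epochs = control$max_epochs, seed = seed + 2L)
  net1 <- train_nn(cfg1, X1[bp_idx, , drop = FALSE], T1[bp_idx, , drop = FALSE],
                   X1[val_idx, , drop = FALSE], T1[val_idx, , drop = FALSE],
                   feature_names = colnames(X1), stage = "net1")

  ## stage 1 classifies the training spectra; its estimates feed stage 2
  p1 <- lapply(spectra, function(sp)
    nn_forward(net1, build_feature_vectors(sp, "net1", hist, control = control)))
  X2 <- do.call(rbind, Map(function(sp, p)
    build_feature_vectors(sp, "net2", hist, net1_probs = p, control = control),
    spectra, p1))
  cfg2 <- net_config(ncol(X2), hidden_dim = round(control$hidden_multiplier * ncol(X2)),
                     learning_rate = control$learning_rate,
                     momentum = control$momentum,
                     max_epochs = control$max_epochs, seed = seed + 3L)
  net2 <- train_nn(cfg2, X2[bp_idx, , drop = FALSE], T1[bp_idx, , drop = FALSE],
                   X2[val_idx, , drop = FALSE], T1[val_idx, , drop = FALSE],
                   feature_names = colnames(X2), stage = "net2")

  structure(list(net1 = net1, net2 = net2, isotope_histogram = hist,
                 control = control, seed = as.integer(seed),
                 n_spectra = n, backprop_spectra = bp_spectra,
                 label_counts = table(lab_vec),
                 n_balanced = length(bp_idx)),
            class = "snn")
}

#' @export
print.snn <- function(x, ...) {
  cat("Staged neural-network b-/y-ion classifier\n")
  cat(sprintf("  trained on %d spectra (%d peaks: %d b, %d y, %d u)\n",
              x$n_spectra, sum(x$label_counts),
              x$label_counts[["b"]], x$label_counts[["y"]], x$label_counts[["u"]]))
  cat(sprintf("  net1: %d -> %d -> 3; net2: %d -> %d -> 3\n",
              x$net1$config$input_dim, x$net1$config$hidden_dim,
              x$net2$config$input_dim, x$net2$config$hidden_dim))
  cat(sprintf("  net1 kept epoch %d (val err %.4f); net2 kept epoch %d (val err %.4f)\n",
              x$net1$stopped_epoch,
              x$net1$training_log$val_error[x$net1$stopped_epoch],
              x$net2$stopped_epoch,
              x$net2$training_log$val_error[x$net2$stopped_epoch]))
  invisible(x)
}

#' @export
summary.snn <- function(object, ...) {
  structure(list(model = object), class = "summary.snn")
}

#' @export
print.summary.snn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  balanced backprop instances: %d (u:b+y ratio %.2f)\n",
              x$model$n_balanced, x$model$control$balance_ratio))
  cat("\nnet1 training log:\n")
  print(x$model$net1$training_log, row.names = FALSE)
  cat("\nnet2 training log:\n")
  print(x$model$net2$training_log, row.names = FALSE)
  invisible(x)
}

#' @export
coef.snn <- function(object, ...) {
  list(net1 = object$net1[c("W1", "b1", "W2", "b2")],
       net2 = object$net2[c("W1", "b1", "W2", "b2")])
}

#' @export
plot.snn <- function(x, ...) {
  logs <- list(net1 = x$net1$training_log, net2 = x$net2$training_log)
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  for (nm in names(logs)) {
    lg <- logs[[nm]]
    graphics::matplot(lg$epoch, cbind(lg$train_error, lg$val_error),
                      type = "b", pch = c(1, 2), lty = 1,
                      xlab = "epoch", ylab = "error", main = nm, ...)
    graphics::legend("topright", c("train (cross-entropy)", "val (misclass.)"),
                     pch = c(1, 2), bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Classify spectra with a fitted staged model
#'
#' Runs both stages on each spectrum: peaks are prefiltered with the model's
#' intensity floor, stage-1 features and probabilities computed, then stage-2
#' features (which consume the stage-1 estimates) and probabilities.
#'
#' @param object a fitted [snn_fit] model.
#' @param spectra a [spectrum] or list of spectra to classify.
#' @param type `"prob"` returns per-peak class probabilities; `"select"`
#'   returns per-peak logical selections under `rule`.
#' @param stage which stage's output to report (default `"net2"`; the other
#'   stage's probabilities are always available in the `"snn_pred"` result).
#' @param rule,theta selection rule, see [select_peaks].
#' @param ... unused.
#' @return for `type = "prob"` an object of class `snn_pred`: a list with one
#'   element per spectrum, each holding `scan_id`, `mass`, `intensity` and
#'   the raw stage-1/stage-2 probability matrices `net1`, `net2`; for
#'   `type = "select"` a list of logical vectors.
#' @export
predict.snn <- function(object, spectra, type = c("prob", "select"),
                        stage = c("net2", "net1"), rule = c("argmax", "threshold"),
                        theta = 0.5, ...) {
  type <- match.arg(type); stage <- match.arg(stage); rule <- match.arg(rule)
  single <- inherits(spectra, "spectrum")
  if (single) spectra <- list(spectra)
  spectra <- prefilter_intensity(spectra, floor = object$control$intensity_floor)
  ctl <- object$control
  hist <- object$isotope_histogram
  out <- lapply(spectra, function(sp) {
    if (!n_peaks(sp)) {
      empty <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("b", "y", "u")))
      return(list(scan_id = sp$scan_id, mass = numeric(0),
                  intensity = numeric(0), net1 = empty, net2 = empty))
    }
    p1 <- nn_forward(object$net1,
                     build_feature_vectors(sp, "net1", hist, control = ctl))
    p2 <- nn_forward(object$net2,
                     build_feature_vectors(sp, "net2", hist, net1_probs = p1,
                                           control = ctl))
    list(scan_id = sp$scan_id, mass = sp$mass, intensity = sp$intensity,
         net1 = p1, net2 = p2)
  })
  class(out) <- "snn_pred"
  if (type == "select")
    out <- lapply(unclass(out), function(p)
      select_peaks(p[[stage]], rule = rule, theta = theta))
  if (single) out[[1]] else out
}

#' @export
print.snn_pred <- function(x, ...) {
  cat(sprintf("staged classification of %d spectrum/spectra (%d peaks)\n",
              length(x), sum(vapply(x, function(p) length(p$mass), 0L))))
  invisible(x)
}

#' Turn class probabilities into a peak selection
#'
#' The default `argmax` rule selects a peak when its combined b/y evidence
#' beats the unknown class: `max(P_b, P_y) > P_u`. The `threshold` rule
#' selects peaks with renormalised `max(P_b, P_y) >= theta`.
#'
#' @param probs k x 3 probability matrix (columns b, y, u).
#' @param rule `"argmax"` or `"threshold"`.
#' @param theta threshold in `[0, 1]` for the threshold rule.
#' @return logical vector of per-peak selections.
#' @export
select_peaks <- function(probs, rule = c("argmax", "threshold"), theta = 0.5) {
  rule <- match.arg(rule)
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 3)
  if (rule == "argmax")
    return(pmax(probs[, 1], probs[, 2]) > probs[, 3])
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  pn <- probs / pmax(rowSums(probs), .Machine$double.eps)
  pmax(pn[, 1], pn[, 2]) >= theta
}

#' Save / load a fitted staged model
#'
#' Single-file JSON bundle holding both networks, the isotope histogram, the
#' control parameters and the training provenance, at full numeric precision
#' (a reloaded model predicts bit-identically, and refitting with the same
#' seed reproduces the file byte for byte).
#'
#' @param model a fitted `snn`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `snn`.
#' @export
write_snn <- function(model, path) {
  ctl <- unclass(model$control)
  ctl$neutral_loss_offsets <- as.list(ctl$neutral_loss_offsets)
  payload <- list(schema = "peakstage-snn-1",
                  seed = model$seed, n_spectra = model$n_spectra,
                  backprop_spectra = model$backprop_spectra,
                  label_counts = as.list(model$label_counts),
                  n_balanced = model$n_balanced,
                  control = ctl,
                  histogram = unclass(model$isotope_histogram),
                  net1 = .net_payload(model$net1),
                  net2 = .net_payload(model$net2))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

.net_payload <- function(net) {
  list(stage = net$stage, feature_names = net$feature_names,
       config = unclass(net$config),
       W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
       training_log = net$training_log, stopped_epoch = net$stopped_epoch)
}

.net_from_payload <- function(x) {
  cfg <- do.call(net_config, x$config[c("input_dim", "hidden_dim",
                                        "learning_rate", "momentum",
                                        "max_epochs", "seed")])
  structure(list(W1 = x$W1, b1 = as.numeric(x$b1), W2 = x$W2,
                 b2 = as.numeric(x$b2), config = cfg, stage = x$stage,
                 feature_names = x$feature_names,
                 training_log = as.data.frame(x$training_log),
                 stopped_epoch = x$stopped_epoch),
            class = "ffnet")
}

#' @rdname write_snn
#' @export
read_snn <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot read model bundle: ",
                                         conditionMessage(e)))
  if (!identical(x$schema, "peakstage-snn-1"))
    stop("unrecognised model bundle schema in ", path)
  hist <- x$histogram
  class(hist) <- "isotope_histogram"
  ctl <- x$control
  ctl$neutral_loss_offsets <- unlist(ctl$neutral_loss_offsets)
  class(ctl) <- "snn_control"
  structure(list(net1 = .net_from_payload(x$net1),
                 net2 = .net_from_payload(x$net2),
                 isotope_histogram = hist, control = ctl,
                 seed = x$seed, n_spectra = x$n_spectra,
                 backprop_spectra = x$backprop_spectra,
                 label_counts = unlist(x$label_counts),
                 n_balanced = x$n_balanced),
            class = "snn")
}
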