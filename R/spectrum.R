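#' Construct an MS/MS spectrum
#'
#' A `spectrum` holds a centroided peak list together with its precursor
#' information. Peaks are stored mass-sorted; the parent ion mass `pI` is the
#' singly protonated precursor mass MH+, computed as
#' `precursor_mz * charge - (charge - 1) * 1.007276`.
#'
#' @param mass numeric vector of peak m/z values (Da), any order.
#' @param intensity numeric vector of peak abundances, same length as `mass`.
#' @param precursor_mz precursor m/z (the MGF PEPMASS value).
#' @param charge integer precursor charge state.
#' @param peptide optional known peptide sequence (standard one-letter codes).
#' @param scan_id identifier for the scan.
#' @param mass_slack peaks may exceed `parent_ion_mass` by at most this many Da.
#' @return an object of class `spectrum` with fields `mass`, `intensity`
#'   (parallel, mass-sorted), `precursor_mz`, `charge`, `parent_ion_mass`,
#'   `peptide`, `scan_id`.
#' @export
#' @examples
#' sp <- spectrum(c(300, 100), c(5, 10), precursor_mz = 500, charge = 2)
#' sp$parent_ion_mass
spectrum <- function(mass, intensity, precursor_mz, charge = 2L,
                     peptide = NA_character_, scan_id = "",
                     mass_slack = 5) {
  stopifnot(length(mass) == length(intensity), charge >= 1)
  if (length(mass) && (any(mass <= 0) || any(intensity < 0)))
    stop("peak masses must be positive and intensities non-negative")
  ord <- order(mass)
  mass <- as.numeric(mass[ord]); intensity <- as.numeric(intensity[ord])
  p_mass <- precursor_mz * charge - (charge - 1) * PROTON_MASS
  if (length(mass) && max(mass) > p_mass + mass_slack)
    warning(sprintf("scan %s: peak mass %.3f exceeds parent ion mass %.3f + %g",
                    scan_id, max(mass), p_mass, mass_slack))
  if (!is.na(peptide)) {
    peptide <- toupper(peptide)
    bad <- setdiff(strsplit(peptide, "")[[1]], names(.RESIDUE_MASSES))
    if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  structure(list(mass = mass, intensity = intensity,
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 parent_ion_mass = p_mass,
                 peptide = peptide, scan_id = as.character(scan_id)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum %s: %d peaks, precursor m/z %.4f (%d+), pI %.4f\n",
              x$scan_id, length(x$mass), x$precursor_mz, x$charge,
              x$parent_ion_mass))
  if (!is.na(x$peptide)) cat("  peptide:", x$peptide, "\n")
  invisible(x)
}

n_peaks <- function(sp) length(sp$mass)

#' Read a Mascot generic format (MGF) peak list
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE`, optional
#' `TITLE` and `SEQ` headers and whitespace-separated mass/intensity pairs.
#' Charge is accepted as `2+`, `+2` or `2`; unknown headers are ignored.
#'
#' @param path path to an MGF file.
#' @param lenient if `TRUE` (default), malformed blocks are skipped and
#'   recorded in the `"parse_errors"` attribute of the result (a data frame
#'   with the block's line range and message); if `FALSE`, the first
#'   malformed block raises an error.
#' @return list of [spectrum] objects (possibly empty), with attribute
#'   `"parse_errors"`.
#' @export
#' @examples
#' mgf <- system.file("extdata", "example.mgf", package = "peakstage")
#' spectra <- read_mgf(mgf)
#' spectra[[1]]
read_mgf <- function(path, lenient = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  errors <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    first <- i
    j <- i + 1L
    while (j <= n && trimws(lines[j]) != "END IONS") j <- j + 1L
    last <- min(j, n)
    block <- trimws(lines[(first + 1L):(last - 1L)])
    res <- tryCatch(parse_mgf_block(block), error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      if (!lenient) stop(sprintf("MGF parse error (lines %d-%d): %s", first, last, msg))
      errors[[length(errors) + 1L]] <-
        data.frame(first_line = first, last_line = last, message = msg)
    } else {
      spectra[[length(spectra) + 1L]] <- res
    }
    i <- last + 1L
  }
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(first_line = integer(), last_line = integer(), message = character())
  if (nrow(errors)) warning(sprintf("%d malformed MGF block(s) skipped", nrow(errors)))
  attr(spectra, "parse_errors") <- errors
  spectra
}

parse_mgf_block <- function(block) {
  block <- block[nzchar(block)]
  is_hdr <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
  hdr <- block[is_hdr]
  keys <- toupper(sub("=.*$", "", hdr))
  vals <- sub("^[^=]*=", "", hdr)
  get1 <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  pm <- get1("PEPMASS")
  if (is.na(pm)) stop("missing PEPMASS")
  pepmass <- suppressWarnings(as.numeric(strsplit(trimws(pm), "\\s+")[[1]][1]))
  if (is.na(pepmass)) stop("non-numeric PEPMASS: ", pm)
  ch <- get1("CHARGE")
  charge <- if (is.na(ch)) 2L else {
    z <- suppressWarnings(as.integer(gsub("[+\\s]", "", ch)))
    if (is.na(z) || z < 1) stop("unparseable CHARGE: ", ch)
    z
  }
  peaks <- block[!is_hdr]
  mass <- numeric(0); intensity <- numeric(0)
  if (length(peaks)) {
    fields <- strsplit(peaks, "[\t ]+")
    if (any(lengths(fields) < 2)) stop("peak line with fewer than two fields")
    mass <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    intensity <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    if (anyNA(mass) || anyNA(intensity)) stop("non-numeric peak line")
  }
  spectrum(mass, intensity, precursor_mz = pepmass, charge = charge,
           peptide = get1("SEQ"),
           scan_id = if (!is.na(get1("TITLE"))) get1("TITLE") else "")
}

#' Write spectra to an MGF file
#'
#' Writes one `BEGIN IONS` block per spectrum with `TITLE`, `PEPMASS`,
#' `CHARGE` and, when known, `SEQ` headers. Output is deterministic: masses
#' are printed with 6 decimals and intensities with 4.
#'
#' @param spectra a [spectrum] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$scan_id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (!is.na(sp$peptide)) writeLines(sprintf("SEQ=%s", sp$peptide), con)
    if (n_peaks(sp))
      writeLines(sprintf("%.6f %.4f", sp$mass, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Remove low-intensity peaks
#'
#' Drops every peak whose raw intensity is below `floor`. The default floor of
#' 50 intensity units removes roughly half of the noise in typical ion-trap
#' CID spectra while losing few fragment ions; it is applied before feature
#' computation and training.
#'
#' @param x a [spectrum] or a list of spectra.
#' @param floor minimum retained intensity (peaks with intensity >= `floor`
#'   are kept).
#' @return object of the same shape with the filtered peak list; precursor
#'   fields unchanged.
#' @export
prefilter_intensity <- function(x, floor = 50) {
  stopifnot(floor >= 0)
  if (is.list(x) && !inherits(x, "spectrum"))
    return(lapply(x, prefilter_intensity, floor = floor))
  keep <- x$intensity >= floor
  x$mass <- x$mass[keep]
  x$intensity <- x$intensity[keep]
  x
}

#' Write a per-peak classification report
#'
#' Tab-separated report with one row per retained peak: scan id, mass,
#' intensity, the three class-probability estimates (renormalised to sum to
#' one) and the predicted label. Rows are ordered by scan, then mass.
#'
#' @param spectra list of [spectrum] objects.
#' @param probabilities list of k x 3 probability matrices (columns b, y, u),
#'   one row per peak of the matching spectrum.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_classified <- function(spectra, probabilities, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (length(spectra) != length(probabilities))
    stop("one probability matrix required per spectrum")
  rows <- vector("list", length(spectra))
  for (s in seq_along(spectra)) {
    sp <- spectra[[s]]
    p <- probabilities[[s]]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    if (nrow(p) != n_peaks(sp))
      stop(sprintf("scan %s: %d peaks but %d probability rows",
                   sp$scan_id, n_peaks(sp), nrow(p)))
    if (n_peaks(sp) == 0) next
    pn <- p / pmax(rowSums(p), .Machine$double.eps)
    lab <- c("b", "y", "u")[max.col(pn, ties.method = "last")]
    rows[[s]] <- data.frame(scan_id = sp$scan_id, mass = sp$mass,
                            intensity = sp$intensity,
                            p_b = pn[, 1], p_y = pn[, 2], p_u = pn[, 3],
                            label = lab)
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(scan_id = character(), mass = numeric(), intensity = numeric(),
               p_b = numeric(), p_y = numeric(), p_u = numeric(),
               label = character()))))
  out <- out[order(out$scan_id, out$mass), , drop = FALSE]
  fmt <- out
  for (col in c("mass", "intensity")) fmt[[col]] <- sprintf("%.5f", out[[col]])
  for (col in c("p_b", "p_y", "p_u")) fmt[[col]] <- sprintf("%.6f", out[[col]])
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan-to-peptide assignment table
#'
#' Sidecar for MGF files without `SEQ` lines: a two-column TSV with header
#' `scan_id` and `peptide`. [assign_peptides] merges it into a spectrum list.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `scan_id`, `peptide`.
#' @export
read_peptide_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("scan_id", "peptide") %in% names(tab)))
    stop("peptide table needs columns scan_id and peptide")
  tab
}

#' @rdname read_peptide_table
#' @param spectra list of [spectrum] objects.
#' @param table data frame as returned by [read_peptide_table].
#' @export
assign_peptides <- function(spectra, table) {
  lapply(spectra, function(sp) {
    hit <- match(sp$scan_id, table$scan_id)
    if (!is.na(hit)) sp$peptide <- toupper(table$peptide[hit])
    sp
  })
}
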