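# Per-residue derived NMR observables: chemical-shift perturbation on metal
# substitution, steady-state heteronuclear NOE with noise-propagated errors,
# and H/D-exchange protection classification.

#' Chemical shift table
#'
#' @param residue Integer residue numbers.
#' @param nucleus Nucleus labels (`"H"`, `"N"`, `"HA"`, `"HB"`, ...).
#' @param shift Chemical shifts in ppm.
#' @param condition Optional condition label (e.g. `"Zn-form"`).
#' @return A tibble of class `shift_table`; `(residue, nucleus)` pairs must
#'   be unique.
#' @export
shift_table <- function(residue, nucleus, shift, condition = NA_character_) {
  tbl <- tibble::tibble(residue = as.integer(residue),
                        nucleus = as.character(nucleus),
                        shift = as.numeric(shift))
  if (anyDuplicated(tbl[c("residue", "nucleus")])) {
    stop_input("(residue, nucleus) pairs must be unique within a shift table")
  }
  attr(tbl, "condition") <- condition
  class(tbl) <- c("shift_table", class(tbl))
  tbl
}

#' Chemical shift perturbation between two conditions
#'
#' Signed per-residue, per-nucleus difference `delta = shift_b - shift_a`
#' over the `(residue, nucleus)` keys shared by both tables.  Keys present
#' in only one table are reported in the `missing_in_a` / `missing_in_b`
#' attributes, never imputed as zero.
#'
#' @param a,b [shift_table()] objects (e.g. Zn-form and Cd-form).
#' @return Tibble with columns `residue`, `nucleus`, `delta`.
#' @export
chemical_shift_perturbation <- function(a, b) {
  a <- tibble::as_tibble(a)[c("residue", "nucleus", "shift")]
  b <- tibble::as_tibble(b)[c("residue", "nucleus", "shift")]
  shared <- dplyr::inner_join(a, b, by = c("residue", "nucleus"),
                              suffix = c("_a", "_b"))
  if (nrow(shared) == 0L) {
    stop_input("no shared (residue, nucleus) keys between the two tables")
  }
  out <- dplyr::arrange(
    tibble::tibble(residue = shared$residue, nucleus = shared$nucleus,
                   delta = shared$shift_b - shared$shift_a),
    residue, nucleus)
  key <- function(x) paste(x$residue, x$nucleus)
  attr(out, "missing_in_b") <- a[!key(a) %in% key(b), c("residue", "nucleus")]
  attr(out, "missing_in_a") <- b[!key(b) %in% key(a), c("residue", "nucleus")]
  out
}

#' Summary statistics of absolute shift perturbations
#'
#' @param csp Output of [chemical_shift_perturbation()].
#' @param nuclei Optional subset of nuclei (e.g. `c("HA", "HB")`).
#' @return List with `mean_abs` and `max_abs` in ppm, and `n`.
#' @export
csp_summary <- function(csp, nuclei = NULL) {
  if (!is.null(nuclei)) csp <- csp[csp$nucleus %in% nuclei, , drop = FALSE]
  list(mean_abs = mean(abs(csp$delta)),
       max_abs = max(abs(csp$delta)),
       n = nrow(csp))
}

#' Peak intensity table
#'
#' @param residue Integer residue numbers.
#' @param intensity Peak intensities (arbitrary units).
#' @param time Optional timepoints (minutes), for exchange series.
#' @param noise_level Spectrum background noise, same units as intensity.
#' @return A tibble of class `intensity_table` with a `noise_level`
#'   attribute.
#' @export
intensity_table <- function(residue, intensity, time = NULL, noise_level = 1) {
  if (!is.numeric(noise_level) || noise_level <= 0) {
    stop_input("noise_level must be > 0")
  }
  if (any(!is.finite(intensity))) stop_input("intensities must be finite")
  tbl <- tibble::tibble(residue = as.integer(residue),
                        intensity = as.numeric(intensity))
  if (!is.null(time)) tbl$time <- as.numeric(time)
  attr(tbl, "noise_level") <- noise_level
  class(tbl) <- c("intensity_table", class(tbl))
  tbl
}

noise_of <- function(tbl, default = 1) {
  nl <- attr(tbl, "noise_level")
  if (is.null(nl)) default else nl
}

#' Steady-state heteronuclear NOE with propagated errors
#'
#' The NOE value per residue is the ratio of the peak intensity in the
#' proton-saturated spectrum to that in the reference (unsaturated)
#' spectrum.  The uncertainty is propagated from the spectrum background
#' noise sigma of each table:
#' `error = |NOE| * sqrt((sigma_sat/I_sat)^2 + (sigma_ref/I_ref)^2)`.
#' Residues with zero reference intensity are flagged `undefined`, not
#' errors.
#'
#' @param saturated,reference [intensity_table()] objects on matching
#'   residues.
#' @return Tibble with columns `residue`, `noe`, `error`, `undefined`.
#' @export
heteronuclear_noe <- function(saturated, reference) {
  s <- tibble::as_tibble(saturated)[c("residue", "intensity")]
  r <- tibble::as_tibble(reference)[c("residue", "intensity")]
  m <- dplyr::inner_join(s, r, by = "residue", suffix = c("_sat", "_ref"))
  if (nrow(m) == 0L) stop_input("no matching residues between the two tables")
  sig_s <- noise_of(saturated)
  sig_r <- noise_of(reference)
  undef <- m$intensity_ref == 0
  noe <- ifelse(undef, NA_real_, m$intensity_sat / m$intensity_ref)
  # algebraically |noe|*sqrt((sig_s/I_sat)^2+(sig_r/I_ref)^2), robust at I_sat=0
  err <- ifelse(undef, NA_real_,
                sqrt(sig_s^2 + noe^2 * sig_r^2) / abs(m$intensity_ref))
  dplyr::arrange(
    tibble::tibble(residue = m$residue, noe = noe, error = err,
                   undefined = undef),
    residue)
}

#' Classify H/D-exchange protection from an intensity decay series
#'
#' A residue counts as detected at a timepoint when its amide peak
#' intensity exceeds `threshold_multiple` times the background noise.  The
#' protection class is set by the last *class boundary* timepoint at which
#' the residue is still detected (default boundaries: the first spectrum,
#' 2 h and 24 h); intermediate timepoints are retained in the per-residue
#' detection output but do not define classes.
#'
#' @param decays [intensity_table()] with columns `residue`, `time`
#'   (minutes), `intensity`.
#' @param timepoints Strictly increasing timepoints to evaluate (defaults
#'   to the times present in `decays`).
#' @param threshold_multiple Detection threshold as a multiple of the noise
#'   level (default 3, the conventional signal-to-noise floor).
#' @param class_times Class boundary timepoints (minutes); must be a subset
#'   of `timepoints`.
#' @return List with `per_residue` (tibble: `residue`, `last_detected`,
#'   `class`), `counts` (named integer vector: residues detected at each
#'   class boundary) and `detection` (logical matrix residues x
#'   timepoints).
#' @export
hdx_classify <- function(decays, timepoints = NULL, threshold_multiple = 3,
                         class_times = c(0, 120, 1440)) {
  stopifnot("time" %in% names(decays))
  if (!is.numeric(threshold_multiple) || threshold_multiple <= 0) {
    stop_input("threshold_multiple must be > 0")
  }
  if (is.null(timepoints)) timepoints <- sort(unique(decays$time))
  if (any(diff(timepoints) <= 0)) {
    stop_input("timepoints must be strictly increasing")
  }
  if (!all(class_times %in% timepoints)) {
    stop_input("class_times must be a subset of the evaluated timepoints")
  }
  thr <- threshold_multiple * noise_of(decays)
  residues <- sort(unique(decays$residue))
  det <- matrix(FALSE, length(residues), length(timepoints),
                dimnames = list(residues, timepoints))
  for (k in seq_len(nrow(decays))) {
    i <- match(decays$residue[k], residues)
    j <- match(decays$time[k], timepoints)
    if (!is.na(j)) det[i, j] <- det[i, j] | (decays$intensity[k] > thr)
  }
  class_idx <- match(class_times, timepoints)
  class_labels <- c("undetected", paste0("t", class_times))
  per_class_det <- det[, class_idx, drop = FALSE]
  cls <- apply(per_class_det, 1L, function(row) {
    hit <- which(row)
    if (length(hit) == 0L) "undetected" else paste0("t", class_times[max(hit)])
  })
  last_det <- apply(det, 1L, function(row) {
    hit <- which(row)
    if (length(hit) == 0L) NA_real_ else timepoints[max(hit)]
  })
  counts <- colSums(per_class_det)
  names(counts) <- paste0("t", class_times)
  list(per_residue = tibble::tibble(
         residue = residues,
         last_detected = last_det,
         class = factor(cls, levels = class_labels)),
       counts = counts,
       detection = det)
}

#' Read a shift or intensity CSV table
#'
#' @param path CSV path.  Shift tables need columns `residue`, `nucleus`,
#'   `shift`; intensity tables need `residue`, `intensity` and optionally
#'   `time`.
#' @param noise_level Noise level attached to intensity tables.
#' @return A [shift_table()] or [intensity_table()] depending on columns.
#' @export
read_nmr_table <- function(path, noise_level = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("residue", "nucleus", "shift") %in% names(df))) {
    shift_table(df$residue, df$nucleus, df$shift)
  } else if (all(c("residue", "intensity") %in% names(df))) {
    intensity_table(df$residue, df$intensity,
                    time = if ("time" %in% names(df)) df$time else NULL,
                    noise_level = noise_level)
  } else {
    stop_input("unrecognized NMR table columns in %s", path)
  }
}
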