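# Metal-binding stoichiometry from native ESI-MS monoisotopic peaks.
#
# Native electrospray of an intact metalloprotein yields charge-state series
# whose monoisotopic neutral mass can be compared against the apo protein
# plus n metal adducts.  Two arithmetic conventions are supported: a
# "paper" convention in which the charge carrier is 1.0 Da per charge and a
# divalent metal contributes (isotope mass - charge) Da, and an "accurate"
# convention that uses the proton mass and subtracts only the electron mass
# per unit of metal charge.

ELECTRON_MASS <- 0.000548579909  # Da
PROTON_MASS <- 1.007276          # Da

#' Metal ion species for adduct arithmetic
#'
#' Bundles the monoisotopic neutral-atom mass of one isotope with the ion
#' charge, the two quantities needed to convert an apo protein mass into a
#' holo mass.
#'
#' @param name Metal name, e.g. `"Zn"`.
#' @param isotope_mass Monoisotopic mass of the neutral atom in Da.
#' @param charge Positive integer ion charge.
#' @return A `metal_spec` object.
#' @examples
#' zn_spec()  # 64Zn2+, the most abundant zinc isotope
#' @export
metal_spec <- function(name, isotope_mass, charge = 2L) {
  if (!is.numeric(isotope_mass) || isotope_mass <= 0) {
    stop_input("isotope_mass must be a positive number, got %s", isotope_mass)
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop_input("metal charge must be >= 1")
  structure(list(name = as.character(name), isotope_mass = isotope_mass,
                 charge = charge),
            class = "metal_spec")
}

#' @export
format.metal_spec <- function(x, ...) {
  sprintf("<metal_spec %s%d+ (%.4f Da)>", x$name, x$charge, x$isotope_mass)
}

#' @export
print.metal_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname metal_spec
#' @export
zn_spec <- function() metal_spec("Zn", 63.929, 2L)

#' @rdname metal_spec
#' @export
cd_spec <- function() metal_spec("Cd", 112.904408, 2L)

#' Neutral monoisotopic mass from an m/z peak
#'
#' Multiplies the m/z of a monoisotopic peak by its charge and subtracts the
#' mass of the charge carriers.  The default carrier mass of 1.0 Da
#' reproduces the integer-subtraction convention commonly used when quoting
#' native-MS masses; pass `charge_carrier_mass = 1.007276` for the accurate
#' proton mass.
#'
#' @param mz Mass-to-charge ratio of the monoisotopic peak (Th).
#' @param z Positive integer charge of the species.
#' @param charge_carrier_mass Mass subtracted per charge, Da.
#' @return Neutral mass in Da.
#' @examples
#' neutral_mass_from_peak(1165.8361, 5)  # 5824.1805
#' @export
neutral_mass_from_peak <- function(mz, z, charge_carrier_mass = 1.0) {
  if (!is.numeric(mz) || any(mz <= 0)) stop_input("invalid peak: mz must be > 0")
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop_input("invalid peak: charge z must be >= 1")
  if (!is.numeric(charge_carrier_mass) || charge_carrier_mass <= 0) {
    stop_input("charge_carrier_mass must be positive")
  }
  mz * z - z * charge_carrier_mass
}

#' Holo mass of a protein with n metal adducts
#'
#' In `"paper"` mode each bound divalent metal contributes
#' `isotope_mass - charge` Da (the metal mass minus one Da per positive
#' charge, compensating the protons displaced on binding).  In `"accurate"`
#' mode only the electron mass is removed per unit charge.
#'
#' @param apo_mass Monoisotopic mass of the metal-free protein, Da.
#' @param n Number of bound metal ions (>= 0).
#' @param metal A [metal_spec()].
#' @param mode `"paper"` or `"accurate"`.
#' @return Predicted holo mass in Da.
#' @examples
#' metal_adduct_mass(5638.48, 3)  # 5824.267
#' @export
metal_adduct_mass <- function(apo_mass, n, metal = zn_spec(),
                              mode = c("paper", "accurate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(metal, "metal_spec"))
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 0L)) stop_input("number of metals n must be >= 0")
  per_metal <- switch(mode,
    paper = metal$isotope_mass - metal$charge,
    accurate = metal$isotope_mass - metal$charge * ELECTRON_MASS
  )
  apo_mass + n * per_metal
}

#' Infer metal-binding stoichiometry from an observed neutral mass
#'
#' Searches n = 0..`n_max` for the metal count whose predicted holo mass
#' best matches the observed mass; ties are broken toward the smaller n
#' (parsimony).  A result outside `tolerance` is flagged, not an error.
#'
#' @param observed_mass Observed neutral monoisotopic mass, Da.
#' @param apo_mass Metal-free protein mass, Da.
#' @param metal A [metal_spec()].
#' @param n_max Largest stoichiometry considered.
#' @param tolerance Acceptance window in Da.
#' @param mode Adduct-mass convention, see [metal_adduct_mass()].
#' @return A `stoichiometry_result`: list with `n_metals`, `predicted_mass`,
#'   `residual` and `within_tolerance`.
#' @examples
#' infer_stoichiometry(5824.1805, 5638.48)  # selects n = 3
#' @export
infer_stoichiometry <- function(observed_mass, apo_mass, metal = zn_spec(),
                                n_max = 6L, tolerance = 0.5,
                                mode = c("paper", "accurate")) {
  mode <- match.arg(mode)
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 0L) stop_input("n_max must be >= 0")
  if (!is.numeric(tolerance) || tolerance <= 0) stop_input("tolerance must be > 0")
  ns <- 0:n_max
  predicted <- metal_adduct_mass(apo_mass, ns, metal, mode)
  residuals <- abs(observed_mass - predicted)
  best <- which.min(residuals)  # which.min returns the first (smallest n) tie
  structure(list(
    n_metals = ns[best],
    predicted_mass = predicted[best],
    residual = residuals[best],
    within_tolerance = residuals[best] <= tolerance
  ), class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("Stoichiometry: n = %d metal ion(s)\n", x$n_metals))
  cat(sprintf("  predicted mass: %.4f Da\n", x$predicted_mass))
  cat(sprintf("  residual:       %.4f Da (%s tolerance)\n", x$residual,
              if (x$within_tolerance) "within" else "OUTSIDE"))
  invisible(x)
}

# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MASS <- 18.010565

#' Monoisotopic mass of a peptide sequence
#'
#' Standard residue-mass summation plus one water.  Supports validating an
#' apo mass from a construct sequence.
#'
#' @param sequence One-letter amino-acid string (20 canonical letters).
#' @return Monoisotopic peptide mass in Da.
#' @export
sequence_monoisotopic_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop_input("empty sequence")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!letters1 %in% names(RESIDUE_MASS))
  if (length(bad)) {
    stop_input("unknown residue letter '%s' at position %d",
               letters1[bad[1]], bad[1])
  }
  sum(RESIDUE_MASS[letters1]) + WATER_MASS
}

#' Read an m/z peak list from CSV
#'
#' Expects at least columns `mz` and `z`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `mz` and `z`.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "z") %in% names(df))) {
    stop_input("peak list must have columns 'mz' and 'z'")
  }
  tibble::as_tibble(df[, c("mz", "z")])
}
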