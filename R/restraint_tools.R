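# NOE restraint bookkeeping and metal-coordination restraint generation.

#' Distance restraint list
#'
#' @param res_i,res_j Integer residue numbers of the two protons.
#' @param atom_i,atom_j Atom names.
#' @param upper Upper bound in Angstrom.
#' @param ambiguous Logical; restraint has multiple assignment options.
#' @return Tibble of class `restraint_list`.
#' @export
distance_restraints <- function(res_i, atom_i, res_j, atom_j, upper,
                                ambiguous = FALSE) {
  tbl <- tibble::tibble(res_i = as.integer(res_i),
                        atom_i = as.character(atom_i),
                        res_j = as.integer(res_j),
                        atom_j = as.character(atom_j),
                        upper = as.numeric(upper),
                        ambiguous = rep_len(as.logical(ambiguous),
                                            length(res_i)))
  class(tbl) <- c("restraint_list", class(tbl))
  tbl
}

#' Classify NOE restraints by sequence range
#'
#' Ambiguous restraints are counted only under `ambiguous`; unambiguous
#' ones by residue separation `|i - j|`: 0 intra-residue, 1 sequential,
#' 2-4 medium-range, >= 5 long-range.  The five categories partition the
#' list.
#'
#' @param restraints A [distance_restraints()] table.
#' @return Named integer vector with elements `intra`, `sequential`,
#'   `medium`, `long`, `ambiguous` and attribute `total`.
#' @export
classify_noe <- function(restraints) {
  stopifnot(all(c("res_i", "res_j", "ambiguous") %in% names(restraints)))
  sep <- abs(restraints$res_i - restraints$res_j)
  amb <- restraints$ambiguous
  counts <- c(
    intra = sum(!amb & sep == 0L),
    sequential = sum(!amb & sep == 1L),
    medium = sum(!amb & sep >= 2L & sep <= 4L),
    long = sum(!amb & sep >= 5L),
    ambiguous = sum(amb))
  attr(counts, "total") <- nrow(restraints)
  counts
}

#' Restraint density per residue
#'
#' @param total_restraints Total number of restraints (e.g. NOE distance
#'   plus dihedral restraints).
#' @param n_residues Number of residues; by convention the construct span
#'   (last - first + 1) rather than the count of assigned residues.
#' @return List with `density` (restraints per residue) and `rounded`
#'   (nearest integer, half-to-even).
#' @export
restraint_density <- function(total_restraints, n_residues) {
  if (!is.numeric(n_residues) || n_residues <= 0) {
    stop_input("n_residues must be > 0")
  }
  density <- total_restraints / n_residues
  list(density = density, rounded = as.integer(round(density)))
}

#' Calibrate NOE peak volumes to distance upper bounds
#'
#' Uses the isolated spin-pair relation V proportional to d^-6, i.e.
#' `d = d_ref * (V_ref / V)^(1/6)`, then clamps the result to the
#' calibration window (default 2.2-6.0 Angstrom).  Non-positive volumes
#' yield a per-peak error record rather than an exception.
#'
#' @param peak_volumes Numeric vector of peak volumes.
#' @param reference Length-2 numeric `c(volume, distance)` of the
#'   calibration reference.
#' @param clamp Length-2 numeric lower/upper clamp in Angstrom.
#' @return Tibble with columns `volume`, `upper`, `valid`, `note`.
#' @export
calibrate_distances <- function(peak_volumes, reference,
                                clamp = c(2.2, 6.0)) {
  stopifnot(length(reference) == 2L, length(clamp) == 2L, clamp[1] < clamp[2])
  v_ref <- reference[1]
  d_ref <- reference[2]
  if (v_ref <= 0) stop_input("reference volume must be > 0")
  valid <- is.finite(peak_volumes) & peak_volumes > 0
  d <- rep(NA_real_, length(peak_volumes))
  d[valid] <- d_ref * (v_ref / peak_volumes[valid])^(1 / 6)
  d[valid] <- pmin(pmax(d[valid], clamp[1]), clamp[2])
  tibble::tibble(
    volume = peak_volumes,
    upper = d,
    valid = valid,
    note = ifelse(valid, "", "non-positive volume"))
}

#' Generate tetrahedral metal-coordination restraints
#'
#' Emits one bond restraint per metal-ligand edge and one angle restraint
#' per unordered ligand pair within each metal (`choose(k, 2)` for a
#' k-coordinate metal).  Defaults reproduce the canonical zinc-thiolate
#' geometry: Zn-Sgamma 2.3 Angstrom and Sgamma-Zn-Sgamma 109.5 degrees.
#'
#' @param a A [assignment()].
#' @param bond Bond-length target in Angstrom.
#' @param angle Angle target in degrees.
#' @return Tibble with columns `kind` (`"bond"`/`"angle"`), `metal`,
#'   `ligand_i`, `ligand_j` (`NA` for bonds), `target`.
#' @export
build_metal_restraints <- function(a, bond = 2.3, angle = 109.5) {
  stopifnot(inherits(a, "zn_assignment"))
  if (bond <= 0) stop_input("bond target must be > 0")
  if (angle <= 0 || angle >= 180) stop_input("angle target must be in (0, 180)")
  bonds <- tibble::tibble(
    kind = "bond", metal = a$edges$metal,
    ligand_i = a$edges$ligand, ligand_j = NA_integer_,
    target = bond)
  angles <- list()
  for (m in unique(a$edges$metal)) {
    ligs <- sort(a$edges$ligand[a$edges$metal == m])
    if (length(ligs) >= 2L) {
      pairs <- utils::combn(ligs, 2L)
      angles[[m]] <- tibble::tibble(
        kind = "angle", metal = m,
        ligand_i = pairs[1, ], ligand_j = pairs[2, ],
        target = angle)
    }
  }
  dplyr::bind_rows(bonds, dplyr::bind_rows(angles))
}

#' Read a tabular restraint file
#'
#' Tab-separated columns: `res_i`, `atom_i`, `res_j`, `atom_j`, `upper`,
#' `ambiguous`.
#'
#' @param path TSV file path.
#' @return A [distance_restraints()] table.
#' @export
read_restraint_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  distance_restraints(df$res_i, df$atom_i, df$res_j, df$atom_j, df$upper,
                      as.logical(df$ambiguous))
}

#' Read CNS/XPLOR-style "assign" distance restraints
#'
#' Parses lines of the form
#' `assign (resid 10 and name HA) (resid 12 and name HN) 4.0 1.8 2.0`
#' where the three numbers are distance, minus and plus bounds; the upper
#' bound is distance + plus.  Restraints with `or` clauses are flagged
#' ambiguous.
#'
#' @param path File path.
#' @return A [distance_restraints()] table.
#' @export
read_xplor_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[grepl("^assign", lines, ignore.case = TRUE)]
  sel <- "\\(\\s*resid\\s+(\\d+)\\s+and\\s+name\\s+(\\S+?)\\s*\\)"
  rx <- paste0("^assign\\s*", sel, "\\s*", sel,
               "\\s+([0-9.]+)\\s+([0-9.]+)\\s+([0-9.]+)")
  m <- regmatches(lines, regexec(rx, lines, ignore.case = TRUE))
  keep <- lengths(m) == 8L
  if (!any(keep)) stop_input("no parseable assign statements in %s", path)
  m <- m[keep]
  get <- function(i) vapply(m, `[[`, "", i)
  distance_restraints(
    res_i = as.integer(get(2)), atom_i = get(3),
    res_j = as.integer(get(4)), atom_j = get(5),
    upper = as.numeric(get(6)) + as.numeric(get(8)),
    ambiguous = grepl("\\bor\\b", lines[keep], ignore.case = TRUE))
}

#' Write metal-coordination restraints
#'
#' @param restraints Output of [build_metal_restraints()].
#' @param path Output file.
#' @param format `"csv"` or `"xplor"` (CNS-style assign statements; bonds
#'   only, angles are written as comments since XPLOR encodes angles via
#'   its own angle statement dialect).
#' @return `path`, invisibly.
#' @export
write_metal_restraints <- function(restraints, path,
                                   format = c("csv", "xplor")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(restraints, path, row.names = FALSE)
  } else {
    lines <- character(0)
    for (k in seq_len(nrow(restraints))) {
      r <- restraints[k, ]
      if (r$kind == "bond") {
        lines <- c(lines, sprintf(
          "assign (resid %d and name ZN) (resid %d and name SG) %.2f 0.10 0.10",
          900L + match(r$metal, unique(restraints$metal)), r$ligand_i, r$target))
      } else {
        lines <- c(lines, sprintf(
          "! angle %s: SG %d - ZN - SG %d = %.1f deg",
          r$metal, r$ligand_i, r$ligand_j, r$target))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}
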