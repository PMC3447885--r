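# Multi-model coordinate ensembles: a light container plus PDB round-trip.
# Reading goes through bio3d; writing is done in-package so synthetic
# ensembles serialize to byte-identical text for a given generator config.

#' Structure ensemble container
#'
#' Holds one atom identity table shared by all models plus an
#' `n_models x 3N` coordinate matrix (x1, y1, z1, x2, ... per row, the
#' bio3d layout).
#'
#' @param atoms Data frame with columns `eleno`, `elety` (atom name),
#'   `resid` (residue name), `chain`, `resno`, `element`.
#' @param xyz Numeric matrix of coordinates, one row per model.
#' @param source Free-text label for provenance.
#' @return A `zn_ensemble` object.
#' @export
structure_ensemble <- function(atoms, xyz, source = "") {
  atoms <- tibble::as_tibble(atoms)
  need <- c("eleno", "elety", "resid", "chain", "resno", "element")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L * nrow(atoms))
  if (!all(is.finite(xyz))) stop_input("coordinates must be finite")
  structure(list(atoms = atoms, xyz = xyz, n_models = nrow(xyz),
                 source = source),
            class = "zn_ensemble")
}

#' @export
print.zn_ensemble <- function(x, ...) {
  cat(sprintf("<zn_ensemble: %d model(s), %d atoms%s>\n", x$n_models,
              nrow(x$atoms),
              if (nzchar(x$source)) paste0(", ", x$source) else ""))
  invisible(x)
}

#' Extract one model as an atom table with coordinates
#'
#' @param ens A [structure_ensemble()].
#' @param model Model index (default 1).
#' @return Tibble: the atom table plus `x`, `y`, `z` columns.
#' @export
ensemble_model <- function(ens, model = 1L) {
  stopifnot(inherits(ens, "zn_ensemble"))
  model <- as.integer(model)
  if (model < 1L || model > ens$n_models) {
    stop_input("model %d out of range (ensemble has %d)", model, ens$n_models)
  }
  co <- matrix(ens$xyz[model, ], ncol = 3L, byrow = TRUE)
  out <- ens$atoms
  out$x <- co[, 1]
  out$y <- co[, 2]
  out$z <- co[, 3]
  out
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' @param path PDB file path.
#' @return A [structure_ensemble()].
#' @export
read_structure_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  atoms <- tibble::tibble(
    eleno = pdb$atom$eleno,
    elety = pdb$atom$elety,
    resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resno = pdb$atom$resno,
    element = toupper(trimws(ifelse(
      is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
      substr(trimws(pdb$atom$elety), 1L, 1L), pdb$atom$elesy))))
  structure_ensemble(atoms, unclass(xyz), source = basename(path))
}

pdb_atom_name4 <- function(elety, element) {
  ifelse(nchar(element) >= 2L,
         formatC(elety, width = -4L),
         formatC(paste0(" ", elety), width = -4L))
}

#' Write an ensemble as multi-model PDB text
#'
#' Metal atoms (Zn, Cd) are written as HETATM records.  Output is
#' deterministic: identical ensembles serialize to identical bytes.
#'
#' @param ens A [structure_ensemble()].
#' @param path Output file, or `NULL` to return the text.
#' @return The PDB text (invisibly when `path` is given).
#' @export
write_ensemble_pdb <- function(ens, path = NULL) {
  stopifnot(inherits(ens, "zn_ensemble"))
  at <- ens$atoms
  rec <- ifelse(at$element %in% c("ZN", "CD"), "HETATM", "ATOM  ")
  name4 <- pdb_atom_name4(at$elety, at$element)
  lines <- character(0)
  multi <- ens$n_models > 1L
  for (m in seq_len(ens$n_models)) {
    co <- matrix(ens$xyz[m, ], ncol = 3L, byrow = TRUE)
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, sprintf(
      "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, at$eleno, name4, at$resid, at$chain, at$resno,
      co[, 1], co[, 2], co[, 3], 1.00, 0.00,
      formatC(at$element, width = 2L)))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(text)
}
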