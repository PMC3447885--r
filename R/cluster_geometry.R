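# Structure-side cluster analysis: metal-site detection, topology
# fingerprinting, coordination geometry, superposition and ensemble RMSD.

TETRAHEDRAL_ANGLE <- 109.5  # conventional reporting target, degrees

#' Detect metal-thiolate sites in a coordinate model
#'
#' Metals are Zn/Cd atoms; candidate donors are cysteine Sgamma atoms and,
#' optionally, histidine Ndelta1/Nepsilon2.  A bond is assigned when the
#' metal-donor distance is within the element-specific cutoff (defaults
#' 2.9 Angstrom for S, 2.5 for N, wider than the 2.3 Angstrom restraint
#' target to tolerate refinement scatter).  Metals sharing a ligand are
#' merged into a single polynuclear site.
#'
#' @param model Atom table with coordinates, as from [ensemble_model()].
#' @param donor_cutoffs Named numeric, Angstrom per donor element.
#' @param include_his Accept His Ndelta1/Nepsilon2 donors (default FALSE:
#'   non-conserved histidines are not treated as cluster ligands).
#' @return List of `zn_site` objects (possibly empty), each with `metals`,
#'   `ligands` and `bonds` tables.
#' @export
detect_metal_sites <- function(model, donor_cutoffs = c(S = 2.9, N = 2.5),
                               include_his = FALSE) {
  stopifnot(all(c("elety", "resid", "resno", "element", "x", "y", "z") %in%
                  names(model)))
  el <- toupper(model$element)
  is_metal <- el %in% c("ZN", "CD")
  is_donor <- model$resid == "CYS" & model$elety == "SG"
  if (include_his) {
    is_donor <- is_donor |
      (model$resid == "HIS" & model$elety %in% c("ND1", "NE2"))
  }
  metals <- model[is_metal, , drop = FALSE]
  donors <- model[is_donor, , drop = FALSE]
  if (nrow(metals) == 0L) return(list())
  donor_el <- ifelse(donors$elety == "SG", "S", "N")

  bonds <- list()
  for (i in seq_len(nrow(metals))) {
    for (j in seq_len(nrow(donors))) {
      cutoff <- donor_cutoffs[[donor_el[j]]]
      d <- sqrt((metals$x[i] - donors$x[j])^2 +
                (metals$y[i] - donors$y[j])^2 +
                (metals$z[i] - donors$z[j])^2)
      if (d <= cutoff) {
        bonds[[length(bonds) + 1L]] <- data.frame(
          metal_idx = i, ligand_idx = j, length = d)
      }
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else {
    data.frame(metal_idx = integer(), ligand_idx = integer(),
               length = numeric())
  }

  # merge metals connected through shared ligands (union-find)
  parent <- seq_len(nrow(metals))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in unique(bonds$ligand_idx)) {
    ms <- bonds$metal_idx[bonds$ligand_idx == j]
    for (k in seq_along(ms)[-1]) {
      a <- find(ms[1]); b <- find(ms[k])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(nrow(metals)), find, integer(1))
  sites <- list()
  for (r in unique(roots)) {
    midx <- which(roots == r)
    b <- bonds[bonds$metal_idx %in% midx, , drop = FALSE]
    lidx <- sort(unique(b$ligand_idx))
    mt <- metals[midx, , drop = FALSE]
    mt$label <- paste0(mt$element, mt$resno)
    lg <- donors[lidx, , drop = FALSE]
    sites[[length(sites) + 1L]] <- structure(list(
      metals = tibble::as_tibble(mt),
      ligands = tibble::as_tibble(lg),
      bonds = tibble::tibble(
        metal = mt$label[match(b$metal_idx, midx)],
        ligand_resno = donors$resno[b$ligand_idx],
        donor = donors$elety[b$ligand_idx],
        length = b$length)),
      class = "zn_site")
  }
  sites
}

#' @export
print.zn_site <- function(x, ...) {
  cat(sprintf("<zn_site: %d metal(s), %d ligand atom(s), %d bond(s)>\n",
              nrow(x$metals), nrow(x$ligands), nrow(x$bonds)))
  invisible(x)
}

#' Topology fingerprint of a metal-thiolate cluster
#'
#' Ligands are sorted by residue number and relabeled 1..n; each metal is
#' described by its sorted set of ligand indices and metals are ordered by
#' their ligand-index sets (lexicographically), making the fingerprint
#' invariant under rigid motion and uniform residue renumbering.  Bridging
#' indices are ligands bound to two or more metals.
#'
#' @param x A `zn_site` (from [detect_metal_sites()]) or a
#'   [assignment()].
#' @param ... Unused.
#' @return A `cluster_topology`: list with `ligand_index` (named map
#'   residue -> index), `metal_ligands` (list of sorted integer vectors)
#'   and `bridging` (sorted integer vector).
#' @export
cluster_topology <- function(x, ...) UseMethod("cluster_topology")

topology_from_edges <- function(metal, ligand) {
  ligs <- sort(unique(ligand))
  idx <- stats::setNames(seq_along(ligs), ligs)
  ml <- lapply(split(ligand, metal), function(l) unname(sort(idx[as.character(l)])))
  ord <- order(vapply(ml, function(v) paste(formatC(v, width = 4, flag = "0"),
                                            collapse = ","), ""))
  ml <- ml[ord]
  deg <- table(ligand)
  bridging <- sort(unname(idx[names(deg)[deg >= 2L]]))
  structure(list(ligand_index = idx, metal_ligands = unname(ml),
                 bridging = as.integer(bridging)),
            class = "cluster_topology")
}

#' @rdname cluster_topology
#' @export
cluster_topology.zn_site <- function(x, ...) {
  stopifnot(nrow(x$metals) >= 1L)
  topology_from_edges(x$bonds$metal, x$bonds$ligand_resno)
}

#' @rdname cluster_topology
#' @export
cluster_topology.zn_assignment <- function(x, ...) {
  topology_from_edges(x$edges$metal, x$edges$ligand)
}

#' @export
format.cluster_topology <- function(x, ...) {
  jsonlite::toJSON(list(metal_ligands = x$metal_ligands,
                        bridging = x$bridging),
                   auto_unbox = FALSE)
}

#' @export
print.cluster_topology <- function(x, ...) {
  cat("cluster topology fingerprint\n")
  for (k in seq_along(x$metal_ligands)) {
    cat(sprintf("  metal %d: {%s}\n", k,
                paste(x$metal_ligands[[k]], collapse = ",")))
  }
  cat(sprintf("  bridging: {%s}\n", paste(x$bridging, collapse = ",")))
  invisible(x)
}

#' Coordination geometry report for a metal site
#'
#' Per metal: bond lengths, all inter-ligand angles at the metal and the
#' tetrahedrality deviation (root-mean-square deviation of those angles
#' from the 109.5 degree tetrahedral target).  Metals with fewer than two
#' ligands report no angles.
#'
#' @param site A `zn_site`.
#' @param reference_angle Target angle for the deviation, degrees.
#' @return List with `per_metal` (list of `bonds`, `angles`,
#'   `tetrahedrality`) and `summary` (`mean_bond`, `mean_angle`,
#'   `rms_angle_deviation`).
#' @export
coordination_report <- function(site, reference_angle = TETRAHEDRAL_ANGLE) {
  stopifnot(inherits(site, "zn_site"))
  per_metal <- list()
  all_bonds <- numeric(0)
  all_angles <- numeric(0)
  for (k in seq_len(nrow(site$metals))) {
    lab <- site$metals$label[k]
    mpos <- c(site$metals$x[k], site$metals$y[k], site$metals$z[k])
    b <- site$bonds[site$bonds$metal == lab, , drop = FALSE]
    li <- match(paste(b$ligand_resno, b$donor),
                paste(site$ligands$resno, site$ligands$elety))
    lpos <- cbind(site$ligands$x[li], site$ligands$y[li], site$ligands$z[li])
    angles <- tibble::tibble(ligand_i = integer(), ligand_j = integer(),
                             angle = numeric())
    if (nrow(b) >= 2L) {
      pr <- utils::combn(seq_len(nrow(b)), 2L)
      angles <- tibble::tibble(
        ligand_i = b$ligand_resno[pr[1, ]],
        ligand_j = b$ligand_resno[pr[2, ]],
        angle = vapply(seq_len(ncol(pr)), function(q) {
          angle_deg(lpos[pr[1, q], ], mpos, lpos[pr[2, q], ])
        }, numeric(1)))
    }
    tet <- if (nrow(angles)) {
      sqrt(mean((angles$angle - reference_angle)^2))
    } else NA_real_
    per_metal[[lab]] <- list(
      bonds = tibble::tibble(ligand = b$ligand_resno, donor = b$donor,
                             length = b$length),
      angles = angles, tetrahedrality = tet)
    all_bonds <- c(all_bonds, b$length)
    all_angles <- c(all_angles, angles$angle)
  }
  list(per_metal = per_metal,
       summary = list(
         mean_bond = mean(all_bonds),
         mean_angle = if (length(all_angles)) mean(all_angles) else NA_real_,
         rms_angle_deviation = if (length(all_angles)) {
           sqrt(mean((all_angles - reference_angle)^2))
         } else NA_real_))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (reflections excluded) and translation that
#' minimize the RMSD between paired coordinates, mapping `p` onto `q`.
#'
#' @param p,q Numeric matrices, n x 3, paired row-wise (n >= 3,
#'   non-collinear).
#' @return List with `rmsd`, `rotation` (3 x 3, applied as
#'   `coords %*% rotation`), `translation`, and `fitted` (p after
#'   transformation).
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 3L, ncol(q) == 3L, nrow(p) == nrow(q))
  if (nrow(p) < 3L) stop_input("need at least 3 paired atoms")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  sv_p <- svd(pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1)) {
    stop_input("degenerate pairing: points are (near-)collinear")
  }
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(pc %*% rot, 2L, cq, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  list(rmsd = rmsd, rotation = rot,
       translation = cq - as.numeric(cp %*% rot), fitted = fitted)
}

site_coords <- function(site) {
  # metals in topology order (lexicographic by sorted ligand residues),
  # then ligand atoms by residue number
  ligsets <- lapply(site$metals$label, function(lab) {
    sort(site$bonds$ligand_resno[site$bonds$metal == lab])
  })
  keys <- vapply(ligsets, function(l) {
    paste(formatC(l, width = 6, flag = "0"), collapse = ",")
  }, "")
  metal_order <- order(keys)
  m <- as.matrix(site$metals[metal_order, c("x", "y", "z")])
  lg <- site$ligands[order(site$ligands$resno, site$ligands$elety), ]
  rbind(m, as.matrix(lg[, c("x", "y", "z")]))
}

#' Superpose two metal sites
#'
#' With no explicit pairing, atoms are matched in canonical order: metals
#' ordered by their smallest bonded ligand residue, then donor atoms by
#' residue number.  Both sites must then have equal atom counts.
#'
#' @param a,b `zn_site` objects.
#' @param pairing Optional two-column integer matrix of row indices into
#'   the canonical coordinate stacks of `a` and `b`.
#' @return See [kabsch_superpose()].
#' @export
superpose_clusters <- function(a, b, pairing = NULL) {
  stopifnot(inherits(a, "zn_site"), inherits(b, "zn_site"))
  pa <- site_coords(a); pb <- site_coords(b)
  if (is.null(pairing)) {
    if (nrow(pa) != nrow(pb)) {
      stop_input("sites have different atom counts (%d vs %d); supply a pairing",
                 nrow(pa), nrow(pb))
    }
    pairing <- cbind(seq_len(nrow(pa)), seq_len(nrow(pb)))
  }
  kabsch_superpose(pa[pairing[, 1], , drop = FALSE],
                   pb[pairing[, 2], , drop = FALSE])
}

select_atoms <- function(atoms, residue_ranges = NULL,
                         atom_set = c("backbone", "heavy"),
                         include_O = FALSE) {
  atom_set <- match.arg(atom_set)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(residue_ranges)) {
    inrange <- rep(FALSE, nrow(atoms))
    for (rg in residue_ranges) {
      inrange <- inrange | (atoms$resno >= rg[1] & atoms$resno <= rg[2])
    }
    keep <- keep & inrange
  }
  if (atom_set == "backbone") {
    bb <- c("N", "CA", "C", if (include_O) "O")
    keep <- keep & atoms$elety %in% bb
  } else {
    keep <- keep & toupper(atoms$element) != "H"
  }
  which(keep)
}

#' RMSD of ensemble models to their mean structure
#'
#' Iteratively superposes every model onto the evolving mean coordinates
#' (Kabsch, proper rotations) until the mean shifts by less than `tol`,
#' then reports each model's RMSD to the converged mean over the selected
#' atoms.
#'
#' @param ens A [structure_ensemble()] with at least 2 models.
#' @param residue_ranges List of `c(first, last)` residue ranges, or `NULL`
#'   for all residues.
#' @param atom_set `"backbone"` (N, CA, C) or `"heavy"` (all non-H).
#' @param include_O Include backbone O in the backbone set.
#' @param tol Convergence threshold on the mean shift, Angstrom.
#' @param max_iter Iteration cap.
#' @return List with `mean`, `sd`, `per_model` (numeric vector),
#'   `n_atoms`.
#' @export
ensemble_rmsd <- function(ens, residue_ranges = NULL,
                          atom_set = c("backbone", "heavy"),
                          include_O = FALSE, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(ens, "zn_ensemble"))
  if (ens$n_models < 2L) stop_input("need at least 2 models")
  sel <- select_atoms(ens$atoms, residue_ranges, atom_set, include_O)
  if (length(sel) == 0L) stop_input("atom selection is empty")
  cols <- as.integer(rbind(3L * sel - 2L, 3L * sel - 1L, 3L * sel))
  coords <- lapply(seq_len(ens$n_models), function(m) {
    matrix(ens$xyz[m, cols], ncol = 3L, byrow = TRUE)
  })
  ref <- coords[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(coords, function(x) kabsch_superpose(x, ref)$fitted)
    newref <- Reduce(`+`, fitted) / length(fitted)
    shift <- sqrt(mean(rowSums((newref - ref)^2)))
    ref <- newref
    if (shift < tol) break
  }
  per_model <- vapply(coords, function(x) kabsch_superpose(x, ref)$rmsd,
                      numeric(1))
  list(mean = mean(per_model), sd = stats::sd(per_model),
       per_model = per_model, n_atoms = length(sel))
}

find_atom <- function(model, residue, atom) {
  i <- which(model$resno == residue & model$elety == atom)
  if (length(i) == 0L) {
    stop_input("atom '%s' of residue %d not found", atom, residue)
  }
  i[1]
}

#' Hydrogen-bond check between a donor and an acceptor atom
#'
#' True when the donor heavy atom is within `dist_cutoff` of the acceptor.
#' When a hydrogen attached to the donor (an H-element atom of the same
#' residue within 1.3 Angstrom) is present, the D-H...A angle must also
#' exceed `angle_cutoff`; without explicit hydrogens only the distance
#' criterion applies.
#'
#' @param model Atom table with coordinates.
#' @param donor,acceptor Lists `list(residue =, atom =)` naming the heavy
#'   atoms.
#' @param dist_cutoff Donor-acceptor distance cutoff, Angstrom.
#' @param angle_cutoff Minimum D-H...A angle, degrees.
#' @return List with `hbond` (logical), `distance`, `angle` (`NA` when no
#'   hydrogen is present) and `hydrogen` (atom name or `NA`).
#' @export
hbond_check <- function(model, donor, acceptor, dist_cutoff = 3.5,
                        angle_cutoff = 120) {
  di <- find_atom(model, donor$residue, donor$atom)
  ai <- find_atom(model, acceptor$residue, acceptor$atom)
  dpos <- c(model$x[di], model$y[di], model$z[di])
  apos <- c(model$x[ai], model$y[ai], model$z[ai])
  dist <- vnorm(dpos - apos)
  # explicit hydrogen on the donor?
  hs <- which(model$resno == donor$residue & toupper(model$element) == "H")
  hpos <- NULL; hname <- NA_character_
  for (h in hs) {
    pos <- c(model$x[h], model$y[h], model$z[h])
    if (vnorm(pos - dpos) <= 1.3) { hpos <- pos; hname <- model$elety[h]; break }
  }
  ang <- if (!is.null(hpos)) angle_deg(dpos, hpos, apos) else NA_real_
  ok <- dist <= dist_cutoff && (is.null(hpos) || ang > angle_cutoff)
  list(hbond = ok, distance = dist, angle = ang, hydrogen = hname)
}
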