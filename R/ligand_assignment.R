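# Completion of partial metal-to-ligand connectivity maps.
#
# 1H-113Cd correlation spectra give direct metal-ligand edges, but weak
# 3J(Hbeta-Cd) couplings can leave some edges unobserved.  Given the pool of
# candidate ligand residues, per-metal coordination numbers, the number of
# bridging ligands and (optionally) pairwise metal-metal coupling evidence
# (2J(Cd-Cd) triplet splitting, implying a shared bridging ligand), the
# admissible completions form a small discrete space that is enumerated
# exhaustively.  Candidate completions are then ranked by an externally
# supplied violation score, e.g. NOE violations from refinement runs.

#' Metal spin descriptor
#'
#' One NMR-observed metal centre (e.g. a 113Cd resonance) with its chemical
#' shift and assumed coordination number.
#'
#' @param label Metal label, e.g. `"Cd-A"`.
#' @param chemical_shift 113Cd chemical shift in ppm (optional).
#' @param coordination_number Number of ligands bound (default 4,
#'   tetrahedral).
#' @return A `metal_spin` object.
#' @export
metal_spin <- function(label, chemical_shift = NA_real_,
                       coordination_number = 4L) {
  coordination_number <- as.integer(coordination_number)
  if (is.na(coordination_number) || coordination_number < 2L) {
    stop_input("coordination_number must be >= 2")
  }
  structure(list(label = as.character(label),
                 chemical_shift = chemical_shift,
                 coordination_number = coordination_number),
            class = "metal_spin")
}

#' Connectivity dataset: the solver's input
#'
#' @param metals List of [metal_spin()] objects (or a character vector of
#'   labels, each taken to be 4-coordinate).
#' @param ligands Integer residue positions of the candidate ligand pool
#'   (1-based, full-length numbering).
#' @param confirmed_edges Data frame with columns `metal`, `ligand` of edges
#'   established experimentally, or `NULL`.
#' @param coupling_pairs Data frame with columns `metal_a`, `metal_b` and
#'   optionally `evidence`; each coupled pair is constrained to share
#'   exactly one ligand.
#' @param max_ligand_degree Maximum number of metals a single ligand may
#'   bridge (default 2).
#' @param n_bridging Number of ligands with degree 2, or `"auto"` to derive
#'   it as (total coordination) - (number of ligands).
#' @return A `connectivity_dataset` object.
#' @export
connectivity_dataset <- function(metals, ligands, confirmed_edges = NULL,
                                 coupling_pairs = NULL,
                                 max_ligand_degree = 2L,
                                 n_bridging = "auto") {
  if (is.character(metals)) metals <- lapply(metals, metal_spin)
  stopifnot(length(metals) >= 1L,
            all(vapply(metals, inherits, TRUE, "metal_spin")))
  labels <- vapply(metals, `[[`, "", "label")
  if (anyDuplicated(labels)) stop_input("metal labels must be unique")
  ligands <- sort(unique(as.integer(ligands)))
  if (length(ligands) == 0L) stop_input("ligand pool is empty")

  if (is.null(confirmed_edges)) {
    confirmed_edges <- data.frame(metal = character(), ligand = integer())
  }
  confirmed_edges <- as.data.frame(confirmed_edges)
  stopifnot(all(c("metal", "ligand") %in% names(confirmed_edges)))
  confirmed_edges$metal <- as.character(confirmed_edges$metal)
  confirmed_edges$ligand <- as.integer(confirmed_edges$ligand)
  if (anyDuplicated(confirmed_edges[c("metal", "ligand")])) {
    stop_input("duplicate confirmed edges")
  }
  if (!all(confirmed_edges$metal %in% labels)) {
    stop_input("confirmed edge references unknown metal '%s'",
               setdiff(confirmed_edges$metal, labels)[1])
  }
  if (!all(confirmed_edges$ligand %in% ligands)) {
    stop_input("confirmed edge references ligand %d outside the pool",
               setdiff(confirmed_edges$ligand, ligands)[1])
  }

  coord <- stats::setNames(
    vapply(metals, `[[`, 0L, "coordination_number"), labels)
  conf_per_metal <- table(factor(confirmed_edges$metal, levels = labels))
  over <- which(as.integer(conf_per_metal) > coord)
  if (length(over)) {
    stop_input("infeasible: metal '%s' has %d confirmed edges but coordination number %d",
               labels[over[1]], conf_per_metal[over[1]], coord[over[1]])
  }
  max_ligand_degree <- as.integer(max_ligand_degree)
  deg <- table(factor(confirmed_edges$ligand, levels = ligands))
  if (any(as.integer(deg) > max_ligand_degree)) {
    bad <- ligands[which(as.integer(deg) > max_ligand_degree)[1]]
    stop_input("infeasible: ligand %d is already over-saturated (degree > %d)",
               bad, max_ligand_degree)
  }

  if (!is.null(coupling_pairs)) {
    coupling_pairs <- as.data.frame(coupling_pairs)
    stopifnot(all(c("metal_a", "metal_b") %in% names(coupling_pairs)))
    if (!"evidence" %in% names(coupling_pairs)) coupling_pairs$evidence <- NA_character_
    if (!all(c(coupling_pairs$metal_a, coupling_pairs$metal_b) %in% labels)) {
      stop_input("coupling pair references unknown metal")
    }
  }

  if (identical(n_bridging, "auto")) {
    n_bridging <- sum(coord) - length(ligands)
    if (n_bridging < 0L) {
      stop_input("infeasible: more ligands (%d) than coordination slots (%d)",
                 length(ligands), sum(coord))
    }
  } else if (!is.null(n_bridging)) {
    n_bridging <- as.integer(n_bridging)
  }

  structure(list(metals = metals, labels = labels, coordination = coord,
                 ligands = ligands, confirmed_edges = confirmed_edges,
                 coupling_pairs = coupling_pairs,
                 max_ligand_degree = max_ligand_degree,
                 n_bridging = n_bridging),
            class = "connectivity_dataset")
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cat(sprintf("<connectivity_dataset: %d metals, %d ligands, %d confirmed edges, %s coupling pairs>\n",
              length(x$metals), length(x$ligands), nrow(x$confirmed_edges),
              if (is.null(x$coupling_pairs)) "no" else nrow(x$coupling_pairs)))
  invisible(x)
}

#' Metal-ligand assignment
#'
#' A complete set of metal-ligand edges.  Bridging ligands are those bound
#' to two metals, terminal ligands to one.
#'
#' @param edges Data frame with columns `metal`, `ligand`.
#' @param max_ligand_degree Maximum allowed ligand degree (default 2).
#' @return A `zn_assignment` object with components `edges`, `bridging` and
#'   `terminal`.
#' @export
assignment <- function(edges, max_ligand_degree = 2L) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("metal", "ligand") %in% names(edges)))
  edges$metal <- as.character(edges$metal)
  edges$ligand <- as.integer(edges$ligand)
  if (anyDuplicated(edges[c("metal", "ligand")])) stop_input("duplicate edges")
  deg <- table(edges$ligand)
  if (any(deg > max_ligand_degree)) {
    stop_input("ligand %s exceeds maximum degree %d",
               names(deg)[which(deg > max_ligand_degree)[1]], max_ligand_degree)
  }
  ligs <- sort(unique(edges$ligand))
  bridging <- sort(as.integer(names(deg)[deg == 2L]))
  structure(list(edges = tibble::as_tibble(edges[order(edges$metal, edges$ligand), ]),
                 ligands = ligs,
                 bridging = bridging,
                 terminal = setdiff(ligs, bridging)),
            class = "zn_assignment")
}

#' @export
print.zn_assignment <- function(x, ...) {
  for (m in unique(x$edges$metal)) {
    cat(sprintf("  %s: %s\n", m,
                paste(sort(x$edges$ligand[x$edges$metal == m]), collapse = ", ")))
  }
  cat(sprintf("  bridging: %s\n", paste(x$bridging, collapse = ", ")))
  invisible(x)
}

#' The MSL2 CXC domain Zn3Cys9 reference assignment
#'
#' The fully determined connectivity of the trinuclear zinc-cysteine
#' cluster: Zn-A bound to Cys525/527/539/544, Zn-B to Cys525/546/553/556
#' and Zn-C to Cys539/553/558/561, with Cys525, Cys539 and Cys553 bridging.
#'
#' @return A `zn_assignment`.
#' @export
cxc_reference_assignment <- function() {
  assignment(data.frame(
    metal = rep(c("A", "B", "C"), each = 4L),
    ligand = c(525L, 527L, 539L, 544L,
               525L, 546L, 553L, 556L,
               539L, 553L, 558L, 561L)))
}

#' Enumerate all admissible completions of a connectivity dataset
#'
#' Exhaustively searches the completions that satisfy: each metal carries
#' exactly its coordination number of ligands; each ligand binds between 1
#' and `max_ligand_degree` metals; the total number of degree-2 (bridging)
#' ligands equals `n_bridging`; and every coupled metal pair shares exactly
#' one ligand.  Output order is deterministic (lexicographic in the added
#' edges, metals in input order).
#'
#' @param data A [connectivity_dataset()].
#' @return List of [assignment()] objects.
#' @export
enumerate_assignments <- function(data) {
  stopifnot(inherits(data, "connectivity_dataset"))
  labels <- data$labels
  ligands <- data$ligands
  coord <- data$coordination
  maxdeg <- data$max_ligand_degree

  conf_by_metal <- lapply(labels, function(m) {
    sort(data$confirmed_edges$ligand[data$confirmed_edges$metal == m])
  })
  names(conf_by_metal) <- labels
  deg0 <- stats::setNames(integer(length(ligands)), ligands)
  for (l in data$confirmed_edges$ligand) {
    deg0[as.character(l)] <- deg0[as.character(l)] + 1L
  }

  results <- list()
  metal_ligs <- conf_by_metal

  accept <- function(deg) {
    if (any(deg < 1L)) return(FALSE)
    if (!is.null(data$n_bridging) && sum(deg >= 2L) != data$n_bridging) return(FALSE)
    if (!is.null(data$coupling_pairs) && nrow(data$coupling_pairs)) {
      for (k in seq_len(nrow(data$coupling_pairs))) {
        shared <- intersect(metal_ligs[[data$coupling_pairs$metal_a[k]]],
                            metal_ligs[[data$coupling_pairs$metal_b[k]]])
        if (length(shared) != 1L) return(FALSE)
      }
    }
    TRUE
  }

  recurse <- function(i, deg) {
    if (i > length(labels)) {
      if (accept(deg)) {
        edges <- data.frame(
          metal = rep(labels, lengths(metal_ligs)),
          ligand = unlist(metal_ligs, use.names = FALSE))
        results[[length(results) + 1L]] <<- assignment(edges, maxdeg)
      }
      return(invisible(NULL))
    }
    m <- labels[i]
    need <- coord[[m]] - length(conf_by_metal[[m]])
    if (need == 0L) {
      metal_ligs[[m]] <<- conf_by_metal[[m]]
      recurse(i + 1L, deg)
      return(invisible(NULL))
    }
    cands <- ligands[deg[as.character(ligands)] < maxdeg]
    cands <- setdiff(cands, conf_by_metal[[m]])
    if (length(cands) < need) return(invisible(NULL))
    combos <- utils::combn(cands, need, simplify = FALSE)
    for (cm in combos) {
      metal_ligs[[m]] <<- sort(c(conf_by_metal[[m]], cm))
      d <- deg
      d[as.character(cm)] <- d[as.character(cm)] + 1L
      recurse(i + 1L, d)
    }
    invisible(NULL)
  }
  recurse(1L, deg0)
  results
}

#' Partition a cluster's ligands into terminal and bridging sets
#'
#' @param a A [assignment()].
#' @return List with integer vectors `terminal` (degree-1 ligands) and
#'   `bridging` (degree-2 ligands).
#' @export
classify_ligands <- function(a) {
  stopifnot(inherits(a, "zn_assignment"))
  list(terminal = a$terminal, bridging = a$bridging)
}

#' Rank candidate assignments by violation count
#'
#' Orders candidates by an externally supplied violation score (e.g. NOE
#' violations observed when each candidate's coordination restraints are
#' imposed during structure calculation).  Ties preserve input order.  A
#' candidate is flagged `"selected"` only when it is the unique
#' zero-violation candidate; multiple zero-violation candidates are all
#' flagged `"ambiguous"`.
#'
#' @param candidates List of [assignment()] objects.
#' @param scores Numeric vector of violation counts, parallel to
#'   `candidates`.
#' @return List with `candidates` (reordered), `ranking` (tibble with
#'   `input_index`, `violations`, `status`) and `selected` (the selected
#'   assignment, or `NULL`).
#' @export
rank_by_violations <- function(candidates, scores) {
  stopifnot(is.list(candidates))
  if (length(scores) != length(candidates)) {
    stop_input("need one score per candidate (%d candidates, %d scores)",
               length(candidates), length(scores))
  }
  missing_score <- which(is.na(scores))
  if (length(missing_score)) {
    stop_input("missing violation score for candidate %d", missing_score[1])
  }
  ord <- order(scores)  # stable: ties keep input order
  zero <- which(scores == 0)
  status <- rep("", length(candidates))
  if (length(zero) == 1L) status[zero] <- "selected"
  if (length(zero) > 1L) status[zero] <- "ambiguous"
  ranking <- tibble::tibble(
    input_index = ord,
    violations = scores[ord],
    status = status[ord])
  list(candidates = candidates[ord],
       ranking = ranking,
       selected = if (length(zero) == 1L) candidates[[zero]] else NULL)
}

#' Synthetic violation scorer against a reference coordinate set
#'
#' Builds a scoring function that counts, for a candidate assignment, the
#' metal-ligand bonds whose distance in a reference structure deviates from
#' the ideal bond length by more than `threshold`.  This mimics ranking by
#' refinement violations without running a refinement engine: only the true
#' connectivity scores zero against coordinates built from it.
#'
#' @param metal_xyz Numeric matrix (one row per metal, 3 columns) with
#'   rownames equal to metal labels.
#' @param ligand_xyz Numeric matrix (one row per ligand donor atom) with
#'   rownames equal to ligand residue positions.
#' @param bond Ideal metal-donor bond length in Angstrom.
#' @param threshold Violation threshold in Angstrom.
#' @return Function mapping a [assignment()] to an integer violation count.
#' @export
distance_violation_scorer <- function(metal_xyz, ligand_xyz, bond = 2.3,
                                      threshold = 0.5) {
  stopifnot(is.matrix(metal_xyz), ncol(metal_xyz) == 3L,
            is.matrix(ligand_xyz), ncol(ligand_xyz) == 3L)
  function(a) {
    stopifnot(inherits(a, "zn_assignment"))
    d <- vapply(seq_len(nrow(a$edges)), function(k) {
      m <- a$edges$metal[k]
      l <- as.character(a$edges$ligand[k])
      if (!m %in% rownames(metal_xyz)) stop_input("unknown metal '%s' in scorer", m)
      if (!l %in% rownames(ligand_xyz)) stop_input("unknown ligand %s in scorer", l)
      vnorm(metal_xyz[m, ] - ligand_xyz[l, ])
    }, numeric(1))
    sum(abs(d - bond) > threshold)
  }
}

#' Read a connectivity dataset from CSV tables
#'
#' The edge table must have columns `metal`, `ligand_position`, `status`;
#' rows with status `"confirmed"` become confirmed edges, any other status
#' (e.g. `"pool"`, with `metal` possibly empty) only declares pool
#' membership.  The optional coupling table has columns `metal_a`,
#' `metal_b` and optionally `evidence`.
#'
#' @param edges_path Path to the edge CSV.
#' @param coupling_path Optional path to the coupling CSV.
#' @param ... Passed to [connectivity_dataset()].
#' @return A [connectivity_dataset()].
#' @export
read_connectivity_csv <- function(edges_path, coupling_path = NULL, ...) {
  df <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  stopifnot(all(c("metal", "ligand_position", "status") %in% names(df)))
  confirmed <- df[df$status == "confirmed", , drop = FALSE]
  metals <- unique(df$metal[!is.na(df$metal) & nzchar(df$metal)])
  coupling <- if (!is.null(coupling_path)) {
    utils::read.csv(coupling_path, stringsAsFactors = FALSE)
  } else NULL
  connectivity_dataset(
    metals = metals,
    ligands = unique(df$ligand_position),
    confirmed_edges = data.frame(metal = confirmed$metal,
                                 ligand = confirmed$ligand_position),
    coupling_pairs = coupling, ...)
}
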