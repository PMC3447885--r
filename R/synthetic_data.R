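# Synthetic-data generators with known ground truth.
#
# Every pipeline stage can be exercised offline: idealized/noised cluster
# coordinate ensembles, partial connectivity datasets, H/D-exchange and
# heteronuclear-NOE intensity tables, and motif-bearing sequences.  All
# generators are deterministic for a given seed (one RNG stream per
# artifact, Mersenne-Twister), so identical configurations produce
# byte-identical outputs.

TETRAHEDRAL_EXACT <- acos(-1 / 3) * 180 / pi  # 109.4712..., the realizable
# all-equal tetrahedral angle; six pairwise angles of exactly 109.5 degrees
# cannot coexist in 3D (the Gram matrix loses positive semi-definiteness)

# unit vector perpendicular to v, chosen deterministically
perp_unit <- function(v) {
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(pracma_cross(ref, v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# complete a metal's ligand directions to a regular tetrahedron:
# `fixed` is a matrix (0..2 rows) of unit vectors already committed
tetrahedral_completion <- function(fixed, n_extra) {
  ct <- -1 / 3
  st <- sqrt(1 - ct^2)
  if (nrow(fixed) == 0L) {
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    return(dirs[seq_len(n_extra), , drop = FALSE])
  }
  if (nrow(fixed) == 1L) {
    u1 <- fixed[1, ]
    e2 <- perp_unit(u1)
    e3 <- pracma_cross(u1, e2)
    phis <- c(0, 2 * pi / 3, 4 * pi / 3)
    dirs <- t(vapply(phis, function(phi) {
      ct * u1 + st * (cos(phi) * e2 + sin(phi) * e3)
    }, numeric(3)))
    return(dirs[seq_len(n_extra), , drop = FALSE])
  }
  if (nrow(fixed) == 2L) {
    u1 <- fixed[1, ]; u2 <- fixed[2, ]
    t_ <- u1 + u2
    nhat <- unit(pracma_cross(u1, u2))
    w <- sqrt(max(0, 1 - sum(t_^2) / 4))
    dirs <- rbind(-t_ / 2 + w * nhat, -t_ / 2 - w * nhat)
    return(dirs[seq_len(n_extra), , drop = FALSE])
  }
  stop_input("cannot complete a tetrahedron from %d fixed directions",
             nrow(fixed))
}

# Ideal coordinates satisfying bond length and tetrahedral angles exactly
# for the supported topology families: an isolated metal, a two-metal
# single-bridge pair, and the trinuclear triangle with three mutual
# bridges (the Zn3Cys9 arrangement).  Returns list(metal_xyz, ligand_xyz).
ideal_cluster_geometry <- function(a, bond = 2.3) {
  deg <- table(a$edges$ligand)
  if (any(deg > 2L)) {
    stop_input("infeasible template: ligand %s has degree > 2",
               names(deg)[which(deg > 2L)[1]])
  }
  metals <- sort(unique(a$edges$metal))
  ligs_of <- lapply(stats::setNames(metals, metals), function(m) {
    sort(a$edges$ligand[a$edges$metal == m])
  })
  # metal graph through shared (bridging) ligands
  shared <- function(m1, m2) intersect(ligs_of[[m1]], ligs_of[[m2]])
  adj <- matrix(FALSE, length(metals), length(metals),
                dimnames = list(metals, metals))
  for (i in seq_along(metals)) for (j in seq_along(metals)) {
    if (i < j) {
      s <- shared(metals[i], metals[j])
      if (length(s) > 1L) {
        stop_input("unsupported template: metals %s and %s share %d ligands",
                   metals[i], metals[j], length(s))
      }
      adj[i, j] <- adj[j, i] <- length(s) == 1L
    }
  }
  # connected components
  comp <- rep(0L, length(metals))
  cid <- 0L
  for (i in seq_along(metals)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cid
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }

  alpha <- (TETRAHEDRAL_EXACT - 60) / 2 * pi / 180
  metal_xyz <- matrix(NA_real_, length(metals), 3L,
                      dimnames = list(metals, NULL))
  ligand_xyz <- matrix(NA_real_, length(deg), 3L,
                       dimnames = list(sort(unique(a$edges$ligand)), NULL))
  offset <- 0
  for (ci in seq_len(cid)) {
    idx <- which(comp == ci)
    nb <- sum(adj[idx, idx]) / 2
    shift <- c(offset, 0, 0)
    if (length(idx) == 1L) {
      metal_xyz[idx, ] <- shift
    } else if (length(idx) == 2L && nb == 1) {
      dd <- 3.9
      h <- sqrt(bond^2 - (dd / 2)^2)
      metal_xyz[idx[1], ] <- shift
      metal_xyz[idx[2], ] <- shift + c(dd, 0, 0)
      br <- shared(metals[idx[1]], metals[idx[2]])
      ligand_xyz[as.character(br), ] <- shift + c(dd / 2, h, 0)
    } else if (length(idx) == 3L && nb == 3) {
      s_len <- 2 * bond * cos(alpha)
      v1 <- c(0, 0, 0)
      v2 <- c(s_len, 0, 0)
      v3 <- c(s_len / 2, s_len * sqrt(3) / 2, 0)
      verts <- rbind(v1, v2, v3)
      centroid <- colMeans(verts)
      h <- bond * sin(alpha)
      for (k in seq_len(3L)) metal_xyz[idx[k], ] <- shift + verts[k, ]
      pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
      for (r in seq_len(3L)) {
        i1 <- idx[pairs[r, 1]]; i2 <- idx[pairs[r, 2]]
        br <- shared(metals[i1], metals[i2])
        if (length(br) != 1L) {
          stop_input("unsupported template: triangle edge without a bridge")
        }
        mid <- (verts[pairs[r, 1], ] + verts[pairs[r, 2], ]) / 2
        out_dir <- unit(mid - centroid)
        ligand_xyz[as.character(br), ] <- shift + mid + h * out_dir
      }
    } else {
      stop_input("unsupported topology template (component with %d metals, %d bridges)",
                 length(idx), nb)
    }
    offset <- offset + 14
  }
  # terminal ligands: complete each metal's tetrahedron
  for (i in seq_along(metals)) {
    m <- metals[i]
    ligs <- ligs_of[[m]]
    placed <- ligs[!is.na(ligand_xyz[as.character(ligs), 1])]
    todo <- setdiff(ligs, placed)
    if (length(todo) == 0L) next
    fixed <- t(vapply(placed, function(l) {
      unit(ligand_xyz[as.character(l), ] - metal_xyz[m, ])
    }, numeric(3)))
    if (length(placed) == 0L) fixed <- matrix(numeric(0), 0L, 3L)
    dirs <- tetrahedral_completion(fixed, length(todo))
    for (k in seq_along(todo)) {
      ligand_xyz[as.character(todo[k]), ] <-
        metal_xyz[m, ] + bond * dirs[k, ]
    }
  }
  list(metal_xyz = metal_xyz, ligand_xyz = ligand_xyz)
}

# plausible (not chemically refined) cysteine scaffold atoms around each SG
cys_scaffold <- function(sg, away_dir) {
  v <- unit(away_dir)
  p <- perp_unit(v)
  q <- pracma_cross(v, p)
  cb <- sg + 1.81 * v
  ca <- cb + 1.53 * unit(0.8 * v + 0.6 * p)
  n <- ca + 1.46 * unit(0.9 * p - 0.45 * v)
  cc <- ca + 1.52 * q
  rbind(N = n, CA = ca, C = cc, CB = cb, SG = sg)
}

#' Generate a synthetic Zn3Cys9 cluster coordinate ensemble
#'
#' Builds idealized coordinates that satisfy the coordination restraints
#' exactly at zero noise: every metal-Sgamma bond at `bond` Angstrom and
#' all Sgamma-metal-Sgamma angles at the exact tetrahedral value
#' (109.4712 degrees; six equal angles of exactly 109.5 degrees are not
#' realizable in 3D).  Metals sit on a triangle with the three bridging
#' Sgamma atoms on the edge bisectors.  Each cysteine is completed with a
#' plausible N/CA/C/CB scaffold; Gaussian coordinate noise is added per
#' model (side-chain atoms scaled by `sidechain_scale`).
#'
#' @param n_models Number of models in the ensemble.
#' @param noise Gaussian coordinate noise sigma, Angstrom.
#' @param seed Integer seed; identical seeds give byte-identical PDB text.
#' @param assignment Cluster connectivity ([assignment()]); defaults to
#'   the MSL2 CXC Zn3Cys9 reference.
#' @param bond Metal-Sgamma bond length, Angstrom.
#' @param sidechain_scale Noise multiplier for side-chain atoms (CB, SG).
#' @param element Metal element symbol for the coordinate records.
#' @return A [structure_ensemble()]; attribute `ground_truth` carries the
#'   assignment, the metal label to residue-number map, and `bond`.
#' @export
make_cluster_coordinates <- function(n_models = 1L, noise = 0, seed = 1L,
                                     assignment = cxc_reference_assignment(),
                                     bond = 2.3, sidechain_scale = 1,
                                     element = "ZN") {
  stopifnot(inherits(assignment, "zn_assignment"), n_models >= 1L,
            noise >= 0)
  geom <- ideal_cluster_geometry(assignment, bond)
  metals <- rownames(geom$metal_xyz)
  lig_resnos <- as.integer(rownames(geom$ligand_xyz))

  rows <- list()
  coords <- list()
  sidechain <- logical(0)
  for (l in lig_resnos) {
    sg <- geom$ligand_xyz[as.character(l), ]
    bound <- assignment$edges$metal[assignment$edges$ligand == l]
    mcent <- colMeans(geom$metal_xyz[bound, , drop = FALSE])
    sc <- cys_scaffold(sg, sg - mcent)
    for (an in rownames(sc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        elety = an, resid = "CYS", chain = "A", resno = l,
        element = if (an == "SG") "S" else substr(an, 1, 1))
      coords[[length(coords) + 1L]] <- sc[an, ]
      sidechain <- c(sidechain, an %in% c("CB", "SG"))
    }
  }
  metal_resno <- stats::setNames(600L + seq_along(metals), metals)
  for (m in metals) {
    rows[[length(rows) + 1L]] <- data.frame(
      elety = toupper(element), resid = toupper(element), chain = "A",
      resno = metal_resno[[m]], element = toupper(element))
    coords[[length(coords) + 1L]] <- geom$metal_xyz[m, ]
    sidechain <- c(sidechain, FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  ideal <- do.call(rbind, coords)

  xyz <- local_seed(seed, {
    t(vapply(seq_len(n_models), function(m) {
      scale <- ifelse(sidechain, sidechain_scale, 1)
      noisy <- ideal + noise * scale *
        matrix(stats::rnorm(length(ideal)), nrow(ideal), 3L)
      as.numeric(t(noisy))
    }, numeric(3L * nrow(atoms))))
  })
  ens <- structure_ensemble(atoms, xyz,
                            source = sprintf("synthetic cluster seed=%d", seed))
  attr(ens, "ground_truth") <- list(assignment = assignment,
                                    metal_resno = metal_resno,
                                    bond = bond)
  ens
}

#' Generate a partial connectivity dataset from a known assignment
#'
#' Hides a chosen (or randomly drawn) subset of the true edges, mimicking
#' metal-ligand correlations missing from the spectra; coupling pairs are
#' derived from the truth's bridging structure (metals sharing a ligand are
#' tagged as 2J-coupled).
#'
#' @param truth The ground-truth [assignment()].
#' @param hidden_edges Data frame (`metal`, `ligand`) of edges to hide, or
#'   `NULL`.
#' @param n_hide Number of random edges to hide when `hidden_edges` is
#'   `NULL`.
#' @param seed Seed for the random hide.
#' @param with_coupling Include the derived coupling pairs.
#' @return A [connectivity_dataset()]; metals left with zero confirmed
#'   edges are reported in the `fully_hidden_metals` attribute.
#' @export
make_connectivity_dataset <- function(truth = cxc_reference_assignment(),
                                      hidden_edges = NULL, n_hide = 0L,
                                      seed = 1L, with_coupling = TRUE) {
  stopifnot(inherits(truth, "zn_assignment"))
  edges <- as.data.frame(truth$edges)
  if (is.null(hidden_edges) && n_hide > 0L) {
    hidden_edges <- local_seed(seed, {
      edges[sample.int(nrow(edges), n_hide), , drop = FALSE]
    })
  }
  key <- function(df) paste(df$metal, df$ligand)
  if (!is.null(hidden_edges)) {
    hidden_edges <- as.data.frame(hidden_edges)
    if (!all(key(hidden_edges) %in% key(edges))) {
      stop_input("hidden_edges must be a subset of the truth's edges")
    }
    confirmed <- edges[!key(edges) %in% key(hidden_edges), , drop = FALSE]
  } else {
    confirmed <- edges
  }
  metals <- sort(unique(edges$metal))
  coupling <- NULL
  if (with_coupling) {
    pairs <- utils::combn(metals, 2L)
    share <- vapply(seq_len(ncol(pairs)), function(k) {
      length(intersect(edges$ligand[edges$metal == pairs[1, k]],
                       edges$ligand[edges$metal == pairs[2, k]])) > 0L
    }, logical(1))
    if (any(share)) {
      coupling <- data.frame(metal_a = pairs[1, share],
                             metal_b = pairs[2, share],
                             evidence = "2J(M-M) triplet splitting")
    }
  }
  ds <- connectivity_dataset(
    metals = metals, ligands = sort(unique(edges$ligand)),
    confirmed_edges = confirmed, coupling_pairs = coupling)
  hidden_metals <- setdiff(metals, unique(confirmed$metal))
  attr(ds, "fully_hidden_metals") <- hidden_metals
  ds
}

#' The paper-style partial connectivity dataset
#'
#' The solver input in which the third metal's two bridging ligands are
#' unobserved: A bound to 525/527/539/544, B to 525/546/553/556, C to
#' 558/561 with two edges missing, plus all three pairwise coupling tags.
#'
#' @return A [connectivity_dataset()].
#' @export
cxc_partial_dataset <- function() {
  make_connectivity_dataset(
    truth = cxc_reference_assignment(),
    hidden_edges = data.frame(metal = c("C", "C"), ligand = c(539L, 553L)))
}

#' Generate synthetic intensity tables
#'
#' `kind = "hdx"`: exponential amide-proton decay series whose detection
#' counts at the class boundaries (first spectrum, 2 h, 24 h) equal
#' `targets` at the default 3-sigma threshold.  Decay rates are set
#' analytically (detected-at-24h residues decay to 10 sigma at 24 h;
#' detected-at-2h residues to 10 sigma at 2 h; first-spectrum-only
#' residues to 0.3 sigma at 2 h; undetected residues start below
#' threshold), and class membership is drawn at random.
#'
#' `kind = "hetnoe"`: saturated/reference intensity pairs realizing a
#' per-residue NOE profile, with optional fractional Gaussian noise.
#'
#' @param kind `"hdx"` or `"hetnoe"`.
#' @param targets For hdx: non-increasing integer vector of detection
#'   counts at the class boundaries.  For hetnoe: named numeric profile of
#'   NOE values per residue.
#' @param seed Integer seed.
#' @param residues Residue numbers (hdx; default the 51-residue construct
#'   span 520-570).
#' @param timepoints Exchange timepoints in minutes (hdx).
#' @param class_times Class boundary timepoints (hdx).
#' @param noise_level Background noise sigma attached to the tables.
#' @param threshold_multiple Detection threshold the rates are built for.
#' @param i_ref Reference peak intensity (hetnoe).
#' @param noise_frac Fractional Gaussian intensity noise (hetnoe).
#' @return For hdx: list with `table` ([intensity_table()]) and `truth`
#'   (per-residue class).  For hetnoe: list with `saturated`, `reference`,
#'   `truth`.
#' @export
make_intensity_tables <- function(kind = c("hdx", "hetnoe"), targets,
                                  seed = 1L,
                                  residues = 520:570,
                                  timepoints = c(0, 30, 75, 120, 160, 390, 1440),
                                  class_times = c(0, 120, 1440),
                                  noise_level = 1,
                                  threshold_multiple = 3,
                                  i_ref = 100, noise_frac = 0) {
  kind <- match.arg(kind)
  if (kind == "hdx") {
    targets <- as.integer(targets)
    if (length(targets) != length(class_times)) {
      stop_input("need one hdx target per class boundary")
    }
    if (any(diff(targets) > 0L)) {
      stop_input("hdx target counts must be non-increasing in time")
    }
    if (targets[1] > length(residues)) {
      stop_input("more detected residues requested than residues available")
    }
    n_slow <- targets[3]
    n_mid <- targets[2] - targets[3]
    n_fast <- targets[1] - targets[2]
    classes <- local_seed(seed, {
      pool <- residues
      slow <- sample_int(pool, n_slow); pool <- setdiff(pool, slow)
      mid <- sample_int(pool, n_mid); pool <- setdiff(pool, mid)
      fast <- sample_int(pool, n_fast); pool <- setdiff(pool, fast)
      list(slow = slow, mid = mid, fast = fast, none = pool)
    })
    i0 <- 100 * noise_level
    thr_t <- c(class_times[2], class_times[3])
    k_slow <- log(i0 / (10 * noise_level)) / thr_t[2]
    k_mid <- log(i0 / (10 * noise_level)) / thr_t[1]
    k_fast <- log(i0 / (0.3 * noise_level)) / thr_t[1]
    rate <- stats::setNames(rep(k_fast, length(residues)), residues)
    amp <- stats::setNames(rep(0.3 * noise_level, length(residues)), residues)
    for (r in classes$slow) { rate[as.character(r)] <- k_slow; amp[as.character(r)] <- i0 }
    for (r in classes$mid) { rate[as.character(r)] <- k_mid; amp[as.character(r)] <- i0 }
    for (r in classes$fast) { rate[as.character(r)] <- k_fast; amp[as.character(r)] <- i0 }
    grid <- expand.grid(residue = residues, time = timepoints)
    grid$intensity <- amp[as.character(grid$residue)] *
      exp(-rate[as.character(grid$residue)] * grid$time)
    truth <- tibble::tibble(
      residue = residues,
      class = dplyr::case_when(
        residues %in% classes$slow ~ paste0("t", class_times[3]),
        residues %in% classes$mid ~ paste0("t", class_times[2]),
        residues %in% classes$fast ~ paste0("t", class_times[1]),
        TRUE ~ "undetected"))
    list(table = intensity_table(grid$residue, grid$intensity,
                                 time = grid$time,
                                 noise_level = noise_level),
         truth = truth)
  } else {
    stopifnot(!is.null(names(targets)))
    res <- as.integer(names(targets))
    tabs <- local_seed(seed, {
      ref <- i_ref * (1 + noise_frac * stats::rnorm(length(res)))
      sat <- ref * targets * (1 + noise_frac * stats::rnorm(length(res)))
      list(ref = ref, sat = sat)
    })
    list(saturated = intensity_table(res, tabs$sat,
                                     noise_level = noise_level),
         reference = intensity_table(res, tabs$ref,
                                     noise_level = noise_level),
         truth = tibble::tibble(residue = res, noe = as.numeric(targets)))
  }
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

draw_uniform <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

# realize one motif instance: residue letters per token (ligand-2 may be
# forced to His for EZ-style units), gap letters from the background
# alphabet, gap lengths uniform within bounds
draw_motif_instance <- function(pattern, alphabet, his_at_2 = FALSE) {
  chars <- character(0)
  rel <- integer(0)
  res_count <- 0L
  for (tk in pattern$tokens) {
    if (tk$type == "residue") {
      res_count <- res_count + 1L
      letter <- if (his_at_2 && res_count == 2L && "H" %in% tk$allowed) {
        "H"
      } else tk$allowed[1]
      chars <- c(chars, letter)
      rel <- c(rel, length(chars))
    } else {
      len <- draw_uniform(tk$min, tk$max)
      if (len > 0L) chars <- c(chars, sample(alphabet, len, replace = TRUE))
    }
  }
  list(string = paste(chars, collapse = ""), rel_positions = rel)
}

#' Generate motif-bearing synthetic sequences
#'
#' Each record embeds exactly one consensus match, with gap lengths drawn
#' uniformly within the pattern bounds, inside a random background free of
#' Cys, His and Asn (no background position can serve as a ligand or
#' signature, so every reported tuple is built from implanted positions).
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param pattern A [parse_pattern()] result.
#' @param flank Integer range `c(min, max)` of background residues on each
#'   side of the implant.
#' @param alphabet Background alphabet (default: 20 canonical letters
#'   minus C, H and N).
#' @return List with `sequences` (named character vector) and `truth`
#'   (tibble: `seq_id`, `ligands` comma-separated, `signature_pos`,
#'   `start`, `end`).
#' @export
make_motif_sequences <- function(n, seed = 1L, pattern = cxc_consensus(),
                                 flank = c(5L, 30L),
                                 alphabet = setdiff(AA20, c("C", "H", "N"))) {
  stopifnot(n >= 1L)
  local_seed(seed, {
    seqs <- character(n)
    rows <- list()
    for (i in seq_len(n)) {
      id <- sprintf("synth%03d", i)
      left <- draw_uniform(flank[1], flank[2])
      right <- draw_uniform(flank[1], flank[2])
      inst <- draw_motif_instance(pattern, alphabet)
      seqs[i] <- paste0(
        paste(sample(alphabet, left, replace = TRUE), collapse = ""),
        inst$string,
        paste(sample(alphabet, right, replace = TRUE), collapse = ""))
      pos <- inst$rel_positions + left
      lig <- if (pattern$has_signature) pos[-length(pos)] else pos
      rows[[i]] <- tibble::tibble(
        seq_id = id,
        ligands = paste(lig, collapse = ","),
        signature_pos = if (pattern$has_signature) pos[length(pos)] else NA_integer_,
        start = pos[1], end = pos[length(pos)])
      names(seqs)[i] <- id
    }
    list(sequences = seqs, truth = dplyr::bind_rows(rows))
  })
}

#' Generate an EZ-style tandem CXC sequence
#'
#' Two immediately adjacent consensus units: the N-terminal unit carries
#' His at ligand 2 (as in EZ pre-SET motifs), the C-terminal unit is
#' all-Cys, for 17 cysteines across the 18 ligand positions.
#'
#' @param seed Integer seed.
#' @param pattern A [parse_pattern()] result.
#' @param flank Background residues on each side.
#' @param alphabet Background alphabet.
#' @return List with `sequence` (named character) and `truth` (tibble with
#'   one row per unit, as in [make_motif_sequences()]).
#' @export
make_ez_tandem_sequence <- function(seed = 1L, pattern = cxc_consensus(),
                                    flank = c(5L, 20L),
                                    alphabet = setdiff(AA20, c("C", "H", "N"))) {
  local_seed(seed, {
    left <- draw_uniform(flank[1], flank[2])
    right <- draw_uniform(flank[1], flank[2])
    u1 <- draw_motif_instance(pattern, alphabet, his_at_2 = TRUE)
    u2 <- draw_motif_instance(pattern, alphabet, his_at_2 = FALSE)
    seqs <- paste0(
      paste(sample(alphabet, left, replace = TRUE), collapse = ""),
      u1$string, u2$string,
      paste(sample(alphabet, right, replace = TRUE), collapse = ""))
    p1 <- u1$rel_positions + left
    p2 <- u2$rel_positions + left + nchar(u1$string)
    mk_row <- function(pos, unit) {
      lig <- if (pattern$has_signature) pos[-length(pos)] else pos
      tibble::tibble(
        seq_id = "ez_tandem", unit = unit,
        ligands = paste(lig, collapse = ","),
        signature_pos = if (pattern$has_signature) pos[length(pos)] else NA_integer_,
        start = pos[1], end = pos[length(pos)])
    }
    list(sequence = stats::setNames(seqs, "ez_tandem"),
         truth = dplyr::bind_rows(mk_row(p1, 1L), mk_row(p2, 2L)))
  })
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
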