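# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different computational route than the code it
# verifies.

# canonical string form of an assignment's edge set
assignment_key <- function(a) {
  paste(sort(paste(a$edges$metal, a$edges$ligand, sep = ":")), collapse = ";")
}

# Brute-force connectivity completion: enumerate ALL subsets of the full
# metal x ligand edge grid of the right total size that contain the
# confirmed edges, then filter by the constraints.  Returns a sorted
# character vector of canonical edge-set strings.
oracle_enumerate <- function(data) {
  labels <- data$labels
  ligands <- data$ligands
  grid <- expand.grid(metal = labels, ligand = ligands,
                      stringsAsFactors = FALSE)
  key <- function(m, l) paste(m, l)
  conf_key <- key(data$confirmed_edges$metal, data$confirmed_edges$ligand)
  cand <- which(!key(grid$metal, grid$ligand) %in% conf_key)
  need <- sum(data$coordination) - nrow(data$confirmed_edges)
  combos <- if (need == 0L) list(integer(0)) else {
    combn(cand, need, simplify = FALSE)
  }
  out <- character(0)
  for (cm in combos) {
    edges <- rbind(data$confirmed_edges[c("metal", "ligand")],
                   grid[cm, c("metal", "ligand")])
    per_metal <- table(factor(edges$metal, levels = labels))
    if (!all(as.integer(per_metal) == data$coordination)) next
    deg <- table(factor(edges$ligand, levels = ligands))
    if (any(deg < 1L) || any(deg > data$max_ligand_degree)) next
    if (!is.null(data$n_bridging) && sum(deg >= 2L) != data$n_bridging) next
    ok <- TRUE
    cp <- data$coupling_pairs
    if (!is.null(cp) && nrow(cp)) {
      for (k in seq_len(nrow(cp))) {
        sh <- intersect(edges$ligand[edges$metal == cp$metal_a[k]],
                        edges$ligand[edges$metal == cp$metal_b[k]])
        if (length(sh) != 1L) { ok <- FALSE; break }
      }
    }
    if (ok) {
      out <- c(out, paste(sort(paste(edges$metal, edges$ligand, sep = ":")),
                          collapse = ";"))
    }
  }
  sort(unique(out))
}

# Horn's quaternion method for the optimal proper-rotation RMSD, entirely
# independent of the SVD-based Kabsch implementation.
oracle_superpose_rmsd <- function(p, q) {
  pc <- sweep(as.matrix(p), 2L, colMeans(p))
  qc <- sweep(as.matrix(q), 2L, colMeans(q))
  s <- crossprod(pc, qc)  # s[i, j] = sum_k pc[k, i] * qc[k, j]
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz),
    4L, 4L, byrow = TRUE)
  lam <- max(eigen(n4, symmetric = TRUE)$values)
  sq <- sum(pc^2) + sum(qc^2) - 2 * lam
  sqrt(max(0, sq) / nrow(pc))
}

# Naive motif matcher: every start position crossed with every gap-length
# combination (expand.grid), practical only for small patterns.
oracle_scan_tuples <- function(seqstr, pattern) {
  chars <- strsplit(toupper(seqstr), "")[[1]]
  toks <- pattern$tokens
  res_tok <- Filter(function(tk) tk$type == "residue", toks)
  gaps <- Filter(function(tk) tk$type == "gap", toks)
  grid <- expand.grid(lapply(gaps, function(g) g$min:g$max))
  tuples <- list()
  for (start in seq_along(chars)) {
    for (r in seq_len(max(1L, nrow(grid)))) {
      lens <- if (length(gaps)) as.integer(grid[r, ]) else integer(0)
      pos <- start + cumsum(c(0L, lens + 1L))
      if (pos[length(pos)] > length(chars)) next
      ok <- all(vapply(seq_along(res_tok), function(i) {
        chars[pos[i]] %in% res_tok[[i]]$allowed
      }, logical(1)))
      if (ok) tuples[[length(tuples) + 1L]] <- pos
    }
  }
  unique(tuples)
}

# rigid motion helpers for invariance tests
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3L))
  r <- qr.Q(qr_dec)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

apply_rigid <- function(model, rot, trans) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% rot
  model$x <- xyz[, 1] + trans[1]
  model$y <- xyz[, 2] + trans[2]
  model$z <- xyz[, 3] + trans[3]
  model
}

# the MSL2-like sequence fixture: Cys at the nine ligand positions,
# signature Asn two past the last, non-conserved His at 557/565, on a
# background free of C/H/N so the implanted tuple is the only match
msl2_like_sequence <- function(from = 520L, to = 570L) {
  aa <- rep("A", to)
  aa[seq(2L, to, by = 3L)] <- "G"
  aa[seq(3L, to, by = 7L)] <- "S"
  aa[c(525L, 527L, 539L, 544L, 546L, 553L, 556L, 558L, 561L)] <- "C"
  aa[563L] <- "N"
  aa[c(557L, 565L)] <- "H"
  paste(aa[from:to], collapse = "")
}
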