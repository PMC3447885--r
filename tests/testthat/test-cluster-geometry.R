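test_that("metal-site detection recovers the generated trinuclear cluster", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0)
  sites <- detect_metal_sites(ensemble_model(ens))
  expect_length(sites, 1L)
  site <- sites[[1]]
  expect_equal(nrow(site$metals), 3L)
  expect_equal(nrow(site$ligands), 9L)
  expect_equal(nrow(site$bonds), 12L)
  deg <- table(site$bonds$ligand_resno)
  expect_setequal(as.integer(names(deg)[deg == 2L]), c(525L, 539L, 553L))
})

test_that("apo models and isolated mononuclear sites are handled", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0)
  model <- ensemble_model(ens)
  expect_length(detect_metal_sites(model[model$element != "ZN", ]), 0L)

  # two metals with disjoint ligand sets do not merge
  iso <- assignment(data.frame(metal = rep(c("M1", "M2"), each = 4L),
                               ligand = 1:8))
  ens2 <- make_cluster_coordinates(assignment = iso, noise = 0)
  sites <- detect_metal_sites(ensemble_model(ens2))
  expect_length(sites, 2L)
  expect_true(all(vapply(sites, function(s) nrow(s$metals), 0L) == 1L))
})

test_that("topology fingerprints match the reference connectivity", {
  topo <- cluster_topology(cxc_reference_assignment())
  expect_identical(topo$metal_ligands,
                   list(c(1L, 2L, 3L, 4L), c(1L, 5L, 6L, 7L),
                        c(3L, 6L, 8L, 9L)))
  expect_identical(topo$bridging, c(1L, 3L, 6L))

  mono <- cluster_topology(assignment(data.frame(metal = "M", ligand = 1:4)))
  expect_identical(mono$metal_ligands, list(1:4))
  expect_length(mono$bridging, 0L)

  # renumbering invariance: the comparable fingerprint ignores absolute
  # residue numbers
  shifted <- cxc_reference_assignment()$edges
  shifted$ligand <- shifted$ligand + 100L
  shifted_topo <- cluster_topology(assignment(shifted))
  expect_identical(shifted_topo[c("metal_ligands", "bridging")],
                   topo[c("metal_ligands", "bridging")])
  expect_identical(format(shifted_topo), format(topo))
})

test_that("fingerprints are invariant under rigid motion of the structure", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0.02, seed = 4L)
  model <- ensemble_model(ens)
  topo <- cluster_topology(detect_metal_sites(model)[[1]])
  set.seed(99)
  moved <- apply_rigid(model, random_rotation(), c(12, -7, 30))
  topo2 <- cluster_topology(detect_metal_sites(moved)[[1]])
  expect_identical(unclass(topo), unclass(topo2))
})

test_that("ideal clusters report the restraint geometry", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0)
  site <- detect_metal_sites(ensemble_model(ens))[[1]]
  rep <- coordination_report(site)
  expect_equal(rep$summary$mean_bond, 2.3, tolerance = 1e-9)
  expect_equal(rep$summary$mean_angle, 109.5, tolerance = 0.05)
  expect_lt(rep$summary$rms_angle_deviation, 0.05)
})

test_that("coordination geometry matches a naive recompute on noisy input", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0.05, seed = 7L)
  model <- ensemble_model(ens)
  site <- detect_metal_sites(model)[[1]]
  rep <- coordination_report(site)
  # independent recompute straight from the coordinate table
  for (lab in names(rep$per_metal)) {
    resno <- as.integer(sub("^ZN", "", lab))
    mrow <- model[model$resno == resno & model$element == "ZN", ]
    mpos <- c(mrow$x, mrow$y, mrow$z)
    pm <- rep$per_metal[[lab]]
    for (k in seq_len(nrow(pm$bonds))) {
      srow <- model[model$resno == pm$bonds$ligand[k] & model$elety == "SG", ]
      expect_equal(pm$bonds$length[k],
                   sqrt(sum((mpos - c(srow$x, srow$y, srow$z))^2)),
                   tolerance = 1e-9)
    }
    for (k in seq_len(nrow(pm$angles))) {
      s1 <- model[model$resno == pm$angles$ligand_i[k] & model$elety == "SG", ]
      s2 <- model[model$resno == pm$angles$ligand_j[k] & model$elety == "SG", ]
      v1 <- c(s1$x, s1$y, s1$z) - mpos
      v2 <- c(s2$x, s2$y, s2$z) - mpos
      naive <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      expect_equal(pm$angles$angle[k], naive, tolerance = 1e-9)
    }
  }
})

test_that("a two-coordinate metal reports a single angle", {
  duo <- assignment(data.frame(metal = "M", ligand = c(5L, 9L)))
  ens <- make_cluster_coordinates(assignment = duo, noise = 0)
  site <- detect_metal_sites(ensemble_model(ens))[[1]]
  rep <- coordination_report(site)
  expect_equal(nrow(rep$per_metal[[1]]$angles), 1L)
  expect_false(is.na(rep$per_metal[[1]]$tetrahedrality))
})

test_that("superposition is exact on rigid copies and refuses degeneracy", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0)
  site <- detect_metal_sites(ensemble_model(ens))[[1]]
  expect_equal(superpose_clusters(site, site)$rmsd, 0, tolerance = 1e-12)

  set.seed(12)
  moved <- apply_rigid(ensemble_model(ens), random_rotation(), c(5, 5, -2))
  site2 <- detect_metal_sites(moved)[[1]]
  expect_lt(superpose_clusters(site, site2)$rmsd, 1e-9)

  # proper rotations cannot superpose a mirror image of a chiral cluster
  mirrored <- ensemble_model(ens)
  mirrored$z <- -mirrored$z
  site3 <- detect_metal_sites(mirrored)[[1]]
  fit <- superpose_clusters(site, site3)
  expect_gt(fit$rmsd, 0.1)
  expect_gt(det(fit$rotation), 0)

  line <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3L, byrow = TRUE)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition RMSD agrees with the quaternion oracle", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0)
  model <- ensemble_model(ens)
  site <- detect_metal_sites(model)[[1]]
  set.seed(31)
  for (rep_i in 1:5) {
    noised <- model
    noised$x <- noised$x + rnorm(nrow(noised), 0, 0.1)
    noised$y <- noised$y + rnorm(nrow(noised), 0, 0.1)
    noised$z <- noised$z + rnorm(nrow(noised), 0, 0.1)
    noised <- apply_rigid(noised, random_rotation(), rnorm(3, 0, 5))
    site2 <- detect_metal_sites(noised)[[1]]
    a <- zincluster:::site_coords(site)
    b <- zincluster:::site_coords(site2)
    expect_equal(superpose_clusters(site, site2)$rmsd,
                 oracle_superpose_rmsd(a, b), tolerance = 1e-6)
    # third opinion: bio3d's fitted RMSD (reported rounded to 3 decimals)
    expect_lt(abs(superpose_clusters(site, site2)$rmsd -
                    bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)),
              5.01e-4)
  }
})

test_that("ensemble RMSD matches the isotropic-noise expectation", {
  ens0 <- make_cluster_coordinates(n_models = 20L, noise = 0)
  expect_equal(ensemble_rmsd(ens0, atom_set = "heavy")$mean, 0,
               tolerance = 1e-9)

  sigma <- 0.2
  ens <- make_cluster_coordinates(n_models = 20L, noise = sigma, seed = 13L)
  r <- ensemble_rmsd(ens, atom_set = "heavy")
  predicted <- sqrt(3) * sigma * sqrt(1 - 1 / 20)
  expect_equal(r$mean, predicted, tolerance = 0.1)
  expect_length(r$per_model, 20L)
})

test_that("backbone RMSD stays below heavy-atom RMSD for variable side chains", {
  ens <- make_cluster_coordinates(n_models = 12L, noise = 0.15, seed = 21L,
                                  sidechain_scale = 2)
  bb <- ensemble_rmsd(ens, atom_set = "backbone")
  heavy <- ensemble_rmsd(ens, atom_set = "heavy")
  expect_lt(bb$mean, heavy$mean)

  # residue-range selection restricts the atom count
  sub <- ensemble_rmsd(ens, residue_ranges = list(c(525, 546)),
                       atom_set = "backbone")
  expect_lt(sub$n_atoms, bb$n_atoms)
})

test_that("hydrogen bonds are judged by distance and, when present, angle", {
  model <- tibble::tibble(
    elety = c("OG1", "HG1", "O", "N"),
    resid = c("THR", "THR", "GLY", "ASN"),
    chain = "A", resno = c(538L, 538L, 560L, 563L),
    element = c("O", "H", "O", "N"),
    x = c(0, 0.96, 2.9, 10), y = 0, z = 0)
  hb <- hbond_check(model, donor = list(residue = 538, atom = "OG1"),
                    acceptor = list(residue = 560, atom = "O"))
  expect_true(hb$hbond)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  far <- hbond_check(model, donor = list(residue = 538, atom = "OG1"),
                     acceptor = list(residue = 563, atom = "N"))
  expect_false(far$hbond)

  expect_error(
    hbond_check(model, donor = list(residue = 538, atom = "OG1"),
                acceptor = list(residue = 551, atom = "O")),
    "residue 551")
})

test_that("ensembles round-trip through multi-model PDB text", {
  ens <- make_cluster_coordinates(n_models = 3L, noise = 0.1, seed = 5L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_structure_ensemble(path)
  expect_equal(back$n_models, 3L)
  expect_equal(back$atoms$resno, ens$atoms$resno)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_equal(back$atoms$element, ens$atoms$element)
  expect_equal(back$xyz, ens$xyz, tolerance = 1e-3)

  # detection works identically on the re-read coordinates
  site <- detect_metal_sites(ensemble_model(back))[[1]]
  expect_equal(nrow(site$bonds), 12L)
})
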