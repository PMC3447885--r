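test_that("the partial Cd-C dataset yields 9 coupled / 15 uncoupled candidates", {
  with_coupling <- cxc_partial_dataset()
  cands <- enumerate_assignments(with_coupling)
  expect_length(cands, 9L)
  # Cd-C completions are one terminal ligand of A crossed with one of B
  cd_c <- lapply(cands, function(a) {
    setdiff(sort(a$edges$ligand[a$edges$metal == "C"]), c(558L, 561L))
  })
  expect_setequal(
    vapply(cd_c, paste, "", collapse = ","),
    apply(expand.grid(c(527, 539, 544), c(546, 553, 556)), 1L,
          function(p) paste(sort(p), collapse = ",")))

  no_coupling <- make_connectivity_dataset(
    hidden_edges = data.frame(metal = c("C", "C"), ligand = c(539L, 553L)),
    with_coupling = FALSE)
  expect_length(enumerate_assignments(no_coupling), choose(6, 2))
})

test_that("a fully specified dataset returns exactly its own assignment", {
  full <- make_connectivity_dataset(n_hide = 0L)
  cands <- enumerate_assignments(full)
  expect_length(cands, 1L)
  expect_identical(assignment_key(cands[[1]]),
                   assignment_key(cxc_reference_assignment()))
})

test_that("enumeration agrees with the brute-force subset oracle", {
  datasets <- list(
    cxc_partial_dataset(),
    make_connectivity_dataset(
      hidden_edges = data.frame(metal = c("C", "C"), ligand = c(539L, 553L)),
      with_coupling = FALSE),
    # a smaller two-metal cluster with one bridge
    connectivity_dataset(
      metals = c("M1", "M2"),
      ligands = c(10L, 20L, 30L, 40L, 50L, 60L, 70L),
      confirmed_edges = data.frame(metal = c("M1", "M1"),
                                   ligand = c(10L, 20L)),
      coupling_pairs = data.frame(metal_a = "M1", metal_b = "M2")))
  for (ds in datasets) {
    got <- sort(vapply(enumerate_assignments(ds), assignment_key, ""))
    expect_identical(got, oracle_enumerate(ds))
  }
})

test_that("the true assignment survives any random edge hiding", {
  truth <- cxc_reference_assignment()
  truth_key <- assignment_key(truth)
  for (seed in 1:50) {
    n_hide <- 1L + seed %% 3L
    ds <- make_connectivity_dataset(truth, n_hide = n_hide, seed = seed)
    keys <- vapply(enumerate_assignments(ds), assignment_key, "")
    expect_true(truth_key %in% keys,
                info = sprintf("seed %d, %d hidden", seed, n_hide))
  }
})

test_that("confirming an edge never enlarges the candidate set", {
  base <- cxc_partial_dataset()
  base_keys <- vapply(enumerate_assignments(base), assignment_key, "")
  richer <- make_connectivity_dataset(
    hidden_edges = data.frame(metal = "C", ligand = 539L))
  richer_keys <- vapply(enumerate_assignments(richer), assignment_key, "")
  expect_true(all(richer_keys %in% base_keys))
  expect_lte(length(richer_keys), length(base_keys))
})

test_that("ligand classification separates bridging from terminal cysteines", {
  cls <- classify_ligands(cxc_reference_assignment())
  expect_identical(cls$bridging, c(525L, 539L, 553L))
  expect_identical(cls$terminal, c(527L, 544L, 546L, 556L, 558L, 561L))

  mono <- assignment(data.frame(metal = "M", ligand = c(1L, 2L, 3L, 4L)))
  expect_length(classify_ligands(mono)$bridging, 0L)

  two_shared <- assignment(data.frame(
    metal = rep(c("M1", "M2"), each = 4L),
    ligand = c(1L, 2L, 3L, 4L, 3L, 4L, 5L, 6L)))
  expect_length(classify_ligands(two_shared)$bridging, 2L)
})

test_that("violation ranking selects the unique zero-violation candidate", {
  cands <- enumerate_assignments(cxc_partial_dataset())
  cd_c_extra <- vapply(cands, function(a) {
    paste(setdiff(sort(a$edges$ligand[a$edges$metal == "C"]),
                  c(558L, 561L)), collapse = ",")
  }, "")
  scores <- ifelse(cd_c_extra == "539,553", 0, 1 + seq_along(cands))
  rk <- rank_by_violations(cands, scores)
  expect_false(is.null(rk$selected))
  expect_identical(assignment_key(rk$selected),
                   assignment_key(cxc_reference_assignment()))
  expect_identical(rk$ranking$status[1], "selected")

  # all-equal scores: order unchanged, nothing selected
  tied <- rank_by_violations(cands, rep(2, length(cands)))
  expect_identical(vapply(tied$candidates, assignment_key, ""),
                   vapply(cands, assignment_key, ""))
  expect_null(tied$selected)

  # two zero-violation candidates: both ambiguous, none selected
  two_zero <- rank_by_violations(cands, c(0, 0, seq_along(cands)[-(1:2)]))
  expect_null(two_zero$selected)
  expect_identical(two_zero$ranking$status[1:2], c("ambiguous", "ambiguous"))

  expect_error(rank_by_violations(cands, c(NA, seq_along(cands)[-1])),
               "candidate 1")
})

test_that("the synthetic distance scorer ranks the true connectivity first", {
  ens <- make_cluster_coordinates(n_models = 1L, noise = 0)
  truth <- attr(ens, "ground_truth")
  model <- ensemble_model(ens)
  metal_xyz <- as.matrix(
    model[match(truth$metal_resno, model$resno), c("x", "y", "z")])
  rownames(metal_xyz) <- names(truth$metal_resno)
  sg <- model[model$elety == "SG", ]
  ligand_xyz <- as.matrix(sg[, c("x", "y", "z")])
  rownames(ligand_xyz) <- sg$resno
  scorer <- distance_violation_scorer(metal_xyz, ligand_xyz)

  cands <- enumerate_assignments(cxc_partial_dataset())
  scores <- vapply(cands, scorer, numeric(1))
  rk <- rank_by_violations(cands, scores)
  expect_identical(assignment_key(rk$selected),
                   assignment_key(truth$assignment))
})

test_that("inconsistent connectivity input raises an infeasibility error", {
  expect_error(
    connectivity_dataset(
      metals = c("M1", "M2", "M3"),
      ligands = c(1L, 2L),
      confirmed_edges = data.frame(metal = c("M1", "M2", "M3"),
                                   ligand = c(1L, 1L, 1L))),
    "over-saturated")
  expect_error(
    connectivity_dataset(
      metals = "M1", ligands = 1:9,
      confirmed_edges = data.frame(metal = rep("M1", 5), ligand = 1:5)),
    "coordination number")
})

test_that("connectivity tables round-trip through CSV", {
  edges <- cxc_partial_dataset()$confirmed_edges
  pool <- cxc_partial_dataset()$ligands
  path <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(metal = edges$metal, ligand_position = edges$ligand,
               status = "confirmed"),
    data.frame(metal = "", ligand_position = pool, status = "pool"))
  write.csv(df, path, row.names = FALSE)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(metal_a = c("A", "A", "B"), metal_b = c("B", "C", "C"),
                       evidence = "2J"), cpath, row.names = FALSE)
  ds <- read_connectivity_csv(path, cpath)
  expect_length(enumerate_assignments(ds), 9L)
})
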