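test_that("the CXC superfamily consensus parses into the expected tokens", {
  p <- cxc_consensus()
  types <- vapply(p$tokens, `[[`, "", "type")
  expect_equal(sum(types == "residue"), 10L)  # 9 ligands + signature Asn
  expect_true(p$has_signature)
  gb <- pattern_gap_bounds(p)
  expect_equal(unname(gb[, "min"]), c(1, 2, 4, 1, 5, 2, 1, 2, 1))
  expect_equal(unname(gb[, "max"]), c(1, 13, 7, 1, 60, 4, 2, 15, 1))
  # ligand 2 admits His, no other slot does
  res_tokens <- Filter(function(tk) tk$type == "residue", p$tokens)
  expect_setequal(res_tokens[[2]]$allowed, c("C", "H"))
  expect_true(all(vapply(res_tokens[-c(2, 10)], function(tk) {
    identical(tk$allowed, "C")
  }, logical(1))))
})

test_that("pattern text round-trips and malformed patterns are rejected", {
  p <- parse_pattern("CXC")
  expect_length(p$tokens, 3L)
  expect_equal(p$tokens[[2]][c("min", "max")], list(min = 1L, max = 1L))
  expect_false(p$has_signature)

  for (text in c(CXC_CONSENSUS_TEXT, "CXC", "CX2-5[C/H]X1-1CXN")) {
    reparsed <- parse_pattern(format(parse_pattern(text)))
    expect_identical(reparsed$tokens, parse_pattern(text)$tokens)
  }

  expect_error(parse_pattern("CX5-2C"), "malformed gap bounds")
  expect_error(parse_pattern("C?C"), "unknown symbol")
  # the typeset form with en-dashes and underscores is accepted
  expect_identical(parse_pattern("CX_2–13_C")$tokens,
                   parse_pattern("CX2-13C")$tokens)
})

test_that("the scanner finds the nine cysteine ligands of the MSL2 region", {
  seqstr <- msl2_like_sequence(520L, 570L)
  matches <- scan_motif(seqstr, cxc_consensus(), seq_id = "MSL2")
  expect_length(matches, 1L)
  m <- matches[[1]]
  expect_equal(m$ligands + 519L,
               c(525L, 527L, 539L, 544L, 546L, 553L, 556L, 558L, 561L))
  expect_equal(m$signature_pos + 519L, 563L)
  expect_equal(m$signature_pos, m$ligands[9] + 2L)

  expect_length(scan_motif(strrep("A", 120)), 0L)
})

test_that("gap reports give the inter-ligand spacing", {
  seqstr <- msl2_like_sequence(520L, 570L)
  m <- scan_motif(seqstr)[[1]]
  gaps <- gap_report(m)
  expect_equal(unname(gaps["g2"]), 11L)  # the long Cys2-Cys3 segment
  expect_equal(unname(gaps["ligand_to_signature"]), 1L)

  # adjacent ligands under a permissive pattern give gap 0
  perm <- parse_pattern("CX0-2CX0-2C")
  m0 <- scan_motif("ACCCA", perm)
  expect_true(any(vapply(m0, function(x) all(gap_report(x) == 0L),
                         logical(1))))
})

test_that("scanner output equals the exhaustive start-and-gap oracle", {
  perm <- parse_pattern("CX1-3CX1-3C")
  set.seed(5)
  for (rep_i in 1:10) {
    seqstr <- paste(sample(c("A", "C", "G", "S", "T"), 60, replace = TRUE),
                    collapse = "")
    got <- lapply(scan_motif(seqstr, perm), `[[`, "ligands")
    want <- oracle_scan_tuples(seqstr, perm)
    key <- function(v) paste(v, collapse = ",")
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("every reported match re-validates token by token", {
  p <- cxc_consensus()
  g <- make_motif_sequences(10, seed = 17)
  gb <- pattern_gap_bounds(p)
  for (i in seq_along(g$sequences)) {
    chars <- strsplit(g$sequences[[i]], "")[[1]]
    for (m in scan_motif(g$sequences[i], p)) {
      pos <- c(m$ligands, m$signature_pos)
      expect_true(all(chars[m$ligands[-2]] == "C"))
      expect_true(chars[m$ligands[2]] %in% c("C", "H"))
      expect_equal(chars[m$signature_pos], "N")
      gaps <- diff(pos) - 1L
      expect_true(all(gaps >= gb[, "min"] & gaps <= gb[, "max"]))
    }
  }
})

test_that("implanted motifs are recovered with no background positions", {
  g <- make_motif_sequences(40, seed = 3)
  truth_pos <- lapply(strsplit(g$truth$ligands, ","), as.integer)
  for (i in seq_len(40)) {
    m <- scan_motif(g$sequences[i], seq_id = names(g$sequences)[i])
    keys <- vapply(m, function(x) paste(x$ligands, collapse = ","), "")
    # full recall of the implanted tuple ...
    expect_true(g$truth$ligands[i] %in% keys, info = names(g$sequences)[i])
    # ... and nothing drawn from the Cys-free background: any alternative
    # registration can only re-use implanted ligand positions
    for (x in m) expect_true(all(x$ligands %in% truth_pos[[i]]))
  }
  tab <- scan_fasta(g$sequences)
  expect_true(all(g$truth$ligands %in% tab$ligands))
})

test_that("tandem scanning distinguishes adjacent and spaced arrangements", {
  ez <- make_ez_tandem_sequence(seed = 2)
  td <- tandem_scan(ez$sequence, max_spacer = 0)
  expect_equal(nrow(td), 1L)
  expect_equal(td$spacer, 0L)
  lig_all <- c(td$first[[1]]$ligands, td$second[[1]]$ligands)
  chars <- strsplit(unname(ez$sequence), "")[[1]]
  expect_equal(sum(chars[lig_all] == "C"), 17L)  # EZ: His at ligand 2 of unit 1
  expect_equal(sum(chars[lig_all] == "H"), 1L)

  # single-domain sequences yield no tandem pairs
  single <- make_motif_sequences(1, seed = 9)
  expect_equal(nrow(tandem_scan(single$sequences[1], max_spacer = 60)), 0L)

  # tesmin/TSO1-style spacing
  g2 <- make_motif_sequences(2, seed = 23, flank = c(0L, 0L))
  spaced <- paste0(g2$sequences[1], strrep("A", 50), g2$sequences[2])
  td2 <- tandem_scan(spaced, max_spacer = 60)
  expect_equal(nrow(td2), 1L)
  expect_equal(td2$spacer, 50L)
  expect_equal(nrow(tandem_scan(spaced, max_spacer = 40)), 0L)
})

test_that("sequences round-trip through FASTA", {
  g <- make_motif_sequences(3, seed = 8)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g$sequences, path)
  back <- read_fasta_sequences(path)
  expect_identical(back, g$sequences)
})
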