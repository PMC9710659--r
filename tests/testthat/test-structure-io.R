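test_that("PDB fixtures round-trip through write_fixture / read_structure", {
  b <- build_backbone(
    dplyr::bind_rows(segment_spec("alpha", 3)),
    seed = 5
  )
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(b$structure, tmp)
  s <- read_structure(tmp, mode = "backbone")
  expect_equal(n_residues(s), 3)
  expect_equal(nrow(s), 12) # 4 backbone atoms per residue
  expect_equal(s$atom, b$structure$atom)
  expect_equal(cbind(s$x, s$y, s$z), cbind(b$structure$x, b$structure$y, b$structure$z),
    tolerance = 1e-3, ignore_attr = TRUE
  )
  s_ca <- read_structure(tmp, mode = "ca")
  expect_equal(n_residues(s_ca), 3)
  expect_equal(nrow(s_ca), 3)
  expect_true(all(s_ca$atom == "CA"))
})

test_that("unreadable and residue-free files raise typed errors", {
  expect_error(read_structure("no-such-file.pdb"), class = "geosec_io_error")
  het <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 101      10.000  10.000  10.000  1.00  0.00           O",
    "END"
  ), het)
  expect_error(read_structure(het), class = "geosec_format_error")
})

test_that("alternate locations resolve to the highest occupancy, ties by altloc", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.460   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       8.000   8.000   8.000  0.50  0.00           C",
    "END"
  ), tmp)
  s <- read_structure(tmp, mode = "backbone")
  expect_equal(n_residues(s), 1)
  expect_equal(s$x[s$atom == "N"], 9.000) # occupancy 0.60 wins
  expect_equal(s$x[s$atom == "CA"], 1.460) # occupancy tie: altloc A wins
})

test_that("residues without CA are dropped with a warning", {
  b <- build_backbone(segment_spec("beta", 4), seed = 9)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(b$structure, tmp)
  lines <- readLines(tmp)
  # drop residue 2's CA record from the file itself
  writeLines(lines[!grepl("^ATOM.* CA  [A-Z]{3} A   2 ", lines)], tmp)
  expect_warning(s <- read_structure(tmp), "without a CA")
  expect_equal(n_residues(s), 3)
})

test_that("DSSP output parses in order, skipping chain breaks", {
  dssp_lines <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "  5  1  4  0  0 ...",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H  >         0   0  200",
    "    2    2 A K  H  3         0   0  150",
    "    3    3 A V  H  <         0   0   80",
    "    4    4 A G              0   0   60",
    "    5        !              0   0    0",
    "    6    5 B L  E           0   0   40"
  )
  tmp <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp_lines, tmp)
  d <- read_dssp(tmp)
  expect_equal(nrow(d), 5)
  expect_equal(d$letter, c("H", "H", "H", "-", "E"))
  expect_equal(d$chain, c("A", "A", "A", "A", "B"))
  expect_equal(d$resnum, c(1, 2, 3, 4, 5))

  empty <- withr::local_tempfile(fileext = ".dssp")
  writeLines(character(0), empty)
  expect_error(read_dssp(empty), class = "geosec_format_error")
})

test_that("label mapping covers all schemes and rejects unknown letters", {
  expect_equal(
    map_labels(c("H", "H", "-", "E"), scheme = "alpha-beta-other")$class_id,
    c(0L, 0L, 2L, 1L)
  )
  expect_equal(
    map_labels(c("H", "G", "I", "E", "B", "T", "S", "-"), scheme = "all8")$class_id,
    0:7
  )
  expect_equal(
    map_labels(c("H", "G", "E"), scheme = "alpha-other")$class_id,
    c(1L, 0L, 0L) # G counts as Other by default
  )
  expect_equal(
    map_labels(c("H", "G", "E"), scheme = "alpha-other", alpha_letters = c("H", "G"))$class_id,
    c(1L, 1L, 0L)
  )
  expect_error(map_labels(c("H", "X"), scheme = "all8"), class = "geosec_validation_error")
})

test_that("label mapping is total on the 8 letters and surjective per scheme", {
  for (scheme in c("alpha-other", "beta-other", "alpha-beta-other", "all8")) {
    ids <- map_labels(c("H", "G", "I", "E", "B", "T", "S", "-"), scheme = scheme)$class_id
    expect_false(anyNA(ids))
    expect_setequal(unique(ids), 0:(n_classes(scheme) - 1))
  }
})

test_that("aligning DSSP rows to a structure follows chain/resnum/icode", {
  b <- build_backbone(segment_spec("alpha", 4), seed = 3)
  dssp <- tibble::tibble(
    chain = "A", resnum = c(2, 1, 4), icode = "", letter = c("H", "H", "-")
  )
  al <- align_labels(b$structure, dssp)
  expect_equal(al$res_id, c(1, 2, 4))
  expect_equal(al$letter, c("H", "H", "-"))
})
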