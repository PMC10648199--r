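test_that("a handcrafted PDB parses into one complete chain", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(helix_residues(6), path)
  ch <- read_structure(path)
  expect_equal(unique(ch$chain_id), "A")
  expect_equal(nrow(ch), 6)
  expect_true(all(ch$coords_known))
  expect_equal(ch$aa, rep("A", 6))
})

test_that("a residue missing its CA is flagged as unknown", {
  res <- helix_residues(6)
  res[[3]]$atoms$CA <- NULL
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(res, path)
  ch <- read_structure(path)
  expect_equal(ch$coords_known, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_true(is.na(ch$ca_x[3]))
})

test_that("altloc atoms resolve to the highest-occupancy location", {
  res <- helix_residues(4)
  # residue 2 CA with two locations: B has higher occupancy and distinct x
  xyzA <- res[[2]]$atoms$CA$xyz
  res[[2]]$atoms <- c(res[[2]]$atoms[c("N")],
                      list(CA = list(xyz = xyzA, alt = "A", occ = 0.3),
                           CA2 = list(xyz = xyzA + c(9, 0, 0), alt = "B", occ = 0.7)),
                      res[[2]]$atoms[c("C")])
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_fixture_pdb(res, path))
  lines <- sub(" CA2", " CA ", lines)  # same atom name, two altlocs
  writeLines(lines, path)
  ch <- read_structure(path)
  expect_equal(ch$ca_x[2], xyzA[1] + 9, tolerance = 1e-3)
})

test_that("chain filtering and empty selections behave as declared", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(helix_residues(6), path, chain = "B")
  expect_equal(unique(read_structure(path, chain_filter = "B")$chain_id), "B")
  expect_error(read_structure(path, chain_filter = "Z"), "no chains")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "cannot read")
})

test_that("non-standard residues map to X", {
  res <- helix_residues(5)
  res[[2]]$resname <- "XYZ"
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(res, path)
  ch <- read_structure(path)
  expect_equal(ch$aa[2], "X")
})

test_that("PDB write/read round trip preserves coordinates at file precision", {
  cfg <- fixture_config(n_chains = 1, length_range = c(12, 12), seed = 5)
  ch <- generate_chain(cfg, length = 12, chain_id = "A")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(ch, path)
  back <- read_structure(path)
  expect_equal(nrow(back), 12)
  for (col in c("n_x", "ca_y", "c_z")) {
    expect_equal(back[[col]], ch[[col]], tolerance = 1e-3)
  }
})

test_that("fragment extraction obeys the window arithmetic", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(helix_residues(9), path)
  ch <- read_structure(path)
  fr <- extract_fragments(ch)
  expect_equal(nrow(fr), 5)                      # L - 4
  expect_equal(fr$center, 2:6)                   # no terminal centers
  # unknown residue at offset 4 kills every window of a 9-residue chain
  ch2 <- ch
  ch2$coords_known[5] <- FALSE
  expect_equal(nrow(extract_fragments(ch2)), 0)
})

test_that("an interior unknown residue drops exactly the windows touching it", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(helix_residues(12), path)
  ch <- read_structure(path)
  ch$coords_known[7] <- FALSE  # 0-based offset 6
  fr <- extract_fragments(ch)
  expect_equal(fr$start, c(0L, 1L, 7L))
  expect_equal(nrow(fr), 3)
})

test_that("numbering gaps are treated as chain breaks", {
  res <- helix_residues(10, resno = c(1:5, 9:13))  # declared gap after 5
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(res, path)
  fr <- extract_fragments(read_structure(path))
  expect_equal(fr$start, c(0L, 5L))  # one window per contiguous run
})

test_that("fragment coordinates are atom-ordered N, CA, C per residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(helix_residues(6), path)
  ch <- read_structure(path)
  fr <- extract_fragments(ch)
  M <- fr$coords[[1]]
  expect_equal(M[1, ], c(ch$n_x[1], ch$n_y[1], ch$n_z[1]), tolerance = 1e-9)
  expect_equal(M[2, ], c(ch$ca_x[1], ch$ca_y[1], ch$ca_z[1]), tolerance = 1e-9)
  expect_equal(M[15, ], c(ch$c_x[5], ch$c_y[5], ch$c_z[5]), tolerance = 1e-9)
})

test_that("label tracks read from TSV and DSSP, with validation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tH", "2\tH", "3\tC", "4\tE", "5\tE"), tsv)
  tr <- read_labels(tsv, "dssp3")
  expect_equal(nrow(tr), 5)
  expect_equal(tr$label, c("H", "H", "C", "E", "E"))
  writeLines(c("1\tH", "2\tQ"), tsv)
  expect_error(read_labels(tsv, "dssp8"), "alphabet")

  dssp <- withr::local_tempfile(fileext = ".dssp")
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  rows <- vapply(1:8, function(i) {
    sprintf("%5d%5d A %s  %s", i, i, "A", c("H", "G", "I", "E", "B", "T", "S", " ")[i])
  }, character(1))
  writeLines(c("==== Secondary Structure Definition ====", hdr, rows), dssp)
  tr8 <- read_labels(dssp, "dssp8")
  expect_equal(tr8$label, c("H", "G", "I", "E", "B", "T", "S", "C"))
})

test_that("the 8-to-3 collapse follows the declared mapping", {
  expect_equal(collapse_dssp(strsplit("HGIEBTSC", "")[[1]]),
               c("H", "H", "H", "E", "E", "C", "C", "C"))
  expect_error(collapse_dssp("Q"), "mapping")
  # configurable: map T to H instead
  alt <- c(H = "H", G = "H", I = "H", E = "E", B = "E", T = "H", S = "C", C = "C")
  expect_equal(collapse_dssp("T", alt), "H")
})

test_that("chain splitting is proportional, deterministic and exhaustive", {
  ids <- sprintf("c%03d", 1:100)
  sp <- split_chains(ids, c(6, 3, 1), seed = 1)
  expect_equal(sort(ids), sort(sp$chain_id))
  expect_equal(unname(table(sp$split)[c("train", "test", "validation")]),
               c(60L, 30L, 10L), ignore_attr = TRUE)
  expect_identical(sp, split_chains(ids, c(6, 3, 1), seed = 1))
  expect_false(identical(sp$split, split_chains(ids, c(6, 3, 1), seed = 2)$split))
  sp10 <- split_chains(sprintf("x%02d", 1:10), c(6, 3, 1), seed = 3)
  expect_equal(unname(table(sp10$split)[c("train", "test", "validation")]),
               c(6L, 3L, 1L), ignore_attr = TRUE)
  expect_error(split_chains(ids, c(0, 0, 0), 1), "positive total")
})

test_that("chain-level splitting partitions fragment windows across sets", {
  cfg <- fixture_config(n_chains = 12, length_range = c(20, 30), seed = 9)
  ds <- generate_dataset(cfg)
  fr <- extract_fragments(ds)
  sp <- split_chains(unique(ds$chain_id), c(6, 3, 1), seed = 9)
  joined <- dplyr::left_join(fr, sp, by = "chain_id")
  windows <- paste(joined$chain_id, joined$start)
  expect_equal(anyDuplicated(windows), 0L)
  per_window_splits <- tapply(joined$split, windows, function(x) length(unique(x)))
  expect_true(all(per_window_splits == 1))
})

test_that("fasta export writes wrapped records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(ch1 = strrep("ACDEF", 30)), path, width = 60)
  lines <- readLines(path)
  expect_equal(lines[1], ">ch1")
  expect_equal(nchar(lines[2]), 60)
  expect_equal(paste(lines[-1], collapse = ""), strrep("ACDEF", 30))
})
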