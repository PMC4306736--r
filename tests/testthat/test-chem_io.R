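test_that("SMILES reading parses simple molecules and counts skips", {
  path <- smiles_fixture(c("C methane", "CC ethane",
                           "this-is-not-smiles bad", "c1ccccc1 benzene"))
  mols <- suppressWarnings(read_smiles(path))
  expect_equal(attr(mols, "skipped"), 1)
  expect_length(mols, 3)
  methane <- normalize_structure(mols[[1]])
  expect_equal(nrow(methane$atoms), 1)
  expect_equal(nrow(methane$bonds), 0)
  expect_equal(methane$atoms$hcount, 4L)
  ethane <- normalize_structure(mols[[2]])
  expect_equal(nrow(ethane$atoms), 2)
  expect_equal(nrow(ethane$bonds), 1)
  expect_equal(ethane$bonds$order, 1L)
})

test_that("SMILES reading fails on missing files, empty input, duplicates", {
  expect_error(read_smiles(tempfile()), "not found")
  path <- smiles_fixture(c("@@nope bad1", "alsonotasmiles bad2"))
  expect_error(suppressWarnings(read_smiles(path)), "no parsable")
  path2 <- smiles_fixture(c("C m1", "CC m1"))
  expect_error(read_smiles(path2), "duplicate")
})

test_that("SDF reading round-trips methane and keeps properties", {
  path <- tempfile(fileext = ".sdf")
  writeLines(methane_sdf_text(), path)
  mols <- read_sdf(path)
  expect_length(mols, 1)
  expect_equal(mols[[1]]$id, "methane")
  m <- normalize_structure(mols[[1]])
  expect_equal(nrow(m$atoms), 1)
  expect_true("origin" %in% names(mols[[1]]$meta))
  # duplicate ids are an error naming the duplicate
  path2 <- tempfile(fileext = ".sdf")
  writeLines(c(methane_sdf_text("dup"), methane_sdf_text("dup")), path2)
  expect_error(read_sdf(path2), "dup")
  expect_error(read_sdf(tempfile()), "not found")
  empty <- tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_error(suppressWarnings(read_sdf(empty)), "no parsable")
})

test_that("SMILES and SDF routes agree on the same molecule", {
  smi <- suppressWarnings(read_smiles(smiles_fixture("C methane")))
  path <- tempfile(fileext = ".sdf")
  writeLines(methane_sdf_text(), path)
  sdf <- read_sdf(path)
  expect_equal(canonical_signature(normalize_structure(smi[[1]])),
               canonical_signature(normalize_structure(sdf[[1]])))
})

test_that("activity tables binarize pK_i values at an inclusive cutoff", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tFXa\tThr\tTry",
               "c1\t6.3\t5.0\t5.9",
               "c2\t6.1\t6.1\t6.1",
               "c3\t5.5\t5.5\t5.5"), path)
  at <- read_activity_table(path, mode = "pki", cutoff = 6.1)
  expect_equal(unname(at$profiles["c1", ]), c(1L, 0L, 0L))
  expect_equal(unname(at$profiles["c2", ]), c(1L, 1L, 1L))  # boundary active
  expect_equal(unname(at$profiles["c3", ]), c(0L, 0L, 0L))
  expect_error(read_activity_table(path, mode = "pki"), "cutoff")
})

test_that("binary activity tables validate cells and pass through", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tT1\tT2\tT3", "a\t1\t0\t1", "b\t0\t0\t0"), path)
  at <- read_activity_table(path, mode = "binary")
  expect_equal(unname(at$profiles["a", ]), c(1L, 0L, 1L))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tT1", "a\t2"), bad)
  expect_error(read_activity_table(bad, mode = "binary"), "outside \\{0,1\\}")
  nonnum <- tempfile(fileext = ".tsv")
  writeLines(c("id\tT1", "a\tx"), nonnum)
  expect_error(read_activity_table(nonnum, mode = "binary"), "row 1")
})

test_that("sparse fingerprint files round-trip bit-exactly", {
  fps <- list(sparse_fp(c(5, 17), c(0.5, 0.5), dim = 64),
              sparse_fp(numeric(0), numeric(0), dim = 64),
              sparse_fp(c(0, 1, 63), c(1, pi, 1 / 3), dim = 64))
  path <- tempfile(fileext = ".svml")
  write_sparse_fingerprints(fps, path, labels = c(3, 0, 1),
                            ids = c("a", "b", "c"))
  rt <- read_sparse_fingerprints(path)
  expect_equal(rt$labels, c(3, 0, 1))
  expect_equal(rt$ids, c("a", "b", "c"))
  for (k in seq_along(fps)) {
    expect_identical(rt$fps[[k]]$index, fps[[k]]$index)
    expect_identical(rt$fps[[k]]$value, fps[[k]]$value)
  }
})

test_that("a 1000-record file round-trips exactly", {
  set.seed(401)
  fps <- lapply(seq_len(1000), function(k) {
    nnz <- sample(0:12, 1)
    idx <- sort(sample(0:4095, nnz))
    sparse_fp(idx, runif(nnz, 0.01, 5), dim = 4096)
  })
  labels <- sample(0:3, 1000, replace = TRUE)
  path <- tempfile(fileext = ".svml")
  write_sparse_fingerprints(fps, path, labels = labels)
  rt <- read_sparse_fingerprints(path)
  expect_equal(rt$labels, as.numeric(labels))
  expect_identical(lapply(rt$fps, `[[`, "index"),
                   lapply(fps, `[[`, "index"))
  expect_identical(lapply(rt$fps, `[[`, "value"),
                   lapply(fps, `[[`, "value"))
})

test_that("malformed sparse fingerprint lines fail with a line number", {
  path <- tempfile()
  writeLines(c("# dim 64", "1 3:0.5 2:0.5"), path)
  expect_error(read_sparse_fingerprints(path), "line 1")
  path2 <- tempfile()
  writeLines(c("# dim 64", "1 3:0.5 3:0.5"), path2)
  expect_error(read_sparse_fingerprints(path2), "unsorted or duplicate")
})

test_that("normalization keeps the largest fragment and is idempotent", {
  mols <- suppressWarnings(
    read_smiles(smiles_fixture(c("CC.[Na+] salt", "c1ccccc1 benzene"))))
  salt <- normalize_structure(mols[[1]])
  expect_equal(salt$atoms$element, c("C", "C"))
  benzene <- normalize_structure(mols[[2]])
  expect_true(all(benzene$bonds$order == 4L))  # Kekule input aromatized
  expect_identical(normalize_structure(benzene), benzene)
  expect_identical(normalize_structure(salt), salt)
})

test_that("normalization output is independent of atom input order", {
  mols <- suppressWarnings(read_smiles(smiles_fixture(
    c("CCO ethanol", "c1ccncc1 pyridine", "CC(=O)O aceticacid"))))
  set.seed(77)
  for (mol in mols) {
    ref <- normalize_structure(mol)
    for (rep in 1:5) {
      perm <- sample(nrow(mol$atoms))
      shuffled <- permute_molecule(mol, perm)
      got <- normalize_structure(shuffled)
      expect_equal(got$atoms, ref$atoms, ignore_attr = TRUE)
      expect_equal(got$bonds, ref$bonds, ignore_attr = TRUE)
    }
  }
})

test_that("molecule invariants are enforced", {
  atoms <- data.frame(element = c("C", "C"), charge = 0L, hcount = 0L)
  expect_error(molecule("x", atoms, data.frame(a1 = 1, a2 = 3, order = 1)),
               "invalid atom index")
  expect_error(molecule("x", atoms,
                        data.frame(a1 = c(1, 2), a2 = c(2, 1),
                                   order = c(1, 1))),
               "duplicate bond")
  expect_error(molecule("x", atoms, data.frame(a1 = 1, a2 = 2, order = 9)),
               "bond order")
})
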