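test_that("XYZ files round-trip coordinates exactly", {
  s <- MolecularStructure(data.frame(
    element = c("N", "C", "H", "Ag"), name = c("N1", "C1", "H1", "Ag1"),
    resname = "MOL", resid = 1L, chain = "A",
    x = c(0, 1.5, -0.5, 3.25), y = c(0, 0.1, 0.9, -1.125),
    z = c(0, -0.25, 0.5, 2)))
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXyz(s, path)
  back <- readStructure(path)
  expect_equal(atoms(back)$x, atoms(s)$x)
  expect_equal(atoms(back)$y, atoms(s)$y)
  expect_equal(atoms(back)$z, atoms(s)$z)
  expect_equal(atoms(back)$element, atoms(s)$element)
})

test_that("malformed XYZ files raise line-numbered errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "C 0 0 0", "N 1 bad 0"), path)
  expect_error(readStructure(path), "line 4")
  writeLines(c("3", "comment", "C 0 0 0"), path)
  expect_error(readStructure(path), "declares 3")
})

test_that("a guanine nucleotide PDB reads with correct residue and atom names", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_guanine_pdb(path)
  s <- readStructure(path)
  at <- atoms(s)
  expect_equal(length(unique(paste(at$chain, at$resid))), 1)
  expect_true(all(c("N9", "C8", "N7", "C1'", "O5'", "P") %in% at$name))
  expect_equal(at$x[at$name == "N9"], 0)
  # PDB's three decimals are preserved
  expect_equal(at$z[at$name == "C1'"], 0.550)
})

test_that("duplicate (chain, residue, atom) triples are a uniqueness error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_guanine_pdb(path))
  writeLines(c(lines[1], lines), path)  # duplicate the first atom
  expect_error(readStructure(path), "duplicate")
})

test_that("stripping one guanine nucleotide leaves the base and one C1'-N9 cut", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_guanine_pdb(path)
  res <- stripBackbone(readStructure(path))
  at <- atoms(res$structure)
  expect_equal(nrow(res$cutBonds), 1)
  expect_equal(res$cutBonds$base_atom, "N9")
  expect_setequal(at$name, c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2",
                             "N2", "N3", "C4", "H8", "H1", "H21", "H22"))
  # no phosphorus or sugar atoms remain
  expect_false(any(at$element == "P"))
  expect_false(any(grepl("'", at$name)))
})

test_that("a tetramer with silver ions gives four cuts and keeps the silver", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tetramer_pdb(path)
  res <- stripBackbone(readStructure(path))
  expect_equal(nrow(res$cutBonds), 4)
  expect_equal(sum(atoms(res$structure)$element == "Ag"), 2)
})

test_that("backbone stripping is idempotent", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_guanine_pdb(path)
  once <- stripBackbone(readStructure(path))
  twice <- stripBackbone(once$structure)
  expect_equal(nrow(twice$cutBonds), 0)
  expect_identical(atoms(twice$structure), atoms(once$structure))
})

test_that("a nucleotide lacking its glycosidic nitrogen is an error naming the residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_guanine_pdb(path))
  writeLines(lines[!grepl(" N9 ", lines)], path)
  expect_error(stripBackbone(readStructure(path)), "N9")
})

test_that("capping places H along N->C1' at exactly the N-H length", {
  cut <- data.frame(chain = "A", resid = 1L, resname = "DG",
                    base_atom = "N9", nx = 0, ny = 0, nz = 0,
                    cx = 1.5, cy = 0, cz = 0)
  base <- MolecularStructure(data.frame(
    element = "N", name = "N9", resname = "DG", resid = 1L, chain = "A",
    x = 0, y = 0, z = 0))
  capped <- capWithHydrogens(base, cut)
  h <- atoms(capped)[atoms(capped)$element == "H", ]
  expect_equal(c(h$x, h$y, h$z), c(1.01, 0, 0))
  expect_equal(h$name, "H9")
})

test_that("capping adds one H per cut, never moves atoms, at 1.01 A over random geometries", {
  set.seed(12)
  path <- withr::local_tempfile(fileext = ".pdb")
  for (rep_ in 1:20) {
    write_guanine_pdb(path, shift = runif(3, -5, 5))
    s <- readStructure(path)
    res <- stripBackbone(s)
    capped <- capWithHydrogens(res$structure, res$cutBonds)
    expect_equal(nrow(atoms(capped)),
                 nrow(atoms(res$structure)) + nrow(res$cutBonds))
    # pre-existing atoms bit-identical
    expect_identical(atoms(capped)[seq_len(nrow(atoms(res$structure))), ],
                     atoms(res$structure))
    h <- atoms(capped)[nrow(atoms(capped)), ]
    n <- res$cutBonds
    d <- sqrt((h$x - n$nx)^2 + (h$y - n$ny)^2 + (h$z - n$nz)^2)
    expect_equal(d, 1.01, tolerance = 1e-9)
  }
})

test_that("a zero-length glycosidic vector is a geometry error", {
  cut <- data.frame(chain = "A", resid = 1L, resname = "DG",
                    base_atom = "N9", nx = 1, ny = 1, nz = 1,
                    cx = 1, cy = 1, cz = 1)
  base <- MolecularStructure(data.frame(
    element = "N", name = "N9", resname = "DG", resid = 1L, chain = "A",
    x = 1, y = 1, z = 1))
  expect_error(capWithHydrogens(base, cut), "geometry")
})
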