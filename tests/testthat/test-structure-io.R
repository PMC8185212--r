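test_that("PDB parsing partitions chains and applies the stated rules", {
  path <- tinyComplexPDB()
  s <- readComplexPDB(path, "A", "B")
  expect_s4_class(s, "ComplexStructure")
  ra <- receptorAtoms(s)
  expect_equal(length(unique(ra$resno)), 2)          # 2 receptor residues
  expect_equal(length(unique(ligandAtoms(s)$resno)), 1)
  expect_equal(nrow(atomTable(s)), 12)

  # empty ligand chain set -> error naming the problem
  expect_error(readComplexPDB(path, c("A", "B"), "Z"),
               "no atoms in ligand")
  expect_error(readComplexPDB(tempfile(), "A", "B"), "not found")
  expect_error(readComplexPDB(path, "A", "A"), "disjoint")
})

test_that("alternate locations resolve to the first conformer", {
  lines <- c(pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
             pdbLine(2, "CA", "GLY", "A", 1, 1.2, 1, 0, altloc = "A",
                     element = "C"),
             pdbLine(3, "CA", "GLY", "A", 1, 9.9, 9, 9, altloc = "B",
                     element = "C"),
             pdbLine(4, "C", "GLY", "A", 1, 2.47, 0, 0, element = "C"),
             pdbLine(5, "O", "GLY", "A", 1, 2.47, -1.23, 0, element = "O"),
             pdbLine(6, "N", "GLY", "B", 1, 0, 0, 4, element = "N"),
             pdbLine(7, "CA", "GLY", "B", 1, 1.2, 1, 4, element = "C"),
             pdbLine(8, "C", "GLY", "B", 1, 2.47, 0, 4, element = "C"))
  s <- readComplexPDB(writePdbFixture(lines), "A", "B")
  ca <- receptorAtoms(s)
  ca <- ca[ca$name == "CA", ]
  expect_equal(nrow(ca), 1)            # exactly one CA kept
  expect_equal(ca$x, 1.2, tolerance = 1e-9)  # the first-listed conformer
})

test_that("hydrogens are retained in the parse but flagged non-heavy", {
  lines <- c(pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
             pdbLine(2, "H", "GLY", "A", 1, -0.5, 0.5, 0, element = "H"),
             pdbLine(3, "CA", "GLY", "A", 1, 1.2, 1, 0, element = "C"),
             pdbLine(4, "C", "GLY", "A", 1, 2.47, 0, 0, element = "C"),
             pdbLine(5, "N", "GLY", "B", 1, 0, 0, 4, element = "N"),
             pdbLine(6, "CA", "GLY", "B", 1, 1.2, 1, 4, element = "C"),
             pdbLine(7, "C", "GLY", "B", 1, 2.47, 0, 4, element = "C"))
  s <- readComplexPDB(writePdbFixture(lines), "A", "B")
  a <- receptorAtoms(s)
  expect_true("H" %in% a$element)
  expect_false(a$heavy[a$element == "H"])
  expect_true(all(a$heavy[a$element != "H"]))
})

test_that("covalent bonds follow the residue templates and peptide rule", {
  # a single glycine: template bonds N-CA, CA-C, C-O
  lines <- c(pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
             pdbLine(2, "CA", "GLY", "A", 1, 1.2, 1, 0, element = "C"),
             pdbLine(3, "C", "GLY", "A", 1, 2.47, 0, 0, element = "C"),
             pdbLine(4, "O", "GLY", "A", 1, 2.47, -1.23, 0, element = "O"),
             pdbLine(5, "N", "GLY", "B", 1, 0, 0, 4, element = "N"),
             pdbLine(6, "CA", "GLY", "B", 1, 1.2, 1, 4, element = "C"),
             pdbLine(7, "C", "GLY", "B", 1, 2.47, 0, 4, element = "C"))
  s <- readComplexPDB(writePdbFixture(lines), "A", "B")
  bg <- inferBonds(s, "receptor")
  expect_equal(nrow(bg$edges), 3)
  pairs <- apply(bg$edges, 1, function(e)
    paste(sort(bg$atoms$name[e]), collapse = "-"))
  expect_setequal(pairs, c("CA-N", "C-CA", "C-O"))

  # consecutive residues: C(i)-N(i+1) at 1.33 A bonds, at 5 A does not
  s2 <- readComplexPDB(tinyComplexPDB(), "A", "B")
  bg2 <- inferBonds(s2, "receptor")
  expect_equal(nrow(bg2$edges), 7)   # 2x3 template + 1 peptide
  far <- c(pdbLine(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
           pdbLine(2, "CA", "ALA", "A", 1, 1.2, 1, 0, element = "C"),
           pdbLine(3, "C", "ALA", "A", 1, 2.47, 0, 0, element = "C"),
           pdbLine(4, "N", "ALA", "A", 2, 7.47, 0, 0, element = "N"),
           pdbLine(5, "CA", "ALA", "A", 2, 8.7, 1, 0, element = "C"),
           pdbLine(6, "C", "ALA", "A", 2, 9.9, 0, 0, element = "C"),
           pdbLine(7, "N", "GLY", "B", 1, 0, 0, 4, element = "N"),
           pdbLine(8, "CA", "GLY", "B", 1, 1.2, 1, 4, element = "C"),
           pdbLine(9, "C", "GLY", "B", 1, 2.47, 0, 4, element = "C"))
  s3 <- readComplexPDB(writePdbFixture(far), "A", "B")
  bg3 <- inferBonds(s3, "receptor")
  # chain break: 2x2 intra bonds (no O atoms), no peptide bond
  expect_equal(nrow(bg3$edges), 4)
})

test_that("feature vectors have the 5+6+5+6+1 block structure", {
  s <- makeNative(4, 3, seed = 1)
  fm <- atomFeatureMatrix(s)
  expect_equal(ncol(fm), 23)
  expect_equal(sum(featureBlocks()), 23L)
  blocks <- featureBlocks()
  starts <- cumsum(c(1, blocks[-length(blocks)]))
  for (r in seq_len(nrow(fm))) {
    for (b in 1:4)  # each one-hot block sums to exactly 1
      expect_equal(sum(fm[r, starts[b]:(starts[b] + blocks[b] - 1)]), 1)
    expect_true(fm[r, 23] %in% c(0, 1))
    expect_equal(sum(fm[r, ]), 4 + fm[r, 23])
  }
})

test_that("individual atom features match the template chemistry", {
  # glycine CA: carbon, degree 2 (N, C), 2 template H, not aromatic
  s <- readComplexPDB(tinyComplexPDB(), "A", "B")
  v <- atomFeatures(s, "receptor", 2)  # CA of residue 1
  expect_equal(v[1:5], c(1, 0, 0, 0, 0))            # C one-hot
  expect_equal(which(v[6:11] == 1) - 1, 2)          # degree 2
  expect_equal(which(v[12:16] == 1) - 1, 2)         # 2 attached H
  expect_equal(v[23], 0)

  # tryptophan ring atom is aromatic
  trp <- c(pdbLine(1, "N", "TRP", "A", 1, 0, 0, 0, element = "N"),
           pdbLine(2, "CA", "TRP", "A", 1, 1.4, 0.5, 0, element = "C"),
           pdbLine(3, "C", "TRP", "A", 1, 2.6, 0, 0, element = "C"),
           pdbLine(4, "O", "TRP", "A", 1, 2.6, -1.2, 0, element = "O"),
           pdbLine(5, "CB", "TRP", "A", 1, 1.4, 2.0, 0, element = "C"),
           pdbLine(6, "CG", "TRP", "A", 1, 1.4, 3.5, 0, element = "C"),
           pdbLine(7, "CZ2", "TRP", "A", 1, 1.4, 5.0, 1, element = "C"),
           pdbLine(8, "N", "GLY", "B", 1, 0, 0, 4, element = "N"),
           pdbLine(9, "CA", "GLY", "B", 1, 1.2, 1, 4, element = "C"),
           pdbLine(10, "C", "GLY", "B", 1, 2.47, 0, 4, element = "C"))
  s2 <- readComplexPDB(writePdbFixture(trp), "A", "B")
  at <- inferBonds(s2, "receptor")$atoms
  cz2 <- which(at$name == "CZ2")
  expect_equal(atomFeatures(s2, "receptor", cz2)[23], 1)
})

test_that("write/parse round trip preserves the retained fields", {
  s <- makeNative(4, 3, seed = 5)
  p <- tempfile(fileext = ".pdb")
  writeComplexPDB(s, p)
  s2 <- readComplexPDB(p, "A", "B")
  expect_equal(nrow(atomTable(s2)), nrow(atomTable(s)))
  expect_equal(atomTable(s2)$name, atomTable(s)$name)
  expect_equal(atomTable(s2)$chain, atomTable(s)$chain)
  expect_equal(atomTable(s2)$x, atomTable(s)$x, tolerance = 5.1e-4)
  # second round trip is exact (fixed-width quantization is idempotent)
  p2 <- tempfile(fileext = ".pdb")
  writeComplexPDB(s2, p2)
  s3 <- readComplexPDB(p2, "A", "B")
  expect_identical(atomTable(s3)$x, atomTable(s2)$x)
})

test_that("bond graph is invariant under rigid transforms", {
  s <- makeNative(4, 3, seed = 2)
  b0 <- inferBonds(s, "receptor")$edges
  f0 <- atomFeatureMatrix(s)
  for (sd in 1:3) {
    st <- applyRigid(s, randomRigidTransform(sd))
    expect_identical(inferBonds(st, "receptor")$edges, b0)
    expect_identical(atomFeatureMatrix(st), f0)
  }
})
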