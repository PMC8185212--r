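test_that("interface selection applies the 10 A min heavy-atom rule", {
  near <- readComplexPDB(tinyComplexPDB(bGap = 4.0), "A", "B")
  sel <- extractInterface(near, 10.0)
  expect_equal(length(sel$receptor), 2)
  expect_equal(length(sel$ligand), 1)

  # boundary: closest pair just inside / outside the cutoff
  mk <- function(gap) {
    lines <- c(pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
               pdbLine(2, "CA", "GLY", "A", 1, 1.2, 1, 0, element = "C"),
               pdbLine(3, "C", "GLY", "A", 1, 2.47, 0, 0, element = "C"),
               pdbLine(4, "N", "GLY", "B", 1, 0, 0, gap, element = "N"),
               pdbLine(5, "CA", "GLY", "B", 1, 1.2, 1, gap, element = "C"),
               pdbLine(6, "C", "GLY", "B", 1, 2.47, 0, gap, element = "C"))
    readComplexPDB(writePdbFixture(lines), "A", "B")
  }
  sel2 <- extractInterface(mk(9.9), 10.0)
  expect_equal(length(sel2$receptor), 1)
  expect_equal(length(sel2$ligand), 1)
  expect_error(extractInterface(mk(10.1), 10.0), "no interface")

  # per-residue rule: a distant receptor residue is excluded
  lines <- c(pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
             pdbLine(2, "CA", "GLY", "A", 1, 1.2, 1, 0, element = "C"),
             pdbLine(3, "C", "GLY", "A", 1, 2.47, 0, 0, element = "C"),
             pdbLine(4, "N", "GLY", "A", 2, 50, 0, 0, element = "N"),
             pdbLine(5, "CA", "GLY", "A", 2, 51.2, 1, 0, element = "C"),
             pdbLine(6, "C", "GLY", "A", 2, 52.5, 0, 0, element = "C"),
             pdbLine(7, "N", "GLY", "B", 1, 0, 0, 5, element = "N"),
             pdbLine(8, "CA", "GLY", "B", 1, 1.2, 1, 5, element = "C"),
             pdbLine(9, "C", "GLY", "B", 1, 2.47, 0, 5, element = "C"))
  s <- readComplexPDB(writePdbFixture(lines), "A", "B")
  sel3 <- extractInterface(s, 10.0)
  expect_equal(sel3$receptor, "A|1|")
})

test_that("adjacency pair matches the edge definitions", {
  s <- makeNative(4, 3, seed = 2)
  g <- buildInterfaceGraph(s)
  adj <- adjacencyPair(g, mu = 0, sigma = 1)
  n <- nodeCount(g)
  # A1: unit diagonal, symmetric, bonded pairs 1
  expect_equal(diag(adj$A1), rep(1, n))
  expect_equal(adj$A1, t(adj$A1))
  expect_true(all(adj$A1 %in% c(0, 1)))
  # A2 equals A1 on within-molecule entries (including diagonal)
  same <- outer(g@molecule, g@molecule, "==")
  expect_equal(adj$A2[same], adj$A1[same])
  # cross entries: exp(-(d - mu)^2 / sigma) for d <= 10, else 0
  cross <- which(is.finite(g@crossDist), arr.ind = TRUE)
  expect_gt(nrow(cross), 0)
  expect_equal(adj$A2[cross], exp(-g@crossDist[cross]^2))
  expect_true(all(adj$A2[!same & !is.finite(g@crossDist)] == 0))
})

test_that("Gaussian cross weights hit their closed-form values", {
  # two single-residue chains with CA pair at an exact distance
  mk <- function(gap) {
    lines <- c(pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
               pdbLine(2, "CA", "GLY", "A", 1, 1.2, 1, 0, element = "C"),
               pdbLine(3, "C", "GLY", "A", 1, 2.47, 0, 0, element = "C"),
               pdbLine(4, "N", "GLY", "B", 1, 0, 0, gap, element = "N"),
               pdbLine(5, "CA", "GLY", "B", 1, 1.2, 1, gap, element = "C"),
               pdbLine(6, "C", "GLY", "B", 1, 2.47, 0, gap, element = "C"))
    buildInterfaceGraph(readComplexPDB(writePdbFixture(lines), "A", "B"))
  }
  g <- mk(3.8)
  ca1 <- which(g@nodes$name == "CA" & g@molecule == "receptor")
  ca2 <- which(g@nodes$name == "CA" & g@molecule == "ligand")
  # at d = mu the weight is exactly 1 regardless of sigma
  adj <- adjacencyPair(g, mu = 3.8, sigma = 0.37)
  expect_equal(adj$A2[ca1, ca2], 1.0)
  # at d = 10, mu = 0, sigma = 1 the weight is e^-100
  g10 <- mk(10.0)
  adj10 <- adjacencyPair(g10, mu = 0, sigma = 1)
  d <- g10@crossDist[ca1, ca2]
  expect_equal(d, 10.0, tolerance = 1e-9)
  expect_equal(adj10$A2[ca1, ca2], exp(-100))
  # monotone decay for mu = 0: weight never increases with distance
  w38 <- adjacencyPair(mk(3.8), mu = 0, sigma = 1)$A2[ca1, ca2]
  w60 <- adjacencyPair(mk(6.0), mu = 0, sigma = 1)$A2[ca1, ca2]
  w95 <- adjacencyPair(mk(9.5), mu = 0, sigma = 1)$A2[ca1, ca2]
  expect_true(w38 > w60 && w60 > w95)
  # sigma <= 0 is clamped with a warning
  expect_warning(adjacencyPair(g, mu = 0, sigma = -1), "clamped")
})

test_that("adjacencies match a brute-force recomputation on a toy", {
  g <- buildInterfaceGraph(readComplexPDB(tinyComplexPDB(4.2), "A", "B"))
  n <- nodeCount(g)
  expect_lte(n, 12)
  mu <- 0.7; sigma <- 2.3
  adj <- adjacencyPair(g, mu, sigma)
  # direct O(N^2) reference from node coordinates and bond lists
  s <- readComplexPDB(tinyComplexPDB(4.2), "A", "B")
  at <- rbind(inferBonds(s, "receptor")$atoms, inferBonds(s, "ligand")$atoms)
  co <- as.matrix(at[, c("x", "y", "z")])
  ref2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d <- sqrt(sum((co[i, ] - co[j, ])^2))
    sameMol <- g@molecule[i] == g@molecule[j]
    ref2[i, j] <- if (sameMol) adj$A1[i, j]
                  else if (d <= 10) exp(-(d - mu)^2 / sigma) else 0
  }
  expect_equal(adj$A2, ref2, tolerance = 1e-9)
})

test_that("graphs are invariant under rigid motions of the complex", {
  s <- makeNative(5, 4, seed = 4)
  g0 <- buildInterfaceGraph(s)
  for (sd in 1:5) {
    g1 <- buildInterfaceGraph(applyRigid(s, randomRigidTransform(sd)))
    expect_identical(g1@A1, g0@A1)
    expect_identical(g1@features, g0@features)
    expect_equal(g1@crossDist, g0@crossDist, tolerance = 1e-9)
  }
})

test_that("graph serialization round-trips exactly", {
  g <- toyGraph()
  p <- tempfile(fileext = ".txt")
  serializeGraph(g, p)
  g2 <- readGraph(p)
  expect_identical(g2@features, g@features)
  expect_identical(g2@A1, g@A1)
  expect_equal(g2@crossDist, g@crossDist)
  expect_identical(g2@molecule, g@molecule)
  expect_identical(g2@nodes$name, g@nodes$name)
  # node order is preserved as written
  expect_identical(g2@nodes$resno, g@nodes$resno)
  # corrupt input is refused
  writeLines("not a graph", p)
  expect_error(readGraph(p), "not a graphdock graph")
})
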